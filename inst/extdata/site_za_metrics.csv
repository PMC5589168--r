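product,batch,site,metric,value
GONAL-f,199F005,alpha_Asn52,Z,211
GONAL-f,199F049,alpha_Asn52,Z,209
GONAL-f,199F051,alpha_Asn52,Z,210
Bemfola,PPS30403,alpha_Asn52,Z,216
Bemfola,PNS30226,alpha_Asn52,Z,217
GONAL-f,199F005,alpha_Asn52,A,225
GONAL-f,199F049,alpha_Asn52,A,224
GONAL-f,199F051,alpha_Asn52,A,222
Bemfola,PPS30403,alpha_Asn52,A,251
Bemfola,PNS30226,alpha_Asn52,A,253
GONAL-f,199F005,alpha_Asn78,Z,175
GONAL-f,199F049,alpha_Asn78,Z,174
GONAL-f,199F051,alpha_Asn78,Z,177
Bemfola,PPS30403,alpha_Asn78,Z,180
Bemfola,PNS30226,alpha_Asn78,Z,180
GONAL-f,199F005,alpha_Asn78,A,212
GONAL-f,199F049,alpha_Asn78,A,211
GONAL-f,199F051,alpha_Asn78,A,211
Bemfola,PPS30403,alpha_Asn78,A,232
Bemfola,PNS30226,alpha_Asn78,A,232
GONAL-f,199F005,beta_Asn7,Z,201
GONAL-f,199F049,beta_Asn7,Z,198
GONAL-f,199F051,beta_Asn7,Z,200
Bemfola,PPS30403,beta_Asn7,Z,246
Bemfola,PNS30226,beta_Asn7,Z,249
GONAL-f,199F005,beta_Asn7,A,367
GONAL-f,199F049,beta_Asn7,A,368
GONAL-f,199F051,beta_Asn7,A,367
Bemfola,PPS30403,beta_Asn7,A,418
Bemfola,PNS30226,beta_Asn7,A,423
GONAL-f,199F005,beta_Asn24,Z,172
GONAL-f,199F049,beta_Asn24,Z,172
GONAL-f,199F051,beta_Asn24,Z,174
Bemfola,PPS30403,beta_Asn24,Z,198
Bemfola,PNS30226,beta_Asn24,Z,197
GONAL-f,199F005,beta_Asn24,A,209
GONAL-f,199F049,beta_Asn24,A,208
GONAL-f,199F051,beta_Asn24,A,210
Bemfola,PPS30403,beta_Asn24,A,240
Bemfola,PNS30226,beta_Asn24,A,238
GONAL-f,199F005,release_simulation,Z,190
GONAL-f,199F049,release_simulation,Z,188
GONAL-f,199F051,release_simulation,Z,190
Bemfola,PPS30403,release_simulation,Z,210
Bemfola,PNS30226,release_simulation,Z,211
GONAL-f,199F005,release_simulation,A,253
GONAL-f,199F049,release_simulation,A,253
GONAL-f,199F051,release_simulation,A,253
Bemfola,PPS30403,release_simulation,A,285
Bemfola,PNS30226,release_simulation,A,287
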
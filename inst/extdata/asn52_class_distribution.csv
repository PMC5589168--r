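product,batch,block,class,percentage
GONAL-f,199F005,antennarity,bi,76.2
GONAL-f,199F005,antennarity,tri,22.9
GONAL-f,199F005,antennarity,tetra,0.9
GONAL-f,199F049,antennarity,bi,76.9
GONAL-f,199F049,antennarity,tri,22.6
GONAL-f,199F049,antennarity,tetra,0.5
GONAL-f,199F051,antennarity,bi,77.8
GONAL-f,199F051,antennarity,tri,22.2
GONAL-f,199F051,antennarity,tetra,0.0
Bemfola,PPS30403,antennarity,bi,53.9
Bemfola,PPS30403,antennarity,tri,40.7
Bemfola,PPS30403,antennarity,tetra,5.3
Bemfola,PNS30226,antennarity,bi,52.7
Bemfola,PNS30226,antennarity,tri,41.8
Bemfola,PNS30226,antennarity,tetra,5.5
GONAL-f,199F005,fucosylation,afucosylated,97.8
GONAL-f,199F005,fucosylation,fucosylated,2.2
GONAL-f,199F049,fucosylation,afucosylated,97.8
GONAL-f,199F049,fucosylation,fucosylated,2.2
GONAL-f,199F051,fucosylation,afucosylated,97.6
GONAL-f,199F051,fucosylation,fucosylated,2.4
Bemfola,PPS30403,fucosylation,afucosylated,98.8
Bemfola,PPS30403,fucosylation,fucosylated,1.2
Bemfola,PNS30226,fucosylation,afucosylated,98.7
Bemfola,PNS30226,fucosylation,fucosylated,1.3
GONAL-f,199F005,sialylation,mono,2.6
GONAL-f,199F005,sialylation,di,84.0
GONAL-f,199F005,sialylation,tri,13.4
GONAL-f,199F005,sialylation,tetra,0.0
GONAL-f,199F049,sialylation,mono,2.7
GONAL-f,199F049,sialylation,di,85.5
GONAL-f,199F049,sialylation,tri,11.8
GONAL-f,199F049,sialylation,tetra,0.0
GONAL-f,199F051,sialylation,mono,2.4
GONAL-f,199F051,sialylation,di,85.7
GONAL-f,199F051,sialylation,tri,11.9
GONAL-f,199F051,sialylation,tetra,0.0
Bemfola,PPS30403,sialylation,mono,6.2
Bemfola,PPS30403,sialylation,di,72.8
Bemfola,PPS30403,sialylation,tri,21.0
Bemfola,PPS30403,sialylation,tetra,0.8
Bemfola,PNS30226,sialylation,mono,6.8
Bemfola,PNS30226,sialylation,di,71.8
Bemfola,PNS30226,sialylation,tri,21.4
Bemfola,PNS30226,sialylation,tetra,1.0
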
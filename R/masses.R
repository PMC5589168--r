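#' Monosaccharide residue mass table
#'
#' Residue masses (Da) of the four monosaccharide building blocks of complex
#' N-glycans, as residues (i.e. after loss of water on glycosidic bond
#' formation), plus the masses of water and the proton. Monoisotopic values
#' are the default and are appropriate for Q-TOF data; average masses are
#' available for low-resolution work.
#'
#' @param type `"monoisotopic"` (default) or `"average"`.
#' @return A named list with elements `HexNAc`, `Hex`, `dHex`, `NeuAc`,
#'   `water` and `proton`, all positive numerics.
#' @examples
#' monosaccharide_masses()$HexNAc
#' @export
monosaccharide_masses <- function(type = c("monoisotopic", "average")) {
  type <- match.arg(type)
  if (type == "monoisotopic") {
    list(
      HexNAc = 203.079373,
      Hex    = 162.052824,
      dHex   = 146.057909,
      NeuAc  = 291.095417,
      water  = 18.0105646,
      proton = 1.007276467
    )
  } else {
    list(
      HexNAc = 203.1925,
      Hex    = 162.1406,
      dHex   = 146.1412,
      NeuAc  = 291.2546,
      water  = 18.01528,
      proton = 1.00739
    )
  }
}

# Monoisotopic residue masses of the 20 standard amino acids (Da).
.aa_residue_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Carbamidomethylation of cysteine (iodoacetamide alkylation), the fixed
# modification of the reduction/alkylation sample preparation.
.carbamidomethyl_mass <- 57.02146

#' Monoisotopic peptide backbone mass
#'
#' Sum of residue masses plus one water, with optional fixed
#' carbamidomethylation of every cysteine (the standard consequence of
#' iodoacetamide alkylation during sample preparation).
#'
#' @param sequence Amino-acid sequence (one-letter codes, standard residues).
#' @param carbamidomethyl Apply +57.02146 Da per cysteine? Default `TRUE`.
#' @return Peptide monoisotopic mass in Da.
#' @examples
#' peptide_mass("PEPTIDE")
#' @export
peptide_mass <- function(sequence, carbamidomethyl = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% names(.aa_residue_masses))
  if (length(bad)) {
    stop("unknown residue '", aa[bad[1]], "' at position ", bad[1],
         " in sequence", call. = FALSE)
  }
  m <- sum(.aa_residue_masses[aa]) + monosaccharide_masses()$water
  if (carbamidomethyl) m <- m + .carbamidomethyl_mass * sum(aa == "C")
  unname(m)
}

# Round half away from zero. base::round() rounds half to even, which does not
# reproduce the published metric tables (e.g. 209.5 -> 210, 252.5 -> 253,
# 286.5 -> 287 must all round up).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
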
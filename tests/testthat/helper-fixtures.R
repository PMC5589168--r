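# Shared helpers: independent oracles and fixture builders.

# Elemental-composition oracle for glycan residue masses, independent of the
# package's monosaccharide table: residue formulas x monoisotopic atom masses.
oracle_glycan_mass <- function(hexnac, hex, dhex, neuac) {
  atoms <- c(C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221)
  formula <- function(C, H, N, O)
    C * atoms["C"] + H * atoms["H"] + N * atoms["N"] + O * atoms["O"]
  unname(
    hexnac * formula(8, 13, 1, 5) +   # HexNAc residue C8H13NO5
    hex    * formula(6, 10, 0, 5) +   # Hex residue C6H10O5
    dhex   * formula(6, 10, 0, 4) +   # dHex residue C6H10O4
    neuac  * formula(11, 17, 1, 8)    # NeuAc residue C11H17NO8
  )
}

# Brute-force digestion oracle: enumerate all subsets of cleavage sites with
# at most `missed` skipped sites between retained cuts.
oracle_digest <- function(sequence, missed) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  cuts <- which(aa %in% c("F", "Y", "W", "L", "M"))
  cuts <- cuts[cuts < n & aa[cuts + 1] != "P"]
  bounds <- c(0, cuts, n)
  peps <- character()
  for (i in seq_len(length(bounds) - 1)) {
    for (j in i:min(length(bounds) - 1, i + missed)) {
      peps <- c(peps, paste(aa[(bounds[i] + 1):bounds[j + 1]], collapse = ""))
    }
  }
  sort(unique(peps))
}

# Random valid glycan composition under a fixed RNG stream.
random_composition <- function() {
  a <- sample(1:4, 1)
  lac <- sample(0:2, 1)
  g <- sample(0:a, 1)
  s <- sample(0:(g + lac), 1)
  glycan_composition(core_fucose = sample(0:1, 1), antennae = a,
                     galactoses = g, sialic_acids = s, lac_repeats = lac)
}

# Class summaries for the published Asn52 table, one per batch.
asn52_class_summaries <- function() {
  tab <- reference_table("asn52_classes")
  lapply(split(tab, tab$batch), function(d) {
    pick <- function(block) {
      b <- d[d$block == block, ]
      stats::setNames(b$percentage, b$class)
    }
    class_summary("alpha_Asn52",
                  antennarity = pick("antennarity"),
                  fucosylation = pick("fucosylation"),
                  sialylation = pick("sialylation"))
  })
}

# A small two-site simulation target used across MS tests.
demo_targets <- function() {
  list(
    alpha_Asn52 = c(A2G2S1 = 10, A2G2S2 = 60, FA2G2S2 = 2, A3G3S1 = 5,
                    A3G3S2 = 10, A3G3S3 = 8, A4G4S2 = 3, A4G4S3 = 2),
    beta_Asn24 = c(FA2G2S1 = 20, FA2G2S2 = 50, A2G2S2 = 10, FA3G3S2 = 12,
                   FA3G3S3 = 8)
  )
}
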
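#' Mature human FSH subunit sequences
#'
#' One-letter sequences of the mature alpha (92 aa, common glycoprotein
#' hormone subunit) and beta (111 aa, FSH-specific) chains. The alpha chain
#' carries N-glycosylation sequons at Asn52 and Asn78, the beta chain at
#' Asn7 and Asn24.
#'
#' @return Named character vector with elements `alpha` and `beta`.
#' @export
fsh_subunit_sequences <- function() {
  c(
    alpha = "APDVQDCPECTLQENPFFSQPGAPILQCMGCCFSRAYPTPLRSKKTMLVQKNVTSESTCCVAKSYNRVTVMGGFKVENHTACHCSTCYYHKS",
    beta  = "NSCELTNITIAIEKEECRFCISINTTWCAGYCYTRDLVYKDPARPKIQKTCTFKELVYETVRVPGCAHHADSLYTYPVATQCHCGKCDSDSTDCTVRGLGPSYCSFGEMKE"
  )
}

# canonical glycosite positions within the mature subunits
.fsh_sites <- data.frame(
  site_id = c("alpha_Asn52", "alpha_Asn78", "beta_Asn7", "beta_Asn24"),
  subunit = c("alpha", "alpha", "beta", "beta"),
  position = c(52L, 78L, 7L, 24L)
)

#' Chymotryptic glycosite peptides of FSH
#'
#' Digests both subunits in silico and, for each of the four glycosites,
#' returns the peptide with the fewest missed cleavages that covers the
#' sequon and carries no second sequon (so that site-specific quantitation
#' is unambiguous).
#'
#' @param missed_cleavages Maximum missed cleavages considered (default 2).
#' @return Named list of [site_peptide()] objects
#'   (`alpha_Asn52`, `alpha_Asn78`, `beta_Asn7`, `beta_Asn24`).
#' @export
fsh_site_peptides <- function(missed_cleavages = 2L) {
  seqs <- fsh_subunit_sequences()
  out <- list()
  for (i in seq_len(nrow(.fsh_sites))) {
    sid <- .fsh_sites$site_id[i]
    sub <- .fsh_sites$subunit[i]
    pos <- .fsh_sites$position[i]
    dig <- chymotryptic_digest(seqs[[sub]], missed_cleavages)
    cover <- dig[dig$start <= pos & dig$end >= pos, , drop = FALSE]
    cover <- cover[order(cover$missed, cover$end - cover$start), , drop = FALSE]
    chosen <- NULL
    for (j in seq_len(nrow(cover))) {
      pep <- cover$peptide[j]
      local_pos <- pos - cover$start[j] + 1L
      sequons <- find_sequons(pep)
      # the sequon can straddle the C-terminal cut; require it intact
      if (identical(sequons, local_pos)) {
        chosen <- site_peptide(sid, pep, local_pos)
        break
      }
    }
    if (is.null(chosen))
      stop("no unambiguous chymotryptic peptide covers ", sid, call. = FALSE)
    out[[sid]] <- chosen
  }
  out
}

#' Bundled comparability reference tables
#'
#' Small CSV fixtures transcribing published comparability measurements for
#' Bemfola and GONAL-f batches, so that the metric layer can be exercised
#' offline:
#'
#' * `"batches"` — nominal content per batch (IU, micrograms) and which assay
#'   each batch entered.
#' * `"asn52_classes"` — antennarity / fucosylation / sialylation class
#'   percentages at the alpha-chain Asn52 site, per batch.
#' * `"site_za"` — published per-site Z-number and A-index values, including
#'   the whole-molecule glycan-release-simulation averages.
#'
#' @param which One of `"batches"`, `"asn52_classes"`, `"site_za"`.
#' @return A data frame.
#' @examples
#' head(reference_table("asn52_classes"))
#' @export
reference_table <- function(which = c("batches", "asn52_classes", "site_za")) {
  which <- match.arg(which)
  file <- switch(which,
    batches = "batch_nominal_content.csv",
    asn52_classes = "asn52_class_distribution.csv",
    site_za = "site_za_metrics.csv"
  )
  path <- system.file("extdata", file, package = "glycopotency")
  if (path == "") stop("fixture ", file, " not installed", call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' A realistic glycan panel per FSH glycosite
#'
#' Species lists reflecting the published qualitative picture: Asn52 and
#' Asn78 dominated by bi-antennary di-sialylated structures, Asn7 by bulky
#' tri/tetra-antennary species with lac repeats, Asn24 bi-antennary and
#' largely core-fucosylated. Used as simulation defaults; any species set
#' can be supplied instead.
#'
#' @return Named list (by site id) of character vectors of glycan names.
#' @export
default_glycan_panel <- function() {
  list(
    alpha_Asn52 = c("A2G2S1", "A2G2S2", "FA2G2S2", "A3G3S1", "A3G3S2",
                    "A3G3S3", "A4G4S2", "A4G4S3"),
    alpha_Asn78 = c("A2G2S1", "A2G2S2", "FA2G2S2", "A3G3S2", "A3G3S3",
                    "A4G4S3"),
    beta_Asn7   = c("A2G2S2", "A3G3S2", "A3G3S3", "FA3G3S3", "A4G4S3",
                    "A4G4S4", "FA4G4S3Lac1", "A4G4S4Lac1", "A4G4S4Lac2"),
    beta_Asn24  = c("FA2G2S1", "FA2G2S2", "A2G2S2", "FA3G3S2", "FA3G3S3",
                    "FA4G4S3")
  )
}
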
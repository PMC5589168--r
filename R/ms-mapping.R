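#' In-silico chymotryptic digestion
#'
#' Cleaves C-terminal to the chymotryptic specificity residues F, Y, W, L, M,
#' except when the next residue is proline, and enumerates all peptides with
#' up to `missed_cleavages` internal missed sites.
#'
#' @param sequence Protein sequence (one-letter codes).
#' @param missed_cleavages Maximum number of missed cleavage sites, `>= 0`.
#' @return Data frame with columns `peptide`, `start`, `end` (1-based,
#'   inclusive) and `missed` (number of internal missed sites).
#' @examples
#' chymotryptic_digest("AYLFK")$peptide
#' @export
chymotryptic_digest <- function(sequence, missed_cleavages = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% names(.aa_residue_masses))
  if (length(bad)) {
    stop("unknown residue '", aa[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  }
  n <- length(aa)
  # cut after position i when aa[i] is a specificity residue and aa[i+1] != P
  cuts <- which(aa %in% c("F", "Y", "W", "L", "M"))
  cuts <- cuts[cuts < n & aa[pmin(cuts + 1L, n)] != "P"]
  bounds <- c(0L, cuts, n)                      # fragment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  k <- length(starts)
  out <- list()
  for (i in seq_len(k)) {
    for (j in i:min(k, i + missed_cleavages)) {
      out[[length(out) + 1L]] <- data.frame(
        peptide = paste(aa[starts[i]:ends[j]], collapse = ""),
        start = starts[i], end = ends[j], missed = j - i
      )
    }
  }
  do.call(rbind, out)
}

#' Glycosite-bearing peptide
#'
#' A peptide backbone carrying exactly one N-glycosylation sequon
#' (N-X-S/T, X != P) at a stated glycosite. The backbone mass includes the
#' fixed carbamidomethylation of cysteines.
#'
#' @param site_id One of `"alpha_Asn52"`, `"alpha_Asn78"`, `"beta_Asn7"`,
#'   `"beta_Asn24"` (other labels are allowed for non-FSH work).
#' @param sequence Peptide sequence.
#' @param glycosite_position 1-based index of the sequon asparagine within
#'   `sequence`. If `NULL`, located automatically (errors unless the peptide
#'   has exactly one sequon).
#' @return Object of class `site_peptide` with fields `site_id`, `sequence`,
#'   `backbone_mass`, `glycosite_position`.
#' @export
site_peptide <- function(site_id, sequence, glycosite_position = NULL) {
  stopifnot(is.character(site_id), length(site_id) == 1L)
  sequence <- toupper(sequence)
  sequons <- find_sequons(sequence)
  if (is.null(glycosite_position)) {
    if (length(sequons) != 1L)
      stop("peptide for ", site_id, " has ", length(sequons),
           " N-glycosylation sequons; expected exactly one", call. = FALSE)
    glycosite_position <- sequons
  } else if (!glycosite_position %in% sequons) {
    stop("position ", glycosite_position, " of '", sequence,
         "' is not an N-glycosylation sequon", call. = FALSE)
  }
  structure(
    list(site_id = site_id, sequence = sequence,
         backbone_mass = peptide_mass(sequence),
         glycosite_position = as.integer(glycosite_position)),
    class = "site_peptide"
  )
}

#' Locate N-glycosylation sequons (N-X-S/T, X != P)
#'
#' @param sequence Protein or peptide sequence.
#' @return Integer vector of 1-based asparagine positions.
#' @export
find_sequons <- function(sequence) {
  m <- gregexpr("N(?=[^P][ST])", toupper(sequence), perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

#' @export
print.site_peptide <- function(x, ...) {
  cat(sprintf("<site_peptide> %s: %s (N at %d, backbone %.4f Da)\n",
              x$site_id, x$sequence, x$glycosite_position, x$backbone_mass))
  invisible(x)
}

#' Peak list container
#'
#' Centroided peak lists as a long data frame: one row per (scan, peak).
#' Retention times must be non-decreasing in scan order and m/z values must
#' lie inside the configured scan range.
#'
#' @param rt_min Retention time per row, minutes.
#' @param mz m/z per row.
#' @param intensity Non-negative intensity per row.
#' @param scan_range Instrument scan range (m/z); rows outside are rejected.
#' @return Object of class `peak_list` (a data frame with columns
#'   `rt_min`, `mz`, `intensity`).
#' @export
peak_list <- function(rt_min, mz, intensity, scan_range = c(100, 2000)) {
  df <- data.frame(rt_min = as.numeric(rt_min), mz = as.numeric(mz),
                   intensity = as.numeric(intensity))
  if (any(df$intensity < 0)) stop("negative intensity", call. = FALSE)
  if (nrow(df) && (any(df$mz < scan_range[1]) || any(df$mz > scan_range[2])))
    stop("m/z outside scan range [", scan_range[1], ", ", scan_range[2], "]",
         call. = FALSE)
  df <- df[order(df$rt_min, df$mz), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("peak_list", "data.frame"),
            scan_range = scan_range)
}

#' Read a peak-list CSV (columns rt_min, mz, intensity)
#'
#' @param file CSV path.
#' @param scan_range Instrument scan range.
#' @return A [peak_list()].
#' @export
read_peak_list <- function(file, scan_range = c(100, 2000)) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("rt_min", "mz", "intensity")
  if (!all(need %in% names(df)))
    stop("peak-list CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  peak_list(df$rt_min, df$mz, df$intensity, scan_range = scan_range)
}

#' Theoretical glycopeptide m/z
#'
#' `(backbone + glycan residue mass + z * proton) / z`.
#'
#' @param peptide A `site_peptide` (or a bare backbone mass in Da).
#' @param glycan A `glycan_composition`, glycan name, or residue mass in Da.
#' @param charge Positive integer charge.
#' @param table Mass table.
#' @return m/z in Da/e.
#' @examples
#' theoretical_mz(1000, "A2G2S2", 2)
#' @export
theoretical_mz <- function(peptide, glycan, charge,
                           table = monosaccharide_masses()) {
  if (any(charge <= 0)) stop("charge must be positive", call. = FALSE)
  backbone <- if (inherits(peptide, "site_peptide")) peptide$backbone_mass
              else as.numeric(peptide)
  gmass <- if (is.numeric(glycan)) glycan else glycan_residue_mass(glycan, table)
  (backbone + gmass + charge * table$proton) / charge
}

#' Build candidate glycopeptide ions
#'
#' Expands (site peptide x glycan x charge) into a candidate table, dropping
#' charge states whose m/z falls outside the scan range (a Q-TOF acquiring
#' 100-2000 m/z cannot observe them).
#'
#' @param peptides List of `site_peptide` objects.
#' @param glycans Character vector of glycan names (or list of compositions).
#' @param charges Integer charges to consider, default `1:4`.
#' @param scan_range m/z range retained.
#' @return Data frame with columns `site_id`, `peptide`, `glycan`, `charge`,
#'   `theoretical_mz`.
#' @export
candidate_ions <- function(peptides, glycans, charges = 1:4,
                           scan_range = c(100, 2000)) {
  if (inherits(peptides, "site_peptide")) peptides <- list(peptides)
  rows <- list()
  for (pep in peptides) {
    for (gl in glycans) {
      comp <- if (is.character(gl)) parse_glycan_name(gl, quiet = TRUE) else gl
      for (z in charges) {
        mz <- theoretical_mz(pep, comp, z)
        if (mz < scan_range[1] || mz > scan_range[2]) next
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = pep$site_id, peptide = pep$sequence,
          glycan = comp$canonical_name, charge = as.integer(z),
          theoretical_mz = mz
        )
      }
    }
  }
  if (!length(rows))
    return(data.frame(site_id = character(), peptide = character(),
                      glycan = character(), charge = integer(),
                      theoretical_mz = numeric()))
  do.call(rbind, rows)
}

#' Match observed peaks to candidate glycopeptide ions
#'
#' Every peak within `tolerance_ppm` of at least one candidate is assigned
#' to the nearest candidate in ppm (ties broken toward the lower theoretical
#' m/z, with a message). Ion counts are the XIC sums over the retention-time
#' window. Candidates with no matching peak are reported with
#' `ion_count = 0` and `NA` observed m/z.
#'
#' @param peaklist A [peak_list()].
#' @param candidates Candidate table from [candidate_ions()].
#' @param tolerance_ppm Match tolerance in ppm, `> 0`. Default 10.
#' @param rt_window Retention-time window (minutes, length-2) over which ion
#'   counts are integrated; default the full run.
#' @return Data frame of assignments: candidate columns plus `observed_mz`,
#'   `ppm_error`, `ion_count`.
#' @export
match_ions <- function(peaklist, candidates, tolerance_ppm = 10,
                       rt_window = NULL) {
  stopifnot(tolerance_ppm > 0)
  if (nrow(peaklist) == 0L)
    warning("empty peak list: all candidates reported absent")
  if (is.null(rt_window)) {
    rt_window <- if (nrow(peaklist)) range(peaklist$rt_min) else c(0, 0)
  }
  cand <- candidates[order(candidates$theoretical_mz), , drop = FALSE]
  in_rt <- peaklist$rt_min >= rt_window[1] & peaklist$rt_min <= rt_window[2]
  pk <- peaklist[in_rt, , drop = FALSE]

  # nearest candidate in ppm for each peak (candidates sorted by m/z; ties in
  # ppm distance go to the lower theoretical m/z, i.e. the earlier row)
  assign_idx <- rep(NA_integer_, nrow(pk))
  if (nrow(pk) && nrow(cand)) {
    for (i in seq_len(nrow(pk))) {
      ppm <- 1e6 * (pk$mz[i] - cand$theoretical_mz) / cand$theoretical_mz
      j <- which.min(abs(ppm))        # first minimum = lower theoretical m/z
      if (sum(abs(abs(ppm) - abs(ppm[j])) < 1e-12) > 1L)
        message("ppm tie at peak m/z ", format(pk$mz[i]),
                ": assigned to lower theoretical m/z")
      if (abs(ppm[j]) <= tolerance_ppm) assign_idx[i] <- j
    }
  }

  cand$observed_mz <- NA_real_
  cand$ppm_error <- NA_real_
  cand$ion_count <- 0
  for (j in seq_len(nrow(cand))) {
    hits <- which(assign_idx == j)
    if (!length(hits)) next
    w <- pk$intensity[hits]
    cand$ion_count[j] <- sum(w)
    # intensity-weighted observed m/z (apex-free centroid of the XIC)
    obs <- if (sum(w) > 0) sum(pk$mz[hits] * w) / sum(w) else mean(pk$mz[hits])
    cand$observed_mz[j] <- obs
    cand$ppm_error[j] <- 1e6 * (obs - cand$theoretical_mz[j]) /
      cand$theoretical_mz[j]
  }
  rownames(cand) <- NULL
  cand
}

#' Extracted ion chromatogram ion count
#'
#' Sum of intensities of all peaks within `tolerance_ppm` of `mz` over scans
#' whose retention time lies in `rt_window`.
#'
#' @param peaklist A [peak_list()].
#' @param mz Target m/z.
#' @param tolerance_ppm Half-window in ppm.
#' @param rt_window Length-2 retention-time window (minutes); default full run.
#' @return Summed ion count (0 if nothing falls in the window).
#' @export
extract_xic <- function(peaklist, mz, tolerance_ppm = 10, rt_window = NULL) {
  if (is.null(rt_window)) {
    rt_window <- if (nrow(peaklist)) range(peaklist$rt_min) else c(0, 0)
  }
  stopifnot(length(rt_window) == 2L, rt_window[1] <= rt_window[2])
  sel <- peaklist$rt_min >= rt_window[1] & peaklist$rt_min <= rt_window[2] &
    abs(peaklist$mz - mz) <= mz * tolerance_ppm * 1e-6
  sum(peaklist$intensity[sel])
}

#' Per-site relative glycan distribution from assignments
#'
#' Pools ion counts of the same (peptide, glycan) across charge states, then
#' normalizes within the site to percentages. Pooling across different
#' backbone peptides (missed-cleavage variants) is off by default: relative
#' quantitation by ion count is only ionization-bias-free within one peptide
#' backbone, so mixed backbones trigger an error unless
#' `pool_backbones = TRUE` is given explicitly.
#'
#' @param assignments Assignment table from [match_ions()].
#' @param site_id Site to quantify.
#' @param pool_backbones Allow pooling over different backbone peptides.
#' @return A `glycan_distribution`: data frame (`species`, `percentage`) with
#'   attribute `site_id`; percentages sum to 100.
#' @export
quantify_site <- function(assignments, site_id, pool_backbones = FALSE) {
  a <- assignments[assignments$site_id == site_id, , drop = FALSE]
  if (!nrow(a)) stop("no assignments for site ", site_id, call. = FALSE)
  if (!pool_backbones && length(unique(a$peptide)) > 1L)
    stop("site ", site_id, " has assignments on multiple backbone peptides; ",
         "set pool_backbones = TRUE to pool them", call. = FALSE)
  counts <- tapply(a$ion_count, a$glycan, sum)
  total <- sum(counts)
  if (total <= 0)
    stop("no quantifiable species at site ", site_id, call. = FALSE)
  glycan_distribution(site_id, names(counts), 100 * as.numeric(counts) / total)
}

#' Glycan distribution container
#'
#' @param site_id Site label.
#' @param species Character vector of glycan names.
#' @param percentage Percentages, `>= 0`, summing to 100 (checked to 0.5
#'   after one-decimal rounding to admit published rounded tables).
#' @return Object of class `glycan_distribution`.
#' @export
glycan_distribution <- function(site_id, species, percentage) {
  stopifnot(length(species) == length(percentage), all(percentage >= 0))
  s <- sum(round(percentage, 1))
  if (abs(s - 100) > 0.5)
    stop("percentages for ", site_id, " sum to ", s, ", not 100", call. = FALSE)
  df <- data.frame(species = as.character(species),
                   percentage = as.numeric(percentage))
  structure(df, class = c("glycan_distribution", "data.frame"),
            site_id = site_id)
}

#' @export
print.glycan_distribution <- function(x, ...) {
  cat("<glycan_distribution> site", attr(x, "site_id"), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write an assignment report CSV
#'
#' Columns mirror the standard identity-assignment report: site, peptide,
#' glycan, charge, theoretical m/z, observed m/z, ppm error, XIC ion count.
#' A header comment records the matching assumptions (ppm tolerance and
#' charge states are method choices, not instrument facts).
#'
#' @param assignments Assignment table from [match_ions()].
#' @param file Output path.
#' @param tolerance_ppm,charges Assumptions recorded in the header.
#' @export
write_assignment_report <- function(assignments, file, tolerance_ppm = 10,
                                    charges = 1:4) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# assumptions: match tolerance %g ppm; charge states %s (not stated by the acquisition method)",
    tolerance_ppm, paste(charges, collapse = ",")), con)
  utils::write.csv(assignments, con, row.names = FALSE)
  invisible(assignments)
}
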
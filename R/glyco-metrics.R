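#' Z-number: hypothetical charge number
#'
#' The percentage-weighted sialic-acid count of a glycan population,
#' `Z = round(sum_i p_i * s_i)` with `p_i` in percent and `s_i` the number of
#' sialic acids of species (or sialylation class) `i`. On a population
#' summing to 100% the Z-number lives on a 0-400 scale; rounding is half
#' away from zero, which is what reproduces the published tables.
#'
#' Methods exist for species-level distributions ([glycan_distribution()])
#' and for class summaries ([class_summary()]). When full species data are
#' available the species-level value is canonical; class-based values can
#' differ by 1-2 units because the class percentages are themselves rounded.
#'
#' @param x A `glycan_distribution` or `class_summary`.
#' @param ... Unused.
#' @return Integer Z-number.
#' @examples
#' z_number(class_summary("alpha_Asn52",
#'   sialylation = c(mono = 2.6, di = 84.0, tri = 13.4, tetra = 0.0)))
#' @export
z_number <- function(x, ...) UseMethod("z_number")

#' @export
z_number.glycan_distribution <- function(x, ...) {
  comps <- .parse_species(x$species)
  s <- vapply(comps, function(c) c$sialic_acids, integer(1))
  as.integer(round_half_up(sum(x$percentage * s)))
}

#' @export
z_number.class_summary <- function(x, ...) {
  if (is.null(x$sialylation))
    stop("class summary has no sialylation block", call. = FALSE)
  w <- .class_weights(names(x$sialylation), "sialylation")
  as.integer(round_half_up(sum(x$sialylation * w)))
}

#' A-index: hypothetical antennarity index
#'
#' The percentage-weighted antenna count, `A = round(sum_i p_i * a_i)` with
#' weights bi = 2, tri = 3, tetra = 4 (mono = 1). Lac repeats extend an
#' antenna and contribute 0 to the antenna count. Same rounding and scale
#' conventions as [z_number()].
#'
#' @inheritParams z_number
#' @return Integer A-index.
#' @export
a_index <- function(x, ...) UseMethod("a_index")

#' @export
a_index.glycan_distribution <- function(x, ...) {
  comps <- .parse_species(x$species)
  a <- vapply(comps, function(c) c$antennae, integer(1))
  as.integer(round_half_up(sum(x$percentage * a)))
}

#' @export
a_index.class_summary <- function(x, ...) {
  if (is.null(x$antennarity))
    stop("class summary has no antennarity block", call. = FALSE)
  w <- .class_weights(names(x$antennarity), "antennarity")
  as.integer(round_half_up(sum(x$antennarity * w)))
}

.parse_species <- function(names_) {
  comps <- lapply(names_, function(nm) {
    tryCatch(parse_glycan_name(nm, quiet = TRUE), error = function(e) NULL)
  })
  bad <- names_[vapply(comps, is.null, logical(1))]
  if (length(bad))
    stop("unparsable species: ", paste(bad, collapse = ", "), call. = FALSE)
  comps
}

.class_weights <- function(classes, block) {
  table <- switch(block,
    sialylation = c(non = 0, mono = 1, di = 2, tri = 3, tetra = 4),
    antennarity = c(mono = 1, bi = 2, tri = 3, tetra = 4)
  )
  unknown <- setdiff(classes, names(table))
  if (length(unknown))
    stop("unknown ", block, " class: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  table[classes]
}

#' Class summary container
#'
#' Per-site percentages aggregated into antennarity (bi/tri/tetra),
#' fucosylation (afucosylated/fucosylated) and sialylation
#' (non/mono/di/tri/tetra) blocks. Each supplied block must total 100
#' within 0.5 after one-decimal rounding.
#'
#' @param site_id Site label.
#' @param antennarity,fucosylation,sialylation Named numeric percentage
#'   vectors (any may be omitted).
#' @return Object of class `class_summary`.
#' @export
class_summary <- function(site_id, antennarity = NULL, fucosylation = NULL,
                          sialylation = NULL) {
  blocks <- list(antennarity = antennarity, fucosylation = fucosylation,
                 sialylation = sialylation)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (is.null(b)) next
    if (any(b < 0)) stop(nm, " percentages must be >= 0", call. = FALSE)
    s <- sum(round(b, 1))
    # published class tables rounded to one decimal can total up to 101.0
    if (abs(s - 100) > 1.0)
      stop(nm, " block sums to ", s, ", not 100", call. = FALSE)
  }
  structure(c(list(site_id = site_id), blocks), class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat("<class_summary> site", x$site_id, "\n")
  for (nm in c("antennarity", "fucosylation", "sialylation")) {
    if (is.null(x[[nm]])) next
    cat(" ", nm, ": ",
        paste(sprintf("%s %.1f", names(x[[nm]]), x[[nm]]), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Aggregate a species distribution into class percentages
#'
#' Sums species percentages by antenna count (bi/tri/tetra, plus mono when
#' present), by core fucosylation, and by sialic-acid count (non through
#' tetra). Classes with zero total are kept only when they are part of the
#' standard reporting layout (bi/tri/tetra; afucosylated/fucosylated;
#' mono-tetra), so tables remain comparable across batches.
#'
#' @param dist A [glycan_distribution()].
#' @return A [class_summary()].
#' @export
classify_distribution <- function(dist) {
  comps <- .parse_species(dist$species)
  a <- vapply(comps, function(c) c$antennae, integer(1))
  f <- vapply(comps, function(c) c$core_fucose, integer(1))
  s <- vapply(comps, function(c) c$sialic_acids, integer(1))
  p <- dist$percentage

  ant_names <- c("mono", "bi", "tri", "tetra")
  ant <- vapply(1:4, function(k) sum(p[a == k]), numeric(1))
  names(ant) <- ant_names
  if (ant[["mono"]] == 0) ant <- ant[c("bi", "tri", "tetra")]

  fuc <- c(afucosylated = sum(p[f == 0]), fucosylated = sum(p[f == 1]))

  sia_names <- c("non", "mono", "di", "tri", "tetra")
  sia <- vapply(0:4, function(k) sum(p[s == k]), numeric(1))
  names(sia) <- sia_names
  if (sia[["non"]] == 0) sia <- sia[c("mono", "di", "tri", "tetra")]

  class_summary(attr(dist, "site_id"), antennarity = ant,
                fucosylation = fuc, sialylation = sia)
}

#' Whole-molecule glycan-release simulation
#'
#' Averages the four site-specific Z-numbers and A-indices into the values a
#' released-glycan (whole molecule) analysis would see: the arithmetic mean
#' over `alpha_Asn52`, `alpha_Asn78`, `beta_Asn7`, `beta_Asn24`, rounded
#' half away from zero.
#'
#' @param metrics Data frame with columns `site`, `Z`, `A` (one row per
#'   site), or a named list of such per-site values.
#' @return List with integer `z_number` and `a_index`.
#' @examples
#' release_simulation(data.frame(
#'   site = c("alpha_Asn52", "alpha_Asn78", "beta_Asn7", "beta_Asn24"),
#'   Z = c(211, 175, 201, 172), A = c(225, 212, 367, 209)))
#' @export
release_simulation <- function(metrics) {
  required <- .fsh_sites$site_id
  if (is.list(metrics) && !is.data.frame(metrics)) {
    metrics <- data.frame(
      site = names(metrics),
      Z = vapply(metrics, function(m) m[["Z"]], numeric(1)),
      A = vapply(metrics, function(m) m[["A"]], numeric(1))
    )
  }
  missing <- setdiff(required, metrics$site)
  if (length(missing))
    stop("missing site(s): ", paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(metrics$site, required)
  if (length(extra))
    stop("unexpected site(s): ", paste(extra, collapse = ", "), call. = FALSE)
  list(
    z_number = as.integer(round_half_up(mean(metrics$Z))),
    a_index  = as.integer(round_half_up(mean(metrics$A)))
  )
}

#' Pharmacopoeial Z-number expectation check
#'
#' Compares a whole-molecule Z-number against the compendial expectation
#' ranges for r-hFSH released-glycan analysis: 177-233 for 2AB fluorescence
#' detection, 178-274 for pulsed amperometric detection. Bounds inclusive.
#'
#' @param z Z-number (integer scale).
#' @param mode `"2AB"` or `"PAD"`.
#' @return List with `in_range` (logical), `range` and `mode`.
#' @export
pharmacopoeia_flag <- function(z, mode = c("2AB", "PAD")) {
  mode <- match.arg(mode)
  range <- switch(mode, `2AB` = c(177L, 233L), PAD = c(178L, 274L))
  list(in_range = z >= range[1] && z <= range[2], range = range, mode = mode)
}

#' Write a per-site metrics report CSV
#'
#' Long-format report mirroring the published layout: one row per
#' (batch, site, metric), with the release-simulation averages appended per
#' batch when all four sites are present.
#'
#' @param metrics Data frame with columns `batch`, `site`, `Z`, `A`.
#' @param file Output path.
#' @return The report data frame, invisibly.
#' @export
write_metrics_report <- function(metrics, file) {
  rows <- list()
  for (b in unique(metrics$batch)) {
    mb <- metrics[metrics$batch == b, , drop = FALSE]
    for (i in seq_len(nrow(mb))) {
      rows[[length(rows) + 1L]] <- data.frame(
        batch = b, site = mb$site[i],
        metric = c("Z", "A"), value = c(mb$Z[i], mb$A[i]))
    }
    if (setequal(mb$site, .fsh_sites$site_id)) {
      rel <- release_simulation(mb[, c("site", "Z", "A")])
      rows[[length(rows) + 1L]] <- data.frame(
        batch = b, site = "release_simulation",
        metric = c("Z", "A"), value = c(rel$z_number, rel$a_index))
    }
  }
  report <- do.call(rbind, rows)
  utils::write.csv(report, file, row.names = FALSE)
  invisible(report)
}
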
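#' Parallel-line assay data
#'
#' Container for a 3x3 (or general k-preparation, d-dose) parallel-line
#' bioassay: ovary-weight responses of immature rats at geometrically spaced
#' doses of a standard and one or more test preparations.
#'
#' @param preparation Character/factor: preparation label per observation.
#' @param dose_IU Dose per animal (IU), positive.
#' @param response Response per animal (ovary weight, mg), positive.
#' @param standard Label of the standard preparation (default `"standard"`;
#'   if absent, the first level is taken as standard with a warning).
#' @param assumed_potency Assigned activity of the standard ampoule
#'   (IU/ampoule); the reference-standard calibration value 147.5 is the
#'   default.
#' @return Object of class `assay_data` (a data frame with attributes
#'   `standard` and `assumed_potency`).
#' @export
assay_data <- function(preparation, dose_IU, response,
                       standard = "standard", assumed_potency = 147.5) {
  df <- data.frame(preparation = as.character(preparation),
                   dose_IU = as.numeric(dose_IU),
                   response = as.numeric(response))
  if (any(df$dose_IU <= 0)) stop("doses must be positive", call. = FALSE)
  if (any(df$response <= 0)) stop("responses must be positive", call. = FALSE)
  preps <- unique(df$preparation)
  if (!standard %in% preps) {
    warning("standard label '", standard, "' not found; using '",
            preps[1], "'")
    standard <- preps[1]
  }
  dose_sets <- lapply(split(df$dose_IU, df$preparation),
                      function(d) sort(unique(d)))
  nlev <- vapply(dose_sets, length, integer(1))
  if (length(unique(nlev)) != 1L)
    stop("preparations have unequal numbers of dose levels", call. = FALSE)
  if (any(nlev < 2L)) stop("need at least 2 dose levels", call. = FALSE)
  for (d in dose_sets) {
    r <- d[-1] / d[-length(d)]
    if (length(r) > 1L && max(abs(r / r[1] - 1)) > 1e-8)
      warning("doses are not geometrically spaced; the symmetric ",
              "parallel-line design assumes a constant dose ratio")
  }
  structure(df, class = c("assay_data", "data.frame"),
            standard = standard, assumed_potency = assumed_potency)
}

#' Read an assay CSV (columns assay_id, preparation, dose_IU, ovary_weight_mg)
#'
#' @param file CSV path. `animal_id` is accepted and ignored.
#' @param ... Passed to [assay_data()].
#' @return A named list of `assay_data`, one per `assay_id` (a single
#'   `assay_data` if the column is absent).
#' @export
read_assay_csv <- function(file, ...) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("preparation", "dose_IU", "ovary_weight_mg")
  if (!all(need %in% names(df)))
    stop("assay CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  build <- function(d) assay_data(d$preparation, d$dose_IU,
                                  d$ovary_weight_mg, ...)
  if ("assay_id" %in% names(df)) lapply(split(df, df$assay_id), build)
  else build(df)
}

#' Fit the common-slope parallel-line model
#'
#' Least-squares fit of response on natural-log dose with a slope common to
#' all preparations, plus the compendial validity ANOVA partitioning the
#' treatment variation into preparations, (common) regression, deviation
#' from parallelism, and deviation from linearity, tested against the
#' within-cell residual.
#'
#' @param data An [assay_data()].
#' @return Object of class `parallel_line_fit`: list with `slope`,
#'   `prep_means` (mean response and mean log-dose per preparation),
#'   `anova` (data frame: term, df, SS, MS, F, p), `s2` and `df_resid`
#'   (residual variance used for Fieller limits), `Sxx` (pooled
#'   within-preparation log-dose sum of squares), `n` (observations per
#'   preparation), `standard`, `assumed_potency`, `data`.
#' @export
fit_parallel_line <- function(data) {
  stopifnot(inherits(data, "assay_data"))
  y <- data$response
  x <- log(data$dose_IU)
  prep <- factor(data$preparation)
  if (stats::var(y) == 0)
    stop("degenerate fit: all responses identical", call. = FALSE)
  cell <- interaction(prep, factor(x), drop = TRUE)

  m_prep   <- stats::lm(y ~ prep)
  m_common <- stats::lm(y ~ prep + x)
  m_sep    <- stats::lm(y ~ prep * x)
  m_cells  <- stats::lm(y ~ cell)

  rss <- function(m) sum(stats::resid(m)^2)
  dfr <- function(m) stats::df.residual(m)

  n_tot <- length(y)
  ss_total <- sum((y - mean(y))^2)
  nn <- function(ss) max(ss, 0)   # clamp floating-point negatives
  ss_prep <- nn(ss_total - rss(m_prep))
  ss_reg  <- nn(rss(m_prep) - rss(m_common))
  ss_par  <- nn(rss(m_common) - rss(m_sep))
  ss_lin  <- nn(rss(m_sep) - rss(m_cells))
  ss_res  <- rss(m_cells)

  df_prep <- nlevels(prep) - 1L
  df_reg  <- 1L
  df_par  <- dfr(m_common) - dfr(m_sep)
  df_lin  <- dfr(m_sep) - dfr(m_cells)
  df_res  <- dfr(m_cells)

  ms_res <- if (df_res > 0) ss_res / df_res else NA_real_
  fstat <- function(ss, df) {
    if (df <= 0 || !is.finite(ms_res) || ms_res <= 0) return(NA_real_)
    (ss / df) / ms_res
  }
  pval <- function(f, df) {
    if (!is.finite(f)) return(NA_real_)
    stats::pf(f, df, df_res, lower.tail = FALSE)
  }
  terms <- data.frame(
    term = c("preparations", "regression", "parallelism", "linearity",
             "residual"),
    df = c(df_prep, df_reg, df_par, df_lin, df_res),
    SS = c(ss_prep, ss_reg, ss_par, ss_lin, ss_res)
  )
  terms$MS <- ifelse(terms$df > 0, terms$SS / terms$df, NA_real_)
  terms$F <- c(fstat(ss_prep, df_prep), fstat(ss_reg, df_reg),
               fstat(ss_par, df_par), fstat(ss_lin, df_lin), NA_real_)
  terms$p <- c(pval(terms$F[1], df_prep), pval(terms$F[2], df_reg),
               pval(terms$F[3], df_par), pval(terms$F[4], df_lin), NA_real_)

  b <- stats::coef(m_common)[["x"]]
  Sxx <- sum(tapply(x, prep, function(v) sum((v - mean(v))^2)))
  prep_means <- data.frame(
    preparation = levels(prep),
    mean_response = as.numeric(tapply(y, prep, mean)),
    mean_logdose = as.numeric(tapply(x, prep, mean)),
    n = as.integer(table(prep))
  )
  # residual variance for fiducial limits: within-cell error when it has df,
  # otherwise the common-slope model residual (zero in noiseless designs)
  if (df_res > 0) {
    s2 <- ms_res; df_s <- df_res
  } else {
    s2 <- rss(m_common) / max(dfr(m_common), 1L); df_s <- dfr(m_common)
  }
  structure(
    list(slope = b, prep_means = prep_means, anova = terms,
         s2 = s2, df_resid = df_s, Sxx = Sxx,
         standard = attr(data, "standard"),
         assumed_potency = attr(data, "assumed_potency"),
         data = data),
    class = "parallel_line_fit"
  )
}

#' @export
print.parallel_line_fit <- function(x, ...) {
  cat("<parallel_line_fit> common slope", format(x$slope, digits = 5),
      "per ln-dose\n")
  print(x$anova, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Relative potency with Fieller fiducial limits
#'
#' Computes the log relative potency `M = (mean_test - mean_standard)/b`
#' (corrected for any difference in mean log-dose between the preparations),
#' the relative potency `rho = exp(M)`, and 95% fiducial limits by Fieller's
#' theorem using the validity-ANOVA residual variance. When the g-criterion
#' `g = t^2 s^2 / (b^2 Sxx)` reaches 1 the regression is too shallow for
#' finite limits; they are returned as `NA` and flagged. At zero residual
#' variance the limits collapse to the point estimate.
#'
#' Validity verdicts follow the compendial convention: significant
#' regression (p < 0.05), non-significant deviations from parallelism and
#' linearity (p > 0.05).
#'
#' @param fit A [fit_parallel_line()] result.
#' @param test Label of the test preparation (default: the single
#'   non-standard preparation).
#' @param assumed Assumed potency of the test container in IU (defaults to
#'   the assay's `assumed_potency`); the estimated potency is
#'   `rho * assumed`.
#' @param level Confidence level, default 0.95.
#' @return Object of class `potency_estimate`: list with `log_rho`, `rho`,
#'   `fiducial_limits` (on the rho scale), `potency_IU`, `potency_limits_IU`,
#'   `g`, `validity` (named logicals + p-values), `level`, `df`.
#' @export
estimate_potency <- function(fit, test = NULL, assumed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "parallel_line_fit"))
  pm <- fit$prep_means
  std <- fit$standard
  others <- setdiff(pm$preparation, std)
  if (is.null(test)) {
    if (length(others) != 1L)
      stop("specify `test`: candidates are ",
           paste(others, collapse = ", "), call. = FALSE)
    test <- others
  }
  if (is.null(assumed)) assumed <- fit$assumed_potency
  i_t <- match(test, pm$preparation)
  i_s <- match(std, pm$preparation)
  if (is.na(i_t)) stop("unknown preparation '", test, "'", call. = FALSE)

  b <- fit$slope
  a <- pm$mean_response[i_t] - pm$mean_response[i_s]
  dx <- pm$mean_logdose[i_t] - pm$mean_logdose[i_s]
  M <- a / b - dx
  n_t <- pm$n[i_t]; n_s <- pm$n[i_s]

  s2 <- fit$s2
  anv <- fit$anova
  p_of <- function(term) anv$p[anv$term == term]
  validity <- list(
    regression = isTRUE(p_of("regression") < 0.05),
    parallelism = isTRUE(p_of("parallelism") > 0.05),
    linearity = if (anv$df[anv$term == "linearity"] > 0)
      isTRUE(p_of("linearity") > 0.05) else NA,
    p_regression = p_of("regression"),
    p_parallelism = p_of("parallelism"),
    p_linearity = p_of("linearity")
  )

  if (!is.finite(s2) || s2 <= .Machine$double.eps * max(1, abs(b))) {
    g <- 0
    lims <- c(M, M)
  } else {
    tval <- stats::qt(1 - (1 - level) / 2, fit$df_resid)
    var_a <- s2 * (1 / n_s + 1 / n_t)
    var_b <- s2 / fit$Sxx
    g <- tval^2 * var_b / b^2
    if (g >= 1) {
      lims <- c(NA_real_, NA_real_)
      warning("g-criterion >= 1: fiducial limits undefined")
    } else {
      Mr <- a / b   # the ratio part; the -dx shift is error-free
      half <- (tval / abs(b)) * sqrt(var_a * (1 - g) + Mr^2 * var_b)
      lims <- (Mr + c(-half, half)) / (1 - g) - dx
    }
  }
  structure(
    list(test = test, standard = std,
         log_rho = M, rho = exp(M),
         fiducial_limits = exp(lims),
         potency_IU = exp(M) * assumed,
         potency_limits_IU = exp(lims) * assumed,
         g = g, level = level, df = fit$df_resid,
         validity = validity),
    class = "potency_estimate"
  )
}

#' @export
print.potency_estimate <- function(x, ...) {
  cat(sprintf("<potency_estimate> %s vs %s\n", x$test, x$standard))
  cat(sprintf("  rho = %.4f  (%.0f%% fiducial limits %.4f - %.4f)\n",
              x$rho, 100 * x$level, x$fiducial_limits[1],
              x$fiducial_limits[2]))
  cat(sprintf("  potency = %.2f IU; validity: regression %s, parallelism %s, linearity %s\n",
              x$potency_IU,
              ifelse(isTRUE(x$validity$regression), "ok", "FAILED"),
              ifelse(isTRUE(x$validity$parallelism), "ok", "FAILED"),
              ifelse(is.na(x$validity$linearity), "n/a",
                     ifelse(x$validity$linearity, "ok", "FAILED"))))
  invisible(x)
}

#' Combine replicate potency estimates
#'
#' Compendial weighted combination on the log scale: each estimate is
#' weighted by the inverse of its squared fiducial half-width in log units,
#' `W = 4 t^2 / L^2` with `L` the full log-limit width (equivalently
#' `1/s_M^2`). Reports the homogeneity chi-square
#' `sum W (M_i - M_bar)^2` on k-1 df; a significant value flags a
#' heterogeneous set, but the combined value is still returned. An
#' unweighted geometric mean is available for comparison.
#'
#' @param estimates List of [estimate_potency()] results with finite limits.
#' @param weighted Use compendial weights (default) or equal weights.
#' @param level Confidence level of combined limits.
#' @return List with `rho`, `log_rho`, `limits` (rho scale), `weights`,
#'   `chisq`, `chisq_df`, `chisq_p`, `homogeneous`, `n`.
#' @export
combine_potencies <- function(estimates, weighted = TRUE, level = 0.95) {
  if (inherits(estimates, "potency_estimate")) estimates <- list(estimates)
  stopifnot(length(estimates) >= 1L)
  if (length(estimates) == 1L) {
    e <- estimates[[1]]
    return(list(rho = e$rho, log_rho = e$log_rho,
                limits = e$fiducial_limits, weights = 1,
                chisq = 0, chisq_df = 0L, chisq_p = 1,
                homogeneous = TRUE, n = 1L))
  }
  M <- vapply(estimates, function(e) e$log_rho, numeric(1))
  Llog <- vapply(estimates, function(e) diff(log(e$fiducial_limits)),
                 numeric(1))
  dfs <- vapply(estimates, function(e) e$df, numeric(1))
  if (any(!is.finite(Llog)))
    stop("all estimates must have finite fiducial limits", call. = FALSE)
  if (weighted && all(Llog > 0)) {
    tv <- stats::qt(1 - (1 - level) / 2, dfs)
    W <- 4 * tv^2 / Llog^2
  } else {
    W <- rep(1, length(M))
    if (weighted)
      message("zero-width limits present: falling back to equal weights")
  }
  Mbar <- sum(W * M) / sum(W)
  chisq <- sum(W * (M - Mbar)^2)
  kdf <- length(M) - 1L
  p <- stats::pchisq(chisq, kdf, lower.tail = FALSE)
  df_comb <- sum(dfs)
  tcomb <- stats::qt(1 - (1 - level) / 2, df_comb)
  half <- if (all(W > 0) && is.finite(sum(W))) tcomb * sqrt(1 / sum(W)) else 0
  if (!weighted) {
    # equal weights: plain mean with empirical spread is not compendial;
    # keep the limit from the pooled weights when available
    half <- tcomb * stats::sd(M) / sqrt(length(M))
  }
  homogeneous <- p > 0.05
  if (!homogeneous)
    warning("heterogeneous potency set (chi-square p = ",
            format(p, digits = 3), "); combined value flagged")
  list(rho = exp(Mbar), log_rho = Mbar,
       limits = exp(Mbar + c(-half, half)),
       weights = W, chisq = chisq, chisq_df = kdf, chisq_p = p,
       homogeneous = homogeneous, n = length(M))
}

#' Specific activity and percent of nominal
#'
#' `specific_activity()` converts a container potency (IU) and its protein
#' content (micrograms) to IU/mg; `relative_percent()` expresses a potency
#' against the nominal label claim.
#'
#' @param potency_IU Measured potency, IU per container.
#' @param mass_ug Protein content, micrograms per container.
#' @return IU/mg.
#' @examples
#' specific_activity(75, 5.5) # 13636.36...
#' @export
specific_activity <- function(potency_IU, mass_ug) {
  if (any(mass_ug <= 0)) stop("mass must be positive", call. = FALSE)
  potency_IU / (mass_ug / 1000)
}

#' @rdname specific_activity
#' @param nominal_IU Nominal content, IU per container.
#' @return `relative_percent()`: percent of nominal.
#' @export
relative_percent <- function(potency_IU, nominal_IU) {
  if (any(nominal_IU <= 0)) stop("nominal must be positive", call. = FALSE)
  100 * potency_IU / nominal_IU
}

#' Batch potency record
#'
#' @param batch_id Batch label.
#' @param potency_IU Measured potency (IU/container).
#' @param nominal_IU,nominal_mass_ug Label claim.
#' @return One-row data frame with `specific_activity_IU_mg` and
#'   `relative_percent` derived.
#' @export
batch_potency <- function(batch_id, potency_IU, nominal_IU, nominal_mass_ug) {
  data.frame(
    batch_id = batch_id, potency_IU = potency_IU,
    nominal_IU = nominal_IU, nominal_mass_ug = nominal_mass_ug,
    specific_activity_IU_mg = specific_activity(potency_IU, nominal_mass_ug),
    relative_percent = relative_percent(potency_IU, nominal_IU)
  )
}
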
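#' MS simulation configuration
#'
#' Describes the synthetic glycopeptide world: per-site target glycan
#' distributions, peptide backbones, charge states, intensity scale,
#' multiplicative log-normal intensity noise, decoy peaks and m/z jitter.
#' Defaults emulate the measured structure of a site-specific glycopeptide
#' run: each site's species abundances follow a prescribed percentage
#' distribution; ion counts are positive and right-skewed, hence log-normal
#' noise (sigma 0.1 by default).
#'
#' @param targets Named list (by site id) of percentage vectors named by
#'   glycan species; each must sum to 100 (tolerance 0.5).
#' @param peptides Named list of [site_peptide()] per site; defaults to the
#'   chymotryptic FSH glycosite peptides.
#' @param charges Charge states emitted, default `2:4` (glycopeptide ions of
#'   this size rarely appear singly charged in-range).
#' @param intensity_scale Total ion count per site, default `1e6`.
#' @param noise_sigma Log-normal sigma of multiplicative intensity noise,
#'   `>= 0`, default 0.1.
#' @param decoy_rate Expected number of decoy peaks per scan, default 0.
#' @param mz_jitter_ppm SD of Gaussian m/z error in ppm, default 0.
#' @param n_scans Number of scans the species elute over, default 5.
#' @param scan_range Instrument m/z range.
#' @param seed Integer seed, recorded in the config and the output.
#' @return Object of class `ms_simulation_config`.
#' @export
ms_simulation_config <- function(targets,
                                 peptides = fsh_site_peptides(),
                                 charges = 2:4,
                                 intensity_scale = 1e6,
                                 noise_sigma = 0.1,
                                 decoy_rate = 0,
                                 mz_jitter_ppm = 0,
                                 n_scans = 5L,
                                 scan_range = c(100, 2000),
                                 seed = 1L) {
  stopifnot(is.list(targets), length(targets) >= 1L, noise_sigma >= 0,
            decoy_rate >= 0, mz_jitter_ppm >= 0, n_scans >= 1L)
  for (sid in names(targets)) {
    t <- targets[[sid]]
    if (is.null(names(t)) || abs(sum(t) - 100) > 0.5)
      stop("target for ", sid,
           " must be a named percentage vector summing to 100", call. = FALSE)
    if (!sid %in% names(peptides))
      stop("no peptide supplied for site ", sid, call. = FALSE)
  }
  structure(
    list(targets = targets, peptides = peptides, charges = charges,
         intensity_scale = intensity_scale, noise_sigma = noise_sigma,
         decoy_rate = decoy_rate, mz_jitter_ppm = mz_jitter_ppm,
         n_scans = as.integer(n_scans), scan_range = scan_range,
         seed = as.integer(seed)),
    class = "ms_simulation_config"
  )
}

#' Simulate a glycopeptide peak list with known ground truth
#'
#' Emits, for every (site, species, in-range charge, scan), a peak at the
#' theoretical m/z (plus Gaussian ppm jitter) whose intensity is
#' proportional to the target percentage, perturbed by multiplicative
#' log-normal noise. Decoy peaks are placed at least 3 matching tolerances
#' (30 ppm) away from every candidate m/z, so they can never satisfy a
#' 10 ppm match. Bit-reproducible for a given (config, seed).
#'
#' @param cfg An [ms_simulation_config()].
#' @return List with `peaklist` (a [peak_list()]), `truth` (data frame:
#'   site_id, peptide, glycan, charge, theoretical_mz, true_percentage,
#'   emitted_intensity) and `seed`.
#' @export
simulate_peaklist <- function(cfg) {
  stopifnot(inherits(cfg, "ms_simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  rts <- seq(10, 10 + 2 * (cfg$n_scans - 1L), length.out = cfg$n_scans)
  rows <- list(); truth <- list()
  for (sid in names(cfg$targets)) {
    pep <- cfg$peptides[[sid]]
    target <- cfg$targets[[sid]]
    cand <- candidate_ions(pep, names(target), charges = cfg$charges,
                           scan_range = cfg$scan_range)
    # canonicalize target names so truth and assignments agree
    names(target) <- vapply(names(target), function(n)
      parse_glycan_name(n, quiet = TRUE)$canonical_name, character(1))
    absent <- setdiff(names(target)[target > 0], unique(cand$glycan))
    if (length(absent))
      stop("species with no in-range charge state at ", sid, ": ",
           paste(absent, collapse = ", "), call. = FALSE)
    for (i in seq_len(nrow(cand))) {
      gl <- cand$glycan[i]
      pct <- target[[gl]]
      n_z <- sum(cand$glycan == gl)        # usable charges for this species
      base <- cfg$intensity_scale * pct / 100 / (n_z * cfg$n_scans)
      emitted <- 0
      for (rt in rts) {
        noise <- if (cfg$noise_sigma > 0)
          exp(stats::rnorm(1, 0, cfg$noise_sigma)) else 1
        jit <- if (cfg$mz_jitter_ppm > 0)
          1 + stats::rnorm(1, 0, cfg$mz_jitter_ppm) * 1e-6 else 1
        inten <- base * noise
        emitted <- emitted + inten
        rows[[length(rows) + 1L]] <- data.frame(
          rt_min = rt, mz = cand$theoretical_mz[i] * jit,
          intensity = inten)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        site_id = sid, peptide = cand$peptide[i], glycan = gl,
        charge = cand$charge[i], theoretical_mz = cand$theoretical_mz[i],
        true_percentage = pct, emitted_intensity = emitted)
    }
  }
  truth <- do.call(rbind, truth)

  # decoys: uniform m/z kept >= 30 ppm away from every candidate
  if (cfg$decoy_rate > 0) {
    all_mz <- unique(truth$theoretical_mz)
    n_decoys <- stats::rpois(1, cfg$decoy_rate * cfg$n_scans)
    placed <- 0L
    while (placed < n_decoys) {
      mz <- stats::runif(1, cfg$scan_range[1], cfg$scan_range[2])
      if (min(abs(1e6 * (mz - all_mz) / all_mz)) < 30) next
      rows[[length(rows) + 1L]] <- data.frame(
        rt_min = sample(rts, 1),
        mz = mz,
        intensity = stats::rlnorm(1, log(cfg$intensity_scale / 1e3), 1))
      placed <- placed + 1L
    }
  }
  pk_df <- do.call(rbind, rows)
  list(
    peaklist = peak_list(pk_df$rt_min, pk_df$mz, pk_df$intensity,
                         scan_range = cfg$scan_range),
    truth = truth,
    seed = cfg$seed
  )
}

#' Bioassay simulation configuration
#'
#' The stated world of the 3x3 in-vivo design: three geometric doses (2, 4,
#' 8 IU per rat), five rats per dose and preparation, responses linear in
#' log dose with normal residuals. Default response parameters put ovary
#' weights in the 50-105 mg range with a residual SD (6 mg) that yields
#' batch potency CVs in the realistic 5-9% band.
#'
#' @param true_rho True relative potency of the test preparation, default 1.
#' @param intercept,slope Response at 1 IU and gain per ln-dose (mg).
#' @param residual_sd Residual SD of ovary weight, mg, `>= 0`.
#' @param doses Dose levels, IU per rat.
#' @param reps Rats per dose and preparation.
#' @param n_assays Number of replicate assays generated.
#' @param assumed_potency Assigned standard activity (IU/ampoule).
#' @param seed Integer seed.
#' @return Object of class `assay_simulation_config`.
#' @export
assay_simulation_config <- function(true_rho = 1, intercept = 30, slope = 35,
                                    residual_sd = 6, doses = c(2, 4, 8),
                                    reps = 5L, n_assays = 1L,
                                    assumed_potency = 147.5, seed = 1L) {
  stopifnot(true_rho > 0, residual_sd >= 0, all(doses > 0), reps >= 1L,
            n_assays >= 1L)
  structure(
    list(true_rho = true_rho, intercept = intercept, slope = slope,
         residual_sd = residual_sd, doses = doses, reps = as.integer(reps),
         n_assays = as.integer(n_assays),
         assumed_potency = assumed_potency, seed = as.integer(seed)),
    class = "assay_simulation_config"
  )
}

#' Simulate parallel-line assay datasets
#'
#' Generates `n_assays` independent assays. For each animal the response is
#' `intercept + slope * log(dose * rho_prep) + N(0, sd)`, with `rho = 1` for
#' the standard and `rho = true_rho` for the test preparation: a test
#' preparation that is rho-fold as potent behaves like the standard given at
#' a rho-fold dose.
#'
#' @param cfg An [assay_simulation_config()].
#' @return List of [assay_data()] (length `n_assays`).
#' @export
simulate_assay <- function(cfg) {
  stopifnot(inherits(cfg, "assay_simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_assays), function(i) {
    one <- function(label, rho) {
      dose <- rep(cfg$doses, each = cfg$reps)
      y <- cfg$intercept + cfg$slope * log(dose * rho) +
        stats::rnorm(length(dose), 0, cfg$residual_sd)
      data.frame(preparation = label, dose_IU = dose, response = y)
    }
    df <- rbind(one("standard", 1), one("test", cfg$true_rho))
    assay_data(df$preparation, df$dose_IU, df$response,
               standard = "standard",
               assumed_potency = cfg$assumed_potency)
  })
}
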
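#' Potency group
#'
#' A labelled set of batch potencies on the relative-percent-of-nominal
#' scale, the normalization used for cross-product comparisons.
#'
#' @param label Product/group name.
#' @param values Numeric vector of relative potencies (% of nominal),
#'   `n >= 2` for any variance-based statistic.
#' @return Object of class `potency_group`.
#' @export
potency_group <- function(label, values) {
  stopifnot(is.character(label), length(label) == 1L, is.numeric(values))
  structure(list(label = label, values = as.numeric(values)),
            class = "potency_group")
}

#' Coefficient of variation (%)
#'
#' @param values Numeric vector, `n >= 2`, non-zero mean.
#' @return `100 * sd / mean`.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need n >= 2", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Compare potency groups: one-way ANOVA with Fisher LSD
#'
#' One-way analysis of variance across groups followed by Fisher's least
#' significant difference pairwise tests (two-sample t tests on the pooled
#' within-group mean square) at the 95% confidence level.
#'
#' @param groups List of [potency_group()] objects (>= 2, each `n >= 2`).
#' @param alpha Significance level for the pairwise verdicts, default 0.05.
#' @return Object of class `comparison_result`: list with `summary` (per
#'   group: n, mean, sd, cv), `F`, `df`, `p`, `pairwise` (data frame:
#'   group1, group2, difference, t, p, significant), `alpha`.
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  stopifnot(length(groups) >= 2L)
  labels <- vapply(groups, function(g) g$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate group labels", call. = FALSE)
  ns <- vapply(groups, function(g) length(g$values), integer(1))
  if (any(ns < 2L)) stop("each group needs n >= 2", call. = FALSE)
  values <- unlist(lapply(groups, function(g) g$values))
  group <- factor(rep(labels, ns), levels = labels)

  k <- length(groups)
  N <- length(values)
  gmeans <- tapply(values, group, mean)
  ss_between <- sum(ns * (gmeans - mean(values))^2)
  ss_within <- sum(tapply(values, group,
                          function(v) sum((v - mean(v))^2)))
  df1 <- k - 1L
  df2 <- N - k
  if (ss_within == 0 && ss_between == 0)
    stop("degenerate comparison: no variance anywhere", call. = FALSE)
  ms_within <- ss_within / df2
  Fstat <- if (ms_within > 0) (ss_between / df1) / ms_within else Inf
  p <- if (is.finite(Fstat)) stats::pf(Fstat, df1, df2, lower.tail = FALSE)
       else 0

  pairs <- utils::combn(seq_len(k), 2)
  pw <- data.frame(
    group1 = labels[pairs[1, ]], group2 = labels[pairs[2, ]],
    difference = gmeans[pairs[1, ]] - gmeans[pairs[2, ]]
  )
  se <- sqrt(ms_within * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  pw$t <- ifelse(se > 0, pw$difference / se,
                 ifelse(pw$difference == 0, 0, Inf))
  pw$p <- 2 * stats::pt(abs(pw$t), df2, lower.tail = FALSE)
  pw$significant <- pw$p < alpha
  rownames(pw) <- NULL

  summary_df <- data.frame(
    group = labels, n = ns,
    mean = as.numeric(gmeans),
    sd = as.numeric(tapply(values, group, stats::sd)),
    cv = vapply(groups, function(g)
      if (mean(g$values) == 0) NA_real_
      else coefficient_of_variation(g$values), numeric(1))
  )
  structure(
    list(summary = summary_df, F = Fstat, df = c(df1, df2), p = p,
         pairwise = pw, alpha = alpha),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>\n")
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n", x$df[1], x$df[2], x$F, x$p))
  sig <- x$pairwise[x$pairwise$significant, , drop = FALSE]
  if (nrow(sig))
    cat("  significant pairs:",
        paste(sig$group1, "vs", sig$group2, collapse = "; "), "\n")
  else cat("  no significant pairwise differences\n")
  invisible(x)
}

#' Bartlett's test of variance homogeneity across groups
#'
#' @param groups List of [potency_group()] objects, each `n >= 2`.
#' @return List with `statistic`, `df`, `p`.
#' @export
bartlett_check <- function(groups) {
  ns <- vapply(groups, function(g) length(g$values), integer(1))
  if (any(ns < 2L)) stop("each group needs n >= 2", call. = FALSE)
  values <- unlist(lapply(groups, function(g) g$values))
  group <- factor(rep(vapply(groups, function(g) g$label, character(1)), ns))
  bt <- stats::bartlett.test(values, group)
  list(statistic = unname(bt$statistic), df = unname(bt$parameter),
       p = bt$p.value)
}

#' Randomized cross-validation subgroup analysis
#'
#' Randomly partitions the reference group into subgroups of the stated
#' sizes (seeded, reproducible) and runs all pairwise subgroup-vs-subgroup
#' and subgroup-vs-comparator comparisons through [compare_groups()],
#' plus a variance-homogeneity check over the subgroups and the comparator.
#' This is the imbalance-robustness check used when one product has many
#' more tested batches than the other.
#'
#' @param reference [potency_group()] to be partitioned.
#' @param comparator [potency_group()] compared against each subgroup.
#' @param subgroup_sizes Integer sizes; must sum to the reference n.
#' @param seed Integer seed for the partition (recorded in the result).
#' @param alpha Significance level.
#' @return List with `subgroups` (list of potency_group), `partition`
#'   (assignment index per reference value), `subgroup_means`,
#'   `comparisons` (pairwise data frame over all subgroup/comparator pairs),
#'   `bartlett`, `seed`.
#' @export
cross_validate <- function(reference, comparator, subgroup_sizes,
                           seed = 17L, alpha = 0.05) {
  n <- length(reference$values)
  if (sum(subgroup_sizes) != n)
    stop("subgroup sizes sum to ", sum(subgroup_sizes),
         ", but reference n = ", n, call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n)
  assignment <- integer(n)
  idx <- 1L
  for (g in seq_along(subgroup_sizes)) {
    take <- perm[idx:(idx + subgroup_sizes[g] - 1L)]
    assignment[take] <- g
    idx <- idx + subgroup_sizes[g]
  }
  sub_labels <- paste0(reference$label, "_", LETTERS[seq_along(subgroup_sizes)])
  subgroups <- lapply(seq_along(subgroup_sizes), function(g)
    potency_group(sub_labels[g], reference$values[assignment == g]))
  all_groups <- c(subgroups, list(comparator))
  cmp <- compare_groups(all_groups, alpha = alpha)
  list(
    subgroups = subgroups,
    partition = assignment,
    subgroup_means = vapply(subgroups, function(g) mean(g$values),
                            numeric(1)),
    comparisons = cmp,
    bartlett = bartlett_check(all_groups),
    seed = seed
  )
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Two-sample statistical power (descriptive)
#'
#' Standard two-sample normal-approximation power for detecting the observed
#' mean difference at the observed pooled SD. Reported descriptively
#' alongside comparisons; the published power figure's exact assumptions are
#' not reproducible, so this is not an acceptance surface.
#'
#' @param g1,g2 [potency_group()] objects.
#' @param alpha Significance level.
#' @return Power in \[0, 1\].
#' @export
two_sample_power <- function(g1, g2, alpha = 0.05) {
  n1 <- length(g1$values); n2 <- length(g2$values)
  delta <- abs(mean(g1$values) - mean(g2$values))
  sp <- sqrt(((n1 - 1) * stats::var(g1$values) +
                (n2 - 1) * stats::var(g2$values)) / (n1 + n2 - 2))
  se <- sp * sqrt(1 / n1 + 1 / n2)
  df <- n1 + n2 - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  ncp <- delta / se
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}
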
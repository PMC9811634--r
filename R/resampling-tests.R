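# Monte-Carlo permutation and bootstrap machinery. All p-values use the
# add-one convention (the observed arrangement counts as one permutation),
# so the smallest attainable p is 1/(n_resamples + 1).

new_perm_result <- function(statistic, p_value, n_resamples, seed,
                            alternative, method, degenerate = FALSE) {
  structure(
    list(statistic = statistic, p_value = p_value,
         n_resamples = n_resamples, seed = seed,
         alternative = alternative, method = method,
         degenerate = degenerate),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  cat(sprintf("statistic = %.4f, p-value = %.4g\n", x$statistic, x$p_value))
  cat(sprintf("alternative: %s; Monte-Carlo resamples: %d (seed %d)\n",
              x$alternative, x$n_resamples, x$seed))
  if (isTRUE(x$degenerate)) cat("note: degenerate input (see docs)\n")
  invisible(x)
}

#' Permutation Mann-Whitney U test on a standardized rank statistic
#'
#' Two-sample rank test with a Monte-Carlo permutation reference
#' distribution. The reported statistic is the standardized linear rank
#' statistic Z: the rank sum of `x` (mid-ranks for ties), centred by its
#' permutation mean and scaled by the tie-corrected permutation standard
#' deviation. Positive Z means `x` carries larger ranks than `y`. The
#' p-value is the proportion of label permutations (observed included)
#' whose statistic is as or more extreme than the observed one.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param n_resamples number of Monte-Carlo permutations, at least 999;
#'   default 10000.
#' @param seed integer seed for the Monte-Carlo draw.
#' @return object of class `perm_test` with fields `statistic` (Z),
#'   `p_value`, `n_resamples`, `seed`, `alternative`.
#' @export
mwu_permutation_test <- function(x, y,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 n_resamples = 10000L, seed = 1L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty")
  }
  stopifnot(n_resamples >= 999L)
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  # exact permutation moments of the rank sum, tie-corrected
  mu <- nx * mean(r)
  v <- nx * ny / (N * (N - 1)) * sum((r - mean(r))^2)
  if (v <= .Machine$double.eps) {
    # all observations tied across both groups
    return(new_perm_result(0, 1, n_resamples, seed, alternative,
                           "Monte-Carlo permutation Mann-Whitney U test",
                           degenerate = TRUE))
  }
  z_obs <- (sum(r[seq_len(nx)]) - mu) / sqrt(v)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  z_perm <- vapply(seq_len(n_resamples), function(i) {
    (sum(r[sample.int(N, nx)]) - mu) / sqrt(v)
  }, numeric(1))
  p <- switch(alternative,
    two.sided = (1 + sum(abs(z_perm) >= abs(z_obs) - 1e-12)) /
      (n_resamples + 1),
    greater = (1 + sum(z_perm >= z_obs - 1e-12)) / (n_resamples + 1),
    less = (1 + sum(z_perm <= z_obs + 1e-12)) / (n_resamples + 1)
  )
  new_perm_result(z_obs, p, n_resamples, seed, alternative,
                  "Monte-Carlo permutation Mann-Whitney U test")
}

#' Pearson chi-squared statistic of a contingency table
#'
#' Plain Pearson X-squared with expected counts from the row/column
#' margins and no continuity correction. A table with a zero row or
#' column margin has no information about association; the statistic is
#' then defined as 0 and flagged via the `"degenerate"` attribute.
#'
#' @param tab matrix of non-negative counts.
#' @return numeric X-squared value with logical attribute `"degenerate"`.
#' @export
pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  n <- sum(tab)
  if (n <= 0) stop("table total must be positive")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    return(structure(0, degenerate = TRUE))
  }
  expected <- outer(rs, cs) / n
  structure(sum((tab - expected)^2 / expected), degenerate = FALSE)
}

#' Permutation chi-squared test of independence
#'
#' Tests association between a class label and an aggressive outcome by
#' permuting labels against outcomes. The observed statistic is the
#' Pearson X-squared of the cross-tabulation; the Monte-Carlo reference
#' holds both margins fixed (label permutation is equivalent to drawing
#' tables from the conditional distribution given the margins, sampled
#' with [stats::r2dtable()]). The p-value is upper-tail with the observed
#' permutation counted.
#'
#' @param labels factor-like vector (e.g. conspecific/heterospecific), at
#'   least two levels present.
#' @param outcomes factor-like vector of the same length (e.g.
#'   signal/chase).
#' @param n_resamples number of Monte-Carlo permutations; default 10000.
#' @param seed integer seed.
#' @return object of class `perm_test` with the X-squared statistic.
#' @export
chisq_permutation_test <- function(labels, outcomes, n_resamples = 10000L,
                                   seed = 1L) {
  labels <- as.character(labels); outcomes <- as.character(outcomes)
  stopifnot(length(labels) == length(outcomes), n_resamples >= 1L)
  if (length(unique(labels)) < 2L) {
    stop("need at least two label levels")
  }
  tab <- table(labels, outcomes)
  obs <- pearson_chisq(tab)
  if (isTRUE(attr(obs, "degenerate"))) {
    return(new_perm_result(0, 1, n_resamples, seed, "greater",
                           "Monte-Carlo permutation chi-squared test",
                           degenerate = TRUE))
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  sims <- stats::r2dtable(n_resamples, rowSums(tab), colSums(tab))
  stat_perm <- vapply(sims, function(m) as.numeric(pearson_chisq(m)),
                      numeric(1))
  p <- (1 + sum(stat_perm >= as.numeric(obs) - 1e-12)) / (n_resamples + 1)
  new_perm_result(as.numeric(obs), p, n_resamples, seed, "greater",
                  "Monte-Carlo permutation chi-squared test")
}

#' Proportion of aggressive encounters resolved by signalling
#'
#' Computes n_signal / (n_signal + n_chase), ignoring passive encounters.
#' When no aggressive encounter is present the proportion is undefined and
#' `NA` is returned with attribute `"undefined" = TRUE`.
#'
#' @param records validated encounter data frame.
#' @return proportion in `[0, 1]`, or flagged `NA`.
#' @export
signalling_proportion <- function(records) {
  n_signal <- sum(records$outcome == "signal")
  n_chase <- sum(records$outcome == "chase")
  if (n_signal + n_chase == 0L) {
    return(structure(NA_real_, undefined = TRUE))
  }
  structure(n_signal / (n_signal + n_chase), undefined = FALSE)
}

#' Bootstrap one encounter per focal individual
#'
#' Repeated encounters on the same individual are pseudoreplicates. Each
#' bootstrap replicate draws, uniformly and independently across
#' individuals, exactly one encounter per focal individual (identity
#' scoped to region/reef/period), applies `inner_test` to the reduced
#' dataset, and records its statistic and p-value. Replicates are
#' aggregated into means and 2.5/97.5 percentile intervals.
#'
#' @param records validated encounter data frame with focal identities.
#' @param inner_test function taking a single-encounter-per-individual
#'   data frame and returning a list/object with elements `statistic` and
#'   `p_value`.
#' @param B number of bootstrap replicates, default 1000.
#' @param seed integer seed.
#' @return object of class `bootstrap_test` with `mean_statistic`,
#'   `mean_p`, `ci95_statistic`, `ci95_p`, `n_bootstrap`, `per_replicate`.
#' @export
bootstrap_one_per_individual <- function(records, inner_test, B = 1000L,
                                         seed = 1L) {
  if (B < 1L) stop("B must be at least 1")
  ind <- individual_key(records)
  idx_by_ind <- split(seq_len(nrow(records)), ind)
  sizes <- lengths(idx_by_ind)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  reps <- matrix(NA_real_, nrow = B, ncol = 2,
                 dimnames = list(NULL, c("statistic", "p")))
  for (b in seq_len(B)) {
    pick <- vapply(idx_by_ind, function(ix) {
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
    }, integer(1))
    res <- inner_test(records[pick, , drop = FALSE])
    reps[b, ] <- c(as.numeric(res$statistic), as.numeric(res$p_value))
  }
  # replicates where the inner test is undefined (e.g. a label level
  # vanished under subsampling) carry NA and are dropped from aggregation
  structure(
    list(mean_statistic = mean(reps[, 1], na.rm = TRUE),
         mean_p = mean(reps[, 2], na.rm = TRUE),
         ci95_statistic = unname(stats::quantile(reps[, 1],
                                                 c(0.025, 0.975),
                                                 type = 7, na.rm = TRUE)),
         ci95_p = unname(stats::quantile(reps[, 2], c(0.025, 0.975),
                                         type = 7, na.rm = TRUE)),
         n_bootstrap = B, n_valid = sum(!is.na(reps[, 1])),
         seed = seed, per_replicate = reps),
    class = "bootstrap_test"
  )
}

#' @export
print.bootstrap_test <- function(x, ...) {
  cat("\n\tBootstrap (one encounter per individual) test\n\n")
  cat(sprintf("mean statistic = %.4f  [95%% CI %.4f, %.4f]\n",
              x$mean_statistic, x$ci95_statistic[1], x$ci95_statistic[2]))
  cat(sprintf("mean p-value  = %.4g  [95%% CI %.4g, %.4g]\n",
              x$mean_p, x$ci95_p[1], x$ci95_p[2]))
  cat(sprintf("bootstrap replicates: %d (seed %d)\n", x$n_bootstrap,
              x$seed))
  invisible(x)
}

# Seed handling: tests and the pipeline must be reproducible without
# clobbering the caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
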
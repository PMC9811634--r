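# Independent oracles used across the suite. These deliberately use
# brute-force enumeration or dense grids, never the package's own code
# paths, so they stay valid checks of the implementation.

# Exact permutation p-value for the standardized rank statistic by full
# enumeration of all C(N, nx) group assignments.
exact_mwu_p <- function(x, y, alternative = "two.sided") {
  nx <- length(x)
  r <- rank(c(x, y))
  N <- length(r)
  mu <- nx * mean(r)
  v <- nx * length(y) / (N * (N - 1)) * sum((r - mean(r))^2)
  z_of <- function(idx) (sum(r[idx]) - mu) / sqrt(v)
  z_obs <- z_of(seq_len(nx))
  all_z <- apply(utils::combn(N, nx), 2, z_of)
  tol <- 1e-12
  switch(alternative,
    two.sided = mean(abs(all_z) >= abs(z_obs) - tol),
    greater = mean(all_z >= z_obs - tol),
    less = mean(all_z <= z_obs + tol)
  )
}

# Exact permutation p-value for the Pearson X^2 of a 2-level x 2-level
# classification, enumerating every permutation of the label vector via
# the distinct tables (hypergeometric weights).
exact_chisq_perm_p <- function(labels, outcomes) {
  tab <- table(labels, outcomes)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  x2 <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  obs <- x2(tab)
  # support of the (1,1) cell under fixed margins
  a_vals <- max(0, rs[1] + cs[1] - n):min(rs[1], cs[1])
  stats <- vapply(a_vals, function(a) {
    m <- matrix(c(a, rs[1] - a, cs[1] - a, n - rs[1] - cs[1] + a), 2, 2)
    x2(m)
  }, numeric(1))
  w <- stats::dhyper(a_vals, cs[1], n - cs[1], rs[1])
  min(1, sum(w[stats >= obs - 1e-12]))
}

# Dense grid search for the common-CV restricted maximum likelihood.
grid_common_cv <- function(groups, taus = seq(0.01, 3, by = 0.0005)) {
  n <- vapply(groups, length, integer(1))
  ll_tau <- vapply(taus, function(tau) {
    sum(vapply(seq_along(groups), function(i) {
      g <- groups[[i]]
      # inner dense grid over the group mean
      mus <- seq(mean(g) * 0.2, mean(g) * 2.5, length.out = 400)
      max(vapply(mus, function(mu) {
        sigma <- tau * mu
        sum(stats::dnorm(g, mu, sigma, log = TRUE))
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  list(tau = taus[which.max(ll_tau)], loglik = max(ll_tau))
}

# A small hand-checkable encounter table used by several tests.
toy_records <- function() {
  df <- data.frame(
    region = "r1", reef = "reef1",
    period = rep("before", 12),
    focal_id = c("i1", "i1", "i2", "i3", "i4", "i5",
                 "i1", "i2", "i6", "i6", "i7", "i8"),
    focal_species = c(rep("A", 6), rep("A", 2), rep("B", 4)),
    partner_species = c(rep("A", 6), "B", "B", "C", "C", "C", "C"),
    proximity_cat = c(1L, 3L, 2L, 4L, 1L, 2L, 3L, 1L, 2L, 2L, 4L, 3L),
    outcome = c("passive", "chase", "signal", "passive", "chase",
                "chase", "signal", "chase", "passive", "chase",
                "signal", "passive"),
    chase_distance_m = c(NA, 2.5, NA, NA, 1.0, 4.0, NA, 3.0, NA, 0.5,
                         NA, NA),
    stringsAsFactors = FALSE
  )
  validate_encounters(df)
}

# Minimal valid generator config for fast tests.
small_config <- function(seed = 1L, n_individuals_per_species_reef = 3L,
                         ...) {
  generator_config(n_species = 4L, n_regions = 2L, reefs_per_region = 2L,
                   n_individuals_per_species_reef =
                     n_individuals_per_species_reef,
                   encounters_per_individual = 3,
                   unaffected_region = NULL, seed = seed, ...)
}
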
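# Pairwise comparative analysis: does phylogenetic distance or body-size
# difference predict how two species behave towards each other?

#' Patristic distances between species on a phylogeny
#'
#' Computes, for every pair of requested species, the sum of branch
#' lengths along the unique path connecting their tips. The tree is read
#' with [ape::read.tree()] (Newick) but the path sums are computed here by
#' accumulating root-to-tip paths and subtracting twice the depth of the
#' most recent common ancestor.
#'
#' @param tree a Newick string, a path to a Newick file, or an
#'   [ape::phylo] object with branch lengths.
#' @param species character vector of tip labels to include; default all
#'   tips.
#' @return symmetric numeric matrix of patristic distances with zero
#'   diagonal, rows/columns named by species.
#' @export
patristic_distances <- function(tree, species = NULL) {
  phy <- as_phylo_tree(tree)
  if (is.null(phy$edge.length) || anyNA(phy$edge.length)) {
    stop("tree must have branch lengths on every edge")
  }
  tips <- phy$tip.label
  if (is.null(species)) species <- tips
  missing <- setdiff(species, tips)
  if (length(missing)) {
    stop("species not found in tree: ", paste(missing, collapse = ", "))
  }

  ntip <- length(tips)
  nnode <- ntip + phy$Nnode
  parent <- integer(nnode)
  plen <- numeric(nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  plen[phy$edge[, 2]] <- phy$edge.length

  # root-to-node path (node indices) and cumulative depth for each tip
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  depth <- numeric(nnode)
  anc <- vector("list", ntip)
  for (tip in seq_len(ntip)) {
    node <- tip
    path <- node
    d <- 0
    while (node != root) {
      d <- d + plen[node]
      node <- parent[node]
      path <- c(path, node)
    }
    depth[tip] <- d
    anc[[tip]] <- path
  }
  # depth of every internal node (walk up once from any containing path)
  for (tip in seq_len(ntip)) {
    path <- anc[[tip]]
    d <- depth[tip]
    for (node in path) {
      depth[node] <- d
      d <- d - plen[node]
    }
  }

  idx <- match(species, tips)
  k <- length(species)
  out <- matrix(0, k, k, dimnames = list(species, species))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      a <- idx[i]; b <- idx[j]
      mrca <- intersect(anc[[a]], anc[[b]])[1]
      out[i, j] <- out[j, i] <- depth[a] + depth[b] - 2 * depth[mrca]
    }
  }
  out
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  tree <- as.character(tree)
  phy <- if (file.exists(tree)) ape::read.tree(tree)
         else ape::read.tree(text = tree)
  if (is.null(phy)) stop("could not parse Newick tree")
  phy
}

#' Body-size difference between two species
#'
#' Absolute difference in maximum body length, symmetric in its
#' arguments.
#'
#' @param traits data frame with columns `species` and `max_length_cm`.
#' @param a,b species labels.
#' @return `|length_a - length_b|` in cm.
#' @export
body_size_difference <- function(traits, a, b) {
  sp <- canonical_species(traits$species)
  ia <- match(canonical_species(a), sp)
  ib <- match(canonical_species(b), sp)
  if (anyNA(ia) || anyNA(ib)) {
    miss <- unique(c(a[is.na(ia)], b[is.na(ib)]))
    stop("species missing from trait table: ", paste(miss, collapse = ", "))
  }
  abs(traits$max_length_cm[ia] - traits$max_length_cm[ib])
}

#' Build the per-pair response table for comparative regressions
#'
#' One row per heterospecific species pair (conspecific pairs carry zero
#' phylogenetic distance and are excluded): mean proximity over the
#' pair's encounters, signal/chase counts over its aggressive encounters,
#' and the CV of its capped chase distances when the pair has at least
#' `min_chases` chases. Each response may therefore have a different
#' number of usable pairs.
#'
#' @param records validated, pair-filtered encounter data frame.
#' @param distances patristic distance matrix from
#'   [patristic_distances()].
#' @param traits trait table (`species`, `max_length_cm`).
#' @param min_chases minimum chases for a pair's chase CV, default 5.
#' @param cap chase-distance cap in metres passed to
#'   [cap_chase_distance()], default 10.
#' @return data frame with columns species_a, species_b, n_encounters,
#'   mean_proximity, n_signal, n_chase, chase_cv, phylo_distance,
#'   size_difference_cm.
#' @export
build_pair_observations <- function(records, distances, traits,
                                    min_chases = 5L, cap = 10) {
  het <- records[records$class == "heterospecific", , drop = FALSE]
  if (nrow(het) == 0L) {
    return(data.frame(species_a = character(), species_b = character(),
                      n_encounters = integer(), mean_proximity = numeric(),
                      n_signal = integer(), n_chase = integer(),
                      chase_cv = numeric(), phylo_distance = numeric(),
                      size_difference_cm = numeric(),
                      stringsAsFactors = FALSE))
  }
  keys <- sort(unique(het$pair))
  ab <- strsplit(keys, "|", fixed = TRUE)
  sp_a <- vapply(ab, `[`, "", 1L)
  sp_b <- vapply(ab, `[`, "", 2L)

  rows <- lapply(seq_along(keys), function(i) {
    sub <- het[het$pair == keys[i], , drop = FALSE]
    chases <- cap_chase_distance(
      sub$chase_distance_m[sub$outcome == "chase"], cap = cap)
    cv <- if (length(chases) >= max(min_chases, 2L) && mean(chases) > 0) {
      coefficient_of_variation(chases)
    } else NA_real_
    data.frame(
      species_a = sp_a[i], species_b = sp_b[i],
      n_encounters = nrow(sub),
      mean_proximity = mean(sub$proximity_cat),
      n_signal = sum(sub$outcome == "signal"),
      n_chase = sum(sub$outcome == "chase"),
      chase_cv = cv, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  dn <- canonical_species(rownames(distances))
  ia <- match(out$species_a, dn)
  ib <- match(out$species_b, dn)
  if (anyNA(ia) || anyNA(ib)) {
    miss <- unique(c(out$species_a[is.na(ia)], out$species_b[is.na(ib)]))
    stop("species missing from distance matrix: ",
         paste(miss, collapse = ", "))
  }
  out$phylo_distance <- distances[cbind(ia, ib)]
  out$size_difference_cm <- body_size_difference(traits, out$species_a,
                                                 out$species_b)
  rownames(out) <- NULL
  out
}

mcfadden_r2 <- function(fit, null_fit) {
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(null_fit))
  if (ll0 == 0) return(0)
  max(0, 1 - ll / ll0)
}

new_regression_result <- function(fit, model, n, mcfadden = NA_real_,
                                  adjusted_r2 = NA_real_,
                                  model_p = NA_real_, notes = character()) {
  cf <- stats::coef(fit)
  structure(
    list(model = model,
         intercept = unname(cf["(Intercept)"]),
         coefficients = cf[setdiff(names(cf), "(Intercept)")],
         model_p = model_p, adjusted_r2 = adjusted_r2,
         mcfadden_r2 = mcfadden, n_pairs = n, fit = fit, notes = notes),
    class = "pair_regression"
  )
}

#' @export
print.pair_regression <- function(x, ...) {
  cat("\n\tPairwise comparative regression:", x$model, "\n\n")
  cat(sprintf("n pairs = %d\n", x$n_pairs))
  print(round(c("(Intercept)" = x$intercept, x$coefficients), 4))
  if (!is.na(x$adjusted_r2)) {
    # human summary floors a (possible) negative adjusted R^2 at zero;
    # the stored value is raw
    cat(sprintf("adjusted R^2 = %.3f, model p = %.3g\n",
                max(0, x$adjusted_r2), x$model_p))
  }
  if (!is.na(x$mcfadden_r2)) {
    cat(sprintf("McFadden R^2 = %.3f\n", x$mcfadden_r2))
  }
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Ordinary least-squares model of a pairwise response
#'
#' Fits `y ~ phylo_distance + size_difference_cm` by OLS and reports the
#' coefficient vector, the overall model F-test p-value and the adjusted
#' R-squared (stored raw; possibly negative).
#'
#' @param pairs pair-observation data frame from
#'   [build_pair_observations()].
#' @param response name of the response column (e.g. `"mean_proximity"`
#'   or `"chase_cv"`).
#' @return object of class `pair_regression`.
#' @export
fit_linear_model <- function(pairs, response) {
  dat <- pairs[is.finite(pairs[[response]]), , drop = FALSE]
  if (nrow(dat) < 4L) {
    stop("need at least 4 complete pairs to fit the linear model")
  }
  notes <- character()
  X <- cbind(1, dat$phylo_distance, dat$size_difference_cm)
  if (kappa(X, exact = TRUE) > 1e8) {
    notes <- c(notes, "predictors near-collinear (condition number > 1e8)")
    warning("predictors are near-collinear")
  }
  f <- stats::as.formula(paste(response,
                               "~ phylo_distance + size_difference_cm"))
  fit <- stats::lm(f, data = dat)
  sm <- summary(fit)
  model_p <- if (is.null(sm$fstatistic)) NA_real_ else {
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  }
  adj <- sm$adj.r.squared
  if (stats::var(dat[[response]]) == 0) {
    # constant response: the F test is undefined and any nonzero slope
    # is numerical noise
    adj <- 0; model_p <- 1
    fit$coefficients[-1] <- 0
  }
  new_regression_result(fit, paste("linear:", response), nrow(dat),
                        adjusted_r2 = adj, model_p = model_p,
                        notes = notes)
}

#' Binomial GLM of per-pair signalling proportions
#'
#' Models the number of aggressive encounters resolved by signalling
#' (successes) against chases (failures) with a logit-link binomial GLM
#' on phylogenetic distance and body-size difference, and reports
#' McFadden's pseudo R-squared, 1 - logLik(model)/logLik(intercept-only).
#'
#' @param pairs pair-observation data frame; rows with no aggressive
#'   encounters are dropped.
#' @param intercept_only fit the null model alone (used for the McFadden
#'   baseline and available for diagnostics).
#' @return object of class `pair_regression`.
#' @export
fit_binomial_glm <- function(pairs, intercept_only = FALSE) {
  dat <- pairs[pairs$n_signal + pairs$n_chase >= 1L, , drop = FALSE]
  if (nrow(dat) < 4L) {
    stop("need at least 4 pairs with aggressive encounters")
  }
  y <- cbind(dat$n_signal, dat$n_chase)
  null_fit <- stats::glm(y ~ 1, family = stats::binomial())
  if (intercept_only) {
    return(new_regression_result(null_fit, "binomial: signalling (null)",
                                 nrow(dat), mcfadden = 0))
  }
  fit <- stats::glm(y ~ phylo_distance + size_difference_cm,
                    data = dat, family = stats::binomial())
  notes <- character()
  mu <- stats::fitted(fit)
  if (!fit$converged || any(mu < 1e-8) || any(mu > 1 - 1e-8)) {
    notes <- c(notes,
               "possible complete separation: fitted probabilities at 0/1")
    warning("possible complete separation in signalling GLM")
  }
  new_regression_result(fit, "binomial: signalling", nrow(dat),
                        mcfadden = mcfadden_r2(fit, null_fit),
                        notes = notes)
}
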
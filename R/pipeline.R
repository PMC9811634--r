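# End-to-end analysis pipeline. run_agonistic_analysis() is the package's
# "fitting function": it takes a run configuration (file inputs or a
# generator scenario), applies the inclusion filters, runs the four
# prediction analyses and returns a classed report with print/summary/plot
# methods and a deterministic machine-readable serialization.

#' Run configuration for the encounter analysis pipeline
#'
#' Exactly one of `paths` (a list with `encounters`, `tree`, `traits`) or
#' `scenario` (a [generator_config()]) must be supplied.
#'
#' @param paths list of input file paths: `encounters` (delimited text),
#'   `tree` (Newick), `traits` (delimited text with species,
#'   max_length_cm).
#' @param scenario a [generator_config()] used to simulate the inputs.
#' @param min_encounters,min_individuals pair inclusion filter, defaults
#'   5 and 5.
#' @param filter_by_period apply the pair filter within period rather
#'   than pooled across periods.
#' @param excluded_after_regions region labels whose after-period records
#'   are dropped (regions that escaped the disturbance). For generated
#'   data, defaults to the scenario's unaffected region.
#' @param n_permutations Monte-Carlo permutations per test, default
#'   10000.
#' @param n_bootstrap bootstrap replicates (one encounter per
#'   individual), default 1000.
#' @param cap_m chase-distance cap (m), default 10.
#' @param min_chases minimum chases for a pair-level or class-level chase
#'   CV, default 5.
#' @param mslr_nr parametric-bootstrap replicates inside the CV-equality
#'   test, default 1000.
#' @param regressions_by_period fit the comparative regressions within
#'   period instead of pooled (default pools).
#' @param seed master seed; child seeds for every random procedure are
#'   derived from it and recorded in the report.
#' @return object of class `run_config`.
#' @export
run_config <- function(paths = NULL, scenario = NULL,
                       min_encounters = 5L, min_individuals = 5L,
                       filter_by_period = FALSE,
                       excluded_after_regions = NULL,
                       n_permutations = 10000L, n_bootstrap = 1000L,
                       cap_m = 10, min_chases = 5L, mslr_nr = 1000L,
                       regressions_by_period = FALSE, seed = 1L) {
  if (is.null(paths) == is.null(scenario)) {
    stop("exactly one of 'paths' or 'scenario' must be supplied")
  }
  if (!is.null(paths)) {
    need <- c("encounters", "tree", "traits")
    if (!all(need %in% names(paths))) {
      stop("paths must name: ", paste(need, collapse = ", "))
    }
  }
  if (is.null(excluded_after_regions) && !is.null(scenario) &&
      !is.null(scenario$unaffected_region)) {
    excluded_after_regions <- sprintf("region%02d",
                                      scenario$unaffected_region)
  }
  structure(
    list(paths = paths, scenario = scenario,
         min_encounters = as.integer(min_encounters),
         min_individuals = as.integer(min_individuals),
         filter_by_period = isTRUE(filter_by_period),
         excluded_after_regions = excluded_after_regions,
         n_permutations = as.integer(n_permutations),
         n_bootstrap = as.integer(n_bootstrap),
         cap_m = cap_m, min_chases = as.integer(min_chases),
         mslr_nr = as.integer(mslr_nr),
         regressions_by_period = isTRUE(regressions_by_period),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

# deterministic child seeds below 2^31, derived from the master seed
derive_seeds <- function(seed, n = 24L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  sample.int(.Machine$integer.max - 1L, n)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$scenario)) {
    ds <- generate_dataset(config$scenario)
    list(records = ds$records, tree = ds$tree, traits = ds$traits)
  } else {
    records <- read_encounters(config$paths$encounters)
    traits <- utils::read.csv(config$paths$traits,
                              stringsAsFactors = FALSE)
    if (!all(c("species", "max_length_cm") %in% names(traits))) {
      stop("trait table must have columns species, max_length_cm")
    }
    tree <- paste(readLines(config$paths$tree, warn = FALSE),
                  collapse = "")
    list(records = records, tree = tree, traits = traits)
  }
}

#' Prediction 1: proximity of approach by encounter class
#'
#' For each period, compares per-individual mean proximity between
#' conspecific and heterospecific encounters with the Monte-Carlo
#' permutation rank test; also tabulates proximity categories restricted
#' to aggressive encounters.
#'
#' @param records filtered encounter data frame.
#' @param n_permutations,seed Monte-Carlo controls.
#' @return list per period: `means` (class-wise mean of individual
#'   means), `test` (a `perm_test`), `aggressive_proximity` (class x
#'   category count table), or a skip note when a class is absent.
#' @export
run_prediction1 <- function(records, n_permutations = 10000L, seed = 1L) {
  out <- list()
  seeds <- derive_seeds(seed, 4L)
  i <- 0L
  for (per in PERIOD_LEVELS) {
    i <- i + 1L
    sub <- records[records$period == per, , drop = FALSE]
    summ <- individual_mean_proximity(sub)
    con <- summ$mean_proximity[summ$class == "conspecific"]
    het <- summ$mean_proximity[summ$class == "heterospecific"]
    aggr <- sub[sub$outcome != "passive", , drop = FALSE]
    prox_tab <- table(factor(aggr$class,
                             c("conspecific", "heterospecific")),
                      factor(aggr$proximity_cat, 1:4))
    if (length(con) == 0L || length(het) == 0L) {
      out[[per]] <- list(skipped = TRUE,
                         note = "a class has no individuals in this period")
      next
    }
    test <- mwu_permutation_test(het, con, alternative = "two.sided",
                                 n_resamples = n_permutations,
                                 seed = seeds[i])
    out[[per]] <- list(
      skipped = FALSE,
      means = c(conspecific = mean(con), heterospecific = mean(het)),
      n_individuals = c(conspecific = length(con),
                        heterospecific = length(het)),
      test = test,
      aggressive_proximity = prox_tab
    )
  }
  out
}

# inner test handed to the bootstrap: chi-squared permutation on the
# signalling/chase split of a one-encounter-per-individual dataset
signalling_inner_test <- function(label_col, n_permutations, seed) {
  force(label_col); force(n_permutations)
  call_no <- 0L
  function(records) {
    call_no <<- call_no + 1L
    aggr <- records[records$outcome %in% c("signal", "chase"), ,
                    drop = FALSE]
    labs <- aggr[[label_col]]
    if (nrow(aggr) == 0L || length(unique(labs)) < 2L) {
      return(list(statistic = NA_real_, p_value = NA_real_))
    }
    # fresh permutation stream per replicate, still fully deterministic
    chisq_permutation_test(labs, aggr$outcome,
                           n_resamples = n_permutations,
                           seed = (seed + call_no) %% .Machine$integer.max)
  }
}

#' Prediction 2: contest resolution by signalling
#'
#' Four bootstrap-wrapped permutation chi-squared contrasts of the
#' signal/chase split: class within each period, and period within each
#' class. Each bootstrap replicate keeps one encounter per focal
#' individual before cross-tabulating.
#'
#' @param records filtered encounter data frame.
#' @param n_bootstrap,n_permutations,seed resampling controls.
#' @return list of contrasts, each a `bootstrap_test` plus the observed
#'   signalling proportions, or a skip note for empty cells.
#' @export
run_prediction2 <- function(records, n_bootstrap = 1000L,
                            n_permutations = 2000L, seed = 1L) {
  aggr <- records[records$outcome %in% c("signal", "chase"), ,
                  drop = FALSE]
  seeds <- derive_seeds(seed, 8L)
  contrasts <- list(
    class_before = list(filter = quote(period == "before"),
                        label = "class"),
    class_after = list(filter = quote(period == "after"),
                       label = "class"),
    period_conspecific = list(filter = quote(class == "conspecific"),
                              label = "period"),
    period_heterospecific = list(filter = quote(class == "heterospecific"),
                                 label = "period")
  )
  out <- list()
  for (i in seq_along(contrasts)) {
    nm <- names(contrasts)[i]
    cdef <- contrasts[[i]]
    sub <- aggr[eval(cdef$filter, aggr), , drop = FALSE]
    levs <- unique(sub[[cdef$label]])
    if (nrow(sub) == 0L || length(levs) < 2L) {
      out[[nm]] <- list(skipped = TRUE, note = "empty contrast cell")
      next
    }
    props <- vapply(split(sub, sub[[cdef$label]]), function(d) {
      as.numeric(signalling_proportion(d))
    }, numeric(1))
    boot <- bootstrap_one_per_individual(
      sub,
      inner_test = signalling_inner_test(cdef$label, n_permutations,
                                         seeds[2 * i]),
      B = n_bootstrap, seed = seeds[2 * i - 1L]
    )
    out[[nm]] <- list(skipped = FALSE, signalling_proportions = props,
                      table = table(sub[[cdef$label]], sub$outcome),
                      bootstrap = boot)
  }
  out
}

#' Prediction 3: variability of chase distances
#'
#' Pools capped chase distances by encounter class and compares the class
#' CVs per period with the CV-equality test, on both the main (pair
#' inclusion filter only) subset and the matched-species subset; class
#' mean chase distances are reported alongside.
#'
#' @param records filtered encounter data frame (main subset).
#' @param matched_records matched-subset data frame (may be the same).
#' @param cap_m chase cap (m).
#' @param mslr_nr,seed CV-test bootstrap controls.
#' @return nested list: subset -> period -> `cv_comparison` plus class
#'   means and counts, or a skip note.
#' @export
run_prediction3 <- function(records, matched_records, cap_m = 10,
                            mslr_nr = 1000L, seed = 1L) {
  seeds <- derive_seeds(seed, 8L)
  subsets <- list(min5 = records, matched = matched_records)
  out <- list()
  i <- 0L
  for (sname in names(subsets)) {
    sub_out <- list()
    for (per in PERIOD_LEVELS) {
      i <- i + 1L
      sub <- subsets[[sname]]
      chases <- sub[sub$period == per & sub$outcome == "chase", ,
                    drop = FALSE]
      d <- cap_chase_distance(chases$chase_distance_m, cap = cap_m)
      groups <- split(d, factor(chases$class,
                                c("conspecific", "heterospecific")))
      ns <- lengths(groups)
      if (any(ns < 2L)) {
        sub_out[[per]] <- list(skipped = TRUE,
                               note = "a class has fewer than 2 chases")
        next
      }
      sub_out[[per]] <- list(
        skipped = FALSE,
        mean_chase_m = vapply(groups, mean, numeric(1)),
        n_chases = ns,
        comparison = mslr_test(groups, nr = mslr_nr, seed = seeds[i])
      )
    }
    # before-vs-after within each class
    for (cls in c("conspecific", "heterospecific")) {
      sub <- subsets[[sname]]
      chases <- sub[sub$class == cls & sub$outcome == "chase", ,
                    drop = FALSE]
      d <- cap_chase_distance(chases$chase_distance_m, cap = cap_m)
      groups <- split(d, factor(chases$period, PERIOD_LEVELS))
      if (any(lengths(groups) < 2L)) {
        sub_out[[paste0("period_", cls)]] <-
          list(skipped = TRUE, note = "a period has fewer than 2 chases")
        next
      }
      i_extra <- (match(sname, names(subsets)) - 1L) * 2L +
        match(cls, c("conspecific", "heterospecific")) + 4L
      sub_out[[paste0("period_", cls)]] <- list(
        skipped = FALSE,
        mean_chase_m = vapply(groups, mean, numeric(1)),
        n_chases = lengths(groups),
        comparison = mslr_test(groups, nr = mslr_nr, seed = seeds[i_extra])
      )
    }
    out[[sname]] <- sub_out
  }
  out
}

#' Prediction 4: comparative regressions on pairwise behaviour
#'
#' Builds the heterospecific pair-observation table and fits three
#' models: OLS for mean proximity and for chase-distance CV, and a
#' binomial GLM (with McFadden's pseudo R-squared) for the signalling
#' proportion, each on patristic distance and body-size difference.
#'
#' @param records filtered encounter data frame.
#' @param tree Newick string or `phylo`.
#' @param traits trait table.
#' @param min_chases,cap_m pair chase-CV controls.
#' @return list with `pairs` (the observation table) and the three
#'   regression results (skip notes where rows are insufficient).
#' @export
run_prediction4 <- function(records, tree, traits, min_chases = 5L,
                            cap_m = 10) {
  species <- unique(c(records$focal_species, records$partner_species))
  distances <- patristic_distances(tree, species)
  pairs <- build_pair_observations(records, distances, traits,
                                   min_chases = min_chases, cap = cap_m)
  fit_or_note <- function(expr) {
    tryCatch(expr, error = function(e) list(skipped = TRUE,
                                            note = conditionMessage(e)))
  }
  list(
    pairs = pairs,
    proximity = fit_or_note(fit_linear_model(pairs, "mean_proximity")),
    signalling = fit_or_note(fit_binomial_glm(pairs)),
    chase_cv = fit_or_note(fit_linear_model(pairs, "chase_cv"))
  )
}

#' Run the full agonistic-encounter analysis
#'
#' Loads or generates the inputs, validates them, drops after-period
#' records from unaffected regions, applies the pair inclusion filter and
#' builds the matched subset, then runs all four prediction analyses.
#' Stages after filtering are independent: an error in one prediction is
#' recorded in the report and the remaining stages still run.
#'
#' @param config a [run_config()].
#' @return object of class `agonistic_report`.
#' @export
run_agonistic_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 8L)
  inputs <- load_pipeline_inputs(config)
  records <- inputs$records
  if (!is.null(config$excluded_after_regions)) {
    records <- suppressWarnings(
      exclude_after_period(records, config$excluded_after_regions))
  }
  flt <- apply_pair_filter(records, config$min_encounters,
                           config$min_individuals,
                           by_period = config$filter_by_period)
  main <- flt$records
  matched <- build_matched_subset(records, config$min_encounters,
                                  config$min_individuals,
                                  by_period = config$filter_by_period)

  stage <- function(expr) {
    tryCatch(expr, error = function(e) list(failed = TRUE,
                                            error = conditionMessage(e)))
  }
  p1 <- stage(run_prediction1(main, config$n_permutations, seeds[1]))
  p1_matched <- stage(run_prediction1(matched, config$n_permutations,
                                      seeds[2]))
  p2 <- stage(run_prediction2(main, config$n_bootstrap,
                              n_permutations = min(config$n_permutations,
                                                   2000L),
                              seed = seeds[3]))
  p3 <- stage(run_prediction3(main, matched, cap_m = config$cap_m,
                              mslr_nr = config$mslr_nr, seed = seeds[4]))
  p4 <- stage(run_prediction4(main, inputs$tree, inputs$traits,
                              min_chases = config$min_chases,
                              cap_m = config$cap_m))

  structure(
    list(config = config,
         n_input_records = nrow(inputs$records),
         n_analysis_records = nrow(main),
         n_matched_records = nrow(matched),
         audit = flt$audit,
         prediction1 = p1, prediction1_matched = p1_matched,
         prediction2 = p2, prediction3 = p3, prediction4 = p4,
         seeds = list(master = config$seed, children = seeds),
         software = list(package = "agonistics",
                         version = as.character(
                           utils::packageVersion("agonistics")))),
    class = "agonistic_report"
  )
}

#' @export
print.agonistic_report <- function(x, ...) {
  cat("Agonistic encounter analysis\n")
  cat(sprintf("  records: %d input, %d after inclusion filter, %d matched\n",
              x$n_input_records, x$n_analysis_records,
              x$n_matched_records))
  cat(sprintf("  master seed %d; permutations %d; bootstrap B %d\n",
              x$seeds$master, x$config$n_permutations,
              x$config$n_bootstrap))
  cat("Components: prediction1 (proximity), prediction2 (signalling),",
      "\n  prediction3 (chase CV), prediction4 (comparative models).",
      "\nUse summary() for the result tables.\n")
  invisible(x)
}

#' @export
summary.agonistic_report <- function(object, ...) {
  x <- object
  cat("== Proximity (per-individual means, permutation rank test) ==\n")
  for (per in names(x$prediction1)) {
    r <- x$prediction1[[per]]
    if (isTRUE(r$skipped)) { cat(per, ": skipped -", r$note, "\n"); next }
    cat(sprintf(
      "%s: con %.3f vs het %.3f  (Z = %.3f, p = %.4g, n = %d/%d)\n",
      per, r$means["conspecific"], r$means["heterospecific"],
      r$test$statistic, r$test$p_value, r$n_individuals["conspecific"],
      r$n_individuals["heterospecific"]))
  }
  cat("\n== Signalling (bootstrap x permutation chi-squared) ==\n")
  for (nm in names(x$prediction2)) {
    r <- x$prediction2[[nm]]
    if (isTRUE(r$skipped)) { cat(nm, ": skipped -", r$note, "\n"); next }
    b <- r$bootstrap
    cat(sprintf(
      "%s: X2 = %.3f [%.3f, %.3f], p = %.3f [%.3f, %.3f]\n",
      nm, b$mean_statistic, b$ci95_statistic[1], b$ci95_statistic[2],
      b$mean_p, b$ci95_p[1], b$ci95_p[2]))
  }
  cat("\n== Chase-distance variability (CV equality) ==\n")
  for (sname in names(x$prediction3)) {
    for (nm in names(x$prediction3[[sname]])) {
      r <- x$prediction3[[sname]][[nm]]
      if (isTRUE(r$skipped)) next
      cmp <- r$comparison
      cat(sprintf("%s/%s: CVs %s; MSLR = %.3f, p = %.3f\n", sname, nm,
                  paste(sprintf("%s %.3f", cmp$group_labels,
                                cmp$group_cvs), collapse = ", "),
                  cmp$statistic_mslrt, cmp$p_mslrt))
    }
  }
  cat("\n== Comparative models (phylo distance + size difference) ==\n")
  for (nm in c("proximity", "signalling", "chase_cv")) {
    r <- x$prediction4[[nm]]
    if (is.null(r) || isTRUE(r$skipped)) { cat(nm, ": skipped\n"); next }
    if (!is.na(r$adjusted_r2)) {
      cat(sprintf("%s: adj R^2 = %.3f, p = %.3g, n = %d\n", nm,
                  max(0, r$adjusted_r2), r$model_p, r$n_pairs))
    } else {
      cat(sprintf("%s: McFadden R^2 = %.3f, n = %d\n", nm,
                  r$mcfadden_r2, r$n_pairs))
    }
  }
  invisible(x)
}

#' @export
plot.agonistic_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  for (per in names(x$prediction1)) {
    r <- x$prediction1[[per]]
    if (isTRUE(r$skipped)) next
    tab <- r$aggressive_proximity
    graphics::barplot(as.matrix(tab), beside = TRUE,
                      names.arg = colnames(tab),
                      legend.text = rownames(tab),
                      xlab = "proximity category (25 cm bins)",
                      ylab = "aggressive encounters",
                      main = paste("aggressive proximity,", per), ...)
  }
  invisible(x)
}

report_to_list <- function(x) {
  strip <- function(v) {
    if (inherits(v, c("perm_test", "bootstrap_test", "cv_comparison"))) {
      v <- unclass(v)
      v$per_replicate <- NULL
      lapply(v, strip)
    } else if (inherits(v, "pair_regression")) {
      list(model = v$model, intercept = v$intercept,
           coefficients = as.list(v$coefficients),
           model_p = v$model_p, adjusted_r2 = v$adjusted_r2,
           mcfadden_r2 = v$mcfadden_r2, n_pairs = v$n_pairs,
           notes = v$notes)
    } else if (inherits(v, "run_config") ||
               inherits(v, "generator_config")) {
      lapply(unclass(v), strip)
    } else if (is.table(v) || is.matrix(v)) {
      list(dimnames = dimnames(v),
           values = as.vector(v))
    } else if (is.data.frame(v)) {
      as.list(v)
    } else if (is.list(v)) {
      lapply(v, strip)
    } else v
  }
  strip(list(
    software = x$software,
    seeds = x$seeds,
    n_records = list(input = x$n_input_records,
                     analysis = x$n_analysis_records,
                     matched = x$n_matched_records),
    config = x$config,
    audit = x$audit,
    prediction1 = x$prediction1,
    prediction1_matched = x$prediction1_matched,
    prediction2 = x$prediction2,
    prediction3 = x$prediction3,
    prediction4 = x$prediction4
  ))
}

#' Write the machine-readable run report
#'
#' Serializes the report (without bulky per-replicate traces) to JSON and
#' the audit table to CSV. The JSON is byte-identical across runs with
#' the same inputs and master seed.
#'
#' @param report an `agonistic_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(report = file.path(dir, "report.json"),
                audit = file.path(dir, "audit.csv"))
  json <- jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
  writeLines(json, paths$report)
  utils::write.csv(report$audit, paths$audit, row.names = FALSE)
  invisible(paths)
}
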
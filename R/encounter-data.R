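# Encounter records are plain data frames with the columns below. All
# functions in the package validate on entry rather than relying on a
# formal class, so users can build records with read_encounters(),
# generate_dataset(), or by hand.
ENCOUNTER_COLUMNS <- c(
  "region", "reef", "period", "focal_id", "focal_species",
  "partner_species", "proximity_cat", "outcome", "chase_distance_m"
)

PERIOD_LEVELS  <- c("before", "after")
OUTCOME_LEVELS <- c("passive", "signal", "chase")

# Field protocol bins the closest approach to the nearest 25 cm within 1 m.
PROXIMITY_LABELS <- c(
  "0-24 cm" = 1L, "25-49 cm" = 2L, "50-74 cm" = 3L, "75-100 cm" = 4L
)

#' Canonicalize a species label
#'
#' Trims surrounding whitespace, collapses internal runs of whitespace to a
#' single space, and case-folds to lower case. No taxonomic synonym
#' resolution is attempted.
#'
#' @param x character vector of species labels.
#' @return character vector of canonical labels.
#' @export
canonical_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

#' Classify an encounter as conspecific or heterospecific
#'
#' An encounter is conspecific when the focal and partner species labels
#' match exactly after canonicalization (see [canonical_species()]).
#'
#' @param focal_species,partner_species character vectors of species labels.
#' @return character vector, `"conspecific"` or `"heterospecific"`.
#' @export
classify_encounter <- function(focal_species, partner_species) {
  f <- canonical_species(focal_species)
  p <- canonical_species(partner_species)
  if (any(!nzchar(f)) || any(!nzchar(p))) {
    stop("species labels must be non-empty")
  }
  ifelse(f == p, "conspecific", "heterospecific")
}

#' Unordered species-pair key
#'
#' Builds an order-independent key for a species pair: labels are
#' canonicalized and sorted, so `pair_key(x, y)` equals `pair_key(y, x)`.
#'
#' @param species_a,species_b character vectors of species labels.
#' @return character vector of keys of the form `"a|b"` with `a <= b`.
#' @export
pair_key <- function(species_a, species_b) {
  a <- canonical_species(species_a)
  b <- canonical_species(species_b)
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Individual identity is only unique within reef + period (the field search
# pattern cannot link individuals across periods), so every per-individual
# computation keys on this composite.
individual_key <- function(records) {
  paste(records$region, records$reef, records$period, records$focal_id,
        sep = "\r")
}

map_proximity_labels <- function(x) {
  raw <- trimws(as.character(x))
  # normalise unicode dashes and drop the unit so "0–24cm" matches
  norm <- gsub("[‒–—―]", "-", raw)
  norm <- tolower(gsub("\\s+", "", norm))
  lab <- sub("cm$", "", norm)
  key <- sub("cm$", "", tolower(gsub("\\s+", "", names(PROXIMITY_LABELS))))
  out <- PROXIMITY_LABELS[match(lab, key)]
  # plain integers 1-4 pass through
  num <- suppressWarnings(as.integer(raw))
  out[is.na(out)] <- num[is.na(out)]
  unname(out)
}

#' Validate a table of encounter records
#'
#' Checks every row against the encounter-record invariants: period must be
#' `before`/`after`, proximity category in 1--4 (encounters are defined
#' within 1 m), outcome one of `passive`/`signal`/`chase`, and a chase
#' distance present if and only if the outcome is `chase`.
#'
#' @param records data frame with the encounter columns.
#' @param collect_rejects if `TRUE`, return invalid rows with reasons in an
#'   attribute instead of erroring.
#' @return the validated data frame (invalid rows removed when
#'   `collect_rejects = TRUE`), with canonicalized species labels, a
#'   `class` column (`conspecific`/`heterospecific`) and a `pair` column
#'   (unordered pair key) appended. When `collect_rejects = TRUE` the
#'   attribute `"rejects"` holds a data frame of row numbers and reasons.
#' @export
validate_encounters <- function(records, collect_rejects = FALSE) {
  records <- as.data.frame(records)
  missing_cols <- setdiff(ENCOUNTER_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }

  n <- nrow(records)
  reasons <- character(n)
  add_reason <- function(bad, msg) {
    bad <- which(bad)
    reasons[bad] <<- ifelse(nzchar(reasons[bad]),
                            paste(reasons[bad], msg, sep = "; "), msg)
  }

  records$period  <- tolower(trimws(as.character(records$period)))
  records$outcome <- tolower(trimws(as.character(records$outcome)))
  records$proximity_cat <- map_proximity_labels(records$proximity_cat)
  records$chase_distance_m <- suppressWarnings(
    as.numeric(records$chase_distance_m))

  add_reason(!records$period %in% PERIOD_LEVELS,
             "period must be 'before' or 'after'")
  add_reason(!records$outcome %in% OUTCOME_LEVELS,
             "outcome must be passive/signal/chase")
  add_reason(is.na(records$proximity_cat) |
               !records$proximity_cat %in% 1:4,
             "proximity_cat must be an integer 1-4 (or a 25 cm bin label)")
  is_chase <- records$outcome == "chase"
  has_d <- !is.na(records$chase_distance_m)
  add_reason(is_chase & !has_d, "chase outcome requires chase_distance_m")
  add_reason(!is_chase & has_d & records$outcome %in% OUTCOME_LEVELS,
             "chase_distance_m present for non-chase outcome")
  add_reason(has_d & records$chase_distance_m < 0,
             "chase_distance_m must be non-negative")
  add_reason(!nzchar(trimws(as.character(records$focal_species))) |
               !nzchar(trimws(as.character(records$partner_species))),
             "species labels must be non-empty")

  bad <- nzchar(reasons)
  if (any(bad) && !collect_rejects) {
    stop("invalid encounter record(s) at row(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "),
         if (sum(bad) > 5L) sprintf(" (and %d more)", sum(bad) - 5L) else "",
         ": ", reasons[which(bad)[1L]])
  }

  rejects <- data.frame(row = which(bad), reason = reasons[bad],
                        stringsAsFactors = FALSE)
  out <- records[!bad, , drop = FALSE]
  out$focal_species   <- canonical_species(out$focal_species)
  out$partner_species <- canonical_species(out$partner_species)
  out$class <- classify_encounter(out$focal_species, out$partner_species)
  out$pair  <- pair_key(out$focal_species, out$partner_species)
  rownames(out) <- NULL
  if (collect_rejects) attr(out, "rejects") <- rejects
  out
}

#' Read encounter records from a delimited text file
#'
#' Reads a comma- (default) or tab-delimited UTF-8 table with a header and
#' validates every row. Columns may be renamed via `column_map`. Proximity
#' may be coded as integers 1--4 or as the 25 cm bin labels
#' `"0-24 cm"` ... `"75-100 cm"` (any dash style).
#'
#' @param path path to the file.
#' @param sep field delimiter, `","` or `"\t"`.
#' @param column_map named character vector mapping file column names to the
#'   canonical names, e.g. `c(site = "reef")` renames `site` to `reef`.
#' @param collect_rejects passed to [validate_encounters()].
#' @return validated encounter data frame (see [validate_encounters()]).
#' @export
read_encounters <- function(path, sep = ",", column_map = NULL,
                            collect_rejects = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8",
                          colClasses = "character")
  if (!is.null(column_map)) {
    idx <- match(names(column_map), names(df))
    if (anyNA(idx)) {
      stop("column_map names not present in file: ",
           paste(names(column_map)[is.na(idx)], collapse = ", "))
    }
    names(df)[idx] <- unname(column_map)
  }
  if (!"chase_distance_m" %in% names(df)) df$chase_distance_m <- NA_character_
  df$chase_distance_m[!nzchar(trimws(df$chase_distance_m))] <- NA_character_
  missing_cols <- setdiff(ENCOUNTER_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("file is missing required column(s): ",
         paste(missing_cols, collapse = ", "),
         " (use column_map to rename)")
  }
  validate_encounters(df, collect_rejects = collect_rejects)
}

#' Inclusion filter on species pairs
#'
#' Keeps a species pair when it has at least `min_encounters` encounters
#' across at least `min_individuals` distinct focal individuals (defaults 5
#' and 5); records belonging to dropped pairs are removed. The audit table
#' lists every pair with both counts and the kept/dropped flag.
#'
#' @param records validated encounter data frame.
#' @param min_encounters,min_individuals minimum counts for a pair to be
#'   retained; both default to 5.
#' @param by_period if `TRUE`, apply the filter within each period
#'   separately (a pair may then be kept in one period only); the default
#'   pools across periods.
#' @return list with elements `records` (kept rows), `pairs` (kept pair
#'   keys) and `audit` (data frame with columns species_a, species_b,
#'   class, period, n_encounters, n_individuals, kept).
#' @export
apply_pair_filter <- function(records, min_encounters = 5L,
                              min_individuals = 5L, by_period = FALSE) {
  stopifnot(min_encounters >= 1L, min_individuals >= 1L)
  if (nrow(records) == 0L) {
    audit <- data.frame(species_a = character(), species_b = character(),
                        class = character(), period = character(),
                        n_encounters = integer(), n_individuals = integer(),
                        kept = logical(), stringsAsFactors = FALSE)
    return(list(records = records, pairs = character(), audit = audit))
  }
  grp <- if (by_period) paste(records$pair, records$period, sep = "\r")
         else records$pair
  ind <- individual_key(records)
  n_enc <- tapply(rep.int(1L, nrow(records)), grp, sum)
  n_ind <- tapply(ind, grp, function(k) length(unique(k)))
  keys <- names(n_enc)
  kept <- n_enc >= min_encounters & n_ind >= min_individuals

  first <- records[match(keys, grp), , drop = FALSE]
  ab <- strsplit(first$pair, "|", fixed = TRUE)
  audit <- data.frame(
    species_a = vapply(ab, `[`, "", 1L),
    species_b = vapply(ab, `[`, "", 2L),
    class = first$class,
    period = if (by_period) first$period else "pooled",
    n_encounters = as.integer(n_enc),
    n_individuals = as.integer(n_ind),
    kept = as.vector(kept),
    stringsAsFactors = FALSE
  )
  audit <- audit[order(audit$species_a, audit$species_b, audit$period), ,
                 drop = FALSE]
  rownames(audit) <- NULL
  keep_rows <- kept[match(grp, keys)]
  out <- records[keep_rows, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, pairs = sort(unique(out$pair)), audit = audit)
}

#' Matched-species subset
#'
#' Restricts the data to species that pass the pair inclusion filter in at
#' least one conspecific pair *and* at least one heterospecific pair, so
#' that class contrasts are not driven by a larger, more variable pool of
#' species on the heterospecific side. Because removing records can change
#' pair counts, the filter-and-restrict step is iterated to a fixed point,
#' which makes the operation idempotent.
#'
#' @inheritParams apply_pair_filter
#' @return data frame of retained records (rows of kept pairs whose focal
#'   species qualifies in both encounter classes).
#' @export
build_matched_subset <- function(records, min_encounters = 5L,
                                 min_individuals = 5L, by_period = FALSE) {
  prev_n <- -1L
  cur <- records
  while (nrow(cur) != prev_n) {
    prev_n <- nrow(cur)
    flt <- apply_pair_filter(cur, min_encounters, min_individuals, by_period)
    kept <- flt$audit[flt$audit$kept, , drop = FALSE]
    con_sp <- kept$species_a[kept$class == "conspecific"]
    het_sp <- unique(c(kept$species_a[kept$class == "heterospecific"],
                       kept$species_b[kept$class == "heterospecific"]))
    qual <- intersect(unique(con_sp), het_sp)
    cur <- flt$records[flt$records$focal_species %in% qual, , drop = FALSE]
  }
  rownames(cur) <- NULL
  cur
}

#' Drop after-period records from unaffected regions
#'
#' Regions that did not experience the disturbance contribute no
#' after-period contrast; their `after` records are removed while their
#' `before` records are untouched.
#'
#' @param records validated encounter data frame.
#' @param regions character vector of region labels to exclude in the
#'   after period. Unknown labels raise a warning, not an error.
#' @return filtered data frame.
#' @export
exclude_after_period <- function(records, regions) {
  if (length(regions) == 0L) return(records)
  unknown <- setdiff(regions, unique(records$region))
  if (length(unknown)) {
    warning("region label(s) not present in data: ",
            paste(unknown, collapse = ", "))
  }
  out <- records[!(records$period == "after" &
                     records$region %in% regions), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-individual mean proximity
#'
#' Averages the ordinal proximity codes (1--4, equal 25 cm widths) over
#' each focal individual's encounters, separately by encounter class and
#' period. One row is produced per (individual, class, period) with at
#' least one encounter. Averaging collapses repeated measures on the same
#' individual, the unit of the rank-based comparison.
#'
#' @param records validated encounter data frame.
#' @return data frame with columns focal_id, region, reef, period, class,
#'   mean_proximity, n_encounters.
#' @export
individual_mean_proximity <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(focal_id = character(), region = character(),
                      reef = character(), period = character(),
                      class = character(), mean_proximity = numeric(),
                      n_encounters = integer(), stringsAsFactors = FALSE))
  }
  grp <- paste(individual_key(records), records$class, sep = "\r")
  mean_prox <- tapply(records$proximity_cat, grp, mean)
  n_enc <- tapply(rep.int(1L, nrow(records)), grp, sum)
  first <- records[match(names(mean_prox), grp), , drop = FALSE]
  out <- data.frame(
    focal_id = first$focal_id, region = first$region, reef = first$reef,
    period = first$period, class = first$class,
    mean_proximity = as.vector(mean_prox),
    n_encounters = as.integer(n_enc), stringsAsFactors = FALSE
  )
  out <- out[order(out$region, out$reef, out$period, out$focal_id,
                   out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cap chase distances
#'
#' Rare long chases are grouped at the cap (default 10 m) to limit their
#' influence on dispersion statistics: values at or above the cap are
#' recorded as the cap itself.
#'
#' @param d numeric vector of chase distances (m), non-negative.
#' @param cap cap in metres, default 10.
#' @return `pmin(d, cap)`.
#' @export
cap_chase_distance <- function(d, cap = 10) {
  d <- as.numeric(d)
  if (any(d < 0, na.rm = TRUE)) stop("chase distances must be non-negative")
  pmin(d, cap)
}
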
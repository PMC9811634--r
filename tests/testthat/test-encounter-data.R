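test_that("reading a delimited file round-trips valid records", {
  df <- data.frame(
    region = "bali", reef = "reef1", period = "before",
    focal_id = c("f1", "f2", "f3"),
    focal_species = "C. trifascialis",
    partner_species = c("C. trifascialis", "C. baronessa", "C. lunula"),
    proximity_cat = c(1, "25-49 cm", "0–24 cm"),
    outcome = c("passive", "chase", "signal"),
    chase_distance_m = c(NA, 3.2, NA)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, na = "")
  rec <- read_encounters(path)
  expect_equal(nrow(rec), 3L)
  # bin labels (any dash style) map onto the ordinal codes
  expect_equal(rec$proximity_cat, c(1L, 2L, 1L))
  expect_equal(rec$class,
               c("conspecific", "heterospecific", "heterospecific"))

  # column re-mapping
  names(df)[2] <- "site"
  write.csv(df, path, row.names = FALSE, na = "")
  expect_error(read_encounters(path), "missing required column")
  expect_equal(nrow(read_encounters(path, column_map = c(site = "reef"))),
               3L)
})

test_that("validation enforces the record invariants", {
  base <- data.frame(
    region = "r", reef = "rf", period = "before", focal_id = "f1",
    focal_species = "a", partner_species = "b", proximity_cat = 2L,
    outcome = "passive", chase_distance_m = NA_real_,
    stringsAsFactors = FALSE
  )
  ok <- validate_encounters(base)
  expect_equal(nrow(ok), 1L)

  chase_no_d <- transform(base, outcome = "chase")
  expect_error(validate_encounters(chase_no_d), "chase")
  passive_with_d <- transform(base, chase_distance_m = 2)
  expect_error(validate_encounters(passive_with_d), "non-chase")
  expect_error(validate_encounters(transform(base, proximity_cat = 5L)),
               "proximity")
  expect_error(validate_encounters(transform(base, period = "during")),
               "period")
  neg <- transform(base, outcome = "chase", chase_distance_m = -1)
  expect_error(validate_encounters(neg), "non-negative")

  # reject collection keeps good rows and reports bad row numbers
  both <- rbind(base, chase_no_d)
  out <- validate_encounters(both, collect_rejects = TRUE)
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "rejects")$row, 2L)
})

test_that("classification is canonical and symmetric in its key", {
  expect_equal(classify_encounter("C. trifascialis", "C. trifascialis"),
               "conspecific")
  expect_equal(classify_encounter("C. trifascialis", "C. baronessa"),
               "heterospecific")
  # labels differing only by whitespace/case are the same species
  expect_equal(classify_encounter("  C. trifascialis ",
                                  "c.  trifascialis"), "conspecific")
  expect_error(classify_encounter("", "x"), "non-empty")
  expect_identical(pair_key("B sp", "A sp"), pair_key("A sp", "B sp"))
})

test_that("pair inclusion filter applies both minimum-count rules", {
  mk <- function(focal, partner, ids) {
    validate_encounters(data.frame(
      region = "r", reef = "rf", period = "before", focal_id = ids,
      focal_species = focal, partner_species = partner,
      proximity_cat = 2L, outcome = "passive",
      chase_distance_m = NA_real_, stringsAsFactors = FALSE
    ))
  }
  # 4 encounters from 4 individuals: fails the encounter minimum
  f4 <- apply_pair_filter(mk("a", "a", paste0("i", 1:4)))
  expect_equal(nrow(f4$records), 0L)
  expect_false(any(f4$audit$kept))
  # 6 encounters from 3 individuals: fails the individual minimum
  f6 <- apply_pair_filter(mk("a", "a", c("i1", "i1", "i2", "i2", "i3",
                                         "i3")))
  expect_equal(nrow(f6$records), 0L)
  # P1 (5 enc, 5 ind) kept; P2 (5 enc, 2 ind) dropped; 5 records survive
  toy <- rbind(mk("a", "a", paste0("i", 1:5)),
               mk("a", "b", c("j1", "j1", "j1", "j2", "j2")))
  ft <- apply_pair_filter(toy)
  expect_equal(ft$pairs, "a|a")
  expect_equal(nrow(ft$records), 5L)
  aud <- ft$audit
  expect_equal(nrow(aud), 2L)
  expect_equal(aud$n_encounters[aud$species_b == "b"], 5L)
  expect_equal(aud$n_individuals[aud$species_b == "b"], 2L)
  # kept pairs in the audit always satisfy both minima
  expect_true(all(aud$n_encounters[aud$kept] >= 5L))
  expect_true(all(aud$n_individuals[aud$kept] >= 5L))
  # empty input is an empty result, not an error
  f0 <- apply_pair_filter(toy[0, , drop = FALSE])
  expect_equal(nrow(f0$audit), 0L)
})

test_that("matched subset keeps species qualifying in both classes", {
  mk <- function(focal, partner, ids) {
    data.frame(region = "r", reef = "rf", period = "before",
               focal_id = ids, focal_species = focal,
               partner_species = partner, proximity_cat = 2L,
               outcome = "passive", chase_distance_m = NA_real_,
               stringsAsFactors = FALSE)
  }
  # A: conspecific + heterospecific pairs pass; B: partner in the kept
  # heterospecific pair and its own conspecific pair passes; C: only a
  # conspecific pair passes -> exactly two of three species qualify
  toy <- validate_encounters(rbind(
    mk("a", "a", paste0("ia", 1:5)),
    mk("b", "b", paste0("ib", 1:5)),
    mk("c", "c", paste0("ic", 1:5)),
    mk("a", "b", paste0("ja", 1:5)),
    mk("a", "c", c("k1", "k2"))
  ))
  matched <- build_matched_subset(toy)
  expect_setequal(unique(matched$focal_species), c("a", "b"))
  expect_equal(nrow(matched), 15L)
  # idempotence
  expect_identical(build_matched_subset(matched), matched)
  # a species passing in one class only is excluded entirely
  expect_false("c" %in% matched$focal_species)
})

test_that("unaffected regions lose only their after-period records", {
  rec <- toy_records()
  rec$period[1:4] <- "after"
  rec$region[c(1, 5)] <- "philippines"
  out <- exclude_after_period(rec, "philippines")
  expect_equal(nrow(out), nrow(rec) - 1L)  # row 1 is after+philippines
  expect_true(all(!(out$period == "after" &
                      out$region == "philippines")))
  # before-period rows in the excluded region survive
  expect_true(any(out$region == "philippines" & out$period == "before"))
  expect_identical(exclude_after_period(rec, character()), rec)
  expect_warning(exclude_after_period(rec, "atlantis"), "atlantis")
})

test_that("individual mean proximity matches hand arithmetic", {
  rec <- toy_records()
  summ <- individual_mean_proximity(rec)
  # i1 conspecific encounters have categories {1, 3}
  expect_equal(summ$mean_proximity[summ$focal_id == "i1" &
                                     summ$class == "conspecific"], 2.0)
  # i1 also has one heterospecific encounter, category 3
  expect_equal(summ$mean_proximity[summ$focal_id == "i1" &
                                     summ$class == "heterospecific"], 3.0)
  # single-encounter individual
  expect_equal(summ$mean_proximity[summ$focal_id == "i3"], 4.0)
  # i6 heterospecific: {2, 2}
  expect_equal(summ$mean_proximity[summ$focal_id == "i6"], 2.0)
  expect_true(all(summ$mean_proximity >= 1 & summ$mean_proximity <= 4))
  # one row per (individual, class) with at least one encounter
  expect_equal(sum(summ$n_encounters), nrow(rec))
})

test_that("chase distances cap at the configured boundary", {
  expect_equal(cap_chase_distance(12.4), 10.0)
  expect_equal(cap_chase_distance(3.5), 3.5)
  expect_equal(cap_chase_distance(10.0), 10.0)
  expect_equal(cap_chase_distance(c(1, 25), cap = 5), c(1, 5))
  expect_error(cap_chase_distance(-0.1), "non-negative")
})

test_that("filtering is monotone and order-independent", {
  ds <- generate_dataset(small_config(seed = 42))
  rec <- ds$records
  n_kept <- function(e, i) {
    nrow(apply_pair_filter(rec, min_encounters = e,
                           min_individuals = i)$records)
  }
  # raising either threshold never enlarges the kept set
  for (e in c(1, 3, 5, 8)) {
    expect_true(n_kept(e, 1) >= n_kept(e, 4))
  }
  kept_seq <- vapply(c(1, 3, 5, 8), n_kept, numeric(1), i = 3)
  expect_true(all(diff(kept_seq) <= 0))

  # row order does not matter
  perm <- sample(nrow(rec))
  a <- apply_pair_filter(rec)
  b <- apply_pair_filter(rec[perm, , drop = FALSE])
  expect_equal(sort(a$pairs), sort(b$pairs))
  expect_identical(a$audit, b$audit)
  m1 <- build_matched_subset(rec)
  m2 <- build_matched_subset(rec[perm, , drop = FALSE])
  expect_equal(sort(pair_key(m1$focal_species, m1$partner_species)),
               sort(pair_key(m2$focal_species, m2$partner_species)))

  # every validated record is classified exactly once
  expect_true(all(rec$class %in% c("conspecific", "heterospecific")))
  expect_equal(sum(rec$class == "conspecific") +
                 sum(rec$class == "heterospecific"), nrow(rec))
})
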
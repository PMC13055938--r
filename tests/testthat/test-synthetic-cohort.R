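test_that("zero-rate config yields clean registries with no deaths", {
  cfg <- synthetic_config(n_matched = 10, seed = 5,
                          death_rate_A = 0, death_rate_B = 0, death_rate_S = 0)
  co <- generate_cohort(cfg)
  expect_identical(nrow(co$registry_A), 10L)
  expect_identical(nrow(co$registry_B), 10L)
  expect_identical(nrow(co$ssadmf), 0L)
  expect_true(all(is.na(co$registry_A$death_date)))
  expect_true(all(is.na(co$registry_B$death_date)))
  expect_true(all(co$truth$true_category == "none"))
})

test_that("generation is byte-identical for identical config and seed", {
  cfg <- synthetic_config(n_matched = 300, n_only_A = 40, n_only_B = 40,
                          name_typo_rate = 0.1, ssn_missing_rate = 0.2,
                          mrn_missing_rate = 0.2, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- synthetic_config(n_matched = 300, n_only_A = 40, n_only_B = 40,
                           name_typo_rate = 0.1, ssn_missing_rate = 0.2,
                           mrn_missing_rate = 0.2, seed = 100)
  expect_false(identical(generate_cohort(cfg)$registry_A,
                         generate_cohort(cfg2)$registry_A))
})

test_that("invalid configurations are rejected", {
  cc <- c(ABS = 1, AB = 1, AS = 1, BS = 1, A_only = 1, B_only = 1,
          S_only = 1, none = 3)
  expect_error(synthetic_config(10, category_counts = cc, death_rate_A = 0.1),
               "mutually exclusive")
  expect_error(synthetic_config(11, category_counts = cc), "sum to n_matched")
  expect_error(synthetic_config(10, category_counts = cc[-1]), "8 categories")
  expect_error(synthetic_config(10, death_rate_A = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_config(10, study_start = "2020-01-01",
                                study_end = "2007-01-01"), "precede")
})

test_that("identity noise perturbs names at the configured rate", {
  cfg <- synthetic_config(n_matched = 10000, seed = 21, name_typo_rate = 0.1)
  set.seed(77)
  clean <- data.frame(
    record_id = sprintf("r%05d", 1:10000),
    first_name = rep(c("Mary", "James", "Linda", "Robert"), 2500),
    last_name = rep(c("Smith", "Garcia", "Chen", "Olson"), each = 2500),
    ssn = rep("123456789", 10000), mrn = rep("M1", 10000),
    stringsAsFactors = FALSE
  )
  noisy <- inject_identity_noise(clean, cfg)
  changed <- noisy$first_name != clean$first_name |
    noisy$last_name != clean$last_name
  # binomial 99% bounds at n = 10,000, p = 0.1
  expect_gte(sum(changed), qbinom(0.005, 10000, 0.1))
  expect_lte(sum(changed), qbinom(0.995, 10000, 0.1))
})

test_that("typo rate 1 changes every record by exactly one character", {
  cfg <- synthetic_config(n_matched = 10, seed = 31, name_typo_rate = 1)
  clean <- data.frame(
    record_id = sprintf("r%02d", 1:50),
    first_name = rep(c("Mary", "James", "Linda", "Robert", "Ana"), 10),
    last_name = rep(c("Smith", "Garcia", "Chen", "Olson", "Reyes"), each = 10),
    stringsAsFactors = FALSE
  )
  noisy <- inject_identity_noise(clean, cfg)
  edits <- mapply(function(c1, n1, c2, n2) {
    sum(strsplit(c1, "")[[1]] != strsplit(n1, "")[[1]]) +
      sum(strsplit(c2, "")[[1]] != strsplit(n2, "")[[1]])
  }, clean$first_name, noisy$first_name, clean$last_name, noisy$last_name)
  expect_true(all(edits == 1L))
  # rate 0 is the identity
  cfg0 <- synthetic_config(n_matched = 10, seed = 31, name_typo_rate = 0)
  expect_identical(inject_identity_noise(clean, cfg0), clean)
})

test_that("sampled per-source death counts match configured rates", {
  cfg <- synthetic_config(n_matched = 20000, seed = 41,
                          death_rate_A = 0.05, death_rate_B = 0.02,
                          death_rate_S = 0.01)
  co <- generate_cohort(cfg)
  ci_ok <- function(x, n, p) {
    x >= qbinom(0.0005, n, p) && x <= qbinom(0.9995, n, p)
  }
  expect_true(ci_ok(sum(!is.na(co$registry_A$death_date)), 20000, 0.05))
  expect_true(ci_ok(sum(!is.na(co$registry_B$death_date)), 20000, 0.02))
  expect_true(ci_ok(nrow(co$ssadmf), 20000, 0.01))
})

test_that("truth categories agree with where death dates were placed", {
  cfg <- synthetic_config(n_matched = 2000, seed = 51,
                          death_rate_A = 0.1, death_rate_B = 0.05,
                          death_rate_S = 0.05, date_shift_fraction = 0)
  co <- generate_cohort(cfg)
  tr <- co$truth
  dead_a <- !is.na(co$registry_A$death_date[match(tr$record_id_A,
                                                  co$registry_A$record_id)])
  dead_b <- !is.na(co$registry_B$death_date[match(tr$record_id_B,
                                                  co$registry_B$record_id)])
  dead_s <- !is.na(tr$record_id_S)
  expected <- as.character(classify_death_status(dead_a, dead_b, dead_s))
  expect_identical(tr$true_category, expected)
})

test_that("cohort tables round-trip through the delimited writers", {
  cfg <- synthetic_config(n_matched = 60, n_only_A = 10, n_only_B = 10,
                          seed = 61, death_rate_A = 0.2, death_rate_B = 0.2,
                          death_rate_S = 0.2)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  ra <- read_table_tsv(file.path(dir, "registry_A.tsv"))
  expect_identical(ra$record_id, co$registry_A$record_id)
  expect_identical(ra$death_date, co$registry_A$death_date)
  expect_identical(ra$birth_date, co$registry_A$birth_date)
  enc <- read_table_tsv(file.path(dir, "encounters.tsv"))
  expect_identical(nrow(enc), nrow(co$encounters))
  expect_s3_class(enc$encounter_date, "Date")
})
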
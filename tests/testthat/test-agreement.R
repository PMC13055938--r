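test_that("per-subject agreement follows the three-rater pair-counting formula", {
  expect_identical(per_subject_agreement(3L), 1)
  expect_identical(per_subject_agreement(0L), 1)
  expect_identical(per_subject_agreement(1L), 1 / 3)
  expect_identical(per_subject_agreement(2L), 1 / 3)
  expect_error(per_subject_agreement(4L), "0..3")
  expect_error(per_subject_agreement(-1L), "0..3")
})

test_that("unanimity across a mixed cohort gives kappa = 1", {
  k <- fleiss_kappa(c(ABS = 1, AB = 0, AS = 0, BS = 0, A_only = 0,
                      B_only = 0, S_only = 0, none = 1))
  expect_identical(k$p_observed, 1)
  expect_identical(k$kappa, 1)
  expect_identical(k$p_all_concur, 1)
})

test_that("degenerate marginals (one category used everywhere) are an error", {
  allnone <- c(ABS = 0, AB = 0, AS = 0, BS = 0, A_only = 0, B_only = 0,
               S_only = 0, none = 100)
  expect_error(fleiss_kappa(allnone), "undefined")
  alldead <- c(ABS = 100, AB = 0, AS = 0, BS = 0, A_only = 0, B_only = 0,
               S_only = 0, none = 0)
  expect_error(fleiss_kappa(alldead), "undefined")
})

test_that("aggregated-count kappa equals the brute-force per-subject oracle", {
  set.seed(202)
  for (rep in 1:6) {
    counts <- c(rmultinom(1, sample(500:10000, 1),
                          c(2, 5, 4, 3, 30, 15, 20, 900)))
    names(counts) <- names(table1_counts)
    if (sum(counts[-8]) == 0) next
    k <- fleiss_kappa(counts)
    o <- oracle_fleiss(counts)
    expect_equal(k$p_observed, o$p_observed, tolerance = 1e-12)
    expect_equal(k$p_expected, o$p_expected, tolerance = 1e-12)
    expect_equal(k$kappa, o$kappa, tolerance = 1e-12)
    expect_equal(k$p_all_concur, o$p_all_concur, tolerance = 1e-12)
  }
})

test_that("kappa is invariant under permutations of the three sources", {
  counts <- c(ABS = 7, AB = 30, AS = 11, BS = 5, A_only = 100, B_only = 40,
              S_only = 60, none = 2000)
  # permuting sources permutes the category labels accordingly
  permute_counts <- function(counts, perm) {
    # perm maps position (A,B,S) -> source index used in that slot
    relabel <- vapply(names(category_triples), function(cat) {
      trip <- category_triples[[cat]][perm]
      names(category_triples)[vapply(category_triples, function(t)
        all(t == trip), logical(1))]
    }, character(1))
    out <- counts
    out[relabel] <- counts
    out
  }
  k0 <- fleiss_kappa(counts)$kappa
  for (perm in list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
    expect_equal(fleiss_kappa(permute_counts(counts, perm))$kappa, k0,
                 tolerance = 1e-14)
  }
})

test_that("kappa never exceeds 1 and hits 1 only at unanimity", {
  set.seed(303)
  for (rep in 1:20) {
    counts <- c(rmultinom(1, 300, runif(8)))
    names(counts) <- names(table1_counts)
    core <- try(fleiss_kappa(counts), silent = TRUE)
    if (inherits(core, "try-error")) next
    expect_lte(core$kappa, 1)
    unanimous <- sum(counts) == counts[["ABS"]] + counts[["none"]]
    expect_identical(core$kappa == 1, unanimous)
  }
})

test_that("growing the unanimous-not-dead mass drives Pe to 1 and kappa away from 0", {
  # fixed discordance structure, ladder over the all-not-dead count: chance
  # agreement approaches 1 and kappa moves monotonically away from zero --
  # the class-imbalance artifact that makes kappa misleading here
  ladder <- c(1L, 2L, 4L, 8L, 16L)
  res <- t(vapply(ladder, function(m) {
    cc <- table1_counts
    cc["none"] <- table1_counts[["none"]] * m
    k <- fleiss_kappa(cc)
    c(kappa = k$kappa, pe = k$p_expected)
  }, c(kappa = 0, pe = 0)))
  expect_true(all(diff(res[, "pe"]) > 0))
  expect_true(all(diff(abs(res[, "kappa"])) > 0))
})

test_that("asymptotic interval tightens as counts scale up", {
  counts <- c(ABS = 5, AB = 12, AS = 8, BS = 4, A_only = 60, B_only = 25,
              S_only = 30, none = 4000)
  k1 <- fleiss_kappa(counts)
  k100 <- fleiss_kappa(counts * 100L)
  expect_equal(k1$kappa, k100$kappa, tolerance = 1e-12) # scale-invariant point estimate
  expect_lt(k100$ci_high - k100$ci_low, k1$ci_high - k1$ci_low)
  expect_lte(k1$ci_low, k1$kappa)
  expect_gte(k1$ci_high, k1$kappa)
})

test_that("bootstrap intervals are reproducible given a seed", {
  counts <- c(ABS = 5, AB = 12, AS = 8, BS = 4, A_only = 60, B_only = 25,
              S_only = 30, none = 4000)
  ci1 <- kappa_ci(counts, method = "bootstrap", n_boot = 500, seed = 7)
  ci2 <- kappa_ci(counts, method = "bootstrap", n_boot = 500, seed = 7)
  expect_identical(ci1, ci2)
  ci3 <- kappa_ci(counts, method = "bootstrap", n_boot = 500, seed = 8)
  expect_false(identical(ci1, ci3))
  expect_error(kappa_ci(counts, method = "bootstrap", n_boot = 50), ">= 200")
})

test_that("bootstrap interval covers the generating-process kappa in most replicates", {
  probs <- c(ABS = 5, AB = 10, AS = 8, BS = 4, A_only = 30, B_only = 20,
             S_only = 15, none = 408) / 500
  big <- round(probs * 1e6)
  names(big) <- names(table1_counts)
  kappa_true <- fleiss_kappa(big)$kappa
  set.seed(404)
  hits <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    counts <- c(rmultinom(1, 500, probs))
    names(counts) <- names(table1_counts)
    ci <- kappa_ci(counts, method = "bootstrap", n_boot = 300, seed = r)
    hits <- hits + (ci[1] <= kappa_true && kappa_true <= ci[2])
  }
  expect_gte(hits, 90L)
})

test_that("the all-concur observed-agreement variant feeds the ratio when asked", {
  k <- fleiss_kappa(table1_counts, observed = "all-concur")
  expect_equal(k$kappa, (k$p_all_concur - k$p_expected) / (1 - k$p_expected),
               tolerance = 1e-14)
  kf <- fleiss_kappa(table1_counts)
  expect_equal(kf$kappa, (kf$p_observed - kf$p_expected) / (1 - kf$p_expected),
               tolerance = 1e-14)
  expect_lt(k$kappa, 0) # unanimity deficit: negative under extreme imbalance
  expect_gt(kf$kappa, 0)
})
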
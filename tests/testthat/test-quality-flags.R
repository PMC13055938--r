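test_that("date-discrepancy summary reproduces the toy delta multiset {1, 2, 20}", {
  st <- make_status(
    c("C1", "C2", "C3"),
    dA = c("2010-01-15", "2011-03-01", "2008-06-10"),
    dB = c("2010-02-15", "2011-05-01", "2010-02-10")
  )
  out <- detect_date_discrepancies(st)
  ab <- out$summary[out$summary$source_pair == "A-B", ]
  expect_identical(ab$n_flagged, 3L)
  expect_identical(ab$median_months, 2)
  expect_identical(ab$min_months, 1L)
  expect_identical(ab$max_months, 20L)
  expect_setequal(out$flags$delta_months, c(1L, 2L, 20L))
})

test_that("equal dates yield no discrepancy flags; threshold 0 flags every dual date", {
  st <- make_status(c("C1", "C2"),
                    dA = c("2010-01-15", "2011-03-01"),
                    dB = c("2010-01-15", "2011-03-01"),
                    dS = c("2010-01-15", NA))
  expect_identical(nrow(detect_date_discrepancies(st)$flags), 0L)
  t0 <- detect_date_discrepancies(st, threshold_months = 0)
  expect_identical(nrow(t0$flags), 4L) # C1 contributes all 3 pairs, C2 one
  # even-count median is the mean of the central pair
  st2 <- make_status(c("C1", "C2"),
                     dA = c("2010-01-15", "2010-01-15"),
                     dB = c("2010-02-15", "2010-05-15"))
  expect_identical(detect_date_discrepancies(st2)$summary$median_months[1], 2.5)
})

lc_fixture <- function(extra_a = NULL) {
  members <- data.frame(cluster_id = c("C1", "C1"),
                        source = c("SYSTEM_A", "SYSTEM_B"),
                        record_id = c("a1", "b1"), stringsAsFactors = FALSE)
  enc <- rbind(
    enc_row("b1", "SYSTEM_B", "2009-05-01"),
    enc_row("b1", "SYSTEM_B", "2010-01-15"),
    enc_row("a1", "SYSTEM_A", "2009-08-01"),
    extra_a
  )
  list(clusters = make_clusters(members), enc = enc)
}

test_that("lost contact requires an other-facility visit strictly after the window", {
  # last B visit 2010-01-15, later A visit well past 12 months: flagged
  f <- lc_fixture(enc_row("a1", "SYSTEM_A", "2012-03-01"))
  flags <- detect_lost_contact(f$enc, f$clusters,
                               study_end = as.Date("2020-07-10"))
  expect_identical(flags$lost_from, "SYSTEM_B")
  expect_identical(flags$switched_to, "SYSTEM_A")
  expect_identical(flags$last_visit_lost_source, as.Date("2010-01-15"))
  expect_identical(flags$first_visit_other_after_window, as.Date("2012-03-01"))

  # A visit within the 12-month window only: not flagged for B
  g <- lc_fixture(enc_row("a1", "SYSTEM_A", "2010-06-01"))
  flags_g <- detect_lost_contact(g$enc, g$clusters,
                                 study_end = as.Date("2020-07-10"))
  expect_false("SYSTEM_B" %in% flags_g$lost_from)

  # boundary: a visit exactly at window end is not "after those 12 months"
  h <- lc_fixture(enc_row("a1", "SYSTEM_A", "2011-01-15"))
  flags_h <- detect_lost_contact(h$enc, h$clusters,
                                 study_end = as.Date("2020-07-10"))
  expect_false("SYSTEM_B" %in% flags_h$lost_from)
})

test_that("insufficient follow-up censors rather than flags", {
  f <- lc_fixture(enc_row("a1", "SYSTEM_A", "2012-03-01"))
  # study ends 6 months after the last B visit: B cannot be evaluated
  flags <- detect_lost_contact(f$enc, f$clusters,
                               study_end = as.Date("2010-07-15"))
  expect_false("SYSTEM_B" %in% flags$lost_from)
  expect_identical(unname(attr(flags, "censored")["SYSTEM_B"]), 1L)
})

test_that("post-death encounter threshold is strict at one year", {
  members <- data.frame(cluster_id = c("C1", "C1"),
                        source = c("SYSTEM_A", "SYSTEM_B"),
                        record_id = c("a1", "b1"), stringsAsFactors = FALSE)
  cl <- make_clusters(members)
  st <- make_status("C1", dA = "2010-01-01")
  flag_for <- function(date) {
    enc <- enc_row("b1", "SYSTEM_B", date)
    detect_postdeath_encounters(st, enc, cl)$flags
  }
  expect_identical(nrow(flag_for("2011-01-02")), 1L) # 366 days: flagged
  expect_identical(nrow(flag_for("2011-01-01")), 0L) # exactly 365: not
  expect_identical(nrow(flag_for("2010-12-31")), 0L)
  fl <- flag_for("2011-01-02")
  expect_identical(fl$death_source, "SYSTEM_A")
  expect_identical(fl$encounter_source, "SYSTEM_B")
  rates <- detect_postdeath_encounters(st, enc_row("b1", "SYSTEM_B", "2011-01-02"),
                                       cl)$rates
  expect_identical(rates$n_flagged[rates$death_source == "SYSTEM_A"], 1L)
  expect_identical(rates$rate_pct[rates$death_source == "SYSTEM_A"], 100)
})

test_that("detectors recover the generator's designated sets exactly at zero noise", {
  cfg <- synthetic_config(n_matched = 5000, seed = 71,
                          death_rate_A = 0.05, death_rate_B = 0.03,
                          death_rate_S = 0.03,
                          lost_contact_fraction = 0.02,
                          postdeath_encounter_fraction = 0.1,
                          date_shift_fraction = 0.3)
  co <- generate_cohort(cfg)
  rep <- run_pipeline(co, seed = 71)
  tr <- co$truth

  # map flagged clusters back to persons through the A-record id
  mem <- rep$clusters$members
  a_of_cluster <- function(cl_ids) {
    m <- mem[mem$source == "SYSTEM_A" & mem$cluster_id %in% cl_ids, ]
    m$record_id
  }

  lc <- rep$qc$lost_contact
  expect_identical(nrow(lc), sum(tr$lost_contact))
  expect_setequal(a_of_cluster(lc$cluster_id), tr$record_id_A[tr$lost_contact])
  # flags name the facility the generator designated
  designated_from <- tr$lost_from[match(a_of_cluster(lc$cluster_id),
                                        tr$record_id_A)]
  expect_identical(sort(lc$lost_from), sort(designated_from))

  pd <- rep$qc$postdeath$flags
  expect_setequal(a_of_cluster(unique(pd$cluster_id)),
                  tr$record_id_A[tr$postdeath_encounter])

  dd <- rep$qc$date_discrepancies$flags
  expect_setequal(a_of_cluster(unique(dd$cluster_id)),
                  tr$record_id_A[tr$date_shift])
  # within each flagged cluster every flagged pair shows the designated shift
  dd_u <- unique(dd[, c("cluster_id", "delta_months")])
  expect_identical(nrow(dd_u), sum(tr$date_shift))
  shift_of <- tr$shift_months[match(a_of_cluster(dd_u$cluster_id),
                                    tr$record_id_A)]
  expect_identical(sort(dd_u$delta_months), sort(as.integer(shift_of)))
})

test_that("raising any threshold never increases flag counts", {
  cfg <- synthetic_config(n_matched = 2000, seed = 81,
                          death_rate_A = 0.1, death_rate_B = 0.05,
                          death_rate_S = 0.05,
                          lost_contact_fraction = 0.05,
                          postdeath_encounter_fraction = 0.2,
                          date_shift_fraction = 0.5)
  co <- generate_cohort(cfg)
  cl <- link_records(co$registry_A, co$registry_B, co$ssadmf, co$crosswalk)
  st <- assign_death_status(cl, co$registry_A, co$registry_B, co$ssadmf)

  dd <- vapply(0:6, function(th)
    nrow(detect_date_discrepancies(st, th)$flags), integer(1))
  expect_true(all(diff(dd) <= 0))

  pd <- vapply(c(0, 100, 365, 500, 800), function(th)
    nrow(detect_postdeath_encounters(st, co$encounters, cl,
                                     threshold_days = th)$flags), integer(1))
  expect_true(all(diff(pd) <= 0))

  lc <- vapply(c(6, 12, 18, 24), function(w)
    nrow(detect_lost_contact(co$encounters, cl, window_months = w,
                             study_end = cfg$study_end)), integer(1))
  expect_true(all(diff(lc) <= 0))
})
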
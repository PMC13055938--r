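# Synthetic cohort generator with ground truth.
#
# Emulates two partially overlapping patient populations (a matched cohort
# present in both health systems plus single-system patients), per-source
# death capture with a configurable 8-category overlap structure, identity
# noise (name typos, missing SSN/MRN), cross-source death-date shifts, and
# encounter streams carrying designated lost-contact and post-death
# patterns. Every record is tied back to a TruthTable so linkage, the
# concordance classifier and the quality detectors can be validated exactly.

CATEGORIES <- c("ABS", "AB", "AS", "BS", "A_only", "B_only", "S_only", "none")

# which sources record a death, per category
.cat_sources <- list(
  ABS = c(TRUE, TRUE, TRUE), AB = c(TRUE, TRUE, FALSE),
  AS = c(TRUE, FALSE, TRUE), BS = c(FALSE, TRUE, TRUE),
  A_only = c(TRUE, FALSE, FALSE), B_only = c(FALSE, TRUE, FALSE),
  S_only = c(FALSE, FALSE, TRUE), none = c(FALSE, FALSE, FALSE)
)

#' Configuration for the synthetic cohort generator
#'
#' @param n_matched Number of patients present in both health systems.
#' @param n_only_A,n_only_B Number of patients present in one system only.
#' @param category_counts Optional named vector/list giving exact counts for
#'   the eight concordance categories (`ABS`, `AB`, `AS`, `BS`, `A_only`,
#'   `B_only`, `S_only`, `none`) among the matched cohort; must sum to
#'   `n_matched`. When supplied, death-rate sampling is disabled and the
#'   rates must not also be set.
#' @param death_rate_A,death_rate_B,death_rate_S Marginal probabilities that
#'   a source records a patient's death. Defaults are the matched-cohort
#'   capture rates of a large two-system regional comparison (1.62%, 0.44%,
#'   0.59%).
#' @param name_typo_rate Probability that a registry record's name carries a
#'   single-character typo.
#' @param ssn_missing_rate,mrn_missing_rate Probabilities that a registry
#'   record's SSN / MRN is blank.
#' @param date_shift_months Distribution of the whole-month cross-source
#'   death-date disagreement for designated discordant-date persons: either
#'   `list(type = "pointmass", values =, probs =)` or
#'   `list(type = "geometric", p =, max =)` (support starts at 1 month).
#'   The default geometric with p = 0.3 has median 2 months, the typical
#'   between-facility discrepancy scale.
#' @param date_shift_fraction Fraction of multi-source deaths designated to
#'   receive a shifted death date in one source.
#' @param lost_contact_fraction Fraction of alive matched patients designated
#'   as lost-contact (no encounters at one facility for over 12 months while
#'   later attending the other).
#' @param postdeath_encounter_fraction Fraction of deceased matched patients
#'   designated to have an encounter more than one year after death.
#' @param encounter_rate Mean number of additional encounters per patient per
#'   facility over the observation window (a Poisson count on top of the
#'   guaranteed final visit).
#' @param study_start,study_end Observation window (defaults 2007-01-01 to
#'   2020-07-10, a 13-year regional comparison window).
#' @param seed Integer seed; all generation is deterministic given the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_matched,
                             n_only_A = 0L, n_only_B = 0L,
                             category_counts = NULL,
                             death_rate_A = 0.0162,
                             death_rate_B = 0.0044,
                             death_rate_S = 0.0059,
                             name_typo_rate = 0,
                             ssn_missing_rate = 0,
                             mrn_missing_rate = 0,
                             date_shift_months = list(type = "geometric", p = 0.3, max = 122L),
                             date_shift_fraction = 0.005,
                             lost_contact_fraction = 0.005,
                             postdeath_encounter_fraction = 0.01,
                             encounter_rate = 4,
                             study_start = as.Date("2007-01-01"),
                             study_end = as.Date("2020-07-10"),
                             seed = 1L) {
  if (!is.null(category_counts)) {
    if (!missing(death_rate_A) || !missing(death_rate_B) || !missing(death_rate_S)) {
      stop("configuration error: category_counts and death rates are mutually exclusive")
    }
    category_counts <- unlist(category_counts)
    if (!setequal(names(category_counts), CATEGORIES)) {
      stop("category_counts must be named with the 8 categories: ",
           paste(CATEGORIES, collapse = ", "))
    }
    category_counts <- category_counts[CATEGORIES]
    if (any(category_counts < 0) || sum(category_counts) != n_matched) {
      stop("configuration error: category_counts must be nonnegative and sum to n_matched")
    }
    death_rate_A <- death_rate_B <- death_rate_S <- 0
  }
  probs <- c(death_rate_A, death_rate_B, death_rate_S, name_typo_rate,
             ssn_missing_rate, mrn_missing_rate, date_shift_fraction,
             lost_contact_fraction, postdeath_encounter_fraction)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (!(study_start < study_end)) stop("study_start must precede study_end")
  stopifnot(n_matched >= 0, n_only_A >= 0, n_only_B >= 0, encounter_rate >= 0)

  structure(list(
    n_matched = as.integer(n_matched), n_only_A = as.integer(n_only_A),
    n_only_B = as.integer(n_only_B), category_counts = category_counts,
    death_rate_A = death_rate_A, death_rate_B = death_rate_B,
    death_rate_S = death_rate_S, name_typo_rate = name_typo_rate,
    ssn_missing_rate = ssn_missing_rate, mrn_missing_rate = mrn_missing_rate,
    date_shift_months = date_shift_months,
    date_shift_fraction = date_shift_fraction,
    lost_contact_fraction = lost_contact_fraction,
    postdeath_encounter_fraction = postdeath_encounter_fraction,
    encounter_rate = encounter_rate,
    study_start = study_start, study_end = study_end,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("synthetic_config: %d matched + %d A-only + %d B-only patients\n",
              x$n_matched, x$n_only_A, x$n_only_B))
  if (!is.null(x$category_counts)) {
    cat("  exact category counts:",
        paste(sprintf("%s=%d", CATEGORIES, x$category_counts), collapse = " "), "\n")
  } else {
    cat(sprintf("  death rates A/B/S: %.4f / %.4f / %.4f\n",
                x$death_rate_A, x$death_rate_B, x$death_rate_S))
  }
  cat(sprintf("  window %s .. %s, seed %d\n",
              format(x$study_start), format(x$study_end), x$seed))
  invisible(x)
}

sample_days <- function(n, from, to) {
  from <- as.integer(from)
  to <- as.integer(to)
  as.Date(from + floor(stats::runif(n) * (to - from + 1L)), origin = "1970-01-01")
}

clip_day28 <- function(d) {
  lt <- as.POSIXlt(d)
  lt$mday <- pmin(lt$mday, 28L)
  as.Date(lt)
}

draw_shift_months <- function(n, spec) {
  if (identical(spec$type, "pointmass")) {
    vals <- as.integer(spec$values)
    probs <- spec$probs %||% rep(1 / length(vals), length(vals))
    k <- sample(vals, n, replace = TRUE, prob = probs)
  } else if (identical(spec$type, "geometric")) {
    k <- 1L + stats::rgeom(n, spec$p)
  } else {
    stop("date_shift_months: unknown distribution type")
  }
  pmax(1L, pmin(k, as.integer(spec$max %||% 122L)))
}

#' Inject identity noise into a registry
#'
#' Applies, independently per record and at the configured rates, a
#' single-character name substitution (in the first or last name, chosen at
#' random) and blanking of the SSN and MRN fields. Record ids and all other
#' fields are untouched, so truth keys survive.
#'
#' @param records Registry data frame.
#' @param config A `synthetic_config` (rates and seed are read from it).
#' @param stream Integer stream offset so that repeated calls within one
#'   generation draw independent noise deterministically.
#' @return The registry with noise applied.
#' @export
inject_identity_noise <- function(records, config, stream = 0L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, 100L + stream))
  n <- nrow(records)
  if (!n) return(records)

  if (config$name_typo_rate > 0) {
    hit <- which(stats::runif(n) < config$name_typo_rate)
    if (length(hit)) {
      which_name <- ifelse(stats::runif(length(hit)) < 0.5, "first_name", "last_name")
      for (col in c("first_name", "last_name")) {
        rows <- hit[which_name == col]
        if (!length(rows)) next
        nm <- records[[col]][rows]
        len <- nchar(nm)
        pos <- 1L + floor(stats::runif(length(rows)) * len)
        old <- substr(nm, pos, pos)
        new <- sample(letters, length(rows), replace = TRUE)
        retry <- which(toupper(new) == toupper(old) | !grepl("[A-Za-z]", old))
        guard <- 0L
        while (length(retry) && guard < 50L) {
          new[retry] <- sample(letters, length(retry), replace = TRUE)
          bad_pos <- !grepl("[A-Za-z]", substr(nm[retry], pos[retry], pos[retry]))
          pos[retry][bad_pos] <- 1L # fall back to first character
          old[retry] <- substr(nm[retry], pos[retry], pos[retry])
          retry <- retry[toupper(new[retry]) == toupper(old[retry])]
          guard <- guard + 1L
        }
        substr(nm, pos, pos) <- new
        records[[col]][rows] <- nm
      }
    }
  }
  if (config$ssn_missing_rate > 0 && "ssn" %in% names(records)) {
    records$ssn[stats::runif(n) < config$ssn_missing_rate] <- NA_character_
  }
  if (config$mrn_missing_rate > 0 && "mrn" %in% names(records)) {
    records$mrn[stats::runif(n) < config$mrn_missing_rate] <- NA_character_
  }
  records
}

#' Generate a synthetic multi-source cohort with ground truth
#'
#' Produces the two health-system registries, a death-master extract, an
#' encounter table, an A-to-B identifier crosswalk and a truth table. Matched
#' persons carry records in both registries; death dates are placed in
#' sources either by exact category counts or by independent per-source
#' death-rate sampling. Identity noise, cross-source death-date shifts,
#' lost-contact encounter patterns and post-death encounters are applied to
#' designated persons recorded in the truth table, and the generator is
#' constructed so that (at zero identity noise) each quality detector's flag
#' set equals its designated set exactly: non-designated matched persons end
#' care with a synchronized final visit at both facilities, encounters stop
#' at the true death date, designated post-death encounters are written to
#' both systems on one date, and date shifts move the recorded date later
#' within the window.
#'
#' @param config A `synthetic_config`.
#' @return An object of class `synthetic_cohort`: list with elements
#'   `registry_A`, `registry_B`, `ssadmf`, `encounters`, `crosswalk`,
#'   `truth`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, 1L))
  n_m <- config$n_matched
  n_a <- config$n_only_A
  n_b <- config$n_only_B
  n <- n_m + n_a + n_b
  d0 <- as.integer(config$study_start)
  d1 <- as.integer(config$study_end)

  group <- rep(c("M", "A", "B"), times = c(n_m, n_a, n_b))
  in_A <- group %in% c("M", "A")
  in_B <- group %in% c("M", "B")
  person_uid <- sprintf("P%07d", seq_len(n))

  gender <- sample(c("F", "M", "U"), n, replace = TRUE, prob = c(0.49, 0.49, 0.02))
  first_name <- sample_first_names(n, gender)
  last_name <- sample_surnames(n)
  birth_date <- sample_days(n, as.Date("1920-01-01"), as.Date("1995-12-31"))

  # enforce uniqueness of (last, first initial, gender, birth date) so that
  # name/demographic matching and token-1 material identify persons uniquely
  # on clean data: within each (last, initial, gender) group, birth dates are
  # drawn without replacement from the birth-year grid
  grid0 <- as.integer(as.Date("1920-01-01"))
  grid1 <- as.integer(as.Date("1995-12-31"))
  ngrid <- grid1 - grid0 + 1L
  k0 <- paste(normalize_name(last_name),
              substr(normalize_name(first_name), 1, 1), gender, sep = "|")
  bd_int <- as.integer(birth_date)
  groups <- split(seq_len(n), k0)
  groups <- groups[lengths(groups) > 1L]
  for (idx in groups) {
    if (length(idx) > ngrid) {
      stop("cohort too large for the name pools: cannot keep identity keys unique")
    }
    bd_int[idx] <- grid0 + sample.int(ngrid, length(idx)) - 1L
  }
  birth_date <- as.Date(bd_int, origin = "1970-01-01")

  ssn <- formatC(sample.int(799999999L, n) + 100000000L, width = 9, flag = "0")
  mrn <- sprintf("M%07d", seq_len(n))

  # --- death placement ---------------------------------------------------
  dead_A <- dead_B <- dead_S <- logical(n)
  true_category <- rep(NA_character_, n)
  im <- which(group == "M")
  if (!is.null(config$category_counts)) {
    cats <- sample(rep(CATEGORIES, times = config$category_counts))
    true_category[im] <- cats
    src <- do.call(rbind, .cat_sources[cats])
    dead_A[im] <- src[, 1]
    dead_B[im] <- src[, 2]
    dead_S[im] <- src[, 3]
  } else {
    dead_A[in_A] <- stats::runif(sum(in_A)) < config$death_rate_A
    dead_B[in_B] <- stats::runif(sum(in_B)) < config$death_rate_B
    dead_S <- stats::runif(n) < config$death_rate_S
    true_category[im] <- names(.cat_sources)[match(
      paste(dead_A[im], dead_B[im], dead_S[im]),
      vapply(.cat_sources, function(s) paste(s[1], s[2], s[3]), character(1))
    )]
  }
  dead_any <- dead_A | dead_B | dead_S
  true_death_date <- rep(as.Date(NA), n)
  true_death_date[dead_any] <- sample_days(sum(dead_any), d0, d1)

  # --- designations -------------------------------------------------------
  n_sources <- dead_A + dead_B + dead_S
  max_shift <- if (identical(config$date_shift_months$type, "pointmass")) {
    max(as.integer(config$date_shift_months$values))
  } else {
    as.integer(config$date_shift_months$max %||% 122L)
  }
  window_months <- month_delta(config$study_start, config$study_end)

  elig_ds <- which(group == "M" & n_sources >= 2)
  n_ds <- round(config$date_shift_fraction * length(elig_ds))
  ds_idx <- if (n_ds > 0) sort(sample(elig_ds, n_ds)) else integer(0)
  date_shift <- logical(n)
  date_shift[ds_idx] <- TRUE
  shift_months <- rep(NA_integer_, n)
  shift_source <- rep(NA_character_, n)
  if (length(ds_idx)) {
    kk <- draw_shift_months(length(ds_idx), config$date_shift_months)
    kk <- pmin(kk, max(1L, window_months - 2L)) # shifted date must stay in window
    shift_months[ds_idx] <- kk
    # resample the true death date early enough that date + shift <= study end;
    # day-of-month capped at 28 so whole-month shifts never lose a month to
    # end-of-month clipping
    latest <- add_months(rep(config$study_end, length(ds_idx)), -kk)
    true_death_date[ds_idx] <- clip_day28(sample_days(length(ds_idx), d0, latest))
    pick <- cbind(dead_A[ds_idx], dead_B[ds_idx], dead_S[ds_idx])
    shift_source[ds_idx] <- vapply(seq_along(ds_idx), function(j) {
      sample(c("SYSTEM_A", "SYSTEM_B", "SSADMF")[pick[j, ]], 1L)
    }, character(1))
  }

  elig_pd <- which(group == "M" & dead_any & !date_shift &
                     !is.na(true_death_date) &
                     as.integer(true_death_date) <= d1 - 760L)
  n_pd <- round(config$postdeath_encounter_fraction *
                  sum(group == "M" & dead_any))
  n_pd <- min(n_pd, length(elig_pd))
  pd_idx <- if (n_pd > 0) sort(sample(elig_pd, n_pd)) else integer(0)
  postdeath <- logical(n)
  postdeath[pd_idx] <- TRUE

  lc_possible <- (d1 - d0) >= 900L # need room for last visit + 13 months + margin
  elig_lc <- if (lc_possible) which(group == "M" & !dead_any) else integer(0)
  n_lc <- round(config$lost_contact_fraction * length(elig_lc))
  lc_idx <- if (n_lc > 0) sort(sample(elig_lc, n_lc)) else integer(0)
  lost_contact <- logical(n)
  lost_contact[lc_idx] <- TRUE
  lost_from <- rep(NA_character_, n)
  if (length(lc_idx)) {
    lost_from[lc_idx] <- sample(c("SYSTEM_A", "SYSTEM_B"), length(lc_idx),
                                replace = TRUE)
  }

  # --- per-source recorded death dates ------------------------------------
  rec_date <- function(dead, source_name) {
    d <- rep(as.Date(NA), n)
    d[dead] <- true_death_date[dead]
    sh <- which(date_shift & dead & shift_source == source_name)
    if (length(sh)) d[sh] <- add_months(true_death_date[sh], shift_months[sh])
    d
  }
  death_date_A <- rec_date(dead_A, "SYSTEM_A")
  death_date_B <- rec_date(dead_B, "SYSTEM_B")
  death_date_S <- rec_date(dead_S, "SSADMF")

  # --- registries ----------------------------------------------------------
  ia <- which(in_A)
  ib <- which(in_B)
  is_ <- which(dead_S)
  record_id_A <- rep(NA_character_, n)
  record_id_B <- rep(NA_character_, n)
  record_id_S <- rep(NA_character_, n)
  record_id_A[ia] <- sprintf("A%07d", seq_along(ia))
  record_id_B[ib] <- sprintf("B%07d", seq_along(ib))
  record_id_S[is_] <- sprintf("S%07d", seq_along(is_))

  registry_A <- data.frame(
    record_id = record_id_A[ia], first_name = first_name[ia],
    last_name = last_name[ia], gender = gender[ia],
    birth_date = birth_date[ia], ssn = ssn[ia], mrn = mrn[ia],
    death_date = death_date_A[ia], stringsAsFactors = FALSE
  )
  registry_B <- data.frame(
    record_id = record_id_B[ib], first_name = first_name[ib],
    last_name = last_name[ib], gender = gender[ib],
    birth_date = birth_date[ib], ssn = ssn[ib], mrn = mrn[ib],
    death_date = death_date_B[ib], stringsAsFactors = FALSE
  )
  ssadmf <- data.frame(
    record_id = record_id_S[is_], first_name = first_name[is_],
    last_name = last_name[is_], gender = gender[is_],
    birth_date = birth_date[is_], ssn = ssn[is_],
    death_date = death_date_S[is_], stringsAsFactors = FALSE
  )

  # --- encounters ----------------------------------------------------------
  # care end: death date for the deceased, otherwise a uniform care-end date;
  # both facilities share it (synchronized final visit) unless the person is
  # a designated lost-contact patient
  care_end <- rep(as.Date(NA), n)
  care_end[dead_any] <- true_death_date[dead_any]
  alive <- which(!dead_any)
  care_end[alive] <- sample_days(length(alive), min(d0 + 90L, d1), d1)

  end_A <- care_end
  end_B <- care_end
  if (length(lc_idx)) {
    # lost facility: last visit L at least 25 months before study end;
    # retained facility: final visit strictly after L + 13 months
    L <- sample_days(length(lc_idx), min(d0 + 90L, d1 - 790L), d1 - 790L)
    after <- add_months(L, 13L)
    Ep <- sample_days(length(lc_idx), pmin(as.integer(after) + 1L, d1), d1)
    from_a <- lost_from[lc_idx] == "SYSTEM_A"
    end_A[lc_idx] <- as.Date(ifelse(from_a, L, Ep), origin = "1970-01-01")
    end_B[lc_idx] <- as.Date(ifelse(from_a, Ep, L), origin = "1970-01-01")
  }

  gen_stream <- function(person_idx, rid, stream_end) {
    n_extra <- stats::rpois(length(person_idx), config$encounter_rate)
    who <- rep(seq_along(person_idx), n_extra)
    extra <- sample_days(length(who), d0, as.integer(stream_end)[who])
    data.frame(
      record_id = c(rid, rid[who]),
      encounter_date = c(stream_end, extra),
      stringsAsFactors = FALSE
    )
  }
  enc_A <- gen_stream(ia, record_id_A[ia], end_A[ia])
  enc_A$source <- "SYSTEM_A"
  enc_B <- gen_stream(ib, record_id_B[ib], end_B[ib])
  enc_B$source <- "SYSTEM_B"
  encounters <- rbind(enc_A, enc_B)

  if (length(pd_idx)) {
    off <- 366L + floor(stats::runif(length(pd_idx)) * 360L)
    pd_date <- as.Date(pmin(as.integer(true_death_date[pd_idx]) + off, d1),
                       origin = "1970-01-01")
    encounters <- rbind(
      encounters,
      data.frame(record_id = record_id_A[pd_idx], encounter_date = pd_date,
                 source = "SYSTEM_A", stringsAsFactors = FALSE),
      data.frame(record_id = record_id_B[pd_idx], encounter_date = pd_date,
                 source = "SYSTEM_B", stringsAsFactors = FALSE)
    )
  }
  encounters <- encounters[, c("record_id", "source", "encounter_date")]
  rownames(encounters) <- NULL

  crosswalk <- data.frame(record_id_A = record_id_A[im],
                          record_id_B = record_id_B[im],
                          stringsAsFactors = FALSE)

  truth <- data.frame(
    person_uid = person_uid, record_id_A = record_id_A,
    record_id_B = record_id_B, record_id_S = record_id_S,
    true_death_date = true_death_date, true_category = true_category,
    lost_contact = lost_contact, lost_from = lost_from,
    postdeath_encounter = postdeath, date_shift = date_shift,
    shift_months = shift_months, shift_source = shift_source,
    stringsAsFactors = FALSE
  )

  registry_A <- inject_identity_noise(registry_A, config, stream = 1L)
  registry_B <- inject_identity_noise(registry_B, config, stream = 2L)

  structure(list(registry_A = registry_A, registry_B = registry_B,
                 ssadmf = ssadmf, encounters = encounters,
                 crosswalk = crosswalk, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_cohort: %d A-records, %d B-records, %d death-master records,\n",
    "  %d encounters; %d matched persons; window %s .. %s\n"),
    nrow(x$registry_A), nrow(x$registry_B), nrow(x$ssadmf),
    nrow(x$encounters), x$config$n_matched,
    format(x$config$study_start), format(x$config$study_end)))
  invisible(x)
}

#' Write a synthetic cohort as delimited tables
#'
#' Writes the four data tables, the crosswalk and the truth table as UTF-8
#' tab-separated files with header rows and ISO-8601 dates.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  parts <- c("registry_A", "registry_B", "ssadmf", "encounters",
             "crosswalk", "truth")
  paths <- file.path(dir, paste0(parts, ".tsv"))
  for (i in seq_along(parts)) {
    utils::write.table(cohort[[parts[i]]], paths[i], sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(paths)
}

#' Read a delimited registry/encounter/truth table
#'
#' Counterpart of [write_cohort()]: reads a tab-separated table, restoring
#' `Date` columns and blank-as-missing fields.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character", na.strings = "",
                         quote = "", comment.char = "")
  for (col in intersect(c("birth_date", "death_date", "encounter_date",
                          "true_death_date"), names(x))) {
    x[[col]] <- as.Date(x[[col]])
  }
  for (col in intersect(c("lost_contact", "postdeath_encounter", "date_shift"),
                        names(x))) {
    x[[col]] <- as.logical(x[[col]])
  }
  x
}
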
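# Exploratory data-quality detectors: cross-source death-date discrepancies,
# lost-contact patients, and post-death encounters.

# map encounters onto clusters; returns encounters with a cluster_id column,
# restricted to records that belong to a cluster
encounters_with_clusters <- function(encounters, clusters) {
  stopifnot(all(c("record_id", "source", "encounter_date") %in% names(encounters)))
  mem <- clusters$members
  cl <- rep(NA_character_, nrow(encounters))
  for (src in unique(encounters$source)) { # per-source match: record ids are source-scoped
    sel <- encounters$source == src
    msel <- mem$source == src
    cl[sel] <- mem$cluster_id[msel][match(encounters$record_id[sel],
                                          mem$record_id[msel])]
  }
  keep <- !is.na(cl)
  out <- encounters[keep, , drop = FALSE]
  out$cluster_id <- cl[keep]
  out
}

# last (max) value of `dates` per group, returned aligned to `levels`
last_date_by <- function(group, dates, levels) {
  ord <- order(group, dates, method = "radix")
  g <- group[ord]
  d <- dates[ord]
  lasts <- !duplicated(g, fromLast = TRUE)
  out <- rep(as.Date(NA), length(levels))
  out[match(g[lasts], levels)] <- d[lasts]
  out
}

#' Detect cross-source death-date discrepancies
#'
#' For every source pair (A-B, A-extract, B-extract) and every matched
#' cluster in which both sources recorded a death date, computes the
#' whole-month difference ([month_delta()]) and flags the cluster when the
#' difference reaches `threshold_months`. Per-pair summary statistics
#' (count, median, min, max of the flagged differences; the median of an
#' even count is the mean of the central pair) are returned alongside.
#'
#' @param status Death-status data frame from [assign_death_status()].
#' @param threshold_months Minimum whole-month difference to flag (default 1).
#' @return List with `flags` (cluster_id, source_pair, delta_months) and
#'   `summary` (per-pair n_flagged, median/min/max months among flagged).
#' @export
detect_date_discrepancies <- function(status, threshold_months = 1) {
  pairs <- list(
    `A-B` = c("death_date_A", "death_date_B"),
    `A-S` = c("death_date_A", "death_date_S"),
    `B-S` = c("death_date_B", "death_date_S")
  )
  flags <- list()
  summ <- list()
  for (pn in names(pairs)) {
    d1 <- status[[pairs[[pn]][1]]]
    d2 <- status[[pairs[[pn]][2]]]
    both <- !is.na(d1) & !is.na(d2)
    delta <- month_delta(d1[both], d2[both])
    hit <- delta >= threshold_months
    if (any(hit)) {
      flags[[pn]] <- data.frame(
        cluster_id = status$cluster_id[both][hit],
        source_pair = pn, delta_months = delta[hit],
        stringsAsFactors = FALSE
      )
    }
    dm <- delta[hit]
    summ[[pn]] <- data.frame(
      source_pair = pn, n_flagged = sum(hit),
      median_months = if (length(dm)) stats::median(dm) else NA_real_,
      min_months = if (length(dm)) min(dm) else NA_integer_,
      max_months = if (length(dm)) max(dm) else NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(cluster_id = character(0), source_pair = character(0),
               delta_months = integer(0), stringsAsFactors = FALSE)
  rownames(flags) <- NULL
  summary <- do.call(rbind, summ)
  rownames(summary) <- NULL
  list(flags = flags, summary = summary)
}

#' Detect lost-contact patients
#'
#' A matched-cohort cluster is flagged for facility X when it has at least
#' one X encounter, no X encounters for `window_months` months after the
#' last one, and at least one encounter at the other facility strictly after
#' that window. At most one flag is emitted per (cluster, lost-from
#' facility). Clusters whose last visit at a facility lies within
#' `window_months` of the study end cannot be evaluated (insufficient
#' follow-up) and are counted as censored in the `censored` attribute.
#'
#' @param encounters Encounter table (`record_id`, `source`,
#'   `encounter_date`).
#' @param clusters A `person_clusters` object; only matched clusters are
#'   considered.
#' @param window_months Lost-contact window (default 12 months).
#' @param study_end End of the observation window; defaults to the latest
#'   encounter date.
#' @return Data frame of flags: `cluster_id`, `lost_from`, `switched_to`,
#'   `last_visit_lost_source`, `first_visit_other_after_window`; attribute
#'   `censored` holds the per-facility censored-cluster counts.
#' @export
detect_lost_contact <- function(encounters, clusters, window_months = 12,
                                study_end = max(encounters$encounter_date)) {
  enc <- encounters_with_clusters(encounters, clusters)
  matched_ids <- clusters$matched$cluster_id[clusters$matched$matched]
  enc <- enc[enc$cluster_id %in% matched_ids, , drop = FALSE]

  ids <- sort(unique(enc$cluster_id))
  a <- enc$source == "SYSTEM_A"
  last_A <- last_date_by(enc$cluster_id[a], enc$encounter_date[a], ids)
  last_B <- last_date_by(enc$cluster_id[!a], enc$encounter_date[!a], ids)

  censored <- c(SYSTEM_A = 0L, SYSTEM_B = 0L)
  out <- list()
  for (side in c("SYSTEM_A", "SYSTEM_B")) {
    last_x <- if (side == "SYSTEM_A") last_A else last_B
    other <- if (side == "SYSTEM_A") "SYSTEM_B" else "SYSTEM_A"
    cutoff <- add_months(last_x, window_months)
    cens <- !is.na(last_x) & cutoff > study_end
    censored[side] <- sum(cens)
    # earliest other-facility encounter strictly after the window
    is_other <- enc$source == other
    cut_enc <- cutoff[match(enc$cluster_id, ids)]
    qual <- is_other & !is.na(cut_enc) & enc$encounter_date > cut_enc
    if (any(qual)) {
      q <- enc[qual, c("cluster_id", "encounter_date")]
      ord <- order(q$cluster_id, q$encounter_date, method = "radix")
      q <- q[ord, ]
      q <- q[!duplicated(q$cluster_id), ]
      i <- match(q$cluster_id, ids)
      ok <- !cens[i]
      if (any(ok)) {
        out[[side]] <- data.frame(
          cluster_id = q$cluster_id[ok], lost_from = side, switched_to = other,
          last_visit_lost_source = last_x[i][ok],
          first_visit_other_after_window = q$encounter_date[ok],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  flags <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster_id = character(0), lost_from = character(0),
               switched_to = character(0),
               last_visit_lost_source = as.Date(character(0)),
               first_visit_other_after_window = as.Date(character(0)),
               stringsAsFactors = FALSE)
  rownames(flags) <- NULL
  attr(flags, "censored") <- censored
  flags
}

#' Detect post-death encounters
#'
#' For each matched cluster and each source that recorded a death date,
#' flags the cluster-source pair when any encounter at either health system
#' falls strictly more than `threshold_days` days after that recorded death
#' date ("more than one year" in the default reading of 365 days; leap years
#' are not special-cased). One flag is emitted per (cluster, death source),
#' carrying the earliest qualifying encounter. Rates are reported per death
#' source with that source's death total as denominator.
#'
#' @param status Death-status data frame from [assign_death_status()].
#' @param encounters Encounter table.
#' @param clusters A `person_clusters` object.
#' @param threshold_days Days after the recorded death beyond which an
#'   encounter is flagged (default 365).
#' @return List with `flags` (cluster_id, death_source, death_date,
#'   encounter_source, encounter_date) and `rates` (per death source:
#'   n_deaths, n_flagged, rate_pct).
#' @export
detect_postdeath_encounters <- function(status, encounters, clusters,
                                        threshold_days = 365) {
  enc <- encounters_with_clusters(encounters, clusters)
  date_cols <- c(SYSTEM_A = "death_date_A", SYSTEM_B = "death_date_B",
                 SSADMF = "death_date_S")
  dead_cols <- c(SYSTEM_A = "dead_A", SYSTEM_B = "dead_B", SSADMF = "dead_S")
  dead_any <- status$dead_A | status$dead_B | status$dead_S
  enc <- enc[enc$cluster_id %in% status$cluster_id[dead_any], , drop = FALSE]

  flags <- list()
  rates <- list()
  for (src in names(date_cols)) {
    dd <- status[[date_cols[src]]]
    has <- !is.na(dd)
    n_deaths <- sum(has)
    n_flagged <- 0L
    if (n_deaths && nrow(enc)) {
      lim <- dd[match(enc$cluster_id, status$cluster_id)] + threshold_days
      qual <- !is.na(lim) & enc$encounter_date > lim
      if (any(qual)) {
        q <- enc[qual, c("cluster_id", "source", "encounter_date")]
        ord <- order(q$cluster_id, q$encounter_date, method = "radix")
        q <- q[ord, ]
        q <- q[!duplicated(q$cluster_id), ]
        n_flagged <- nrow(q)
        flags[[src]] <- data.frame(
          cluster_id = q$cluster_id, death_source = src,
          death_date = dd[match(q$cluster_id, status$cluster_id)],
          encounter_source = q$source, encounter_date = q$encounter_date,
          stringsAsFactors = FALSE
        )
      }
    }
    rates[[src]] <- data.frame(
      death_source = src, n_deaths = n_deaths, n_flagged = n_flagged,
      rate_pct = if (n_deaths) pct2(n_flagged, n_deaths) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(cluster_id = character(0), death_source = character(0),
               death_date = as.Date(character(0)),
               encounter_source = character(0),
               encounter_date = as.Date(character(0)), stringsAsFactors = FALSE)
  rownames(flags) <- NULL
  rates <- do.call(rbind, rates)
  rownames(rates) <- NULL
  list(flags = flags, rates = rates)
}
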
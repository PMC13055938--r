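# Death-status assignment, 8-category concordance classification and the
# derived summaries (union of deaths, per-source totals, printed-style
# percentages, Venn regions).

#' Assign per-source death status to matched clusters
#'
#' For every cluster in the matched cohort (records in both health systems),
#' records whether each source carries a death date and which date. When a
#' source contributes several member records with death dates, the earliest
#' date is retained and the multiplicity is flagged.
#'
#' @param clusters A `person_clusters` object.
#' @param registry_A,registry_B,ssadmf Source tables carrying `record_id` and
#'   `death_date` (the extract may be `NULL` or empty).
#' @return Data frame with one row per matched cluster: `cluster_id`,
#'   `dead_A`, `dead_B`, `dead_S`, `death_date_A/B/S`, `multi_A/B/S`.
#' @export
assign_death_status <- function(clusters, registry_A, registry_B, ssadmf = NULL) {
  stopifnot(inherits(clusters, "person_clusters"))
  matched_ids <- clusters$matched$cluster_id[clusters$matched$matched]
  if (!length(matched_ids)) {
    stop("no matched clusters: every cluster lacks records in one of the systems")
  }
  mem <- clusters$members[clusters$members$cluster_id %in% matched_ids, ]

  status <- data.frame(cluster_id = sort(matched_ids), stringsAsFactors = FALSE)
  pull <- function(registry, source_name) {
    dead <- logical(nrow(status))
    ddate <- rep(as.Date(NA), nrow(status))
    multi <- logical(nrow(status))
    if (is.null(registry) || !nrow(registry)) {
      return(data.frame(dead = dead, ddate = ddate, multi = multi))
    }
    m <- mem[mem$source == source_name, ]
    dd <- registry$death_date[match(m$record_id, registry$record_id)]
    keep <- !is.na(dd)
    if (any(keep)) {
      cl <- m$cluster_id[keep]
      dd <- dd[keep]
      ord <- order(cl, dd, method = "radix")
      cl <- cl[ord]
      dd <- dd[ord]
      firsts <- !duplicated(cl)
      i <- match(cl[firsts], status$cluster_id)
      dead[i] <- TRUE
      ddate[i] <- dd[firsts]
      dup_cl <- unique(cl[duplicated(cl)])
      multi[match(dup_cl, status$cluster_id)] <- TRUE
    }
    data.frame(dead = dead, ddate = ddate, multi = multi)
  }
  a <- pull(registry_A, "SYSTEM_A")
  b <- pull(registry_B, "SYSTEM_B")
  s <- pull(ssadmf, "SSADMF")
  status$dead_A <- a$dead
  status$dead_B <- b$dead
  status$dead_S <- s$dead
  status$death_date_A <- a$ddate
  status$death_date_B <- b$ddate
  status$death_date_S <- s$ddate
  status$multi_A <- a$multi
  status$multi_B <- b$multi
  status$multi_S <- s$multi
  status
}

#' Classify a death-status triple into its concordance category
#'
#' Maps the boolean triple (dead per health system A, health system B,
#' death-master extract) to one of eight mutually exclusive categories:
#' `ABS` (all three sources), `AB`, `AS`, `BS` (two sources), `A_only`,
#' `B_only`, `S_only` (one source), `none` (no source).
#'
#' @param dead_A,dead_B,dead_S Logical vectors, or a single data frame with
#'   those columns passed as `dead_A`.
#' @return Factor with the eight category levels.
#' @examples
#' classify_death_status(TRUE, TRUE, TRUE)   # ABS
#' classify_death_status(FALSE, FALSE, TRUE) # S_only
#' @export
classify_death_status <- function(dead_A, dead_B = NULL, dead_S = NULL) {
  if (is.data.frame(dead_A)) {
    df <- dead_A
    dead_A <- df$dead_A
    dead_B <- df$dead_B
    dead_S <- df$dead_S
  }
  stopifnot(is.logical(dead_A), is.logical(dead_B), is.logical(dead_S))
  lab <- c("none", "S_only", "B_only", "BS", "A_only", "AS", "AB", "ABS")
  idx <- 1L + dead_S + 2L * dead_B + 4L * dead_A
  factor(lab[idx], levels = CATEGORIES)
}

#' Summarize death concordance over the matched cohort
#'
#' Tallies the eight categories, derives the union of deaths (subjects dead
#' in at least one source), per-source totals, and every printed-style
#' percentage (half-up, two decimals): each category as a share of the
#' cohort and of the union, per-source totals as shares of the union
#' (source contributions) and of the cohort (capture rates), plus the seven
#' Venn region counts.
#'
#' @param status Either the data frame from [assign_death_status()] (a
#'   `category` column is added if absent) or a named vector of the eight
#'   category counts.
#' @return An object of class `concordance_summary`.
#' @export
summarize_concordance <- function(status) {
  if (is.data.frame(status)) {
    if (!nrow(status)) stop("empty death-status input")
    category <- status$category
    if (is.null(category)) category <- classify_death_status(status)
    counts <- as.integer(table(factor(category, levels = CATEGORIES)))
  } else {
    counts <- unlist(status)
    if (!setequal(names(counts), CATEGORIES)) {
      stop("counts must be named with the 8 categories: ",
           paste(CATEGORIES, collapse = ", "))
    }
    counts <- as.integer(counts[CATEGORIES])
    if (sum(counts) == 0) stop("empty death-status input")
  }
  names(counts) <- CATEGORIES
  n_matched <- sum(counts)
  union_deaths <- n_matched - counts[["none"]]
  totals <- c(
    SYSTEM_A = counts[["ABS"]] + counts[["AB"]] + counts[["AS"]] + counts[["A_only"]],
    SYSTEM_B = counts[["ABS"]] + counts[["AB"]] + counts[["BS"]] + counts[["B_only"]],
    SSADMF = counts[["ABS"]] + counts[["AS"]] + counts[["BS"]] + counts[["S_only"]]
  )
  death_cats <- setdiff(CATEGORIES, "none")
  pct_of_cohort <- pct2(counts, n_matched)
  pct_of_union <- if (union_deaths > 0) {
    stats::setNames(pct2(counts[death_cats], union_deaths), death_cats)
  } else {
    stats::setNames(rep(NA_real_, 7), death_cats)
  }
  contribution_pct <- if (union_deaths > 0) pct2(totals, union_deaths) else
    stats::setNames(rep(NA_real_, 3), names(totals))
  capture_rate_pct <- pct2(totals, n_matched)
  venn <- c(A = counts[["A_only"]], B = counts[["B_only"]], S = counts[["S_only"]],
            AB = counts[["AB"]], AS = counts[["AS"]], BS = counts[["BS"]],
            ABS = counts[["ABS"]])

  structure(list(
    n_matched = n_matched, counts = counts, union_deaths = union_deaths,
    totals = totals, pct_of_cohort = pct_of_cohort,
    pct_of_union = pct_of_union, contribution_pct = contribution_pct,
    capture_rate_pct = capture_rate_pct, venn = venn
  ), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("Death concordance over %s matched patients\n",
              format(x$n_matched, big.mark = ",")))
  lab <- c(ABS = "Deaths in all 3 sources",
           AB = "Deaths in systems A and B only",
           AS = "Deaths in system A and extract only",
           BS = "Deaths in system B and extract only",
           A_only = "Deaths in system A only",
           B_only = "Deaths in system B only",
           S_only = "Deaths in extract only",
           none = "Not dead in any source")
  for (k in CATEGORIES) {
    cat(sprintf("  %-38s %10s (%.2f%%)\n", lab[[k]],
                format(x$counts[[k]], big.mark = ","), x$pct_of_cohort[[k]]))
  }
  cat(sprintf("  union of deaths: %s; per-source totals A=%s B=%s S=%s\n",
              format(x$union_deaths, big.mark = ","),
              format(x$totals[["SYSTEM_A"]], big.mark = ","),
              format(x$totals[["SYSTEM_B"]], big.mark = ","),
              format(x$totals[["SSADMF"]], big.mark = ",")))
  invisible(x)
}

#' Export the three-set Venn region counts
#'
#' Returns the seven labelled region counts of the A/B/extract Venn diagram;
#' they sum to the union of deaths.
#'
#' @param summary A `concordance_summary`.
#' @return Named integer vector with regions `A`, `B`, `S`, `AB`, `AS`,
#'   `BS`, `ABS`.
#' @export
export_venn <- function(summary) {
  stopifnot(inherits(summary, "concordance_summary"))
  summary$venn
}
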
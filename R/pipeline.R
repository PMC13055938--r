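# End-to-end driver: generate or ingest -> link -> classify -> agreement ->
# quality flags, plus report export and linkage evaluation against truth.

#' Evaluate resolved clusters against a generator truth table
#'
#' Compares the cross-source record pairs implied by the clusters with the
#' pairs implied by the truth table (one pair per source combination per
#' person) and reports pairwise precision and recall.
#'
#' @param clusters A `person_clusters` object.
#' @param truth Truth table from [generate_cohort()].
#' @return List with `precision`, `recall`, `n_predicted`, `n_truth`.
#' @export
evaluate_linkage <- function(clusters, truth) {
  truth_pairs <- function(id1, src1, id2, src2) {
    ok <- !is.na(id1) & !is.na(id2)
    paste(global_id(src1, id1[ok]), global_id(src2, id2[ok]))
  }
  tp <- c(
    truth_pairs(truth$record_id_A, "SYSTEM_A", truth$record_id_B, "SYSTEM_B"),
    truth_pairs(truth$record_id_A, "SYSTEM_A", truth$record_id_S, "SSADMF"),
    truth_pairs(truth$record_id_B, "SYSTEM_B", truth$record_id_S, "SSADMF")
  )
  mem <- clusters$members
  part <- function(src) mem[mem$source == src, c("cluster_id", "record_id")]
  pred_pairs <- function(src1, src2) {
    m <- merge(part(src1), part(src2), by = "cluster_id")
    if (!nrow(m)) return(character(0))
    paste(global_id(src1, m$record_id.x), global_id(src2, m$record_id.y))
  }
  pp <- c(pred_pairs("SYSTEM_A", "SYSTEM_B"),
          pred_pairs("SYSTEM_A", "SSADMF"),
          pred_pairs("SYSTEM_B", "SSADMF"))
  n_hit <- sum(pp %in% tp)
  list(
    precision = if (length(pp)) n_hit / length(pp) else NA_real_,
    recall = if (length(tp)) sum(tp %in% pp) / length(tp) else NA_real_,
    n_predicted = length(pp), n_truth = length(tp)
  )
}

#' Run the full mortality-concordance pipeline
#'
#' Executes generate (or ingest) -> cross-system linkage -> death-master
#' linkage -> cluster resolution -> death-status assignment -> 8-category
#' classification and summary -> Fleiss kappa -> the three quality
#' detectors. Input is either a `synthetic_config` (a cohort is generated),
#' a `synthetic_cohort`, or a plain list with elements `registry_A`,
#' `registry_B`, `ssadmf`, `encounters` and optionally `crosswalk` and
#' `truth`.
#'
#' @param x Input (see above).
#' @param salt Salt keying the linkage token digests.
#' @param use_crosswalk Use the A-B identifier crosswalk when present.
#' @param window_months Lost-contact window (months).
#' @param postdeath_days Post-death encounter threshold (days).
#' @param date_threshold_months Death-date discrepancy threshold (months).
#' @param ci_method,observed,n_boot,seed Passed to [fleiss_kappa()]; `seed`
#'   defaults to the generator seed when the input is synthetic.
#' @return Object of class `concordance_report`.
#' @export
run_pipeline <- function(x, salt = "deathconcord", use_crosswalk = TRUE,
                         window_months = 12, postdeath_days = 365,
                         date_threshold_months = 1,
                         ci_method = "asymptotic",
                         observed = "fleiss", n_boot = 1000L, seed = NULL) {
  stopifnot(window_months > 0, postdeath_days > 0, date_threshold_months >= 0)
  if (inherits(x, "synthetic_config")) {
    seed <- seed %||% x$seed
    x <- generate_cohort(x)
  }
  cohort <- x
  for (part in c("registry_A", "registry_B", "encounters")) {
    if (is.null(cohort[[part]]) || !nrow(cohort[[part]])) {
      stop(sprintf("ingest error: input '%s' is empty", part))
    }
  }
  crosswalk <- if (use_crosswalk) cohort$crosswalk else NULL

  clusters <- link_records(cohort$registry_A, cohort$registry_B,
                           ssadmf = cohort$ssadmf, crosswalk = crosswalk,
                           salt = salt)
  status <- assign_death_status(clusters, cohort$registry_A,
                                cohort$registry_B, cohort$ssadmf)
  status$category <- classify_death_status(status)
  summary <- summarize_concordance(status)
  agreement <- fleiss_kappa(summary, observed = observed,
                            ci_method = ci_method, n_boot = n_boot,
                            seed = seed)
  qc <- list(
    date_discrepancies = detect_date_discrepancies(status,
                                                   date_threshold_months),
    lost_contact = detect_lost_contact(cohort$encounters, clusters,
                                       window_months = window_months),
    postdeath = detect_postdeath_encounters(status, cohort$encounters,
                                            clusters,
                                            threshold_days = postdeath_days)
  )

  # whole-population view (matched and unmatched records per system)
  overall <- data.frame(
    source = c("SYSTEM_A", "SYSTEM_B", "SSADMF"),
    n_records = c(nrow(cohort$registry_A), nrow(cohort$registry_B),
                  if (is.null(cohort$ssadmf)) 0L else nrow(cohort$ssadmf)),
    n_deaths = c(sum(!is.na(cohort$registry_A$death_date)),
                 sum(!is.na(cohort$registry_B$death_date)),
                 if (is.null(cohort$ssadmf)) 0L else
                   sum(!is.na(cohort$ssadmf$death_date))),
    stringsAsFactors = FALSE
  )
  overall$death_pct <- pct2(overall$n_deaths, overall$n_records)

  linkage <- list(
    n_clusters = nrow(clusters$matched),
    n_matched = sum(clusters$matched$matched),
    evidence = if (nrow(clusters$evidence))
      as.data.frame(table(rule = clusters$evidence$rule),
                    stringsAsFactors = FALSE)
    else data.frame(rule = character(0), Freq = integer(0)),
    eval = if (!is.null(cohort$truth)) evaluate_linkage(clusters, cohort$truth)
  )

  params <- list(salt = salt, use_crosswalk = use_crosswalk,
                 window_months = window_months,
                 postdeath_days = postdeath_days,
                 date_threshold_months = date_threshold_months,
                 ci_method = ci_method, observed = observed, seed = seed)
  if (inherits(cohort, "synthetic_cohort")) {
    params$generator <- unclass(cohort$config)
  }
  params$config_hash <- as.character(
    openssl::sha256(paste(deparse(params), collapse = "\n")))

  structure(list(
    summary = summary, agreement = agreement, qc = qc, overall = overall,
    linkage = linkage, clusters = clusters, status = status, params = params,
    versions = list(r = R.version.string,
                    package = as.character(utils::packageVersion("deathconcord")))
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("=== Multi-source death concordance report ===\n")
  cat(sprintf("records: A=%s B=%s S=%s; matched clusters: %s\n",
              format(x$overall$n_records[1], big.mark = ","),
              format(x$overall$n_records[2], big.mark = ","),
              format(x$overall$n_records[3], big.mark = ","),
              format(x$linkage$n_matched, big.mark = ",")))
  print(x$summary)
  print(x$agreement)
  dd <- x$qc$date_discrepancies$summary
  cat(sprintf("date discrepancies >=%s month(s): %s\n",
              x$params$date_threshold_months,
              paste(sprintf("%s n=%d", dd$source_pair, dd$n_flagged),
                    collapse = ", ")))
  cat(sprintf("lost-contact flags: %d; post-death flags: %d\n",
              nrow(x$qc$lost_contact), nrow(x$qc$postdeath$flags)))
  invisible(x)
}

#' @export
summary.concordance_report <- function(object, ...) {
  print(object)
  cat("post-death rates per death source:\n")
  print(object$qc$postdeath$rates, row.names = FALSE)
  if (!is.null(object$linkage$eval)) {
    cat(sprintf("linkage vs truth: precision %.4f, recall %.4f\n",
                object$linkage$eval$precision, object$linkage$eval$recall))
  }
  invisible(object)
}

#' Write a report bundle to disk
#'
#' Exports the concordance table, Venn regions, agreement result, quality
#' flags and a JSON manifest (seed, parameters, config hash, versions) as
#' plain-text files. On failure, partially written outputs are removed.
#'
#' @param report A `concordance_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "concordance_report"))
  created <- !dir.exists(dir)
  if (created) dir.create(dir, recursive = TRUE)
  written <- character(0)
  emit_tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    written <<- c(written, p)
    p
  }
  emit_json <- function(x, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    written <<- c(written, p)
    p
  }
  tryCatch({
    s <- report$summary
    cat_tab <- data.frame(
      category = CATEGORIES, count = as.integer(s$counts),
      pct_of_cohort = s$pct_of_cohort,
      pct_of_union = c(s$pct_of_union, NA_real_)[match(CATEGORIES,
        c(names(s$pct_of_union), "none"))],
      stringsAsFactors = FALSE
    )
    emit_tsv(cat_tab, "concordance_table.tsv")
    emit_json(as.list(s$venn), "venn_regions.json")
    ag <- report$agreement
    emit_json(list(
      n_subjects = ag$n_subjects, n_raters = ag$n_raters,
      p_observed = ag$p_observed, p_expected = ag$p_expected,
      p_all_concur = ag$p_all_concur, kappa = ag$kappa,
      ci_low = ag$ci_low, ci_high = ag$ci_high, ci_method = ag$ci_method,
      observed = ag$observed
    ), "agreement.json")
    emit_tsv(report$qc$date_discrepancies$flags, "date_discrepancy_flags.tsv")
    emit_tsv(report$qc$date_discrepancies$summary, "date_discrepancy_summary.tsv")
    emit_tsv(report$qc$lost_contact, "lost_contact_flags.tsv")
    emit_tsv(report$qc$postdeath$flags, "postdeath_flags.tsv")
    emit_tsv(report$qc$postdeath$rates, "postdeath_rates.tsv")
    emit_tsv(report$overall, "overall_sources.tsv")
    emit_tsv(report$clusters$members, "clusters.tsv")
    emit_json(list(params = report$params, versions = report$versions,
                   n_matched = report$summary$n_matched,
                   union_deaths = report$summary$union_deaths),
              "manifest.json")
    invisible(written)
  }, error = function(e) {
    unlink(written)
    if (created) unlink(dir, recursive = TRUE)
    stop("report export failed: ", conditionMessage(e))
  })
}
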
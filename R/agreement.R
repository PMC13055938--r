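# Fleiss kappa multi-rater agreement over dead/not-dead assignments by the
# three sources, from the aggregated 8-category count table.
#
# With three raters and two categories, a subject assigned "dead" by k
# sources has per-subject agreement P_i = [k(k-1) + (3-k)(2-k)]/6. The mean
# observed agreement Pbar, the chance agreement Pe from the pooled marginal
# proportion of "dead" assignments, and kappa = (Pbar - Pe)/(1 - Pe) all
# follow from the category counts alone. Because the all-not-dead category
# dominates heavily in mortality data, Pe sits close to 1 and kappa is
# unstable: small discordance drives it strongly negative or positive (the
# classical kappa paradox under extreme class imbalance). The unanimity
# proportion (ABS + none)/N is therefore reported alongside as
# `p_all_concur` and can optionally replace Pbar in the kappa ratio.

.n_dead_by_cat <- c(ABS = 3L, AB = 2L, AS = 2L, BS = 2L,
                    A_only = 1L, B_only = 1L, S_only = 1L, none = 0L)

#' Per-subject agreement for three raters, two categories
#'
#' The Fleiss per-subject agreement for a subject assigned "dead" by
#' `n_dead` of `n_raters` raters: the fraction of concordant rater pairs,
#' `[n_dead (n_dead - 1) + (n - n_dead)(n - n_dead - 1)] / (n (n - 1))`.
#'
#' @param n_dead Integer vector of "dead" assignments per subject, each in
#'   `0..n_raters`.
#' @param n_raters Number of raters (default 3).
#' @return Numeric vector of agreements in `[1/3, 1]` for three raters.
#' @examples
#' per_subject_agreement(3) # 1
#' per_subject_agreement(1) # 1/3
#' @export
per_subject_agreement <- function(n_dead, n_raters = 3L) {
  n_dead <- as.integer(n_dead)
  if (any(is.na(n_dead)) || any(n_dead < 0L | n_dead > n_raters)) {
    stop(sprintf("n_dead must be in 0..%d", n_raters))
  }
  (n_dead * (n_dead - 1L) + (n_raters - n_dead) * (n_raters - n_dead - 1L)) /
    (n_raters * (n_raters - 1L))
}

as_category_counts <- function(x) {
  if (inherits(x, "concordance_summary")) return(x$counts)
  counts <- unlist(x)
  if (!setequal(names(counts), CATEGORIES)) {
    stop("counts must be named with the 8 categories: ",
         paste(CATEGORIES, collapse = ", "))
  }
  counts <- counts[CATEGORIES]
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("counts must be nonnegative with positive total")
  }
  counts
}

kappa_core <- function(counts, observed) {
  N <- sum(counts)
  n_dead <- .n_dead_by_cat[names(counts)]
  p_obs <- sum(counts * per_subject_agreement(n_dead)) / N
  p_dead <- sum(counts * n_dead) / (3 * N)
  p_exp <- p_dead^2 + (1 - p_dead)^2
  p_all <- (counts[["ABS"]] + counts[["none"]]) / N
  if (p_exp >= 1) {
    stop("kappa undefined: expected agreement is 1 (a single category used by all raters everywhere)")
  }
  top <- if (observed == "all-concur") p_all else p_obs
  list(N = N, p_observed = p_obs, p_expected = p_exp, p_all_concur = p_all,
       p_dead = p_dead, kappa = (top - p_exp) / (1 - p_exp))
}

# Fleiss-Nee-Landis large-sample standard error of overall kappa
# (two categories j with marginals pj, qj = 1 - pj; n raters, N subjects)
kappa_se_fnl <- function(N, p_dead, n_raters = 3L) {
  pj <- c(p_dead, 1 - p_dead)
  qj <- 1 - pj
  s <- sum(pj * qj)
  sqrt(2 / (N * n_raters * (n_raters - 1))) *
    sqrt(s^2 - sum(pj * qj * (qj - pj))) / s
}

#' Fleiss kappa from an 8-category death-concordance table
#'
#' Computes observed agreement (mean per-subject pairwise agreement), the
#' unanimity proportion, expected chance agreement from the pooled marginal
#' proportion of "dead" assignments, Fleiss kappa and a confidence interval,
#' all from the aggregated category counts (exactly equivalent to expanding
#' the table into one row per subject).
#'
#' @param counts Named counts for the eight categories, or a
#'   `concordance_summary`.
#' @param observed Which observed-agreement definition feeds the kappa
#'   ratio: `"fleiss"` (default; mean pairwise agreement) or `"all-concur"`
#'   (proportion of subjects on whom all three sources concur). Both
#'   quantities are always reported.
#' @param ci_method `"asymptotic"` (Fleiss-Nee-Landis large-sample standard
#'   error) or `"bootstrap"` (percentile interval over multinomial subject
#'   resampling).
#' @param conf_level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates (>= 200; default 1000).
#' @param seed Seed for the bootstrap; required for reproducible intervals.
#' @return Object of class `fleiss_kappa` with fields `n_subjects`,
#'   `n_raters`, `p_observed`, `p_expected`, `p_all_concur`, `kappa`,
#'   `ci_low`, `ci_high`, `ci_method`, `conf_level`, `se` (asymptotic only),
#'   `observed`, `counts`.
#' @export
fleiss_kappa <- function(counts, observed = c("fleiss", "all-concur"),
                         ci_method = c("asymptotic", "bootstrap"),
                         conf_level = 0.95, n_boot = 1000L, seed = NULL) {
  observed <- match.arg(observed)
  ci_method <- match.arg(ci_method)
  counts <- as_category_counts(counts)
  core <- kappa_core(counts, observed)
  ci <- kappa_ci(counts, method = ci_method, conf_level = conf_level,
                 n_boot = n_boot, seed = seed, observed = observed)

  structure(list(
    n_subjects = core$N, n_raters = 3L,
    p_observed = core$p_observed, p_expected = core$p_expected,
    p_all_concur = core$p_all_concur, kappa = core$kappa,
    ci_low = ci[[1]], ci_high = ci[[2]], ci_method = ci_method,
    conf_level = conf_level, se = attr(ci, "se"),
    observed = observed, counts = counts
  ), class = "fleiss_kappa")
}

#' Confidence interval for Fleiss kappa
#'
#' @inheritParams fleiss_kappa
#' @param method `"asymptotic"` or `"bootstrap"`.
#' @return Length-2 numeric `(ci_low, ci_high)`; the asymptotic interval
#'   carries the standard error as attribute `"se"`.
#' @export
kappa_ci <- function(counts, method = c("asymptotic", "bootstrap"),
                     conf_level = 0.95, n_boot = 1000L, seed = NULL,
                     observed = "fleiss") {
  method <- match.arg(method)
  counts <- as_category_counts(counts)
  core <- kappa_core(counts, observed)
  if (method == "asymptotic") {
    se <- kappa_se_fnl(core$N, core$p_dead)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- c(core$kappa - z * se, core$kappa + z * se)
    attr(ci, "se") <- se
    return(ci)
  }
  if (n_boot < 200L) stop("bootstrap requires n_boot >= 200")
  if (!is.null(seed)) set.seed(sub_seed(seed, 9L))
  reps <- stats::rmultinom(n_boot, size = core$N, prob = counts / core$N)
  rownames(reps) <- names(counts)
  n_dead <- .n_dead_by_cat[names(counts)]
  P_i <- per_subject_agreement(n_dead)
  p_obs <- colSums(reps * P_i) / core$N
  p_dead <- colSums(reps * n_dead) / (3 * core$N)
  p_exp <- p_dead^2 + (1 - p_dead)^2
  top <- if (observed == "all-concur") {
    (reps["ABS", ] + reps["none", ]) / core$N
  } else {
    p_obs
  }
  k <- ifelse(p_exp < 1, (top - p_exp) / (1 - p_exp), NA_real_)
  alpha <- (1 - conf_level) / 2
  stats::quantile(k, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
}

#' @export
print.fleiss_kappa <- function(x, ...) {
  cat(sprintf(
    "Fleiss kappa over %s subjects x %d raters (dead / not dead)\n",
    format(x$n_subjects, big.mark = ","), x$n_raters))
  cat(sprintf("  observed agreement (mean pairwise) : %.4f\n", x$p_observed))
  cat(sprintf("  all-sources-concur proportion      : %.4f\n", x$p_all_concur))
  cat(sprintf("  expected agreement (chance)        : %.4f\n", x$p_expected))
  cat(sprintf("  kappa [observed = %s]%s: %.3f  (%d%% CI %.3f to %.3f, %s)\n",
              x$observed,
              strrep(" ", max(0, 13 - nchar(x$observed))), x$kappa,
              round(100 * x$conf_level), x$ci_low, x$ci_high, x$ci_method))
  invisible(x)
}

#' @export
summary.fleiss_kappa <- function(object, ...) {
  print(object)
  cat("  category counts:\n")
  for (k in CATEGORIES) {
    cat(sprintf("    %-7s %12s\n", k, format(object$counts[[k]], big.mark = ",")))
  }
  invisible(object)
}

#' @export
confint.fleiss_kappa <- function(object, parm = "kappa", level = 0.95, ...) {
  ci <- kappa_ci(object$counts, method = object$ci_method, conf_level = level,
                 observed = object$observed, seed = NULL)
  out <- matrix(as.numeric(ci), nrow = 1,
                dimnames = list("kappa",
                                sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                           1 - (1 - level) / 2))))
  out
}
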
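#' Synthetic cohort configuration
#'
#' Parameters of the simulated lesion cohort. Defaults mirror the structure
#' of a 39-lesion clinical series: 33 invasive carcinomas (IBC) and 6 in-situ
#' lesions (DCIS), visibility probability 29/39, CAIX positivity confined to
#' IBC at 11/33, a lesion SO2 deficit of 0.15 against an 0.85 subcutaneous
#' baseline, and per-measurement noise SD 0.08.
#'
#' @param n_ibc,n_dcis,n_benign class counts.
#' @param subcut_mean mean subcutaneous-vessel SO2 (fraction).
#' @param lesion_shift lesion SO2 shift relative to the contralateral-normal
#'   level (negative = hypoxic lesions).
#' @param contralateral_shift contralateral-normal shift from the
#'   subcutaneous baseline.
#' @param noise_sd per-measurement Gaussian noise SD.
#' @param visibility_prob probability a malignant lesion produces signal.
#' @param caix_prob_ibc,caix_prob_dcis CAIX positivity probabilities.
#' @param pst_prob probability of primary systemic therapy history.
#' @param tvp_meanlog,tvp_sdlog log-normal parameters of TVP/area (um/mm^2).
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_ibc = 33, n_dcis = 6, n_benign = 0,
                        subcut_mean = 0.85, lesion_shift = -0.15,
                        contralateral_shift = -0.03, noise_sd = 0.08,
                        visibility_prob = 29 / 39,
                        caix_prob_ibc = 11 / 33, caix_prob_dcis = 0,
                        pst_prob = 13 / 39,
                        tvp_meanlog = log(6), tvp_sdlog = 0.55) {
  probs <- c(visibility_prob, caix_prob_ibc, caix_prob_dcis, pst_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_ibc >= 0, n_dcis >= 0, n_benign >= 0, noise_sd >= 0)
  structure(list(n_ibc = n_ibc, n_dcis = n_dcis, n_benign = n_benign,
                 subcut_mean = subcut_mean, lesion_shift = lesion_shift,
                 contralateral_shift = contralateral_shift, noise_sd = noise_sd,
                 visibility_prob = visibility_prob,
                 caix_prob_ibc = caix_prob_ibc, caix_prob_dcis = caix_prob_dcis,
                 pst_prob = pst_prob, tvp_meanlog = tvp_meanlog,
                 tvp_sdlog = tvp_sdlog),
            class = "cohort_spec")
}

#' Sample a synthetic lesion cohort
#'
#' One row per lesion with paired SO2 readings. Per case, the subcutaneous
#' SO2 is `subcut_mean` plus noise; the contralateral-normal SO2 adds
#' `contralateral_shift`; the lesional SO2 equals that case's contralateral
#' value plus `lesion_shift` plus noise — so with zero shift and zero noise
#' the lesional and contralateral readings are identical, and the paired
#' lesion-minus-normal difference has expectation `lesion_shift`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; the table is reproducible for a fixed spec+seed.
#' @return data.frame: case_id, class (IBC/DCIS/benign), so2_lesion,
#'   so2_subcutaneous, so2_contralateral, visible, caix, pst, tvp_area.
#' @export
cohort_sampler <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_ibc + spec$n_dcis + spec$n_benign
  cls <- c(rep("IBC", spec$n_ibc), rep("DCIS", spec$n_dcis),
           rep("benign", spec$n_benign))
  with_seed(seed, {
    subcut <- spec$subcut_mean + stats::rnorm(n, 0, spec$noise_sd)
    contral <- spec$subcut_mean + spec$contralateral_shift +
      stats::rnorm(n, 0, spec$noise_sd)
    lesion <- contral + spec$lesion_shift + stats::rnorm(n, 0, spec$noise_sd)
    caix_p <- ifelse(cls == "IBC", spec$caix_prob_ibc,
                     ifelse(cls == "DCIS", spec$caix_prob_dcis, 0))
    data.frame(case_id = sprintf("case_%03d", seq_len(n)),
               class = cls,
               so2_lesion = lesion,
               so2_subcutaneous = subcut,
               so2_contralateral = contral,
               visible = stats::runif(n) < spec$visibility_prob,
               caix = stats::runif(n) < caix_p,
               pst = stats::runif(n) < spec$pst_prob,
               tvp_area = stats::rlnorm(n, spec$tvp_meanlog, spec$tvp_sdlog),
               stringsAsFactors = FALSE)
  })
}

new_test_result <- function(statistic, p_value, method, n, ties = 0L,
                            zeros = 0L, extra = list()) {
  structure(c(list(statistic = unname(statistic), p_value = unname(p_value),
                   method = method, n = n, ties = ties, zeros = zeros), extra),
            class = "pam_test_result")
}

#' @export
print.pam_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Pearson chi-square test of association (2 x 2)
#'
#' Without continuity correction by default (the convention that reproduces
#' standard clinical-software output for contingency rows); Yates correction
#' is available via `correct = TRUE`.
#'
#' @param tab 2 x 2 matrix of counts.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return a `pam_test_result` with chi-square statistic and df = 1 p value.
#' @export
pearson_chi_square <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square test undefined: a row or column margin is zero", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  new_test_result(res$statistic, res$p.value, "pearson_chi_square",
                  n = sum(tab), extra = list(df = unname(res$parameter)))
}

#' Mann-Whitney U test (two independent samples)
#'
#' Exact p when min(n) <= 8 and there are no ties; otherwise the normal
#' approximation with tie-corrected variance and no continuity correction.
#'
#' @param x,y numeric samples (both nonempty).
#' @return a `pam_test_result` with U (the Wilcoxon rank-sum W of `x`).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  ties <- sum(duplicated(c(x, y)))
  if (length(unique(c(x, y))) == 1) {
    # fully tied samples: U at its null expectation, no evidence either way
    return(new_test_result(length(x) * length(y) / 2, 1, "mann_whitney_u",
                           n = c(length(x), length(y)), ties = ties,
                           extra = list(exact = FALSE)))
  }
  exact <- min(length(x), length(y)) <= 8 && ties == 0
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  new_test_result(res$statistic, res$p.value, "mann_whitney_u",
                  n = c(length(x), length(y)), ties = ties,
                  extra = list(exact = exact))
}

#' Wilcoxon signed-rank test (paired)
#'
#' Zero differences are dropped (classic convention) and counted. Exact p for
#' at most 20 nonzero differences without tied magnitudes; otherwise the
#' tie-corrected normal approximation without continuity correction. All
#' differences zero gives a flagged degenerate result (p = NA).
#'
#' @param x,y paired numeric vectors of equal length; alternatively pass the
#'   differences as `x` with `y = NULL`.
#' @return a `pam_test_result` with V, zeros dropped, and `degenerate` flag.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  if (length(d) == 0) stop("no pairs supplied", call. = FALSE)
  zeros <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0) {
    return(new_test_result(NA_real_, NA_real_, "wilcoxon_signed_rank",
                           n = 0L, zeros = zeros,
                           extra = list(degenerate = TRUE, exact = FALSE)))
  }
  ties <- sum(duplicated(abs(d)))
  exact <- length(d) <= 20 && ties == 0
  res <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = FALSE))
  new_test_result(res$statistic, res$p.value, "wilcoxon_signed_rank",
                  n = length(d), ties = ties, zeros = zeros,
                  extra = list(degenerate = FALSE, exact = exact))
}

#' Kruskal-Wallis rank test (three or more groups)
#'
#' @param groups list of at least three nonempty numeric samples.
#' @return a `pam_test_result` with the tie-corrected H statistic and
#'   chi-square (k - 1 df) p value.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 3) {
    stop("fewer than 3 groups: use mann_whitney_u() for two-group comparisons",
         call. = FALSE)
  }
  if (any(lengths(groups) == 0)) stop("all groups must be nonempty", call. = FALSE)
  res <- stats::kruskal.test(groups)
  new_test_result(res$statistic, res$p.value, "kruskal_wallis",
                  n = lengths(groups), extra = list(df = unname(res$parameter)))
}

#' Pearson correlation with t-based test
#'
#' @param x,y numeric samples of equal length >= 3, neither constant.
#' @return a `pam_test_result` carrying r, R^2 and the two-sided p value from
#'   the t transform with n - 2 degrees of freedom.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant sample", call. = FALSE)
  }
  res <- stats::cor.test(x, y, method = "pearson")
  new_test_result(unname(res$estimate), res$p.value, "pearson_correlation",
                  n = length(x),
                  extra = list(r = unname(res$estimate),
                               r_squared = unname(res$estimate)^2,
                               t = unname(res$statistic)))
}

#' Cohort visibility accounting
#'
#' Overall, non-visibility and per-class (IBC, DCIS) visibility rates among
#' malignant lesions; benign rows are excluded before any rate is computed.
#' Rates are percentages with numerators and denominators reported.
#'
#' @param cohort data.frame with columns `class` (IBC/DCIS/benign) and
#'   `visible` (logical).
#' @return list of rates (percent) and count pairs.
#' @export
visibility_summary <- function(cohort) {
  stopifnot(all(c("class", "visible") %in% names(cohort)))
  mal <- cohort[cohort$class %in% c("IBC", "DCIS"), ]
  if (nrow(mal) == 0) stop("no malignant lesions in the cohort", call. = FALSE)
  rate <- function(sub) {
    if (nrow(sub) == 0) return(list(rate_pct = NA_real_, n_visible = 0L, n = 0L))
    list(rate_pct = 100 * sum(sub$visible) / nrow(sub),
         n_visible = sum(sub$visible), n = nrow(sub))
  }
  overall <- rate(mal)
  list(visibility_rate_pct = overall$rate_pct,
       non_visibility_rate_pct = 100 - overall$rate_pct,
       n_visible = overall$n_visible,
       n_malignant = overall$n,
       ibc = rate(mal[mal$class == "IBC", ]),
       dcis = rate(mal[mal$class == "DCIS", ]),
       n_benign_excluded = sum(cohort$class == "benign"))
}
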
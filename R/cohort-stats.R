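# Cohort statistics layer: normality-gated summaries, Mann-Whitney
# comparisons, Spearman correlation with OLS regression overlay, PM-metric
# scaling, and RI/CXI probability histograms.

#' Normality-gated summary of a metric
#'
#' Applies a Shapiro-Wilk normality test; if normality is not rejected
#' (p > alpha) the value is summarized as mean +/- sample SD, otherwise as
#' median +/- MAD. The MAD is the raw median absolute deviation from the
#' median, without the 1.4826 normal-consistency factor, matching the
#' convention of cohort tables that pair medians with raw MADs.
#'
#' @param values numeric vector, n >= 3
#' @param alpha significance level of the normality gate (default 0.05)
#' @return list with n, normal, center, dispersion, min, max, center_kind
#'   ("mean_sd" or "median_mad") and shapiro_p
#' @export
summarize_metric <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("insufficient data: need at least 3 finite values")
  # shapiro.test errors on zero-variance input; constant data is non-normal
  sw <- try(stats::shapiro.test(values), silent = TRUE)
  p <- if (inherits(sw, "try-error")) 0 else sw$p.value
  normal <- p > alpha
  if (normal) {
    center <- mean(values); dispersion <- stats::sd(values)
  } else {
    center <- stats::median(values)
    dispersion <- stats::mad(values, constant = 1)
  }
  list(n = n, normal = normal, center = center, dispersion = dispersion,
       min = min(values), max = max(values),
       center_kind = if (normal) "mean_sd" else "median_mad",
       shapiro_p = p)
}

#' Two-sided Mann-Whitney comparison of two groups
#'
#' Wraps the Wilcoxon rank-sum test: exact null distribution when both
#' groups have at most `exact_max` observations and there are no ties,
#' otherwise the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param a,b numeric vectors (non-empty)
#' @param exact_max size threshold below which the exact test is used
#' @return list with statistic (U), p_value, n_a, n_b, exact
#' @export
mann_whitney <- function(a, b, exact_max = 8) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= exact_max && length(b) <= exact_max && !ties
  wt <- stats::wilcox.test(a, b, exact = exact, correct = !exact)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(a), n_b = length(b), exact = exact)
}

#' Spearman correlation with OLS regression overlay
#'
#' Computes Spearman's rho (average ranks for ties) with its p-value, an
#' ordinary least-squares fit of y on the raw x values, and the pointwise
#' 95% mean-response confidence band of the fit on a grid over the x range.
#'
#' @param x,y numeric vectors of equal length, n >= 3
#' @param grid_n number of grid points for the confidence band
#' @return list with spearman_rho, p_value, slope, intercept and `band`
#'   (data.frame x, fit, lwr, upr)
#' @export
spearman_regression <- function(x, y, grid_n = 50) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("insufficient data: need at least 3 paired values")
  if (stats::sd(x) == 0) stop("constant x: regression undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  fit <- stats::lm(y ~ x)
  grid <- data.frame(x = seq(min(x), max(x), length.out = grid_n))
  pr <- stats::predict(fit, newdata = grid, interval = "confidence", level = 0.95)
  list(spearman_rho = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
       band = data.frame(x = grid$x, fit = pr[, "fit"], lwr = pr[, "lwr"],
                         upr = pr[, "upr"]))
}

#' Scale PM segment metrics by the specimen's muscular area
#'
#' For cross-specimen comparability, segment area is normalized to the total
#' muscular area CTI_m, and segment length and diameter to sqrt(CTI_m)
#' (lengths scale with the square root of area). The scaled metrics are
#' invariant under a uniform rescaling of all geometry.
#'
#' @param metrics data.frame with columns A, L, D (as from
#'   [segment_morphometry()])
#' @param cti_m total muscular area of the specimen (mm^2), > 0
#' @return the input data.frame with columns A_scaled, L_scaled, D_scaled
#'   appended
#' @export
scale_pm_metrics <- function(metrics, cti_m) {
  if (!is.finite(cti_m) || cti_m <= 0) stop("cti_m must be > 0")
  metrics$A_scaled <- metrics$A / cti_m
  metrics$L_scaled <- metrics$L / sqrt(cti_m)
  metrics$D_scaled <- metrics$D / sqrt(cti_m)
  metrics
}

#' Pairwise Mann-Whitney comparison across groups
#'
#' Unadjusted two-sided p-values for every pair of groups, as a symmetric
#' matrix with an empty (NA) diagonal. No multiple-testing adjustment is
#' applied by default; set `adjust = "holm"` (or any [stats::p.adjust()]
#' method) to adjust the off-diagonal p-values.
#'
#' @param groups named list of numeric vectors (>= 2 groups)
#' @param adjust p-value adjustment method, default "none"
#' @return symmetric matrix of p-values; cells with insufficient data are NA
#' @export
pairwise_compare <- function(groups, adjust = "none") {
  if (length(groups) < 2) stop("need at least 2 groups")
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      res <- try(mann_whitney(groups[[i]], groups[[j]]), silent = TRUE)
      if (!inherits(res, "try-error")) p[i, j] <- p[j, i] <- res$p_value
    }
  }
  if (adjust != "none") {
    up <- upper.tri(p)
    adj <- stats::p.adjust(p[up], method = adjust)
    p[up] <- adj
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  p
}

#' Per-level probability histograms of RI and CXI
#'
#' For each ramification level, tabulates the ramification index RI and the
#' complexity index CXI over all (non-virtual) ramifications at that level
#' and normalizes the counts so each table sums to 1. At level c the CXI
#' table equals the RI table (no afferent segments exist at TC exit sites);
#' at level v it equals the RI table mirrored to negative values (no
#' efferents). Levels with no ramifications are skipped with a note in
#' `skipped`.
#'
#' @param records complexity table from [complexity()] (rows may span many
#'   specimens)
#' @return list with `levels` (per level: list of RI and CXI named
#'   probability vectors and their supports) and `skipped`
#' @export
ri_cxi_histogram <- function(records) {
  records <- records[!records$virtual, , drop = FALSE]
  out <- list()
  skipped <- character(0)
  for (lev in CTI_LEVELS) {
    rr <- records[records$level == lev, , drop = FALSE]
    if (nrow(rr) == 0) { skipped <- c(skipped, lev); next }
    ri_t <- table(rr$RI) / nrow(rr)
    cxi_t <- table(rr$CXI) / nrow(rr)
    out[[lev]] <- list(
      RI = stats::setNames(as.numeric(ri_t), names(ri_t)),
      CXI = stats::setNames(as.numeric(cxi_t), names(cxi_t)),
      RI_support = range(rr$RI), CXI_support = range(rr$CXI), n = nrow(rr))
  }
  list(levels = out, skipped = skipped)
}
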
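#' Classify an I-squared percentage into the standard bands
#'
#' 0-25% low, 25-50% moderate, 50-75% large, 75-100% extreme; boundaries
#' belong to the upper band except 100, so the bands are exhaustive and
#' mutually exclusive over [0, 100].
#'
#' @param i2 numeric vector of I-squared values in percent.
#' @return Factor with levels `low`, `moderate`, `large`, `extreme`.
#' @export
i2_band <- function(i2) {
  stopifnot(all(i2 >= 0 & i2 <= 100))
  cut(i2, breaks = c(0, 25, 50, 75, 100), right = FALSE,
      include.lowest = TRUE,
      labels = c("low", "moderate", "large", "extreme"))
}

#' Cochran's Q and I-squared for one variant across two datasets
#'
#' Treats the two datasets' Wald ratios of the same variant as two study
#' estimates in a fixed-effect meta-analysis. With inverse-variance weights
#' w = 1/v and pooled mean theta_bar, Q = sum w (theta - theta_bar)^2,
#' which for k = 2 reduces to (theta_a - theta_b)^2 / (v_a + v_b); the tail
#' probability is chi-square with k - 1 = 1 df and
#' I^2 = max(0, (Q - 1)/Q) * 100.
#'
#' @param wald_a,wald_b single-row data frames (or lists) with `rsid`,
#'   `theta`, `variance` — one variant's Wald estimate in each dataset.
#' @return One-row data frame: `rsid`, `theta_a`, `theta_b`, `var_a`,
#'   `var_b`, `q`, `q_p`, `i2`, `band`.
#' @export
variant_heterogeneity <- function(wald_a, wald_b) {
  if (!identical(as.character(wald_a$rsid), as.character(wald_b$rsid)))
    stop("rsid mismatch: ", wald_a$rsid, " vs ", wald_b$rsid)
  if (wald_a$variance <= 0 || wald_b$variance <= 0)
    stop("nonpositive variance")
  w_a <- 1 / wald_a$variance; w_b <- 1 / wald_b$variance
  pooled <- (w_a * wald_a$theta + w_b * wald_b$theta) / (w_a + w_b)
  q <- w_a * (wald_a$theta - pooled)^2 + w_b * (wald_b$theta - pooled)^2
  i2 <- max(0, (q - 1) / q) * 100
  data.frame(rsid = as.character(wald_a$rsid),
             theta_a = wald_a$theta, theta_b = wald_b$theta,
             var_a = wald_a$variance, var_b = wald_b$variance,
             q = q, q_p = stats::pchisq(q, df = 1, lower.tail = FALSE),
             i2 = i2, band = as.character(i2_band(i2)),
             stringsAsFactors = FALSE)
}

#' Per-variant heterogeneity between two harmonized panels
#'
#' Computes each shared variant's Wald ratio in both panels and its
#' two-dataset Cochran's Q / I-squared, plus the counts of variants whose
#' I-squared strictly exceeds 25% and 50% (boundary values land in the
#' lower count) and a paired t test of the two sets of Wald estimators.
#'
#' @param panel_a,panel_b `harmonized_panel`s sharing the requested rsids
#'   (same exposure).
#' @param rsids variants to compare; defaults to all shared variants.
#' @return An `mr_het` object: `table` (one row per variant), `n_gt25`,
#'   `n_gt50`, `paired_t` (see [paired_t_test()]), and the dataset labels.
#' @export
heterogeneity_table <- function(panel_a, panel_b, rsids = NULL) {
  stopifnot(inherits(panel_a, "harmonized_panel"),
            inherits(panel_b, "harmonized_panel"))
  if (is.null(rsids))
    rsids <- intersect(panel_a$variants$rsid, panel_b$variants$rsid)
  rsids <- as.character(rsids)
  if (length(rsids) == 0L) stop("no variants to compare")
  if (!all(rsids %in% panel_a$variants$rsid) ||
      !all(rsids %in% panel_b$variants$rsid))
    stop("some requested rsids are absent from one of the panels")
  wa <- wald_ratio(subset_panel(panel_a, rsids))
  wb <- wald_ratio(subset_panel(panel_b, rsids))
  rownames(wa) <- wa$rsid; rownames(wb) <- wb$rsid
  wa <- wa[rsids, ]; wb <- wb[rsids, ]
  tab <- do.call(rbind, lapply(seq_along(rsids), function(i)
    variant_heterogeneity(wa[i, ], wb[i, ])))
  rownames(tab) <- NULL
  pt <- if (length(rsids) >= 2L && stats::sd(wa$theta - wb$theta) > 0) {
    paired_t_test(wa$theta, wb$theta)
  } else {
    # identical estimates (or a single variant): the paired test is
    # degenerate, report the means without a statistic
    list(mean_a = mean(wa$theta), mean_b = mean(wb$theta),
         mean_diff = mean(wa$theta - wb$theta), t_stat = NA_real_,
         df = length(rsids) - 1L, pvalue = NA_real_, n = length(rsids))
  }
  structure(list(table = tab,
                 n_gt25 = sum(tab$i2 > 25),
                 n_gt50 = sum(tab$i2 > 50),
                 paired_t = pt,
                 label_a = panel_a$outcome_label,
                 label_b = panel_b$outcome_label),
            class = "mr_het")
}

#' @export
print.mr_het <- function(x, ...) {
  n <- nrow(x$table)
  cat(sprintf("Per-variant heterogeneity: %s vs %s (%d variants)\n",
              x$label_a, x$label_b, n))
  cat(sprintf("  I2 > 25%%: %d (%.0f%%);  I2 > 50%%: %d (%.0f%%)\n",
              x$n_gt25, 100 * x$n_gt25 / n, x$n_gt50, 100 * x$n_gt50 / n))
  pt <- x$paired_t
  cat(sprintf(paste0("  paired t: mean_a = %.3f, mean_b = %.3f, ",
                     "t = %.3f (df %d), p = %.3g\n"),
              pt$mean_a, pt$mean_b, pt$t_stat, pt$df, pt$pvalue))
  invisible(x)
}

#' Paired t test of Wald estimators between two datasets
#'
#' Tests whether the per-variant causal ratios differ on average between
#' two outcome datasets: d_j = theta_a_j - theta_b_j,
#' t = mean(d) / (sd(d)/sqrt(n)) with the sample (n - 1) standard
#' deviation, two-sided p from the t distribution with n - 1 df. Thin
#' wrapper over [stats::t.test()] that exposes the fields downstream
#' reports need.
#'
#' @param thetas_a,thetas_b equal-length numeric vectors (>= 2), aligned by
#'   variant.
#' @return List: `mean_a`, `mean_b`, `mean_diff`, `t_stat`, `df`, `pvalue`,
#'   `n`.
#' @export
paired_t_test <- function(thetas_a, thetas_b) {
  stopifnot(length(thetas_a) == length(thetas_b), length(thetas_a) >= 2L)
  d <- thetas_a - thetas_b
  if (stats::sd(d) == 0)
    stop("degenerate differences: zero variance between datasets")
  ht <- stats::t.test(thetas_a, thetas_b, paired = TRUE)
  list(mean_a = mean(thetas_a), mean_b = mean(thetas_b),
       mean_diff = mean(d), t_stat = unname(ht$statistic),
       df = as.integer(unname(ht$parameter)), pvalue = ht$p.value,
       n = length(d))
}
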
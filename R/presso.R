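#' @keywords internal
# deterministic per-variant seed derived from the master seed and the rsid,
# so simulation draws are keyed to variants, not to their position: results
# are invariant to row order. Kept below 2^31.
.rsid_seed <- function(seed, rsid) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(rsid)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# leave-one-out IVW slopes of beta_y on beta_x (weights 1/se_y^2); identical
# to the inverse-variance weighted mean of the ratios with variant j held out
.loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

# simulate n_sim parametric replicates of the panel under the no-pleiotropy
# null and return the replicate RSS values plus each variant's weighted
# squared residual across replicates (J x n_sim)
.presso_simulate <- function(v, theta_loo, n_sim, seed) {
  J <- nrow(v)
  w <- 1 / v$se_y^2
  X <- matrix(0, J, n_sim)
  Y <- matrix(0, J, n_sim)
  old <- .save_rng(); on.exit(.restore_rng(old))
  for (j in seq_len(J)) {
    set.seed(.rsid_seed(seed, v$rsid[j]))
    X[j, ] <- stats::rnorm(n_sim, mean = v$beta_x[j], sd = v$se_x[j])
    Y[j, ] <- stats::rnorm(n_sim, mean = theta_loo[j] * v$beta_x[j],
                           sd = v$se_y[j])
  }
  sxy <- colSums(w * X * Y)
  sxx <- colSums(w * X * X)
  loo <- (rep(sxy, each = J) - w * X * Y) / (rep(sxx, each = J) - w * X * X)
  r <- w * (Y - loo * X)^2
  list(rss = colSums(r), per_variant = r)
}

.presso_observed <- function(v) {
  w <- 1 / v$se_y^2
  theta_loo <- .loo_slopes(v$beta_x, v$beta_y, w)
  r_obs <- w * (v$beta_y - theta_loo * v$beta_x)^2
  list(w = w, theta_loo = theta_loo, r_obs = r_obs, rss = sum(r_obs))
}

#' Global pleiotropy test by simulated residual sums of squares
#'
#' Measures how far a panel departs from a single shared causal slope. The
#' observed statistic is the inverse-variance weighted residual sum of
#' squares, RSS = sum_j w_j (beta_y_j - theta_(-j) beta_x_j)^2 with
#' w_j = 1/se_y_j^2 and theta_(-j) the leave-one-out IVW slope. Its null
#' distribution is built by parametric simulation: each replicate redraws
#' beta_x_j ~ Normal(beta_x_j, se_x_j^2) and
#' beta_y_j ~ Normal(theta_(-j) beta_x_j, se_y_j^2) and recomputes the RSS
#' (with leave-one-out slopes re-estimated on the replicate). The p-value is
#' the add-one empirical tail probability, so it is never exactly zero and
#' is bounded below by 1/(n_sim + 1).
#'
#' Draws are taken from rsid-keyed substreams of `seed`, so the p-value does
#' not depend on variant order.
#'
#' @param panel a `harmonized_panel` with at least 4 variants.
#' @param n_sim number of simulated replicates (>= 100).
#' @param seed integer master seed.
#' @return An `mr_presso` object with `rss_observed`, `global_p`, `n_sim`,
#'   `seed`; the outlier fields are empty (see [presso_outlier_test()]).
#' @export
presso_global_test <- function(panel, n_sim = 10000L, seed = 1L) {
  v <- if (inherits(panel, "harmonized_panel")) panel$variants else panel
  if (nrow(v) < 4L) stop("global test needs >= 4 variants")
  if (n_sim < 100L) stop("n_sim < 100 gives an unstable p-value")
  obs <- .presso_observed(v)
  sim <- .presso_simulate(v, obs$theta_loo, n_sim, seed)
  structure(list(rss_observed = obs$rss,
                 global_p = (1 + sum(sim$rss >= obs$rss)) / (n_sim + 1),
                 n_sim = as.integer(n_sim),
                 outliers = data.frame(rsid = character(),
                                       outlier_p = numeric(),
                                       outlier_p_adj = numeric()),
                 corrected_estimate = NULL,
                 seed = as.integer(seed)),
            class = "mr_presso")
}

#' Per-variant outlier test and corrected estimate
#'
#' Runs the global simulation of [presso_global_test()] and additionally
#' compares each variant's observed weighted squared residual with its own
#' simulated null distribution, giving a per-variant empirical p-value
#' (add-one estimator), Bonferroni-adjusted by the number of variants.
#' Variants with adjusted p below `alpha` are flagged as horizontal-
#' pleiotropy outliers; the corrected estimate is the IVW fit of the panel
#' with the flagged variants removed (a single exclusion pass).
#'
#' @inheritParams presso_global_test
#' @param alpha significance level for flagging (applied to the
#'   Bonferroni-adjusted per-variant p).
#' @param ivw_model variance model for the corrected IVW estimate.
#' @return An `mr_presso` object; `outliers` lists the flagged rsids with
#'   raw and adjusted p-values, `corrected_estimate` is a `causal_estimate`.
#' @export
presso_outlier_test <- function(panel, n_sim = 10000L, seed = 1L,
                                alpha = 0.05, ivw_model = "auto") {
  v <- if (inherits(panel, "harmonized_panel")) panel$variants else panel
  if (nrow(v) < 4L) stop("outlier test needs >= 4 variants")
  if (n_sim < 100L) stop("n_sim < 100 gives an unstable p-value")
  J <- nrow(v)
  obs <- .presso_observed(v)
  sim <- .presso_simulate(v, obs$theta_loo, n_sim, seed)
  p_raw <- (1 + rowSums(sim$per_variant >= obs$r_obs)) / (n_sim + 1)
  p_adj <- pmin(1, p_raw * J)
  flag <- p_adj < alpha
  outliers <- data.frame(rsid = v$rsid[flag], outlier_p = p_raw[flag],
                         outlier_p_adj = p_adj[flag],
                         stringsAsFactors = FALSE)
  keep <- v[!flag, , drop = FALSE]
  corrected <- ivw(wald_ratio(keep), model = ivw_model)
  corrected$method <- "MR_PRESSO"
  structure(list(rss_observed = obs$rss,
                 global_p = (1 + sum(sim$rss >= obs$rss)) / (n_sim + 1),
                 n_sim = as.integer(n_sim),
                 outliers = outliers,
                 corrected_estimate = corrected,
                 seed = as.integer(seed)),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("Residual-sum-of-squares pleiotropy screen (n_sim = %d)\n",
              x$n_sim))
  cat(sprintf("  observed RSS = %.4f, global p = %.4g\n",
              x$rss_observed, x$global_p))
  if (nrow(x$outliers) > 0L) {
    cat("  outliers:", paste(x$outliers$rsid, collapse = ", "), "\n")
  } else if (!is.null(x$corrected_estimate)) {
    cat("  no significant outliers\n")
  }
  if (!is.null(x$corrected_estimate)) {
    cat("  corrected ")
    print(x$corrected_estimate)
  }
  invisible(x)
}
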
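#' Per-variant Wald ratio estimates
#'
#' For each harmonized variant the causal effect of the exposure on the
#' outcome is estimated by the ratio of the outcome and exposure effects,
#' theta_j = beta_y / beta_x, with first-order variance
#' v_j = se_y^2 / beta_x^2. The ratio is invariant to which allele is
#' declared the effect allele, since a flip negates numerator and
#' denominator together.
#'
#' @param panel a `harmonized_panel` (or its `variants` data frame).
#' @return Data frame with columns `rsid`, `theta`, `variance`.
#' @export
wald_ratio <- function(panel) {
  v <- if (inherits(panel, "harmonized_panel")) panel$variants else panel
  stopifnot(is.data.frame(v), nrow(v) >= 1L)
  if (any(abs(v$beta_x) < 1e-12))
    stop("undefined ratio: zero exposure effect (pre-filter with harmonize)")
  data.frame(rsid = v$rsid,
             theta = v$beta_y / v$beta_x,
             variance = v$se_y^2 / v$beta_x^2,
             stringsAsFactors = FALSE)
}

.z975 <- 1.959964

.causal_estimate <- function(method, beta, se, n_variants, df = Inf,
                             crit = .z975, extra = list()) {
  p <- if (is.finite(df)) 2 * stats::pt(-abs(beta / se), df = df)
       else 2 * stats::pnorm(-abs(beta / se))
  ci <- c(beta - crit * se, beta + crit * se)
  or <- to_odds_ratio(beta, se, crit = crit)
  structure(c(list(method = method, beta = beta, se = se,
                   ci_low = ci[1], ci_high = ci[2], pvalue = p,
                   or = or[["or"]], or_low = or[["or_low"]],
                   or_high = or[["or_high"]], n_variants = n_variants),
              extra),
            class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("%s (%d variants): OR %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$n_variants, x$or, x$or_low, x$or_high, x$pvalue))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  intercept %.4f [%.4f, %.4f], p = %.3g\n",
                x$egger_intercept, x$egger_intercept_ci[1],
                x$egger_intercept_ci[2], x$egger_intercept_p))
  invisible(x)
}

#' @export
as.data.frame.causal_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
             or = x$or, or_low = x$or_low, or_high = x$or_high,
             n_variants = x$n_variants, stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimate
#'
#' Combines per-variant Wald ratios with weights w_j = 1/v_j:
#' beta = sum(w theta) / sum(w). Under the fixed-effect model
#' se = (sum w)^(-1/2); the multiplicative random-effects model inflates it
#' by max(1, sqrt(Q/(J-1))) where Q = sum w (theta - beta)^2. `auto` uses
#' the fixed model below 4 variants and multiplicative random effects
#' otherwise. The point estimate is identical under every model.
#'
#' @param estimates data frame from [wald_ratio()] (columns `theta`,
#'   `variance`, optionally `rsid`).
#' @param model `"auto"`, `"fixed"` or `"multiplicative_random"`.
#' @return A `causal_estimate` (log-odds scale plus OR scale), p-value from
#'   the normal reference.
#' @export
ivw <- function(estimates, model = c("auto", "fixed",
                                     "multiplicative_random")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(estimates), nrow(estimates) >= 1L,
            all(estimates$variance > 0))
  w <- 1 / estimates$variance
  J <- nrow(estimates)
  beta <- sum(w * estimates$theta) / sum(w)
  se <- sqrt(1 / sum(w))
  if (model == "auto") model <- if (J < 4L) "fixed" else
    "multiplicative_random"
  if (model == "multiplicative_random" && J >= 2L) {
    q <- sum(w * (estimates$theta - beta)^2)
    se <- se * max(1, sqrt(q / (J - 1)))
  }
  .causal_estimate("IVW", beta, se, J)
}

#' Weighted median estimate
#'
#' The weighted median of the Wald ratios under inverse-variance weights:
#' with ratios sorted ascending and standardized cumulative weights
#' p_j = (S_j - w_j/2) / S_J, the estimate interpolates theta linearly at
#' p = 0.5. Consistent when at least half the weight comes from valid
#' instruments. The standard error is a parametric bootstrap: each ratio is
#' re-drawn as Normal(theta_j, v_j), the median recomputed, and the SD over
#' replicates taken.
#'
#' @inheritParams ivw
#' @param n_boot bootstrap replicates for the SE (default 10000).
#' @param seed integer seed for the bootstrap (required for
#'   reproducibility).
#' @return A `causal_estimate`, p-value from the normal reference.
#' @export
weighted_median <- function(estimates, n_boot = 10000L, seed) {
  stopifnot(is.data.frame(estimates), all(estimates$variance > 0))
  if (nrow(estimates) < 3L) stop("weighted median needs >= 3 variants")
  if (missing(seed)) stop("seed is required")
  w <- 1 / estimates$variance
  beta <- .weighted_median_point(estimates$theta, w)
  J <- nrow(estimates)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  draws <- matrix(stats::rnorm(J * n_boot, mean = estimates$theta,
                               sd = sqrt(estimates$variance)),
                  nrow = J, ncol = n_boot)
  boot <- vapply(seq_len(n_boot),
                 function(b) .weighted_median_point(draws[, b], w),
                 numeric(1))
  se <- stats::sd(boot)
  .causal_estimate("weighted_median", beta, se, J)
}

.weighted_median_point <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1] >= 0.5) return(theta[1])
  if (p[length(p)] <= 0.5) return(theta[length(theta)])
  k <- max(which(p < 0.5))
  theta[k] + (theta[k + 1] - theta[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects with an unconstrained intercept, weights 1/se_y^2. The slope is
#' the causal estimate; the intercept estimates the average directional
#' pleiotropy and its test (t reference, J - 2 df) is the usual screen for
#' directional pleiotropy. Each variant is first oriented so beta_x >= 0
#' (both betas negated otherwise), which the intercept requires for
#' identifiability. Standard errors use the multiplicative overdispersion
#' convention: the fixed-effect SE inflated by max(1, residual standard
#' error). Confidence intervals and p-values use the t distribution with
#' J - 2 df.
#'
#' @param panel a `harmonized_panel` (needs beta_x, beta_y, se_y).
#' @return A `causal_estimate` with extra fields `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_ci`, `egger_intercept_p`.
#' @export
mr_egger <- function(panel) {
  v <- if (inherits(panel, "harmonized_panel")) panel$variants else panel
  J <- nrow(v)
  if (J < 3L) stop("MR-Egger needs >= 3 variants")
  s <- ifelse(v$beta_x < 0, -1, 1)
  bx <- s * v$beta_x
  by <- s * v$beta_y
  if (max(bx) - min(bx) < 1e-14)
    stop("singular design: no spread in exposure effects")
  fit <- stats::lm(by ~ bx, weights = 1 / v$se_y^2)
  sm <- summary(fit)
  # fixed-effect SEs are sqrt(diag((X'WX)^-1)); the multiplicative
  # overdispersion model inflates them by the residual SD, floored at 1
  se_fixed <- sqrt(diag(sm$cov.unscaled))
  infl <- max(1, sm$sigma)
  slope <- unname(stats::coef(fit)[2])
  slope_se <- unname(se_fixed[2]) * infl
  int <- unname(stats::coef(fit)[1])
  int_se <- unname(se_fixed[1]) * infl
  crit <- stats::qt(0.975, df = J - 2)
  est <- .causal_estimate(
    "MR_Egger", slope, slope_se, J, df = J - 2, crit = crit,
    extra = list(egger_intercept = int,
                 egger_intercept_se = int_se,
                 egger_intercept_ci = c(int - crit * int_se,
                                        int + crit * int_se),
                 egger_intercept_p = 2 * stats::pt(-abs(int / int_se),
                                                   df = J - 2)))
  est
}

#' Convert a log-odds estimate to the odds-ratio scale
#'
#' @param beta log odds ratio per unit exposure.
#' @param se its standard error (> 0).
#' @param crit critical value for the 95% interval (default 1.959964).
#' @return Named numeric vector `or`, `or_low`, `or_high`.
#' @export
to_odds_ratio <- function(beta, se, crit = .z975) {
  stopifnot(se > 0)
  c(or = exp(beta), or_low = exp(beta - crit * se),
    or_high = exp(beta + crit * se))
}

# RNG bookkeeping: estimator seeds must not disturb the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Fit the full set of Mendelian randomization estimators to a panel
#'
#' The central model fit: per-variant Wald ratios combined by the requested
#' methods — inverse-variance weighted (the primary estimate), weighted
#' median, MR-Egger, and the outlier-corrected estimate after the
#' simulation-based residual screen ([presso_outlier_test()]). Reported on
#' both the log-odds and odds-ratio scales.
#'
#' @param panel a `harmonized_panel`.
#' @param methods subset of `c("ivw", "weighted_median", "mr_egger",
#'   "mr_presso")`.
#' @param seed integer seed driving the weighted-median bootstrap and the
#'   outlier-screen simulations.
#' @param n_boot bootstrap replicates for the weighted-median SE.
#' @param n_sim simulation replicates for the outlier screen.
#' @param alpha significance level of the outlier screen.
#' @param ivw_model IVW variance model, see [ivw()].
#' @return An `mr_fit` object: list with `estimates` (named list of
#'   `causal_estimate`s), `wald` (per-variant ratios), `panel`, `presso`
#'   (when run), and the call. Methods: `print`, `summary`, `coef`,
#'   `confint`, `plot`.
#' @examples
#' study <- simulate_study(sim_config(n_variants = 30, seed = 7))
#' panel <- harmonize_panel(study$exposure, study$outcomes$GWAS)
#' fit <- mr_fit(panel, methods = c("ivw", "weighted_median"), seed = 7,
#'               n_boot = 500)
#' coef(fit)
#' @export
mr_fit <- function(panel,
                   methods = c("ivw", "weighted_median", "mr_egger",
                               "mr_presso"),
                   seed = 1L, n_boot = 10000L, n_sim = 10000L,
                   alpha = 0.05, ivw_model = "auto") {
  stopifnot(inherits(panel, "harmonized_panel"))
  methods <- match.arg(methods, several.ok = TRUE)
  wald <- wald_ratio(panel)
  estimates <- list()
  presso <- NULL
  if ("ivw" %in% methods)
    estimates$ivw <- ivw(wald, model = ivw_model)
  if ("weighted_median" %in% methods)
    estimates$weighted_median <- weighted_median(wald, n_boot = n_boot,
                                                 seed = seed)
  if ("mr_egger" %in% methods)
    estimates$mr_egger <- mr_egger(panel)
  if ("mr_presso" %in% methods) {
    presso <- presso_outlier_test(panel, n_sim = n_sim, seed = seed,
                                  alpha = alpha, ivw_model = ivw_model)
    estimates$mr_presso <- presso$corrected_estimate
    estimates$mr_presso$method <- "MR_PRESSO"
  }
  structure(list(estimates = estimates, wald = wald, panel = panel,
                 presso = presso, seed = seed, call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("Mendelian randomization fit: %s -> %s (%d variants)\n",
              x$panel$exposure_label, x$panel$outcome_label,
              nrow(x$panel$variants)))
  for (est in x$estimates) print(est)
  if (!is.null(x$presso) && nrow(x$presso$outliers) > 0L)
    cat("  outliers removed:",
        paste(x$presso$outliers$rsid, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$estimates, as.data.frame))
  rownames(tab) <- NULL
  structure(list(table = tab, exposure = object$panel$exposure_label,
                 outcome = object$panel$outcome_label,
                 egger = object$estimates$mr_egger,
                 presso = object$presso),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  cat(sprintf("MR estimates, %s -> %s\n", x$exposure, x$outcome))
  print(x$table, digits = 4)
  if (!is.null(x$egger))
    cat(sprintf("Egger intercept: %.4f [%.4f, %.4f], p = %.3g\n",
                x$egger$egger_intercept, x$egger$egger_intercept_ci[1],
                x$egger$egger_intercept_ci[2], x$egger$egger_intercept_p))
  if (!is.null(x$presso))
    cat(sprintf("Outlier screen: global p = %.4g, %d outlier(s)\n",
                x$presso$global_p, nrow(x$presso$outliers)))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$beta, numeric(1))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95)
    stop("only the 95% interval computed at fit time is stored")
  out <- t(vapply(object$estimates,
                  function(e) c(e$ci_low, e$ci_high), numeric(2)))
  colnames(out) <- c("2.5 %", "97.5 %")
  out
}

#' @export
residuals.mr_fit <- function(object, ...) {
  b <- object$estimates$ivw
  if (is.null(b)) stop("IVW estimate not part of this fit")
  v <- object$panel$variants
  stats::setNames(v$beta_y - b$beta * v$beta_x, v$rsid)
}

#' Scatter plot of a fitted panel
#'
#' Exposure effects against outcome effects (oriented to nonnegative
#' exposure effect), with one fitted line per combined estimate.
#'
#' @param x an `mr_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  v <- x$panel$variants
  s <- ifelse(v$beta_x < 0, -1, 1)
  bx <- s * v$beta_x; by <- s * v$beta_y
  graphics::plot(bx, by, xlab = "exposure effect (oriented)",
                 ylab = "outcome effect (log odds)",
                 main = sprintf("%s -> %s", x$panel$exposure_label,
                                x$panel$outcome_label), ...)
  cols <- seq_along(x$estimates) + 1
  i <- 0
  for (nm in names(x$estimates)) {
    i <- i + 1
    e <- x$estimates[[nm]]
    if (identical(nm, "mr_egger"))
      graphics::abline(a = e$egger_intercept, b = e$beta, col = cols[i])
    else graphics::abline(a = 0, b = e$beta, col = cols[i])
  }
  graphics::legend("topleft", legend = names(x$estimates), col = cols,
                   lty = 1, bty = "n")
  invisible(x)
}
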
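# Independent brute-force oracles; these deliberately take different code
# paths from the package (stats::approx interpolation, unweighted lm on
# transformed data, explicit sums) so agreement is a real cross-check.

bf_ivw <- function(theta, variance) {
  w <- 1 / variance
  list(beta = sum(w * theta) / sum(w), se = sqrt(1 / sum(w)))
}

bf_weighted_median <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]
  w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(p, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

# weighted LS via the transformed unweighted regression:
# by/se_y = intercept * (1/se_y) + slope * (bx/se_y) + error
bf_egger <- function(bx, by, se_y) {
  s <- ifelse(bx < 0, -1, 1)
  bx <- s * bx
  by <- s * by
  fit <- stats::lm(I(by / se_y) ~ 0 + I(1 / se_y) + I(bx / se_y))
  sm <- summary(fit)
  co <- sm$coefficients
  infl <- max(1, sm$sigma)
  list(intercept = unname(co[1, 1]), slope = unname(co[2, 1]),
       intercept_se = unname(co[1, 2]) / sm$sigma * infl,
       slope_se = unname(co[2, 2]) / sm$sigma * infl)
}

# t-distribution two-sided tail through the incomplete beta function
bf_t_pvalue <- function(t, df) {
  stats::pbeta(df / (df + t^2), df / 2, 0.5)
}

# quick random harmonized panel around a true slope
random_panel <- function(J, theta = 0, seed = 1, se_y = NULL,
                         pleio = numeric(J)) {
  set.seed(seed)
  bx <- runif(J, 0.01, 0.05) * sample(c(-1, 1), J, replace = TRUE)
  se_x <- runif(J, 0.002, 0.004)
  if (is.null(se_y)) se_y <- runif(J, 0.01, 0.04)
  by <- theta * bx + pleio + rnorm(J, 0, se_y)
  as_harmonized_panel(data.frame(
    rsid = sprintf("rs%04d", seq_len(J)), beta_x = bx, se_x = se_x,
    beta_y = by, se_y = se_y))
}

# minimal well-formed association rows
assoc_row <- function(rsid = "rs1", ea = "A", oa = "G", beta = 0.02,
                      se = 0.003, pvalue = 1e-9, eaf = NA_real_,
                      n = NA_real_) {
  data.frame(rsid = rsid, effect_allele = ea, other_allele = oa,
             beta = beta, se = se, pvalue = pvalue, eaf = eaf, n = n,
             stringsAsFactors = FALSE)
}

make_dataset <- function(rows, label = "d", trait_type = "outcome") {
  summary_dataset(do.call(rbind, rows), label = label,
                  trait_type = trait_type)
}
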
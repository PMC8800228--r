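#' Configuration for the summary-statistics generator
#'
#' Describes a two-sample MR study: J shared instruments with true effects
#' gamma_j on the exposure, and one or more outcome datasets, each with its
#' own causal slope theta_d (log odds per exposure SD), a multiplicative
#' attenuation lambda_d of the genetic signal (proxy-phenotype dilution),
#' optional directional pleiotropy in a fraction of variants, and
#' per-variant between-dataset heterogeneity of spread tau.
#'
#' The defaults mirror a well-powered educational-attainment -> Alzheimer's
#' study: 162 instruments with effects of a few percent of an SD
#' (`gamma_sd = 0.02`), exposure SEs from a ~400k-person continuous-trait
#' GWAS, outcome SEs (log odds) from case-control samples of tens of
#' thousands, and per-dataset slopes matching a clinically diagnosed GWAS
#' (protective, -0.34) against two family-history proxy GWAX datasets (null
#' to strongly positive, +0.09 and +0.61). Pleiotropy, dilution and extra
#' heterogeneity are off by default: the default study satisfies the MR
#' validity assumptions.
#'
#' @param n_variants number of instruments J (>= 3).
#' @param gamma_sd SD of true instrument effects on the exposure (SD units
#'   of the exposure per effect allele).
#' @param gamma_min minimum magnitude of a true instrument effect. Published
#'   instrument lists contain only genome-wide significant variants, so true
#'   effects are drawn from the tails of Normal(0, gamma_sd^2) beyond
#'   `gamma_min` (random sign); 0 disables the truncation.
#' @param se_x_range,se_y_range ranges the per-variant standard errors are
#'   drawn from, uniformly.
#' @param theta named numeric: true causal slope per outcome dataset.
#' @param pleiotropy_fraction fraction of variants with a direct
#'   (horizontal) effect on every outcome.
#' @param pleiotropy_mean,pleiotropy_sd distribution of those direct
#'   effects; a nonzero mean is directional pleiotropy.
#' @param dilution named numeric (or scalar recycled over datasets):
#'   multiplicative attenuation lambda_d in [-1, 1] of the genetic effect in
#'   each outcome dataset.
#' @param tau SD of per-variant, per-dataset heterogeneity added to the
#'   outcome effect (0 = none).
#' @param swap_fraction fraction of outcome records whose allele labels are
#'   reported swapped (beta sign inverted accordingly) — exercises
#'   harmonization.
#' @param complement_fraction fraction of outcome records reported on the
#'   opposite strand (complement alleles, same sign).
#' @param seed integer master seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_variants = 162L,
                       gamma_sd = 0.02,
                       gamma_min = 0.016,
                       se_x_range = c(0.0025, 0.004),
                       se_y_range = c(0.015, 0.04),
                       theta = c(GWAS = -0.34, GWAX2018 = 0.09,
                                 GWAX2021 = 0.61),
                       pleiotropy_fraction = 0,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       dilution = 1,
                       tau = 0,
                       swap_fraction = 0,
                       complement_fraction = 0,
                       seed = 1L) {
  stopifnot(n_variants >= 3L, gamma_sd >= 0, gamma_min >= 0,
            length(se_x_range) == 2L, all(se_x_range > 0),
            length(se_y_range) == 2L, all(se_y_range > 0),
            length(theta) >= 1L, !is.null(names(theta)),
            pleiotropy_fraction >= 0, pleiotropy_fraction <= 1,
            pleiotropy_sd >= 0, tau >= 0,
            swap_fraction >= 0, swap_fraction <= 1,
            complement_fraction >= 0, complement_fraction <= 1)
  if (length(dilution) == 1L && is.null(names(dilution)))
    dilution <- stats::setNames(rep(dilution, length(theta)), names(theta))
  stopifnot(setequal(names(dilution), names(theta)),
            all(abs(dilution) <= 1))
  structure(list(n_variants = as.integer(n_variants), gamma_sd = gamma_sd,
                 gamma_min = gamma_min,
                 se_x_range = se_x_range, se_y_range = se_y_range,
                 theta = theta, pleiotropy_fraction = pleiotropy_fraction,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 dilution = dilution[names(theta)], tau = tau,
                 swap_fraction = swap_fraction,
                 complement_fraction = complement_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# non-palindromic unordered allele pairs
.allele_pairs <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))

#' Simulate a two-sample MR study with recorded ground truth
#'
#' Generates an exposure dataset and one outcome dataset per entry of
#' `config$theta`, all sharing the same instruments and allele assignments.
#' The structural model is, per variant j and dataset d:
#' \deqn{\hat\beta_{Xj} = \gamma_j + e_{Xj},\quad
#'       \hat\beta_{Ydj} = \lambda_d \theta_d \gamma_j
#'         + sign(\gamma_j)\,\alpha_j 1[j\ pleiotropic] + b_{dj} + e_{Ydj}}
#' (pleiotropy oriented to the exposure-increasing allele) with
#' gamma_j ~ Normal(0, gamma_sd^2), b_dj ~ Normal(0, tau^2) and
#' independent sampling noise e with the drawn standard errors. P-values
#' are normal Wald tests. All draws come from purpose-keyed substreams of
#' the master seed.
#'
#' @param config a [sim_config()].
#' @return A `simulated_study`: list with `exposure` (a
#'   `summary_dataset`), `outcomes` (named list of `summary_dataset`s),
#'   `truth` (per-variant gamma, pleiotropy indicator and effect alpha;
#'   per-dataset heterogeneity draws and reporting-orientation flags) and
#'   `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  J <- config$n_variants
  old <- .save_rng(); on.exit(.restore_rng(old))

  set.seed(.rsid_seed(config$seed, "structure"))
  rsid <- sprintf("rs%06d", sample.int(999999L, J))
  pair <- .allele_pairs[sample.int(nrow(.allele_pairs), J, replace = TRUE), ,
                        drop = FALSE]
  ea <- pair[, 1]; oa <- pair[, 2]
  swap_stated <- sample(c(TRUE, FALSE), J, TRUE,
                        prob = c(0.5, 0.5))   # which allele the source calls
  ea_x <- ifelse(swap_stated, oa, ea)
  oa_x <- ifelse(swap_stated, ea, oa)
  eaf_x <- stats::runif(J, 0.1, 0.9)
  gamma <- if (config$gamma_min > 0 && config$gamma_sd > 0) {
    # tail of Normal(0, gamma_sd^2) beyond gamma_min, random sign:
    # instruments as published, i.e. post-selection
    p0 <- stats::pnorm(config$gamma_min / config$gamma_sd)
    mag <- config$gamma_sd *
      stats::qnorm(stats::runif(J, p0, 1))
    mag * sample(c(-1, 1), J, replace = TRUE)
  } else {
    stats::rnorm(J, 0, config$gamma_sd)
  }
  pleio <- stats::runif(J) < config$pleiotropy_fraction
  alpha <- ifelse(pleio,
                  stats::rnorm(J, config$pleiotropy_mean,
                               config$pleiotropy_sd), 0)
  se_x <- stats::runif(J, config$se_x_range[1], config$se_x_range[2])

  set.seed(.rsid_seed(config$seed, "exposure"))
  beta_x <- gamma + stats::rnorm(J, 0, se_x)
  exposure <- summary_dataset(
    data.frame(rsid = rsid, effect_allele = ea_x, other_allele = oa_x,
               beta = ifelse(swap_stated, -beta_x, beta_x),
               se = se_x, pvalue = .wald_p(beta_x, se_x),
               eaf = ifelse(swap_stated, 1 - eaf_x, eaf_x),
               n = 405072, stringsAsFactors = FALSE),
    label = "exposure", trait_type = "exposure")
  # exposure is stored in its stated orientation; the analysis-truth betas
  # below refer to allele `ea`, frequency eaf_x
  truth_dataset <- list()
  outcomes <- list()
  for (label in names(config$theta)) {
    set.seed(.rsid_seed(config$seed, paste0("outcome:", label)))
    se_y <- stats::runif(J, config$se_y_range[1], config$se_y_range[2])
    b <- if (config$tau > 0) stats::rnorm(J, 0, config$tau) else numeric(J)
    # pleiotropy is directional with respect to the exposure-increasing
    # allele (sign(gamma)); a fixed-allele offset would cancel under the
    # orientation MR-Egger requires
    mu <- config$dilution[[label]] * config$theta[[label]] * gamma +
      sign(gamma) * alpha + b
    beta_y <- mu + stats::rnorm(J, 0, se_y)
    swapped <- stats::runif(J) < config$swap_fraction
    complemented <- stats::runif(J) < config$complement_fraction
    ea_y <- ifelse(swapped, oa, ea)
    oa_y <- ifelse(swapped, ea, oa)
    ea_y <- ifelse(complemented, .complement[ea_y], ea_y)
    oa_y <- ifelse(complemented, .complement[oa_y], oa_y)
    eaf_y <- pmin(pmax(eaf_x + stats::rnorm(J, 0, 0.01), 0.01), 0.99)
    outcomes[[label]] <- summary_dataset(
      data.frame(rsid = rsid, effect_allele = unname(ea_y),
                 other_allele = unname(oa_y),
                 beta = ifelse(swapped, -beta_y, beta_y),
                 se = se_y, pvalue = .wald_p(beta_y, se_y),
                 eaf = ifelse(swapped, 1 - eaf_y, eaf_y),
                 n = NA_real_, stringsAsFactors = FALSE),
      label = label, trait_type = "outcome")
    truth_dataset[[label]] <- data.frame(
      rsid = rsid, b = b, beta_y_true = beta_y, swapped = swapped,
      complemented = complemented, stringsAsFactors = FALSE)
  }
  structure(list(exposure = exposure, outcomes = outcomes,
                 truth = list(variants = data.frame(
                                rsid = rsid, gamma = gamma,
                                beta_x_true = beta_x, pleiotropic = pleio,
                                alpha = alpha, exposure_swapped = swap_stated,
                                stringsAsFactors = FALSE),
                              datasets = truth_dataset,
                              injected = data.frame(dataset = character(),
                                                    rsid = character(),
                                                    shift_in_se = numeric())),
                 config = config),
            class = "simulated_study")
}

.wald_p <- function(beta, se) pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300)

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("Simulated two-sample MR study: %d instruments, %d outcome dataset(s)\n",
              x$config$n_variants, length(x$outcomes)))
  for (label in names(x$outcomes))
    cat(sprintf("  %s: true slope %.3f, dilution %.2f\n", label,
                x$config$theta[[label]], x$config$dilution[[label]]))
  if (nrow(x$truth$injected) > 0L)
    cat(sprintf("  %d injected outlier(s)\n", nrow(x$truth$injected)))
  invisible(x)
}

#' Inject a horizontal-pleiotropy outlier into a simulated study
#'
#' Shifts one variant's outcome effect by a multiple of its standard error
#' in one dataset, recording the manipulation in the study's ground truth.
#' A shift of 0 leaves the study unchanged.
#'
#' @param study a `simulated_study`.
#' @param dataset outcome dataset label.
#' @param rsid variant to shift.
#' @param shift_in_se shift expressed in units of the variant's outcome SE.
#' @return The modified `simulated_study`.
#' @export
inject_outlier <- function(study, dataset, rsid, shift_in_se) {
  stopifnot(inherits(study, "simulated_study"),
            dataset %in% names(study$outcomes))
  out <- study$outcomes[[dataset]]
  i <- match(rsid, out$rsid)
  if (is.na(i)) stop("unknown rsid: ", rsid)
  swapped <- study$truth$datasets[[dataset]]$swapped[i]
  sgn <- if (isTRUE(swapped)) -1 else 1   # shift on the analysis orientation
  out$beta[i] <- out$beta[i] + sgn * shift_in_se * out$se[i]
  out$pvalue[i] <- .wald_p(out$beta[i], out$se[i])
  study$outcomes[[dataset]] <- out
  study$truth$injected <- rbind(
    study$truth$injected,
    data.frame(dataset = dataset, rsid = rsid, shift_in_se = shift_in_se,
               stringsAsFactors = FALSE))
  study
}

#' Write a simulated study as summary-statistic TSV files
#'
#' One file per dataset (`exposure.tsv`, `<label>.tsv`) in the canonical
#' column layout of [write_summary_table()].
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"))
  write_summary_table(study$exposure, paths[["exposure"]])
  for (label in names(study$outcomes)) {
    paths[[label]] <- file.path(dir, paste0(label, ".tsv"))
    write_summary_table(study$outcomes[[label]], paths[[label]])
  }
  invisible(paths)
}
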
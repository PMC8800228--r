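.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.as_dataset <- function(x, label, trait_type) {
  if (inherits(x, "summary_dataset")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(read_summary_table(x, label = label, trait_type = trait_type))
  stop("expected a summary_dataset or a file path for '", label, "'")
}

#' Run the full cross-dataset Mendelian randomization analysis
#'
#' Orchestrates the whole procedure for one exposure and several outcome
#' datasets: harmonization per dataset; a pleiotropy screen (MR-Egger
#' intercept test on the full panel, then the simulation-based global and
#' per-variant outlier tests); exclusion of flagged outliers; the four
#' combined estimates (IVW, weighted median, MR-Egger, outlier-corrected)
#' per dataset; a secondary analysis restricted to the variants shared by
#' every outcome dataset minus the union of all flagged outliers; and, for
#' each requested dataset pair, the per-variant Cochran's Q / I-squared
#' heterogeneity table and paired t test of Wald estimators on that shared
#' set.
#'
#' Exclusion is driven by the outlier test only; the Egger intercept test is
#' reported as a screen but never removes variants. The report is a pure
#' function of the inputs, the configuration and the seed.
#'
#' @param exposure a `summary_dataset` or file path (instrument list for
#'   the exposure).
#' @param outcomes named list of `summary_dataset`s or file paths, one per
#'   outcome dataset.
#' @param compare character vector of dataset pairs `"A:B"` for the
#'   heterogeneity comparisons (default: none).
#' @param p_threshold optional instrument p-value screen applied to the
#'   exposure first; `NULL` (default) takes the exposure table as an
#'   already-curated instrument list.
#' @param exclude rsids excluded from every analysis up front.
#' @param seed master seed; per-dataset analyses use substreams keyed by
#'   dataset label.
#' @param n_sim,n_boot,alpha,ivw_model passed to the screen and estimators.
#' @param palindrome_policy,eaf_window passed to [harmonize_panel()].
#' @return An `mr_report`: per-dataset results (`datasets`), the shared
#'   variant set (`shared_rsids`), pooled exclusions (`excluded`),
#'   heterogeneity comparisons (`heterogeneity`), flat result tables
#'   (`tables$screen`, `tables$primary`, `tables$secondary`,
#'   `tables$heterogeneity`) and provenance (`seed`, counts).
#' @export
run_full_analysis <- function(exposure, outcomes, compare = character(),
                              p_threshold = NULL, exclude = character(),
                              seed = 1L, n_sim = 10000L, n_boot = 10000L,
                              alpha = 0.05, ivw_model = "auto",
                              palindrome_policy = "eaf_infer",
                              eaf_window = 0.08) {
  stopifnot(length(outcomes) >= 1L, !is.null(names(outcomes)))
  exposure <- .stage("read exposure",
                     .as_dataset(exposure, "exposure", "exposure"))
  outcomes <- .stage("read outcomes", {
    out <- list()
    for (label in names(outcomes))
      out[[label]] <- .as_dataset(outcomes[[label]], label, "outcome")
    out
  })
  if (!is.null(p_threshold))
    exposure <- .stage("instrument selection",
                       select_instruments(exposure, p_threshold))
  if (length(exclude) > 0L) {
    keep <- !exposure$rsid %in% exclude
    exposure <- structure(exposure[keep, , drop = FALSE],
                          label = attr(exposure, "label"),
                          trait_type = "exposure",
                          rejected = attr(exposure, "rejected"),
                          class = c("summary_dataset", "data.frame"))
  }

  datasets <- list()
  for (label in names(outcomes)) {
    dseed <- .rsid_seed(seed, label)
    panel <- .stage(paste0("harmonize ", label),
                    harmonize_panel(exposure, outcomes[[label]],
                                    palindrome_policy = palindrome_policy,
                                    eaf_window = eaf_window))
    egger_full <- .stage(paste0("Egger intercept screen ", label),
                         mr_egger(panel))
    presso <- .stage(paste0("outlier screen ", label),
                     presso_outlier_test(panel, n_sim = n_sim, seed = dseed,
                                         alpha = alpha,
                                         ivw_model = ivw_model))
    reduced <- subset_panel(panel, presso$outliers$rsid, invert = TRUE)
    fit <- .stage(paste0("MR estimation ", label), {
      f <- mr_fit(reduced, methods = c("ivw", "weighted_median", "mr_egger"),
                  seed = dseed, n_boot = n_boot, ivw_model = ivw_model)
      f$estimates$mr_presso <- presso$corrected_estimate
      f
    })
    datasets[[label]] <- list(panel = panel, egger_screen = egger_full,
                              presso = presso, fit = fit)
  }

  flagged <- unique(unlist(lapply(datasets,
                                  function(d) d$presso$outliers$rsid)))
  shared <- .stage("shared variant set", {
    panels <- lapply(datasets, function(d)
      data.frame(rsid = d$panel$variants$rsid))
    sort(setdiff(Reduce(intersect, lapply(panels, `[[`, "rsid")), flagged))
  })

  secondary <- list()
  for (label in names(datasets)) {
    dseed <- .rsid_seed(seed, paste0("secondary:", label))
    sub <- subset_panel(datasets[[label]]$panel, shared)
    secondary[[label]] <- .stage(paste0("secondary MR ", label), {
      pres <- presso_outlier_test(sub, n_sim = n_sim, seed = dseed,
                                  alpha = alpha, ivw_model = ivw_model)
      f <- mr_fit(sub, methods = c("ivw", "weighted_median", "mr_egger"),
                  seed = dseed, n_boot = n_boot, ivw_model = ivw_model)
      f$estimates$mr_presso <- pres$corrected_estimate
      f
    })
  }

  heterogeneity <- list()
  for (cmp in compare) {
    ab <- strsplit(cmp, ":", fixed = TRUE)[[1]]
    if (length(ab) != 2L || !all(ab %in% names(datasets)))
      stop("comparison '", cmp, "' does not name two outcome datasets")
    heterogeneity[[cmp]] <- .stage(paste0("heterogeneity ", cmp),
      heterogeneity_table(subset_panel(datasets[[ab[1]]]$panel, shared),
                          subset_panel(datasets[[ab[2]]]$panel, shared),
                          shared))
  }

  report <- structure(list(datasets = datasets, shared_rsids = shared,
                           excluded = flagged, secondary = secondary,
                           heterogeneity = heterogeneity,
                           seed = as.integer(seed), n_sim = as.integer(n_sim),
                           n_boot = as.integer(n_boot), alpha = alpha),
                      class = "mr_report")
  report$tables <- .report_tables(report)
  report
}

.estimates_df <- function(fits) {
  do.call(rbind, lapply(names(fits), function(label) {
    tab <- do.call(rbind, lapply(fits[[label]], as.data.frame))
    cbind(dataset = label, tab, row.names = NULL)
  }))
}

.report_tables <- function(report) {
  screen <- do.call(rbind, lapply(names(report$datasets), function(label) {
    d <- report$datasets[[label]]
    e <- d$egger_screen
    data.frame(dataset = label, n_variants = nrow(d$panel$variants),
               egger_intercept = e$egger_intercept,
               egger_ci_low = e$egger_intercept_ci[1],
               egger_ci_high = e$egger_intercept_ci[2],
               egger_p = e$egger_intercept_p,
               presso_global_p = d$presso$global_p,
               outliers = paste(d$presso$outliers$rsid, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  hetero <- if (length(report$heterogeneity) > 0L)
    do.call(rbind, lapply(names(report$heterogeneity), function(cmp) {
      h <- report$heterogeneity[[cmp]]
      data.frame(comparison = cmp, n_variants = nrow(h$table),
                 n_i2_gt25 = h$n_gt25, n_i2_gt50 = h$n_gt50,
                 mean_a = h$paired_t$mean_a, mean_b = h$paired_t$mean_b,
                 t_stat = h$paired_t$t_stat, pvalue = h$paired_t$pvalue,
                 stringsAsFactors = FALSE)
    })) else NULL
  list(screen = screen,
       primary = .estimates_df(lapply(report$datasets,
                                      function(d) d$fit$estimates)),
       secondary = .estimates_df(lapply(report$secondary,
                                        function(f) f$estimates)),
       heterogeneity = hetero)
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("Cross-dataset MR report: %d outcome dataset(s), seed %d\n",
              length(x$datasets), x$seed))
  cat(sprintf("Shared variants after pooled exclusions: %d (excluded: %s)\n",
              length(x$shared_rsids),
              if (length(x$excluded)) paste(x$excluded, collapse = ", ")
              else "none"))
  cat("\nPleiotropy screen:\n")
  print(x$tables$screen, digits = 4)
  cat("\nPrimary estimates (per-dataset instruments, outliers removed):\n")
  print(x$tables$primary[c("dataset", "method", "or", "or_low", "or_high",
                           "pvalue", "n_variants")], digits = 4)
  cat("\nSecondary estimates (shared variants):\n")
  print(x$tables$secondary[c("dataset", "method", "or", "or_low", "or_high",
                             "pvalue", "n_variants")], digits = 4)
  if (!is.null(x$tables$heterogeneity)) {
    cat("\nHeterogeneity comparisons:\n")
    print(x$tables$heterogeneity, digits = 4)
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (screen, estimates, heterogeneity summaries,
#' provenance) plus flat TSVs: `screen.tsv`, `primary.tsv`,
#' `secondary.tsv`, and one `hetero_<pair>.tsv` of per-variant records per
#' comparison.
#'
#' @param report an `mr_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(x, name) utils::write.table(
    x, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(report$tables$screen, "screen.tsv")
  tsv(report$tables$primary, "primary.tsv")
  tsv(report$tables$secondary, "secondary.tsv")
  for (cmp in names(report$heterogeneity))
    tsv(report$heterogeneity[[cmp]]$table,
        paste0("hetero_", gsub(":", "_vs_", cmp, fixed = TRUE), ".tsv"))
  payload <- list(screen = report$tables$screen,
                  primary = report$tables$primary,
                  secondary = report$tables$secondary,
                  heterogeneity = report$tables$heterogeneity,
                  shared_rsids = report$shared_rsids,
                  excluded = report$excluded,
                  provenance = list(seed = report$seed, n_sim = report$n_sim,
                                    n_boot = report$n_boot,
                                    alpha = report$alpha,
                                    package_version =
                                      as.character(utils::packageVersion("mrdiv"))))
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
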
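#' @keywords internal
.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) .complement[a1] == a2

#' Harmonize one variant across exposure and outcome datasets
#'
#' Aligns the outcome association of a single variant to the exposure's
#' effect allele. Four configurations are reconcilable: identical alleles
#' (kept as is), swapped alleles (outcome beta negated), strand-complement
#' alleles (relabelled, kept), and complement-swapped (relabelled, negated).
#' Palindromic variants (A/T or C/G) cannot be distinguished from their
#' strand complement and are handled by `palindrome_policy`:
#' \describe{
#'   \item{`drop`}{always dropped (`"palindromic"`).}
#'   \item{`keep`}{assume both studies report the same strand and align on
#'     the stated alleles — appropriate when sources share a reference.}
#'   \item{`eaf_infer`}{orient by comparing effect-allele frequencies; a
#'     variant is dropped as `"palindromic-ambiguous"` when either frequency
#'     is missing or within `eaf_window` of 0.5.}
#' }
#'
#' @param exposure_rec,outcome_rec single-row data frames (or lists) with
#'   the `summary_dataset` columns for the same rsid.
#' @param palindrome_policy one of `"eaf_infer"`, `"drop"`, `"keep"`.
#' @param eaf_window half-width of the ambiguous frequency band around 0.5
#'   used by `eaf_infer` (default 0.08, i.e. drop when EAF is in
#'   [0.42, 0.58]).
#' @return A list: either `list(variant = <row>)` with fields `rsid`,
#'   `beta_x`, `se_x`, `beta_y`, `se_y`, `flipped`, or
#'   `list(drop_reason = <string>)`.
#' @export
harmonize_pair <- function(exposure_rec, outcome_rec,
                           palindrome_policy = c("eaf_infer", "drop", "keep"),
                           eaf_window = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (!identical(as.character(exposure_rec$rsid),
                 as.character(outcome_rec$rsid)))
    stop("rsid mismatch: ", exposure_rec$rsid, " vs ", outcome_rec$rsid)
  res <- .harmonize_vec(as.data.frame(exposure_rec, stringsAsFactors = FALSE),
                        as.data.frame(outcome_rec, stringsAsFactors = FALSE),
                        palindrome_policy, eaf_window)
  if (nrow(res$variants) == 1L) list(variant = res$variants)
  else list(drop_reason = res$dropped$reason)
}

# vectorized core: ex and ou are row-aligned data frames of the same rsids
.harmonize_vec <- function(ex, ou, policy, eaf_window) {
  n <- nrow(ex)
  xe <- ex$effect_allele; xo <- ex$other_allele
  ye <- ou$effect_allele; yo <- ou$other_allele
  reason <- rep(NA_character_, n)
  flip <- rep(NA, n)

  pal_x <- .complement[xe] == xo
  pal_y <- .complement[ye] == yo
  reason[xor(pal_x, pal_y)] <- "allele-mismatch"

  np <- !pal_x & !pal_y
  direct <- np & ye == xe & yo == xo
  swapped <- np & ye == xo & yo == xe
  comp <- np & .complement[ye] == xe & .complement[yo] == xo
  comp_swap <- np & .complement[ye] == xo & .complement[yo] == xe
  flip[direct | comp] <- FALSE
  flip[swapped | comp_swap] <- TRUE
  reason[np & !(direct | swapped | comp | comp_swap)] <- "allele-mismatch"

  pal <- pal_x & pal_y
  if (any(pal)) {
    stated_ok <- (ye == xe & yo == xo) | (ye == xo & yo == xe)
    reason[pal & !stated_ok] <- "allele-mismatch"
    ok <- pal & stated_ok
    stated_swap <- ok & ye == xo
    if (policy == "drop") {
      reason[ok] <- "palindromic"
    } else if (policy == "keep") {
      flip[ok] <- stated_swap[ok]
    } else {                    # eaf_infer
      fx <- ex$eaf
      fy <- ifelse(stated_swap, 1 - ou$eaf, ou$eaf)
      ambiguous <- is.na(fx) | is.na(fy) |
        abs(fx - 0.5) <= eaf_window | abs(fy - 0.5) <= eaf_window
      reason[ok & ambiguous] <- "palindromic-ambiguous"
      use <- ok & !ambiguous
      # discordant frequency sides of 0.5 imply opposite strands
      flip[use] <- xor(stated_swap[use],
                       (fx[use] - 0.5) * (fy[use] - 0.5) < 0)
    }
  }

  weak <- is.na(reason) & abs(ex$beta) < 1e-12
  reason[weak] <- "weak-zero exposure effect"

  keep <- is.na(reason)
  variants <- data.frame(
    rsid = as.character(ex$rsid[keep]),
    beta_x = ex$beta[keep], se_x = ex$se[keep],
    beta_y = ifelse(flip[keep], -ou$beta[keep], ou$beta[keep]),
    se_y = ou$se[keep], flipped = flip[keep],
    stringsAsFactors = FALSE)
  dropped <- data.frame(rsid = as.character(ex$rsid[!keep]),
                        reason = reason[!keep], stringsAsFactors = FALSE)
  list(variants = variants, dropped = dropped)
}

#' Harmonize an exposure/outcome dataset pair into an analysis panel
#'
#' Applies [harmonize_pair()] to every requested variant, producing the
#' `harmonized_panel` all estimators consume. Every requested rsid ends up
#' either in the panel or in the `dropped` table with a reason — nothing is
#' discarded silently.
#'
#' @param exposure,outcome `summary_dataset` objects.
#' @param rsids variants to harmonize; defaults to the rsids present in
#'   both datasets (variants missing from either side are dropped with
#'   reason `"missing"`, and a message reports the count).
#' @inheritParams harmonize_pair
#' @return A `harmonized_panel`: list with `variants` (data frame: rsid,
#'   beta_x, se_x, beta_y, se_y, flipped), `dropped` (rsid, reason),
#'   `exposure_label`, `outcome_label`.
#' @export
harmonize_panel <- function(exposure, outcome, rsids = NULL,
                            palindrome_policy = c("eaf_infer", "drop", "keep"),
                            eaf_window = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  if (is.null(rsids)) rsids <- exposure$rsid
  rsids <- as.character(rsids)
  present <- rsids %in% exposure$rsid & rsids %in% outcome$rsid
  n_missing <- sum(!present)
  if (n_missing > 0L)
    message(n_missing, " variant(s) absent from '", attr(outcome, "label"),
            "' or the exposure; dropped")
  missing_df <- data.frame(rsid = rsids[!present],
                           reason = rep("missing", n_missing),
                           stringsAsFactors = FALSE)
  ex <- as.data.frame(exposure)
  ou <- as.data.frame(outcome)
  ids <- rsids[present]
  res <- .harmonize_vec(ex[match(ids, ex$rsid), , drop = FALSE],
                        ou[match(ids, ou$rsid), , drop = FALSE],
                        palindrome_policy, eaf_window)
  variants <- res$variants
  if (nrow(variants) == 0L)
    stop("no instruments survive harmonization for '",
         attr(outcome, "label"), "'")
  rownames(variants) <- NULL
  structure(list(variants = variants,
                 dropped = rbind(missing_df, res$dropped),
                 exposure_label = attr(exposure, "label"),
                 outcome_label = attr(outcome, "label")),
            class = "harmonized_panel")
}

#' Build a harmonized panel directly from aligned effect estimates
#'
#' Convenience constructor for already-aligned summary statistics (e.g.
#' simulated data or panels exchanged as TSV).
#'
#' @param variants data frame with columns `rsid`, `beta_x`, `se_x`,
#'   `beta_y`, `se_y` and optionally `flipped`.
#' @param exposure_label,outcome_label dataset labels.
#' @return A `harmonized_panel`.
#' @export
as_harmonized_panel <- function(variants, exposure_label = "exposure",
                                outcome_label = "outcome") {
  stopifnot(is.data.frame(variants),
            all(c("rsid", "beta_x", "se_x", "beta_y", "se_y") %in%
                  names(variants)))
  if (!"flipped" %in% names(variants)) variants$flipped <- FALSE
  stopifnot(all(variants$se_x > 0), all(variants$se_y > 0),
            !anyDuplicated(variants$rsid))
  variants <- variants[c("rsid", "beta_x", "se_x", "beta_y", "se_y",
                         "flipped")]
  rownames(variants) <- NULL
  structure(list(variants = variants,
                 dropped = data.frame(rsid = character(),
                                      reason = character()),
                 exposure_label = exposure_label,
                 outcome_label = outcome_label),
            class = "harmonized_panel")
}

#' @export
print.harmonized_panel <- function(x, ...) {
  cat(sprintf("Harmonized panel: %s -> %s\n", x$exposure_label,
              x$outcome_label))
  cat(sprintf("  %d variants (%d orientation-flipped), %d dropped\n",
              nrow(x$variants), sum(x$variants$flipped), nrow(x$dropped)))
  if (nrow(x$dropped) > 0L) {
    tab <- table(x$dropped$reason)
    cat("  drop reasons:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a harmonized panel by rsid
#'
#' @param panel a `harmonized_panel`.
#' @param rsids variants to keep (or drop, with `invert = TRUE`).
#' @param invert drop instead of keep.
#' @return A `harmonized_panel` restricted to the requested variants.
#' @export
subset_panel <- function(panel, rsids, invert = FALSE) {
  stopifnot(inherits(panel, "harmonized_panel"))
  keep <- panel$variants$rsid %in% rsids
  if (invert) keep <- !keep
  out <- panel
  out$variants <- panel$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  out
}

#' Write / read the harmonized-panel exchange TSV
#'
#' @param panel a `harmonized_panel`.
#' @param path file path.
#' @return `write_panel` returns `path` invisibly; `read_panel` a
#'   `harmonized_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "harmonized_panel"))
  utils::write.table(panel$variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @param exposure_label,outcome_label labels for the panel read back.
#' @export
read_panel <- function(path, exposure_label = "exposure",
                       outcome_label = "outcome") {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  as_harmonized_panel(x, exposure_label, outcome_label)
}
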
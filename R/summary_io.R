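#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited summary-statistics file (header row
#' required) into a validated `summary_dataset`. One row per variant with,
#' at minimum, an rsid, the effect and other alleles, the per-allele effect
#' size (`beta`: log-odds for a binary trait, phenotype SD units for a
#' continuous one), its standard error and a p-value. Effect-allele
#' frequency (`eaf`) and sample size (`n`) are optional.
#'
#' Rows violating the per-variant invariants (non A/C/G/T alleles, equal
#' alleles, non-numeric or non-positive SE, p outside (0, 1], eaf outside
#' [0, 1]) are rejected, not repaired: they are dropped from the dataset and
#' returned row-by-row in the `rejected` attribute with the reason. A
#' duplicated rsid is ambiguous as an instrument and is a hard error.
#'
#' @param path path to a TSV/CSV file with a header row.
#' @param column_map named character vector mapping canonical names
#'   (`rsid`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`,
#'   `eaf`, `n`) to the file's column headers. Only names you supply are
#'   remapped; the rest default to the canonical names themselves.
#' @param label dataset label, e.g. `"GWAS"` or `"GWAX2018"`.
#' @param trait_type `"exposure"` or `"outcome"`.
#' @return A `summary_dataset`: a data frame with canonical columns and
#'   attributes `label`, `trait_type` and `rejected` (a data frame of
#'   row number, rsid and reason for every rejected input row).
#' @seealso [select_instruments()], [intersect_datasets()],
#'   [write_summary_table()]
#' @export
read_summary_table <- function(path, column_map = NULL, label = "dataset",
                               trait_type = c("outcome", "exposure")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  map <- .canonical_map(column_map)
  missing_cols <- setdiff(unname(map[.required_cols]), names(raw))
  if (length(missing_cols) > 0L) {
    stop("format error: mapped column(s) not in file: ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(rsid = raw[[map[["rsid"]]]],
                    effect_allele = toupper(raw[[map[["effect_allele"]]]]),
                    other_allele = toupper(raw[[map[["other_allele"]]]]),
                    beta = suppressWarnings(as.numeric(raw[[map[["beta"]]]])),
                    se = suppressWarnings(as.numeric(raw[[map[["se"]]]])),
                    pvalue = suppressWarnings(as.numeric(raw[[map[["pvalue"]]]])),
                    stringsAsFactors = FALSE)
  out$eaf <- if (map[["eaf"]] %in% names(raw))
    suppressWarnings(as.numeric(raw[[map[["eaf"]]]])) else NA_real_
  out$n <- if (map[["n"]] %in% names(raw))
    suppressWarnings(as.numeric(raw[[map[["n"]]]])) else NA_real_
  summary_dataset(out, label = label, trait_type = trait_type)
}

.required_cols <- c("rsid", "effect_allele", "other_allele",
                    "beta", "se", "pvalue")

.canonical_map <- function(column_map) {
  map <- c(rsid = "rsid", effect_allele = "effect_allele",
           other_allele = "other_allele", beta = "beta", se = "se",
           pvalue = "pval", eaf = "eaf", n = "n")
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(map))
    if (length(bad) > 0L)
      stop("unknown canonical column name(s): ", paste(bad, collapse = ", "))
    map[names(column_map)] <- unname(column_map)
  }
  map
}

#' Construct a summary dataset from a data frame
#'
#' Validates per-variant invariants and packs the result as a
#' `summary_dataset`. Invalid rows are dropped and recorded in the
#' `rejected` attribute; duplicated rsids among the valid rows are an error.
#'
#' @param x data frame with columns `rsid`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `pvalue` and optionally `eaf`, `n`.
#' @inheritParams read_summary_table
#' @return A `summary_dataset`.
#' @export
summary_dataset <- function(x, label = "dataset",
                            trait_type = c("outcome", "exposure")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(x))
  miss <- setdiff(.required_cols, names(x))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"eaf" %in% names(x)) x$eaf <- NA_real_
  if (!"n" %in% names(x)) x$n <- NA_real_
  x <- x[c(.required_cols, "eaf", "n")]
  reason <- .row_reject_reason(x)
  rejected <- data.frame(row = which(!is.na(reason)),
                         rsid = x$rsid[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  x <- x[is.na(reason), , drop = FALSE]
  dup <- unique(x$rsid[duplicated(x$rsid)])
  if (length(dup) > 0L)
    stop("duplicate rsid(s) in dataset '", label, "': ",
         paste(utils::head(dup, 5L), collapse = ", "))
  rownames(x) <- NULL
  structure(x, label = label, trait_type = trait_type, rejected = rejected,
            class = c("summary_dataset", "data.frame"))
}

# one reason per row, NA when the row is valid; first failing check wins
.row_reject_reason <- function(x) {
  bases <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(x))
  set <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- why
  }
  set(is.na(x$rsid) | !nzchar(x$rsid), "missing rsid")
  set(!(x$effect_allele %in% bases), "invalid effect allele")
  set(!(x$other_allele %in% bases), "invalid other allele")
  set(x$effect_allele == x$other_allele, "identical alleles")
  set(is.na(x$beta), "non-numeric beta")
  set(is.na(x$se), "non-numeric SE")
  set(x$se <= 0, "nonpositive SE")
  set(is.na(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1, "p-value outside (0,1]")
  set(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1), "EAF outside [0,1]")
  set(!is.na(x$n) & x$n <= 0, "nonpositive N")
  reason
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("Summary dataset '%s' (%s): %d variants\n",
              attr(x, "label"), attr(x, "trait_type"), nrow(x)))
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej) > 0L)
    cat(sprintf("  %d input row(s) rejected during validation\n", nrow(rej)))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("  ... %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' Write a summary dataset to a tab-delimited file
#'
#' Canonical column names; a round trip through
#' [read_summary_table()] reproduces the dataset field-for-field.
#'
#' @param x a `summary_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(x, path) {
  stopifnot(inherits(x, "summary_dataset"))
  out <- as.data.frame(x)
  names(out)[names(out) == "pvalue"] <- "pval"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select genome-wide significant instruments
#'
#' Subsets an exposure dataset to variants below the association p-value
#' threshold, the usual instrument-relevance screen. Genome-wide
#' significance, p < 5e-8, is the default.
#'
#' @param exposure a `summary_dataset` with `trait_type = "exposure"`.
#' @param p_threshold strict upper bound on the association p-value.
#' @return A `summary_dataset` with the retained variants, input order
#'   preserved. An empty result raises a warning, not an error.
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8) {
  stopifnot(inherits(exposure, "summary_dataset"))
  if (!identical(attr(exposure, "trait_type"), "exposure"))
    stop("instrument selection expects an exposure dataset")
  keep <- exposure$pvalue < p_threshold
  out <- exposure[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no variant passes p < ", format(p_threshold), call. = FALSE)
  structure(out, label = attr(exposure, "label"), trait_type = "exposure",
            rejected = attr(exposure, "rejected"),
            class = c("summary_dataset", "data.frame"))
}

#' Intersect variant sets across datasets
#'
#' Returns the rsids present in every supplied dataset, minus an explicit
#' exclusion list — the shared-instrument set used when the same variants
#' must enter each per-dataset analysis.
#'
#' @param datasets list of `summary_dataset` objects (at least one).
#' @param exclude character vector of rsids to remove from the result.
#' @return Sorted character vector of shared rsids.
#' @export
intersect_datasets <- function(datasets, exclude = character()) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  ids <- Reduce(intersect, lapply(datasets, function(d) d$rsid))
  sort(setdiff(ids, exclude))
}
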
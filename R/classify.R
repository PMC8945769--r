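#' Factor thresholds for the two-factor mutability classification
#'
#' F(i) is telomere proximity below `proximity_cutoff` megabases (default
#' 50 Mb, the 50 cM linkage criterion under the 1 cM ~ 1 Mbp heuristic);
#' F(ii) is A+T content above `at_cutoff` percent (default 59%, the human
#' genome-wide average). Both comparisons are strict by default — a gene at
#' exactly 59% A+T does not meet F(ii), which is how the grey "None" rows
#' of the reference tables are marked — and can be relaxed to `<=`/`>=` for
#' sensitivity analysis.
#'
#' @param proximity_cutoff F(i) cutoff in Mb, `> 0`.
#' @param at_cutoff F(ii) cutoff in percent, `> 0`.
#' @param strict_fi,strict_fii use strict inequalities (default `TRUE`).
#' @return an object of class `"factor_thresholds"`.
#' @examples
#' factor_thresholds()
#' factor_thresholds(at_cutoff = 55, strict_fii = FALSE)
#' @export
factor_thresholds <- function(proximity_cutoff = 50, at_cutoff = 59,
                              strict_fi = TRUE, strict_fii = TRUE) {
  stopifnot(is.numeric(proximity_cutoff), length(proximity_cutoff) == 1,
            is.numeric(at_cutoff), length(at_cutoff) == 1,
            is.logical(strict_fi), is.logical(strict_fii))
  if (proximity_cutoff <= 0 || at_cutoff <= 0) {
    stop("cutoffs must be positive", call. = FALSE)
  }
  structure(list(proximity_cutoff = proximity_cutoff, at_cutoff = at_cutoff,
                 strict_fi = strict_fi, strict_fii = strict_fii),
            class = "factor_thresholds")
}

#' @export
print.factor_thresholds <- function(x, ...) {
  cat(sprintf("F(i): proximity %s %g Mb; F(ii): A+T %s %g%%\n",
              if (x$strict_fi) "<" else "<=", x$proximity_cutoff,
              if (x$strict_fii) ">" else ">=", x$at_cutoff))
  invisible(x)
}

factor_categories <- c("BOTH", "FI_ONLY", "FII_ONLY", "NONE")

#' Classify genes by the two mutability factors
#'
#' Applies the F(i) proximity and F(ii) A+T thresholds to each record and
#' assigns the mutability category: `BOTH` (predicted most mutable),
#' `FI_ONLY`, `FII_ONLY`, or `NONE` (predicted least mutable).
#'
#' @param records gene-record data frame with `proximity` and `a_plus_t`
#'   populated for every row (see [read_gene_table()],
#'   [run_two_factor_analysis()] for filling them from reference files).
#' @param thresholds a [factor_thresholds()] object.
#' @return data.frame of factor calls: `symbol`, `meets_fi`, `meets_fii`,
#'   `category` (factor with levels BOTH, FI_ONLY, FII_ONLY, NONE).
#' @examples
#' calls <- classify_genes(drug_target_table("ion_channels"))
#' table(calls$category)
#' @export
classify_genes <- function(records, thresholds = factor_thresholds()) {
  stopifnot(is.data.frame(records), inherits(thresholds, "factor_thresholds"))
  missing <- is.na(records$proximity) | is.na(records$a_plus_t)
  if (any(missing)) {
    stop("missing proximity or a_plus_t for gene ",
         paste(records$symbol[missing], collapse = ", "), call. = FALSE)
  }
  meets_fi <- if (thresholds$strict_fi) {
    records$proximity < thresholds$proximity_cutoff
  } else {
    records$proximity <= thresholds$proximity_cutoff
  }
  meets_fii <- if (thresholds$strict_fii) {
    records$a_plus_t > thresholds$at_cutoff
  } else {
    records$a_plus_t >= thresholds$at_cutoff
  }
  category <- ifelse(meets_fi & meets_fii, "BOTH",
              ifelse(meets_fi, "FI_ONLY",
              ifelse(meets_fii, "FII_ONLY", "NONE")))
  data.frame(symbol = records$symbol,
             meets_fi = meets_fi,
             meets_fii = meets_fii,
             category = factor(category, levels = factor_categories),
             stringsAsFactors = FALSE)
}

#' @rdname classify_genes
#' @param record a single gene record (one-row data frame or named list
#'   with `symbol`, `proximity`, `a_plus_t`).
#' @export
classify_gene <- function(record, thresholds = factor_thresholds()) {
  df <- as.data.frame(record[c("symbol", "proximity", "a_plus_t")],
                      stringsAsFactors = FALSE)
  classify_genes(df, thresholds)
}

#' Summarize factor calls for a cohort
#'
#' Counts the four categories and computes the matching rate: the fraction
#' of genes meeting at least one of the two factors, the cohort-level
#' mutability summary (e.g. 9 of the 11 drug-targeted ion-channel genes,
#' an 82% match).
#'
#' @param calls factor-call data frame from [classify_genes()]; non-empty.
#' @return an object of class `"cohort_summary"`: `n`, `counts` (named
#'   vector over the four categories), `fi_count`, `fii_count`,
#'   `either_count`, `matching_rate` (fraction), and the round-half-up
#'   integer percentages `matching_pct`, `fi_pct`, `fii_pct`.
#' @examples
#' summarize_cohort(classify_genes(drug_target_table("ion_channels")))
#' @export
summarize_cohort <- function(calls) {
  stopifnot(is.data.frame(calls))
  if (nrow(calls) == 0) {
    stop("empty cohort: matching rate undefined", call. = FALSE)
  }
  n <- nrow(calls)
  counts <- table(factor(as.character(calls$category),
                         levels = factor_categories))
  counts <- stats::setNames(as.integer(counts), factor_categories)
  either <- n - counts[["NONE"]]
  structure(list(
    n = n,
    counts = counts,
    fi_count = sum(calls$meets_fi),
    fii_count = sum(calls$meets_fii),
    either_count = either,
    matching_rate = either / n,
    matching_pct = round_half_up(100 * either / n),
    fi_pct = round_half_up(100 * sum(calls$meets_fi) / n),
    fii_pct = round_half_up(100 * sum(calls$meets_fii) / n)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d genes\n", x$n))
  cat(sprintf("  F(i) met by %d (%d%%), F(ii) by %d (%d%%)\n",
              x$fi_count, x$fi_pct, x$fii_count, x$fii_pct))
  cat(sprintf("  categories: BOTH %d | FI_ONLY %d | FII_ONLY %d | NONE %d\n",
              x$counts[["BOTH"]], x$counts[["FI_ONLY"]],
              x$counts[["FII_ONLY"]], x$counts[["NONE"]]))
  cat(sprintf("  matching rate (either factor): %d/%d = %d%%\n",
              x$either_count, x$n, x$matching_pct))
  invisible(x)
}

#' Prioritize candidate genes within the Both or None group
#'
#' Ranks the genes of the requested category and returns the top `k`
#' symbols. The `BOTH` group (predicted most mutable) is ordered by A+T
#' content descending, then proximity ascending, then symbol; the `NONE`
#' group (predicted least mutable, the attractive drug targets) by A+T
#' ascending, then proximity descending, then symbol. The ranking keys are
#' a package convention: they order genes by how far inside (or outside)
#' the factor regions they sit.
#'
#' @param records gene-record data frame.
#' @param calls matching factor calls from [classify_genes()].
#' @param group `"BOTH"` or `"NONE"`.
#' @param k number of symbols to return (`>= 0`).
#' @return character vector of up to `k` gene symbols.
#' @examples
#' tab1 <- drug_target_table("ion_channels")
#' prioritize(tab1, classify_genes(tab1), "NONE", k = 5)
#' @export
prioritize <- function(records, calls, group = c("BOTH", "NONE"), k = 5) {
  group <- match.arg(group)
  stopifnot(is.numeric(k), length(k) == 1, k >= 0)
  keep <- as.character(calls$category) == group
  sub <- records[keep, , drop = FALSE]
  if (nrow(sub) == 0) return(character(0))
  ord <- if (group == "BOTH") {
    order(-sub$a_plus_t, sub$proximity, sub$symbol)
  } else {
    order(sub$a_plus_t, -sub$proximity, sub$symbol)
  }
  utils::head(sub$symbol[ord], k)
}
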
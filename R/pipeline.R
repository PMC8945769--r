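#' Run the end-to-end two-factor mutability analysis
#'
#' Orchestrates the full workflow on a gene cohort: fill in missing
#' telomere proximities (from a chromosome map and optional telomere
#' intervals) and missing A+T content (from sequences), classify every gene
#' against the factor thresholds, summarize the cohort matching rate, run
#' the supporting statistics (full-length size vs proximity and vs A+T
#' Pearson correlations; size-bin grouping with one-way ANOVA + Tukey on
#' proximity and A+T), and prioritize the Both/None candidate lists.
#'
#' Values already present in the table take precedence over computed ones
#' (the reference tables carry viewer-read values that must not be
#' recomputed); the per-gene `proximity_source` / `at_source` columns
#' record which path filled each field. Genes for which neither a table
#' value nor a computation path exists are collected as per-gene errors;
#' the run fails only if no gene is classifiable.
#'
#' @param records gene-record data frame (see [read_gene_table()],
#'   [generate_cohort()]).
#' @param thresholds a [factor_thresholds()].
#' @param chrom_map optional named chromosome-length vector (Mb) enabling
#'   proximity computation via [nearest_telomere_distance()].
#' @param telomeres optional telomere intervals from [read_telomere_bed()].
#' @param sequences optional named character vector (or `DNAStringSet`) of
#'   nucleotide sequences, names matched to gene symbols case-insensitively,
#'   enabling A+T computation via [base_composition()].
#' @param top_k number of candidates in each prioritized list.
#' @return an object of class `"tf_report"`: list with `genes` (per-gene
#'   table with calls and provenance columns), `summary`
#'   (a `"cohort_summary"`), `diagnostics` (strict vs non-strict factor
#'   counts), `correlations`, `size_groups` (per-bin n and group tests),
#'   `prioritized`, `errors` (per-gene failures) and `provenance`.
#' @examples
#' report <- run_two_factor_analysis(drug_target_table("ion_channels"))
#' report$summary
#' @export
run_two_factor_analysis <- function(records,
                                    thresholds = factor_thresholds(),
                                    chrom_map = NULL,
                                    telomeres = NULL,
                                    sequences = NULL,
                                    top_k = 5) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("empty cohort", call. = FALSE)
  recs <- records
  n_input <- nrow(recs)
  errors <- character(0)

  recs$proximity_source <- ifelse(!is.na(recs$proximity), "table", NA)
  recs$at_source <- ifelse(!is.na(recs$a_plus_t), "table", NA)

  if (!is.null(sequences)) {
    seq_names <- names(sequences)  # as.character() on a DNAStringSet/named
    sequences <- as.character(sequences)  # vector can drop the names
    if (is.null(names(sequences))) names(sequences) <- seq_names
  }

  drop <- logical(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    if (is.na(recs$proximity[i])) {
      filled <- FALSE
      if (!is.null(chrom_map) && !is.na(recs$gene_locus[i])) {
        res <- tryCatch(
          nearest_telomere_distance(recs$gene_locus[i], recs$chrom_name[i],
                                    chrom_map, telomeres),
          error = function(e) e)
        if (!inherits(res, "error")) {
          recs$proximity[i] <- res$distance
          recs$telomere_locus[i] <- if (res$arm == "p") 0
            else unname(chrom_map[[recs$chrom_name[i]]])
          recs$proximity_source[i] <- "computed"
          filled <- TRUE
        } else {
          errors <- c(errors, sprintf("%s: %s", recs$symbol[i],
                                      conditionMessage(res)))
        }
      } else {
        errors <- c(errors,
                    sprintf("%s: no proximity value and no computation path",
                            recs$symbol[i]))
      }
      if (!filled) drop[i] <- TRUE
    }
    if (is.na(recs$a_plus_t[i])) {
      filled <- FALSE
      if (!is.null(sequences)) {
        hit <- which(toupper(names(sequences)) == toupper(recs$symbol[i]))
        if (length(hit) >= 1) {
          res <- tryCatch(base_composition(sequences[[hit[1]]]),
                          error = function(e) e)
          if (!inherits(res, "error")) {
            recs$a_plus_t[i] <- res$a_plus_t
            recs$a_pct[i] <- unname(res$pct["A"])
            recs$t_pct[i] <- unname(res$pct["T"])
            if (is.na(recs$fl_size[i])) recs$fl_size[i] <- res$length
            recs$at_source[i] <- "computed"
            filled <- TRUE
          } else {
            errors <- c(errors, sprintf("%s: %s", recs$symbol[i],
                                        conditionMessage(res)))
          }
        }
      }
      if (!filled) {
        errors <- c(errors,
                    sprintf("%s: no A+T value and no sequence supplied",
                            recs$symbol[i]))
        drop[i] <- TRUE
      }
    }
  }
  recs_ok <- recs[!drop, , drop = FALSE]
  if (nrow(recs_ok) == 0) {
    stop("no gene has a usable proximity/composition path:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }

  calls <- classify_genes(recs_ok, thresholds)
  summary <- summarize_cohort(calls)
  genes <- cbind(recs_ok, calls[, c("meets_fi", "meets_fii", "category")])

  # strict-vs-relaxed factor counts: the boundary genes (e.g. A+T exactly
  # at the cutoff) are exactly the ones these two counts disagree on
  relaxed <- factor_thresholds(thresholds$proximity_cutoff,
                               thresholds$at_cutoff,
                               strict_fi = FALSE, strict_fii = FALSE)
  calls_relaxed <- classify_genes(recs_ok, relaxed)
  diagnostics <- list(
    fi_count_strict = sum(calls$meets_fi),
    fi_count_relaxed = sum(calls_relaxed$meets_fi),
    fii_count_strict = sum(calls$meets_fii),
    fii_count_relaxed = sum(calls_relaxed$meets_fii),
    boundary_genes = recs_ok$symbol[calls$meets_fii != calls_relaxed$meets_fii |
                                      calls$meets_fi != calls_relaxed$meets_fi]
  )

  correlations <- list(fl_vs_proximity = NULL, fl_vs_at = NULL, notice = NULL)
  if (nrow(recs_ok) >= 3 &&
      var(recs_ok$fl_size) > 0 && var(recs_ok$proximity) > 0 &&
      var(recs_ok$a_plus_t) > 0) {
    correlations$fl_vs_proximity <- pearson_with_p(recs_ok$fl_size,
                                                   recs_ok$proximity)
    correlations$fl_vs_at <- pearson_with_p(recs_ok$fl_size, recs_ok$a_plus_t)
  } else {
    correlations$notice <- "correlations not computed (n < 3 or zero variance)"
  }

  bin <- assign_size_bin(recs_ok$fl_size)
  bin_label <- size_bin_labels()[bin]
  size_groups <- list(
    bin = bin,
    n_per_bin = stats::setNames(tabulate(bin, nbins = 3), size_bin_labels()),
    proximity_anova = NULL, at_anova = NULL, notice = NULL
  )
  usable <- which(tabulate(bin, nbins = 3) >= 2)
  if (length(usable) >= 2) {
    grp <- function(v) split(v, bin_label)[size_bin_labels()[usable]]
    prox_groups <- grp(recs_ok$proximity)
    at_groups <- grp(recs_ok$a_plus_t)
    size_groups$proximity_anova <- tryCatch(anova_tukey(prox_groups),
                                            error = function(e) NULL)
    size_groups$at_anova <- tryCatch(anova_tukey(at_groups),
                                     error = function(e) NULL)
  } else {
    size_groups$notice <- "group tests not computed (fewer than 2 usable bins)"
  }

  prioritized <- list(
    most_mutable = prioritize(recs_ok, calls, "BOTH", top_k),
    least_mutable = prioritize(recs_ok, calls, "NONE", top_k)
  )

  structure(list(
    genes = genes,
    summary = summary,
    diagnostics = diagnostics,
    correlations = correlations,
    size_groups = size_groups,
    prioritized = prioritized,
    errors = errors,
    provenance = list(
      n_input = n_input,
      n_classified = nrow(recs_ok),
      n_failed = sum(drop),
      thresholds = unclass(thresholds),
      proximity_sources = table(recs_ok$proximity_source),
      at_sources = table(recs_ok$at_source),
      package_version = as.character(utils::packageVersion("telomut"))
    )
  ), class = "tf_report")
}

#' @export
print.tf_report <- function(x, ...) {
  cat("Two-factor mutability analysis\n")
  cat(sprintf("  %d gene(s) in, %d classified, %d failed\n",
              x$provenance$n_input, x$provenance$n_classified,
              x$provenance$n_failed))
  print(x$summary)
  if (!is.null(x$correlations$fl_vs_proximity)) {
    cat(sprintf("  FL size vs proximity: r = %.3g (p = %.3g)\n",
                x$correlations$fl_vs_proximity$r, x$correlations$fl_vs_proximity$p))
    cat(sprintf("  FL size vs A+T:       r = %.3g (p = %.3g)\n",
                x$correlations$fl_vs_at$r, x$correlations$fl_vs_at$p))
  } else if (!is.null(x$correlations$notice)) {
    cat("  ", x$correlations$notice, "\n", sep = "")
  }
  if (length(x$prioritized$most_mutable) > 0) {
    cat("  most mutable (Both): ",
        paste(x$prioritized$most_mutable, collapse = ", "), "\n", sep = "")
  }
  if (length(x$prioritized$least_mutable) > 0) {
    cat("  least mutable (None): ",
        paste(x$prioritized$least_mutable, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a report to JSON
#'
#' Writes the cohort summary, diagnostics, correlations, size-bin tests,
#' prioritized lists and provenance as a JSON document. Output is
#' deterministic given the report.
#'
#' @param report a `"tf_report"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  stopifnot(inherits(report, "tf_report"))
  payload <- list(
    summary = unclass(report$summary),
    diagnostics = report$diagnostics,
    correlations = lapply(
      Filter(Negate(is.null), report$correlations),
      function(x) if (inherits(x, "pearson_result")) unclass(x) else x),
    size_groups = list(
      n_per_bin = as.list(report$size_groups$n_per_bin),
      proximity_anova = anova_payload(report$size_groups$proximity_anova),
      at_anova = anova_payload(report$size_groups$at_anova)
    ),
    prioritized = report$prioritized,
    errors = report$errors,
    provenance = lapply(report$provenance, function(x)
      if (inherits(x, "table")) as.list(stats::setNames(as.integer(x), names(x)))
      else x)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

anova_payload <- function(x) {
  if (is.null(x)) return(NULL)
  list(F = x$F, p_overall = x$p_overall, df = as.list(x$df),
       pairwise = x$pairwise)
}
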
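#' Render the summary plots for an analysis report
#'
#' Writes three figures to `out_dir`:
#' \enumerate{
#'   \item `proximity_scatter.png` — per-gene telomere proximity with the
#'     F(i) cutoff line; genes below the line are inside the factor region;
#'   \item `at_scatter.png` — per-gene A+T content with the F(ii) cutoff;
#'   \item `heat_strip.png` — a per-gene tile strip of chromosome index,
#'     proximity and A+T content (the compact cohort overview).
#' }
#' A sidecar `plots_meta.json` records the threshold lines, gene order and
#' file list, so the plot content is machine-checkable; figures are
#' deterministic given the report.
#'
#' @param report a `"tf_report"` from [run_two_factor_analysis()].
#' @param out_dir output directory (created if missing).
#' @param width,height figure size in inches.
#' @return invisible character vector of the created file paths.
#' @importFrom rlang .data
#' @export
render_summary_plots <- function(report, out_dir, width = 6, height = 4) {
  stopifnot(inherits(report, "tf_report"))
  genes <- report$genes
  if (is.null(genes) || nrow(genes) == 0) {
    stop("report contains no classified genes", call. = FALSE)
  }
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || !dir.exists(out_dir)) {
    stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  th <- report$provenance$thresholds
  df <- data.frame(
    index = seq_len(nrow(genes)),
    symbol = genes$symbol,
    chromosome = genes$chromosome,
    proximity = genes$proximity,
    a_plus_t = genes$a_plus_t,
    category = as.character(genes$category),
    stringsAsFactors = FALSE
  )

  p1 <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$proximity,
                                         colour = .data$category)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = th$proximity_cutoff, linetype = "dashed") +
    ggplot2::labs(x = "gene", y = "proximity to telomere (Mb)",
                  title = sprintf("F(i): proximity %s %g Mb",
                                  if (th$strict_fi) "<" else "<=",
                                  th$proximity_cutoff)) +
    ggplot2::theme_minimal()

  p2 <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$a_plus_t,
                                         colour = .data$category)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = th$at_cutoff, linetype = "dashed") +
    ggplot2::labs(x = "gene", y = "A+T content (%)",
                  title = sprintf("F(ii): A+T %s %g%%",
                                  if (th$strict_fii) ">" else ">=",
                                  th$at_cutoff)) +
    ggplot2::theme_minimal()

  long <- data.frame(
    symbol = factor(rep(df$symbol, 3), levels = rev(df$symbol)),
    track = factor(rep(c("chromosome", "proximity (Mb)", "A+T (%)"),
                       each = nrow(df)),
                   levels = c("chromosome", "proximity (Mb)", "A+T (%)")),
    value = c(df$chromosome, df$proximity, df$a_plus_t)
  )
  p3 <- ggplot2::ggplot(long, ggplot2::aes(x = .data$track, y = .data$symbol,
                                           fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~track, scales = "free_x", nrow = 1) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())

  files <- file.path(out_dir, c("proximity_scatter.png", "at_scatter.png",
                                "heat_strip.png"))
  ggplot2::ggsave(files[1], p1, width = width, height = height, dpi = 120)
  ggplot2::ggsave(files[2], p2, width = width, height = height, dpi = 120)
  ggplot2::ggsave(files[3], p3, width = width,
                  height = max(height, 0.25 * nrow(df) + 1), dpi = 120)

  meta <- list(
    files = basename(files),
    n_genes = nrow(df),
    gene_order = df$symbol,
    thresholds = list(proximity_cutoff = th$proximity_cutoff,
                      at_cutoff = th$at_cutoff,
                      strict_fi = th$strict_fi, strict_fii = th$strict_fii)
  )
  meta_path <- file.path(out_dir, "plots_meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, meta_path))
}
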
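#' Read a gene-record table
#'
#' Parses a delimited per-gene table into the standard gene-record data
#' frame used throughout the package. Two dialects are understood:
#'
#' \describe{
#'   \item{`"table1_2"`}{The layout of the published drug-target tables:
#'     columns `Drug`, `Target Gene`, `Chr`, `Gene Loci`, `Telomere Loci`,
#'     `Proximity (Mb)`, `A,T (%)` (a comma-joined A,T percentage pair),
#'     `A+T (%)` and `FL Size (bp)`. Thousands separators in sizes
#'     (`13,744`) are accepted. Values are stored exactly as printed; the
#'     A+T column is never recomputed from the A,T pair.}
#'   \item{`"generic"`}{Machine-friendly columns `drug`, `gene`, `chr`,
#'     `gene_locus_mb`, `telomere_locus_mb`, `proximity_mb`, `a_pct`,
#'     `t_pct`, `at_pct`, `fl_size_bp`, optionally `protein_class`; only
#'     `gene` and `chr` are required, extra columns are kept.}
#' }
#'
#' Chromosome `X` is encoded as index 23 (column `chromosome`) while the
#' printed name is preserved in `chrom_name`. Gene aliases such as
#' `"HERG (KCNH2)"` or `"NK1R or TACR1"` resolve to the final symbol
#' (`KCNH2`, `TACR1`); the printed name is kept in `gene_name`.
#'
#' @param path path to a tab- or comma-separated file with a header row.
#' @param dialect `"table1_2"` or `"generic"`.
#' @param protein_class class assigned to every record when the file carries
#'   no `protein_class` column: `"ion_channel"`, `"gpcr"` or `"other"`.
#' @param sep field separator; default tab.
#' @return a `data.frame` of gene records with columns `symbol`,
#'   `gene_name`, `drug`, `protein_class`, `chromosome`, `chrom_name`,
#'   `gene_locus`, `telomere_locus`, `proximity`, `a_pct`, `t_pct`,
#'   `a_plus_t`, `fl_size` (coordinates in Mb, sizes in bp).
#' @seealso [drug_target_table()] for the packaged reference tables,
#'   [validate_gene_records()] for the field invariants.
#' @examples
#' tab1 <- drug_target_table("ion_channels")
#' nrow(tab1)      # 11
#' tab1$symbol[1]  # "CACNA1C"
#' @export
read_gene_table <- function(path, dialect = c("table1_2", "generic"),
                            protein_class = c("other", "ion_channel", "gpcr"),
                            sep = "\t") {
  dialect <- match.arg(dialect)
  protein_class <- match.arg(protein_class)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, sep = sep, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (dialect == "table1_2") {
    records <- parse_table1_2(raw)
  } else {
    records <- parse_generic(raw)
  }
  if (!"protein_class" %in% names(raw)) {
    records$protein_class <- rep(protein_class, nrow(records))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  rownames(records) <- NULL
  if (nrow(records) > 0) validate_gene_records(records)
  records
}

# canonical symbol from a printed gene name: "HERG (KCNH2)" -> KCNH2,
# "NK1R or TACR1" -> TACR1, "*SMO*" -> SMO
extract_symbol <- function(gene_name) {
  x <- gsub("\\*", "", trimws(gene_name))
  paren <- regmatches(x, regexpr("\\(([^)]+)\\)", x))
  has_paren <- lengths(regmatches(x, gregexpr("\\(([^)]+)\\)", x))) > 0
  out <- x
  out[has_paren] <- sub(".*\\(([^)]+)\\).*", "\\1", x[has_paren])
  has_or <- grepl("\\bor\\b", out)
  out[has_or] <- sub(".*\\bor\\b\\s*", "", out[has_or])
  trimws(out)
}

require_columns <- function(raw, cols) {
  missing <- setdiff(cols, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

parse_table1_2 <- function(raw) {
  cols <- c("Drug", "Target Gene", "Chr", "Gene Loci", "Telomere Loci",
            "Proximity (Mb)", "A,T (%)", "A+T (%)", "FL Size (bp)")
  require_columns(raw, cols)
  n <- nrow(raw)
  rows <- seq_len(n)
  # "A,T (%)" is a comma-joined pair, not a thousands separator
  at_pair <- strsplit(trimws(raw[["A,T (%)"]]), ",")
  bad <- lengths(at_pair) != 2
  if (any(bad)) {
    stop(sprintf("cannot parse 'A,T (%%)' value '%s' (row %d)",
                 raw[["A,T (%)"]][bad][1], which(bad)[1]), call. = FALSE)
  }
  a_pct <- parse_printed_number(vapply(at_pair, `[`, "", 1), "A (%)", rows)
  t_pct <- parse_printed_number(vapply(at_pair, `[`, "", 2), "T (%)", rows)
  gene_name <- gsub("\\*", "", trimws(raw[["Target Gene"]]))
  data.frame(
    symbol        = extract_symbol(raw[["Target Gene"]]),
    gene_name     = gene_name,
    drug          = trimws(raw[["Drug"]]),
    chromosome    = chrom_index(raw[["Chr"]]),
    chrom_name    = normalize_chrom(raw[["Chr"]]),
    gene_locus    = parse_printed_number(raw[["Gene Loci"]], "Gene Loci", rows),
    telomere_locus = parse_printed_number(raw[["Telomere Loci"]],
                                          "Telomere Loci", rows),
    proximity     = parse_printed_number(raw[["Proximity (Mb)"]],
                                         "Proximity (Mb)", rows),
    a_pct         = a_pct,
    t_pct         = t_pct,
    a_plus_t      = parse_printed_number(raw[["A+T (%)"]], "A+T (%)", rows),
    fl_size       = parse_printed_number(raw[["FL Size (bp)"]],
                                         "FL Size (bp)", rows),
    stringsAsFactors = FALSE
  )
}

parse_generic <- function(raw) {
  require_columns(raw, c("gene", "chr"))
  n <- nrow(raw)
  rows <- seq_len(n)
  num <- function(col, what) {
    if (col %in% names(raw)) parse_printed_number(raw[[col]], what, rows)
    else rep(NA_real_, n)
  }
  chr_ok <- if (n > 0) raw[["chr"]] else character(0)
  out <- data.frame(
    symbol        = extract_symbol(raw[["gene"]]),
    gene_name     = gsub("\\*", "", trimws(raw[["gene"]])),
    drug          = if ("drug" %in% names(raw)) trimws(raw[["drug"]])
                    else rep(NA_character_, n),
    chromosome    = if (n > 0) chrom_index(chr_ok) else integer(0),
    chrom_name    = if (n > 0) normalize_chrom(chr_ok) else character(0),
    gene_locus    = num("gene_locus_mb", "gene_locus_mb"),
    telomere_locus = num("telomere_locus_mb", "telomere_locus_mb"),
    proximity     = num("proximity_mb", "proximity_mb"),
    a_pct         = num("a_pct", "a_pct"),
    t_pct         = num("t_pct", "t_pct"),
    a_plus_t      = num("at_pct", "at_pct"),
    fl_size       = num("fl_size_bp", "fl_size_bp"),
    stringsAsFactors = FALSE
  )
  if ("protein_class" %in% names(raw)) out$protein_class <- raw[["protein_class"]]
  for (extra in intersect(c("meets_fi", "meets_fii", "category"), names(raw))) {
    out[[extra]] <- if (extra == "category") raw[[extra]]
                    else as.logical(raw[[extra]])
  }
  out
}

#' Validate gene-record invariants
#'
#' Checks the field invariants of a gene-record data frame: percentages in
#' \[0, 100\] with the printed A+T within 1 point of A% + T% (printed-
#' rounding slack), non-negative proximity, chromosome index in 1..23 and
#' positive full-length size.
#'
#' @param records gene-record data frame as returned by [read_gene_table()].
#' @return `records`, invisibly; stops with an informative error otherwise.
#' @export
validate_gene_records <- function(records) {
  stopifnot(is.data.frame(records))
  chk <- function(cond, msg) {
    bad <- which(!(cond | is.na(cond)))
    if (length(bad) > 0) {
      stop(sprintf("%s (gene %s)", msg,
                   paste(records$symbol[bad], collapse = ", ")), call. = FALSE)
    }
  }
  for (col in c("a_pct", "t_pct", "a_plus_t")) {
    if (col %in% names(records)) {
      chk(records[[col]] >= 0 & records[[col]] <= 100,
          sprintf("%s outside [0, 100]", col))
    }
  }
  full <- !is.na(records$a_pct) & !is.na(records$t_pct) & !is.na(records$a_plus_t)
  if (any(full)) {
    slack <- abs(records$a_plus_t[full] - (records$a_pct[full] + records$t_pct[full]))
    if (any(slack > 1)) {
      stop("a_plus_t deviates from a_pct + t_pct by more than 1 point (gene ",
           paste(records$symbol[full][slack > 1], collapse = ", "), ")",
           call. = FALSE)
    }
  }
  chk(records$proximity >= 0, "negative proximity")
  chk(records$chromosome >= 1 & records$chromosome <= 23,
      "chromosome index outside 1..23")
  chk(records$fl_size >= 1, "non-positive fl_size")
  invisible(records)
}

#' Packaged drug-target reference tables
#'
#' Returns the packaged two-factor characteristics of the genes targeted by
#' FDA-approved drugs: 11 ion-channel genes (amlodipine/CACNA1C through
#' riluzole/KCNK4) or 20 GPCR genes (siponimod/S1PR1 through
#' vraylar/DRD3), with the published per-gene coordinates, telomere
#' proximity, A/T composition and full-length sizes reproduced verbatim.
#'
#' Data-quality note: in the GPCR table the aripiprazole-lauroxil/HTR1A row
#' prints chromosome 5 with gene locus 197 and telomere locus 197 — values
#' identical to the NR1I2 row and beyond the ~181 Mb length of chromosome 5.
#' This is reproduced as printed (a likely transcription error in the
#' source); classification uses the printed proximity column, which is
#' unaffected.
#'
#' @param which `"ion_channels"` (11 records) or `"gpcrs"` (20 records).
#' @return gene-record data frame (see [read_gene_table()]) with
#'   `protein_class` set accordingly.
#' @examples
#' gpcrs <- drug_target_table("gpcrs")
#' table(gpcrs$chrom_name)
#' @export
drug_target_table <- function(which = c("ion_channels", "gpcrs")) {
  which <- match.arg(which)
  read_gene_table(
    drug_target_table_path(which),
    dialect = "table1_2",
    protein_class = if (which == "ion_channels") "ion_channel" else "gpcr"
  )
}

#' @rdname drug_target_table
#' @export
drug_target_table_path <- function(which = c("ion_channels", "gpcrs")) {
  which <- match.arg(which)
  fname <- if (which == "ion_channels") "table1_ion_channels.tsv"
           else "table2_gpcrs.tsv"
  system.file("extdata", fname, package = "telomut", mustWork = TRUE)
}

#' Write classified gene records to a tab-separated file
#'
#' Emits the generic-dialect table (see [read_gene_table()]) with the
#' factor calls appended as `meets_fi`, `meets_fii`, `category` columns.
#' The output round-trips through `read_gene_table(dialect = "generic")`.
#'
#' @param records gene-record data frame.
#' @param calls factor-call data frame from [classify_genes()], one row per
#'   record (matched by `symbol` and order).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, calls, path) {
  if (nrow(records) != nrow(calls) ||
      (nrow(records) > 0 && !all(records$symbol == calls$symbol))) {
    stop("records and calls must align one-to-one by symbol", call. = FALSE)
  }
  out <- data.frame(
    drug = records$drug %||% rep(NA_character_, nrow(records)),
    gene = records$gene_name,
    chr = records$chrom_name,
    gene_locus_mb = records$gene_locus,
    telomere_locus_mb = records$telomere_locus,
    proximity_mb = records$proximity,
    a_pct = records$a_pct,
    t_pct = records$t_pct,
    at_pct = records$a_plus_t,
    fl_size_bp = records$fl_size,
    protein_class = records$protein_class,
    meets_fi = calls$meets_fi,
    meets_fii = calls$meets_fii,
    category = as.character(calls$category),
    stringsAsFactors = FALSE
  )
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
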
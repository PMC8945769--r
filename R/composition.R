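#' Per-base nucleotide composition of a sequence
#'
#' Counts A, C, G, T (case-insensitive; U counts as T) and computes each
#' base's percentage of the unambiguous length. IUPAC ambiguity codes
#' (N, R, Y, S, W, K, M, B, D, H, V) are tallied in `n_ambiguous` and
#' excluded from the percentage denominator. The A+T content is the exact
#' (unrounded) sum of the A and T percentages; rounding to the integer
#' style of the reference tables happens only at report time via
#' [round_half_up()].
#'
#' @param sequence a single nucleotide string; whitespace is ignored.
#' @return an object of class `"composition_result"`: a list with `counts`
#'   (named integer vector over A, C, G, T), `n_ambiguous`, `length`
#'   (total bases incl. ambiguous), `pct` (named percentages over the
#'   unambiguous length) and `a_plus_t`.
#' @examples
#' base_composition("ATGCATGCAA")$a_plus_t  # 60
#' @export
base_composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  seq <- gsub("[[:space:]]", "", sequence)
  if (nchar(seq) == 0) stop("empty sequence", call. = FALSE)
  chars <- strsplit(toupper(seq), "")[[1]]
  chars[chars == "U"] <- "T"
  ambiguity <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  legal <- c("A", "C", "G", "T", ambiguity)
  bad <- which(!chars %in% legal)
  if (length(bad) > 0) {
    stop(sprintf("illegal character '%s' at position %d", chars[bad[1]], bad[1]),
         call. = FALSE)
  }
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) sum(chars == b), integer(1))
  n_unamb <- sum(counts)
  if (n_unamb == 0) {
    stop("sequence is entirely ambiguous; composition undefined", call. = FALSE)
  }
  pct <- 100 * counts / n_unamb
  structure(
    list(counts = counts,
         n_ambiguous = length(chars) - n_unamb,
         length = length(chars),
         pct = pct,
         a_plus_t = unname(pct["A"] + pct["T"])),
    class = "composition_result"
  )
}

#' @export
print.composition_result <- function(x, ...) {
  cat(sprintf("Nucleotide composition (%d bases, %d ambiguous)\n",
              x$length, x$n_ambiguous))
  cat(sprintf("  A %.2f%%  C %.2f%%  G %.2f%%  T %.2f%%\n",
              x$pct["A"], x$pct["C"], x$pct["G"], x$pct["T"]))
  cat(sprintf("  A+T content: %.2f%%\n", x$a_plus_t))
  invisible(x)
}

#' Combine printed A and T percentages
#'
#' The reference tables print per-gene A and T percentages as a pair
#' (`"29,31"`) next to an integer A+T column; this helper reproduces that
#' sum from the printed pair.
#'
#' @param a_pct,t_pct percentages in \[0, 100\] with `a_pct + t_pct <= 100`;
#'   vectorized.
#' @return `a_pct + t_pct`.
#' @examples
#' at_from_printed(29, 31)  # 60, the KCNJ6 row
#' @export
at_from_printed <- function(a_pct, t_pct) {
  stopifnot(is.numeric(a_pct), is.numeric(t_pct), length(a_pct) == length(t_pct))
  if (any(a_pct < 0 | t_pct < 0)) stop("negative percentage", call. = FALSE)
  if (any(a_pct + t_pct > 100)) {
    stop("a_pct + t_pct exceeds 100", call. = FALSE)
  }
  a_pct + t_pct
}

#' Composition of every record in a FASTA file
#'
#' Reads a (multi-record) FASTA file and computes [base_composition()] for
#' each sequence. Record ids are matched to gene symbols case-insensitively
#' by the pipeline. Requires the Biostrings package for FASTA parsing.
#'
#' @param path path to an uncompressed FASTA file.
#' @return data.frame with columns `symbol`, `a_pct`, `t_pct`, `a_plus_t`
#'   (unrounded percentages) and `fl_size` (total sequence length in bases).
#' @export
composition_from_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("composition_from_fasta() requires the Biostrings package",
         call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  res <- lapply(as.character(seqs), base_composition)
  data.frame(
    symbol = ids,
    a_pct = vapply(res, function(r) unname(r$pct["A"]), numeric(1)),
    t_pct = vapply(res, function(r) unname(r$pct["T"]), numeric(1)),
    a_plus_t = vapply(res, function(r) r$a_plus_t, numeric(1)),
    fl_size = vapply(res, function(r) r$length, numeric(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
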
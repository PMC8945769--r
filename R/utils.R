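#' Round half away from zero
#'
#' Rounding used for all reported integer percentages: halves round up
#' (63.6 -> 64, 2.5 -> 3), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` rounded with ties away from zero.
#' @examples
#' round_half_up(c(63.6, 2.5, 81.8))
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a chromosome name
#'
#' Maps the spellings found in genome files and tables onto the canonical
#' names `"1".."22", "X"`: a leading `"chr"` is stripped, case is ignored,
#' and the numeric alias `23` is accepted for X.
#'
#' @param chrom character or numeric vector of chromosome names.
#' @return character vector of canonical names.
#' @seealso [chrom_index()] for the numeric 1-23 encoding.
#' @export
normalize_chrom <- function(chrom) {
  x <- toupper(trimws(as.character(chrom)))
  x <- sub("^CHR", "", x)
  x[x == "23"] <- "X"
  ok <- x %in% c(as.character(1:22), "X")
  if (any(!ok)) {
    stop("unrecognized chromosome name(s): ",
         paste(unique(chrom[!ok]), collapse = ", "), call. = FALSE)
  }
  x
}

#' Numeric chromosome index (X encoded as 23)
#'
#' @inheritParams normalize_chrom
#' @return integer vector in 1..23.
#' @export
chrom_index <- function(chrom) {
  x <- normalize_chrom(chrom)
  out <- rep(23L, length(x))
  num <- x != "X"
  out[num] <- as.integer(x[num])
  out
}

# parse a printed numeric cell, tolerating thousands separators ("13,744")
parse_printed_number <- function(x, what, row = NULL) {
  raw <- trimws(as.character(x))
  cleaned <- gsub(",", "", raw)
  out <- suppressWarnings(as.numeric(cleaned))
  bad <- !is.na(raw) & nzchar(raw) & is.na(out)
  if (any(bad)) {
    idx <- if (is.null(row)) which(bad)[1] else row[which(bad)[1]]
    stop(sprintf("cannot parse %s value '%s' (row %d)", what, raw[bad][1], idx),
         call. = FALSE)
  }
  out[!nzchar(raw) | is.na(raw)] <- NA_real_
  out
}
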
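#' Built-in human chromosome sizes
#'
#' Approximate GRCh38 chromosome lengths in megabases for chromosomes 1-22
#' and X, used as the default reference for nearest-telomere distances and
#' by the synthetic cohort generator so no external download is needed.
#'
#' @return named numeric vector of lengths in Mb; names `"1".."22", "X"`.
#' @export
human_chrom_sizes <- function() {
  c(`1` = 248.956422, `2` = 242.193529, `3` = 198.295559, `4` = 190.214555,
    `5` = 181.538259, `6` = 170.805979, `7` = 159.345973, `8` = 145.138636,
    `9` = 138.394717, `10` = 133.797422, `11` = 135.086622, `12` = 133.275309,
    `13` = 114.364328, `14` = 107.043718, `15` = 101.991189, `16` = 90.338345,
    `17` = 83.257441, `18` = 80.373285, `19` = 58.617616, `20` = 64.444167,
    `21` = 46.709983, `22` = 50.818468, X = 156.040895)
}

#' Read a UCSC chrom.sizes file
#'
#' Two whitespace-separated columns, chromosome name and length in base
#' pairs; lengths are converted to megabases (p-terminus fixed at
#' coordinate 0). Names are normalized so `"chr12"`, `"12"` and `"chrX"`,
#' `"X"`, `"23"` coincide.
#'
#' @param path path to the chrom.sizes file.
#' @return named numeric vector of chromosome lengths in Mb.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "length_bp"),
                    colClasses = c("character", "character"))
  nm <- normalize_chrom(raw$chrom)
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  len_bp <- parse_printed_number(raw$length_bp, "chromosome length")
  if (any(is.na(len_bp) | len_bp <= 0)) {
    stop("non-positive chromosome length for ",
         paste(nm[is.na(len_bp) | len_bp <= 0], collapse = ", "), call. = FALSE)
  }
  stats::setNames(len_bp / 1e6, nm)
}

#' Read telomere intervals from a BED3 file
#'
#' 0-based half-open intervals in bp (UCSC BED convention), converted to Mb.
#' When supplied to the proximity computations these intervals override the
#' idealized `{0, chromosome length}` telomere coordinates.
#'
#' @param path path to a BED3 file (chrom, start, end).
#' @return data.frame with columns `chrom` (normalized name), `start`,
#'   `end` (Mb, start-inclusive, end-exclusive).
#' @export
read_telomere_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("BED3 requires chrom, start, end columns", call. = FALSE)
  out <- data.frame(
    chrom = normalize_chrom(raw[[1]]),
    start = as.numeric(raw[[2]]) / 1e6,
    end = as.numeric(raw[[3]]) / 1e6,
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$start) | is.na(out$end) | out$end <= out$start)) {
    stop("malformed BED interval (need numeric start < end)", call. = FALSE)
  }
  out
}
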
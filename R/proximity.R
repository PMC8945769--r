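#' Distance between a gene locus and a stated telomere locus
#'
#' The table-mode distance: the absolute difference of the two printed
#' megabase coordinates, e.g. the KCNH2 locus at 150 Mb against the 7q
#' telomere at 158 Mb gives 8 Mb.
#'
#' @param gene_locus,telomere_locus coordinates in Mb from the p-terminus;
#'   vectorized, both `>= 0`.
#' @return distance in Mb (absolute difference, cleaned of floating-point
#'   dust so printed one-decimal inputs give one-decimal outputs).
#' @examples
#' distance_to_given_telomere(150, 158)   # 8
#' distance_to_given_telomere(138, 138.1) # 0.1
#' @export
distance_to_given_telomere <- function(gene_locus, telomere_locus) {
  stopifnot(is.numeric(gene_locus), is.numeric(telomere_locus))
  if (any(gene_locus < 0, na.rm = TRUE) || any(telomere_locus < 0, na.rm = TRUE)) {
    stop("coordinates must be non-negative", call. = FALSE)
  }
  round(abs(gene_locus - telomere_locus), 6)
}

#' Distance from a gene locus to the nearest telomere
#'
#' With only a chromosome length available, the telomeres are idealized as
#' coordinate 0 (p-terminus) and the chromosome length (q-terminus); the
#' gene (reduced to a single point locus) is assigned to whichever is
#' nearer, ties going to the p arm. When explicit telomere intervals are
#' supplied they override the idealized coordinates and the distance is to
#' the nearest interval edge (zero inside an interval).
#'
#' @param gene_locus gene coordinate in Mb from the p-terminus.
#' @param chromosome chromosome name (any spelling accepted by
#'   [normalize_chrom()]).
#' @param chrom_map named vector of chromosome lengths in Mb, e.g. from
#'   [read_chrom_sizes()] or [human_chrom_sizes()].
#' @param telomeres optional telomere intervals from [read_telomere_bed()].
#' @return a list of class `"proximity_result"`: `distance` (Mb), `arm`
#'   (`"p"` or `"q"`) and `linked` (the 50 cM linkage call, see
#'   [linkage_status()]).
#' @examples
#' nearest_telomere_distance(1.9, "12", human_chrom_sizes())
#' @export
nearest_telomere_distance <- function(gene_locus, chromosome, chrom_map,
                                      telomeres = NULL) {
  stopifnot(is.numeric(gene_locus), length(gene_locus) == 1)
  chrom <- normalize_chrom(chromosome)
  if (!chrom %in% names(chrom_map)) {
    stop("chromosome ", chromosome, " not in chromosome map", call. = FALSE)
  }
  len <- unname(chrom_map[[chrom]])
  if (gene_locus < 0 || gene_locus > len) {
    stop(sprintf("locus %g Mb outside chromosome %s (length %g Mb)",
                 gene_locus, chrom, len), call. = FALSE)
  }
  if (!is.null(telomeres) && any(telomeres$chrom == chrom)) {
    tel <- telomeres[telomeres$chrom == chrom, , drop = FALSE]
    gaps <- pmax(tel$start - gene_locus, gene_locus - tel$end, 0)
    i <- which.min(gaps)
    d <- round(gaps[i], 6)
    arm <- if ((tel$start[i] + tel$end[i]) / 2 <= len / 2) "p" else "q"
  } else {
    d_p <- gene_locus
    d_q <- len - gene_locus
    arm <- if (d_p <= d_q) "p" else "q"
    d <- round(min(d_p, d_q), 6)
  }
  structure(list(distance = d, arm = arm,
                 linked = linkage_status(d) == "linked"),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("%g Mb to the %s-arm telomere (%s at the 50 cM criterion)\n",
              x$distance, x$arm, if (x$linked) "linked" else "unlinked"))
  invisible(x)
}

#' Linkage call at the 50-centimorgan criterion
#'
#' Loci within 50 cM of a telomere are called linked (proximal); above
#' 50 cM they are unlinked (distal). Megabase distances are converted with
#' the 1 cM ~ 1 Mbp heuristic before comparison, so [mb_to_cm()] is the
#' identity on the number.
#'
#' @param distance_cm non-negative genetic distance in cM (vectorized).
#' @return character vector, `"linked"` (<= 50 cM) or `"unlinked"`.
#' @examples
#' linkage_status(c(0, 50, 50.1))
#' @export
linkage_status <- function(distance_cm) {
  stopifnot(is.numeric(distance_cm))
  if (any(distance_cm < 0, na.rm = TRUE)) {
    stop("distance must be non-negative", call. = FALSE)
  }
  ifelse(distance_cm <= 50, "linked", "unlinked")
}

#' Megabase to centimorgan conversion (1 cM ~ 1 Mbp heuristic)
#'
#' @param mb physical distance in Mb.
#' @return genetic distance in cM under the 1:1 heuristic.
#' @export
mb_to_cm <- function(mb) {
  stopifnot(is.numeric(mb))
  mb
}
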
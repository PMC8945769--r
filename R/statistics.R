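#' Pearson correlation with two-sided significance
#'
#' Product-moment correlation with the two-sided p-value from the exact
#' t transform: `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. This is the statistic reported for the full-length size vs
#' telomere-proximity and full-length size vs A+T-content relationships.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, each with nonzero
#'   variance; pairs with missing values are dropped.
#' @return an object of class `"pearson_result"`: `r`, `p` (two-sided),
#'   `n` (pairs used).
#' @examples
#' pearson_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4))$r  # 0.8
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t_stat), df = n - 2)
  }
  structure(list(r = r, p = p, n = n), class = "pearson_result")
}

#' @export
print.pearson_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4g (two-sided p = %.4g, n = %d)\n", x$r, x$p, x$n))
  invisible(x)
}

#' Full-length size bins
#'
#' Assigns genes to the three nucleotide-length categories used for the
#' group comparisons: 1-3000, 3001-6000 and 6001+ bases. The upper bin is
#' displayed as "6001-17,000" after its cohort maximum but is mathematically
#' open-ended (the reference tables contain a 19,659 bp gene).
#'
#' @param fl_size full-length sizes in bases (`>= 1`); vectorized.
#' @return integer bin index 1-3.
#' @examples
#' assign_size_bin(c(3000, 3001, 19659))  # 1 2 3
#' @export
assign_size_bin <- function(fl_size) {
  stopifnot(is.numeric(fl_size))
  if (any(fl_size < 1, na.rm = TRUE)) {
    stop("fl_size must be at least 1", call. = FALSE)
  }
  as.integer(cut(fl_size, breaks = c(0, 3000, 6000, Inf), labels = FALSE))
}

#' @rdname assign_size_bin
#' @export
size_bin_labels <- function() {
  c("1-3000", "3001-6000", "6001-17,000")
}

#' One-way ANOVA with Tukey multiple comparisons
#'
#' Overall F test across groups followed by Tukey's honestly-significant-
#' difference pairwise comparisons (the Tukey-Kramer form, valid for the
#' unequal group sizes of the length bins). Fitted with [stats::aov()] and
#' [stats::TukeyHSD()]. Pairwise differences are flagged significant at
#' `p < 0.05`.
#'
#' @param groups named or unnamed list of `>= 2` numeric vectors, each with
#'   `>= 2` values.
#' @return an object of class `"anova_tukey_result"`: `F`, `p_overall`,
#'   `df` (between/within degrees of freedom) and `pairwise`, a data.frame
#'   with `group_a`, `group_b`, `mean_diff`, `p_adjusted`, `significant`.
#'   If every value in every group is identical the test degenerates to
#'   `F = 0`, `p = 1` (no variance to explain).
#' @examples
#' anova_tukey(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(8, 9, 10)))
#' @export
anova_tukey <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  nm <- names(groups)
  if (is.null(nm) || any(!nzchar(nm))) nm <- paste0("g", seq_along(groups))
  # fit under safe internal labels (user names may contain "-", which would
  # collide with TukeyHSD's "b-a" row naming), map back for output
  safe <- paste0("grp", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(safe, sizes), levels = safe)
  pairs_idx <- utils::combn(length(nm), 2)
  if (length(unique(values)) == 1) {
    pairwise <- data.frame(
      group_a = nm[pairs_idx[1, ]], group_b = nm[pairs_idx[2, ]],
      mean_diff = 0, p_adjusted = 1, significant = FALSE,
      stringsAsFactors = FALSE)
    return(structure(list(F = 0, p_overall = 1,
                          df = c(between = length(nm) - 1L,
                                 within = length(values) - length(nm)),
                          pairwise = pairwise),
                     class = "anova_tukey_result"))
  }
  fit <- aov(values ~ grp)
  tab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$grp
  # TukeyHSD labels rows "b-a" for level pair (a, b)
  pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
  to_user <- function(s) nm[match(s, safe)]
  pairwise <- data.frame(
    group_a = to_user(vapply(pair_names, `[`, "", 2)),
    group_b = to_user(vapply(pair_names, `[`, "", 1)),
    mean_diff = unname(tk[, "diff"]),
    p_adjusted = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE
  )
  pairwise$significant <- pairwise$p_adjusted < 0.05
  structure(list(
    F = tab[["F value"]][1],
    p_overall = tab[["Pr(>F)"]][1],
    df = c(between = tab[["Df"]][1], within = tab[["Df"]][2]),
    pairwise = pairwise
  ), class = "anova_tukey_result")
}

#' @export
print.anova_tukey_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[["between"]], x$df[["within"]], x$F, x$p_overall))
  cat("Tukey pairwise comparisons:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] with the preconditions made
#' explicit; used to check normality before the group comparisons
#' (significance level 0.05).
#'
#' @param x numeric vector, `3 <= n <= 5000`, nonzero variance.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  stopifnot(is.numeric(x))
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (var(x) == 0) stop("constant vector: normality test undefined", call. = FALSE)
  res <- shapiro.test(x)
  list(W = unname(res$statistic), p = res$p.value)
}
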
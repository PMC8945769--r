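# shared builders for tiny in-code cohorts

make_records <- function(symbol, proximity, a_plus_t,
                         fl_size = rep(5000, length(symbol)),
                         chromosome = rep(1L, length(symbol))) {
  data.frame(
    symbol = symbol,
    gene_name = symbol,
    drug = NA_character_,
    protein_class = "other",
    chromosome = chromosome,
    chrom_name = as.character(chromosome),
    gene_locus = proximity,
    telomere_locus = 0,
    proximity = proximity,
    a_pct = a_plus_t / 2,
    t_pct = a_plus_t / 2,
    a_plus_t = a_plus_t,
    fl_size = fl_size,
    stringsAsFactors = FALSE
  )
}

random_cohort <- function(n) {
  make_records(
    symbol = sprintf("G%03d", seq_len(n)),
    proximity = runif(n, 0, 150),
    a_plus_t = runif(n, 30, 80),
    fl_size = sample(500:20000, n, replace = TRUE)
  )
}

# independent recount of summarize_cohort: one gene at a time, no vector ops
brute_force_summary <- function(calls) {
  counts <- c(BOTH = 0L, FI_ONLY = 0L, FII_ONLY = 0L, NONE = 0L)
  either <- 0L
  for (i in seq_len(nrow(calls))) {
    fi <- calls$meets_fi[i]
    fii <- calls$meets_fii[i]
    cat_i <- if (fi && fii) "BOTH" else if (fi) "FI_ONLY" else
             if (fii) "FII_ONLY" else "NONE"
    counts[cat_i] <- counts[cat_i] + 1L
    if (fi || fii) either <- either + 1L
  }
  list(counts = counts, either_count = either,
       matching_rate = either / nrow(calls))
}

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
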
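# Brute-force oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (all-pairs scans, direct formulas) and
# independent of the package's implementation paths.

# all-pairs interval overlap, half-open semantics
bf_overlap <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(a_index = integer(), b_index = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(a_index = m[, 1], b_index = m[, 2])
}

# per-bin scan mean of track values over one region
bf_mean_over_region <- function(track, region) {
  vals <- c()
  for (i in seq_len(nrow(track))) {
    if (track$chrom[i] == region$chrom &&
        track$start[i] < region$end && region$start < track$end[i]) {
      vals <- c(vals, track$value[i])
    }
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# exhaustive hypergeometric upper tail by enumerating draw compositions
bf_hypergeom_upper <- function(n_genes, n_success, n_draw, k_min) {
  ks <- 0:n_draw
  probs <- vapply(ks, function(k) {
    if (k > n_success || (n_draw - k) > (n_genes - n_success)) return(0)
    choose(n_success, k) * choose(n_genes - n_success, n_draw - k) /
      choose(n_genes, n_draw)
  }, numeric(1))
  sum(probs[ks >= k_min])
}

# direct-formula Pearson chi-square on a 2x2 table
bf_chisq_2x2 <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE))
}

# random interval set on a toy genome
random_intervals <- function(n, chrom_sizes, max_len = 5000) {
  chrom <- sample(chrom_sizes$chrom, n, replace = TRUE)
  L <- chrom_sizes$length[match(chrom, chrom_sizes$chrom)]
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n, 0, pmax(1, L - len)))
  tibble::tibble(chrom = chrom, start = start, end = start + len)
}

toy_sizes <- function() {
  tibble::tibble(chrom = c("chrA", "chrB"), length = c(100000, 50000))
}

# a small filled track on the toy genome
toy_track <- function(values_a, values_b = NULL, bin = 1000,
                      kind = "log2_ratio") {
  tr <- binned_track(toy_sizes(), bin, kind)
  na <- sum(tr$chrom == "chrA")
  va <- rep_len(values_a, na)
  tr$value[tr$chrom == "chrA"] <- va
  if (!is.null(values_b)) {
    nb <- sum(tr$chrom == "chrB")
    tr$value[tr$chrom == "chrB"] <- rep_len(values_b, nb)
  }
  tr
}
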
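# Template-strand-based single-cell copy-number calling from Strand-seq
# 200-kb bin counts, and the Welch-t label-permutation test used to compare
# treated and control cells.
#
# The input count table has one row per cell per bin:
#   cell, chrom, start, end, watson, crick, qc_pass

#' Classify the strand inheritance of a segment
#'
#' `NO_SIGNAL` if fewer than `min_reads` total reads; `MIXED` if the minor
#' strand carries at least `minor_frac` of the reads; otherwise
#' `WATSON_ONLY` / `CRICK_ONLY` by the dominant strand. Vectorised.
#'
#' @param watson,crick Non-negative read counts.
#' @param min_reads Minimum total reads to call a state (default 10).
#' @param minor_frac Minor-strand fraction defining "significant signal on
#'   both strands" (default 0.1; must be in (0, 0.5)).
#' @return Character vector in
#'   `{"WATSON_ONLY","CRICK_ONLY","MIXED","NO_SIGNAL"}`.
#' @export
classify_strand_state <- function(watson, crick, min_reads = 10,
                                  minor_frac = 0.1) {
  if (min_reads < 1) abort("min_reads must be >= 1")
  if (minor_frac <= 0 || minor_frac >= 0.5) abort("minor_frac must be in (0, 0.5)")
  if (any(watson < 0) || any(crick < 0)) abort("negative counts")
  total <- watson + crick
  out <- rep("NO_SIGNAL", length(total))
  has <- total >= min_reads
  minor <- pmin(watson, crick) / pmax(total, 1)
  out[has & minor >= minor_frac] <- "MIXED"
  one <- has & minor < minor_frac
  out[one & watson >= crick] <- "WATSON_ONLY"
  out[one & watson < crick] <- "CRICK_ONLY"
  out
}

smooth_states <- function(states, min_run = 5) {
  if (length(states) == 0 || min_run <= 1) return(states)
  repeat {
    r <- rle(states)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_run)
    if (length(short) == 0) break
    i <- short[1]
    # absorb the short run into its left neighbour (right neighbour if first)
    r$values[i] <- if (i > 1) r$values[i - 1] else r$values[i + 1]
    states <- inverse.rle(r)
  }
  states
}

# A single-strand run bordered by mixed segments is either a true
# inheritance block (an SCE switched one template: total coverage is
# conserved) or a haplotype-specific dropout (a deletion: total coverage
# falls to about half). Runs whose mean total coverage is below
# dropout_ratio times that of the neighbouring mixed runs are folded back
# into the mixed segment so the CN caller can see them.
reclassify_dropouts <- function(states, totals, dropout_ratio = 0.75) {
  r <- rle(states)
  if (length(r$lengths) <= 1) return(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  run_mean <- vapply(seq_along(starts), function(i) {
    mean(totals[starts[i]:ends[i]])
  }, numeric(1))
  for (i in seq_along(r$values)) {
    if (!r$values[i] %in% c("WATSON_ONLY", "CRICK_ONLY")) next
    nb <- c(if (i > 1) i - 1, if (i < length(r$values)) i + 1)
    nb <- nb[r$values[nb] == "MIXED"]
    if (length(nb) == 0) next
    if (run_mean[i] < dropout_ratio * mean(run_mean[nb])) {
      r$values[i] <- "MIXED"
    }
  }
  inverse.rle(r)
}

#' Per-bin inheritance-segment states for a cohort
#'
#' Classifies every bin's strand state, collapses noise by relabelling runs
#' shorter than `min_run` bins to their neighbouring run's state within each
#' cell and chromosome, then distinguishes haplotype dropouts from true
#' inheritance blocks: a single-strand run flanked by mixed segments whose
#' total coverage has fallen below `dropout_ratio` of its mixed neighbours
#' is a deletion signature and stays part of the mixed segment (an SCE
#' conserves total coverage and keeps its own segment). State changes
#' between the remaining runs are the inferred sister-chromatid-exchange
#' boundaries.
#'
#' @param counts Strand-seq count table (`cell`, `chrom`, `start`, `end`,
#'   `watson`, `crick`, `qc_pass`).
#' @param min_reads,minor_frac See [classify_strand_state()].
#' @param min_run Minimum run length in bins (default 5).
#' @param dropout_ratio Coverage ratio below which a single-strand run
#'   flanked by mixed segments is treated as a haplotype dropout
#'   (default 0.75).
#' @return `counts` with added columns `state` (raw per-bin state) and
#'   `segment_state` (smoothed, dropout-aware).
#' @export
add_segment_states <- function(counts, min_reads = 10, minor_frac = 0.1,
                               min_run = 5, dropout_ratio = 0.75) {
  counts <- as_tibble(counts)
  counts$state <- classify_strand_state(counts$watson, counts$crick,
                                        min_reads, minor_frac)
  counts |>
    dplyr::group_by(.data$cell, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(segment_state = reclassify_dropouts(
      smooth_states(.data$state, min_run),
      .data$watson + .data$crick, dropout_ratio)) |>
    dplyr::ungroup()
}

cn_from_pooled <- function(watson, crick, min_reads, minor_frac) {
  total <- watson + crick
  out <- rep(NA_real_, length(total))
  has <- total >= min_reads
  minor <- pmin(watson, crick) / pmax(total, 1)
  out[has] <- 1 + (minor[has] >= minor_frac)
  out
}

#' Gene-level copy number for every cell
#'
#' For each cell, pools Watson and Crick counts over the QC-passing bins that
#' overlap the gene and lie in mixed (Watson/Crick) inheritance segments --
#' the only configuration where strand-specific coverage acts as an internal
#' reference. Copy number 2 if both pooled strands carry significant signal,
#' 1 if exactly one does, `NA` if the cell has no eligible bins (or too few
#' pooled reads).
#'
#' @param counts Strand-seq count table.
#' @param genes Interval tibble with a `name` column.
#' @param min_reads,minor_frac,min_run See [add_segment_states()].
#' @return Tibble with columns `cell`, `gene`, `cn` (1, 2 or `NA`).
#' @export
gene_cn_profile <- function(counts, genes, min_reads = 10, minor_frac = 0.1,
                            min_run = 5) {
  genes <- validate_intervals(genes)
  if (!"name" %in% names(genes)) abort("genes must have a name column")
  binned <- add_segment_states(counts, min_reads, minor_frac, min_run)
  eligible <- binned[binned$qc_pass & binned$segment_state == "MIXED", ]
  cells <- unique(counts$cell)
  grid <- tidyr::expand_grid(cell = cells, gene = genes$name)
  if (nrow(eligible) == 0) {
    grid$cn <- NA_real_
    return(grid)
  }
  hits <- overlap_query(genes, eligible)
  pooled <- tibble(gene = genes$name[hits$a_index],
                   cell = eligible$cell[hits$b_index],
                   watson = eligible$watson[hits$b_index],
                   crick = eligible$crick[hits$b_index]) |>
    dplyr::group_by(.data$cell, .data$gene) |>
    dplyr::summarise(watson = sum(.data$watson), crick = sum(.data$crick),
                     .groups = "drop")
  pooled$cn <- cn_from_pooled(pooled$watson, pooled$crick, min_reads,
                              minor_frac)
  dplyr::left_join(grid, pooled[c("cell", "gene", "cn")],
                   by = c("cell", "gene"))
}

#' Gene-level copy number for a single cell
#'
#' @param cell_bins One cell's rows of the Strand-seq count table.
#' @param gene One-row interval tibble (with or without `name`).
#' @inheritParams gene_cn_profile
#' @return Copy number 1, 2 or `NA`.
#' @export
call_gene_cn <- function(cell_bins, gene, min_reads = 10, minor_frac = 0.1,
                         min_run = 5) {
  gene <- as_tibble(gene)
  gene$name <- "gene"
  if (!"cell" %in% names(cell_bins)) cell_bins$cell <- "cell"
  gene_cn_profile(cell_bins, gene, min_reads, minor_frac, min_run)$cn[1]
}

#' Genome-wide mean copy number of each cell
#'
#' Applies the per-bin presence test (same `min_reads`/`minor_frac` rule as
#' gene calling) to every QC-passing bin in a mixed inheritance segment and
#' averages the resulting 1/2 calls. Cells whose mean falls below
#' `low_cn_threshold` are flagged as carrying substantial genome-wide loss.
#'
#' @param counts Strand-seq count table.
#' @param min_reads,minor_frac,min_run See [add_segment_states()].
#' @param low_cn_threshold Mean-CN flag threshold (default 1.92).
#' @return Tibble with `cell`, `mean_cn`, `n_bins`, `low_cn`.
#' @export
genome_cn_profile <- function(counts, min_reads = 10, minor_frac = 0.1,
                              min_run = 5, low_cn_threshold = 1.92) {
  binned <- add_segment_states(counts, min_reads, minor_frac, min_run)
  eligible <- binned[binned$qc_pass & binned$segment_state == "MIXED", ]
  eligible$cn <- cn_from_pooled(eligible$watson, eligible$crick,
                                min_reads, minor_frac)
  out <- eligible |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(mean_cn = mean(.data$cn, na.rm = TRUE),
                     n_bins = sum(!is.na(.data$cn)), .groups = "drop")
  out$mean_cn[out$n_bins == 0] <- NA_real_
  all_cells <- tibble(cell = unique(counts$cell))
  out <- dplyr::left_join(all_cells, out, by = "cell")
  out$low_cn <- !is.na(out$mean_cn) & out$mean_cn < low_cn_threshold
  out
}

#' Genome-wide mean copy number of a single cell
#'
#' @param cell_bins One cell's rows of the Strand-seq count table.
#' @inheritParams genome_cn_profile
#' @return Mean copy number in `[1, 2]`, or `NA`.
#' @export
genome_mean_cn <- function(cell_bins, min_reads = 10, minor_frac = 0.1,
                           min_run = 5) {
  if (!"cell" %in% names(cell_bins)) cell_bins$cell <- "cell"
  genome_cn_profile(cell_bins, min_reads, minor_frac, min_run)$mean_cn[1]
}

welch_t_stat <- function(a, b) {
  na <- length(a); nb <- length(b)
  se2 <- stats::var(a) / na + stats::var(b) / nb
  diff <- mean(a) - mean(b)
  if (se2 == 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else {
    diff / sqrt(se2)
  }
}

#' Welch-t label-permutation test
#'
#' Observed statistic is the unequal-variance (Welch) two-sample t of group A
#' minus group B. Cell labels are shuffled between the groups (group sizes
#' preserved) `n_perm` times; the one-sided p-value uses the add-one
#' convention `p = (1 + #{t_perm as or more extreme}) / (1 + n_perm)`, so its
#' floor is `1/(n_perm + 1)`. Ties count as extreme. Deterministic given
#' `seed`.
#'
#' @param group_a,group_b Numeric vectors (each length >= 2); `NA`s dropped.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @param alternative `"less"` tests A < B (e.g. treated copy number below
#'   control); `"greater"` mirrors it.
#' @return A `perm_test` object: `statistic`, `p_value`, `n_perm`,
#'   `alternative`, and the permutation null sample.
#' @export
welch_label_permutation <- function(group_a, group_b, n_perm = 10000, seed,
                                    alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs >= 2 non-missing values")
  }
  if (n_perm < 1) abort("n_perm must be >= 1")
  t_obs <- welch_t_stat(group_a, group_b)
  pooled <- c(group_a, group_b)
  na <- length(group_a)
  n <- length(pooled)
  t_null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, na)
      welch_t_stat(pooled[idx], pooled[-idx])
    }, numeric(1))
  })
  extreme <- if (alternative == "less") t_null <= t_obs else t_null >= t_obs
  p <- (1 + sum(extreme)) / (1 + n_perm)
  structure(
    list(statistic = t_obs, p_value = p, n_perm = n_perm,
         alternative = alternative, null = t_null, seed = seed),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Welch-t label permutation: t = %.4g, one-sided (%s) p = %.4g (%d permutations)\n",
              x$statistic, x$alternative, x$p_value, x$n_perm))
  invisible(x)
}

#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_perm = x$n_perm, alternative = x$alternative)
}

#' Per-gene treated-vs-control permutation tests
#'
#' Runs [welch_label_permutation()] on the gene-level copy-number values of
#' two conditions, one test per gene, dropping cells with missing calls.
#'
#' @param cn_a,cn_b Outputs of [gene_cn_profile()] for the two conditions
#'   (condition A is the one tested for loss, i.e. A < B).
#' @param n_perm,seed,alternative Passed to [welch_label_permutation()];
#'   per-gene seeds are derived from `seed`.
#' @return Tibble with `gene`, `n_a`, `n_b`, `statistic`, `p_value`.
#' @export
gene_cn_permutation_tests <- function(cn_a, cn_b, n_perm = 10000, seed,
                                      alternative = "less") {
  genes <- unique(c(cn_a$gene, cn_b$gene))
  purrr::map_dfr(seq_along(genes), function(i) {
    g <- genes[i]
    a <- cn_a$cn[cn_a$gene == g]
    b <- cn_b$cn[cn_b$gene == g]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble(gene = g, n_a = length(a), n_b = length(b),
                    statistic = NA_real_, p_value = NA_real_))
    }
    res <- welch_label_permutation(a, b, n_perm = n_perm,
                                   seed = seed + i,
                                   alternative = alternative)
    tibble(gene = g, n_a = length(a), n_b = length(b),
           statistic = res$statistic, p_value = res$p_value)
  })
}
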
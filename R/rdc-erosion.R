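# Coverage-erosion scoring of RDC intervals against a length-preserving
# shuffled-region null, plus the gene-level hypergeometric enrichment and
# the LAD 2x2 association test.

#' Depth-normalised log2 ratio of two count tracks
#'
#' Each bin becomes `log2((t/d_t + pc) / (c/d_c + pc))` where `d_t`, `d_c`
#' are the genome-wide mean per-bin depths of the treatment and control
#' tracks (computed over non-missing bins) and `pc` is a pseudocount on the
#' depth-normalised scale. Bins missing in either input are missing in the
#' output.
#'
#' @param treat,control `binned_track`s of raw counts on identical bin grids.
#' @param pseudocount Positive pseudocount per depth-normalised bin (default 0.5).
#' @return A `binned_track` with `value_kind = "log2_ratio"`.
#' @export
compute_log2_ratio <- function(treat, control, pseudocount = 0.5) {
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  if (nrow(treat) != nrow(control) ||
      !identical(treat$chrom, control$chrom) ||
      !identical(treat$start, control$start) ||
      !isTRUE(all.equal(bin_size(treat), bin_size(control)))) {
    abort("treat and control tracks must share an identical bin grid")
  }
  d_t <- mean(treat$value, na.rm = TRUE)
  d_c <- mean(control$value, na.rm = TRUE)
  if (!is.finite(d_t) || d_t <= 0 || !is.finite(d_c) || d_c <= 0) {
    abort("tracks must contain positive counts")
  }
  out <- treat
  out$value <- log2((treat$value / d_t + pseudocount) /
                      (control$value / d_c + pseudocount))
  new_binned_track(out, bin_size(treat), "log2_ratio")
}

#' Length-preserving random repositioning of regions
#'
#' Generates `n_sets` shuffled copies of `regions`. Each shuffled interval
#' keeps its original length; its chromosome is drawn with probability
#' proportional to chromosome length and its start uniformly in
#' `[0, L - len]`. Placements overlapping `exclude` are rejection-resampled.
#' Deterministic given `seed`.
#'
#' @param regions Interval tibble (optionally with `name`).
#' @param chrom_sizes Tibble with `chrom`, `length`.
#' @param n_sets Number of shuffled sets (default 10).
#' @param exclude Optional interval tibble no shuffled region may touch
#'   (e.g. the input regions themselves, or a blacklist).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget per interval before erroring.
#' @return A `shuffle_null` object whose `$sets` tibble has columns `set`,
#'   `chrom`, `start`, `end`, `source_index`.
#' @export
shuffle_regions <- function(regions, chrom_sizes, n_sets = 10, exclude = NULL,
                            seed, max_tries = 1000) {
  regions <- validate_intervals(regions)
  if (n_sets < 1) abort("n_sets must be >= 1")
  lens <- regions$end - regions$start
  if (any(lens >= max(chrom_sizes$length))) {
    abort("every region must be shorter than the longest chromosome")
  }
  excl_gr <- if (!is.null(exclude) && nrow(exclude) > 0) {
    as_granges(validate_intervals(exclude))
  } else NULL
  n <- nrow(regions)
  sets <- withr::with_seed(seed, {
    purrr::map(seq_len(n_sets), function(s) {
      chrom <- character(n)
      start <- numeric(n)
      pending <- seq_len(n)
      for (try in seq_len(max_tries)) {
        m <- length(pending)
        ch <- sample(chrom_sizes$chrom, m, replace = TRUE,
                     prob = chrom_sizes$length / sum(chrom_sizes$length))
        L <- chrom_length(chrom_sizes, ch)
        fits <- L > lens[pending]
        st <- floor(runif(m, 0, pmax(L - lens[pending] + 1, 1)))
        ok <- fits
        if (!is.null(excl_gr) && any(ok)) {
          cand <- GenomicRanges::GRanges(
            ch[ok], IRanges::IRanges(st[ok] + 1, st[ok] + lens[pending[ok]]))
          clash <- suppressWarnings(
            GenomicRanges::countOverlaps(cand, excl_gr)) > 0
          ok[ok] <- !clash
        }
        chrom[pending[ok]] <- ch[ok]
        start[pending[ok]] <- st[ok]
        pending <- pending[!ok]
        if (length(pending) == 0) break
      }
      if (length(pending) > 0) {
        abort(paste0("could not place ", length(pending),
                     " shuffled region(s) in set ", s, " after ", max_tries,
                     " tries; exclude set too dense"))
      }
      tibble(set = s, chrom = chrom, start = start, end = start + lens,
             source_index = seq_len(n))
    })
  })
  structure(
    list(sets = dplyr::bind_rows(sets), n_sets = n_sets,
         n_regions = n, seed = seed),
    class = "shuffle_null"
  )
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf("<shuffle_null> %d sets x %d regions (seed %s)\n",
              x$n_sets, x$n_regions, format(x$seed)))
  invisible(x)
}

#' @method tidy shuffle_null
#' @export
tidy.shuffle_null <- function(x, ...) x$sets

#' Rank-ordered erosion table of regions against a shuffled null
#'
#' Scores each region by its mean log2 ratio ([mean_over_regions()]),
#' summarises the null by the pooled per-region means of all shuffled sets
#' (single `mu0`, `sigma0`), and reports each region's deviation in null-SD
#' units. Regions at or below -3 SD are flagged as eroded. Rows are sorted
#' by decreasing mean (rank 1 = least eroded).
#'
#' @param ratio_track `binned_track` of log2 ratios.
#' @param rdcs Interval tibble of regions of interest (optionally with `name`).
#' @param null A `shuffle_null` built from the same regions.
#' @param flag_sd Flagging threshold in null-SD units (default -3).
#' @return An `erosion_table` tibble with columns `name`, `chrom`, `start`,
#'   `end`, `mean_log2`, `rank`, `sd_deviation`, `flag_3sd`; the null mean,
#'   SD and size are attached as attributes and reported by [glance()].
#' @export
erosion_table <- function(ratio_track, rdcs, null, flag_sd = -3) {
  rdcs <- validate_intervals(rdcs)
  stopifnot(inherits(null, "shuffle_null"))
  null_means <- mean_over_regions(ratio_track, null$sets)
  null_means <- null_means[!is.na(null_means)]
  if (length(null_means) < 2) abort("null has fewer than 2 scored regions")
  mu0 <- mean(null_means)
  sigma0 <- sd(null_means)
  if (sigma0 == 0) abort("degenerate null: sigma0 = 0")
  out <- tibble(
    name = if ("name" %in% names(rdcs)) rdcs$name else
      sprintf("region_%03d", seq_len(nrow(rdcs))),
    chrom = rdcs$chrom, start = rdcs$start, end = rdcs$end,
    mean_log2 = mean_over_regions(ratio_track, rdcs)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_log2))
  out$rank <- seq_len(nrow(out))
  out$sd_deviation <- (out$mean_log2 - mu0) / sigma0
  out$flag_3sd <- !is.na(out$sd_deviation) & out$sd_deviation <= flag_sd
  structure(out, mu0 = mu0, sigma0 = sigma0, n_null = length(null_means),
            flag_sd = flag_sd,
            class = c("erosion_table", class(out)))
}

#' @method glance erosion_table
#' @export
glance.erosion_table <- function(x, ...) {
  tibble(mu0 = attr(x, "mu0"), sigma0 = attr(x, "sigma0"),
         n_regions = nrow(x), n_flagged = sum(x$flag_3sd, na.rm = TRUE),
         n_null_regions = attr(x, "n_null"), flag_sd = attr(x, "flag_sd"))
}

#' Upper-tail hypergeometric enrichment of CNVs in RDC genes
#'
#' Probability that at least `n_cnv_in_rdc` of `n_cnv` CNV-bearing genes fall
#' among the `n_rdc_genes` RDC genes when drawn without replacement from a
#' population of `n_genes` genes: `P(X >= n_cnv_in_rdc)`.
#'
#' @param n_genes Population size (genes in the genome annotation).
#' @param n_rdc_genes Number of RDC genes (successes in the population).
#' @param n_cnv Number of CNV genes drawn.
#' @param n_cnv_in_rdc Number of CNV genes that are RDC genes.
#' @return Upper-tail probability.
#' @export
hypergeom_rdc_enrichment <- function(n_genes, n_rdc_genes, n_cnv,
                                     n_cnv_in_rdc) {
  if (!(n_cnv_in_rdc <= n_cnv && n_cnv <= n_genes && n_rdc_genes <= n_genes &&
        n_cnv_in_rdc >= 0 && n_rdc_genes >= 0)) {
    abort("require 0 <= n_cnv_in_rdc <= n_cnv <= n_genes and 0 <= n_rdc_genes <= n_genes")
  }
  phyper(n_cnv_in_rdc - 1, n_rdc_genes, n_genes - n_rdc_genes, n_cnv,
         lower.tail = FALSE)
}

#' Chi-square association between CNV status and LAD membership
#'
#' Pearson chi-square on a 2x2 contingency table, 1 df, without continuity
#' correction, two-sided p-value.
#'
#' @param table 2x2 matrix of counts, e.g. CNV-bearing vs CNV-free regions
#'   (rows) by in-LAD vs out-of-LAD (columns).
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
lad_association_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("table must be 2x2")
  if (any(table < 0)) abort("counts must be >= 0")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero row or column margin")
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}
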
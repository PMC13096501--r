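# Clustered permutation test for enrichment of single-cell breakpoints in
# region sets (RDCs, and their timing-transition subset). Each breakpoint is
# expanded into a symmetric window; a window scores at most one hit however
# many regions it crosses; the null redraws every breakpoint uniformly on
# its own chromosome, keeping the per-cell, per-chromosome structure fixed.

#' Expand breakpoints into symmetric windows
#'
#' Each breakpoint becomes the interval
#' `[pos - half_width, pos + half_width)`, clipped to its chromosome.
#'
#' @param breakpoints Tibble with `cell`, `chrom`, `pos` (0-based bp).
#' @param chrom_sizes Tibble with `chrom`, `length`.
#' @param half_width Half window width in bp (default 1 Mb, i.e. 2-Mb windows).
#' @return Interval tibble with `cell`, `chrom`, `start`, `end`.
#' @export
expand_breakpoints <- function(breakpoints, chrom_sizes, half_width = 1e6) {
  if (half_width <= 0) abort("half_width must be > 0")
  L <- chrom_length(chrom_sizes, breakpoints$chrom)
  if (anyNA(L)) abort("breakpoint chromosome absent from size table")
  if (any(breakpoints$pos < 0) || any(breakpoints$pos >= L)) {
    abort("breakpoint position outside chromosome bounds")
  }
  tibble(cell = breakpoints$cell, chrom = breakpoints$chrom,
         start = pmax(0, breakpoints$pos - half_width),
         end = pmin(L, breakpoints$pos + half_width))
}

#' Number of windows hitting at least one region
#'
#' Binary overlap logic: a window crossing several regions still counts once.
#'
#' @param windows,regions Interval tibbles with consistent chromosome naming.
#' @return Integer hit count (between 0 and `nrow(windows)`).
#' @export
count_region_hits <- function(windows, regions) {
  if (nrow(windows) == 0 || nrow(regions) == 0) return(0L)
  length(unique(overlap_query(windows, regions)$a_index))
}

# Merged hit zones: a breakpoint at integer position p (window half-width h)
# hits a region [s, e) iff s - h < p < e + h, i.e. p in the closed integer
# interval [s - h + 1, e + h - 1]. Returns, per chromosome, the sorted
# boundary vector of the merged zones, offset by +/-0.5 so findInterval()
# lands integer positions inside a zone on an odd interval index.
hit_zone_boundaries <- function(regions, half_width) {
  zones <- split(
    tibble(a = regions$start - half_width + 1,
           b = regions$end + half_width - 1),
    regions$chrom
  )
  lapply(zones, function(z) {
    z <- z[order(z$a), ]
    a <- z$a; b <- z$b
    keep_a <- numeric(0); keep_b <- numeric(0)
    cur_a <- a[1]; cur_b <- b[1]
    for (i in seq_along(a)[-1]) {
      if (a[i] <= cur_b + 1) {
        cur_b <- max(cur_b, b[i])
      } else {
        keep_a <- c(keep_a, cur_a); keep_b <- c(keep_b, cur_b)
        cur_a <- a[i]; cur_b <- b[i]
      }
    }
    keep_a <- c(keep_a, cur_a); keep_b <- c(keep_b, cur_b)
    as.numeric(rbind(keep_a - 0.5, keep_b + 0.5))
  })
}

hits_at_positions <- function(pos, boundaries) {
  if (is.null(boundaries)) return(rep(FALSE, length(pos)))
  findInterval(pos, boundaries) %% 2 == 1
}

#' Clustered per-cell, per-chromosome breakpoint permutation test
#'
#' Observed statistic: total number of breakpoint windows intersecting at
#' least one region, summed over all cells. Null: each permutation redraws
#' every breakpoint's position uniformly on its own chromosome (cell and
#' chromosome assignments fixed), re-expands the windows and re-counts.
#' One-sided p-value with the add-one convention; the z-score standardises
#' the observed count against the permutation null.
#'
#' @param breakpoints Tibble with `cell`, `chrom`, `pos`.
#' @param regions Interval tibble (e.g. RDCs).
#' @param chrom_sizes Tibble with `chrom`, `length`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param half_width Window half-width in bp (default 1 Mb).
#' @return An `enrichment_result`: `observed`, `null` (length `n_perm`),
#'   `p_value`, `z_score`, `n_perm`, `n_windows`, `seed`.
#' @export
clustered_permutation_test <- function(breakpoints, regions, chrom_sizes,
                                       n_perm = 10000, seed,
                                       half_width = 1e6) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  regions <- validate_intervals(regions)
  windows <- expand_breakpoints(breakpoints, chrom_sizes, half_width)
  bnd <- hit_zone_boundaries(regions, half_width)
  observed <- sum(hits_at_positions_by_chrom(breakpoints$chrom,
                                             breakpoints$pos, bnd))
  null <- withr::with_seed(seed, {
    per_chrom <- split(seq_len(nrow(breakpoints)), breakpoints$chrom)
    hits_per_perm <- numeric(n_perm)
    for (ch in names(per_chrom)) {
      idx <- per_chrom[[ch]]
      L <- chrom_length(chrom_sizes, ch)
      draws <- floor(runif(length(idx) * n_perm, 0, L))
      hit <- hits_at_positions(draws, bnd[[ch]])
      hits_per_perm <- hits_per_perm +
        colSums(matrix(hit, nrow = length(idx), ncol = n_perm))
    }
    hits_per_perm
  })
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  s <- sd(null)
  z <- if (s == 0) {
    warn("null hit counts have zero variance; z-score undefined")
    NA_real_
  } else {
    (observed - mean(null)) / s
  }
  structure(
    list(observed = observed, null = null, p_value = p, z_score = z,
         n_perm = n_perm, n_windows = nrow(windows), seed = seed,
         half_width = half_width),
    class = "enrichment_result"
  )
}

hits_at_positions_by_chrom <- function(chrom, pos, bnd) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    out[sel] <- hits_at_positions(pos[sel], bnd[[ch]])
  }
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Breakpoint-region enrichment: %d/%d windows hit; null %.2f +/- %.2f; one-sided p = %.4g; z = %.2f (%d permutations)\n",
    x$observed, x$n_windows, mean(x$null), sd(x$null), x$p_value,
    x$z_score, x$n_perm))
  invisible(x)
}

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(observed = x$observed, n_windows = x$n_windows,
         null_mean = mean(x$null), null_sd = sd(x$null),
         p_value = x$p_value, z_score = x$z_score, n_perm = x$n_perm)
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(permutation = seq_len(x$n_perm), null_hits = x$null)
}

#' Enrichment of region-associated breakpoints in a region subset
#'
#' Restricts the breakpoints to those whose windows hit any region of the
#' full set (e.g. any RDC), then runs the clustered permutation test of the
#' restricted breakpoints against the subset (e.g. TTR-class RDCs), permuting
#' only the restricted windows.
#'
#' @param breakpoints Tibble with `cell`, `chrom`, `pos`.
#' @param rdc_regions Full region set.
#' @param ttr_rdc_regions Subset of interest (by annotation a subset of
#'   `rdc_regions`).
#' @inheritParams clustered_permutation_test
#' @return An `enrichment_result` for the restricted test.
#' @export
ttr_subset_test <- function(breakpoints, rdc_regions, ttr_rdc_regions,
                            chrom_sizes, n_perm = 10000, seed,
                            half_width = 1e6) {
  bnd <- hit_zone_boundaries(validate_intervals(rdc_regions), half_width)
  in_rdc <- hits_at_positions_by_chrom(breakpoints$chrom, breakpoints$pos, bnd)
  restricted <- breakpoints[in_rdc, ]
  if (nrow(restricted) == 0) abort("no breakpoint window hits the full region set")
  clustered_permutation_test(restricted, ttr_rdc_regions, chrom_sizes,
                             n_perm = n_perm, seed = seed,
                             half_width = half_width)
}
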
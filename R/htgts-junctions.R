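# LAM-HTGTS junction-table (tlx-like) I/O and the junction metrics:
# JPTM density, microhomology, bait length, microhomology spectra, and the
# binwise and paired tests comparing conditions.
#
# Column dialect (tab-separated, header required):
#   library    library identifier (optional; default "lib1")
#   B_Rname    bait chromosome
#   B_Strand   bait strand, "+"/"-" (1/-1 accepted)
#   B_Rstart   reference start of the recovered bait segment (1-based)
#   B_Rend     reference end of the recovered bait segment
#   B_Qend     read-internal end of the bait alignment (1-based inclusive)
#   PrimStartCo reference position of the nested LAM-PCR primer start
#   Rname      prey chromosome
#   Junction   prey junction position (bp)
#   Strand     prey strand
#   Qstart     read-internal start of the prey alignment (1-based inclusive)

tlx_required <- c("B_Rname", "B_Strand", "B_Rstart", "B_Rend", "B_Qend",
                  "PrimStartCo", "Rname", "Junction", "Strand", "Qstart")

normalize_strand <- function(x) {
  x <- as.character(x)
  out <- ifelse(x %in% c("+", "1"), "+", ifelse(x %in% c("-", "-1"), "-", NA))
  if (anyNA(out)) abort("strand must be +/- (or 1/-1)")
  out
}

#' Parse a tlx-like junction table
#'
#' Rows violating the record invariants (`B_Rstart <= B_Rend`, `Qstart >= 1`,
#' `B_Qend >= 1`) are dropped with a warning giving the count. A missing
#' mandatory column is an error. A missing `library` column defaults to
#' `"lib1"`.
#'
#' @param path File path (plain or gzip).
#' @return Tibble of junction records.
#' @export
parse_tlx <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                       show_col_types = FALSE)
  missing_cols <- setdiff(tlx_required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("tlx file lacks mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"library" %in% names(x)) x$library <- "lib1"
  x$B_Strand <- normalize_strand(x$B_Strand)
  x$Strand <- normalize_strand(x$Strand)
  bad <- x$B_Rstart > x$B_Rend | x$Qstart < 1 | x$B_Qend < 1
  if (any(bad)) {
    warn(paste0("dropping ", sum(bad), " junction record(s) violating invariants"))
    x <- x[!bad, ]
  }
  as_tibble(x[c("library", tlx_required)])
}

#' Write a tlx-like junction table
#'
#' @param junctions Junction tibble (as from [parse_tlx()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tlx <- function(junctions, path) {
  readr::write_tsv(junctions, path, progress = FALSE)
  invisible(path)
}

#' Junctions per thousand per megabase (JPTM)
#'
#' DSB density of a region: junction count divided by the library's total
#' non-bait-chromosome junctions, times 1000, divided by the region length
#' in Mb.
#'
#' @param junction_count_in_region Junctions mapping to the region.
#' @param total_nonbait_junctions Library total on non-bait chromosomes (> 0).
#' @param region_length_bp Region length in bp (> 0).
#' @return Density in junctions per thousand per Mb.
#' @export
jptm <- function(junction_count_in_region, total_nonbait_junctions,
                 region_length_bp) {
  if (any(total_nonbait_junctions <= 0)) abort("total_nonbait_junctions must be > 0")
  if (any(region_length_bp <= 0)) abort("region_length_bp must be > 0")
  (junction_count_in_region / total_nonbait_junctions) * 1000 /
    (region_length_bp / 1e6)
}

#' Per-library, per-region JPTM table
#'
#' Counts prey junctions falling in each region, using only junctions on
#' non-bait chromosomes (both for counts and for the library totals).
#'
#' @param junctions Junction tibble.
#' @param regions Interval tibble with a `name` column (e.g. RDCs).
#' @param bait_chrom Bait chromosome to exclude; defaults to each record's
#'   own `B_Rname`.
#' @return Tibble with `library`, `name`, `count`, `total`, `jptm`.
#' @export
rdc_jptm <- function(junctions, regions, bait_chrom = NULL) {
  regions <- validate_intervals(regions)
  if (!"name" %in% names(regions)) {
    regions$name <- sprintf("region_%03d", seq_len(nrow(regions)))
  }
  bait <- bait_chrom %||% junctions$B_Rname
  nonbait <- junctions[junctions$Rname != bait, ]
  totals <- dplyr::count(nonbait, .data$library, name = "total")
  prey <- tibble(chrom = nonbait$Rname, start = nonbait$Junction,
                 end = nonbait$Junction + 1)
  hits <- overlap_query(prey, regions)
  counts <- tibble(library = nonbait$library[hits$a_index],
                   name = regions$name[hits$b_index]) |>
    dplyr::count(.data$library, .data$name, name = "count")
  grid <- tidyr::expand_grid(library = totals$library, name = regions$name)
  out <- grid |>
    dplyr::left_join(counts, by = c("library", "name")) |>
    dplyr::left_join(totals, by = "library") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  len <- (regions$end - regions$start)[match(out$name, regions$name)]
  out$jptm <- jptm(out$count, out$total, len)
  out
}

#' Microhomology length at a junction
#'
#' `MH = -(Qstart - B_Qend - 1)` with 1-based inclusive read-internal
#' coordinates: `MH > 0` is microhomology, `MH = 0` a direct (blunt) join,
#' `MH < 0` inserted nucleotides.
#'
#' @param Qstart Read-internal start of the prey alignment.
#' @param B_Qend Read-internal end of the bait alignment.
#' @return Signed microhomology length in bp (vectorised).
#' @export
microhomology <- function(Qstart, B_Qend) {
  -(Qstart - B_Qend - 1)
}

#' Recovered bait length at a junction
#'
#' Distance from the nested primer start to the junction-proximal bait end:
#' `B_Rend - PrimStartCo + 1` for a plus-orientation bait,
#' `PrimStartCo - B_Rstart + 1` for minus. Non-positive lengths are invalid
#' and returned as `NA` with a warning.
#'
#' @param junctions Junction tibble (needs `B_Strand`, `B_Rstart`, `B_Rend`,
#'   `PrimStartCo`).
#' @return Numeric vector of bait lengths in bp.
#' @export
bait_length <- function(junctions) {
  strand <- normalize_strand(junctions$B_Strand)
  blen <- ifelse(strand == "+",
                 junctions$B_Rend - junctions$PrimStartCo + 1,
                 junctions$PrimStartCo - junctions$B_Rstart + 1)
  bad <- blen <= 0
  if (any(bad)) {
    warn(paste0(sum(bad), " junction(s) with non-positive bait length flagged NA"))
    blen[bad] <- NA_real_
  }
  blen
}

#' Classify junctions relative to the bait
#'
#' `"interchromosomal"` when the prey lies on a different chromosome from the
#' bait; `"intra_near_bait"` when it lies on the bait chromosome within
#' `max_dist` of the bait cut site (intrachromosomal deletions/inversions);
#' `NA` for same-chromosome junctions beyond `max_dist`, which the junction
#' analyses exclude.
#'
#' @param junctions Junction tibble.
#' @param bait_pos Bait cut-site position; defaults to the primer-distal bait
#'   end of each record (`B_Rend` on plus, `B_Rstart` on minus).
#' @param max_dist Distance defining "near bait" (default 1 Mb).
#' @return Character vector.
#' @export
classify_junctions <- function(junctions, bait_pos = NULL, max_dist = 1e6) {
  strand <- normalize_strand(junctions$B_Strand)
  cut <- bait_pos %||% ifelse(strand == "+", junctions$B_Rend,
                              junctions$B_Rstart)
  same <- junctions$Rname == junctions$B_Rname
  near <- same & abs(junctions$Junction - cut) <= max_dist
  dplyr::case_when(!same ~ "interchromosomal",
                   near ~ "intra_near_bait",
                   TRUE ~ NA_character_)
}

#' Per-library microhomology spectrum
#'
#' Relative frequency of microhomology lengths 0-10 bp per library.
#' Junctions outside the 0-10 bp range (insertions, MH > 10) are excluded
#' from the denominator unless `include_insertions` is set, in which case
#' insertions are pooled into the `mh = -1` bin for sensitivity analysis.
#' Libraries with no eligible junction are dropped with a warning.
#'
#' @param junctions Junction tibble.
#' @param mh_range Integer microhomology support (default `0:10`).
#' @param include_insertions Keep `MH < 0` junctions as an extra bin.
#' @return Tibble with `library`, `mh`, `n`, `freq` (frequencies sum to 1
#'   within each library).
#' @export
mh_spectrum <- function(junctions, mh_range = 0:10,
                        include_insertions = FALSE) {
  mh <- microhomology(junctions$Qstart, junctions$B_Qend)
  lib <- junctions$library %||% rep("lib1", length(mh))
  keep <- mh %in% mh_range
  bin <- mh
  if (include_insertions) {
    ins <- mh < 0
    bin[ins] <- -1
    keep <- keep | ins
  }
  empty <- setdiff(unique(lib), unique(lib[keep]))
  if (length(empty) > 0) {
    warn(paste0("excluding ", length(empty),
                " library(ies) with no eligible junction"))
  }
  support <- if (include_insertions) c(-1, mh_range) else mh_range
  tibble(library = lib[keep], mh = bin[keep]) |>
    dplyr::count(.data$library, .data$mh) |>
    tidyr::complete(library = unique(lib[keep]), mh = support,
                    fill = list(n = 0L)) |>
    dplyr::group_by(.data$library) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Mean and SEM of a microhomology spectrum across libraries
#'
#' @param spectrum Output of [mh_spectrum()].
#' @return Tibble with `mh`, `mean_freq`, `sem`, `n_libraries`.
#' @export
mh_spectrum_summary <- function(spectrum) {
  spectrum |>
    dplyr::group_by(.data$mh) |>
    dplyr::summarise(mean_freq = mean(.data$freq),
                     sem = sd(.data$freq) / sqrt(dplyr::n()),
                     n_libraries = dplyr::n(), .groups = "drop")
}

welch_p_two_sided <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  diff <- mean(a) - mean(b)
  if (se2 == 0) return(if (diff == 0) 1 else 0)
  t <- diff / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * pt(-abs(t), df)
}

#' Binwise two-condition comparison with FDR control
#'
#' Per-bin two-sided Welch t-test between the per-library frequencies (or
#' any per-library bin values) of two conditions, with Benjamini-Hochberg
#' adjustment across bins.
#'
#' @param freq_a,freq_b Matrices or data frames, libraries in rows, the same
#'   bins in columns.
#' @param fdr_q FDR threshold for the `significant` flag (default 0.05).
#' @return Tibble with `bin`, `mean_a`, `mean_b`, `p_value`, `q_value`,
#'   `significant`.
#' @export
binwise_group_test <- function(freq_a, freq_b, fdr_q = 0.05) {
  freq_a <- as.matrix(freq_a); freq_b <- as.matrix(freq_b)
  if (nrow(freq_a) < 2 || nrow(freq_b) < 2) {
    abort("need >= 2 libraries per condition")
  }
  if (ncol(freq_a) != ncol(freq_b)) abort("conditions must share the same bins")
  p <- vapply(seq_len(ncol(freq_a)), function(j) {
    welch_p_two_sided(freq_a[, j], freq_b[, j])
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  bins <- colnames(freq_a) %||% as.character(seq_len(ncol(freq_a)))
  tibble(bin = bins, mean_a = colMeans(freq_a), mean_b = colMeans(freq_b),
         p_value = p, q_value = q, significant = q <= fdr_q)
}

#' Paired per-region density test between conditions
#'
#' Paired two-sided t-test on per-region mean densities (e.g. JPTM per RDC)
#' measured under two conditions on the same region set. All-zero differences
#' return p = 1 with a warning.
#'
#' @param density_a,density_b Numeric vectors, same region order, length >= 2.
#' @return Tibble with `estimate` (mean difference A - B), `statistic`,
#'   `p_value`, `n`.
#' @export
paired_rdc_density_test <- function(density_a, density_b) {
  if (length(density_a) != length(density_b)) {
    abort("conditions must cover the same regions")
  }
  if (length(density_a) < 2) abort("need >= 2 regions")
  d <- density_a - density_b
  if (all(d == 0)) {
    warn("all paired differences are zero; p = 1 by convention")
    return(tibble(estimate = 0, statistic = 0, p_value = 1,
                  n = length(d)))
  }
  tt <- t.test(density_a, density_b, paired = TRUE)
  tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
         p_value = tt$p.value, n = length(d))
}
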
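# Interval and binned-track data model. All coordinates are 0-based,
# half-open [start, end), the BED convention; conversion from 1-based
# sources happens at the reader boundary.

standard_chrom <- function(chrom) {
  !grepl("_", chrom) & !grepl("^chrUn", chrom)
}

#' Validate an interval table
#'
#' Checks that a data frame has `chrom`, `start`, `end` columns with
#' 0-based half-open coordinates satisfying `0 <= start < end`, and (when a
#' chromosome-size table is supplied) that every interval lies within its
#' chromosome.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`.
#' @param chrom_sizes Optional tibble with columns `chrom`, `length`.
#' @return The input as a tibble, invisibly usable downstream.
#' @export
validate_intervals <- function(intervals, chrom_sizes = NULL) {
  intervals <- as_tibble(intervals)
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(intervals))
  if (length(missing_cols) > 0) {
    abort(paste0("interval table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(intervals) > 0) {
    if (any(intervals$start < 0) || any(intervals$start >= intervals$end)) {
      abort("intervals must satisfy 0 <= start < end")
    }
    if (!is.null(chrom_sizes)) {
      len <- chrom_length(chrom_sizes, intervals$chrom)
      if (anyNA(len)) {
        abort(paste0("chromosome(s) absent from size table: ",
                     paste(unique(intervals$chrom[is.na(len)]), collapse = ", ")))
      }
      if (any(intervals$end > len)) {
        abort("interval(s) extend beyond chromosome end")
      }
    }
  }
  intervals
}

chrom_length <- function(chrom_sizes, chrom) {
  chrom_sizes$length[match(chrom, chrom_sizes$chrom)]
}

#' Read a chromosome-size table
#'
#' Two tab-separated columns: chromosome name and length in bp. Accepts
#' gzip-compressed files.
#'
#' @param path File path.
#' @return Tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", progress = FALSE)
  if (any(x$length <= 0)) abort("chromosome lengths must be > 0")
  if (anyDuplicated(x$chrom)) abort("duplicated chromosome names")
  x
}

#' Read a BED file of genomic intervals
#'
#' BED coordinates are taken verbatim as 0-based half-open. The optional
#' 4th column becomes `name`. Non-standard chromosomes (alt/random/chrUn
#' contigs) are dropped with a warning. Accepts gzip-compressed files.
#'
#' @param path File path.
#' @param keep_nonstandard Keep alt/random contigs instead of dropping them.
#' @return Tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name`.
#' @export
read_bed <- function(path, keep_nonstandard = FALSE) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("BED line ", lineno[which(nf < 3)[1]],
                 ": fewer than 3 tab-separated columns"))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad) > 0) {
    abort(paste0("BED line ", lineno[bad[1]], ": non-integer coordinates"))
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(paste0("BED line ", lineno[bad[1]],
                 ": requires 0 <= start < end"))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (any(nf >= 4)) {
    out$name <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, "")
  }
  if (!keep_nonstandard) {
    drop <- !standard_chrom(out$chrom)
    if (any(drop)) {
      warn(paste0("dropping ", sum(drop), " interval(s) on non-standard chromosomes"))
      out <- out[!drop, ]
    }
  }
  out
}

#' Write intervals to a BED file
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`, optional `name`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- validate_intervals(intervals)
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(intervals)) cols <- c(cols, "name")
  out <- intervals[cols]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Construct an empty binned track
#'
#' A binned track is a tibble with one row per fixed-width genome bin
#' (`chrom`, `start`, `end`, `value`). Uncovered bins carry `NA`, never zero,
#' so absence of data cannot masquerade as zero coverage. The bin width and
#' the declared value kind travel as attributes.
#'
#' @param chrom_sizes Tibble with `chrom`, `length`.
#' @param bin_size Bin width in bp.
#' @param value_kind One of `"raw_count"`, `"depth_normalized"`, `"log2_ratio"`.
#' @return A `binned_track` tibble with `value = NA` everywhere.
#' @export
binned_track <- function(chrom_sizes, bin_size,
                         value_kind = c("raw_count", "depth_normalized",
                                        "log2_ratio")) {
  value_kind <- match.arg(value_kind)
  stopifnot(bin_size > 0)
  grids <- purrr::map2(chrom_sizes$chrom, chrom_sizes$length, function(ch, L) {
    n <- ceiling(L / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    tibble(chrom = ch, start = start, end = pmin(start + bin_size, L),
           value = NA_real_)
  })
  out <- dplyr::bind_rows(grids)
  new_binned_track(out, bin_size, value_kind)
}

new_binned_track <- function(df, bin_size, value_kind) {
  structure(as_tibble(df),
            bin_size = bin_size, value_kind = value_kind,
            class = c("binned_track", class(as_tibble(df))))
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> bin_size=%s value_kind=%s\n",
              format(attr(x, "bin_size"), big.mark = ","),
              attr(x, "value_kind")))
  NextMethod()
}

#' Bin width of a binned track
#' @param track A `binned_track`.
#' @return Bin width in bp.
#' @export
bin_size <- function(track) attr(track, "bin_size")

#' Declared value kind of a binned track
#' @param track A `binned_track`.
#' @return One of `"raw_count"`, `"depth_normalized"`, `"log2_ratio"`.
#' @export
value_kind <- function(track) attr(track, "value_kind")

#' Read a bedGraph file onto a fixed bin grid
#'
#' Each record's value is assigned to every bin its span intersects. Records
#' must be non-overlapping at bin resolution: two records writing to the same
#' bin is an error, as is a record extending past its chromosome end. Bins
#' with no record stay `NA`.
#'
#' @param path File path (plain or gzip).
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Tibble with `chrom`, `length`.
#' @param value_kind Declared kind of the values (never inferred).
#' @return A `binned_track`.
#' @export
read_bedgraph <- function(path, bin_size, chrom_sizes,
                          value_kind = c("log2_ratio", "raw_count",
                                         "depth_normalized")) {
  value_kind <- match.arg(value_kind)
  rec <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                         col_types = "cddd", comment = "#", progress = FALSE)
  rec <- rec[!grepl("^(track|browser)", rec$chrom), ]
  drop <- !standard_chrom(rec$chrom)
  if (any(drop)) {
    warn(paste0("dropping ", sum(drop), " bedGraph record(s) on non-standard chromosomes"))
    rec <- rec[!drop, ]
  }
  track <- binned_track(chrom_sizes, bin_size, value_kind)
  if (nrow(rec) == 0) return(track)
  validate_intervals(rec, chrom_sizes)
  key <- paste0(track$chrom, ":", track$start)
  vals <- track$value
  for (ch in unique(rec$chrom)) {
    r <- rec[rec$chrom == ch, ]
    first_bin <- floor(r$start / bin_size)
    last_bin <- ceiling(r$end / bin_size) - 1
    bins <- unlist(purrr::map2(first_bin, last_bin, seq))
    vv <- rep(r$value, last_bin - first_bin + 1)
    if (anyDuplicated(bins)) {
      abort(paste0("overlapping bedGraph records on ", ch,
                   " (two records write to the same bin)"))
    }
    idx <- match(paste0(ch, ":", bins * bin_size), key)
    vals[idx] <- vv
  }
  track$value <- vals
  new_binned_track(track, bin_size, value_kind)
}

#' Write a binned track as bedGraph
#'
#' One record per non-missing bin; `NA` bins are omitted so a round trip
#' through [read_bedgraph()] is the identity on the non-missing values.
#'
#' @param track A `binned_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  out <- track[!is.na(track$value), c("chrom", "start", "end", "value")]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

as_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1, end = intervals$end)
  )
}

#' All pairs of overlapping intervals between two sets
#'
#' Half-open semantics: `[0,10)` and `[10,20)` do not overlap. Output is
#' sorted by the first-set index, then the second-set index.
#'
#' @param intervals_a,intervals_b Interval tibbles sharing chromosome naming.
#' @return Tibble with columns `a_index`, `b_index` (1-based row indices).
#' @export
overlap_query <- function(intervals_a, intervals_b) {
  intervals_a <- validate_intervals(intervals_a)
  intervals_b <- validate_intervals(intervals_b)
  if (nrow(intervals_a) == 0 || nrow(intervals_b) == 0) {
    return(tibble(a_index = integer(), b_index = integer()))
  }
  # disjoint seqlevels between the two sets are legitimate (no overlap)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(intervals_a),
                                as_granges(intervals_b)))
  out <- tibble(a_index = S4Vectors::queryHits(hits),
                b_index = S4Vectors::subjectHits(hits))
  dplyr::arrange(out, .data$a_index, .data$b_index)
}

#' Mean track value over each of several regions
#'
#' Unweighted arithmetic mean of all bins whose span intersects the region
#' (a partially overlapped bin counts fully), skipping `NA` bins. A region
#' covered only by `NA` bins gets `NA`.
#'
#' @param track A `binned_track`.
#' @param regions Interval tibble.
#' @return Numeric vector, one mean per region row.
#' @export
mean_over_regions <- function(track, regions) {
  regions <- validate_intervals(regions)
  if (nrow(regions) == 0) return(numeric(0))
  absent <- setdiff(unique(regions$chrom), unique(track$chrom))
  if (length(absent) > 0) {
    abort(paste0("region chromosome(s) absent from track: ",
                 paste(absent, collapse = ", ")))
  }
  hits <- overlap_query(regions, track)
  vals <- track$value[hits$b_index]
  ok <- !is.na(vals)
  means <- tapply(vals[ok], hits$a_index[ok], mean)
  out <- rep(NA_real_, nrow(regions))
  out[as.integer(names(means))] <- as.numeric(means)
  out
}

#' Mean track value over a single region
#'
#' @param track A `binned_track`.
#' @param region One-row interval tibble (or list with `chrom`, `start`, `end`).
#' @return A single mean, or `NA` if no non-missing bin overlaps.
#' @export
mean_over_region <- function(track, region) {
  region <- as_tibble(region[c("chrom", "start", "end")])
  mean_over_regions(track, region)[1]
}
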
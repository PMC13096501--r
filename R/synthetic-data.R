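# Synthetic-data generators. They produce every input the analysis stages
# consume -- binned coverage pairs, Strand-seq bin counts, breakpoint sets
# and tlx-like junction tables -- together with machine-readable ground
# truth, emulating the statistical structure the analyses assume. All
# generators are bit-reproducible under a fixed seed.

#' Simulated genome configuration
#'
#' A reduced-scale diploid genome: a few equally sized chromosomes carrying
#' non-overlapping RDC intervals (each labelled with a replication-timing
#' class), gene bodies coinciding with the RDCs (RDCs live inside long
#' genes), and a set of lamina-associated domains.
#'
#' @param n_chrom Number of chromosomes (default 5).
#' @param chrom_length Length of each chromosome in bp (default 60 Mb).
#' @param n_rdc Number of RDC intervals (default 40).
#' @param rdc_length Two-element range of RDC lengths in bp
#'   (default 200-550 kb, about 5% of the default genome in total).
#' @param ttr_prob Probability an RDC is labelled `"TTR"` rather than
#'   `"CTR"` (default 0.6, the timing-transition share among classified RDCs).
#' @param n_lads,lad_length Number and length range of LAD intervals.
#' @param seed Integer seed.
#' @return A `sim_genome` list: `chrom_sizes`, `rdcs` (with `name`,
#'   `timing_class`), `genes`, `lads`, `seed`.
#' @export
sim_genome <- function(n_chrom = 5, chrom_length = 60e6, n_rdc = 40,
                       rdc_length = c(2e5, 5.5e5), ttr_prob = 0.6,
                       n_lads = 30, lad_length = c(5e5, 2e6), seed = 1) {
  chrom_sizes <- tibble(chrom = paste0("chr", seq_len(n_chrom)),
                        length = rep(chrom_length, n_chrom))
  withr::with_seed(seed, {
    place <- function(n, len_range, avoid = NULL) {
      out <- tibble(chrom = character(0), start = numeric(0), end = numeric(0))
      for (i in seq_len(n)) {
        len <- floor(runif(1, len_range[1], len_range[2] + 1))
        repeat {
          ch <- sample(chrom_sizes$chrom, 1,
                       prob = chrom_sizes$length / sum(chrom_sizes$length))
          st <- floor(runif(1, 0, chrom_length(chrom_sizes, ch) - len + 1))
          cand <- tibble(chrom = ch, start = st, end = st + len)
          if (is.null(avoid) || nrow(avoid) == 0 ||
              nrow(overlap_query(cand, avoid)) == 0) break
        }
        out <- dplyr::bind_rows(out, cand)
        if (!is.null(avoid)) avoid <- dplyr::bind_rows(avoid, cand)
      }
      out
    }
    rdcs <- place(n_rdc, rdc_length, avoid = tibble(chrom = character(0),
                                                    start = numeric(0),
                                                    end = numeric(0)))
    rdcs <- dplyr::arrange(rdcs, .data$chrom, .data$start)
    rdcs$name <- sprintf("rdc_%02d", seq_len(n_rdc))
    rdcs$timing_class <- ifelse(runif(n_rdc) < ttr_prob, "TTR", "CTR")
    genes <- tibble(chrom = rdcs$chrom, start = rdcs$start, end = rdcs$end,
                    name = sprintf("gene_%02d", seq_len(n_rdc)))
    lads <- place(n_lads, lad_length)
    structure(list(chrom_sizes = chrom_sizes, rdcs = rdcs, genes = genes,
                   lads = lads, seed = seed),
              class = "sim_genome")
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  terr <- sum(x$rdcs$end - x$rdcs$start) / sum(x$chrom_sizes$length)
  cat(sprintf("<sim_genome> %d chrom x %s bp; %d RDCs (%.1f%% of genome); %d LADs\n",
              nrow(x$chrom_sizes), format(x$chrom_sizes$length[1], big.mark = ","),
              nrow(x$rdcs), 100 * terr, nrow(x$lads)))
  invisible(x)
}

#' Simulate a treated/control binned coverage pair
#'
#' Control bins draw `Poisson(mean_depth)` reads; treated bins draw
#' `Poisson(mean_depth * (1 - f * o / 2))` inside a planted heterozygous
#' deletion of clone fraction `f` (with `o` the bin's overlap fraction) and
#' `Poisson(mean_depth)` elsewhere. A clonal heterozygous deletion (`f = 1`)
#' therefore yields an expected log2 ratio of -1 at the locus; `f = 0.8`
#' yields `log2(0.6)`.
#'
#' @param genome A `sim_genome`.
#' @param deletions Tibble with `chrom`, `start`, `end`, `clone_fraction`
#'   (disjoint intervals; `NULL` for a null genome).
#' @param mean_depth Mean reads per bin (default 30).
#' @param bin_size Bin width in bp (default 10 kb).
#' @param seed Integer seed.
#' @return List with `treat`, `control` (raw-count `binned_track`s) and
#'   `truth` (the deletion table).
#' @export
gen_coverage_pair <- function(genome, deletions = NULL, mean_depth = 30,
                              bin_size = 1e4, seed) {
  stopifnot(mean_depth > 0)
  if (!is.null(deletions)) {
    deletions <- validate_intervals(deletions, genome$chrom_sizes)
    if (any(deletions$clone_fraction <= 0 | deletions$clone_fraction > 1)) {
      abort("clone_fraction must be in (0, 1]")
    }
  }
  control <- binned_track(genome$chrom_sizes, bin_size, "raw_count")
  treat <- control
  factor <- rep(1, nrow(control))
  if (!is.null(deletions) && nrow(deletions) > 0) {
    for (ch in unique(deletions$chrom)) {
      sel <- control$chrom == ch
      dd <- deletions[deletions$chrom == ch, ]
      # depth factor scales with each bin's overlap fraction of the deletion
      for (k in seq_len(nrow(dd))) {
        ov <- pmax(0, pmin(control$end[sel], dd$end[k]) -
                     pmax(control$start[sel], dd$start[k])) /
          (control$end[sel] - control$start[sel])
        factor[sel] <- pmin(factor[sel], 1 - dd$clone_fraction[k] * ov / 2)
      }
    }
  }
  withr::with_seed(seed, {
    control$value <- as.numeric(rpois(nrow(control), mean_depth))
    treat$value <- as.numeric(rpois(nrow(treat), mean_depth * factor))
  })
  list(treat = treat, control = control,
       truth = deletions %||% tibble(chrom = character(0), start = numeric(0),
                                     end = numeric(0),
                                     clone_fraction = numeric(0)))
}

#' Simulate a Strand-seq cohort
#'
#' Each cell inherits, per chromosome, two template strands drawn
#' independently (Watson/Crick each with probability 1/2, so WW/CC/WC occur
#' 1/4 : 1/4 : 1/2). Sister-chromatid exchanges are placed
#' `Poisson(sce_rate)` per cell at uniform genomic positions, each switching
#' one haplotype's template downstream. Every haplotype contributes
#' `Poisson(reads_per_bin / 2)` reads per bin to its template strand.
#' A planted haplotype-specific deletion silences one haplotype's
#' contribution across its span in the selected cells, producing the
#' single-strand dropout signature in WC segments.
#'
#' @param genome A `sim_genome`.
#' @param n_cells Number of cells (default 40).
#' @param reads_per_bin Mean total reads per bin per cell (default 40, a
#'   medium-depth single-cell library at 200-kb bins).
#' @param sce_rate Mean SCE count per cell (default 8, the observed per-cell
#'   rate in aphidicolin/solvent-treated neural progenitors).
#' @param deletion_plan Tibble with `chrom`, `start`, `end`, `gene`,
#'   `n_cells` (how many cells carry each deletion), or `NULL`.
#' @param bin_size Bin width (default 200 kb).
#' @param cell_prefix Prefix for cell ids.
#' @param seed Integer seed.
#' @return List with `counts` (tibble `cell`, `chrom`, `start`, `end`,
#'   `watson`, `crick`, `qc_pass`) and `truth` (list: `inheritance`, `sces`,
#'   `deletions` with the affected cell ids and haplotypes).
#' @export
gen_strandseq_cohort <- function(genome, n_cells = 40, reads_per_bin = 40,
                                 sce_rate = 8, deletion_plan = NULL,
                                 bin_size = 2e5, cell_prefix = "cell",
                                 seed) {
  stopifnot(reads_per_bin > 0)
  grid <- binned_track(genome$chrom_sizes, bin_size, "raw_count")
  grid <- tibble(chrom = grid$chrom, start = grid$start, end = grid$end)
  cells <- sprintf("%s_%03d", cell_prefix, seq_len(n_cells))
  withr::with_seed(seed, {
    del_truth <- NULL
    if (!is.null(deletion_plan) && nrow(deletion_plan) > 0) {
      validate_intervals(deletion_plan, genome$chrom_sizes)
      del_truth <- purrr::map_dfr(seq_len(nrow(deletion_plan)), function(k) {
        aff <- sample(cells, deletion_plan$n_cells[k])
        tibble(cell = aff, gene = deletion_plan$gene[k],
               chrom = deletion_plan$chrom[k],
               start = deletion_plan$start[k], end = deletion_plan$end[k],
               haplotype = sample(1:2, length(aff), replace = TRUE))
      })
    }
    inheritance <- list()
    sces <- list()
    counts <- purrr::map(cells, function(cl) {
      cell_rows <- purrr::map(unique(grid$chrom), function(ch) {
        bins <- grid[grid$chrom == ch, ]
        nb <- nrow(bins)
        # template per haplotype, switched downstream of each SCE
        templ <- matrix(sample(c("W", "C"), 2, replace = TRUE),
                        nrow = nb, ncol = 2, byrow = TRUE)
        L <- chrom_length(genome$chrom_sizes, ch)
        n_sce <- rpois(1, sce_rate * L / sum(genome$chrom_sizes$length))
        if (n_sce > 0) {
          for (s in seq_len(n_sce)) {
            pos <- floor(runif(1, 0, L))
            hap <- sample(1:2, 1)
            after <- bins$start >= pos
            templ[after, hap] <- ifelse(templ[after, hap] == "W", "C", "W")
            sces[[length(sces) + 1]] <<- tibble(cell = cl, chrom = ch,
                                                pos = pos, haplotype = hap)
          }
        }
        st0 <- templ[1, ]
        inheritance[[paste(cl, ch)]] <<- tibble(
          cell = cl, chrom = ch,
          state = if (all(st0 == "W")) "WW" else if (all(st0 == "C")) "CC"
                  else "WC")
        reads <- matrix(rpois(2 * nb, reads_per_bin / 2), ncol = 2)
        if (!is.null(del_truth)) {
          dd <- del_truth[del_truth$cell == cl & del_truth$chrom == ch, ]
          for (k in seq_len(nrow(dd))) {
            hit <- bins$start < dd$end[k] & bins$end > dd$start[k]
            reads[hit, dd$haplotype[k]] <- 0L
          }
        }
        watson <- rowSums(reads * (templ == "W"))
        crick <- rowSums(reads * (templ == "C"))
        tibble(cell = cl, chrom = ch, start = bins$start, end = bins$end,
               watson = watson, crick = crick, qc_pass = TRUE)
      })
      dplyr::bind_rows(cell_rows)
    })
    list(counts = dplyr::bind_rows(counts),
         truth = list(
           inheritance = dplyr::bind_rows(inheritance),
           sces = if (length(sces)) dplyr::bind_rows(sces) else
             tibble(cell = character(0), chrom = character(0),
                    pos = numeric(0), haplotype = integer(0)),
           deletions = del_truth %||%
             tibble(cell = character(0), gene = character(0),
                    chrom = character(0), start = numeric(0),
                    end = numeric(0), haplotype = integer(0))
         ))
  })
}

#' Simulate a clustered breakpoint set
#'
#' Each breakpoint lands inside a uniformly chosen RDC with probability
#' `rdc_hit_prob` (choosing a TTR-class RDC with probability `ttr_pref`),
#' otherwise uniformly outside all RDCs. Breakpoints are dealt round-robin
#' to cells.
#'
#' @param genome A `sim_genome`.
#' @param n_cells Number of cells (default 29).
#' @param n_breakpoints Total breakpoints (default 300).
#' @param rdc_hit_prob Probability a breakpoint is planted inside an RDC.
#' @param ttr_pref Probability an in-RDC breakpoint picks a TTR-class RDC.
#' @param seed Integer seed.
#' @return List with `breakpoints` (tibble `cell`, `chrom`, `pos`) and
#'   `truth` (adds `in_rdc`, `rdc_name`).
#' @export
gen_breakpoint_set <- function(genome, n_cells = 29, n_breakpoints = 300,
                               rdc_hit_prob, ttr_pref = 0.5, seed) {
  if (rdc_hit_prob < 0 || rdc_hit_prob > 1) abort("rdc_hit_prob must be in [0, 1]")
  rdcs <- genome$rdcs
  withr::with_seed(seed, {
    cell <- sprintf("cell_%03d", rep_len(seq_len(n_cells), n_breakpoints))
    in_rdc <- runif(n_breakpoints) < rdc_hit_prob
    chrom <- character(n_breakpoints)
    pos <- numeric(n_breakpoints)
    rdc_name <- rep(NA_character_, n_breakpoints)
    ttr_rdcs <- which(rdcs$timing_class == "TTR")
    ctr_rdcs <- which(rdcs$timing_class == "CTR")
    for (i in seq_len(n_breakpoints)) {
      if (in_rdc[i]) {
        pool <- if (runif(1) < ttr_pref && length(ttr_rdcs) > 0) ttr_rdcs
                else if (length(ctr_rdcs) > 0) ctr_rdcs else ttr_rdcs
        k <- pool[sample.int(length(pool), 1)]
        chrom[i] <- rdcs$chrom[k]
        pos[i] <- floor(runif(1, rdcs$start[k], rdcs$end[k]))
        rdc_name[i] <- rdcs$name[k]
      } else {
        repeat {
          ch <- sample(genome$chrom_sizes$chrom, 1,
                       prob = genome$chrom_sizes$length /
                         sum(genome$chrom_sizes$length))
          p <- floor(runif(1, 0, chrom_length(genome$chrom_sizes, ch)))
          on_rdc <- rdcs$chrom == ch & rdcs$start <= p & p < rdcs$end
          if (!any(on_rdc)) break
        }
        chrom[i] <- ch
        pos[i] <- p
      }
    }
    bp <- tibble(cell = cell, chrom = chrom, pos = pos)
    list(breakpoints = bp,
         truth = dplyr::mutate(bp, in_rdc = in_rdc, rdc_name = rdc_name))
  })
}

#' Simulate tlx-like LAM-HTGTS junction libraries
#'
#' Prey positions are drawn genome-wide with RDC territory upweighted by
#' `rdc_weight`. Each junction's microhomology is drawn from `mh_probs` and
#' encoded read-internally as `Qstart = B_Qend + 1 - MH`, so
#' [microhomology()] recovers the drawn value exactly. Bait lengths are
#' normal around `base_bait_len - bait_shorten_bp`, and the bait reference
#' coordinates follow the bait strand so [bait_length()] recovers them.
#'
#' @param genome A `sim_genome`.
#' @param bait List with `chrom`, `pos`, `strand` (default chr1:30 Mb, plus).
#' @param n_junctions Junctions per library (default 2000).
#' @param n_libraries Number of libraries (default 3).
#' @param rdc_weight Per-bp sampling weight of RDC territory relative to the
#'   rest of the genome (default 5; must be >= 1).
#' @param mh_probs Named probability vector over microhomology lengths, names
#'   are the MH values (default peaked at 2 bp, the theta-mediated end-joining
#'   signature).
#' @param bait_shorten_bp Mean bait-end shortening in bp (models lost end
#'   protection / gap filling; default 0).
#' @param base_bait_len,bait_len_sd Baseline bait-length distribution.
#' @param seed Integer seed.
#' @return List with `junctions` (tlx-like tibble incl. `library`) and
#'   `truth` (per-junction drawn `mh`, `blen`, `in_rdc`).
#' @export
gen_junction_table <- function(genome,
                               bait = list(chrom = "chr1", pos = 30e6,
                                           strand = "+"),
                               n_junctions = 2000, n_libraries = 3,
                               rdc_weight = 5,
                               mh_probs = c(`0` = 0.15, `1` = 0.2, `2` = 0.3,
                                            `3` = 0.15, `4` = 0.1, `5` = 0.05,
                                            `6` = 0.05),
                               bait_shorten_bp = 0, base_bait_len = 60,
                               bait_len_sd = 8, seed) {
  if (rdc_weight < 1) abort("rdc_weight must be >= 1")
  if (abs(sum(mh_probs) - 1) > 1e-8) abort("mh_probs must sum to 1")
  mh_support <- as.integer(names(mh_probs))
  rdcs <- genome$rdcs
  rdc_len <- sum(rdcs$end - rdcs$start)
  genome_len <- sum(genome$chrom_sizes$length)
  p_in_rdc <- rdc_weight * rdc_len /
    (rdc_weight * rdc_len + (genome_len - rdc_len))
  withr::with_seed(seed, {
    libs <- purrr::map(seq_len(n_libraries), function(l) {
      n <- n_junctions
      in_rdc <- runif(n) < p_in_rdc
      chrom <- character(n); pos <- numeric(n)
      for (i in seq_len(n)) {
        if (in_rdc[i]) {
          k <- sample.int(nrow(rdcs), 1,
                          prob = rdcs$end - rdcs$start)
          chrom[i] <- rdcs$chrom[k]
          pos[i] <- floor(runif(1, rdcs$start[k], rdcs$end[k]))
        } else {
          repeat {
            ch <- sample(genome$chrom_sizes$chrom, 1,
                         prob = genome$chrom_sizes$length / genome_len)
            p <- floor(runif(1, 0, chrom_length(genome$chrom_sizes, ch)))
            if (!any(rdcs$chrom == ch & rdcs$start <= p & p < rdcs$end)) break
          }
          chrom[i] <- ch; pos[i] <- p
        }
      }
      mh <- mh_support[sample.int(length(mh_support), n, replace = TRUE,
                                  prob = mh_probs)]
      blen <- pmax(20, round(rnorm(n, base_bait_len - bait_shorten_bp,
                                   bait_len_sd)))
      b_qend <- blen
      qstart <- b_qend + 1 - mh
      if (bait$strand == "+") {
        b_rstart <- rep(bait$pos, n)
        b_rend <- bait$pos + blen - 1
        prim <- rep(bait$pos, n)
      } else {
        b_rend <- rep(bait$pos, n)
        b_rstart <- bait$pos - blen + 1
        prim <- rep(bait$pos, n)
      }
      tibble(library = sprintf("lib_%02d", l),
             B_Rname = bait$chrom, B_Strand = bait$strand,
             B_Rstart = b_rstart, B_Rend = b_rend, B_Qend = b_qend,
             PrimStartCo = prim, Rname = chrom, Junction = pos,
             Strand = sample(c("+", "-"), n, replace = TRUE),
             Qstart = qstart, mh_truth = mh, blen_truth = blen,
             in_rdc_truth = in_rdc)
    })
    all <- dplyr::bind_rows(libs)
    truth <- all[c("library", "mh_truth", "blen_truth", "in_rdc_truth")]
    junctions <- all[c("library", "B_Rname", "B_Strand", "B_Rstart", "B_Rend",
                       "B_Qend", "PrimStartCo", "Rname", "Junction", "Strand",
                       "Qstart")]
    list(junctions = junctions, truth = truth)
  })
}
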
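test_that("log2 ratio is zero for identical tracks and -1 for halved depth-matched counts", {
  tr <- toy_track(rep(100, 10))
  expect_equal(compute_log2_ratio(tr, tr)$value[1:10], rep(0, 10))

  # a local halving against a diploid background at matched genome-wide depth
  control <- toy_track(rep(100, 100))
  treat2 <- toy_track(rep(100, 100)); treat2$value[3] <- 50
  r <- compute_log2_ratio(treat2, control, pseudocount = 1e-9)
  expect_equal(r$value[3], log2(50 / mean(treat2$value[!is.na(treat2$value)]) /
                                  (100 / 100)), tolerance = 1e-6)
  expect_true(is.na(compute_log2_ratio(toy_track(c(NA, 1, 2)),
                                       toy_track(c(1, NA, 2)))$value[2]))
  expect_error(compute_log2_ratio(tr, binned_track(toy_sizes(), 500, "raw_count")),
               "grid")
})

test_that("shuffled sets preserve lengths, avoid exclusions and reproduce under a seed", {
  withr::local_seed(3)
  sizes <- toy_sizes()
  regions <- random_intervals(20, sizes, max_len = 3000)
  null1 <- shuffle_regions(regions, sizes, n_sets = 10, exclude = regions,
                           seed = 99)
  expect_equal(nrow(null1$sets), 200)
  for (s in 1:10) {
    set <- null1$sets[null1$sets$set == s, ]
    expect_equal(sort(set$end - set$start),
                 sort(regions$end - regions$start))
  }
  expect_equal(nrow(overlap_query(null1$sets, regions)), 0)
  expect_true(all(set$end <= sizes$length[match(set$chrom, sizes$chrom)]))
  null2 <- shuffle_regions(regions, sizes, n_sets = 10, exclude = regions,
                           seed = 99)
  expect_identical(null1$sets, null2$sets)
  expect_error(shuffle_regions(tibble::tibble(chrom = "chrA", start = 0,
                                              end = 99999),
                               sizes, n_sets = 1, exclude = regions, seed = 1,
                               max_tries = 5),
               "tries")
})

test_that("pooled null mean converges to the genome-wide track mean", {
  withr::local_seed(5)
  sizes <- toy_sizes()
  tr <- binned_track(sizes, 1000, "log2_ratio")
  tr$value <- rnorm(nrow(tr), mean = 0.3)
  regions <- random_intervals(30, sizes, max_len = 4000)
  null <- shuffle_regions(regions, sizes, n_sets = 20, seed = 17)
  nm <- mean_over_regions(tr, null$sets)
  mc_se <- sd(nm) / sqrt(length(nm))
  expect_lt(abs(mean(nm) - mean(tr$value)), 2.5 * mc_se + 0.01)
})

test_that("erosion table ranks, deviations and flags follow the null summary", {
  withr::local_seed(21)
  sizes <- toy_sizes()
  tr <- binned_track(sizes, 1000, "log2_ratio")
  tr$value <- rnorm(nrow(tr), 0, 0.05)
  rdcs <- tibble::tibble(chrom = "chrA",
                         start = seq(0, 90000, by = 10000),
                         end = seq(5000, 95000, by = 10000),
                         name = sprintf("r%02d", 1:10))
  # erode two regions hard
  for (k in c(2, 7)) {
    sel <- tr$chrom == "chrA" & tr$start >= rdcs$start[k] & tr$end <= rdcs$end[k]
    tr$value[sel] <- tr$value[sel] - 1
  }
  null <- shuffle_regions(rdcs, sizes, n_sets = 10, exclude = rdcs, seed = 8)
  et <- erosion_table(tr, rdcs, null)
  expect_setequal(et$rank, 1:10)
  expect_equal(et$rank, order(order(-et$mean_log2)))
  expect_setequal(et$name[et$flag_3sd], c("r02", "r07"))
  expect_equal(et$sd_deviation,
               (et$mean_log2 - attr(et, "mu0")) / attr(et, "sigma0"))
  g <- glance(et)
  expect_equal(g$n_flagged, 2)

  # deviations invariant under adding a constant to every bin (null re-derived)
  tr2 <- tr; tr2$value <- tr$value + 0.7
  et2 <- erosion_table(tr2, rdcs, null)
  expect_equal(et2$sd_deviation, et$sd_deviation, tolerance = 1e-9)
})

test_that("hypergeometric enrichment matches exhaustive enumeration and edge cases", {
  expect_equal(hypergeom_rdc_enrichment(10, 5, 2, 2), 2 / 9, tolerance = 1e-12)
  expect_equal(hypergeom_rdc_enrichment(100, 0, 10, 0), 1)
  withr::local_seed(9)
  for (rep in 1:25) {
    N <- sample(5:25, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_rdc_enrichment(N, K, n, k),
                 bf_hypergeom_upper(N, K, n, k), tolerance = 1e-10)
  }
  expect_error(hypergeom_rdc_enrichment(10, 5, 12, 2), "<=")
})

test_that("LAD chi-square is the uncorrected Pearson statistic", {
  res <- lad_association_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  withr::local_seed(2)
  for (rep in 1:20) {
    m <- matrix(sample(1:40, 4, replace = TRUE), 2)
    res <- lad_association_test(m)
    oracle <- bf_chisq_2x2(m)
    expect_equal(res$statistic, oracle$statistic, tolerance = 1e-10)
    expect_equal(res$p_value, oracle$p_value, tolerance = 1e-10)
  }
  expect_error(lad_association_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("no flags arise on a null genome and planted deletions are recovered", {
  g <- sim_genome(seed = 301)
  # null: no deletions
  cv0 <- gen_coverage_pair(g, NULL, mean_depth = 30, seed = 302)
  ratio0 <- compute_log2_ratio(cv0$treat, cv0$control)
  null <- shuffle_regions(g$rdcs, g$chrom_sizes, n_sets = 10,
                          exclude = g$rdcs, seed = 303)
  et0 <- erosion_table(ratio0, g$rdcs, null)
  expect_lte(sum(et0$flag_3sd), 1)
  # planted: five RDCs at clone fraction 0.8
  dels <- g$rdcs[c(3, 9, 17, 25, 33), c("chrom", "start", "end")]
  dels$clone_fraction <- 0.8
  cv <- gen_coverage_pair(g, dels, mean_depth = 30, seed = 304)
  ratio <- compute_log2_ratio(cv$treat, cv$control)
  et <- erosion_table(ratio, g$rdcs, null)
  expect_setequal(et$name[et$flag_3sd], g$rdcs$name[c(3, 9, 17, 25, 33)])
})
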
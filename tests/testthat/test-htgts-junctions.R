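toy_junctions <- function(n = 6, lib = "lib1") {
  tibble::tibble(
    library = lib,
    B_Rname = "chr6", B_Strand = "+",
    B_Rstart = 1000, B_Rend = 1000 + 59,
    B_Qend = 60, PrimStartCo = 1000,
    Rname = rep(c("chr8", "chr6"), length.out = n),
    Junction = seq(2e6, by = 1e6, length.out = n),
    Strand = "+", Qstart = 61
  )
}

test_that("tlx parsing round-trips and drops invariant-violating rows", {
  j <- toy_junctions()
  f <- withr::local_tempfile(fileext = ".tlx")
  write_tlx(j, f)
  back <- parse_tlx(f)
  expect_equal(as.data.frame(back), as.data.frame(j))

  j_bad <- j
  j_bad$B_Rstart[2] <- j_bad$B_Rend[2] + 5
  j_bad$Qstart[4] <- 0
  write_tlx(j_bad, f)
  expect_warning(kept <- parse_tlx(f), "dropping 2")
  expect_equal(nrow(kept), 4)

  j_short <- j[, setdiff(names(j), "Qstart")]
  write_tlx(j_short, f)
  expect_error(parse_tlx(f), "Qstart")
})

test_that("microhomology follows the read-internal identity", {
  # direct join: prey starts right after the bait end
  expect_equal(microhomology(Qstart = 61, B_Qend = 60), 0)
  # 2-bp microhomology: prey alignment starts inside the bait
  expect_equal(microhomology(Qstart = 59, B_Qend = 60), 2)
  # insertion of 3 nt between the ends
  expect_equal(microhomology(Qstart = 64, B_Qend = 60), -3)
})

test_that("bait length follows strand orientation and flags invalid records", {
  plus <- tibble::tibble(B_Strand = "+", B_Rstart = 101, B_Rend = 120,
                         PrimStartCo = 101)
  expect_equal(bait_length(plus), 20)
  minus <- tibble::tibble(B_Strand = "-", B_Rstart = 181, B_Rend = 200,
                          PrimStartCo = 200)
  expect_equal(bait_length(minus), 20)
  bad <- tibble::tibble(B_Strand = "+", B_Rstart = 90, B_Rend = 100,
                        PrimStartCo = 120)
  expect_warning(bl <- bait_length(bad), "non-positive")
  expect_true(is.na(bl))
})

test_that("jptm computes density and respects the length-weighted identity", {
  expect_equal(jptm(50, 10000, 2e6), 2.5)
  expect_equal(jptm(0, 10000, 2e6), 0)
  expect_error(jptm(5, 0, 1e6), "total")
  expect_error(jptm(5, 10, 0), "length")
  # union of disjoint regions: JPTM on summed counts and lengths equals the
  # length-weighted mean of per-region JPTMs
  withr::local_seed(121)
  counts <- sample(0:50, 8)
  lens <- sample(2:20, 8) * 1e5
  total <- 5000
  per <- jptm(counts, total, lens)
  expect_equal(jptm(sum(counts), total, sum(lens)),
               sum(per * lens) / sum(lens), tolerance = 1e-12)
})

test_that("junction classification applies the 1-Mb near-bait rule", {
  j <- toy_junctions(4)
  j$Rname <- c("chr8", "chr6", "chr6", "chr6")
  j$Junction <- c(5e6, j$B_Rend[1] + 0.9e6, j$B_Rend[1] + 1.1e6,
                  j$B_Rend[1] + 1e6)
  cls <- classify_junctions(j)
  expect_equal(cls, c("interchromosomal", "intra_near_bait", NA,
                      "intra_near_bait"))
})

test_that("mh spectrum normalises per library and partitions junction classes", {
  j <- toy_junctions(12)
  # encode MH: 6 at 0, 3 at 2, 1 at -2 (insertion), 2 at 12 (out of range)
  j$Qstart <- j$B_Qend + 1 - c(rep(0, 6), rep(2, 3), -2, 12, 12)
  sp <- mh_spectrum(j)
  expect_equal(sum(sp$freq), 1)
  expect_equal(sp$freq[sp$mh == 0], 6 / 9)
  expect_equal(sp$freq[sp$mh == 2], 3 / 9)
  # partition: in-range + insertions + long MH = total
  mh <- microhomology(j$Qstart, j$B_Qend)
  expect_equal(sum(mh %in% 0:10) + sum(mh < 0) + sum(mh > 10), nrow(j))
  # with insertions kept, they form their own bin
  sp_ins <- mh_spectrum(j, include_insertions = TRUE)
  expect_equal(sp_ins$freq[sp_ins$mh == -1], 1 / 10)
  # all-MH-0 library
  j0 <- toy_junctions(5)
  sp0 <- mh_spectrum(j0)
  expect_equal(sp0$freq[sp0$mh == 0], 1)
  expect_true(all(sp0$freq[sp0$mh != 0] == 0))
})

test_that("binwise test flags a constructed shifted bin and BH is monotone", {
  withr::local_seed(131)
  a <- matrix(rnorm(4 * 11, 0.1, 0.01), nrow = 4)
  b <- a + rnorm(length(a), 0, 0.01)
  same <- binwise_group_test(a, b)
  expect_false(any(same$significant))
  # shift one bin by ~10 SDs
  b2 <- b
  b2[, 5] <- b2[, 5] + 0.1
  res <- binwise_group_test(a, b2)
  expect_true(res$significant[5])
  expect_equal(sum(res$significant), 1)
  # BH adjusted values are monotone in the raw p ranks
  ord <- order(res$p_value)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
  expect_error(binwise_group_test(a[1, , drop = FALSE], b), ">= 2")
})

test_that("paired density test matches t.test and handles zero differences", {
  withr::local_seed(141)
  a <- rnorm(40, 2)
  b <- a - 0.5 + rnorm(40, 0, 0.01)
  res <- paired_rdc_density_test(a, b)
  oracle <- t.test(a, b, paired = TRUE)
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-10)
  expect_lt(res$p_value, 1e-3)
  expect_warning(zero <- paired_rdc_density_test(a, a), "zero")
  expect_equal(zero$p_value, 1)
})

test_that("per-RDC JPTM table counts non-bait prey junctions", {
  g <- sim_genome(seed = 151)
  jt <- gen_junction_table(g, n_junctions = 500, n_libraries = 2, seed = 152)
  tab <- rdc_jptm(jt$junctions, g$rdcs)
  expect_equal(nrow(tab), 2 * nrow(g$rdcs))
  # totals equal non-bait junction counts per library
  nb <- jt$junctions[jt$junctions$Rname != jt$junctions$B_Rname, ]
  expect_equal(sort(unique(tab$total)),
               sort(as.integer(table(nb$library))))
  # counts consistent with direct interval overlap per region
  r1 <- g$rdcs[1, ]
  lib1 <- nb[nb$library == "lib_01", ]
  manual <- sum(lib1$Rname == r1$chrom & lib1$Junction >= r1$start &
                  lib1$Junction < r1$end)
  expect_equal(tab$count[tab$library == "lib_01" & tab$name == r1$name],
               manual)
})
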
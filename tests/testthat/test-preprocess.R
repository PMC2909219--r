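test_that("insert estimation removes exactly the stated outliers", {
  st <- estimate_insert_size(c(900, 1000, 1100, 5000), 1000)
  expect_equal(st$mean, 1000)
  expect_equal(st$n_outliers, 1)
  expect_equal(st$n_retained, 3)
  st2 <- estimate_insert_size(rep(1000, 10), 1000)
  expect_equal(st2$mean, 1000)
  expect_equal(st2$sd, 0)
  # boundary: |separation - Ins0| == Ins0 is retained (strict "more than")
  st3 <- estimate_insert_size(c(1000, 2000), 1000)
  expect_equal(st3$n_retained, 2)
  expect_warning(st4 <- estimate_insert_size(c(5000, 6000), 1000), "outliers")
  expect_equal(st4$mean, 1000)
})

test_that("insert estimation recovers a noisy library mean", {
  set.seed(1)
  seps <- stats::rnorm(10000, 1350, 270)
  st <- estimate_insert_size(seps, 1350)
  expect_lt(abs(st$mean - 1350) / 1350, 0.01)
  expect_lt(abs(st$sd - 270) / 270, 0.1)
  # idempotence: re-estimating on the retained pairs barely moves the mean
  st2 <- estimate_insert_size(st$separations, st$mean)
  expect_lt(abs(st2$mean - st$mean), st$sd / sqrt(st$n_retained))
})

test_that("self-consistency thresholds work as counts and fractions", {
  st <- list(mean = 1000, sd = 100)
  expect_true(self_consistency_filter(rep(1000, 10), rep(TRUE, 10), st, 3))
  # 4 orientation-contradicting pairs against an absolute threshold of 3
  expect_false(self_consistency_filter(rep(1000, 10),
                                       c(rep(FALSE, 4), rep(TRUE, 6)),
                                       st, 3))
  # separation at mean + 0.99 sd is not a violation (strict "more than")
  expect_true(self_consistency_filter(c(1099, rep(1000, 3)), rep(TRUE, 4),
                                      st, 0))
  expect_false(self_consistency_filter(c(1101, rep(1000, 3)), rep(TRUE, 4),
                                       st, 0.2))
  # fractional threshold
  expect_true(self_consistency_filter(c(1101, rep(1000, 3)), rep(TRUE, 4),
                                      st, 0.5))
})

test_that("the spanning-count splitter cuts chimeras and only chimeras", {
  # uniform synthetic coverage over a 10 kb contig, Ins = 1 kb
  set.seed(7)
  n <- 1500
  pR <- round(stats::runif(n, 0, 10000 - 1035))
  pF <- pR + round(stats::rnorm(n, 1000, 50))
  keep <- pF <= 10000 - 35
  expect_identical(split_low_span(10000, pR[keep], pF[keep], 35, 3, 1000),
                   integer(0))
  # chimeric concatenation of two 5 kb halves: no pair crosses the junction
  left <- pR < 5000 - 1100
  right <- pR > 5000
  cuts <- split_low_span(10000, c(pR[left], pR[right]),
                         c(pF[left], pF[right]), 35, 3, 1000)
  expect_length(cuts, 1)
  expect_lt(abs(cuts - 5000), 150)
  # short contigs pass through untouched
  expect_identical(split_low_span(1800, pR[keep], pF[keep], 35, 3, 1000),
                   integer(0))
})

test_that("chimera splitting remaps placements onto sub-contigs", {
  gen <- simulate_genome(60000, 0.5, seed = 21)
  fr <- fragment_to_contigs(gen, 6, min_len = 8000, chimera_count = 1L,
                            seed = 21)
  lib <- scaf_library("l", "solid_mate", 1000, sd = 50, read_len = 35)
  sim <- simulate_mate_pairs(60000, fr$truth, lib, 15000, 0, seed = 21)
  ch <- unique(fr$truth$contig[fr$truth$chimeric])
  res <- apply_chimera_splits(fr$contigs, sim$placements, sim$pairs,
                              35, 3, 1000)
  expect_true(ch %in% names(res$cuts))
  expect_false(ch %in% names(res$contigs))
  subs <- grep(paste0("^", gsub("\\+", "\\\\+", ch), "\\."),
               names(res$contigs), value = TRUE)
  expect_gte(length(subs), 2)
  # remapped offsets stay within their sub-contig
  pl <- res$placements[res$placements$contig_id %in% subs, ]
  expect_true(all(pl$offset >= 0 &
                    pl$offset < nchar(res$contigs)[pl$contig_id]))
})

test_that("coverage filtering removes collapsed repeats and hot reads", {
  contigs <- c(a = strrep("A", 1000), b = strrep("C", 1000),
               c = strrep("G", 1000))
  mk <- function(ctg, n, region = c(0, 900)) {
    data.frame(read_id = paste0(ctg, seq_len(n)), contig_id = ctg,
               offset = round(seq(region[1], region[2], length.out = n)),
               tau = 1L, stringsAsFactors = FALSE)
  }
  pl <- rbind(mk("a", 100), mk("b", 100), mk("c", 300))
  cf <- coverage_filter(contigs, pl, 100L, 2.5, 3, 100L)
  expect_identical(cf$removed_contigs, "c")
  # equal coverage: nothing removed
  pl2 <- rbind(mk("a", 100), mk("b", 100), mk("c", 100))
  cf2 <- coverage_filter(contigs, pl2, 100L, 2.5, 3, 100L)
  expect_length(cf2$removed_contigs, 0)
  expect_length(cf2$excluded_reads, 0)
  # a local pile-up excludes only the reads inside the hot window
  hot <- data.frame(read_id = paste0("h", 1:40), contig_id = "a",
                    offset = 450L, tau = 1L, stringsAsFactors = FALSE)
  cf3 <- coverage_filter(contigs, rbind(pl2, hot), 100L, 10, 3, 100L)
  expect_length(cf3$removed_contigs, 0)
  expect_true(all(paste0("h", 1:40) %in% cf3$excluded_reads))
  # only reads starting in the pile-up's hot windows are excluded (the
  # 100-base reads at offset 450 heat both the 401-500 and 501-600 windows)
  all_pl <- rbind(pl2, hot)
  off <- all_pl$offset[match(cf3$excluded_reads, all_pl$read_id)]
  expect_true(all(off >= 400 & off < 600))
})

test_that("a collapsed repeat contig shows ~3x coverage and is removed", {
  # three repeat copies collapse: reads from all copies pile on one contig
  contigs <- c(rep1 = strrep("ACGT", 500), u1 = strrep("AC", 1000),
               u2 = strrep("GT", 1000))
  mk <- function(ctg, n) data.frame(
    read_id = paste0(ctg, seq_len(n)), contig_id = ctg,
    offset = round(seq(0, nchar(contigs[[ctg]]) - 101, length.out = n)),
    tau = 1L, stringsAsFactors = FALSE)
  pl <- rbind(mk("rep1", 600), mk("u1", 200), mk("u2", 200))
  cf <- coverage_filter(contigs, pl, 100L, 2.5, 3, 100L)
  expect_identical(cf$removed_contigs, "rep1")
})
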
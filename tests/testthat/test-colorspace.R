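test_that("the di-base code has the documented structure", {
  expect_identical(encode_colors("AG"), 2L)
  expect_identical(encode_colors("GA"), 2L)
  expect_identical(encode_colors("TC"), 2L)
  expect_identical(encode_colors("CT"), 2L)
  expect_identical(encode_colors("AA"), 0L)
  expect_identical(encode_colors("ATGC"), c(3L, 1L, 3L))
  # symmetric, reflexive class 0, and each color class holds 4 dinucleotides
  pairs <- expand.grid(b1 = BASES, b2 = BASES, stringsAsFactors = FALSE)
  cols <- vapply(seq_len(16), function(k)
    encode_colors(paste0(pairs$b1[k], pairs$b2[k])), 0L)
  expect_true(all(table(cols) == 4))
  for (k in seq_len(16)) {
    expect_identical(cols[k], encode_colors(paste0(pairs$b2[k], pairs$b1[k])))
    # first base + color determines the second base
    expect_identical(next_base(pairs$b1[k], cols[k]), pairs$b2[k])
  }
  expect_error(encode_colors("ANT"), "base")
})

test_that("naive translation inverts encoding and propagates single errors", {
  set.seed(11)
  for (r in 1:10) {
    s <- paste(sample(BASES, 30, TRUE), collapse = "")
    cols <- encode_colors(s)
    expect_identical(naive_translate(substr(s, 1, 1), cols),
                     substr(s, 2, nchar(s)))
  }
  expect_identical(naive_translate("A", integer(0)), "")
  # flipping one color corrupts downstream bases heavily (2/3 per position
  # in expectation for a random wrong color)
  n_diff <- 0; n_pos <- 0
  for (r in 1:200) {
    s <- paste(sample(BASES, 20, TRUE), collapse = "")
    cols <- encode_colors(s)
    k <- sample(length(cols), 1)
    cols[k] <- (cols[k] + sample(1:3, 1)) %% 4L
    out <- naive_translate(substr(s, 1, 1), cols)
    truth <- substr(s, 2, nchar(s))
    tail_idx <- k:nchar(truth)
    n_diff <- n_diff + sum(strsplit(out, "")[[1]][tail_idx] !=
                             strsplit(truth, "")[[1]][tail_idx])
    n_pos <- n_pos + length(tail_idx)
  }
  expect_gt(n_diff / n_pos, 0.5)
})

test_that("robust translation equals the exhaustive argmax", {
  set.seed(21)
  grid_r <- c(1e-4, 1e-3, 1e-2, 1e-1)
  for (n in 2:8) {
    for (rep in 1:3) {
      s <- paste(sample(BASES, n, TRUE), collapse = "")
      cols <- encode_colors(s)
      f <- matrix(0L, 4, n, dimnames = list(BASES, NULL))
      for (i in seq_len(n)) {
        if (stats::runif(1) < 0.6) {
          b <- sample(BASES, 1)
          if (stats::runif(1) < 0.8) b <- substr(s, i, i)  # mostly true votes
          f[b, i] <- f[b, i] + sample(1:3, 1)
        }
      }
      if (stats::runif(1) < 0.4) {
        k <- sample(length(cols), 1)
        cols[k] <- (cols[k] + sample(1:3, 1)) %% 4L
      }
      r_c <- sample(grid_r, 1); r_s <- sample(grid_r, 1)
      cc <- color_contig(cols, f, r_c = r_c, r_s = r_s)
      got <- robust_translate(cc)
      oracle <- brute_translate(cc)
      expect_equal(translation_logp(cc, got$sequence), oracle$best_lp,
                   tolerance = 1e-10)
      expect_equal(got$logp, oracle$best_lp, tolerance = 1e-10)
    }
  }
})

test_that("error-free input is recovered exactly with zero flags", {
  set.seed(5)
  s <- paste(sample(BASES, 40, TRUE), collapse = "")
  f <- matrix(0L, 4, 40, dimnames = list(BASES, NULL))
  for (i in 1:40) f[substr(s, i, i), i] <- 2L
  cc <- color_contig(encode_colors(s), f, 0.01, 0.03)
  got <- robust_translate(cc)
  expect_identical(got$sequence, s)
  expect_false(any(got$color_flags))
  expect_true(all(got$suggestion_flags == 0L))
})

test_that("a single color error with downstream suggestions is corrected on
           the whole (r_c, r_s) grid", {
  s <- "ATGCATTG"
  n <- nchar(s)
  true_cols <- encode_colors(s)
  f <- matrix(0L, 4, n, dimnames = list(BASES, NULL))
  for (i in c(1, 3, 4, 5, 6, 8)) f[substr(s, i, i), i] <- 2L  # >= 2 correct
  cols <- true_cols
  cols[3] <- (cols[3] + 1L) %% 4L   # inject one error
  for (r_c in 10^seq(-4, -1)) for (r_s in 10^seq(-4, -1)) {
    cc <- color_contig(cols, f, r_c = r_c, r_s = r_s)
    got <- robust_translate(cc)
    expect_identical(got$sequence, s)
    expect_identical(which(got$color_flags), 3L)
  }
})

test_that("the returned sequence never scores below the naive translation", {
  set.seed(33)
  for (rep in 1:30) {
    n <- sample(5:20, 1)
    s <- paste(sample(BASES, n, TRUE), collapse = "")
    cols <- encode_colors(s)
    flip <- stats::runif(length(cols)) < 0.1
    cols[flip] <- (cols[flip] + sample(1:3, sum(flip), TRUE)) %% 4L
    f <- matrix(0L, 4, n, dimnames = list(BASES, NULL))
    for (i in seq_len(n)) if (stats::runif(1) < 0.5)
      f[substr(s, i, i), i] <- 1L
    cc <- color_contig(cols, f, 0.01, 0.03)
    naive <- paste0(substr(s, 1, 1),
                    naive_translate(substr(s, 1, 1), cols))
    got <- robust_translate(cc, ref = substr(s, 1, 1))
    expect_gte(got$logp, translation_logp(cc, naive, ref = substr(s, 1, 1)) -
                 1e-10)
  }
})

test_that("degenerate inputs reduce to the naive chain and stay deterministic", {
  cols <- encode_colors("ATGC")
  cc <- color_contig(cols, NULL, 0.01, 0.03)
  got <- robust_translate(cc, ref = "A")
  expect_identical(got$sequence, paste0("A", naive_translate("A", cols)))
  # no suggestions, no reference: deterministic representative of the 4-fold
  # symmetric optimum
  g1 <- robust_translate(cc)
  g2 <- robust_translate(cc)
  expect_identical(g1$sequence, g2$sequence)
  expect_false(any(g1$color_flags))
})

test_that("default error rates follow the platform rate and coverage", {
  er <- default_error_rates(0.03, 1)
  expect_equal(er$r_s, 0.03)
  expect_equal(er$r_c, 0.03)
  expect_lt(default_error_rates(0.03, 30)$r_c, er$r_c)
  # scaling both rates leaves the worked example's translation unchanged
  s <- "ATGC"
  f <- matrix(0L, 4, 4, dimnames = list(BASES, NULL))
  for (i in 1:4) f[substr(s, i, i), i] <- 2L
  cols <- encode_colors(s); cols[2] <- 0L
  t1 <- robust_translate(color_contig(cols, f, 0.01, 0.03))
  t2 <- robust_translate(color_contig(cols, f, 0.02, 0.06))
  expect_identical(t1$sequence, t2$sequence)
})
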
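test_that("consistent constraints give exact positions with zero residuals", {
  sol <- solve_spring(c("i", "j"),
                      data.frame(ci = "i", cj = "j", w = 3, d = 100))
  expect_equal(unname(sol$x), c(0, 100))
  expect_equal(sol$delta, 0)
})

test_that("the hand-solved triangle fixture is reproduced", {
  ed <- data.frame(ci = c("c1", "c1", "c2"), cj = c("c2", "c3", "c3"),
                   w = c(2, 1, 1), d = c(100, 250, 140))
  sol <- solve_spring(c("c1", "c2", "c3"), ed)
  # normal equations 3*x2 - x3 = 60, 2*x3 - x2 = 390
  expect_equal(unname(sol$x), c(0, 102, 246))
  expect_equal(sol$delta, c(2, 4, 4))
})

test_that("force balance holds and the optimum beats any other position", {
  set.seed(9)
  for (r in 1:10) {
    n <- sample(5:200, 1)
    vs <- sprintf("n%03d", 1:n)
    # random connected graph: spanning chain plus extra edges
    ed <- data.frame(ci = vs[-n], cj = vs[-1],
                     w = sample(1:9, n - 1, TRUE),
                     d = stats::rnorm(n - 1, 500, 100))
    extra <- sample(n, min(n, 20), replace = TRUE)
    extra2 <- sample(n, length(extra), replace = TRUE)
    keep <- extra != extra2
    if (any(keep))
      ed <- rbind(ed, data.frame(ci = vs[pmin(extra, extra2)[keep]],
                                 cj = vs[pmax(extra, extra2)[keep]],
                                 w = sample(1:9, sum(keep), TRUE),
                                 d = stats::rnorm(sum(keep), 500, 300)))
    sol <- solve_spring(vs, ed)
    # analytic gradient of the quadratic at the solution is zero
    resid <- (sol$x[ed$cj] - sol$x[ed$ci]) - ed$d
    grad <- stats::setNames(numeric(n), vs)
    for (e in seq_len(nrow(ed))) {
      grad[ed$ci[e]] <- grad[ed$ci[e]] - 2 * ed$w[e] * resid[e]
      grad[ed$cj[e]] <- grad[ed$cj[e]] + 2 * ed$w[e] * resid[e]
    }
    free <- setdiff(vs, sort(vs)[1])
    scale <- max(1, max(abs(ed$w * ed$d)))
    expect_lt(max(abs(grad[free])) / scale, 1e-8)
    # quadratic value at the solution is minimal vs random perturbations
    q <- function(x) sum(ed$w * ((x[ed$cj] - x[ed$ci]) - ed$d)^2)
    for (k in 1:5) {
      pert <- sol$x + stats::rnorm(n, 0, 50)
      expect_lte(q(sol$x), q(pert) + 1e-9)
    }
  }
})

test_that("translation of all relaxed lengths shifts positions rigidly", {
  ed <- data.frame(ci = c("a", "b"), cj = c("b", "c"), w = c(2, 3),
                   d = c(100, 200))
  s1 <- solve_spring(c("a", "b", "c"), ed)
  ed2 <- ed; ed2$d <- ed2$d + 0   # anchor convention: x[a] stays 0
  s2 <- solve_spring(c("a", "b", "c"), ed2)
  expect_equal(s1$x, s2$x)
})

test_that("zero-noise components recover true start offsets exactly", {
  a <- sim_assembly(sd = 0, n_pairs = 8000, seed = 23)
  pt <- pair_table(a$sim$placements, a$sim$pairs)
  cross <- pt[pt$ci != pt$cj, ]
  lens <- nchar(a$frag$contigs)
  cons <- pair_constraints(cross, lens, list(lib1 = a$lib))
  g <- build_graph(cons, lens, W = 5, L = 150, 0.7)
  cfg <- scaf_config(libraries = a$lib)
  ao <- assign_orientations(g, cfg)
  ee <- g$edges[g$edges$kept & !ao$violated, ]
  ee$w <- abs(ee$J)
  ee$d <- spring_lengths(ee, ao$S, g$lens)
  vs <- unique(c(ee$ci, ee$cj))
  sol <- solve_spring(vs, ee)
  tstart <- stats::setNames(a$frag$truth$genome_start, a$frag$truth$contig)
  shift <- tstart[sort(vs)[1]]
  expect_true(all(abs(sol$x[vs] - (tstart[vs] - shift)) < 1e-6))
  expect_true(all(sol$delta < 1e-6))
})

test_that("a planted wrong separation removes the offending contigs", {
  # chain plus skip springs: a pure chain is a tree and satisfies any
  # separations exactly, so frustration needs the redundant skip constraints
  vs <- sprintf("k%02d", 1:8)
  chain <- data.frame(ci = vs[-8], cj = vs[-1], w = 20, d = 1000)
  skips <- data.frame(ci = vs[1:6], cj = vs[3:8], w = 10, d = 2000)
  # contig k04 displaced by 5 kb: its chain springs contradict the skips
  chain$d[3] <- 6000; chain$d[4] <- -4000
  ed <- rbind(chain, skips)
  sol <- solve_spring(vs, ed)
  pr <- prune_stretched(sol, ed, sigma = 200, delta_k = 5)
  expect_true("k04" %in% pr$contigs)
  expect_length(pr$edges, 0)
  # all residuals small: nothing removed and the loop would stop
  ed$d <- c(rep(1000, 7), rep(2000, 6))
  sol2 <- solve_spring(vs, ed)
  pr2 <- prune_stretched(sol2, ed, sigma = 200, delta_k = 5)
  expect_length(pr2$contigs, 0)
})

test_that("with support information spurious springs are cut as edges", {
  vs <- sprintf("k%02d", 1:8)
  ed <- data.frame(ci = vs[-8], cj = vs[-1], w = 50, d = 1000)
  ed <- rbind(ed, data.frame(ci = "k02", cj = "k07", w = 5, d = 300))
  sol <- solve_spring(vs, ed)
  support <- stats::setNames(numeric(8), vs)
  for (e in seq_len(nrow(ed))) {
    support[ed$ci[e]] <- support[ed$ci[e]] + ed$w[e]
    support[ed$cj[e]] <- support[ed$cj[e]] + ed$w[e]
  }
  pr <- prune_stretched(sol, ed, sigma = 50, delta_k = 5, support = support)
  expect_identical(pr$edges, 8L)   # the k02-k07 background spring
  expect_length(pr$contigs, 0)
})

test_that("positions are recovered within tolerance under realistic noise", {
  hits <- 0; tot <- 0
  for (seed in 1:5) {
    a <- sim_assembly(genome_len = 60000, n_contigs = 20, insert = 1000,
                      sd = 200, n_pairs = 12000, seed = 300 + seed)
    res <- run_pipeline(a$frag$contigs, a$sim$placements, a$sim$pairs,
                        scaf_config(libraries = a$lib, seed = seed))
    tstart <- stats::setNames(a$frag$truth$genome_start,
                              a$frag$truth$contig)
    for (l in res$scaffolds) {
      if (nrow(l) < 3) next
      g <- tstart[l$contig]
      flip <- if (stats::cor(l$x, g) < 0) -1 else 1
      fit <- stats::lm(g ~ I(flip * l$x))
      tot <- tot + nrow(l)
      hits <- hits + sum(abs(stats::resid(fit)) < 3 * 200)
    }
  }
  expect_gt(tot, 30)
  expect_gte(hits / tot, 0.95)
})
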
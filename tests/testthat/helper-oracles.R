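# Independent brute-force oracles and shared fixtures. These never call the
# code paths they are used to check.

BASES <- c("A", "C", "G", "T")

# exhaustive argmax translation over all 4^N base sequences
brute_translate <- function(cc, ref = NULL) {
  n <- length(cc$colors) + 1L
  grid <- do.call(expand.grid, c(rep(list(BASES), n),
                                 stringsAsFactors = FALSE))
  cand <- apply(grid, 1, paste, collapse = "")
  lp <- vapply(cand, function(s) translation_logp(cc, s, ref), 0)
  list(best = cand[which.max(lp)], best_lp = max(lp), all = cand, lp = lp)
}

# exhaustive Ising ground-state energy of an igraph with edge attribute J
brute_ising <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  J <- igraph::E(g)$J
  n <- igraph::vcount(g)
  best <- Inf
  for (m in 0:(2^n - 1)) {
    S <- ifelse(bitwAnd(bitwShiftR(m, 0:(n - 1)), 1) == 1, 1L, -1L)
    E0 <- -sum(J * S[el[, 1]] * S[el[, 2]])
    if (E0 < best) best <- E0
  }
  best
}

# exhaustive Potts minimum over q^n labelings
brute_potts <- function(D, O, q) {
  n <- nrow(D)
  W <- O - D
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[ut]
  best <- Inf
  lab <- integer(n)
  total <- q^n
  for (m in 0:(total - 1)) {
    x <- m
    for (i in seq_len(n)) { lab[i] <- x %% q; x <- x %/% q }
    E0 <- sum(w[lab[ut[, 1]] == lab[ut[, 2]]])
    if (E0 < best) best <- E0
  }
  best
}

# random connected igraph with signed integer couplings
random_ising_graph <- function(n, p = 0.4, jmax = 3) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::ecount(g) > 0 && igraph::components(g)$no == 1) break
  }
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  igraph::E(g)$J <- sample(c(-jmax:-1, 1:jmax), igraph::ecount(g),
                           replace = TRUE)
  g
}

# scaf_graph wrapper around an edge table (all edges retained)
edge_graph <- function(edges, lens = NULL) {
  vs <- sort(unique(c(edges$ci, edges$cj)))
  if (is.null(lens)) lens <- stats::setNames(rep(500, length(vs)), vs)
  edges$dbar <- if (is.null(edges$dbar)) 0 else edges$dbar
  edges$n <- abs(edges$J)
  edges$kept <- TRUE
  structure(list(vertices = vs, edges = edges, lens = lens),
            class = "scaf_graph")
}

# standard small simulated assembly (zero noise unless stated)
sim_assembly <- function(genome_len = 50000, n_contigs = 15, insert = 1000,
                         sd = 0, n_pairs = 6000, background = 0, seed = 3,
                         type = "solid_mate", read_len = 35L,
                         chimera_count = 0L) {
  gen <- simulate_genome(genome_len, 0.5, seed = seed)
  fr <- fragment_to_contigs(gen, n_contigs, chimera_count = chimera_count,
                            seed = seed)
  lib <- scaf_library("lib1", type, insert, sd = sd, read_len = read_len)
  sim <- simulate_mate_pairs(genome_len, fr$truth, lib, n_pairs, background,
                             seed = seed)
  list(genome = gen, frag = fr, lib = lib, sim = sim)
}

# the two-scaffold tangle fixture: two 4-contig chains fused by one chimeric
# contig, with one overarching pair on the magenta side (positions solved,
# Ins = 100 so no small-component penalty applies)
tangle_fixture <- function() {
  ids <- c("c1", "c2", "CH", "c4", "c5", "c6", "c8")
  layout <- data.frame(
    contig = ids,
    x = c(0, 1000, 2000, 3000, 0, 1000, 3000),
    S = 1L,
    len = 900,
    stringsAsFactors = FALSE)
  D <- matrix(0L, 7, 7, dimnames = list(ids, ids))
  link <- function(a, b) {
    D[a, b] <<- 1L; D[b, a] <<- 1L
  }
  link("c1", "c2"); link("c2", "CH"); link("CH", "c4")
  link("c5", "c6"); link("c6", "CH"); link("CH", "c8")
  link("c6", "c8")   # overarching pair
  list(layout = layout, D = D, chimera = "CH")
}
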
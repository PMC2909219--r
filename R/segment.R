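# Tangled-scaffold detection and segmentation. A genuine scaffold's contig
# density profile is ~1 everywhere (0 in gaps); wrongly fused scaffolds stack
# contigs on top of each other, producing near-integer plateaus of 2, 3, ...
# The contigs are then labeled by minimizing a q-state Potts energy in which
# mate-pair neighbors attract (same label) and positionally overlapping
# contigs repel (different labels); junctures - chimeric or collapsed-repeat
# contigs fusing the scaffolds - end up at label boundaries, and the best
# subset of suspected junctures to remove is chosen by explicit scoring.

#' Contig density profile of a scaffold layout
#'
#' @param layout data frame with columns `contig`, `x` (start position), `len`
#'   (and usually `S`); coordinates may be negative.
#' @param window window length in bases.
#' @return data frame with `window` (1-based index), `start` (coordinate of
#'   the window's first base) and `density` (mean per-base count of covering
#'   contigs).
#' @export
density_profile <- function(layout, window = 1000L) {
  x0 <- floor(min(layout$x))
  a <- as.integer(round(layout$x - x0))
  b <- a + as.integer(layout$len)
  span <- max(b)
  d <- tabulate(a + 1L, span + 1L) - tabulate(b + 1L, span + 1L)
  cov <- cumsum(d)[seq_len(span)]
  nw <- ceiling(span / window)
  dens <- vapply(seq_len(nw), function(w)
    mean(cov[((w - 1L) * window + 1L):min(w * window, span)]), 0)
  data.frame(window = seq_len(nw),
             start = x0 + (seq_len(nw) - 1L) * window,
             density = dens)
}

#' Estimate the number of Potts labels from a density profile
#'
#' Finds maximal runs of at least `min_run` consecutive windows with density
#' >= `threshold`; each run of peak density p indicates round(p) stacked
#' scaffolds, i.e. round(p) - 1 labels beyond the background one:
#' `q = 1 + sum(round(peak) - 1)`.
#'
#' @param profile value of [density_profile()].
#' @param threshold high-density threshold.
#' @param min_run minimum run length in windows.
#' @return integer q >= 1 (1 means no segmentation needed).
#' @export
estimate_q <- function(profile, threshold = 1.5, min_run = 2L) {
  high <- profile$density >= threshold
  if (!any(high)) return(1L)
  r <- rle(high)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  q <- 1L
  for (k in which(r$values & r$lengths >= min_run)) {
    peak <- max(profile$density[starts[k]:ends[k]])
    q <- q + max(0L, as.integer(round(peak)) - 1L)
  }
  q
}

#' Potts energy of a label assignment
#'
#' `E = sum_{i<j} (O_ij - D_ij) * [sigma_i == sigma_j]`: mate-pair neighbors
#' (D) lower the energy by sharing a label, overlapping contigs (O) raise it.
#'
#' @param labels integer labels.
#' @param D symmetric 0/1 mate-pair adjacency matrix.
#' @param O symmetric non-negative overlap matrix.
#' @return energy value.
#' @export
potts_energy <- function(labels, D, O) {
  same <- outer(labels, labels, "==")
  sum(((O - D) * same)[upper.tri(same)])
}

#' Minimize the Potts energy by simulated annealing
#'
#' Starts from a uniform random label assignment and proposes relabelings of
#' a random contig to a random new label, accepted by the Metropolis rule
#' under an exponential cooling schedule; returns the best labeling seen.
#'
#' @param D,O coupling matrices (see [potts_energy()]).
#' @param q number of labels (>= 2).
#' @param T0 initial temperature (default `2 * max|O - D|`).
#' @param alpha cooling factor per sweep.
#' @param max_sweeps,plateau,T_floor stopping rules.
#' @param seed optional seed.
#' @return list(labels, energy).
#' @export
anneal_potts <- function(D, O, q, T0 = NULL, alpha = 0.995,
                         max_sweeps = 2000L, plateau = 50L, T_floor = 1e-3,
                         seed = NULL) {
  stopifnot(q >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(D)
  W <- O - D
  labels <- sample.int(q, n, replace = TRUE)
  E <- potts_energy(labels, D, O)
  bestL <- labels; bestE <- E
  Tt <- if (is.null(T0)) 2 * max(abs(W), 1e-6) else T0
  stale <- 0L
  T_cold <- max(T_floor, 0.05 * Tt)
  for (sweep in seq_len(max_sweeps)) {
    before <- bestE
    vs <- sample.int(n, n, replace = TRUE)
    newl <- sample.int(q, n, replace = TRUE)
    us <- stats::runif(n)
    for (t in seq_len(n)) {
      v <- vs[t]; nl <- newl[t]
      if (nl == labels[v]) next
      # diagonal of W is zero, so including v in its own-label sum is harmless
      dE <- sum(W[v, ][labels == nl]) - sum(W[v, ][labels == labels[v]])
      if (dE <= 0 || us[t] < exp(-dE / Tt)) {
        labels[v] <- nl
        E <- E + dE
        if (E < bestE) { bestE <- E; bestL <- labels }
      }
    }
    stale <- if (bestE < before) 0L else stale + 1L
    Tt <- Tt * alpha
    # an energy plateau only counts once the system is cold
    if ((stale >= plateau && Tt <= T_cold) || Tt < T_floor) break
  }
  # zero-temperature descent: move each contig to its best label until stable
  labels <- bestL
  repeat {
    improved <- FALSE
    for (v in seq_len(n)) {
      cur <- sum(W[v, ][labels == labels[v]])
      gains <- vapply(seq_len(q), function(l)
        sum(W[v, ][labels == l]) - W[v, v] * (l == labels[v]), 0)
      gains[labels[v]] <- cur
      l_best <- which.min(gains)
      if (gains[l_best] < cur - 1e-12) {
        bestE <- bestE + gains[l_best] - cur
        labels[v] <- l_best
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(labels = labels, energy = bestE)
}

# overlap matrix of a layout: O_ij = overlap length / mean contig length
.overlap_matrix <- function(layout) {
  n <- nrow(layout)
  a <- layout$x; b <- layout$x + layout$len
  ov <- pmax(outer(b, b, pmin) - outer(a, a, pmax), 0)
  diag(ov) <- 0
  ov / mean(layout$len)
}

# per-contig window coverage on the layout's shared window grid: W[i, w] =
# bases of contig i inside window w
.window_cover <- function(layout, window) {
  x0 <- floor(min(layout$x))
  a <- layout$x - x0; b <- a + layout$len
  nw <- ceiling(max(b) / window)
  wlo <- (seq_len(nw) - 1) * window
  whi <- wlo + window
  t(vapply(seq_len(nrow(layout)), function(i)
    pmax(pmin(b[i], whi) - pmax(a[i], wlo), 0), numeric(nw)))
}

# score a removal subset: count of small surviving components plus 5 x count
# of still-overloaded windows; lower is better. `WC` is the window-cover
# matrix of `layout` (rows follow layout order).
.subset_score <- function(remove, layout, D, window, threshold, ins,
                          WC = NULL) {
  keep <- setdiff(layout$contig, remove)
  if (length(keep) == 0) return(list(score = Inf, comps = list()))
  idx <- match(keep, layout$contig)
  sub <- layout[idx, , drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(
    D[match(keep, rownames(D)), match(keep, rownames(D)), drop = FALSE] > 0,
    mode = "undirected", diag = FALSE)
  igraph::V(g)$name <- keep
  mem <- igraph::components(g)$membership
  comps <- split(keep, mem)
  if (is.null(WC)) WC <- .window_cover(layout, window)
  n_small <- 0L; n_dense <- 0L
  for (cp in comps) {
    l <- sub[match(cp, sub$contig), , drop = FALSE]
    span <- max(l$x + l$len) - min(l$x)
    if (span < 2 * ins) n_small <- n_small + 1L
    dens <- colSums(WC[match(cp, layout$contig), , drop = FALSE]) / window
    n_dense <- n_dense + sum(dens >= threshold)
  }
  list(score = n_small + 5 * n_dense, comps = comps)
}

#' Detect and remove junctures from a tangled scaffold
#'
#' Labels the contigs with [anneal_potts()] (q from [estimate_q()]); suspected
#' junctures are the contigs with at least one mate-pair or overlap neighbor
#' carrying a different label. All removal subsets are scored exhaustively
#' when there are at most `subset_cap` candidates; otherwise candidates are
#' restricted to those overlapping the densest run, and failing that a random
#' sample of subsets is scored. The best subset is removed; surviving
#' components whose density profile is still overloaded are segmented
#' recursively. Removed contigs and single-contig components are reported as
#' single contigs.
#'
#' @param layout scaffold layout (contig, x, S, len).
#' @param D mate-pair adjacency matrix (dimnames = contig ids).
#' @param ins insert size (sets the "small component" span 2*Ins).
#' @param window,threshold density profile parameters.
#' @param subset_cap exhaustive-search cap on the candidate count.
#' @param n_random number of random subsets scored in the fallback.
#' @param seed optional seed.
#' @return list: `scaffolds` (layouts with >= 2 contigs, re-anchored at 0),
#'   `singletons` (contig ids in single-contig components), `removed`
#'   (juncture ids removed).
#' @export
resolve_tangles <- function(layout, D, ins, window = 1000L, threshold = 1.5,
                            subset_cap = 12L, n_random = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .resolve_rec(layout, D, ins, window, threshold, subset_cap, n_random)
}

.finish_component <- function(l) {
  l$x <- l$x - min(l$x)
  l[order(l$x), , drop = FALSE]
}

.resolve_rec <- function(layout, D, ins, window, threshold, subset_cap,
                         n_random) {
  out <- list(scaffolds = list(), singletons = character(0),
              removed = character(0))
  prof <- density_profile(layout, window)
  q <- estimate_q(prof, threshold)
  if (q == 1L || nrow(layout) < 3L) {
    if (nrow(layout) >= 2L)
      out$scaffolds <- list(.finish_component(layout))
    else out$singletons <- layout$contig
    return(out)
  }
  O <- .overlap_matrix(layout)
  idx <- match(layout$contig, rownames(D))
  Dm <- D[idx, idx, drop = FALSE]
  pot <- anneal_potts(Dm, O, q)
  nb <- (Dm > 0) | (O > 0)
  cand <- layout$contig[vapply(seq_len(nrow(layout)), function(i)
    any(nb[i, ] & pot$labels != pot$labels[i]), TRUE)]
  if (length(cand) > subset_cap) {
    # restrict to candidates overlapping the densest run of windows
    dw <- which(prof$density >= threshold)
    if (length(dw)) {
      lo <- prof$start[min(dw)]; hi <- prof$start[max(dw)] + window
      inside <- layout$x < hi & (layout$x + layout$len) > lo
      cand2 <- intersect(cand, layout$contig[inside])
      if (length(cand2)) cand <- cand2
    }
  }
  WC <- .window_cover(layout, window)
  pick_best <- function(subsets) {
    scores <- lapply(subsets, .subset_score, layout = layout, D = D,
                     window = window, threshold = threshold, ins = ins,
                     WC = WC)
    sc <- vapply(scores, `[[`, 0, "score")
    sz <- lengths(subsets)
    keyv <- vapply(subsets, function(s) paste(sort(s), collapse = ","), "")
    best <- order(sc, sz, keyv)[1]
    list(subset = subsets[[best]], score = scores[[best]],
         value = sc[best])
  }
  if (length(cand) <= subset_cap) {
    nsub <- bitwShiftL(1L, length(cand))
    best <- pick_best(lapply(seq_len(nsub) - 1L, function(m)
      cand[bitwAnd(bitwShiftR(m, seq_along(cand) - 1L), 1L) == 1L]))
  } else {
    # subsets of size <= 2 first (single junctures are the common case); the
    # random sample of larger subsets is only scored when needed
    small <- c(list(character(0)), lapply(cand, identity))
    if (length(cand) > 1)
      small <- c(small, utils::combn(cand, 2L, simplify = FALSE))
    best <- pick_best(small)
    if (best$value > 0) {
      alt <- pick_best(lapply(seq_len(n_random), function(k)
        cand[stats::runif(length(cand)) < 0.5]))
      if (alt$value < best$value) best <- alt
    }
  }
  out$removed <- best$subset
  for (cp in best$score$comps) {
    l <- layout[match(cp, layout$contig), , drop = FALSE]
    p <- density_profile(l, window)
    if (length(cp) >= 3L && any(p$density >= threshold) &&
        length(cp) < nrow(layout)) {
      sub <- .resolve_rec(l, D, ins, window, threshold, subset_cap, n_random)
      out$scaffolds <- c(out$scaffolds, sub$scaffolds)
      out$singletons <- c(out$singletons, sub$singletons)
      out$removed <- c(out$removed, sub$removed)
    } else if (length(cp) >= 2L) {
      out$scaffolds <- c(out$scaffolds, list(.finish_component(l)))
    } else {
      out$singletons <- c(out$singletons, cp)
    }
  }
  out
}
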
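# Positioning: with orientations fixed, the mate pairs joining contigs i and j
# act as a spring of constant |J_ij| and relaxed length d_ij between the
# contig start points; the maximum-probability positions are the equilibrium
# of the spring network, found by solving the zero-force linear system.
# Stretched or compressed springs (large residuals) flag inconsistent
# constraints; the contigs at their ends are removed and the assembly loop
# returns to orientation assignment.

#' Orientation-adjusted relaxed spring lengths
#'
#' Edge separations are stored in the canonical frame (lower contig oriented
#' +1); under a flipped assignment the implied separation of an edge becomes
#' `-dbar + M_lo - M_hi`.
#'
#' @param edges retained, orientation-consistent edge rows (ci, cj, J, dbar).
#' @param S named orientation vector.
#' @param lens named contig lengths.
#' @return numeric vector of relaxed lengths (target `x_cj - x_ci`).
#' @export
spring_lengths <- function(edges, S, lens) {
  ifelse(S[edges$ci] == 1L, edges$dbar,
         -edges$dbar + lens[edges$ci] - lens[edges$cj])
}

#' Solve the spring model on one connected component
#'
#' Minimizes `sum_e w_e ((x_j - x_i) - d_e)^2` with the anchor vertex pinned
#' at 0 (the alphabetically first vertex: the solution is unique only up to
#' translation). The normal equations form a weighted-Laplacian system,
#' symmetric positive definite once the anchor row is eliminated.
#'
#' @param vertices character vector of component vertex names.
#' @param edges data frame with ci, cj, weight `w` (= |J|) and relaxed length
#'   `d` (target `x_cj - x_ci`); must connect the component.
#' @return list: `x` (named positions, anchor at 0), `delta` (per-edge
#'   absolute residual `|x_j - x_i - d|`), `w` (edge weights).
#' @export
solve_spring <- function(vertices, edges) {
  n <- length(vertices)
  x <- stats::setNames(numeric(n), vertices)
  if (n == 1L || nrow(edges) == 0L)
    return(list(x = x, delta = numeric(nrow(edges)), w = edges$w))
  anchor <- sort(vertices)[1]
  free <- setdiff(vertices, anchor)
  ii <- match(edges$ci, vertices); jj <- match(edges$cj, vertices)
  L <- matrix(0, n, n, dimnames = list(vertices, vertices))
  b <- stats::setNames(numeric(n), vertices)
  for (e in seq_len(nrow(edges))) {
    i <- ii[e]; j <- jj[e]; w <- edges$w[e]; d <- edges$d[e]
    L[i, i] <- L[i, i] + w; L[j, j] <- L[j, j] + w
    L[i, j] <- L[i, j] - w; L[j, i] <- L[j, i] - w
    b[i] <- b[i] - w * d; b[j] <- b[j] + w * d
  }
  sol <- solve(L[free, free, drop = FALSE], b[free])
  x[free] <- sol
  sep <- x[edges$cj] - x[edges$ci]
  list(x = x, delta = unname(abs(sep - edges$d)), w = edges$w)
}

#' Find stretched springs and decide what to remove
#'
#' An edge is stretched when its residual exceeds `max(delta_k * sigma /
#' sqrt(w), delta_floor * sigma)` (the standard error of a mean of `w` pair
#' separations of spread `sigma`, floored because the separation-biased
#' sampling of bridging pairs leaves a bias that does not shrink with `w`).
#' Without `support`, the single worst stretched edge (largest
#' residual-to-threshold ratio) is relaxed by removing both endpoint contigs;
#' removing one edge at a time keeps good contigs when several springs share
#' a culprit. With `support` (total incident link weight per contig),
#' stretched springs carrying at most `spurious_frac` of each endpoint's
#' remaining support are classified as spurious background constraints and
#' dropped as edges (all of them at once), while a stretched spring dominant
#' for one of its endpoints indicates a mis-assembled or repeat-like contig
#' and removes both endpoints (worst such edge only).
#'
#' @param sol value of [solve_spring()].
#' @param edges the edge data frame passed to [solve_spring()].
#' @param sigma empirical per-pair separation spread.
#' @param delta_k threshold factor.
#' @param delta_floor threshold floor in units of sigma.
#' @param support optional named vector of total incident edge weight per
#'   contig; enables the spurious-edge classification.
#' @param spurious_frac classification threshold (see above).
#' @return list with `contigs` (to remove) and `edges` (integer row indices
#'   of `edges` to drop); both empty when all springs are within threshold.
#' @export
prune_stretched <- function(sol, edges, sigma, delta_k = 5, delta_floor = 0.5,
                            support = NULL, spurious_frac = 0.5) {
  none <- list(contigs = character(0), edges = integer(0))
  if (nrow(edges) == 0) return(none)
  thr <- pmax(delta_k * sigma / sqrt(edges$w), delta_floor * sigma)
  ratio <- sol$delta / thr
  stretched <- which(ratio > 1)
  if (!length(stretched)) return(none)
  if (is.null(support)) {
    worst <- which.max(ratio)
    return(list(contigs = unique(c(edges$ci[worst], edges$cj[worst])),
                edges = integer(0)))
  }
  # a spring carrying a small minority of both endpoints' support is a
  # background constraint: drop all such springs first, since a handful of
  # them distorts the whole solution and can stretch genuine springs
  rest_i <- support[edges$ci] - edges$w
  rest_j <- support[edges$cj] - edges$w
  spurious <- stretched[edges$w[stretched] <=
                          spurious_frac * pmin(rest_i, rest_j)[stretched]]
  if (length(spurious)) return(list(contigs = character(0), edges = spurious))
  # no clear background spring left: blame the worst spring's contigs when it
  # dominates the support of both its endpoints (mis-assembled/repeat contig),
  # otherwise relax just that constraint
  worst <- stretched[which.max(ratio[stretched])]
  dominant <- edges$w[worst] > spurious_frac * rest_i[worst] &&
    edges$w[worst] > spurious_frac * rest_j[worst]
  if (dominant)
    list(contigs = unique(c(edges$ci[worst], edges$cj[worst])),
         edges = integer(0))
  else list(contigs = character(0), edges = worst)
}
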
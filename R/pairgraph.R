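# Contig connectivity graph: every cross-contig pair votes on the relative
# orientation parity of its two contigs and suggests a start-to-start
# separation; votes are aggregated per contig pair into a signed link count
# J_ij (majority-filtered) and a mean suggested separation d_ij.
#
# Coordinate convention: x_i is the scaffold coordinate of the contig's start;
# S_i = +1 means the stored sequence reads left-to-right. A read placed at
# 0-based offset p on a contig of length M has scaffold-forward leftmost
# coordinate x_i + p when S_i = +1 and x_i + M - p - read_len when S_i = -1,
# and its scaffold strand is tau * S_i. For both library types the pair
# geometry is sigma_R * (g_F - g_R) = Ins, where g are leftmost coordinates
# and sigma_R is the strand of the R read; the parity (expected sign of
# S_i S_j) is tau_R tau_F for same-strand SOLiD mates and -tau_R tau_F for
# opposite-strand paired ends.

#' Per-pair orientation parity and suggested separation
#'
#' Vectorized over pairs. The suggested separation is stored in the canonical
#' frame where the lower-indexed contig of each pair has orientation +1 (and
#' its partner the parity-implied orientation); the value for the globally
#' flipped frame is `-l + M_lo - M_hi`.
#'
#' @param pt cross-contig pair table (see [pair_table()]): columns ci, cj, pR,
#'   pF, tauR, tauF, library.
#' @param contig_lens named lengths of all contigs.
#' @param libraries named list of [scaf_library()] objects.
#' @param inserts named numeric vector of (empirical) insert sizes per
#'   library; defaults to the nominal values.
#' @return data frame with `lo`, `hi` (contig ids, lo < hi), `parity` and
#'   `l` (suggested `x_hi - x_lo` in the canonical frame).
#' @export
pair_constraints <- function(pt, contig_lens, libraries, inserts = NULL) {
  stopifnot(all(pt$ci != pt$cj))
  type <- vapply(libraries[pt$library], `[[`, "", "type")
  rho <- vapply(libraries[pt$library], `[[`, 0L, "read_len")
  ins <- if (is.null(inserts))
    vapply(libraries[pt$library], `[[`, 0, "insert")
  else inserts[pt$library]
  parity <- ifelse(type == "solid_mate", 1L, -1L) * pt$tauR * pt$tauF
  swap <- pt$ci > pt$cj
  lo <- ifelse(swap, pt$cj, pt$ci)
  hi <- ifelse(swap, pt$ci, pt$cj)
  Mr <- contig_lens[pt$ci]
  Mf <- contig_lens[pt$cj]
  # canonical frame: S(lo) = +1, S(hi) = parity
  S_R <- ifelse(swap, parity, 1L)   # orientation of the R-read's contig
  S_F <- ifelse(swap, 1L, parity)
  sigma <- pt$tauR * S_R
  pR_fwd <- ifelse(S_R == 1L, pt$pR, Mr - pt$pR - rho)
  pF_fwd <- ifelse(S_F == 1L, pt$pF, Mf - pt$pF - rho)
  l_fr <- sigma * ins - pF_fwd + pR_fwd   # x(F contig) - x(R contig)
  data.frame(lo = lo, hi = hi, parity = as.integer(parity),
             l = ifelse(swap, -l_fr, l_fr), stringsAsFactors = FALSE)
}

#' Build the contig connectivity graph
#'
#' Aggregates per-pair constraints per contig pair. On each edge the pairs are
#' split by parity; if the dominant group reaches `majority_fraction` the
#' minority pairs are dropped and `J` is the signed dominant count, otherwise
#' the whole edge is ignored (comparable group sizes signal a repeat or
#' chimera rather than a few spurious pairs). Edges with fewer than `W`
#' agreeing pairs are ignored. Contigs shorter than `L` are excluded
#' beforehand.
#'
#' @param constraints data frame from [pair_constraints()].
#' @param contig_lens named lengths of all contigs.
#' @param W minimum link count.
#' @param L minimum contig length.
#' @param majority_fraction required dominant-parity fraction.
#' @param outlier_cut per-edge background filter: among dominant-parity pairs,
#'   those whose suggested separation deviates from the edge median by more
#'   than this value are dropped before averaging (and do not count towards
#'   `J`). The pipeline passes the empirical insert size, mirroring the
#'   outlier rule used for insert-size estimation; `Inf` disables it.
#' @return a `scaf_graph` list: `vertices` (eligible contig ids), `edges`
#'   (lo, hi, J, dbar, n, kept), `lens`.
#' @export
build_graph <- function(constraints, contig_lens, W = 5L, L = 150L,
                        majority_fraction = 0.7, outlier_cut = Inf) {
  eligible <- names(contig_lens)[contig_lens >= L]
  cs <- constraints[constraints$lo %in% eligible &
                      constraints$hi %in% eligible, , drop = FALSE]
  if (nrow(cs) == 0) {
    edges <- data.frame(ci = character(), cj = character(), J = integer(),
                        dbar = numeric(), n = integer(), kept = logical(),
                        stringsAsFactors = FALSE)
    return(structure(list(vertices = eligible, edges = edges,
                          lens = contig_lens[eligible]),
                     class = "scaf_graph"))
  }
  key <- paste(cs$lo, cs$hi, sep = "\r")
  pos <- cs$parity == 1L
  n_pos <- tapply(pos, key, sum)
  n_tot <- tapply(pos, key, length)
  keys <- names(n_tot)
  n_pos <- as.integer(n_pos[keys]); n_tot <- as.integer(n_tot[keys])
  n_neg <- n_tot - n_pos
  dom_sign <- ifelse(n_pos >= n_neg, 1L, -1L)
  n_dom <- pmax(n_pos, n_neg)
  majority_ok <- n_dom / n_tot >= majority_fraction
  # separations over dominant-parity pairs, with per-edge outlier removal
  dom_of_pair <- dom_sign[match(key, keys)]
  sel <- cs$parity == dom_of_pair
  med <- tapply(cs$l[sel], key[sel], stats::median)
  inlier <- sel
  inlier[sel] <- abs(cs$l[sel] - med[key[sel]]) <= outlier_cut
  dbar <- rep(NA_real_, length(keys))
  m <- tapply(cs$l[inlier], key[inlier], mean)
  dbar[match(names(m), keys)] <- as.numeric(m)
  n_in <- integer(length(keys))
  cnt <- tapply(inlier, key, sum)
  n_in[match(names(cnt), keys)] <- as.integer(cnt)
  n_dom <- n_in
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(ci = vapply(parts, `[[`, "", 1L),
                      cj = vapply(parts, `[[`, "", 2L),
                      J = dom_sign * n_dom,
                      dbar = dbar, n = n_tot,
                      kept = majority_ok & n_dom >= W,
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(vertices = eligible, edges = edges,
                 lens = contig_lens[eligible]),
            class = "scaf_graph")
}

# igraph of the retained edges only
.retained_igraph <- function(graph) {
  e <- graph$edges[graph$edges$kept, , drop = FALSE]
  igraph::graph_from_data_frame(
    data.frame(from = e$ci, to = e$cj, J = e$J, dbar = e$dbar),
    directed = FALSE,
    vertices = data.frame(name = graph$vertices))
}
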
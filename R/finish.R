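# Sequence finishing: convert a solved layout (ordered, oriented, positioned
# contigs) into a scaffold sequence. Neighboring contigs whose ends agree are
# joined; otherwise the positional gap is rendered as a run of 'N's rounded
# to the nearest multiple of 50 (a small positional overlap with dissimilar
# ends gets a fixed 50-base spacer).

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Round a gap length to the emitted spacer length
#'
#' Nearest positive multiple of 50; exact midpoints round up; the minimum
#' spacer is 50 (a zero-length spacer would silently merge dissimilar
#' contigs).
#'
#' @param g positional gap (bases).
#' @return spacer length, a positive multiple of 50.
#' @export
round_gap <- function(g) {
  max(50L, as.integer(floor(g / 50 + 0.5)) * 50L)
}

# best suffix(left)/prefix(right) overlap within a window; returns list(len,
# identity) of the best-identity overlap (ties -> longer), or NULL
.best_end_overlap <- function(left, right, window) {
  nl <- nchar(left); nr <- nchar(right)
  cap <- min(window, nl, nr)
  if (cap < 1L) return(NULL)
  best <- NULL
  for (o in seq_len(cap)) {
    a <- substr(left, nl - o + 1L, nl)
    b <- substr(right, 1L, o)
    idt <- 1 - utils::adist(a, b)[1, 1] / o
    if (is.null(best) || idt > best$identity ||
        (idt == best$identity && o > best$len))
      best <- list(len = o, identity = idt)
  }
  best
}

#' Decide whether to join neighboring contigs or insert a gap
#'
#' If the positional gap `g` is negative (overlap) or smaller than
#' `small_gap_cutoff`, the contig ends are tested for sequence similarity
#' (best suffix-prefix alignment over a window of `max(2|g|, 30)` bases at
#' >= `min_identity` identity) and joined on success. Otherwise a run of 'N's
#' of length [round_gap()]`(g)` is inserted; a small positional overlap with
#' dissimilar ends gets exactly 50 'N's.
#'
#' @param left_seq,right_seq neighboring contig sequences, already oriented.
#' @param g positional gap: `x_right - (x_left + len_left)`.
#' @param small_gap_cutoff gaps below this trigger the similarity test.
#' @param min_identity similarity threshold.
#' @return list with `action` ("merge" or "gap"), `overlap` (merge length) or
#'   `n_len` (spacer length).
#' @export
join_or_gap <- function(left_seq, right_seq, g, small_gap_cutoff = 10L,
                        min_identity = 0.9) {
  if (g < small_gap_cutoff) {
    window <- max(2L * abs(as.integer(g)), 30L)
    best <- .best_end_overlap(left_seq, right_seq, window)
    if (!is.null(best) && best$identity >= min_identity && best$len >= 5L)
      return(list(action = "merge", overlap = best$len))
    if (g < 0) return(list(action = "gap", n_len = 50L))
  }
  list(action = "gap", n_len = round_gap(max(g, 0)))
}

#' Render a solved layout as a scaffold sequence
#'
#' Contigs are laid out in position order; a contig with orientation -1
#' contributes its reverse complement. Each adjacency is resolved by
#' [join_or_gap()]; merged overlaps take the left contig's bases at
#' disagreeing columns (or the higher-coverage contig's when mean coverages
#' are supplied).
#'
#' @param layout data frame: contig, x, S, len, ordered or orderable by x.
#' @param contigs named contig sequences.
#' @param small_gap_cutoff,min_identity see [join_or_gap()].
#' @param coverage optional named mean coverage per contig.
#' @return list: `sequence`, `decisions` (per-adjacency data frame: left,
#'   right, gap, action, n_len).
#' @export
render_scaffold <- function(layout, contigs, small_gap_cutoff = 10L,
                            min_identity = 0.9, coverage = NULL) {
  l <- layout[order(layout$x), , drop = FALSE]
  seqs <- vapply(seq_len(nrow(l)), function(i) {
    s <- contigs[[l$contig[i]]]
    if (l$S[i] == -1L) .revcomp(s) else s
  }, "")
  out <- seqs[1]
  dec <- data.frame(left = character(), right = character(), gap = numeric(),
                    action = character(), n_len = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(l) > 1) for (i in 2:nrow(l)) {
    g <- l$x[i] - (l$x[i - 1] + l$len[i - 1])
    d <- join_or_gap(seqs[i - 1], seqs[i], g, small_gap_cutoff, min_identity)
    if (d$action == "merge") {
      o <- d$overlap
      left_wins <- TRUE
      if (!is.null(coverage)) {
        cl <- coverage[l$contig[i - 1]]; cr <- coverage[l$contig[i]]
        if (isTRUE(cr > cl)) left_wins <- FALSE
      }
      tail_part <- if (left_wins) substr(seqs[i], o + 1L, nchar(seqs[i]))
      else substr(seqs[i], 1L, nchar(seqs[i]))
      if (!left_wins) out <- substr(out, 1L, nchar(out) - o)
      out <- paste0(out, tail_part)
      dec <- rbind(dec, data.frame(left = l$contig[i - 1],
                                   right = l$contig[i], gap = g,
                                   action = "merge", n_len = 0L,
                                   stringsAsFactors = FALSE))
    } else {
      out <- paste0(out, strrep("N", d$n_len), seqs[i])
      dec <- rbind(dec, data.frame(left = l$contig[i - 1],
                                   right = l$contig[i], gap = g,
                                   action = "gap", n_len = d$n_len,
                                   stringsAsFactors = FALSE))
    }
  }
  list(sequence = out, decisions = dec)
}
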
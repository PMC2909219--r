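# SOLiD di-base color algebra and robust color-space -> base-space translation.
#
# The SOLiD chemistry reads dinucleotides through four color probes (0-3); the
# sixteen dinucleotides fall into four classes of four, designed so that the
# first base together with the color call uniquely determines the second base.
# One wrong color call therefore corrupts every downstream base under naive
# chain translation; the robust translator below treats the true sequence as
# the hidden state of a chain model observed through color calls and per-read
# first-base suggestions and recovers the maximum-probability sequence by
# dynamic programming.

.BASES <- c("A", "C", "G", "T")

# color class matrix: 0={AA,CC,GG,TT}, 1={AC,CA,GT,TG}, 2={AG,GA,CT,TC},
# 3={AT,TA,CG,GC}; symmetric with zero diagonal.
.COLOR_MAT <- matrix(c(0L, 1L, 2L, 3L,
                       1L, 0L, 3L, 2L,
                       2L, 3L, 0L, 1L,
                       3L, 2L, 1L, 0L),
                     4, 4, byrow = TRUE,
                     dimnames = list(.BASES, .BASES))

.base_idx <- function(b) {
  i <- match(b, .BASES)
  if (anyNA(i)) stop("ambiguous or invalid base: ",
                     paste(unique(b[is.na(i)]), collapse = ","))
  i
}

#' Encode a base sequence as SOLiD colors
#'
#' @param seq a character scalar over A/C/G/T (length >= 2) or a character
#'   vector of single bases.
#' @return integer vector of N-1 color calls in 0..3.
#' @examples
#' encode_colors("AG")    # 2
#' encode_colors("ATGC")  # 3 1 3
#' @export
encode_colors <- function(seq) {
  b <- if (length(seq) == 1L && nchar(seq) > 1L)
    strsplit(toupper(seq), "")[[1]] else toupper(seq)
  if (length(b) < 2L) stop("need at least 2 bases to encode colors")
  i <- .base_idx(b)
  .COLOR_MAT[cbind(i[-length(i)], i[-1L])]
}

#' Next base implied by a base and a color call
#'
#' For a fixed color the map from first to second base is a bijection.
#'
#' @param base character vector of bases.
#' @param color integer vector of colors in 0..3.
#' @return character vector of implied next bases.
#' @export
next_base <- function(base, color) {
  i <- .base_idx(toupper(base))
  stopifnot(all(color %in% 0:3))
  # row i of .COLOR_MAT maps second-base index -> color; invert per row
  out <- character(length(i))
  for (k in seq_along(i)) out[k] <- .BASES[match(color[k], .COLOR_MAT[i[k], ])]
  out
}

#' Naive chain translation of a color sequence
#'
#' Iterates [next_base()] from a reference base. A single color error corrupts
#' every downstream base, which is exactly the failure mode the robust
#' translator avoids.
#'
#' @param ref single reference base.
#' @param colors integer vector of color calls.
#' @return character scalar of `length(colors)` bases (empty for no colors).
#' @export
naive_translate <- function(ref, colors) {
  if (length(colors) == 0L) return("")
  b <- character(length(colors))
  cur <- toupper(ref)
  for (k in seq_along(colors)) {
    cur <- next_base(cur, colors[k])
    b[k] <- cur
  }
  paste(b, collapse = "")
}

#' Construct a color-space contig
#'
#' @param colors integer vector of N-1 consensus color calls (c_i sits between
#'   base positions i and i+1).
#' @param suggestions 4 x N integer matrix of first-base suggestion counts,
#'   rows named A, C, G, T (f\[b, i\] = number of reads voting base b at
#'   position i), or NULL for none.
#' @param r_c probability that a consensus color call is wrong.
#' @param r_s probability that a base suggestion is wrong.
#' @return a `color_contig` list.
#' @export
color_contig <- function(colors, suggestions = NULL, r_c = 0.01, r_s = 0.03) {
  colors <- as.integer(colors)
  stopifnot(all(colors %in% 0:3), r_c > 0, r_c < 1, r_s > 0, r_s < 1)
  n <- length(colors) + 1L
  if (is.null(suggestions)) {
    suggestions <- matrix(0L, 4L, n, dimnames = list(.BASES, NULL))
  } else {
    stopifnot(is.matrix(suggestions), nrow(suggestions) == 4L,
              ncol(suggestions) == n, all(suggestions >= 0))
    if (!identical(rownames(suggestions), .BASES))
      rownames(suggestions) <- .BASES
    storage.mode(suggestions) <- "integer"
  }
  structure(list(colors = colors, suggestions = suggestions,
                 r_c = r_c, r_s = r_s),
            class = "color_contig")
}

#' Default error rates for robust translation
#'
#' The suggestion error rate is taken directly as the platform base error rate
#' `e_s`; the consensus color error rate decreases with read depth `d`, since
#' each consensus call is a majority over roughly `d` reads.
#'
#' @param e_s platform per-call error rate in (0, 1).
#' @param d mean read depth (>= 1).
#' @return list with elements `r_c` and `r_s`.
#' @export
default_error_rates <- function(e_s, d) {
  stopifnot(e_s > 0, e_s < 1, d >= 1)
  list(r_c = min(0.5, e_s / d), r_s = e_s)
}

# per-position log-weights of the 4 bases from the suggestion counts
.suggestion_logw <- function(f, r_s) {
  tot <- colSums(f)
  # w[b, i] = f[b,i]*log(1-r_s) + (tot[i]-f[b,i])*log(r_s/3)
  log(1 - r_s) * f + log(r_s / 3) * sweep(-f, 2, tot, "+")
}

#' Robust translation of a color-space contig
#'
#' Finds the base sequence `B` maximizing the chain-model probability: each
#' color position contributes `1 - r_c` when the color of the dinucleotide
#' `b_i b_{i+1}` matches the consensus call and `r_c/3` otherwise; each base
#' suggestion contributes `1 - r_s` when it matches `b_i` and `r_s/3`
#' otherwise, raised to its multiplicity. A forward pass keeps, per position
#' and per candidate base, the best log-probability and a backpointer; the
#' backtrace starts from the best final base. Ties always prefer the
#' alphabetically earlier base, making the result deterministic even for the
#' fully degenerate no-suggestion case. All arithmetic is in log space.
#'
#' @param cc a [color_contig()].
#' @param ref optional known first base (e.g. from the library primer); pins
#'   position 1.
#' @return list with `sequence` (character scalar), `logp` (log-probability of
#'   the returned sequence), `color_flags` (logical, length N-1: color calls
#'   declared erroneous, i.e. inconsistent with the returned sequence) and
#'   `suggestion_flags` (integer, length N: count of suggestions at each
#'   position declared erroneous).
#' @export
robust_translate <- function(cc, ref = NULL) {
  stopifnot(inherits(cc, "color_contig"))
  n <- length(cc$colors) + 1L
  logw <- .suggestion_logw(cc$suggestions, cc$r_s)
  if (!is.null(ref)) {
    i <- .base_idx(toupper(ref))
    logw[, 1L] <- -Inf
    logw[i, 1L] <- 0
  }
  lc_ok <- log(1 - cc$r_c)
  lc_bad <- log(cc$r_c / 3)
  # score[b] = best log P over prefixes ending in base b; bp[b, k] backpointer
  score <- logw[, 1L]
  bp <- matrix(NA_integer_, 4L, n)
  for (k in 2L:n) {
    # trans[a, b] = color factor for dinucleotide (a, b) against call c_{k-1}
    trans <- ifelse(.COLOR_MAT == cc$colors[k - 1L], lc_ok, lc_bad)
    cand <- score + trans            # cand[a, b]
    bp[, k] <- apply(cand, 2L, which.max)  # first max => alphabetical tie rule
    score <- cand[cbind(bp[, k], 1:4)] + logw[, k]
  }
  b <- integer(n)
  b[n] <- which.max(score)
  for (k in n:2L) b[k - 1L] <- bp[b[k], k]
  seq_bases <- .BASES[b]
  implied <- .COLOR_MAT[cbind(b[-n], b[-1L])]
  f <- cc$suggestions
  wrong_sugg <- as.integer(colSums(f) - f[cbind(b, seq_len(n))])
  list(sequence = paste(seq_bases, collapse = ""),
       logp = unname(score[b[n]]),
       color_flags = implied != cc$colors,
       suggestion_flags = wrong_sugg)
}

#' Log-probability of a candidate base sequence under the chain model
#'
#' Companion scorer to [robust_translate()], useful for comparing candidate
#' translations (e.g. the naive chain translation) on the same model.
#'
#' @param cc a [color_contig()].
#' @param sequence candidate base sequence (character scalar, length N).
#' @param ref optional pinned first base; a mismatching candidate scores -Inf.
#' @return log-probability.
#' @export
translation_logp <- function(cc, sequence, ref = NULL) {
  stopifnot(inherits(cc, "color_contig"))
  b <- .base_idx(strsplit(toupper(sequence), "")[[1]])
  n <- length(cc$colors) + 1L
  stopifnot(length(b) == n)
  if (!is.null(ref) && .BASES[b[1L]] != toupper(ref)) return(-Inf)
  logw <- .suggestion_logw(cc$suggestions, cc$r_s)
  implied <- .COLOR_MAT[cbind(b[-n], b[-1L])]
  sum(ifelse(implied == cc$colors, log(1 - cc$r_c), log(cc$r_c / 3))) +
    sum(logw[cbind(b, seq_len(n))])
}
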
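# Preprocessing: insert-size estimation from same-contig pairs, the contig
# self-consistency check, chimera splitting by spanning-link counts, and
# removal of high-coverage (repeat-like) contigs and reads.

#' Join pairs against placements
#'
#' One row per pair whose two reads are both placed, with the contig, offset
#' and strand of each read.
#'
#' @param placements placement data frame.
#' @param pairs pairs data frame.
#' @return data frame with columns r_read, f_read, library, ci, cj, pR, pF,
#'   tauR, tauF.
#' @export
pair_table <- function(placements, pairs) {
  ir <- match(pairs$r_read, placements$read_id)
  iff <- match(pairs$f_read, placements$read_id)
  ok <- !is.na(ir) & !is.na(iff)
  data.frame(r_read = pairs$r_read[ok], f_read = pairs$f_read[ok],
             library = pairs$library[ok],
             ci = placements$contig_id[ir[ok]],
             cj = placements$contig_id[iff[ok]],
             pR = placements$offset[ir[ok]], pF = placements$offset[iff[ok]],
             tauR = placements$tau[ir[ok]], tauF = placements$tau[iff[ok]],
             stringsAsFactors = FALSE)
}

#' Signed same-contig pair separations
#'
#' Separation between the leftmost read coordinates, signed so that a
#' geometry-consistent pair yields (about) the insert size.
#' Orientation-consistent means tauR == tauF for SOLiD mate pairs and
#' tauR == -tauF for paired ends.
#'
#' @param pt pair table restricted to same-contig pairs.
#' @param libraries named list of [scaf_library()] objects.
#' @return data frame with contig, separation, orient_ok.
#' @export
same_contig_separation <- function(pt, libraries) {
  type <- vapply(libraries[pt$library], `[[`, "", "type")
  sep <- pt$tauR * (pt$pF - pt$pR)
  orient_ok <- ifelse(type == "solid_mate", pt$tauR == pt$tauF,
                      pt$tauR == -pt$tauF)
  data.frame(contig = pt$ci, separation = sep, orient_ok = orient_ok)
}

#' Estimate the empirical insert size from same-contig pairs
#'
#' Pairs whose separation differs from the suggested insert size by more than
#' the suggested insert size itself (equivalently, more than five standard
#' deviations if the spread is 20% of the mean) are removed as background
#' outliers; the empirical insert size is the mean separation of the remaining
#' pairs and the empirical sigma their standard deviation.
#'
#' @param separations numeric vector of same-contig pair separations (signed;
#'   negative values are geometry-inconsistent and always removed).
#' @param ins0 suggested insert size from the library preparation protocol.
#' @return list with `mean`, `sd`, `n_retained`, `n_outliers`, and the
#'   retained `separations`.
#' @export
estimate_insert_size <- function(separations, ins0) {
  stopifnot(length(separations) >= 1, ins0 > 0)
  keep <- abs(separations - ins0) <= ins0
  if (!any(keep)) {
    warning("all same-contig pairs removed as outliers; falling back to ",
            "suggested insert size")
    return(list(mean = ins0, sd = 0.2 * ins0, n_retained = 0L,
                n_outliers = length(separations), separations = numeric(0)))
  }
  s <- separations[keep]
  list(mean = mean(s), sd = if (length(s) > 1) stats::sd(s) else 0,
       n_retained = length(s), n_outliers = sum(!keep), separations = s)
}

#' Contig self-consistency check
#'
#' Counts same-contig pairs whose relative orientation contradicts the library
#' geometry or whose separation deviates from the empirical insert size by
#' strictly more than one empirical standard deviation. The contig is
#' discarded when the count exceeds `max_violations` (an absolute count when
#' >= 1, a fraction of the contig's same-contig pairs when < 1).
#'
#' @param separations signed separations of the contig's same-contig pairs.
#' @param orient_ok logical vector: geometry-consistent orientation per pair.
#' @param stats insert statistics from [estimate_insert_size()].
#' @param max_violations threshold (count or fraction).
#' @return TRUE to keep the contig, FALSE to discard it.
#' @export
self_consistency_filter <- function(separations, orient_ok, stats,
                                    max_violations = 0.5) {
  n <- length(separations)
  if (n == 0) return(TRUE)
  viol <- sum(!orient_ok | abs(separations - stats$mean) > stats$sd)
  lim <- if (max_violations < 1) max_violations * n else max_violations
  viol <= lim
}

#' Split a contig where few mate pairs span
#'
#' For each interior position of a long contig, the spanning count is the
#' number of same-contig pairs with one read entirely to the left and the
#' other entirely to the right. A genuine contig a few times longer than the
#' insert size is spanned everywhere; a chimeric concatenation has (near) zero
#' spanning pairs at the junction. The contig is cut at the minimum of every
#' maximal interior region where the count falls below `min_span` (leftmost
#' minimum on ties). Contigs not longer than twice the insert size pass
#' through unchanged, as spanning counts are meaningless there. The scan is
#' restricted to positions at least one insert size from either end, where a
#' genuine contig's spanning count is at full strength.
#'
#' @param contig_len contig length.
#' @param pR,pF same-contig pair read offsets (0-based).
#' @param read_len read length.
#' @param min_span minimum spanning count.
#' @param ins insert size.
#' @return integer vector of cut positions (possibly empty); a cut at `p`
#'   splits the contig into `[0, p)` and `[p, len)`.
#' @export
split_low_span <- function(contig_len, pR, pF, read_len, min_span, ins) {
  if (contig_len <= 2 * ins) return(integer(0))
  lo <- as.integer(ceiling(ins)); hi <- as.integer(floor(contig_len - ins))
  if (hi <= lo) return(integer(0))
  # a pair spans position x iff min_end <= x <= max_start
  l_end <- pmin(pR, pF) + read_len
  r_start <- pmax(pR, pF)
  valid <- l_end <= r_start
  cover <- integer(contig_len + 2L)  # difference array over 0..contig_len+1
  if (any(valid)) {
    a <- pmax(l_end[valid], lo); b <- pmin(r_start[valid], hi)
    ok <- a <= b
    cover <- tabulate(a[ok] + 1L, contig_len + 2L) -
      tabulate(b[ok] + 2L, contig_len + 2L)
  }
  span <- cumsum(cover)[(lo + 1L):(hi + 1L)]  # span[i] = count at pos lo+i-1
  low <- span < min_span
  if (!any(low)) return(integer(0))
  r <- rle(low)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cuts <- integer(0)
  for (k in which(r$values)) {
    seg <- span[starts[k]:ends[k]]
    cuts <- c(cuts, lo + starts[k] - 1L + which.min(seg) - 1L)
  }
  cuts
}

#' Apply chimera splitting to a contig set
#'
#' Runs [split_low_span()] per contig and remaps placements onto the
#' sub-contigs; reads straddling a cut are dropped.
#'
#' @param contigs named character vector of sequences.
#' @param placements placement data frame.
#' @param pairs pairs data frame.
#' @param read_len read length.
#' @param min_span,ins splitter parameters.
#' @return list(contigs, placements, cuts) where `cuts` names the contigs cut.
#' @export
apply_chimera_splits <- function(contigs, placements, pairs, read_len,
                                 min_span, ins) {
  pt <- pair_table(placements, pairs)
  same <- pt[pt$ci == pt$cj, , drop = FALSE]
  cuts_log <- list()
  for (id in intersect(unique(same$ci), names(contigs))) {
    sub <- same[same$ci == id, ]
    cuts <- split_low_span(nchar(contigs[[id]]), sub$pR, sub$pF, read_len,
                           min_span, ins)
    if (!length(cuts)) next
    cuts_log[[id]] <- cuts
    bounds <- c(0L, cuts, nchar(contigs[[id]]))
    pieces <- character(length(bounds) - 1L)
    for (k in seq_along(pieces))
      pieces[k] <- substr(contigs[[id]], bounds[k] + 1L, bounds[k + 1L])
    new_ids <- sprintf("%s.%d", id, seq_along(pieces))
    contigs <- contigs[names(contigs) != id]
    contigs[new_ids] <- pieces
    sel <- placements$contig_id == id
    off <- placements$offset[sel]
    piece <- findInterval(off, bounds[-length(bounds)])
    fits <- off + read_len <= bounds[piece + 1L]
    placements$contig_id[sel] <- ifelse(fits, new_ids[piece], NA)
    placements$offset[sel] <- ifelse(fits, off - bounds[piece], off)
    placements <- placements[!is.na(placements$contig_id), , drop = FALSE]
  }
  list(contigs = contigs, placements = placements, cuts = cuts_log)
}

#' Remove repeat-like high-coverage contigs and reads
#'
#' Coverage is the per-base count of covering reads. Contigs whose mean
#' coverage exceeds `mean_cov_factor` times the median of contig mean
#' coverages are removed from scaffolding (kept as singletons). Reads lying in
#' `window`-base windows whose coverage exceeds `local_cov_factor` times the
#' same median are excluded from pairing.
#'
#' @param contigs named character vector.
#' @param placements placement data frame.
#' @param read_len read length.
#' @param mean_cov_factor,local_cov_factor,window thresholds.
#' @return list(removed_contigs, excluded_reads, mean_coverage).
#' @export
coverage_filter <- function(contigs, placements, read_len,
                            mean_cov_factor = 2.5, local_cov_factor = 3,
                            window = 100L) {
  lens <- nchar(contigs)
  placements <- placements[placements$contig_id %in% names(contigs), ,
                           drop = FALSE]
  covered <- tapply(pmin(placements$offset + read_len,
                         lens[placements$contig_id]) -
                      placements$offset,
                    placements$contig_id, sum)
  mean_cov <- stats::setNames(rep(0, length(contigs)), names(contigs))
  mean_cov[names(covered)] <- as.numeric(covered) / lens[names(covered)]
  med <- stats::median(mean_cov[mean_cov > 0])
  if (!is.finite(med) || med == 0) med <- 1
  removed <- names(contigs)[mean_cov > mean_cov_factor * med]
  excluded <- character(0)
  for (id in setdiff(unique(placements$contig_id), removed)) {
    sel <- placements$contig_id == id
    off <- placements$offset[sel]
    M <- lens[[id]]
    nb <- max(1L, ceiling(M / window))
    d <- tabulate(off + 1L, M + 1L) -
      tabulate(pmin(off + read_len, M) + 1L, M + 1L)
    cov <- cumsum(d)[seq_len(M)]
    wcov <- vapply(seq_len(nb), function(w)
      mean(cov[((w - 1L) * window + 1L):min(w * window, M)]), 0)
    hot <- which(wcov > local_cov_factor * med)
    if (length(hot)) {
      in_hot <- (off %/% window + 1L) %in% hot
      excluded <- c(excluded, placements$read_id[sel][in_hot])
    }
  }
  list(removed_contigs = removed, excluded_reads = excluded,
       mean_coverage = mean_cov)
}
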
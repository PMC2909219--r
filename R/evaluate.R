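# Assembly-quality metrics against simulator ground truth: N50, the four
# error categories (no-match and mismatch base rates; chimeric, orientation
# and separation rearrangement events per Mbp of assembly) and genome
# coverage. Ground-truth coordinates stand in for alignment of the assembly
# to a reference: the event definitions are unchanged, only the mapping step
# is exact instead of heuristic.

#' N50 of a set of piece lengths
#'
#' The smallest length L such that pieces of length >= L together cover at
#' least half of the total.
#'
#' @param lengths numeric vector of piece lengths.
#' @return the N50 value.
#' @examples
#' n50(c(10, 8, 6, 4, 2))  # 8
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("empty length set")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

# per-scaffold global flip relative to the genome: majority direction of
# adjacent truth starts (+1 = scaffold runs left-to-right along the genome)
.scaffold_flip <- function(l, tstart) {
  g <- tstart[l$contig]
  ok <- !is.na(g)
  if (sum(ok) < 2) return(1L)
  d <- diff(g[ok])
  if (sum(sign(d)) < 0) -1L else 1L
}

#' Fraction of true adjacencies recovered in correct order and orientation
#'
#' A true adjacency is a consecutive pair of (non-chimeric) contigs along the
#' genome. It is recovered when the two contigs are adjacent in a scaffold
#' with the truth-implied relative orientation and, up to the scaffold's
#' global flip, the truth-implied order.
#'
#' @param layouts list of scaffold layouts (contig, x, S, len).
#' @param truth truth data frame from [fragment_to_contigs()].
#' @return list(recovered, total, fraction).
#' @export
adjacency_recovery <- function(layouts, truth) {
  tt <- truth[!truth$chimeric, , drop = FALSE]
  tt <- tt[order(tt$genome_start), , drop = FALSE]
  total <- max(0L, nrow(tt) - 1L)
  tstrand <- stats::setNames(tt$strand, tt$contig)
  hits <- 0L
  if (total == 0L) return(list(recovered = 0L, total = 0L, fraction = NA))
  adj <- list()
  for (l in layouts) {
    l <- l[order(l$x), , drop = FALSE]
    if (nrow(l) < 2) next
    for (i in 2:nrow(l))
      adj[[length(adj) + 1L]] <- list(u = l$contig[i - 1], v = l$contig[i],
                                      Su = l$S[i - 1], Sv = l$S[i])
  }
  for (k in seq_len(total)) {
    a <- tt$contig[k]; b <- tt$contig[k + 1]
    ta <- tstrand[a]; tb <- tstrand[b]
    found <- FALSE
    for (e in adj) {
      if (!setequal(c(e$u, e$v), c(a, b))) next
      if (e$Su * e$Sv != ta * tb) next
      # in the unflipped frame a precedes b; u==a requires S_u * t_u == +1
      first_is_a <- e$u == a
      frame <- if (first_is_a) e$Su * ta else e$Su * tb
      if ((first_is_a && frame == 1L) || (!first_is_a && frame == -1L)) {
        found <- TRUE; break
      }
    }
    if (found) hits <- hits + 1L
  }
  list(recovered = hits, total = total, fraction = hits / total)
}

#' Full error report against ground truth
#'
#' @param layouts list of scaffold layouts.
#' @param singletons character vector of contig ids emitted as single contigs.
#' @param truth truth data frame.
#' @param genome_len genome length (bases).
#' @param contig_lens named contig lengths for every emitted contig.
#' @param contigs optional named contig sequences (enables the mismatch rate).
#' @param genome optional genome sequence (with `contigs`).
#' @return list with `n50` (over scaffold spans and singleton lengths),
#'   `eps_no_m`, `eps_mis_m` (% of assembled bases), `eps_ch_small`,
#'   `eps_ch_large`, `eps_orient`, `eps_sep` (events per Mbp of assembly) and
#'   `coverage_pct`.
#' @export
error_report <- function(layouts, singletons, truth, genome_len, contig_lens,
                         contigs = NULL, genome = NULL) {
  used <- c(unlist(lapply(layouts, `[[`, "contig")), singletons)
  assembled <- sum(contig_lens[used])
  mbp <- assembled / 1e6
  tstart <- stats::setNames(truth$genome_start, truth$contig)
  tstrand <- stats::setNames(truth$strand, truth$contig)
  # no-match: emitted contigs absent from truth
  no_match <- setdiff(used, truth$contig)
  eps_no_m <- 100 * sum(contig_lens[no_match]) / assembled
  # mismatch: direct base comparison over truth intervals
  eps_mis_m <- 0
  if (!is.null(contigs) && !is.null(genome)) {
    mm <- 0
    for (id in intersect(used, truth$contig)) {
      for (r in which(truth$contig == id)) {
        gs <- truth$genome_start[r]; ln <- truth$length[r]
        off <- truth$contig_offset[r]
        ref <- substr(genome, gs + 1L, gs + ln)
        got <- substr(contigs[[id]], off + 1L, off + ln)
        if (truth$strand[r] == -1L) got <- .revcomp(got)
        mm <- mm + sum(strsplit(ref, "")[[1]] != strsplit(got, "")[[1]])
      }
    }
    eps_mis_m <- 100 * mm / assembled
  }
  # chimeric events: one per junction inside a multi-interval contig
  ch_small <- 0L; ch_large <- 0L
  for (id in intersect(used, unique(truth$contig[truth$chimeric]))) {
    iv <- truth[truth$contig == id, , drop = FALSE]
    iv <- iv[order(iv$contig_offset), , drop = FALSE]
    for (k in seq_len(nrow(iv) - 1L)) {
      gap <- abs(iv$genome_start[k + 1L] -
                   (iv$genome_start[k] + iv$length[k]))
      if (gap <= 500) ch_small <- ch_small + 1L else ch_large <- ch_large + 1L
    }
  }
  # orientation / separation events over adjacent scaffold pairs
  n_orient <- 0L; n_sep <- 0L
  for (l in layouts) {
    l <- l[order(l$x), , drop = FALSE]
    if (nrow(l) < 2) next
    flip <- .scaffold_flip(l, tstart)
    for (i in 2:nrow(l)) {
      a <- l$contig[i - 1]; b <- l$contig[i]
      if (!(a %in% names(tstart)) || !(b %in% names(tstart))) next
      if (any(truth$chimeric[truth$contig %in% c(a, b)])) next
      ta <- tstrand[a]; tb <- tstrand[b]
      if (l$S[i - 1] * l$S[i] != ta * tb) { n_orient <- n_orient + 1L; next }
      if (flip == 1L) {
        est <- l$x[i] - l$x[i - 1]
        true_sep <- tstart[b] - tstart[a]
      } else {
        # reversed scaffold: genome coordinate decreases as x increases
        est <- (l$x[i] + l$len[i]) - (l$x[i - 1] + l$len[i - 1])
        true_sep <- tstart[a] - tstart[b]
      }
      if (abs(est - true_sep) > 500) n_sep <- n_sep + 1L
    }
  }
  # coverage: union of truth intervals of emitted contigs
  iv <- truth[truth$contig %in% used, , drop = FALSE]
  cov_pct <- if (nrow(iv)) {
    o <- order(iv$genome_start)
    s <- iv$genome_start[o]; e <- s + iv$length[o]
    covered <- 0; cur_s <- s[1]; cur_e <- e[1]
    if (length(s) > 1) for (k in 2:length(s)) {
      if (s[k] <= cur_e) cur_e <- max(cur_e, e[k])
      else { covered <- covered + cur_e - cur_s; cur_s <- s[k]; cur_e <- e[k] }
    }
    covered <- covered + cur_e - cur_s
    100 * covered / genome_len
  } else 0
  spans <- c(vapply(layouts, function(l) max(l$x + l$len) - min(l$x), 0),
             as.numeric(contig_lens[singletons]))
  list(n50 = if (length(spans)) n50(spans) else NA,
       eps_no_m = eps_no_m, eps_mis_m = eps_mis_m,
       eps_ch_small = ch_small / mbp, eps_ch_large = ch_large / mbp,
       eps_orient = n_orient / mbp, eps_sep = n_sep / mbp,
       coverage_pct = cov_pct)
}
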
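# Synthetic assembly simulator: genomes, contig tilings with recorded ground
# truth, and mate-pair/paired-end libraries with the statistical structure of
# real data (a Gaussian peak around the insert size on top of a broad uniform
# background, standard deviation around 20% of the mean).

#' Simulate a genome sequence
#'
#' I.i.d. bases at a given GC content, with optional exact repeat copies
#' planted at recorded positions.
#'
#' @param length genome length in bases.
#' @param gc_fraction GC content in \[0, 1\].
#' @param repeat_spec list of `c(unit_length, copy_number)` pairs; each unit is
#'   drawn once and pasted at `copy_number` non-overlapping random loci.
#' @param seed random seed.
#' @return list with `sequence` (character scalar) and `repeats` (data frame
#'   of planted copies: unit id, start (0-based), length).
#' @export
simulate_genome <- function(length, gc_fraction = 0.5, repeat_spec = list(),
                            seed = 1L) {
  stopifnot(length > 0, gc_fraction >= 0, gc_fraction <= 1)
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  g <- sample(names(p), length, replace = TRUE, prob = p)
  reps <- data.frame(unit = integer(), start = integer(), length = integer())
  taken <- integer(0)
  for (u in seq_along(repeat_spec)) {
    ul <- repeat_spec[[u]][1]; cn <- repeat_spec[[u]][2]
    if (ul > length) stop("repeat unit longer than genome")
    unit <- sample(names(p), ul, replace = TRUE, prob = p)
    placed <- 0L; tries <- 0L
    while (placed < cn && tries < 1000L) {
      s <- sample.int(length - ul + 1L, 1L) - 1L
      tries <- tries + 1L
      if (any(taken %in% (s + seq_len(ul) - 1L))) next
      g[s + seq_len(ul)] <- unit
      taken <- c(taken, s + seq_len(ul) - 1L)
      reps <- rbind(reps, data.frame(unit = u, start = s, length = ul))
      placed <- placed + 1L
    }
    if (placed < cn) stop("could not place all repeat copies")
  }
  list(sequence = paste(g, collapse = ""), repeats = reps)
}

#' Fragment a genome into contigs with ground truth
#'
#' Tiles the genome into non-overlapping contigs separated by gaps drawn from
#' `gap_model` (multiples of `gap_model$multiple` between `min` and `max`,
#' emulating the downstream gap-rounding resolution). Optionally fuses
#' `chimera_count` randomly chosen non-adjacent contig pairs into chimeric
#' contigs, the classic mis-assembly that joins two distant regions of the
#' genome into one sequence.
#'
#' @param genome character scalar (or the list from [simulate_genome()]).
#' @param n_contigs number of contigs to tile.
#' @param gap_model list(min, max, multiple) for inter-contig gap lengths.
#' @param chimera_count number of chimeric fusions to plant.
#' @param min_len minimum contig length.
#' @param seed random seed.
#' @return list with `contigs` (named character vector) and `truth`: a data
#'   frame with one row per truth interval (`contig`, `genome_start` 0-based,
#'   `length`, `strand` (+1), `contig_offset`, `chimeric` flag).
#' @export
fragment_to_contigs <- function(genome, n_contigs,
                                gap_model = list(min = 50, max = 300,
                                                 multiple = 50),
                                chimera_count = 0L, min_len = 300L,
                                seed = 1L) {
  if (is.list(genome)) genome <- genome$sequence
  G <- nchar(genome)
  stopifnot(n_contigs >= 1)
  set.seed(seed)
  gap_choices <- seq(gap_model$min, gap_model$max, by = gap_model$multiple)
  gaps <- if (n_contigs > 1)
    sample(gap_choices, n_contigs - 1L, replace = TRUE) else integer(0)
  avail <- G - sum(gaps) - n_contigs * min_len
  if (avail < 0) stop("n_contigs too large for genome")
  # random composition of the spare bases over contigs
  extra <- if (n_contigs > 1) {
    cuts <- sort(sample.int(avail + 1L, n_contigs - 1L, replace = TRUE) - 1L)
    diff(c(0L, cuts, avail))
  } else avail
  lens <- as.integer(min_len + extra)
  starts <- cumsum(c(0L, lens[-n_contigs] + gaps))
  ids <- sprintf("ctg%03d", seq_len(n_contigs))
  contigs <- vapply(seq_len(n_contigs), function(i)
    substr(genome, starts[i] + 1L, starts[i] + lens[i]), "")
  names(contigs) <- ids
  truth <- data.frame(contig = ids, genome_start = starts, length = lens,
                      strand = 1L, contig_offset = 0L, chimeric = FALSE,
                      stringsAsFactors = FALSE)
  if (chimera_count > 0) {
    for (k in seq_len(chimera_count)) {
      ord <- match(truth$contig[!duplicated(truth$contig)], names(contigs))
      idx <- which(!truth$chimeric & !duplicated(truth$contig))
      if (length(idx) < 4L) stop("not enough contigs left to fuse")
      # pick two non-adjacent plain contigs
      repeat {
        ab <- sort(sample(idx, 2L))
        if (abs(diff(ab)) > 1L) break
      }
      ra <- truth[ab[1], ]; rb <- truth[ab[2], ]
      nid <- paste0(ra$contig, "+", rb$contig)
      newseq <- paste0(contigs[[ra$contig]], contigs[[rb$contig]])
      contigs <- contigs[setdiff(names(contigs), c(ra$contig, rb$contig))]
      contigs[[nid]] <- newseq
      truth <- truth[-ab, ]
      truth <- rbind(truth, data.frame(
        contig = nid,
        genome_start = c(ra$genome_start, rb$genome_start),
        length = c(ra$length, rb$length),
        strand = 1L,
        contig_offset = c(0L, ra$length),
        chimeric = TRUE, stringsAsFactors = FALSE))
    }
  }
  rownames(truth) <- NULL
  list(contigs = contigs, truth = truth)
}

# map genome-forward read starts (0-based) + strands to (contig, offset, tau);
# reads falling in gaps or straddling interval ends are dropped (NA rows).
.place_reads <- function(gstart, strand, truth, read_len) {
  iv_start <- truth$genome_start
  iv_end <- truth$genome_start + truth$length
  ord <- order(iv_start)
  idx <- findInterval(gstart, iv_start[ord])
  hit <- ifelse(idx >= 1L, ord[pmax(idx, 1L)], NA_integer_)
  ok <- !is.na(hit) & gstart + read_len <= iv_end[ifelse(is.na(hit), 1L, hit)]
  hit[!ok] <- NA_integer_
  within <- gstart - iv_start[hit]
  t <- truth$strand[hit]
  offset <- ifelse(t == 1L,
                   truth$contig_offset[hit] + within,
                   truth$contig_offset[hit] + truth$length[hit] - within -
                     read_len)
  data.frame(contig = truth$contig[hit], offset = as.integer(offset),
             tau = as.integer(strand * t), stringsAsFactors = FALSE)
}

#' Simulate a mate-pair or paired-end library over a fragmented genome
#'
#' Non-background pairs draw a separation from Normal(Ins, sd) (negative draws
#' are redrawn) and are placed with the library's strand geometry: SOLiD mate
#' pairs put both reads on the same strand with the F3 read to the right of
#' the R3 read along that strand; Illumina paired ends put the two reads on
#' opposite strands facing each other. Background pairs (a fraction
#' `background_fraction`) give the F read a uniform random coordinate,
#' emulating the broad background of spurious pairs seen in real libraries.
#' Genome coordinates are converted to contig placements through the truth
#' layout; reads falling in gaps or straddling a contig end are discarded.
#'
#' @param genome_len genome length in bases.
#' @param truth truth data frame from [fragment_to_contigs()].
#' @param library a [scaf_library()].
#' @param n_pairs number of pairs to draw.
#' @param background_fraction fraction of spurious pairs in \[0, 1).
#' @param seed random seed.
#' @return list with `placements` (read_id, contig_id, offset, tau),
#'   `pairs` (r_read, f_read, library) restricted to pairs with both reads
#'   placed, and `truth_pairs`: per emitted pair the true genome coordinates.
#' @export
simulate_mate_pairs <- function(genome_len, truth, library, n_pairs,
                                background_fraction = 0, seed = 1L) {
  stopifnot(inherits(library, "scaf_library"),
            library$read_len < library$insert,
            background_fraction >= 0, background_fraction < 1)
  set.seed(seed)
  rho <- library$read_len
  sep <- stats::rnorm(n_pairs, library$insert, library$sd)
  while (any(bad <- sep <= rho))
    sep[bad] <- stats::rnorm(sum(bad), library$insert, library$sd)
  sep <- round(sep)
  strand <- sample(c(-1L, 1L), n_pairs, replace = TRUE)
  # R read leftmost coordinate uniform where the pair fits
  gR <- integer(n_pairs)
  fwd <- strand == 1L
  span <- sep + rho
  gR[fwd] <- floor(stats::runif(sum(fwd), 0, pmax(1, genome_len - span[fwd])))
  gR[!fwd] <- floor(stats::runif(sum(!fwd), sep[!fwd],
                                 pmax(sep[!fwd] + 1, genome_len - rho)))
  gF <- gR + strand * sep
  strand_R <- strand
  strand_F <- if (library$type == "solid_mate") strand else -strand
  # background pairs: the second read lands anywhere, on a random strand
  # (spurious molecules carry no orientation information)
  nbg <- round(background_fraction * n_pairs)
  if (nbg > 0) {
    bg <- sample.int(n_pairs, nbg)
    gF[bg] <- floor(stats::runif(nbg, 0, genome_len - rho))
    strand_F[bg] <- sample(c(-1L, 1L), nbg, replace = TRUE)
  }
  pr <- .place_reads(gR, strand_R, truth, rho)
  pf <- .place_reads(gF, strand_F, truth, rho)
  keep <- !is.na(pr$contig) & !is.na(pf$contig)
  rid <- sprintf("p%06d_R", seq_len(n_pairs))
  fid <- sprintf("p%06d_F", seq_len(n_pairs))
  placements <- rbind(
    data.frame(read_id = rid[keep], contig_id = pr$contig[keep],
               offset = pr$offset[keep], tau = pr$tau[keep],
               stringsAsFactors = FALSE),
    data.frame(read_id = fid[keep], contig_id = pf$contig[keep],
               offset = pf$offset[keep], tau = pf$tau[keep],
               stringsAsFactors = FALSE))
  pairs <- data.frame(r_read = rid[keep], f_read = fid[keep],
                      library = library$name, stringsAsFactors = FALSE)
  truth_pairs <- data.frame(r_read = rid[keep], g_R = gR[keep], g_F = gF[keep],
                            strand = strand[keep],
                            background = seq_len(n_pairs)[keep] %in%
                              (if (nbg > 0) bg else integer(0)),
                            stringsAsFactors = FALSE)
  list(placements = placements, pairs = pairs, truth_pairs = truth_pairs)
}

#' Simulate a color-space contig with base suggestions
#'
#' Encodes the true sequence to colors, tiles it with reads at depth `d`, and
#' per read translates only the first color call to produce a base suggestion
#' at the read's start (the downstream translator never chains beyond that, so
#' color errors cannot propagate into the suggestions). Each color call is
#' flipped to a uniformly random wrong color with probability
#' `color_error_rate`, both in the suggestions and in the per-read calls that
#' form the consensus color sequence (majority per position; ties resolved to
#' the smallest tied color).
#'
#' @param sequence true base sequence.
#' @param d mean read depth.
#' @param read_len read length (in color calls).
#' @param color_error_rate per-call error probability in \[0, 1).
#' @param seed random seed.
#' @return a [color_contig()] with error rates from [default_error_rates()]
#'   (using `color_error_rate`, floored at 0.001, as the platform rate).
#' @export
corrupt_colorspace <- function(sequence, d, read_len = 25L,
                               color_error_rate = 0, seed = 1L) {
  stopifnot(color_error_rate >= 0, color_error_rate < 1)
  set.seed(seed)
  b <- strsplit(toupper(sequence), "")[[1]]
  n <- length(b)
  true_colors <- encode_colors(b)
  nc <- n - 1L
  rl <- min(read_len, nc)
  n_reads <- max(1L, round(d * nc / rl))
  starts <- sample.int(nc - rl + 1L, n_reads, replace = TRUE)  # 1-based color pos
  votes <- matrix(0L, 4L, nc, dimnames = list(0:3, NULL))
  f <- matrix(0L, 4L, n, dimnames = list(.BASES, NULL))
  for (r in seq_len(n_reads)) {
    s <- starts[r]
    calls <- true_colors[s:(s + rl - 1L)]
    err <- stats::runif(rl) < color_error_rate
    calls[err] <- (calls[err] + sample.int(3L, sum(err), replace = TRUE)) %% 4L
    votes[cbind(calls + 1L, s:(s + rl - 1L))] <-
      votes[cbind(calls + 1L, s:(s + rl - 1L))] + 1L
    # suggestion: primer base = true base at s, translated via first call
    sugg <- next_base(b[s], calls[1L])
    f[sugg, s + 1L] <- f[sugg, s + 1L] + 1L
  }
  consensus <- integer(nc)
  for (i in seq_len(nc)) {
    v <- votes[, i]
    if (sum(v) == 0L) consensus[i] <- true_colors[i]  # uncovered: keep truth
    else consensus[i] <- as.integer(names(v)[which.max(v)])
  }
  er <- default_error_rates(max(color_error_rate, 1e-3), d)
  color_contig(consensus, f, r_c = er$r_c, r_s = er$r_s)
}
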
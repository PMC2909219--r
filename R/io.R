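# On-disk formats: FASTA contigs/scaffolds (via Biostrings), TSV placements
# and pairs, DOT export of the connectivity graph, density-profile tables and
# a plain-text run log. Placement offsets are 0-based, half-open (BED-like):
# a placed read occupies [offset, offset + read_len).

#' Read scaffolder inputs
#'
#' @param contigs_path FASTA of contig sequences.
#' @param placements_path TSV with header
#'   `read_id  contig_id  offset  same_strand`: 0-based offset of the read's
#'   leftmost base in the contig; `same_strand` +1 if the read itself (not its
#'   reverse complement) was used in the contig, -1 otherwise.
#' @param pairs_path TSV with header `r_read_id  f_read_id  library_id`; for
#'   SOLiD libraries column 1 is the R3 read, for Illumina the read sequenced
#'   first.
#' @param config a [scaf_config()]; library ids are validated against it.
#' @return list with `contigs` (named character vector), `placements`,
#'   `pairs` (data frames as documented above, with `tau` for the strand
#'   column).
#' @export
read_inputs <- function(contigs_path, placements_path, pairs_path, config) {
  stopifnot(file.exists(contigs_path), file.exists(placements_path),
            file.exists(pairs_path))
  dss <- Biostrings::readDNAStringSet(contigs_path)
  contigs <- as.character(dss)
  names(contigs) <- sub("\\s.*$", "", names(dss))
  pl <- utils::read.delim(placements_path, stringsAsFactors = FALSE)
  need <- c("read_id", "contig_id", "offset", "same_strand")
  if (!all(need %in% names(pl)))
    stop("placements file must have columns: ", paste(need, collapse = ", "))
  if (anyNA(pl$offset) || !is.numeric(pl$offset))
    stop("parse error in placements: non-numeric offset")
  if (anyDuplicated(pl$read_id))
    stop("duplicate read id in placements: ",
         pl$read_id[duplicated(pl$read_id)][1])
  bad <- !(pl$contig_id %in% names(contigs))
  if (any(bad)) stop("placement references undeclared contig: ",
                     pl$contig_id[bad][1])
  if (any(pl$offset < 0 | pl$offset >= nchar(contigs)[match(pl$contig_id,
                                                            names(contigs))]))
    stop("placement offset outside contig bounds (offsets are 0-based)")
  if (!all(pl$same_strand %in% c(-1, 1)))
    stop("same_strand must be +1 or -1")
  placements <- data.frame(read_id = as.character(pl$read_id),
                           contig_id = as.character(pl$contig_id),
                           offset = as.integer(pl$offset),
                           tau = as.integer(pl$same_strand),
                           stringsAsFactors = FALSE)
  pr <- utils::read.delim(pairs_path, stringsAsFactors = FALSE)
  need <- c("r_read_id", "f_read_id", "library_id")
  if (!all(need %in% names(pr)))
    stop("pairs file must have columns: ", paste(need, collapse = ", "))
  known <- placements$read_id
  for (col in c("r_read_id", "f_read_id")) {
    miss <- !(pr[[col]] %in% known)
    if (any(miss)) stop("pair references undeclared read id: ",
                        pr[[col]][miss][1])
  }
  if (length(config$libraries) &&
      !all(pr$library_id %in% names(config$libraries)))
    stop("unknown library id: ",
         setdiff(pr$library_id, names(config$libraries))[1])
  pairs <- data.frame(r_read = as.character(pr$r_read_id),
                      f_read = as.character(pr$f_read_id),
                      library = as.character(pr$library_id),
                      stringsAsFactors = FALSE)
  list(contigs = contigs, placements = placements, pairs = pairs)
}

#' Write a connectivity graph as GraphViz DOT
#'
#' @param graph graph object from [build_graph()].
#' @param path output file.
#' @param all_edges include ignored edges (dashed) as well as retained ones.
#' @export
write_dot <- function(graph, path, all_edges = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("graph connectivity {", con)
  for (v in graph$vertices)
    writeLines(sprintf("  \"%s\";", v), con)
  e <- graph$edges
  if (!all_edges) e <- e[e$kept, , drop = FALSE]
  if (nrow(e))
    writeLines(sprintf("  \"%s\" -- \"%s\" [label=\"%d\"%s];",
                       e$ci, e$cj, e$J,
                       ifelse(e$kept, "", ", style=dashed")), con)
  writeLines("}", con)
  invisible(path)
}

#' Write pipeline outputs
#'
#' Emits the scaffold FASTA (gaps rendered as runs of 'N'), a FASTA of contigs
#' removed from scaffolding (reported as single contigs), the connectivity
#' graph in DOT, per-scaffold density profiles as TSV and a plain-text run
#' log.
#'
#' @param result value of [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return invisible character vector of written paths.
#' @export
write_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  sc <- result$scaffold_seqs
  fa <- file.path(out_dir, "scaffolds.fasta")
  if (length(sc) == 0) {
    writeLines(character(0), fa)
    warning("empty scaffold set; wrote empty FASTA")
  } else {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sc), fa)
  }
  paths <- c(paths, fa)
  rm_fa <- file.path(out_dir, "removed_contigs.fasta")
  rems <- result$singleton_seqs
  if (length(rems)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(rems), rm_fa)
  } else writeLines(character(0), rm_fa)
  paths <- c(paths, rm_fa)
  if (!is.null(result$graph)) {
    dot <- file.path(out_dir, "connectivity.dot")
    write_dot(result$graph, dot, all_edges = TRUE)
    paths <- c(paths, dot)
  }
  dp <- file.path(out_dir, "density_profiles.tsv")
  prof <- do.call(rbind, lapply(names(result$scaffolds), function(nm) {
    p <- density_profile(result$scaffolds[[nm]],
                         window = result$config$density_window)
    cbind(scaffold = nm, p)
  }))
  if (is.null(prof))
    prof <- data.frame(scaffold = character(), window = integer(),
                       start = numeric(), density = numeric())
  utils::write.table(prof, dp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, dp)
  logf <- file.path(out_dir, "run.log")
  writeLines(result$log, logf)
  paths <- c(paths, logf)
  invisible(paths)
}

#' Write placements/pairs TSVs in the dialect [read_inputs()] reads
#'
#' Convenience for round-tripping simulator output through the public
#' interface.
#'
#' @param sim value of [simulate_mate_pairs()].
#' @param contigs named character vector of contig sequences.
#' @param dir output directory.
#' @return list of the three file paths.
#' @export
write_sim_inputs <- function(sim, contigs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "contigs.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs), fa)
  pl <- file.path(dir, "placements.tsv")
  utils::write.table(
    data.frame(read_id = sim$placements$read_id,
               contig_id = sim$placements$contig_id,
               offset = sim$placements$offset,
               same_strand = sim$placements$tau),
    pl, sep = "\t", quote = FALSE, row.names = FALSE)
  pp <- file.path(dir, "pairs.tsv")
  utils::write.table(
    data.frame(r_read_id = sim$pairs$r_read, f_read_id = sim$pairs$f_read,
               library_id = sim$pairs$library),
    pp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(contigs = fa, placements = pl, pairs = pp)
}
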
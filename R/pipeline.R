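# End-to-end driver: preprocess -> connectivity graph -> [orient -> position
# -> prune]-loop -> segmentation -> finishing, with every input contig
# accounted for exactly once in the output (in a scaffold or as a single
# contig).

#' Run the full scaffolding pipeline
#'
#' @param contigs named character vector of contig sequences.
#' @param placements placement data frame (read_id, contig_id, offset, tau).
#' @param pairs pairs data frame (r_read, f_read, library).
#' @param config a [scaf_config()] with at least one library.
#' @param evaluate_truth optional truth data frame from
#'   [fragment_to_contigs()]; when given, an [error_report()] and
#'   [adjacency_recovery()] are attached.
#' @param genome_len genome length (only with `evaluate_truth`).
#' @return list: `scaffolds` (named list of layouts), `scaffold_seqs`,
#'   `singletons` + `singleton_seqs` (all contigs not in a scaffold, with the
#'   reason), `graph` (last connectivity graph), `insert_stats` (per
#'   library), `orientation`, `log`, `config`, and optionally `evaluation`.
#' @export
run_pipeline <- function(contigs, placements, pairs, config,
                         evaluate_truth = NULL, genome_len = NULL) {
  stopifnot(length(config$libraries) >= 1)
  set.seed(config$seed)
  logl <- c(sprintf("input: %d contigs, %d placements, %d pairs",
                    length(contigs), nrow(placements), nrow(pairs)))
  reasons <- stats::setNames(character(0), character(0))
  read_len <- max(vapply(config$libraries, `[[`, 0L, "read_len"))

  # --- preprocess -----------------------------------------------------------
  pt <- pair_table(placements, pairs)
  same <- pt[pt$ci == pt$cj, , drop = FALSE]
  insert_stats <- list()
  for (lb in config$libraries) {
    sl <- same[same$library == lb$name, , drop = FALSE]
    if (nrow(sl)) {
      sc <- same_contig_separation(sl, config$libraries)
      insert_stats[[lb$name]] <- estimate_insert_size(sc$separation,
                                                      lb$insert)
    } else {
      insert_stats[[lb$name]] <- list(mean = lb$insert, sd = lb$sd,
                                      n_retained = 0L, n_outliers = 0L)
    }
    logl <- c(logl, sprintf(
      "library %s: empirical insert %.1f (sd %.1f) from %d pairs",
      lb$name, insert_stats[[lb$name]]$mean, insert_stats[[lb$name]]$sd,
      insert_stats[[lb$name]]$n_retained))
  }
  emp_ins <- vapply(insert_stats, `[[`, 0, "mean")
  emp_sd <- vapply(insert_stats, `[[`, 0, "sd")
  main_lib <- config$libraries[[1]]
  sigma <- emp_sd[[main_lib$name]]
  if (sigma <= 0) sigma <- 0.2 * emp_ins[[main_lib$name]]

  # contig self-consistency; only meaningful for contigs long enough to host
  # typical inserts (shorter contigs see only the truncated left tail of the
  # separation distribution and would always look inconsistent)
  if (nrow(same)) {
    sc <- same_contig_separation(same, config$libraries)
    st_of <- insert_stats[[main_lib$name]]
    long_enough <- names(contigs)[nchar(contigs) >=
                                    1.5 * emp_ins[[main_lib$name]]]
    for (id in intersect(unique(sc$contig), long_enough)) {
      sel <- sc$contig == id
      if (!self_consistency_filter(sc$separation[sel], sc$orient_ok[sel],
                                   st_of,
                                   config$self_consistency_max_violations))
        reasons[id] <- "self_consistency"
    }
  }
  if (any(reasons == "self_consistency"))
    logl <- c(logl, sprintf("self-consistency check discarded %d contigs",
                            sum(reasons == "self_consistency")))

  # chimera splitting on surviving contigs
  ok_ids <- setdiff(names(contigs), names(reasons))
  split <- apply_chimera_splits(contigs[ok_ids], placements, pairs, read_len,
                                config$min_span, emp_ins[[main_lib$name]])
  work_contigs <- split$contigs
  placements <- split$placements
  if (length(split$cuts))
    logl <- c(logl, sprintf("chimera splitter cut %d contigs (%s)",
                            length(split$cuts),
                            paste(names(split$cuts), collapse = ",")))

  # coverage filter
  cf <- coverage_filter(work_contigs, placements, read_len,
                        config$mean_cov_factor, config$local_cov_factor,
                        config$cov_window)
  for (id in cf$removed_contigs) reasons[id] <- "high_coverage"
  if (length(cf$excluded_reads))
    placements <- placements[!(placements$read_id %in% cf$excluded_reads), ,
                             drop = FALSE]
  logl <- c(logl, sprintf(
    "coverage filter removed %d contigs, excluded %d reads",
    length(cf$removed_contigs), length(cf$excluded_reads)))

  eligible <- setdiff(names(work_contigs), names(reasons))
  lens_all <- nchar(work_contigs)
  short <- eligible[lens_all[eligible] < config$L]
  for (id in short) reasons[id] <- "below_min_length"
  eligible <- setdiff(eligible, short)

  # --- orient / position / prune loop --------------------------------------
  graph <- NULL; ori <- NULL
  comp_layouts <- list()
  dropped_edges <- character(0)   # "lo\rhi" keys of springs removed as spurious
  pt <- pair_table(placements, pairs)
  cross0 <- pt[pt$ci != pt$cj, , drop = FALSE]
  cons0 <- if (nrow(cross0))
    pair_constraints(cross0, lens_all, config$libraries, inserts = emp_ins)
  else NULL
  for (iter in seq_len(config$max_iterations)) {
    if (is.null(cons0)) break
    cons <- cons0[cons0$lo %in% eligible & cons0$hi %in% eligible &
                    !(paste(cons0$lo, cons0$hi, sep = "\r") %in%
                        dropped_edges), , drop = FALSE]
    if (nrow(cons) == 0) break
    graph <- build_graph(cons, lens_all[eligible], config$W, config$L,
                         config$majority_fraction,
                         outlier_cut = emp_ins[[main_lib$name]])
    ori <- assign_orientations(graph, config)
    e <- graph$edges
    use <- e$kept & !ori$violated
    ee <- e[use, , drop = FALSE]
    ee$w <- abs(ee$J)
    ee$d <- spring_lengths(ee, ori$S, graph$lens)
    support <- stats::setNames(numeric(length(graph$vertices)),
                               graph$vertices)
    for (side in c("ci", "cj")) {
      agg <- tapply(ee$w, ee[[side]], sum)
      support[names(agg)] <- support[names(agg)] + agg
    }
    ig <- igraph::graph_from_data_frame(ee[, c("ci", "cj")],
                                        directed = FALSE,
                                        vertices = graph$vertices)
    mem <- igraph::components(ig)$membership
    comp_layouts <- list()
    pruned <- character(0)
    cut_edges <- character(0)
    for (k in unique(mem)) {
      vs <- names(mem)[mem == k]
      if (length(vs) < 2) next
      sub_e <- ee[ee$ci %in% vs, , drop = FALSE]
      sol <- solve_spring(vs, sub_e)
      pr <- prune_stretched(sol, sub_e, sigma, config$delta_k,
                            config$delta_floor, support,
                            config$spurious_frac)
      if (length(pr$contigs) || length(pr$edges)) {
        pruned <- c(pruned, pr$contigs)
        cut_edges <- c(cut_edges, paste(sub_e$ci[pr$edges],
                                        sub_e$cj[pr$edges], sep = "\r"))
        next
      }
      comp_layouts[[length(comp_layouts) + 1L]] <-
        data.frame(contig = vs, x = sol$x[vs], S = ori$S[vs],
                   len = as.numeric(lens_all[vs]),
                   stringsAsFactors = FALSE)
    }
    if (length(pruned) || length(cut_edges)) {
      for (id in pruned) reasons[id] <- "stretched_spring"
      eligible <- setdiff(eligible, pruned)
      dropped_edges <- c(dropped_edges, cut_edges)
      logl <- c(logl, sprintf(
        "iteration %d: dropped %d spurious springs, removed %d contigs, restarting",
        iter, length(cut_edges), length(pruned)))
    } else {
      logl <- c(logl, sprintf(
        "iteration %d: all springs relaxed (energy %g, floor %g, %d violated edges)",
        iter, ori$energy, ori$E_min, sum(ori$violated)))
      break
    }
    if (iter == config$max_iterations)
      logl <- c(logl, "warning: max iterations reached with springs still stretched")
  }

  # --- segmentation ---------------------------------------------------------
  final_layouts <- list()
  if (length(comp_layouts)) {
    # mate-pair adjacency over all eligible contigs, from consistent edges
    ids <- eligible
    D <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
    if (!is.null(graph)) {
      e <- graph$edges
      use <- e$kept & !ori$violated & e$ci %in% ids & e$cj %in% ids
      if (any(use)) {
        D[cbind(e$ci[use], e$cj[use])] <- 1L
        D[cbind(e$cj[use], e$ci[use])] <- 1L
      }
    }
    for (l in comp_layouts) {
      seg <- resolve_tangles(l, D, ins = emp_ins[[main_lib$name]],
                             window = config$density_window,
                             threshold = config$density_threshold)
      final_layouts <- c(final_layouts, seg$scaffolds)
      for (id in seg$removed) reasons[id] <- "juncture"
      for (id in seg$singletons)
        if (!(id %in% names(reasons))) reasons[id] <- "unscaffolded"
      if (length(seg$removed))
        logl <- c(logl, sprintf("segmentation removed junctures: %s",
                                paste(seg$removed, collapse = ",")))
    }
  }

  # --- finishing ------------------------------------------------------------
  names(final_layouts) <- sprintf("scaffold%03d", seq_along(final_layouts))
  scaffold_seqs <- character(0)
  decisions <- list()
  for (nm in names(final_layouts)) {
    r <- render_scaffold(final_layouts[[nm]], work_contigs,
                         config$small_gap_cutoff, config$min_identity,
                         coverage = cf$mean_coverage)
    scaffold_seqs[[nm]] <- r$sequence
    decisions[[nm]] <- r$decisions
  }
  in_scaffold <- unlist(lapply(final_layouts, `[[`, "contig"))
  singles <- setdiff(names(work_contigs), in_scaffold)
  for (id in setdiff(singles, names(reasons))) reasons[id] <- "unscaffolded"
  logl <- c(logl, sprintf("output: %d scaffolds, %d single contigs",
                          length(final_layouts), length(singles)))

  out <- list(scaffolds = final_layouts, scaffold_seqs = scaffold_seqs,
              singletons = reasons[singles],
              singleton_seqs = work_contigs[singles],
              decisions = decisions,
              graph = graph, orientation = ori,
              insert_stats = insert_stats,
              log = logl, config = config)
  if (!is.null(evaluate_truth)) {
    out$evaluation <- error_report(final_layouts, singles, evaluate_truth,
                                   genome_len, lens_all)
    out$adjacency <- adjacency_recovery(final_layouts, evaluate_truth)
  }
  out
}
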
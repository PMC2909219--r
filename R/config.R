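#' Describe a mate-pair or paired-end library
#'
#' A library description carries the geometry the scaffolder needs: the
#' sequencing chemistry (SOLiD mate pairs are sequenced in the same direction
#' with the F3 read to the right of the R3 read; Illumina paired ends face each
#' other from opposite strands), the nominal insert size, and the read length.
#'
#' @param name library identifier, matched against the `library_id` column of
#'   the pairs file.
#' @param type `"solid_mate"` or `"illumina_pe"`.
#' @param insert nominal insert size in bases: the expected separation between
#'   the leftmost genome coordinates of the two reads of a pair.
#' @param sd optional prior standard deviation of the insert size; defaults to
#'   20% of the mean, the spread observed in real libraries.
#' @param read_len read length in bases.
#' @return a `scaf_library` list.
#' @export
scaf_library <- function(name, type = c("solid_mate", "illumina_pe"),
                         insert, sd = NULL, read_len = 35L) {
  type <- match.arg(type)
  stopifnot(is.character(name), length(name) == 1L, insert > 0, read_len > 0)
  if (is.null(sd)) sd <- 0.2 * insert
  stopifnot(sd >= 0)
  structure(list(name = name, type = type, insert = as.numeric(insert),
                 sd = as.numeric(sd), read_len = as.integer(read_len)),
            class = "scaf_library")
}

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the scaffolder with validated defaults.
#' The defaults for `W` (minimum number of mate pairs that must join two
#' contigs) and `L` (minimum contig length admitted to scaffolding) are
#' working values for bacterial-scale mate-pair data.
#'
#' @param libraries list of [scaf_library()] objects.
#' @param W minimum link count per retained edge of the connectivity graph.
#' @param L minimum contig length used in scaffold assembly.
#' @param majority_fraction minimum fraction of same-parity links for an edge
#'   to be kept; edges with a weaker majority are ignored entirely.
#' @param self_consistency_max_violations threshold of the contig
#'   self-consistency check. A value >= 1 is an absolute count of violating
#'   same-contig pairs; a value in (0, 1) is a fraction of that contig's
#'   same-contig pairs (the default 0.5 discards a contig only when a majority
#'   of its own pairs contradict it, which tolerates the ~1/3 of genuine pairs
#'   expected beyond one standard deviation under 20% insert-size noise).
#' @param min_span minimum number of spanning mate pairs below which a long
#'   contig is cut (chimera splitting).
#' @param mean_cov_factor,local_cov_factor,cov_window coverage-filter
#'   thresholds: contigs whose mean coverage exceeds `mean_cov_factor` times
#'   the median contig coverage are removed from scaffolding; reads in
#'   `cov_window`-base windows above `local_cov_factor` times the median are
#'   excluded from pairing.
#' @param delta_k spring-residual threshold factor: an edge is declared
#'   stretched when its residual exceeds `delta_k * sigma / sqrt(|J|)`.
#' @param delta_floor lower bound on the stretch threshold, as a multiple of
#'   sigma. Pairs able to bridge two contigs are a separation-biased sample,
#'   so the mean suggested separation of even a heavily linked edge carries a
#'   bias of a fraction of sigma that does not shrink with the link count.
#' @param spurious_frac a stretched spring carrying at most this fraction of
#'   each endpoint's total link weight is removed as a spurious constraint
#'   (background links); above it, the endpoint contigs themselves are
#'   removed (mis-assembled or repeat-like contig).
#' @param sa_T0,sa_alpha,sa_max_sweeps,sa_plateau,sa_T_floor simulated
#'   annealing schedule (initial temperature, exponential cooling factor per
#'   sweep, sweep cap, stop after this many sweeps without improvement,
#'   temperature floor). `sa_T0 = NULL` uses `2 * max|J|`.
#' @param layer_cap largest breadth-first layer for which the exact layered
#'   dynamic program is used; larger layers fall back to annealing.
#' @param density_window window (bases) of the contig density profile.
#' @param density_threshold density above which a window counts as overloaded.
#' @param small_gap_cutoff positional gaps below this many bases trigger an
#'   end-similarity test and possible contig join.
#' @param min_identity minimum identity for an end-similarity join.
#' @param max_iterations cap on the orient/position/prune loop.
#' @param seed random seed controlling every stochastic step.
#' @return a validated `scaf_config` list.
#' @export
scaf_config <- function(libraries = list(),
                        W = 5L, L = 150L, majority_fraction = 0.7,
                        self_consistency_max_violations = 0.5,
                        min_span = 3L,
                        mean_cov_factor = 2.5, local_cov_factor = 3,
                        cov_window = 100L,
                        delta_k = 5, delta_floor = 0.5, spurious_frac = 0.5,
                        sa_T0 = NULL, sa_alpha = 0.995,
                        sa_max_sweeps = 2000L, sa_plateau = 50L,
                        sa_T_floor = 1e-3,
                        layer_cap = 6L,
                        density_window = 1000L, density_threshold = 1.5,
                        small_gap_cutoff = 10L, min_identity = 0.9,
                        max_iterations = 20L,
                        seed = 1L) {
  if (inherits(libraries, "scaf_library")) libraries <- list(libraries)
  stopifnot(W >= 1, L >= 0,
            majority_fraction > 0.5, majority_fraction <= 1,
            self_consistency_max_violations > 0,
            min_span >= 1, mean_cov_factor > 0, local_cov_factor > 0,
            cov_window >= 1, delta_k > 0, delta_floor >= 0,
            spurious_frac >= 0, spurious_frac < 1,
            sa_alpha > 0, sa_alpha < 1, sa_max_sweeps >= 1,
            sa_plateau >= 1, sa_T_floor > 0, layer_cap >= 1,
            density_window >= 1, density_threshold > 1,
            small_gap_cutoff >= 0, min_identity > 0, min_identity <= 1,
            max_iterations >= 1)
  for (lb in libraries) stopifnot(inherits(lb, "scaf_library"))
  names(libraries) <- vapply(libraries, `[[`, "", "name")
  structure(list(libraries = libraries, W = as.integer(W), L = as.integer(L),
                 majority_fraction = majority_fraction,
                 self_consistency_max_violations = self_consistency_max_violations,
                 min_span = as.integer(min_span),
                 mean_cov_factor = mean_cov_factor,
                 local_cov_factor = local_cov_factor,
                 cov_window = as.integer(cov_window),
                 delta_k = delta_k, delta_floor = delta_floor,
                 spurious_frac = spurious_frac,
                 sa_T0 = sa_T0, sa_alpha = sa_alpha,
                 sa_max_sweeps = as.integer(sa_max_sweeps),
                 sa_plateau = as.integer(sa_plateau),
                 sa_T_floor = sa_T_floor,
                 layer_cap = as.integer(layer_cap),
                 density_window = as.integer(density_window),
                 density_threshold = density_threshold,
                 small_gap_cutoff = as.integer(small_gap_cutoff),
                 min_identity = min_identity,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "scaf_config")
}
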
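#' Simulation configuration for the synthetic-data generator
#'
#' Bundles every knob of the ground-truth simulator: the redundant
#' transcript pool (gene families with mutated, truncated, UTR-flanked and
#' isoform copies), the four-stage negative-binomial count matrix with
#' planted fold-changes, the polymorphism pool, and the GO annotation
#' fixture.  Defaults describe a small but realistic larval RNA-seq study:
#' four developmental stages with the blastula as reference, well-expressed
#' transcripts (500 expected read pairs per stage), edgeR-style dispersion
#' 0.1 (variance \eqn{\mu + \phi \mu^2}), a quarter of genes perturbed
#' 8-fold at one stage, and a variant pool at 30 SNVs/kb with a
#' transition/transversion ratio of 1.5.
#'
#' @param seed Integer seed; identical configurations give byte-identical
#'   output.
#' @param n_genes Number of gene families.
#' @param gene_length Length of each full-length reference CDS, nt.
#' @param copies_per_gene Redundant copies generated per gene on top of the
#'   full-length reference.
#' @param isoform_rate Probability that a copy is an isoform (an internal
#'   block is spliced out) rather than a redundant fragment.
#' @param point_mutation_rate Per-base substitution rate applied to copies.
#' @param truncation_fraction Maximum total fraction of a copy's length
#'   removed from its ends.
#' @param utr_noise_len Maximum length of the random UTR-like flank added
#'   to each end of a copy, nt.
#' @param stages Ordered character vector of stage names; the first is the
#'   reference stage for differential expression.
#' @param baseline_mean Expected read-pair count per gene and stage.
#' @param dispersion Negative-binomial dispersion \eqn{\phi};
#'   variance \eqn{= \mu + \phi\mu^2}.
#' @param de_fraction Fraction of genes receiving a planted fold-change at
#'   one non-reference stage.
#' @param fold_change Planted fold-change (> 1); applied as multiplication
#'   or division with equal probability.
#' @param snv_density Expected variants per kilobase.
#' @param tstv_ratio Transition/transversion ratio among simulated SNVs.
#' @param indel_fraction Fraction of variants that are indels.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 5)
#' cfg$dispersion
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       gene_length = 1000L,
                       copies_per_gene = 3L,
                       isoform_rate = 0.2,
                       point_mutation_rate = 0.01,
                       truncation_fraction = 0.2,
                       utr_noise_len = 100L,
                       stages = c("blastula", "gastrula",
                                  "auricularia", "pentactula"),
                       baseline_mean = 500,
                       dispersion = 0.1,
                       de_fraction = 0.25,
                       fold_change = 8,
                       snv_density = 30,
                       tstv_ratio = 1.5,
                       indel_fraction = 0.05) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              copies_per_gene = as.integer(copies_per_gene),
              isoform_rate = isoform_rate,
              point_mutation_rate = point_mutation_rate,
              truncation_fraction = truncation_fraction,
              utr_noise_len = as.integer(utr_noise_len),
              stages = as.character(stages),
              baseline_mean = baseline_mean,
              dispersion = dispersion,
              de_fraction = de_fraction,
              fold_change = fold_change,
              snv_density = snv_density,
              tstv_ratio = tstv_ratio,
              indel_fraction = indel_fraction)
  for (f in c("isoform_rate", "point_mutation_rate", "truncation_fraction",
              "de_fraction", "indel_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("'", f, "' must be a fraction in [0, 1]", call. = FALSE)
  }
  if (cfg$n_genes < 1L) stop("'n_genes' must be >= 1", call. = FALSE)
  if (cfg$gene_length < 300L)
    stop("'gene_length' must be >= 300 nt", call. = FALSE)
  if (cfg$dispersion <= 0) stop("'dispersion' must be > 0", call. = FALSE)
  if (cfg$fold_change <= 1) stop("'fold_change' must be > 1", call. = FALSE)
  if (cfg$snv_density < 0) stop("'snv_density' must be >= 0", call. = FALSE)
  if (cfg$tstv_ratio <= 0) stop("'tstv_ratio' must be > 0", call. = FALSE)
  if (anyDuplicated(cfg$stages)) stop("stage names must be unique",
                                      call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Differential-expression parameters
#'
#' Thresholds of the stage-wise DE caller: fixed negative-binomial
#' dispersion, fold-change and adjusted-p cutoffs, and the two expression
#' pre-filters (total mapped read pairs, and enough read bases for a
#' minimum fold-coverage of the transcript).
#'
#' @param dispersion Fixed NB dispersion \eqn{\phi} used by the exact test.
#' @param fold_threshold Minimum fold-change called differential
#'   (applied two-sided on \eqn{|log2 FC| \ge log2(F)}).
#' @param alpha Adjusted-p cutoff.
#' @param min_pairs A gene must have strictly more than this many mapped
#'   read pairs summed over stages.
#' @param coverage_multiple Summed read bases must cover every nucleotide
#'   of the transcript at least this many times.
#'
#' @return An object of class `de_params`.
#' @export
de_params <- function(dispersion = 0.1, fold_threshold = 2, alpha = 0.05,
                      min_pairs = 20, coverage_multiple = 10) {
  if (dispersion <= 0) stop("'dispersion' must be > 0", call. = FALSE)
  if (fold_threshold <= 1) stop("'fold_threshold' must be > 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)",
                                     call. = FALSE)
  structure(list(dispersion = dispersion, fold_threshold = fold_threshold,
                 alpha = alpha, min_pairs = min_pairs,
                 coverage_multiple = coverage_multiple),
            class = "de_params")
}

#' Clustering parameters (identity / coverage of the shorter sequence)
#'
#' Mirrors the CD-HIT-EST convention: a sequence joins a cluster when its
#' best alignment to the representative reaches global identity `identity_c`
#' (`-c`) and covers at least `coverage_aS` (`-aS`) of the shorter
#' sequence; `min_aln_len` (`-A`, 0 = unused) additionally requires an
#' absolute aligned length.
#'
#' @param identity_c Identity threshold in (0, 1].
#' @param coverage_aS Minimum aligned fraction of the shorter sequence.
#' @param min_aln_len Minimum alignment length in nt; 0 disables.
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(identity_c, coverage_aS, min_aln_len = 0L) {
  if (identity_c <= 0 || identity_c > 1)
    stop("'identity_c' must be in (0, 1]", call. = FALSE)
  if (coverage_aS < 0 || coverage_aS > 1)
    stop("'coverage_aS' must be in [0, 1]", call. = FALSE)
  structure(list(identity_c = identity_c, coverage_aS = coverage_aS,
                 min_aln_len = as.integer(min_aln_len)),
            class = "cluster_params")
}

#' End-overlap merging parameters
#'
#' @param min_overlap Minimum end-overlap length, nt.
#' @param overlap_identity Minimum identity within the overlap.
#' @param max_clip Maximum number of terminal bases that may be clipped
#'   from either sequence when seeking an overlap.
#' @return An object of class `merge_params`.
#' @export
merge_params <- function(min_overlap = 21L, overlap_identity = 0.99,
                         max_clip = 0L) {
  if (min_overlap < 1) stop("'min_overlap' must be >= 1", call. = FALSE)
  if (overlap_identity <= 0 || overlap_identity > 1)
    stop("'overlap_identity' must be in (0, 1]", call. = FALSE)
  structure(list(min_overlap = as.integer(min_overlap),
                 overlap_identity = overlap_identity,
                 max_clip = as.integer(max_clip)),
            class = "merge_params")
}

#' Redundancy-reduction schedule
#'
#' An ordered list of rounds, each a greedy clustering pass followed by
#' within-cluster end-overlap merging, then a final relaxed-coverage
#' clustering pass that groups the surviving contigs into genes (isoform
#' grouping).  The default is the declining-identity schedule
#' (0.95, 0.90) then (0.90, 0.80) then (0.80, 0.80), with a strict
#' 99%-identity merge in the first round and 80% thereafter, and isoform
#' grouping at (0.95, 0.5) with a 120-nt minimum alignment.
#'
#' @param rounds List of rounds; each round is a list with elements
#'   `cluster` (a [cluster_params()]) and `merge_identity` (the overlap
#'   identity used for merging within that round's clusters).
#' @param isoform A [cluster_params()] used for the final gene grouping.
#' @return An object of class `reduction_schedule`.
#' @export
reduction_schedule <- function(rounds = list(
                                 list(cluster = cluster_params(0.95, 0.90),
                                      merge_identity = 0.99),
                                 list(cluster = cluster_params(0.90, 0.80),
                                      merge_identity = 0.80),
                                 list(cluster = cluster_params(0.80, 0.80),
                                      merge_identity = 0.80)),
                               isoform = cluster_params(0.95, 0.5, 120L)) {
  ids <- vapply(rounds, function(r) r$cluster$identity_c, numeric(1))
  if (is.unsorted(rev(ids)))
    stop("cluster identity thresholds must be non-increasing across rounds",
         call. = FALSE)
  structure(list(rounds = rounds, isoform = isoform),
            class = "reduction_schedule")
}
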
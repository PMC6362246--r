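## Ground-truth simulator: every input the pipeline consumes can be
## generated here with a known answer.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a redundant transcript pool with known gene structure
#'
#' Emulates the raw contig pool of a fragmented de novo assembly: each
#' gene family contributes one full-length reference plus
#' `copies_per_gene` redundant copies carrying point mutations, end
#' truncations, random UTR-like flanks, and (at `isoform_rate`) an
#' internal splice-like deletion.
#'
#' @param config A [sim_config()].
#' @return A list with `transcripts` (named character vector) and `truth`
#'   (data frame: `contig_id`, `gene_id`, `role` in `full_length`,
#'   `truncated_copy`, `utr_variant`, `isoform`).
#' @export
generate_redundant_transcripts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seqs <- character(0)
  truth <- list()
  for (g in seq_len(config$n_genes)) {
    gene <- sprintf("gene%03d", g)
    ref <- random_dna(config$gene_length)
    rid <- paste0(gene, "_ref")
    seqs[[rid]] <- ref
    truth[[rid]] <- c(rid, gene, "full_length")
    for (cp in seq_len(config$copies_per_gene)) {
      s <- mutate_seq(ref, config$point_mutation_rate)
      role <- "full_length"
      if (stats::runif(1) < config$isoform_rate) {
        # splice out an internal block of 10-30% of the length
        L <- nchar(s)
        blk <- round(stats::runif(1, 0.1, 0.3) * L)
        at <- sample(seq.int(round(0.2 * L), round(0.8 * L) - blk), 1L)
        s <- paste0(substr(s, 1L, at - 1L), substr(s, at + blk, L))
        role <- "isoform"
      }
      cut5 <- round(stats::runif(1, 0, config$truncation_fraction / 2) *
                      nchar(s))
      cut3 <- round(stats::runif(1, 0, config$truncation_fraction / 2) *
                      nchar(s))
      if (cut5 + cut3 > 0) {
        s <- substr(s, cut5 + 1L, nchar(s) - cut3)
        if (role == "full_length") role <- "truncated_copy"
      }
      if (config$utr_noise_len > 0) {
        f5 <- sample(0:config$utr_noise_len, 1L)
        f3 <- sample(0:config$utr_noise_len, 1L)
        if (f5 + f3 > 0) {
          s <- paste0(if (f5 > 0) random_dna(f5) else "", s,
                      if (f3 > 0) random_dna(f3) else "")
          if (role == "full_length") role <- "utr_variant"
        }
      }
      cid <- sprintf("%s_copy%02d", gene, cp)
      seqs[[cid]] <- s
      truth[[cid]] <- c(cid, gene, role)
    }
  }
  truth <- as.data.frame(do.call(rbind, truth), stringsAsFactors = FALSE)
  names(truth) <- c("contig_id", "gene_id", "role")
  rownames(truth) <- NULL
  list(transcripts = seqs, truth = truth)
}

#' Spike contaminant contigs into a transcript set
#'
#' Adds `n` random-composition contigs and builds the matching synthetic
#' similarity-hit table: each contaminant gets a non-target best hit with
#' coverage above 0.7 and identity above 80, and every host contig gets a
#' target-clade hit.
#'
#' @param tset Named character vector of host contigs.
#' @param n Number of contaminants (>= 0).
#' @param seed Integer seed.
#' @return A list with `transcripts` (host + contaminants), `hits` (hit
#'   data frame as consumed by [classify_contig()]), and
#'   `contaminant_ids`.
#' @export
spike_contaminants <- function(tset, n, seed = 1L) {
  if (n < 0) stop("'n' must be >= 0", call. = FALSE)
  set.seed(seed)
  seqs <- as_seqchar(tset)
  host_hits <- if (length(seqs) > 0) data.frame(
    query_id = names(seqs),
    subject_id = paste0("target_prot_", seq_along(seqs)),
    subject_group = "target_clade",
    percent_identity = round(stats::runif(length(seqs), 60, 95), 1),
    query_coverage = round(stats::runif(length(seqs), 0.4, 0.95), 3),
    bitscore = round(stats::runif(length(seqs), 100, 800), 1),
    evalue = 10^-stats::runif(length(seqs), 10, 100),
    stringsAsFactors = FALSE) else NULL
  contam_ids <- character(0)
  contam_hits <- NULL
  if (n > 0) {
    contam_ids <- sprintf("contam%02d", seq_len(n))
    for (id in contam_ids) seqs[[id]] <- random_dna(sample(400:1200, 1L))
    contam_hits <- data.frame(
      query_id = contam_ids,
      subject_id = paste0("bacterial_prot_", seq_len(n)),
      subject_group = "other",
      percent_identity = round(stats::runif(n, 85, 99), 1),
      query_coverage = round(stats::runif(n, 0.75, 0.95), 3),
      bitscore = round(stats::runif(n, 200, 900), 1),
      evalue = 10^-stats::runif(n, 20, 120),
      stringsAsFactors = FALSE)
  }
  list(transcripts = seqs, hits = rbind(host_hits, contam_hits),
       contaminant_ids = contam_ids)
}

#' Simulate a stage count matrix with planted fold-changes
#'
#' Counts are drawn from a negative binomial with mean \eqn{\mu_{gs}} and
#' dispersion \eqn{\phi} (variance \eqn{\mu + \phi\mu^2}).  For
#' `de_fraction` of genes, the mean at one randomly chosen non-reference
#' stage is multiplied or divided (equal probability) by `fold_change`.
#'
#' @param config A [sim_config()]; needs at least 2 stages.
#' @return A list with `cm` (a [count_matrix()]) and `truth` (data frame:
#'   `gene`, `stage`, `direction` in `up`/`down` for the planted genes).
#' @export
simulate_stage_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$stages) < 2L)
    stop("need at least 2 stages", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("gene%05d", seq_len(n))
  lengths <- setNames(sample(500:2000, n, replace = TRUE), genes)
  mu <- matrix(config$baseline_mean, n, length(config$stages),
               dimnames = list(genes, config$stages))
  nde <- round(config$de_fraction * n)
  truth <- data.frame(gene = character(0), stage = character(0),
                      direction = character(0), stringsAsFactors = FALSE)
  if (nde > 0) {
    planted <- sample(genes, nde)
    stage <- sample(config$stages[-1L], nde, replace = TRUE)
    up <- sample(c(TRUE, FALSE), nde, replace = TRUE)
    for (i in seq_len(nde)) {
      mu[planted[i], stage[i]] <- mu[planted[i], stage[i]] *
        if (up[i]) config$fold_change else 1 / config$fold_change
    }
    truth <- data.frame(gene = planted, stage = stage,
                        direction = ifelse(up, "up", "down"),
                        stringsAsFactors = FALSE)
  }
  counts <- matrix(stats::rnbinom(length(mu), size = 1 / config$dispersion,
                                  mu = mu),
                   n, length(config$stages),
                   dimnames = dimnames(mu))
  list(cm = count_matrix(counts, lengths), truth = truth)
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

#' Simulate a variant table over a set of contigs
#'
#' Per-contig variant counts are Poisson with mean
#' `length/1000 * snv_density`.  Each variant is an indel with
#' probability `indel_fraction`; otherwise it is a transition with
#' probability `tstv_ratio / (1 + tstv_ratio)`.  Positions are unique per
#' contig; DP is drawn uniformly on 5..100 and MQ uniformly on
#' \[20, 60\].
#'
#' @param contigs Named character vector of contig sequences.
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to the config seed).
#' @param population Population label attached to every record.
#' @return Variant data frame: `contig`, `pos` (1-based), `ref`, `alt`,
#'   `population`, `dp`, `mq`.
#' @export
simulate_variants <- function(contigs, config, seed = config$seed,
                              population = "all") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  seqs <- as_seqchar(contigs)
  rows <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    L <- nchar(s)
    nv <- stats::rpois(1, L / 1000 * config$snv_density)
    nv <- min(nv, L - 1L)  # unique positions, deletions need pos < L
    if (nv == 0L) next
    pos <- sort(sample.int(L - 1L, nv))
    base <- substring(s, pos, pos)
    is_indel <- stats::runif(nv) < config$indel_fraction
    is_ts <- stats::runif(nv) < config$tstv_ratio / (1 + config$tstv_ratio)
    ref <- base; alt <- base
    for (i in seq_len(nv)) {
      if (is_indel[i]) {
        if (stats::runif(1) < 0.5) {           # insertion
          alt[i] <- paste0(base[i], sample(c("A", "C", "G", "T"), 1L))
        } else {                               # deletion of next base
          ref[i] <- substr(s, pos[i], pos[i] + 1L)
        }
      } else if (is_ts[i]) {
        alt[i] <- TRANSITION[[base[i]]]
      } else {
        alt[i] <- sample(TRANSVERSIONS[[base[i]]], 1L)
      }
    }
    rows[[id]] <- data.frame(
      contig = id, pos = pos, ref = ref, alt = alt,
      population = population,
      dp = sample(5:100, nv, replace = TRUE),
      mq = round(stats::runif(nv, 20, 60), 2),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      population = character(0), dp = integer(0),
                      mq = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Generate a GO annotation fixture with one planted enriched term
#'
#' Background terms are assigned uniformly at random; the planted term is
#' additionally assigned to every planted gene.  A minimal ontology table
#' containing every used term is emitted alongside.
#'
#' @param genes Character vector of gene ids.
#' @param n_terms Number of background terms.
#' @param terms_per_gene Background terms drawn per gene.
#' @param planted_term Term id planted in `planted_genes` (`NULL` for
#'   none).
#' @param planted_genes Subset of `genes` receiving the planted term.
#' @param seed Integer seed.
#' @return A list with `annotation` (data frame `gene`, `term`) and
#'   `terms` (data frame `term`, `name`, `namespace`).
#' @export
generate_annotation <- function(genes, n_terms = 50, terms_per_gene = 3,
                                planted_term = NULL,
                                planted_genes = character(0), seed = 1L) {
  if (!all(planted_genes %in% genes))
    stop("planted genes must be a subset of 'genes'", call. = FALSE)
  set.seed(seed)
  background <- sprintf("GO:%07d", seq_len(n_terms))
  ann <- NULL
  if (terms_per_gene > 0 && length(genes) > 0) {
    ann <- do.call(rbind, lapply(genes, function(g) {
      data.frame(gene = g,
                 term = sample(background, min(terms_per_gene, n_terms)),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(planted_term) && length(planted_genes) > 0)
    ann <- rbind(ann, data.frame(gene = planted_genes,
                                 term = planted_term,
                                 stringsAsFactors = FALSE))
  if (is.null(ann))
    ann <- data.frame(gene = character(0), term = character(0),
                      stringsAsFactors = FALSE)
  ann <- unique(ann[order(ann$gene, ann$term), , drop = FALSE])
  rownames(ann) <- NULL
  used <- sort(unique(ann$term))
  terms <- data.frame(term = used,
                      name = sprintf("synthetic process %d",
                                     seq_along(used)),
                      namespace = rep("biological_process", length(used)),
                      stringsAsFactors = FALSE)
  list(annotation = ann, terms = terms)
}
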
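#' Hypergeometric GO-term enrichment without ancestor propagation
#'
#' One row per term directly annotated to at least one test-set gene.
#' Counts use direct annotations only (no propagation up the ontology
#' graph; term definitions are used solely for names and namespaces).
#' For a term with `k_ref` annotated genes among the `n_ref` reference
#' genes and `k_test` among the `n_test` test genes, the enrichment ratio
#' is `(k_test/n_test) / (k_ref/n_ref)` and the p-value the hypergeometric
#' upper tail \eqn{P[X \ge k_{test}]}.  A BH-adjusted column is reported
#' for information but is not used by [filter_terms()].
#'
#' @param test Character vector of test-set gene ids; must be a subset of
#'   `reference`.
#' @param reference Character vector of reference gene ids (non-empty);
#'   typically all DEGs.
#' @param ann An annotation object as returned by [generate_annotation()]
#'   or [read_annotation()]: a list with `annotation` (data frame `gene`,
#'   `term`) and `terms` (data frame `term`, `name`, `namespace`).
#' @return Data frame with columns `term`, `name`, `k_test`, `n_test`,
#'   `k_ref`, `n_ref`, `ratio`, `p_value`, `p_adjusted`, ordered by
#'   `p_value` then term.
#' @export
go_enrich <- function(test, reference, ann) {
  if (length(reference) == 0L) stop("reference set is empty", call. = FALSE)
  if (!all(test %in% reference))
    stop("test set must be a subset of the reference set", call. = FALSE)
  a <- ann$annotation
  a <- a[a$gene %in% reference, , drop = FALSE]
  a <- unique(a[, c("gene", "term")])
  n_test <- length(unique(test))
  n_ref <- length(unique(reference))
  in_test <- a$gene %in% test
  terms <- sort(unique(a$term[in_test]))
  if (length(terms) == 0L)
    return(data.frame(term = character(0), name = character(0),
                      k_test = integer(0), n_test = integer(0),
                      k_ref = integer(0), n_ref = integer(0),
                      ratio = numeric(0), p_value = numeric(0),
                      p_adjusted = numeric(0), stringsAsFactors = FALSE))
  k_test <- vapply(terms, function(t) sum(a$term == t & in_test),
                   integer(1))
  k_ref <- vapply(terms, function(t) sum(a$term == t), integer(1))
  p <- stats::phyper(k_test - 1L, k_ref, n_ref - k_ref, n_test,
                     lower.tail = FALSE)
  name <- ann$terms$name[match(terms, ann$terms$term)]
  res <- data.frame(term = terms, name = name, k_test = k_test,
                    n_test = n_test, k_ref = k_ref, n_ref = n_ref,
                    ratio = (k_test / n_test) / (k_ref / n_ref),
                    p_value = p, p_adjusted = bh_adjust(p),
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter enrichment rows by count and ratio
#'
#' Removes terms supported by fewer than `min_count` test-set sequences
#' or with an enrichment ratio lower than `min_ratio` (both bounds
#' inclusive on the kept side).
#'
#' @param rows Enrichment data frame from [go_enrich()].
#' @param min_count Minimum `k_test` kept (default 5).
#' @param min_ratio Minimum ratio kept (default 1.5).
#' @return Filtered data frame.
#' @export
filter_terms <- function(rows, min_count = 5, min_ratio = 1.5) {
  rows[rows$k_test >= min_count & rows$ratio >= min_ratio, , drop = FALSE]
}

#' Stage-predominance test set
#'
#' The DEGs whose TPM at the given stage is strictly greater than their
#' mean TPM over all stages and strictly greater than 1.
#'
#' @param tpm Numeric TPM matrix, genes x stages.
#' @param degs Character vector of DEG ids.
#' @param stage Stage (column) name.
#' @return Character vector of gene ids.
#' @export
stage_test_set <- function(tpm, degs, stage) {
  tpm <- as.matrix(tpm)
  if (!stage %in% colnames(tpm)) stop("unknown stage: ", stage,
                                      call. = FALSE)
  degs <- intersect(degs, rownames(tpm))
  x <- tpm[degs, , drop = FALSE]
  degs[x[, stage] > rowMeans(x) & x[, stage] > 1]
}

#' Rank terms by total TPM at a stage
#'
#' Scores each (already filtered) term by the summed stage TPM of the
#' test-set genes directly annotated with it, and returns the `top_k`
#' highest-scoring terms in descending order (ties by term id).
#'
#' @param rows Filtered enrichment data frame.
#' @param ann Annotation object (see [go_enrich()]).
#' @param tpm Numeric TPM matrix.
#' @param test_set Character vector of test-set gene ids.
#' @param stage Stage name.
#' @param top_k Number of terms returned (default 10).
#' @return Data frame `term`, `name`, `tpm_total`, at most `top_k` rows.
#' @export
rank_predominant_terms <- function(rows, ann, tpm, test_set, stage,
                                   top_k = 10) {
  tpm <- as.matrix(tpm)
  a <- unique(ann$annotation[, c("gene", "term")])
  a <- a[a$gene %in% test_set & a$term %in% rows$term, , drop = FALSE]
  score <- vapply(rows$term, function(t) {
    g <- intersect(a$gene[a$term == t], rownames(tpm))
    sum(tpm[g, stage])
  }, numeric(1))
  o <- order(-score, rows$term)
  res <- data.frame(term = rows$term[o], name = rows$name[o],
                    tpm_total = score[o], stringsAsFactors = FALSE)
  utils::head(res, top_k)
}
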
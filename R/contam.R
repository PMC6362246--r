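#' Classify a contig as contaminant or host from its similarity hits
#'
#' A contig is dropped only when all three conditions hold for its hits:
#' the best hit (highest bitscore; ties by lowest e-value, then subject
#' id) is to a non-target taxon (`subject_group == "other"`), that hit
#' covers strictly more than `cov_min` of the query at strictly more than
#' `ident_min` percent identity, and no hit in the list is against the
#' host genome (`subject_group == "host_genome"`).
#'
#' @param hits Data frame of hits for one query, with columns `query_id`,
#'   `subject_id`, `subject_group` (one of `target_clade`, `host_genome`,
#'   `other`), `percent_identity` (0-100), `query_coverage` (0-1),
#'   `bitscore`, `evalue`.
#' @param cov_min Coverage threshold (strict, default 0.70).
#' @param ident_min Percent-identity threshold (strict, default 80).
#' @return A list with `decision` (`"keep"` or `"drop"`), `reason`, and
#'   `best_hit` (a one-row data frame, or `NULL` without hits).
#' @export
classify_contig <- function(hits, cov_min = 0.70, ident_min = 80) {
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(decision = "keep", reason = "no_evidence", best_hit = NULL))
  if (length(unique(hits$query_id)) != 1L)
    stop("hits must all share one query_id", call. = FALSE)
  o <- order(-hits$bitscore, hits$evalue, hits$subject_id)
  best <- hits[o[1L], , drop = FALSE]
  has_host <- any(hits$subject_group == "host_genome")
  if (best$subject_group == "other" &&
      best$query_coverage > cov_min &&
      best$percent_identity > ident_min &&
      !has_host)
    return(list(decision = "drop", reason = "contaminant_best_hit",
                best_hit = best))
  reason <- if (best$subject_group != "other") "best_hit_in_target"
            else if (has_host) "host_genome_hit"
            else if (best$query_coverage <= cov_min) "coverage_below_min"
            else "identity_below_min"
  list(decision = "keep", reason = reason, best_hit = best)
}

#' Remove contaminant contigs from a transcript set
#'
#' Applies [classify_contig()] per contig.  Hit rows referencing contigs
#' absent from the set raise a warning and are ignored; contigs without
#' hits are kept.
#'
#' @param tset Named character vector or `DNAStringSet` of contigs.
#' @param hits Hit data frame (see [classify_contig()]) covering any
#'   subset of the contigs.
#' @param cov_min,ident_min Thresholds passed to [classify_contig()].
#' @return A list with `kept` (same container type as a character vector),
#'   and `report` (data frame: `contig_id`, `decision`, `reason`, plus the
#'   triggering hit's subject, coverage and identity for dropped contigs).
#' @export
filter_contaminants <- function(tset, hits, cov_min = 0.70, ident_min = 80) {
  seqs <- as_seqchar(tset)
  ids <- names(seqs)
  unknown <- setdiff(unique(hits$query_id), ids)
  if (length(unknown) > 0L) {
    warning("ignoring hits for unknown contigs: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    hits <- hits[!hits$query_id %in% unknown, , drop = FALSE]
  }
  report <- do.call(rbind, lapply(ids, function(id) {
    cl <- classify_contig(hits[hits$query_id == id, , drop = FALSE],
                          cov_min, ident_min)
    data.frame(contig_id = id, decision = cl$decision, reason = cl$reason,
               subject_id = if (is.null(cl$best_hit)) NA_character_
                            else cl$best_hit$subject_id,
               query_coverage = if (is.null(cl$best_hit)) NA_real_
                                else cl$best_hit$query_coverage,
               percent_identity = if (is.null(cl$best_hit)) NA_real_
                                  else cl$best_hit$percent_identity,
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  list(kept = seqs[report$decision == "keep"], report = report)
}
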
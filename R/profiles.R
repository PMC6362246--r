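#' Stage-expression profiles from a TPM matrix
#'
#' log2(TPM + 1), median-centered per gene.  Stage order is taken from the
#' TPM column order and is fixed pipeline-wide.
#'
#' @param tpm Numeric matrix, genes x stages.
#' @return Numeric matrix of normalized profiles.
#' @export
expression_profiles <- function(tpm) {
  x <- log2(as.matrix(tpm) + 1)
  sweep(x, 1, apply(x, 1, stats::median), "-")
}

profile_cluster_set <- function(assignment, profiles) {
  assignment <- assignment[order(names(assignment))]
  cl_ids <- sort(unique(assignment))
  means <- t(vapply(cl_ids, function(cl) {
    colMeans(profiles[names(assignment)[assignment == cl], , drop = FALSE])
  }, numeric(ncol(profiles))))
  rownames(means) <- cl_ids
  structure(list(assignment = assignment, means = means,
                 retained = setNames(rep(TRUE, length(cl_ids)),
                                     as.character(cl_ids))),
            class = "profile_clusters")
}

# correlation distance with the zero-variance convention: a constant
# profile has zero correlation with everything (distance 1)
cor_dist <- function(profiles) {
  r <- suppressWarnings(stats::cor(t(profiles)))
  r[is.na(r)] <- 0
  diag(r) <- 1
  1 - r
}

#' Cluster expression profiles at a matching threshold
#'
#' Hierarchical clustering with distance 1 - Pearson correlation and
#' average linkage.  At the default interpretation (`cut = "height"`) the
#' tree is cut at `(1 - match_threshold)` times the maximum merge height;
#' `cut = "correlation"` instead cuts at absolute height
#' `1 - match_threshold` (a minimum-correlation reading of the same
#' threshold).  Genes are ordered by id before clustering so the result
#' is invariant to input order.
#'
#' @param profiles Numeric matrix, genes x stages (see
#'   [expression_profiles()]); at least 2 stages.
#' @param match_threshold Profile-matching threshold in \[0, 1\]
#'   (default 0.80).
#' @param cut Threshold interpretation, `"height"` or `"correlation"`.
#' @return An object of class `profile_clusters`: `assignment` (named
#'   integer vector), `means` (cluster x stage matrix), `retained`
#'   (logical flags, all `TRUE` until [retain_clusters()]).
#' @export
cluster_profiles <- function(profiles, match_threshold = 0.80,
                             cut = c("height", "correlation")) {
  cut <- match.arg(cut)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 1L) stop("need at least one profile", call. = FALSE)
  if (ncol(profiles) < 2L) stop("need at least two stages", call. = FALSE)
  if (is.null(rownames(profiles)))
    stop("profiles must have gene row names", call. = FALSE)
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  if (nrow(profiles) == 1L)
    return(profile_cluster_set(setNames(1L, rownames(profiles)), profiles))
  d <- cor_dist(profiles)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  h <- if (cut == "height") (1 - match_threshold) * max(hc$height)
       else 1 - match_threshold
  assignment <- stats::cutree(hc, h = h)
  profile_cluster_set(assignment, profiles)
}

#' Merge clusters with near-identical mean profiles
#'
#' Repeatedly merges the pair of clusters whose mean profiles are most
#' highly correlated, while that correlation is at least `r_min`,
#' recomputing means after each merge.  Ties are broken toward the pair
#' with the smallest ids.  This automates the manual combination of
#' similar expression patterns.
#'
#' @param cs A `profile_clusters` object.
#' @param profiles The profile matrix the clustering was built from.
#' @param r_min Minimum Pearson correlation between mean profiles for a
#'   merge (default 0.90).
#' @return A `profile_clusters` object with clusters relabelled 1..k.
#' @export
merge_similar_clusters <- function(cs, profiles, r_min = 0.90) {
  profiles <- as.matrix(profiles)[names(cs$assignment), , drop = FALSE]
  assignment <- cs$assignment
  repeat {
    ids <- sort(unique(assignment))
    if (length(ids) < 2L) break
    means <- t(vapply(ids, function(cl) {
      colMeans(profiles[assignment == cl, , drop = FALSE])
    }, numeric(ncol(profiles))))
    r <- suppressWarnings(stats::cor(t(means)))
    r[is.na(r)] <- 0
    diag(r) <- -Inf
    best <- which(r == max(r), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1L, ]
    if (r[best[1], best[2]] < r_min) break
    a <- ids[min(best)]; b <- ids[max(best)]
    assignment[assignment == b] <- a
  }
  relabel <- setNames(seq_along(sort(unique(assignment))),
                      sort(unique(assignment)))
  assignment <- setNames(relabel[as.character(assignment)],
                         names(assignment))
  profile_cluster_set(assignment, profiles)
}

#' Flag clusters worth retaining
#'
#' A cluster is retained when it contains at least one transcription
#' factor and strictly more than `min_annotated` members annotated in the
#' GO database.  Retention only flags clusters; the partition is never
#' changed.
#'
#' @param cs A `profile_clusters` object.
#' @param tf_ids Character vector of transcription-factor gene ids.
#' @param go_annotated Character vector of GO-annotated gene ids.
#' @param min_annotated Strict lower bound on annotated members
#'   (default 20).
#' @return `cs` with its `retained` flags updated.
#' @export
retain_clusters <- function(cs, tf_ids, go_annotated, min_annotated = 20) {
  for (cl in names(cs$retained)) {
    mem <- names(cs$assignment)[cs$assignment == as.integer(cl)]
    cs$retained[[cl]] <- length(intersect(mem, tf_ids)) >= 1L &&
      length(intersect(mem, go_annotated)) > min_annotated
  }
  cs
}

#' Select per-stage predominant transcription factors
#'
#' At each stage, a TF is predominant when its TPM is strictly greater
#' than `multiple` times the mean TPM over all TFs at that stage.
#'
#' @param tf_tpm Numeric matrix, TFs x stages.
#' @param multiple Predominance multiple (default 3).
#' @return Named list, one character vector of TF ids per stage.
#' @export
select_predominant_tfs <- function(tf_tpm, multiple = 3) {
  tf_tpm <- as.matrix(tf_tpm)
  if (nrow(tf_tpm) == 0L)
    return(setNames(vector("list", ncol(tf_tpm)), colnames(tf_tpm)))
  lapply(setNames(colnames(tf_tpm), colnames(tf_tpm)), function(s) {
    thr <- multiple * mean(tf_tpm[, s])
    rownames(tf_tpm)[tf_tpm[, s] > thr]
  })
}
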
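#' Construct a count matrix with effective lengths
#'
#' Container for per-gene, per-stage mapped read-pair counts.  The first
#' stage (column) is the reference stage for differential expression.
#'
#' @param counts Non-negative integer matrix, genes x stages, with row and
#'   column names.
#' @param lengths Per-gene effective lengths in nt (named or in row
#'   order).
#' @param read_pair_span Nucleotides contributed by one read pair
#'   (default 200, i.e. 2 x 100-nt reads).
#' @return An object of class `count_matrix` with elements `counts`,
#'   `lengths`, `stages`, `read_pair_span`.
#' @export
count_matrix <- function(counts, lengths, read_pair_span = 200) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row (gene) and column (stage) names",
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("stage names must be unique", call. = FALSE)
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  lengths <- setNames(as.numeric(lengths), rownames(counts))
  if (length(lengths) != nrow(counts) || any(is.na(lengths)) ||
      any(lengths <= 0))
    stop("'lengths' must be positive, one per gene", call. = FALSE)
  structure(list(counts = counts, lengths = lengths,
                 stages = colnames(counts),
                 read_pair_span = read_pair_span),
            class = "count_matrix")
}

#' Transcripts-per-million normalization
#'
#' \eqn{tpm_{gs} = 10^6 (c_{gs}/l_g) / \sum_h (c_{hs}/l_h)}.  A stage with
#' all-zero counts yields an all-zero column (not `NaN`).
#'
#' @param counts A `count_matrix`, or a counts matrix.
#' @param lengths Effective lengths (ignored when `counts` is a
#'   `count_matrix`).
#' @return Numeric matrix of TPM values, same dimnames as the counts.
#' @export
#' @examples
#' m <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' compute_tpm(m, c(1000, 2000))
compute_tpm <- function(counts, lengths = NULL) {
  if (inherits(counts, "count_matrix")) {
    lengths <- counts$lengths
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rate <- counts / lengths
  tot <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
  tpm[, tot == 0] <- 0
  tpm
}

#' Expression pre-filter
#'
#' A gene is analysable when it has strictly more than `min_pairs` mapped
#' read pairs summed over all stages, and those pairs contribute enough
#' bases (`pairs x read_pair_span`) to cover every nucleotide of the
#' transcript at least `coverage_multiple` times.  A zero count at any
#' individual stage never by itself excludes a gene.
#'
#' @param cm A [count_matrix()].
#' @param p A [de_params()].
#' @return Named logical vector, one entry per gene.
#' @export
filter_expressed <- function(cm, p = de_params()) {
  total <- rowSums(cm$counts)
  total > p$min_pairs &
    total * cm$read_pair_span >= p$coverage_multiple * cm$lengths
}

#' Negative-binomial exact test at fixed dispersion
#'
#' Two-sided exact test for a difference between two unreplicated counts
#' under a negative-binomial model with fixed dispersion \eqn{\phi}
#' (variance \eqn{\mu + \phi\mu^2}).  Counts are first rescaled to a
#' common effective library size (each count multiplied by the ratio of
#' the geometric-mean library size to its own library size, rounded to the
#' nearest integer).  With \eqn{s} the rescaled total and null mean
#' \eqn{\mu = s/2} on both sides, the p-value is the total probability of
#' all splits \eqn{(k, s-k)} whose probability
#' \eqn{f(k)f(s-k)} does not exceed that of the observed split, normalized
#' by the probability of all splits.
#'
#' @param y_ref,y_alt Observed counts (reference and alternative stage).
#' @param lib_ref,lib_alt Library sizes (total mapped pairs).
#' @param dispersion Fixed dispersion \eqn{\phi}.
#' @return p-value in (0, 1]; `1` when the rescaled total is 0.
#' @export
#' @examples
#' nb_exact_test(5, 5, 1e6, 1e6)    # symmetric mode: p = 1
#' nb_exact_test(20, 0, 1e6, 1e6)
nb_exact_test <- function(y_ref, y_alt, lib_ref = 1, lib_alt = 1,
                          dispersion = 0.1) {
  if (y_ref < 0 || y_alt < 0) stop("counts must be >= 0", call. = FALSE)
  if (lib_ref <= 0 || lib_alt <= 0)
    stop("library sizes must be > 0", call. = FALSE)
  if (dispersion <= 0) stop("'dispersion' must be > 0", call. = FALSE)
  geo <- sqrt(lib_ref * lib_alt)
  y1 <- round(y_ref * geo / lib_ref)
  y2 <- round(y_alt * geo / lib_alt)
  s <- y1 + y2
  if (s == 0) return(1)
  size <- 1 / dispersion
  k <- 0:s
  lp <- stats::dnbinom(k, size = size, mu = s / 2, log = TRUE) +
    stats::dnbinom(s - k, size = size, mu = s / 2, log = TRUE)
  lp <- lp - max(lp)
  pr <- exp(lp)
  obs <- pr[y1 + 1L]
  sum(pr[pr <= obs * (1 + 1e-12)]) / sum(pr)
}

#' Effective library sizes by median-of-ratios
#'
#' Total column counts are sensitive to composition: a stage where many
#' genes are strongly up-regulated looks "deeper" and biases every null
#' gene's normalized ratio.  The effective size of each library is
#' therefore estimated from the median ratio of its counts to the
#' per-gene geometric means (genes with a zero anywhere are ignored),
#' rescaled to the magnitude of the raw totals.  Falls back to the raw
#' totals when too few genes are everywhere-positive.
#'
#' @param counts Non-negative gene x stage count matrix.
#' @return Named numeric vector of effective library sizes.
#' @export
effective_lib_sizes <- function(counts) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  lgm <- rowMeans(log(counts))
  ok <- is.finite(lgm)
  if (sum(ok) < 10L) return(tot)
  sf <- vapply(seq_len(ncol(counts)), function(j)
    exp(stats::median(log(counts[ok, j]) - lgm[ok])), numeric(1))
  if (any(!is.finite(sf) | sf <= 0)) return(tot)
  setNames(sf / exp(mean(log(sf))) * exp(mean(log(tot))), colnames(counts))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (wrapper around
#' [stats::p.adjust()] kept as the pipeline's single adjustment point).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Call differentially expressed genes against the reference stage
#'
#' For every gene passing [filter_expressed()] and every non-reference
#' stage, computes the library-normalized log2 fold-change (with a 0.5
#' pseudo-count on both sides only when either count is zero), the exact
#' NB p-value at fixed dispersion, and the BH-adjusted p-value within each
#' stage.  A gene is called at a stage when
#' \eqn{|log2 FC| \ge log2(F)} and the adjusted p-value is below `alpha`.
#'
#' @param cm A [count_matrix()]; the first stage is the reference.
#' @param p A [de_params()].
#' @return Data frame with columns `gene`, `stage`, `log2_fold_change`,
#'   `p_value`, `p_adjusted`, `is_deg`.  Genes failing the expression
#'   filter are absent.
#' @export
call_degs <- function(cm, p = de_params()) {
  if (length(cm$stages) < 2L) stop("need at least 2 stages", call. = FALSE)
  libs <- effective_lib_sizes(cm$counts)
  keep <- names(which(filter_expressed(cm, p)))
  ref <- cm$stages[1L]
  out <- list()
  for (stage in cm$stages[-1L]) {
    y_ref <- cm$counts[keep, ref]
    y_alt <- cm$counts[keep, stage]
    pv <- mapply(nb_exact_test, y_ref, y_alt,
                 MoreArgs = list(lib_ref = libs[[ref]],
                                 lib_alt = libs[[stage]],
                                 dispersion = p$dispersion))
    pseudo <- ifelse(y_ref == 0 | y_alt == 0, 0.5, 0)
    lfc <- log2(((y_alt + pseudo) / libs[[stage]]) /
                ((y_ref + pseudo) / libs[[ref]]))
    padj <- bh_adjust(pv)
    out[[stage]] <- data.frame(
      gene = keep, stage = stage, log2_fold_change = lfc,
      p_value = pv, p_adjusted = padj,
      is_deg = abs(lfc) >= log2(p$fold_threshold) & padj < p$alpha,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
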
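#' Classify a variant as transition, transversion or indel
#'
#' Indel when allele lengths differ; transition for purine-purine (A/G)
#' or pyrimidine-pyrimidine (C/T) substitutions; transversion otherwise.
#' Vectorized over alleles.
#'
#' @param ref,alt Reference and alternate alleles over `A,C,G,T`.
#' @return Character vector of `"transition"`, `"transversion"`,
#'   `"indel"`.
#' @export
#' @examples
#' classify_variant("A", "G")   # transition
#' classify_variant("AC", "A")  # indel
classify_variant <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(ref == alt)) stop("ref and alt alleles must differ", call. = FALSE)
  if (any(!grepl("^[ACGT]+$", ref)) || any(!grepl("^[ACGT]+$", alt)))
    stop("alleles must be non-empty over A,C,G,T", call. = FALSE)
  out <- rep("transversion", length(ref))
  out[nchar(ref) != nchar(alt)] <- "indel"
  snv <- nchar(ref) == nchar(alt)
  pair <- paste0(pmin(ref, alt), pmax(ref, alt))
  out[snv & pair %in% c("AG", "CT")] <- "transition"
  out
}

#' Filter variants on depth and mapping quality
#'
#' Removes records with `DP < min_dp` or `MQ < min_mq` (boundary values
#' are kept).  Records with missing DP or MQ are removed and tallied in a
#' warning.
#'
#' @param records Variant data frame with columns `contig`, `pos`, `ref`,
#'   `alt`, `dp`, `mq` (and optionally `population`).
#' @param min_dp Minimum depth kept (default 20).
#' @param min_mq Minimum mapping quality kept (default 40).
#' @return Filtered data frame.
#' @export
filter_variants <- function(records, min_dp = 20, min_mq = 40) {
  miss <- is.na(records$dp) | is.na(records$mq)
  if (any(miss))
    warning(sum(miss), " record(s) removed for missing DP/MQ",
            call. = FALSE)
  keep <- !miss & records$dp >= min_dp & records$mq >= min_mq
  records[keep, , drop = FALSE]
}

#' Summarize a variant set
#'
#' Counts by class, density per kilobase of summed contig length, and the
#' transition/transversion ratio.  Indels are included in the per-kb
#' numerator by default (set `include_indels_in_density = FALSE` to count
#' SNVs only).
#'
#' @param records Variant data frame (post-filtering) with `contig`,
#'   `ref`, `alt` columns.
#' @param contig_lengths Named numeric vector of contig lengths, covering
#'   every contig referenced by `records`.
#' @param population Optional population label carried into the summary.
#' @param include_indels_in_density Include indels in `snps_per_kb`.
#' @return A one-row data frame of class `variant_summary` with columns
#'   `population`, `n_transitions`, `n_transversions`, `n_indels`,
#'   `snps_per_kb`, `tstv` (`NA` when there are no transversions).
#' @export
summarize_variants <- function(records, contig_lengths, population = "all",
                               include_indels_in_density = TRUE) {
  total_kb <- sum(contig_lengths) / 1000
  if (total_kb <= 0) stop("total contig length must be > 0", call. = FALSE)
  if (nrow(records) > 0) {
    unknown <- setdiff(unique(records$contig), names(contig_lengths))
    if (length(unknown) > 0L)
      stop("records reference unknown contigs: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    cls <- classify_variant(records$ref, records$alt)
  } else cls <- character(0)
  ts <- sum(cls == "transition")
  tv <- sum(cls == "transversion")
  ind <- sum(cls == "indel")
  n <- if (include_indels_in_density) ts + tv + ind else ts + tv
  variant_summary_from_counts(population, ts, tv, ind,
                              total_kb = total_kb, n_density = n)
}

#' Build a variant summary from class counts
#'
#' The arithmetic core of [summarize_variants()], usable directly on
#' published count tables: transition/transversion ratio and optional
#' per-kilobase density from the class counts alone.
#'
#' @param population Population label.
#' @param n_transitions,n_transversions,n_indels Class counts.
#' @param total_kb Summed contig length in kb (`NA` when unknown).
#' @param n_density Numerator for the density; defaults to the sum of all
#'   three class counts.
#' @return A one-row `variant_summary` data frame.
#' @export
#' @examples
#' variant_summary_from_counts("all", 689365, 455283, 58932)$tstv
variant_summary_from_counts <- function(population, n_transitions,
                                        n_transversions, n_indels,
                                        total_kb = NA_real_,
                                        n_density = NULL) {
  if (is.null(n_density))
    n_density <- n_transitions + n_transversions + n_indels
  structure(data.frame(
    population = population,
    n_transitions = n_transitions,
    n_transversions = n_transversions,
    n_indels = n_indels,
    snps_per_kb = if (is.na(total_kb)) NA_real_ else n_density / total_kb,
    tstv = if (n_transversions > 0) n_transitions / n_transversions
           else NA_real_,
    stringsAsFactors = FALSE), class = c("variant_summary", "data.frame"))
}

#' Per-contig polymorphism density
#'
#' @param records Variant data frame with a `contig` column.
#' @param contig_lengths Named numeric vector defining the contig
#'   universe; contigs without variants get density 0.
#' @return Named numeric vector, variants per kilobase.
#' @export
per_contig_density <- function(records, contig_lengths) {
  unknown <- setdiff(unique(records$contig), names(contig_lengths))
  if (length(unknown) > 0L)
    stop("records reference unknown contigs: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  counts <- table(factor(records$contig, levels = names(contig_lengths)))
  setNames(as.numeric(counts) / (contig_lengths / 1000),
           names(contig_lengths))
}

#' Select highly polymorphic contigs
#'
#' Contigs whose density is at least `multiple` times the mean density
#' over the provided universe.  When the mean density is zero the set is
#' empty.
#'
#' @param densities Named numeric vector from [per_contig_density()].
#' @param multiple Multiple of the mean (default 2).
#' @return Character vector of contig ids.
#' @export
#' @examples
#' highly_polymorphic(c(a = 1, b = 2, c = 3, d = 10))  # "d"
highly_polymorphic <- function(densities, multiple = 2) {
  if (length(densities) < 1L) stop("need at least one contig",
                                   call. = FALSE)
  m <- mean(densities)
  if (m == 0) return(character(0))
  names(densities)[densities >= multiple * m]
}
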
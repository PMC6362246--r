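## Redundancy reduction: greedy identity clustering over a declining
## identity schedule, automatic merge-parameter selection, within-cluster
## end-overlap consensus merging, and final isoform grouping.

.reduce_cache <- new.env(parent = emptyenv())

nuc_mat <- function() {
  if (is.null(.reduce_cache$mat))
    .reduce_cache$mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE)
  .reduce_cache$mat
}

align_pair <- function(a, b, type) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
    type = type, substitutionMatrix = nuc_mat(),
    gapOpening = 2, gapExtension = 1)
}

aln_stats <- function(aln) {
  cols <- Biostrings::nchar(aln)  # alignment columns incl. gaps
  list(matches = Biostrings::nmatch(aln), columns = cols,
       ps = IRanges::start(Biostrings::pattern(aln)),
       pe = IRanges::end(Biostrings::pattern(aln)),
       ss = IRanges::start(Biostrings::subject(aln)),
       se = IRanges::end(Biostrings::subject(aln)))
}

#' Best-local-alignment identity between two sequences
#'
#' Semantics mirror the identity/coverage definitions of greedy identity
#' clustering tools: identity is matches over alignment columns of the
#' best local alignment; coverage of the shorter sequence is the aligned
#' span on the shorter sequence divided by its length.
#'
#' @param a,b Non-empty nucleotide strings (or `DNAString`s).
#' @return A list with `identity`, `aligned_len` (alignment columns) and
#'   `coverage_short`.
#' @export
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")$identity  # 1
pairwise_identity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("sequences must be non-empty", call. = FALSE)
  st <- aln_stats(align_pair(a, b, "local"))
  span <- if (nchar(a) <= nchar(b)) st$pe - st$ps + 1L else st$se - st$ss + 1L
  list(identity = st$matches / st$columns,
       aligned_len = st$columns,
       coverage_short = span / min(nchar(a), nchar(b)))
}

# best of forward and reverse-complement local alignments
best_identity_2strand <- function(a, b) {
  f <- pairwise_identity(a, b)
  f$orientation <- "+"
  r <- pairwise_identity(a, revcomp(b))
  r$orientation <- "-"
  score_f <- f$identity * f$aligned_len
  score_r <- r$identity * r$aligned_len
  if (score_f >= score_r) f else r
}

# unique k-mers of a sequence; used only as an alignment prescreen
kmer_set <- function(s, k = 8L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Greedy longest-first identity clustering
#'
#' Sequences are sorted by decreasing length (ties by id) and assigned
#' first-fit: each sequence joins the first existing representative it
#' matches at `identity_c` identity, `coverage_aS` coverage of the shorter
#' sequence, and `min_aln_len` aligned length (both orientations are
#' tried); otherwise it founds a new cluster.
#'
#' Pairs sharing too few 8-mers (in either orientation) to possibly reach
#' the identity/coverage thresholds are skipped without alignment; at the
#' module's thresholds (identity at least 0.80 over at least half of the
#' shorter sequence) true matches share an order of magnitude more 8-mers
#' than the screen requires.
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param p A [cluster_params()].
#' @return A list with `clusters` (named list: representative id ->
#'   character vector of member ids, representative first) and
#'   `assignment` (named character: id -> representative id).
#' @export
greedy_cluster <- function(seqs, p) {
  seqs <- as_seqchar(seqs)
  if (length(seqs) == 0L)
    return(list(clusters = list(), assignment = character(0)))
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must have unique names", call. = FALSE)
  fwd <- lapply(seqs, kmer_set)
  rcs <- lapply(seqs, function(s) kmer_set(revcomp(s)))
  ord <- order(-nchar(seqs), ids)
  reps <- character(0)
  assignment <- setNames(character(length(seqs)), ids)
  for (id in ids[ord]) {
    q <- seqs[[id]]
    hit <- NA_character_
    for (r in reps) {
      minlen <- min(nchar(q), nchar(seqs[[r]]))
      shared <- c("+" = length(intersect(fwd[[r]], fwd[[id]])),
                  "-" = length(intersect(fwd[[r]], rcs[[id]])))
      for (o in names(shared)[order(-shared)]) {
        if (shared[[o]] < 0.04 * minlen) next
        ba <- pairwise_identity(seqs[[r]], if (o == "+") q else revcomp(q))
        if (ba$identity >= p$identity_c &&
            ba$coverage_short >= p$coverage_aS &&
            ba$aligned_len >= p$min_aln_len) { hit <- r; break }
      }
      if (!is.na(hit)) break
    }
    if (is.na(hit)) reps <- c(reps, id) else assignment[id] <- hit
    if (is.na(hit)) assignment[id] <- id
  }
  clusters <- lapply(setNames(reps, reps), function(r) {
    mem <- ids[assignment == r]
    c(r, setdiff(mem, r))
  })
  list(clusters = clusters, assignment = assignment)
}

#' Automatic merge-parameter selection for a cluster
#'
#' Chooses end-overlap merging parameters from the cluster's length
#' distribution: `min_overlap` is 5% of the 10th-percentile member length
#' with a floor of 21 nt, `max_clip` is 2% of the median member length,
#' and the overlap identity is the round's merge identity.
#'
#' @param members Cluster member sequences (named character vector or
#'   `DNAStringSet`), non-empty.
#' @param round_identity Overlap identity for this round.
#' @return A [merge_params()].
#' @export
auto_merge_params <- function(members, round_identity) {
  lens <- nchar(as_seqchar(members))
  if (length(lens) == 0L) stop("cluster must be non-empty", call. = FALSE)
  merge_params(
    min_overlap = max(21L, as.integer(round(0.05 * stats::quantile(
      lens, 0.1, names = FALSE)))),
    overlap_identity = round_identity,
    max_clip = as.integer(round(0.02 * stats::median(lens))))
}

# classify the ends-free alignment of A vs B (already oriented) into a
# merge candidate; returns NULL if nothing qualifies
overlap_candidate <- function(A, B, m) {
  st <- aln_stats(align_pair(A, B, "overlap"))
  identity <- st$matches / st$columns
  if (st$columns < m$min_overlap || identity < m$overlap_identity)
    return(NULL)
  lenA <- nchar(A); lenB <- nchar(B); clip <- m$max_clip
  if (st$ss - 1L <= clip && lenB - st$se <= clip && lenB <= lenA)
    return(list(kind = "containB", ov = st$columns, identity = identity,
                st = st))
  if (st$ps - 1L <= clip && lenA - st$pe <= clip && lenA < lenB)
    return(list(kind = "containA", ov = st$columns, identity = identity,
                st = st))
  if (lenA - st$pe <= clip && st$ss - 1L <= clip)
    return(list(kind = "AB", ov = st$columns, identity = identity, st = st))
  if (lenB - st$se <= clip && st$ps - 1L <= clip)
    return(list(kind = "BA", ov = st$columns, identity = identity, st = st))
  NULL
}

join_overlap <- function(A, B, st) {
  # A then B; overlap segment taken from the longer contig
  mid <- if (nchar(A) >= nchar(B)) substr(A, st$ps, st$pe)
         else substr(B, st$ss, st$se)
  paste0(substr(A, 1L, st$ps - 1L), mid,
         substr(B, st$se + 1L, nchar(B)))
}

#' Merge a cluster's members by end-overlap consensus
#'
#' Repeatedly finds the best qualifying suffix-prefix overlap (either
#' orientation, allowing up to `max_clip` terminal bases to be clipped)
#' between any two current contigs and joins them; at mismatching overlap
#' columns the base of the longer contig is taken.  Sequences contained in
#' a longer contig (up to `max_clip` at the ends) collapse into the
#' container.  Terminates when no overlap of at least `min_overlap` nt at
#' `overlap_identity` identity remains.
#'
#' @param members Named character vector or `DNAStringSet` of contigs.
#' @param m A [merge_params()].
#' @param provenance Optional named list mapping each member id to the
#'   original sequence ids it represents; carried through merges.
#' @return A list with `seqs` (named character vector, longest first then
#'   id) and `members` (named list: contig id -> original ids).
#' @export
merge_cluster <- function(members, m, provenance = NULL) {
  seqs <- toupper(as_seqchar(members))
  ids <- names(seqs)
  if (length(seqs) > 0L && (is.null(ids) || anyDuplicated(ids)))
    stop("members must have unique names", call. = FALSE)
  if (is.null(provenance)) provenance <- lapply(setNames(ids, ids), identity)
  # pair candidates are cached across iterations: a join only invalidates
  # pairs involving the merged contigs
  cache <- new.env(parent = emptyenv())
  pair_cands <- function(i, j) {
    key <- paste(sort(c(names(seqs)[i], names(seqs)[j])), collapse = "\r")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- list()
    for (orient in c("+", "-")) {
      B <- if (orient == "+") seqs[[j]] else revcomp(seqs[[j]])
      cand <- overlap_candidate(seqs[[i]], B, m)
      if (is.null(cand)) next
      cand$orient <- orient
      cand$rank <- c(containB = 0, containA = 0, AB = 1, BA = 1)[cand$kind]
      res[[length(res) + 1L]] <- cand
    }
    cache[[key]] <- res
    res
  }
  drop_cached <- function(id) {
    keys <- ls(cache)
    hits <- keys[vapply(keys, function(k)
      id %in% strsplit(k, "\r", fixed = TRUE)[[1]], logical(1))]
    rm(list = hits, envir = cache)
  }
  repeat {
    n <- length(seqs)
    if (n < 2L) break
    ord <- order(-nchar(seqs), names(seqs))
    seqs <- seqs[ord]
    best <- NULL
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      for (cand in pair_cands(i, j)) {
        cand$i <- i; cand$j <- j
        if (is.null(best) ||
            cand$rank < best$rank ||
            (cand$rank == best$rank &&
             (cand$ov > best$ov ||
              (cand$ov == best$ov && cand$identity > best$identity))))
          best <- cand
      }
    }
    if (is.null(best)) break
    i <- best$i; j <- best$j
    A <- seqs[[i]]
    B <- if (best$orient == "+") seqs[[j]] else revcomp(seqs[[j]])
    idA <- names(seqs)[i]; idB <- names(seqs)[j]
    new_seq <- switch(best$kind,
      containB = A,
      containA = B,
      AB = join_overlap(A, B, best$st),
      BA = join_overlap(B, A, list(ps = best$st$ss, pe = best$st$se,
                                   ss = best$st$ps, se = best$st$pe)))
    keep_id <- if (nchar(seqs[[i]]) >= nchar(seqs[[j]])) idA else idB
    drop_cached(idA); drop_cached(idB)
    new_members <- c(provenance[[idA]], provenance[[idB]])
    seqs <- seqs[-c(i, j)]
    provenance[[idA]] <- NULL; provenance[[idB]] <- NULL
    seqs[[keep_id]] <- new_seq
    provenance[[keep_id]] <- new_members
  }
  if (length(seqs) > 0L) seqs <- seqs[order(-nchar(seqs), names(seqs))]
  list(seqs = seqs, members = provenance[names(seqs)])
}

#' Run the full redundancy-reduction schedule
#'
#' Applies, for each round of the schedule, greedy identity clustering
#' followed by within-cluster end-overlap merging with automatically
#' selected parameters; then groups the surviving contigs into genes with
#' the relaxed-coverage isoform clustering pass.
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet] of
#'   input sequences (e.g. extracted CDSs).
#' @param schedule A [reduction_schedule()].
#' @return A list with elements `contigs` (named character vector),
#'   `gene_groups` (data frame: `contig`, `gene`), `members` (data frame
#'   mapping every original `input_id` to its final `contig` and `gene`),
#'   and `log` (per-round record counts).
#' @export
run_schedule <- function(seqs, schedule = reduction_schedule()) {
  seqs <- toupper(as_seqchar(seqs))
  if (length(seqs) == 0L)
    return(list(contigs = character(0),
                gene_groups = data.frame(contig = character(0),
                                         gene = character(0)),
                members = data.frame(input_id = character(0),
                                     contig = character(0),
                                     gene = character(0)),
                log = data.frame()))
  provenance <- lapply(setNames(names(seqs), names(seqs)), identity)
  log <- list()
  for (r in seq_along(schedule$rounds)) {
    round <- schedule$rounds[[r]]
    cl <- greedy_cluster(seqs, round$cluster)
    out_seqs <- character(0)
    out_prov <- list()
    for (mem_ids in cl$clusters) {
      mp <- auto_merge_params(seqs[mem_ids], round$merge_identity)
      mg <- merge_cluster(seqs[mem_ids], mp, provenance[mem_ids])
      out_seqs <- c(out_seqs, mg$seqs)
      out_prov <- c(out_prov, mg$members)
    }
    log[[r]] <- data.frame(round = r, n_in = length(seqs),
                           n_clusters = length(cl$clusters),
                           n_out = length(out_seqs))
    seqs <- out_seqs
    provenance <- out_prov
  }
  seqs <- seqs[order(-nchar(seqs), names(seqs))]
  iso <- greedy_cluster(seqs, schedule$isoform)
  gene_groups <- data.frame(contig = names(iso$assignment),
                            gene = unname(iso$assignment),
                            stringsAsFactors = FALSE)
  members <- do.call(rbind, lapply(names(seqs), function(id) {
    data.frame(input_id = provenance[[id]], contig = id,
               gene = iso$assignment[[id]], stringsAsFactors = FALSE)
  }))
  rownames(members) <- NULL
  list(contigs = seqs, gene_groups = gene_groups, members = members,
       log = do.call(rbind, log))
}

# coerce a transcript set (DNAStringSet or character) to a named
# character vector without losing names
as_seqchar <- function(x) {
  if (is.character(x)) x else setNames(as.character(x), names(x))
}
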
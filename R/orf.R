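#' Translate a nucleotide sequence in a given frame and strand
#'
#' Standard genetic code.  Codons containing `N` translate to `X`; stop
#' codons translate to `*`.  Trailing bases that do not fill a codon are
#' ignored.
#'
#' @param dna Nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param frame Frame offset 0, 1 or 2.
#' @param strand `"+"` or `"-"`; for `"-"` the reverse complement is
#'   translated.
#' @return A single protein string.
#' @export
#' @examples
#' translate_dna("ATGAAACCC")  # "MKP"
#' translate_dna("ATGNAA")     # "MX"
translate_dna <- function(dna, frame = 0L, strand = "+") {
  s <- toupper(as.character(dna))
  if (strand == "-") s <- revcomp(s)
  codons <- frame_codons(s, frame)
  if (length(codons) == 0L) return("")
  paste(codon_aa(codons), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

frame_codons <- function(s, frame) {
  n <- nchar(s)
  starts <- seq.int(frame + 1L, length.out = max(0L, (n - frame) %/% 3L),
                    by = 3L)
  if (length(starts) == 0L) return(character(0))
  substring(s, starts, starts + 2L)
}

# vectorized codon -> amino acid; N-containing codons are X, never stops
codon_aa <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Extract stop-to-stop coding regions from a contig
#'
#' Implements the stop-anchored CDS rule used for fragmented de novo
#' transcriptome contigs: instead of requiring an `ATG`, a coding region
#' runs from one in-frame stop codon to the next.  All six frames (three
#' per strand) are scanned; every inter-stop segment, plus the leading
#' segment before the first stop (flagged `partial5`) and the trailing
#' segment after the last stop (flagged `partial3`), is a candidate CDS and
#' is reported when it encodes at least `min_aa_len` residues.  Codons
#' containing `N` never count as stops and translate to `X`.
#'
#' Coordinates are 0-based half-open on the forward strand of the input
#' contig.  When a terminal stop codon is present its three nucleotides are
#' included in `[start, end)` but excluded from `aa_length`; a leading stop
#' codon is not included.
#'
#' @param sequence Nucleotide string over `A,C,G,T,N` (case-insensitive),
#'   or a [Biostrings::DNAString].
#' @param min_aa_len Minimum number of encoded residues for a record to be
#'   retained (default 30).
#' @return A data frame with one row per CDS: `strand`, `frame`, `start`,
#'   `end`, `aa_length`, `partial5`, `partial3`, `protein`.  Zero rows for
#'   an empty sequence or when nothing reaches `min_aa_len`.
#' @seealso [select_primary_cds()]
#' @export
#' @examples
#' cds <- extract_cds("TAAATGAAACCCTGA", min_aa_len = 3)
#' subset(cds, !partial5 & !partial3)$protein  # "MKP"
extract_cds <- function(sequence, min_aa_len = 30L) {
  s <- toupper(as.character(sequence))
  if (nchar(s) == 0L) return(empty_cds())
  if (grepl("[^ACGTN]", s))
    stop("sequence contains characters outside A,C,G,T,N", call. = FALSE)
  if (min_aa_len < 1L) stop("'min_aa_len' must be >= 1", call. = FALSE)
  L <- nchar(s)
  out <- list()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") s else revcomp(s)
    for (frame in 0:2) {
      codons <- frame_codons(w, frame)
      k <- length(codons)
      if (k == 0L) next
      stops <- which(codons %in% STOP_CODONS)
      # segment boundaries in codon indices: [from, to] coding codons
      seg_from <- c(1L, stops + 1L)
      seg_to <- c(stops - 1L, k)
      p5 <- c(TRUE, rep(FALSE, length(stops)))
      p3 <- c(rep(FALSE, length(stops)), TRUE)
      for (i in seq_along(seg_from)) {
        aa <- seg_to[i] - seg_from[i] + 1L
        if (aa < min_aa_len) next
        start_w <- frame + 3L * (seg_from[i] - 1L)      # 0-based on w
        end_w <- frame + 3L * seg_to[i] + if (p3[i]) 0L else 3L
        if (strand == "+") {
          start <- start_w; end <- end_w
        } else {
          start <- L - end_w; end <- L - start_w
        }
        out[[length(out) + 1L]] <- data.frame(
          strand = strand, frame = frame, start = start, end = end,
          aa_length = aa, partial5 = p5[i], partial3 = p3[i],
          protein = paste(codon_aa(codons[seg_from[i]:seg_to[i]]),
                          collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty_cds())
  res <- do.call(rbind, out)
  res[order(-res$aa_length, res$strand, res$start), , drop = FALSE]
}

empty_cds <- function() {
  data.frame(strand = character(0), frame = integer(0), start = integer(0),
             end = integer(0), aa_length = integer(0),
             partial5 = logical(0), partial3 = logical(0),
             protein = character(0), stringsAsFactors = FALSE)
}

#' Select the primary CDS of a contig
#'
#' Keeps the record with maximal `aa_length`; ties are broken by complete
#' (neither partial flag) over partial, `+` strand over `-`, then lowest
#' start coordinate.
#'
#' @param records A CDS data frame as returned by [extract_cds()], all from
#'   one contig.
#' @return A one-row data frame, or `NULL` for empty input.
#' @export
select_primary_cds <- function(records) {
  if (is.null(records) || nrow(records) == 0L) return(NULL)
  npartial <- records$partial5 + records$partial3
  o <- order(-records$aa_length, npartial, records$strand, records$start)
  records[o[1L], , drop = FALSE]
}

#' Extract CDS records for every contig of a transcript set
#'
#' @param tset A named [Biostrings::DNAStringSet] (or named character
#'   vector) of contigs.
#' @param min_aa_len Minimum encoded residues, see [extract_cds()].
#' @param primary_only If `TRUE` keep only the primary CDS per contig.
#' @return A data frame with a leading `contig_id` column.
#' @export
extract_cds_set <- function(tset, min_aa_len = 30L, primary_only = FALSE) {
  seqs <- as_seqchar(tset)
  ids <- names(seqs)
  if (is.null(ids)) stop("transcript set must be named", call. = FALSE)
  rows <- lapply(ids, function(id) {
    r <- extract_cds(seqs[[id]], min_aa_len)
    if (primary_only) r <- select_primary_cds(r)
    if (is.null(r) || nrow(r) == 0L) return(NULL)
    cbind(contig_id = id, r, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(cbind(contig_id = character(0), empty_cds()))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
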
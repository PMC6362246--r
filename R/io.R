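## Readers and writers for the pipeline's plain-text formats: FASTA,
## counts TSV, 12-column tabular hit files, VCF 4.2, OBO subset,
## gene->term TSV, and id lists.  All writers round-trip with the
## readers on synthetic fixtures.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences as FASTA (80-column wrapped)
#'
#' @param tset Named character vector or `DNAStringSet`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(tset, path) {
  x <- Biostrings::DNAStringSet(toupper(as_seqchar(tset)))
  names(x) <- names(tset)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a counts table (gene, length, one column per stage)
#'
#' @param path Tab-separated file with header `gene`, `length`, then the
#'   stage columns in pipeline order.
#' @param read_pair_span Passed to [count_matrix()].
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, read_pair_span = 200) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (ncol(d) < 3L || names(d)[1] != "gene" || names(d)[2] != "length")
    stop("counts file must have columns gene, length, <stages>",
         call. = FALSE)
  m <- as.matrix(d[, -(1:2), drop = FALSE])
  rownames(m) <- d$gene
  count_matrix(m, setNames(d$length, d$gene), read_pair_span)
}

#' Write a counts table
#'
#' @param cm A [count_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  d <- data.frame(gene = rownames(cm$counts),
                  length = unname(cm$lengths),
                  cm$counts, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a 12-column tabular similarity-hit file
#'
#' Standard tabular hit format (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore); `#` comment lines
#' are skipped.  Query coverage is computed as alignment length over the
#' supplied query length; subject groups come from a subject -> group
#' map (subjects absent from the map get `"other"`).
#'
#' @param path Hit file.
#' @param query_lengths Named numeric vector of query lengths.
#' @param group_map Named character vector mapping subject ids to
#'   `target_clade`, `host_genome` or `other`.
#' @return Hit data frame as consumed by [classify_contig()].
#' @export
read_hit_table <- function(path, query_lengths, group_map = character(0)) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(query_id = character(0), subject_id = character(0),
                      subject_group = character(0),
                      percent_identity = numeric(0),
                      query_coverage = numeric(0), bitscore = numeric(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad) > 0L)
    stop("line ", bad[1L], ": expected 12 tab-separated columns",
         call. = FALSE)
  m <- do.call(rbind, fields)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stop("line ", which(is.na(v))[1L], ": non-numeric ", what,
           call. = FALSE)
    v
  }
  qlen <- query_lengths[m[, 1]]
  if (anyNA(qlen))
    stop("missing query length for: ",
         paste(unique(m[is.na(qlen), 1]), collapse = ", "), call. = FALSE)
  grp <- unname(group_map[m[, 2]])
  grp[is.na(grp)] <- "other"
  data.frame(query_id = m[, 1], subject_id = m[, 2], subject_group = grp,
             percent_identity = num(3, "percent identity"),
             query_coverage = num(4, "alignment length") / unname(qlen),
             bitscore = num(12, "bitscore"), evalue = num(11, "e-value"),
             stringsAsFactors = FALSE)
}

#' Write hits in the 12-column tabular format
#'
#' Alignment lengths are reconstructed from coverage and the supplied
#' query lengths; unused columns are written as zeros.
#'
#' @param hits Hit data frame (see [classify_contig()]).
#' @param path Output file.
#' @param query_lengths Named numeric vector of query lengths.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path, query_lengths) {
  aln_len <- round(hits$query_coverage * query_lengths[hits$query_id])
  d <- data.frame(hits$query_id, hits$subject_id, hits$percent_identity,
                  aln_len, 0L, 0L, 0L, 0L, 0L, 0L,
                  format(hits$evalue, digits = 3), hits$bitscore)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read variant records from a VCF file
#'
#' Uses CHROM, POS, REF, ALT and the INFO keys DP and MQ.  Multi-allelic
#' records are split into one record per alternate allele.
#'
#' @param path VCF 4.x file.
#' @param population Population label attached to the records (default
#'   taken from the `##population=` header line when present, else
#'   `"all"`).
#' @return Variant data frame: `contig`, `pos`, `ref`, `alt`,
#'   `population`, `dp`, `mq`.
#' @export
read_vcf <- function(path, population = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(population)) {
    meta <- grep("^##population=", v@meta, value = TRUE)
    population <- if (length(meta) > 0)
      sub("^##population=", "", meta[1]) else "all"
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      population = character(0), dp = numeric(0),
                      mq = numeric(0), stringsAsFactors = FALSE))
  dp <- as.numeric(vcfR::extract.info(v, "DP"))
  mq <- as.numeric(vcfR::extract.info(v, "MQ"))
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(fix)), lengths(alts))
  data.frame(contig = fix$CHROM[idx],
             pos = as.integer(fix$POS[idx]),
             ref = fix$REF[idx], alt = unlist(alts),
             population = population, dp = dp[idx], mq = mq[idx],
             stringsAsFactors = FALSE)
}

#' Write variant records as VCF 4.2
#'
#' @param records Variant data frame (see [read_vcf()]).
#' @param path Output file.
#' @param contig_lengths Optional named vector emitted as `##contig`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (length(unique(records$population)) == 1L &&
               nrow(records) > 0)
             paste0("##population=", records$population[1]),
           if (!is.null(contig_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                     as.integer(contig_lengths)),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste0("##INFO=<ID=MQ,Number=1,Type=Float,",
                  "Description=\"Mapping quality\">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(records) > 0)
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;MQ=%s",
            records$contig, as.integer(records$pos), records$ref,
            records$alt, as.integer(records$dp),
            format(records$mq, trim = TRUE)) else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal OBO-subset ontology file
#'
#' Parses `[Term]` stanzas with `id:`, `name:` and `namespace:` lines;
#' everything else is ignored.
#'
#' @param path OBO file.
#' @return Data frame `term`, `name`, `namespace`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  flush <- function(cur, out) {
    if (!is.null(cur) && !is.null(cur$id))
      out[[cur$id]] <- data.frame(term = cur$id,
                                  name = cur$name %||% NA_character_,
                                  namespace = cur$namespace %||%
                                    NA_character_,
                                  stringsAsFactors = FALSE)
    out
  }
  in_term <- FALSE
  for (ln in lines) {
    if (ln == "[Term]") { out <- flush(cur, out); cur <- list()
                          in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { out <- flush(cur, out); cur <- NULL
                             in_term <- FALSE; next }
    if (!in_term) next
    if (startsWith(ln, "id: ")) cur$id <- sub("^id: ", "", ln)
    else if (startsWith(ln, "name: ")) cur$name <- sub("^name: ", "", ln)
    else if (startsWith(ln, "namespace: "))
      cur$namespace <- sub("^namespace: ", "", ln)
  }
  out <- flush(cur, out)
  if (length(out) == 0L)
    return(data.frame(term = character(0), name = character(0),
                      namespace = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a minimal OBO-subset ontology file
#'
#' @param terms Data frame `term`, `name`, `namespace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_obo <- function(terms, path) {
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(terms))) {
    lines <- c(lines, "[Term]",
               paste0("id: ", terms$term[i]),
               paste0("name: ", terms$name[i]),
               paste0("namespace: ", terms$namespace[i]), "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a two-column gene-to-term annotation table
#'
#' @param path Tab-separated file with header `gene`, `term`.
#' @param obo_path Optional OBO file resolving the terms; when given,
#'   every annotated term must resolve.
#' @return A list with `annotation` and `terms` (see [go_enrich()]).
#' @export
read_annotation <- function(path, obo_path = NULL) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(ann)))
    stop("annotation file must have columns gene, term", call. = FALSE)
  terms <- if (!is.null(obo_path)) read_obo(obo_path)
           else data.frame(term = sort(unique(ann$term)),
                           name = NA_character_,
                           namespace = NA_character_,
                           stringsAsFactors = FALSE)
  missing <- setdiff(ann$term, terms$term)
  if (length(missing) > 0L)
    stop("annotated terms missing from the ontology: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  list(annotation = ann[, c("gene", "term")], terms = terms)
}

#' @rdname read_annotation
#' @param ann Annotation object (list with `annotation` and `terms`).
#' @export
write_annotation <- function(ann, path, obo_path = NULL) {
  utils::write.table(ann$annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(obo_path)) write_obo(ann$terms, obo_path)
  invisible(path)
}

#' Read / write a plain-text id list (one id per line)
#'
#' @param path File with one id per line; blank lines and `#` comments
#'   are skipped on read.
#' @return Character vector of ids.
#' @export
read_id_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname read_id_list
#' @param ids Character vector of ids.
#' @export
write_id_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}
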
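#' Gene lengths from a genome annotation file
#'
#' Length is the genomic span of a gene: leftmost to rightmost coordinate of
#' all records sharing a gene id, 1-based inclusive (`end - start + 1`), so
#' multiple transcripts contribute their union span. Duplicate ids with
#' conflicting spans keep the widest, with a message.
#'
#' @param annotation_file GTF/GFF path (read with `rtracklayer`).
#' @param feature_types annotation record types used (default gene,
#'   transcript and mRNA records; exons would give the same span).
#' @return named integer vector: gene id to length in bp.
#' @export
gene_lengths_from_annotation <- function(annotation_file,
                                         feature_types = c("gene",
                                                           "transcript",
                                                           "mRNA")) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("gene_lengths_from_annotation needs the rtracklayer package",
         call. = FALSE)
  gr <- rtracklayer::import(annotation_file)
  meta <- as.data.frame(gr)
  if (!nrow(meta)) stop("no records in ", annotation_file, call. = FALSE)
  if ("type" %in% names(meta) && any(meta$type %in% feature_types))
    meta <- meta[meta$type %in% feature_types, , drop = FALSE]
  id_col <- intersect(c("gene_id", "ID", "Name"), names(meta))[1]
  if (is.na(id_col)) stop("no gene_id attribute in annotation", call. = FALSE)
  meta <- meta[!is.na(meta[[id_col]]), , drop = FALSE]
  lo <- tapply(meta$start, meta[[id_col]], min)
  hi <- tapply(meta$end, meta[[id_col]], max)
  n_rec <- tapply(meta$start, meta[[id_col]], length)
  if (any(n_rec > 1))
    message(sum(n_rec > 1), " gene id(s) with multiple records: using the ",
            "union span")
  out <- as.integer(hi - lo + 1)
  names(out) <- names(lo)
  out
}

#' Promoter GC fraction around transcription start sites
#'
#' Extracts the window `[TSS - window_bp, TSS + window_bp]` (clipped at the
#' chromosome ends) from the genome and reports `(G + C) / (A + C + G + T)`.
#' Ambiguous bases are excluded from the denominator; an all-ambiguous
#' window is flagged `NA`. GC content is strand-symmetric, so the plus-strand
#' sequence is counted for both strands.
#'
#' @param genome a FASTA path or a `Biostrings::DNAStringSet` whose names
#'   are chromosome ids.
#' @param tss_table a file path or data.frame with columns gene_id, chrom,
#'   position (1-based TSS), and optionally strand.
#' @param window_bp half-window in bp (default 1000, i.e. a 2001 bp window).
#' @return named numeric vector: gene id to GC fraction in `[0, 1]` (`NA`
#'   where undefined).
#' @export
promoter_gc <- function(genome, tss_table, window_bp = 1000) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("promoter_gc needs the Biostrings package", call. = FALSE)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(tss_table))
    tss_table <- utils::read.table(tss_table, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "chrom", "position") %in% names(tss_table)))
  out <- stats::setNames(rep(NA_real_, nrow(tss_table)), tss_table$gene_id)
  for (i in seq_len(nrow(tss_table))) {
    chrom <- tss_table$chrom[i]
    if (!chrom %in% names(genome))
      stop("unknown chromosome: ", chrom, call. = FALSE)
    len <- Biostrings::width(genome[chrom])
    pos <- tss_table$position[i]
    if (pos < 1 || pos > len)
      stop(sprintf("TSS %d outside chromosome %s (length %d)",
                   pos, chrom, len), call. = FALSE)
    win <- Biostrings::subseq(genome[[chrom]],
                              start = max(1, pos - window_bp),
                              end = min(len, pos + window_bp))
    f <- Biostrings::letterFrequency(win, c("A", "C", "G", "T"))
    denom <- sum(f)
    out[i] <- if (denom == 0) NA_real_ else (f[["C"]] + f[["G"]]) / denom
  }
  out
}

#' Load a phylostratum map
#'
#' Reads a two-column tab-separated table mapping gene ids to integer
#' phylostrata (evolutionary age ranks, 1 = oldest stratum).
#'
#' @param table_file path to the phylomap TSV (gene_id, phylostratum;
#'   a header line is auto-detected).
#' @return named integer vector; empty (with a warning) for an empty file.
#' @export
load_phylomap <- function(table_file) {
  lines <- readLines(table_file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty phylomap: ", table_file)
    return(stats::setNames(integer(0), character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2))
    stop("phylomap rows need two tab-separated columns", call. = FALSE)
  first <- suppressWarnings(as.numeric(parts[[1]][2]))
  if (is.na(first)) { lines <- lines[-1]; parts <- parts[-1] }  # header
  ids <- vapply(parts, `[`, "", 1)
  strata <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  if (anyNA(strata) || any(strata != round(strata)))
    stop("non-integer phylostratum value(s)", call. = FALSE)
  dup <- duplicated(ids)
  if (any(dup)) {
    agree <- vapply(unique(ids[dup]), function(g)
      length(unique(strata[ids == g])) == 1, logical(1))
    if (!all(agree))
      stop("conflicting phylostrata for gene(s): ",
           paste(unique(ids[dup])[!agree], collapse = ", "), call. = FALSE)
  }
  keep <- !dup
  stats::setNames(as.integer(strata[keep]), ids[keep])
}

#' Assemble a gene annotation table
#'
#' Joins the characteristic maps into one table keyed by gene id, with `NA`
#' where a gene is missing from a source.
#'
#' @param gene_ids character vector of gene ids (the row universe).
#' @param lengths named vector from [gene_lengths_from_annotation()].
#' @param gc named vector from [promoter_gc()].
#' @param phylostrata named vector from [load_phylomap()].
#' @return data.frame with gene_id, length_bp, promoter_gc, phylostratum.
#' @export
gene_annotation_table <- function(gene_ids, lengths = NULL, gc = NULL,
                                  phylostrata = NULL) {
  df <- data.frame(gene_id = gene_ids)
  df$length_bp <- if (is.null(lengths)) NA_integer_ else
    unname(lengths[gene_ids])
  df$promoter_gc <- if (is.null(gc)) NA_real_ else unname(gc[gene_ids])
  df$phylostratum <- if (is.null(phylostrata)) NA_integer_ else
    unname(phylostrata[gene_ids])
  df
}
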
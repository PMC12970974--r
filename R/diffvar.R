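#' Load a count matrix plus cell labels into an expression dataset
#'
#' Accepts a 10x-style triplet directory (`matrix.mtx` + `features.tsv` +
#' `barcodes.tsv`), a directory of such per-condition subdirectories (as
#' written by [write_10x()]), or a dense delimited table (genes in rows,
#' header of cell ids, first column gene ids). Cell labels come from a
#' `labels.tsv` (cell_id, condition, optional timepoint) found alongside the
#' counts or passed explicitly.
#'
#' @param path counts directory or dense table file.
#' @param labels labels file path or data.frame; default
#'   `file.path(path, "labels.tsv")` for directories.
#' @return an object of class `expression_dataset`: list with `counts`
#'   (integer genes x cells matrix), `cells` (data.frame with cell_id,
#'   condition, timepoint), and `log` (QC provenance, appended to by the
#'   pipeline steps).
#' @export
load_counts <- function(path, labels = NULL) {
  if (dir.exists(path)) {
    if (file.exists(file.path(path, "matrix.mtx"))) {
      counts <- read_triplet_dir(path)
    } else {
      subs <- list.dirs(path, recursive = FALSE)
      subs <- subs[file.exists(file.path(subs, "matrix.mtx"))]
      if (!length(subs))
        stop("no matrix.mtx found under ", path, call. = FALSE)
      mats <- lapply(subs, read_triplet_dir)
      ids <- rownames(mats[[1]])
      for (m in mats[-1])
        if (!identical(rownames(m), ids))
          stop("feature ids differ between condition directories",
               call. = FALSE)
      counts <- do.call(cbind, mats)
    }
    if (is.null(labels)) labels <- file.path(path, "labels.tsv")
  } else if (file.exists(path)) {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, row.names = 1)
    counts <- as.matrix(df)
    if (any(counts != round(counts)))
      stop("non-integer entries in counts table", call. = FALSE)
    storage.mode(counts) <- "integer"
  } else stop("path not found: ", path, call. = FALSE)

  if (is.null(labels))
    stop("a labels table (cell_id, condition) is required", call. = FALSE)
  if (is.character(labels))
    labels <- utils::read.table(labels, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  if (!all(c("cell_id", "condition") %in% names(labels)))
    stop("labels need columns cell_id and condition", call. = FALSE)
  missing <- setdiff(colnames(counts), labels$cell_id)
  if (length(missing))
    stop("label table is missing barcode(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  if (anyDuplicated(labels$cell_id))
    stop("duplicate cell ids in label table", call. = FALSE)
  labels <- labels[match(colnames(counts), labels$cell_id), , drop = FALSE]
  if (is.null(labels$timepoint)) labels$timepoint <- "T0"
  rownames(labels) <- NULL
  new_dataset(counts, labels)
}

read_triplet_dir <- function(d) {
  m <- as.matrix(Matrix::readMM(file.path(d, "matrix.mtx")))
  if (any(m != round(m)))
    stop("non-integer entries in ", file.path(d, "matrix.mtx"),
         call. = FALSE)
  storage.mode(m) <- "integer"
  feats <- utils::read.table(file.path(d, "features.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  rownames(m) <- feats[[1]]
  colnames(m) <- readLines(file.path(d, "barcodes.tsv"))
  m
}

new_dataset <- function(counts, cells, log = list()) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  structure(list(counts = counts, cells = cells, scaled = NULL,
                 normalized = NULL, log = log),
            class = "expression_dataset")
}

#' Convert a synthetic study to an expression dataset in memory
#'
#' Equivalent to `load_counts(write_10x(study, d))` without touching disk.
#'
#' @param study a [make_two_condition_study()] object.
#' @return an `expression_dataset` (see [load_counts()]).
#' @export
study_to_dataset <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  counts <- do.call(cbind, lapply(study$counts, unclass))
  new_dataset(counts, study$labels)
}

#' @exportS3Method base::print
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d cells (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(table(x$cells$condition)),
                            table(x$cells$condition)), collapse = ", ")))
  if (length(x$log)) cat(sprintf("pipeline steps: %s\n",
                                 paste(names(x$log), collapse = " -> ")))
  invisible(x)
}

#' Quality-control parameters
#'
#' Defaults: cells are kept with 500-7000 detected genes, at least 800 UMIs,
#' and at most 20% mitochondrial counts; genes are then kept if expressed
#' (count > 0) in at least 10 surviving cells. Mitochondrial genes are
#' recognized by a case-insensitive id prefix (default `"mt-"`).
#'
#' @param min_genes,max_genes detected-gene bounds per cell.
#' @param min_umis minimum UMIs per cell.
#' @param max_mito_frac maximum mitochondrial count fraction per cell.
#' @param min_cells_per_gene minimum expressing cells per gene.
#' @param mito_prefix id prefix marking mitochondrial genes.
#' @return a list of class `qc_params`.
#' @export
qc_params <- function(min_genes = 500, max_genes = 7000, min_umis = 800,
                      max_mito_frac = 0.20, min_cells_per_gene = 10,
                      mito_prefix = "mt-") {
  stopifnot(min_genes >= 0, max_genes > min_genes, min_umis >= 0,
            max_mito_frac >= 0, max_mito_frac <= 1, min_cells_per_gene >= 0)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_umis = min_umis, max_mito_frac = max_mito_frac,
                 min_cells_per_gene = min_cells_per_gene,
                 mito_prefix = mito_prefix), class = "qc_params")
}

#' Filter cells and genes on quality control thresholds
#'
#' Cells are kept iff `min_genes <= detected genes <= max_genes`, UMIs >=
#' `min_umis`, and mitochondrial fraction <= `max_mito_frac`; genes are then
#' kept iff expressed in at least `min_cells_per_gene` surviving cells.
#' Removal counts are appended to the dataset's provenance log.
#'
#' @param ds an `expression_dataset` (raw counts).
#' @param params a [qc_params()] object.
#' @return the filtered `expression_dataset`.
#' @export
qc_filter <- function(ds, params = qc_params()) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(params, "qc_params"))
  m <- ds$counts
  mito <- startsWith(tolower(rownames(m)), tolower(params$mito_prefix))
  detected <- colSums(m > 0)
  umis <- colSums(m)
  mito_frac <- if (any(mito)) colSums(m[mito, , drop = FALSE]) / pmax(umis, 1)
               else rep(0, ncol(m))
  keep_cell <- detected >= params$min_genes & detected <= params$max_genes &
    umis >= params$min_umis & mito_frac <= params$max_mito_frac
  if (!any(keep_cell))
    stop("QC removed every cell; check thresholds", call. = FALSE)
  m2 <- m[, keep_cell, drop = FALSE]
  keep_gene <- rowSums(m2 > 0) >= params$min_cells_per_gene
  out <- new_dataset(m2[keep_gene, , drop = FALSE],
                     ds$cells[keep_cell, , drop = FALSE], ds$log)
  out$log$qc <- list(params = unclass(params),
                     cells_removed = sum(!keep_cell),
                     genes_removed = sum(!keep_gene),
                     cells_kept = sum(keep_cell),
                     genes_kept = sum(keep_gene))
  out
}

#' Depth-normalize counts
#'
#' Scales each cell to a common library size (default 10,000) and stores both
#' the depth-scaled matrix (`scaled`) and its `log(1 + x)` transform
#' (`normalized`). The Fano factor is computed on the scaled matrix by
#' default (see [variability_table()]); the log matrix backs mean-expression
#' summaries and the Wilcoxon test.
#'
#' @param ds a QC-filtered `expression_dataset`.
#' @param scale_factor target library size (default 1e4).
#' @return the dataset with `scaled` and `normalized` matrices filled.
#' @export
normalize_counts <- function(ds, scale_factor = 1e4) {
  stopifnot(inherits(ds, "expression_dataset"))
  depth <- colSums(ds$counts)
  if (any(depth == 0)) stop("zero-depth cell; run qc_filter first",
                            call. = FALSE)
  ds$scaled <- t(t(ds$counts) / depth) * scale_factor
  ds$normalized <- log1p(ds$scaled)
  ds$log$normalize <- list(scale_factor = scale_factor)
  ds
}

#' Drop lowly expressed, mitochondrial and ribosomal genes
#'
#' Removes genes whose mean log-normalized expression across all cells of the
#' comparison is below `min_mean_expr`, plus genes matching the mitochondrial
#' and ribosomal id prefixes (case-insensitive), which track technical rather
#' than biological variability.
#'
#' @param ds a normalized `expression_dataset`.
#' @param min_mean_expr threshold on mean log-normalized expression (default
#'   0.05; 0 disables it).
#' @param drop_prefixes id prefixes to remove (default mitochondrial `mt-`
#'   and ribosomal `Rps`/`Rpl`).
#' @return the filtered dataset.
#' @export
expression_filter <- function(ds, min_mean_expr = 0.05,
                              drop_prefixes = c("mt-", "Rps", "Rpl")) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$normalized)) stop("run normalize_counts first", call. = FALSE)
  ids <- tolower(rownames(ds$counts))
  pref <- Reduce(`|`, lapply(tolower(drop_prefixes),
                             function(p) startsWith(ids, p)),
                 init = rep(FALSE, length(ids)))
  low <- rowMeans(ds$normalized) < min_mean_expr
  keep <- !pref & !low
  out <- ds
  out$counts <- ds$counts[keep, , drop = FALSE]
  out$scaled <- ds$scaled[keep, , drop = FALSE]
  out$normalized <- ds$normalized[keep, , drop = FALSE]
  out$log$expression_filter <- list(min_mean_expr = min_mean_expr,
                                    prefixes_removed = sum(pref),
                                    low_removed = sum(low & !pref),
                                    genes_kept = sum(keep))
  out
}

#' Per-gene differential variability between two conditions
#'
#' Computes every gene's variance-to-mean ratio (Fano factor) within each
#' condition, the change `delta_vmr = VMR(condition_b) - VMR(condition_a)`,
#' and the ranking by `|delta_vmr|` (descending, ties broken by gene id).
#' The VMR is evaluated on the depth-scaled matrix by default — the Fano
#' factor's Poisson reference only has meaning on the count scale — with the
#' log-normalized matrix available via `vmr_on = "lognorm"`. Also reports
#' per-condition fraction of expressing cells (raw count > 0) and mean
#' log-normalized expression, and their changes.
#'
#' @param ds a normalized (and typically QC- and expression-filtered)
#'   `expression_dataset`.
#' @param condition_a,condition_b condition labels (the change is B minus A).
#' @param vmr_on `"scaled"` (default) or `"lognorm"`: matrix on which the
#'   VMR is computed.
#' @return a data.frame of class `variability_table` with columns gene_id,
#'   vmr_a, vmr_b, delta_vmr, abs_delta_vmr, rank, frac_expr_a, frac_expr_b,
#'   delta_frac, mean_expr_a, mean_expr_b, delta_mean. Genes whose VMR is
#'   undefined in either condition (zero mean) carry `NA` and sort last.
#' @export
variability_table <- function(ds, condition_a, condition_b,
                              vmr_on = c("scaled", "lognorm")) {
  stopifnot(inherits(ds, "expression_dataset"))
  vmr_on <- match.arg(vmr_on)
  if (is.null(ds$normalized)) stop("run normalize_counts first", call. = FALSE)
  ia <- which(ds$cells$condition == condition_a)
  ib <- which(ds$cells$condition == condition_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("both conditions need at least 2 cells", call. = FALSE)
  v <- if (vmr_on == "scaled") ds$scaled else ds$normalized
  row_vmr <- function(m) {
    mu <- rowMeans(m)
    va <- rowSums((m - mu)^2) / (ncol(m) - 1)
    ifelse(mu == 0, NA_real_, va / mu)
  }
  vmr_a <- row_vmr(v[, ia, drop = FALSE])
  vmr_b <- row_vmr(v[, ib, drop = FALSE])
  delta <- vmr_b - vmr_a
  out <- data.frame(
    gene_id = rownames(ds$counts),
    vmr_a = vmr_a, vmr_b = vmr_b,
    delta_vmr = delta, abs_delta_vmr = abs(delta),
    frac_expr_a = rowMeans(ds$counts[, ia, drop = FALSE] > 0),
    frac_expr_b = rowMeans(ds$counts[, ib, drop = FALSE] > 0),
    mean_expr_a = rowMeans(ds$normalized[, ia, drop = FALSE]),
    mean_expr_b = rowMeans(ds$normalized[, ib, drop = FALSE]),
    row.names = NULL)
  out$delta_frac <- out$frac_expr_b - out$frac_expr_a
  out$delta_mean <- out$mean_expr_b - out$mean_expr_a
  ord <- order(-out$abs_delta_vmr, out$gene_id, na.last = TRUE)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  attr(out, "conditions") <- c(a = condition_a, b = condition_b)
  attr(out, "vmr_on") <- vmr_on
  class(out) <- c("variability_table", "data.frame")
  out
}

#' Wilcoxon rank-sum differential expression between two conditions
#'
#' Per gene, a two-sided Wilcoxon rank-sum test on the log-normalized values,
#' with Benjamini-Hochberg adjustment across the tested genes. The p-value
#' uses the exact rank-sum null distribution when both groups have at most 25
#' cells and no ties, exhaustive permutation enumeration for small tied
#' groups, and the tie- and continuity-corrected normal approximation
#' otherwise (see [rank_sum_test()]). The log fold change is
#' `log2((mean(expm1(normalized_b)) + 1) / (mean(expm1(normalized_a)) + 1))`.
#'
#' @param ds a normalized `expression_dataset`.
#' @param condition_a,condition_b condition labels.
#' @param p_cutoff adjusted-p significance cutoff (default 0.05).
#' @return a data.frame of class `deg_table` with gene_id, log_fc, p_value,
#'   p_adjusted, significant.
#' @export
wilcoxon_de <- function(ds, condition_a, condition_b, p_cutoff = 0.05) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$normalized)) stop("run normalize_counts first", call. = FALSE)
  ia <- which(ds$cells$condition == condition_a)
  ib <- which(ds$cells$condition == condition_b)
  if (length(ia) < 3 || length(ib) < 3)
    stop("both conditions need at least 3 cells", call. = FALSE)
  pv <- apply(ds$normalized, 1, function(x)
    rank_sum_test(x[ia], x[ib])$p_value)
  ma <- rowMeans(expm1(ds$normalized[, ia, drop = FALSE]))
  mb <- rowMeans(expm1(ds$normalized[, ib, drop = FALSE]))
  out <- data.frame(gene_id = rownames(ds$counts),
                    log_fc = log2((mb + 1) / (ma + 1)),
                    p_value = pv,
                    p_adjusted = stats::p.adjust(pv, method = "BH"),
                    row.names = NULL)
  out$significant <- out$p_adjusted <= p_cutoff
  attr(out, "conditions") <- c(a = condition_a, b = condition_b)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Overlap between top differentially expressed and top variable genes
#'
#' Ranks DEGs by adjusted p (ascending; ties by |log fold change| descending,
#' then gene id) and variable genes by their |delta VMR| rank, and reports
#' the fraction of the two top-`k` lists that coincide.
#'
#' @param deg a [wilcoxon_de()] table.
#' @param vt a [variability_table()].
#' @param k list size (default 100).
#' @return list with `overlap_fraction`, `k`, and the id sets `both`,
#'   `deg_only`, `variability_only`.
#' @export
top_k_overlap <- function(deg, vt, k = 100) {
  stopifnot(inherits(deg, "deg_table"), inherits(vt, "variability_table"))
  universe <- intersect(deg$gene_id, vt$gene_id)
  if (k > length(universe))
    stop("k exceeds the shared gene universe", call. = FALSE)
  deg <- deg[deg$gene_id %in% universe, ]
  vt <- vt[vt$gene_id %in% universe, ]
  top_deg <- deg$gene_id[order(deg$p_adjusted, -abs(deg$log_fc),
                               deg$gene_id)][seq_len(k)]
  top_var <- vt$gene_id[order(vt$rank)][seq_len(k)]
  both <- intersect(top_deg, top_var)
  list(overlap_fraction = length(both) / k, k = k, both = both,
       deg_only = setdiff(top_deg, top_var),
       variability_only = setdiff(top_var, top_deg))
}

#' Kendall correlations of variability change with gene characteristics
#'
#' Kendall's tau-b (with tie handling) between `|delta VMR|` and each of:
#' transcript level (mean log-normalized expression across both conditions),
#' gene length, promoter GC content, and phylostratum; and between the signed
#' `delta VMR` and both the change in expressing-cell fraction and the change
#' in mean expression. P-values follow `stats::cor.test` (exact for small
#' untied samples, normal approximation otherwise).
#'
#' @param vt a [variability_table()].
#' @param ann annotation data.frame with gene_id and any of length_bp,
#'   promoter_gc, phylostratum.
#' @return a data.frame of class `correlation_report` with characteristic,
#'   tau, p_value, n.
#' @export
characteristic_correlations <- function(vt, ann) {
  stopifnot(inherits(vt, "variability_table"))
  df <- merge(as.data.frame(vt), ann, by = "gene_id")
  df$transcript_level <- (df$mean_expr_a + df$mean_expr_b) / 2
  pairs <- list(
    transcript_level = c("abs_delta_vmr", "transcript_level"),
    length_bp = c("abs_delta_vmr", "length_bp"),
    promoter_gc = c("abs_delta_vmr", "promoter_gc"),
    phylostratum = c("abs_delta_vmr", "phylostratum"),
    delta_frac = c("delta_vmr", "delta_frac"),
    delta_mean = c("delta_vmr", "delta_mean"))
  rows <- lapply(names(pairs), function(nm) {
    cols <- pairs[[nm]]
    if (!all(cols %in% names(df))) return(NULL)
    ok <- stats::complete.cases(df[, cols])
    x <- df[[cols[1]]][ok]; y <- df[[cols[2]]][ok]
    if (length(x) < 3)
      stop("fewer than 3 paired observations for ", nm, call. = FALSE)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
    data.frame(characteristic = nm, tau = unname(ct$estimate),
               p_value = ct$p.value, n = length(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' Export ranked gene lists for external enrichment tools
#'
#' Writes `variability.rnk` (gene, signed delta VMR, ordered descending),
#' `deg.rnk` (gene, log fold change, DEGs ordered by significance), and
#' plain-text top-`k` id lists for each ranking.
#'
#' @param vt a [variability_table()].
#' @param deg a [wilcoxon_de()] table.
#' @param path output directory.
#' @param k size of the top-gene id lists (default 100).
#' @return named character vector of the file paths, invisibly.
#' @export
export_ranked_lists <- function(vt, deg, path, k = 100) {
  stopifnot(inherits(vt, "variability_table"), inherits(deg, "deg_table"))
  if (nrow(vt) == 0 || nrow(deg) == 0) stop("empty table", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  vto <- vt[order(-vt$delta_vmr, vt$gene_id), ]
  dego <- deg[order(deg$p_adjusted, -abs(deg$log_fc), deg$gene_id), ]
  files <- c(variability_rnk = file.path(path, "variability.rnk"),
             deg_rnk = file.path(path, "deg.rnk"),
             top_variability = file.path(path, "top_variability.txt"),
             top_deg = file.path(path, "top_deg.txt"))
  utils::write.table(vto[, c("gene_id", "delta_vmr")],
                     files["variability_rnk"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(dego[, c("gene_id", "log_fc")], files["deg_rnk"],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  writeLines(vt$gene_id[order(vt$rank)][seq_len(min(k, nrow(vt)))],
             files["top_variability"])
  writeLines(dego$gene_id[seq_len(min(k, nrow(dego)))], files["top_deg"])
  invisible(files)
}
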
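#' Generate a complete synthetic two-condition scRNA-seq study
#'
#' Emulates a two-condition UMI study (control vs case) with negative
#' binomial marginals, a high zero fraction, mitochondrial content for QC,
#' and annotation tables, with known ground truth for two disjoint planted
#' compartments:
#'
#' * **Variable genes** (`frac_variable`): the case condition's NB size is
#'   reduced so the theoretical Fano factor is multiplied by
#'   `dispersion_shift` while the mean is unchanged — a pure dispersion
#'   shift. Planted variable genes are drawn from genes with baseline mean
#'   >= 0.5 so the planted signal survives the pipeline's low-expression
#'   filter (variability planted below detection would be unmeasurable by
#'   construction).
#' * **Differentially expressed genes** (`frac_de`): the case mean is scaled
#'   by `2^lfc` with `lfc ~ +/- U(lfc_range)` while the NB size scales with
#'   it, keeping the Fano factor unchanged — a pure mean shift. Real
#'   two-condition designs have substantial DE compartments; planting one
#'   keeps differential expression and differential variability structurally
#'   separate signals.
#'
#' All other genes have identical parameters in both conditions. Baseline:
#' per-gene mean `mu ~ LogUniform(0.1, 10)` (UMI means are usually below 1
#' and range up to ~10) with a common baseline Fano factor of 2, i.e. NB
#' success probability 0.5 as in the dispersion benchmark. A fraction
#' `frac_mito` of genes is flagged mitochondrial (ids prefixed `mt-`) with
#' mean `~ LogUniform(0.5, 10)`, yielding realistic per-cell mitochondrial
#' fractions. Annotation draws gene length `~ LogUniform(200, 2e6)` bp,
#' promoter GC `~ U(0.3, 0.7)`, and phylostratum `~ DiscreteUniform(1, 20)`
#' independently of expression, so the truth for characteristic correlations
#' is null.
#'
#' @param n_genes number of genes.
#' @param n_cells_per_condition cells per condition.
#' @param frac_variable fraction of genes with a planted dispersion shift,
#'   in (0, 1).
#' @param dispersion_shift multiplier (> 1) on the theoretical Fano factor of
#'   planted variable genes in the case condition.
#' @param frac_mito fraction of mitochondrial genes, in `[0, 0.2]`.
#' @param seed integer root seed; the whole study is bit-reproducible.
#' @param frac_de fraction of genes with a planted mean shift (default
#'   0.15; may be 0).
#' @param lfc_range absolute log2 fold-change range for DE genes (default
#'   `c(1, 3)`); sign is random.
#' @param baseline_fano baseline Fano factor (default 2, i.e. NB p = 0.5).
#' @param mean_range baseline mean range for LogUniform draws (default
#'   `c(0.1, 10)`).
#' @return an object of class `synthetic_study`: list with `counts` (named
#'   list of `counts_matrix`, conditions `"control"` and `"case"`), `labels`
#'   (data.frame cell_id, condition, timepoint), `annotation` (gene_id,
#'   length_bp, promoter_gc, phylostratum, is_mito), `truth` (gene_id,
#'   class in none/variable/de, fano_control, fano_case, delta_vmr =
#'   theoretical case - control Fano difference, lfc), and `params`.
#' @examples
#' st <- make_two_condition_study(200, 50, 0.05, 4, 0.05, seed = 1)
#' table(st$truth$class)
#' @export
make_two_condition_study <- function(n_genes, n_cells_per_condition,
                                     frac_variable, dispersion_shift,
                                     frac_mito, seed,
                                     frac_de = 0.15, lfc_range = c(1, 3),
                                     baseline_fano = 2,
                                     mean_range = c(0.1, 10)) {
  if (n_genes < 10 || n_cells_per_condition < 2)
    stop("study too small", call. = FALSE)
  if (!(frac_variable > 0 && frac_variable < 1))
    stop("frac_variable must be in (0, 1)", call. = FALSE)
  if (!(dispersion_shift > 1))
    stop("dispersion_shift must be > 1", call. = FALSE)
  if (frac_mito < 0 || frac_mito > 0.2)
    stop("frac_mito must be in [0, 0.2]", call. = FALSE)
  if (frac_de < 0 || frac_de >= 1) stop("frac_de must be in [0, 1)",
                                        call. = FALSE)
  if (baseline_fano <= 1) stop("baseline_fano must be > 1", call. = FALSE)

  n_mito <- round(frac_mito * n_genes)
  n_var <- round(frac_variable * n_genes)
  n_de <- round(frac_de * n_genes)
  nc <- n_cells_per_condition

  par <- with_seed(derive_seed(seed, 1L), {
    mu <- exp(stats::runif(n_genes, log(mean_range[1]), log(mean_range[2])))
    is_mito <- c(rep(TRUE, n_mito), rep(FALSE, n_genes - n_mito))
    mu[is_mito] <- exp(stats::runif(n_mito, log(0.5), log(10)))
    eligible <- which(!is_mito & mu >= 0.5)
    if (length(eligible) < n_var + n_de)
      stop("not enough well-expressed genes to plant into", call. = FALSE)
    planted <- sample(eligible, n_var + n_de)
    list(mu = mu, is_mito = is_mito,
         var_idx = planted[seq_len(n_var)],
         de_idx = planted[n_var + seq_len(n_de)],
         lfc = stats::runif(n_de, lfc_range[1], lfc_range[2]) *
           sample(c(-1, 1), n_de, replace = TRUE))
  })

  fano_a <- rep(baseline_fano, n_genes)
  fano_b <- fano_a
  fano_b[par$var_idx] <- baseline_fano * dispersion_shift
  mu_a <- par$mu
  mu_b <- mu_a
  mu_b[par$de_idx] <- mu_a[par$de_idx] * 2^par$lfc
  # NB size from mean and Fano: var = fano * mu  =>  size = mu / (fano - 1)
  size_a <- mu_a / (fano_a - 1)
  size_b <- mu_b / (fano_b - 1)

  gene_ids <- character(n_genes)
  gene_ids[par$is_mito] <- sprintf("mt-Sim%04d", which(par$is_mito))
  gene_ids[!par$is_mito] <- sprintf("Gene%05d", which(!par$is_mito))

  draw <- function(mu, size, child, prefix) {
    m <- with_seed(derive_seed(seed, child),
                   matrix(stats::rnbinom(n_genes * nc,
                                         size = rep(size, nc),
                                         mu = rep(mu, nc)),
                          n_genes, nc))
    storage.mode(m) <- "integer"
    rownames(m) <- gene_ids
    colnames(m) <- sprintf("%s_cell%04d", prefix, seq_len(nc))
    m
  }
  counts <- list(
    control = new_counts_matrix(draw(mu_a, size_a, 2L, "ctrl"),
                                dist_spec("negbinom", r = 1, p = 0.5),
                                seed, NA_integer_),
    case = new_counts_matrix(draw(mu_b, size_b, 3L, "case"),
                             dist_spec("negbinom", r = 1, p = 0.5),
                             seed, NA_integer_))

  annotation <- with_seed(derive_seed(seed, 4L), data.frame(
    gene_id = gene_ids,
    length_bp = as.integer(round(exp(stats::runif(n_genes, log(200),
                                                  log(2e6))))),
    promoter_gc = stats::runif(n_genes, 0.3, 0.7),
    phylostratum = sample.int(20L, n_genes, replace = TRUE),
    is_mito = par$is_mito))

  cls <- rep("none", n_genes)
  cls[par$var_idx] <- "variable"
  cls[par$de_idx] <- "de"
  lfc_full <- numeric(n_genes)
  lfc_full[par$de_idx] <- par$lfc
  truth <- data.frame(gene_id = gene_ids, class = cls,
                      fano_control = fano_a, fano_case = fano_b,
                      delta_vmr = fano_b - fano_a, lfc = lfc_full)

  labels <- data.frame(
    cell_id = c(colnames(counts$control), colnames(counts$case)),
    condition = rep(c("control", "case"), each = nc),
    timepoint = "T0")

  structure(list(counts = counts, labels = labels, annotation = annotation,
                 truth = truth,
                 params = list(n_genes = n_genes,
                               n_cells_per_condition = nc,
                               frac_variable = frac_variable,
                               dispersion_shift = dispersion_shift,
                               frac_mito = frac_mito, frac_de = frac_de,
                               lfc_range = lfc_range,
                               baseline_fano = baseline_fano,
                               mean_range = mean_range, seed = seed)),
            class = "synthetic_study")
}

#' @exportS3Method base::print
print.synthetic_study <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<synthetic_study> %d genes x 2 x %d cells; ",
                     "%d variable (Fano x%g), %d DE, %d mito genes\n"),
              p$n_genes, p$n_cells_per_condition,
              sum(x$truth$class == "variable"), p$dispersion_shift,
              sum(x$truth$class == "de"), sum(x$annotation$is_mito)))
  invisible(x)
}

#' Write a synthetic study as 10x-style sparse triplet files
#'
#' Per condition, a subdirectory with `matrix.mtx` (MatrixMarket coordinate
#' triplets, one row per non-zero entry), `features.tsv` and `barcodes.tsv`;
#' at the top level `labels.tsv` (cell_id, condition, timepoint),
#' `annotation.tsv` and `truth.tsv`. Round-trips losslessly through
#' [load_counts()].
#'
#' @param study a [make_two_condition_study()] object.
#' @param path output directory (created).
#' @return `path`, invisibly.
#' @export
write_10x <- function(study, path) {
  stopifnot(inherits(study, "synthetic_study"))
  if (length(study$counts) == 0 || any(vapply(study$counts, nrow, 1L) == 0))
    stop("empty study", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (cond in names(study$counts)) {
    d <- file.path(path, cond)
    dir.create(d, showWarnings = FALSE)
    m <- study$counts[[cond]]
    sm <- Matrix::Matrix(unclass(m)[, , drop = FALSE], sparse = TRUE)
    Matrix::writeMM(sm, file.path(d, "matrix.mtx"))
    utils::write.table(
      data.frame(id = rownames(m), name = rownames(m),
                 type = "Gene Expression"),
      file.path(d, "features.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    writeLines(colnames(m), file.path(d, "barcodes.tsv"))
  }
  wt <- function(df, f) utils::write.table(df, file.path(path, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  wt(study$labels, "labels.tsv")
  wt(study$annotation, "annotation.tsv")
  wt(study$truth, "truth.tsv")
  invisible(path)
}
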
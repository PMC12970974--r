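#' Gini index of a non-negative vector
#'
#' Mean-absolute-difference form with the population (`n^2`) denominator,
#' `G = sum_ij |x_i - x_j| / (2 n^2 xbar)`, computed via the equivalent
#' sorted expression. This equals the Lorenz-curve construction: the ratio of
#' the area between the Lorenz curve and the line of equality to the total
#' area under the line of equality. 0 means perfect equality (constant
#' vector); values approach 1 when all mass sits on one observation.
#'
#' @param x numeric vector of non-negative values, length >= 2.
#' @return the Gini index in `[0, 1]`, or `NA` (flagged undefined) when the
#'   mean is zero.
#' @examples
#' gini(c(0, 0, 1, 3))  # 0.625
#' @export
gini <- function(x) {
  check_metric_input(x)
  if (any(x < 0)) stop("gini requires non-negative values", call. = FALSE)
  x <- as.numeric(x)
  s <- sum(x)
  if (s == 0) return(NA_real_)
  n <- length(x)
  xs <- sort(x)
  2 * sum(seq_len(n) * xs) / (n * s) - (n + 1) / n
}

#' Variance-to-mean ratio (Fano factor)
#'
#' Sample variance (`n - 1` denominator) over the sample mean. Equals 1 for
#' Poisson counts and `1/p` for a negative binomial with success probability
#' `p`; deviation from 1 measures departure from Poisson noise.
#'
#' @param x numeric vector, length >= 2.
#' @return the VMR, or `NA` (flagged undefined) when the mean is zero.
#' @examples
#' vmr(c(0, 0, 1, 3))  # 2
#' @export
vmr <- function(x) {
  check_metric_input(x)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::var(x) / m
}

#' Sample variance (unbiased)
#' @param x numeric vector, length >= 2.
#' @return the `n - 1` denominator sample variance.
#' @export
sample_variance <- function(x) {
  check_metric_input(x)
  stats::var(x)
}

#' Coefficient of variation
#' @param x numeric vector, length >= 2.
#' @return `sd(x)/mean(x)`, or `NA` (flagged undefined) when the mean is zero.
#' @export
cv <- function(x) {
  check_metric_input(x)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}

#' Squared coefficient of variation
#' @param x numeric vector, length >= 2.
#' @return `cv(x)^2`, or `NA` when the mean is zero.
#' @export
cv_squared <- function(x) {
  v <- cv(x)
  v * v
}

#' Plug-in Shannon entropy of the empirical value distribution
#'
#' `-sum_k f_k log f_k` over the empirical frequencies `f_k` of the distinct
#' observed values. A constant vector has entropy 0; `n` all-distinct values
#' give `log(n)`, which is why entropy grows with dataset size for wide
#' (e.g. uniform) distributions.
#'
#' @param x numeric vector, length >= 1.
#' @param base logarithm base (default `exp(1)`: nats).
#' @return the entropy (>= 0).
#' @examples
#' shannon_entropy(c(0, 0, 1, 3))  # 1.0397 nats
#' @export
shannon_entropy <- function(x, base = exp(1)) {
  if (length(x) < 1) stop("need at least 1 value", call. = FALSE)
  f <- empirical_freqs(x)
  -sum(f * log(f, base = base))
}

empirical_freqs <- function(x) {
  if (is.integer(x) || all(x == floor(x))) {
    # fast path for integer counts
    cnt <- tabulate(as.integer(x - min(x)) + 1L)
    cnt <- cnt[cnt > 0]
  } else {
    cnt <- as.numeric(table(x))
  }
  cnt / length(x)
}

check_metric_input <- function(x) {
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  if (anyNA(x)) stop("missing values not allowed", call. = FALSE)
  invisible(TRUE)
}

.metric_names <- c("gini", "vmr", "variance", "entropy", "cv", "cv2")

#' Per-gene dispersion metrics and their aggregate
#'
#' Computes all six metrics for every gene (row) of a counts matrix across
#' cells (columns) and aggregates each metric over genes with the requested
#' statistic. Genes with zero mean have undefined Gini/VMR/CV/CV^2; these are
#' `NA` in the per-gene table, excluded from the aggregate, and counted in
#' `n_undefined` rather than silently zeroed.
#'
#' @param m a matrix (genes x cells), e.g. from [sample_counts()].
#' @param aggregation `"median"` (default) or `"mean"`.
#' @return an object of class `metric_panel`: list with `per_gene`
#'   (data.frame gene_id x six metrics), `aggregate` (named numeric),
#'   `n_undefined` (per metric), `n_genes`, `n_cells`, `aggregation`.
#' @export
metric_panel <- function(m, aggregation = c("median", "mean")) {
  aggregation <- match.arg(aggregation)
  if (!is.matrix(m) || nrow(m) == 0 || ncol(m) == 0)
    stop("m must be a non-empty matrix", call. = FALSE)
  if (ncol(m) < 2) stop("need at least 2 cells", call. = FALSE)
  n <- ncol(m)
  rm_ <- rowMeans(m)
  rv <- rowSums((m - rm_)^2) / (n - 1)
  zero <- rm_ == 0
  sd_ <- sqrt(rv)
  per_gene <- data.frame(
    gene_id = rownames(m) %||% paste0("gene", seq_len(nrow(m))),
    gini = apply(m, 1, gini),
    vmr = ifelse(zero, NA_real_, rv / rm_),
    variance = rv,
    entropy = apply(m, 1, shannon_entropy),
    cv = ifelse(zero, NA_real_, sd_ / rm_),
    cv2 = ifelse(zero, NA_real_, rv / rm_^2),
    row.names = NULL)
  agg_fun <- if (aggregation == "median") stats::median else mean
  aggregate <- vapply(.metric_names,
                      function(k) agg_fun(per_gene[[k]][!is.na(per_gene[[k]])]),
                      numeric(1))
  aggregate[vapply(.metric_names,
                   function(k) all(is.na(per_gene[[k]])), logical(1))] <- NA_real_
  structure(list(per_gene = per_gene, aggregate = aggregate,
                 n_undefined = vapply(.metric_names,
                                      function(k) sum(is.na(per_gene[[k]])),
                                      integer(1)),
                 n_genes = nrow(m), n_cells = ncol(m),
                 aggregation = aggregation),
            class = "metric_panel")
}

#' @exportS3Method base::print
print.metric_panel <- function(x, ...) {
  cat(sprintf("<metric_panel> %d genes x %d cells (%s aggregate)\n",
              x$n_genes, x$n_cells, x$aggregation))
  print(round(x$aggregate, 4))
  if (any(x$n_undefined > 0))
    cat(sprintf("undefined (zero-mean) genes: %d\n", max(x$n_undefined)))
  invisible(x)
}

#' Write a per-gene metric table to a tab-separated file
#'
#' @param panel a [metric_panel()].
#' @param path output file path; `NA` marks undefined values.
#' @return the path, invisibly.
#' @export
write_metric_table <- function(panel, path) {
  stopifnot(inherits(panel, "metric_panel"))
  utils::write.table(panel$per_gene, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
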
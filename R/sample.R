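#' Simulate a counts matrix from a sampling distribution
#'
#' Draws a genes x cells matrix of non-negative integer counts. Entries are
#' i.i.d. across cells; for the beta-Poisson each gene first draws its own
#' latent `B ~ Beta(alpha, beta)` and cells are then conditionally i.i.d.
#' Poisson with rate `lambda1 * B`, scaled by `lambda2` and rounded.
#' Sampling is bit-reproducible: the same `(spec, sizes, seed)` always
#' yields the identical matrix, and the caller's RNG state is untouched.
#'
#' @param spec a [dist_spec()].
#' @param n_genes,n_cells matrix dimensions (>= 1).
#' @param seed integer seed for this draw.
#' @param gene_ids,cell_ids optional id vectors (defaults `gene1..`,
#'   `cell1..`).
#' @param level_index optional integer recording the ladder level this matrix
#'   came from (provenance only).
#' @return an integer matrix of class `counts_matrix` with the generating
#'   `spec`, `seed` and `level_index` stored as attributes.
#' @examples
#' m <- sample_counts(dist_spec("poisson", lambda = 5), 10, 20, seed = 1)
#' stopifnot(identical(m, sample_counts(dist_spec("poisson", lambda = 5),
#'                                      10, 20, seed = 1)))
#' @export
sample_counts <- function(spec, n_genes, n_cells, seed,
                          gene_ids = NULL, cell_ids = NULL,
                          level_index = NA_integer_) {
  stopifnot(inherits(spec, "dist_spec"))
  if (n_genes < 1 || n_cells < 1) stop("sizes must be >= 1", call. = FALSE)
  n_genes <- as.integer(n_genes); n_cells <- as.integer(n_cells)
  n <- n_genes * n_cells
  p <- spec$params
  vals <- with_seed(seed, switch(spec$family,
    poisson = stats::rpois(n, p$lambda),
    negbinom = stats::rnbinom(n, size = p$r, prob = p$p),
    poisson_lognormal =
      stats::rpois(n, stats::rlnorm(n, meanlog = p$mu, sdlog = p$sigma)),
    hurdle_nb = r_hurdle_nb(n, p$pi, p$r, p$p),
    uniform = p$a + sample.int(p$b - p$a + 1, n, replace = TRUE) - 1L,
    betapoisson = {
      b <- stats::rbeta(n_genes, p$alpha, p$beta)
      k <- stats::rpois(n, rep(p$lambda1 * b, times = n_cells))
      as.integer(round(p$lambda2 * k))
    }))
  m <- matrix(as.integer(vals), nrow = n_genes, ncol = n_cells)
  rownames(m) <- gene_ids %||% paste0("gene", seq_len(n_genes))
  colnames(m) <- cell_ids %||% paste0("cell", seq_len(n_cells))
  new_counts_matrix(m, spec, seed, level_index)
}

# Zero-truncated sampling by inverse CDF: u ~ U(q0, 1) maps through qnbinom
# to counts >= 1 exactly.
r_hurdle_nb <- function(n, pi, r, p) {
  nz <- stats::runif(n) < pi
  out <- integer(n)
  k <- sum(nz)
  if (k) {
    q0 <- p^r
    u <- q0 + stats::runif(k) * (1 - q0)
    out[nz] <- stats::qnbinom(u, size = r, prob = p)
  }
  out
}

new_counts_matrix <- function(m, spec, seed, level_index) {
  structure(m, spec = spec, seed = as.integer(seed),
            level_index = as.integer(level_index),
            class = c("counts_matrix", class(m)))
}

#' @exportS3Method base::print
print.counts_matrix <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("<counts_matrix> %d genes x %d cells, %s, seed %d\n",
              nrow(x), ncol(x), sp$family, attr(x, "seed")))
  invisible(x)
}
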
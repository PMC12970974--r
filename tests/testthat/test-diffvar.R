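test_that("load_counts reads triplet and dense forms identically", {
  st <- make_two_condition_study(80, 15, 0.1, 4, 0.05, seed = 2)
  d <- withr::local_tempdir()
  write_10x(st, d)
  ds <- load_counts(d)
  # dense CSV with header gives the same matrix as its triplet form
  dense <- withr::local_tempfile(fileext = ".csv")
  m <- ds$counts
  write.csv(as.data.frame(m), dense, quote = FALSE)
  ds2 <- load_counts(dense, labels = file.path(d, "labels.tsv"))
  expect_identical(ds2$counts, m)
  # label file missing a barcode errors, naming it
  lab <- read.table(file.path(d, "labels.tsv"), header = TRUE, sep = "\t")
  bad <- lab[-1, ]
  f <- withr::local_tempfile()
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_counts(d, labels = f), lab$cell_id[1], fixed = TRUE)
})

test_that("qc_filter applies the cell and gene thresholds literally", {
  # 700 genes so detected-gene counts can straddle the 500 threshold
  ng <- 700
  mk_cell <- function(n_detected, umis, mito_counts) {
    x <- integer(ng)
    x[seq_len(n_detected)] <- 1L
    x[1] <- x[1] + as.integer(umis - n_detected - mito_counts)
    x[ng] <- mito_counts  # the last gene is mitochondrial
    x
  }
  cells <- cbind(
    kept = mk_cell(600, 900, as.integer(0.05 * 900)),
    few_genes = mk_cell(400, 900, as.integer(0.05 * 900)),
    few_umis = mk_cell(600, 700, as.integer(0.05 * 700)),
    high_mito = mk_cell(600, 900, as.integer(0.25 * 900)))
  rownames(cells) <- c(paste0("g", seq_len(ng - 1)), "mt-x")
  ds <- dispvar:::new_dataset(cells, data.frame(
    cell_id = colnames(cells), condition = "A", timepoint = "T0"))
  kept <- qc_filter(ds, qc_params(min_cells_per_gene = 0))
  expect_equal(colnames(kept$counts), "kept")
  expect_equal(kept$log$qc$cells_removed, 3)

  # gene expressed in 9 surviving cells is dropped, in 10 kept
  m <- matrix(5L, nrow = 3, ncol = 12,
              dimnames = list(c("g9", "g10", "g12"),
                              paste0("c", 1:12)))
  m[1, 10:12] <- 0L  # expressed in 9 cells
  m[2, 11:12] <- 0L  # expressed in 10 cells
  ds2 <- dispvar:::new_dataset(m, data.frame(cell_id = colnames(m),
                                             condition = "A",
                                             timepoint = "T0"))
  out <- qc_filter(ds2, qc_params(min_genes = 0, max_genes = 1e6,
                                  min_umis = 0, max_mito_frac = 1,
                                  min_cells_per_gene = 10))
  expect_setequal(rownames(out$counts), c("g10", "g12"))

  # fully permissive parameters are the identity transform
  idp <- qc_params(min_genes = 0, max_genes = 1e6, min_umis = 0,
                   max_mito_frac = 1, min_cells_per_gene = 0)
  expect_identical(qc_filter(ds2, idp)$counts, ds2$counts)
  expect_error(qc_filter(ds2, qc_params(min_umis = 1e9)), "every cell")
})

test_that("qc_filter is idempotent on realistic data", {
  st <- make_two_condition_study(600, 80, 0.05, 4, 0.05, seed = 9)
  ds <- study_to_dataset(st)
  p <- qc_params(min_genes = 50, max_genes = 7000, min_umis = 200,
                 min_cells_per_gene = 10)
  once <- qc_filter(ds, p)
  twice <- qc_filter(once, p)
  expect_identical(once$counts, twice$counts)
  expect_identical(once$cells, twice$cells)
})

test_that("normalization scales depth and is depth-invariant per cell", {
  m <- matrix(c(1L, 1L, 2L, 2L), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  ds <- dispvar:::new_dataset(m, data.frame(cell_id = c("c1", "c2"),
                                            condition = "A",
                                            timepoint = "T0"))
  nds <- normalize_counts(ds)
  # cell of two 1s at scale 10000: each gene becomes log(1 + 5000)
  expect_equal(nds$normalized[, "c1"], c(g1 = log(1 + 5000),
                                         g2 = log(1 + 5000)))
  # doubling every count in a cell leaves its normalized profile unchanged
  expect_equal(nds$normalized[, "c2"], nds$normalized[, "c1"])
  expect_equal(nds$scaled[, "c1"], c(g1 = 5000, g2 = 5000))
})

test_that("expression_filter drops low-mean, mito and ribosomal genes", {
  set.seed(1)
  m <- matrix(rpois(400, 5), 4, 100,
              dimnames = list(c("Gene1", "mt-Co1", "Rpl13", "LowGene"),
                              paste0("c", 1:100)))
  m["LowGene", ] <- 0L   # mean normalized expression 0 < 0.05
  ds <- normalize_counts(dispvar:::new_dataset(
    m, data.frame(cell_id = colnames(m), condition = "A", timepoint = "T0")))
  out <- expression_filter(ds)
  expect_equal(rownames(out$counts), "Gene1")
  out0 <- expression_filter(ds, min_mean_expr = 0)
  expect_setequal(rownames(out0$counts), c("Gene1", "LowGene"))
})

test_that("variability_table computes delta VMR with deterministic ranking", {
  fix <- make_test_dataset(seed = 4)
  vt <- variability_table(fix$ds, "control", "case")
  expect_equal(vt$delta_vmr, vt$vmr_b - vt$vmr_a)
  expect_equal(vt$abs_delta_vmr, abs(vt$delta_vmr))
  expect_equal(sort(vt$rank), seq_len(nrow(vt)))
  ord <- order(-vt$abs_delta_vmr, vt$gene_id)
  expect_equal(vt$rank[ord], seq_len(nrow(vt)))
  expect_true(all(vt$frac_expr_a >= 0 & vt$frac_expr_a <= 1))
  # identical conditions give delta VMR 0 for every gene
  ds <- fix$ds
  ds$cells$condition <- rep(c("X", "Y"), length.out = nrow(ds$cells))
  ds$counts <- ds$counts[, c(1:4, 1:4)]
  ds$scaled <- ds$scaled[, c(1:4, 1:4)]
  ds$normalized <- ds$normalized[, c(1:4, 1:4)]
  ds$cells <- data.frame(cell_id = paste0("c", 1:8),
                         condition = rep(c("X", "Y"), each = 4),
                         timepoint = "T0")
  vt2 <- variability_table(ds, "X", "Y")
  expect_true(all(vt2$delta_vmr[!is.na(vt2$delta_vmr)] == 0))
  expect_error(variability_table(fix$ds, "control", "nosuch"), "2 cells")
})

test_that("wilcoxon_de matches the stated conventions", {
  fix <- make_test_dataset(seed = 6, n_genes = 120, n_cells = 40)
  deg <- wilcoxon_de(fix$ds, "control", "case")
  expect_true(all(deg$p_adjusted >= deg$p_value - 1e-12))
  expect_equal(deg$p_adjusted, brute_bh(deg$p_value), tolerance = 1e-12)
  # identical groups: p = 1, logFC = 0
  ds <- fix$ds
  ds$counts <- ds$counts[, c(1:5, 1:5)]
  ds$scaled <- ds$scaled[, c(1:5, 1:5)]
  ds$normalized <- ds$normalized[, c(1:5, 1:5)]
  ds$cells <- data.frame(cell_id = paste0("c", 1:10),
                         condition = rep(c("X", "Y"), each = 5),
                         timepoint = "T0")
  deg2 <- wilcoxon_de(ds, "X", "Y")
  expect_true(all(deg2$p_value == 1))
  expect_true(all(deg2$log_fc == 0))
})

test_that("rank-sum p-values match enumeration and the exact distribution", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)),
               list(statistic = 6, p_value = 0.1, method = "exact"))
  set.seed(21)
  for (i in 1:40) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    tied <- i %% 2 == 0
    x <- if (tied) sample(0:3, nx, replace = TRUE) else rnorm(nx)
    y <- if (tied) sample(0:3, ny, replace = TRUE) else rnorm(ny)
    got <- rank_sum_test(x, y)
    expect_equal(got$p_value, brute_wilcoxon_p(x, y), tolerance = 1e-12,
                 label = sprintf("case %d (%s)", i, got$method))
  }
})

test_that("BH adjustment equals the hand-computed step-up on fixtures", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_equal(brute_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    adj <- p.adjust(p, "BH")
    expect_equal(adj, brute_bh(p), tolerance = 1e-12)
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("top_k_overlap reports the intersection fraction and sets", {
  mk_deg <- function(ids, padj, lfc) structure(
    data.frame(gene_id = ids, log_fc = lfc, p_value = padj,
               p_adjusted = padj, significant = padj <= 0.05),
    class = c("deg_table", "data.frame"))
  mk_vt <- function(ids, dv) {
    out <- data.frame(gene_id = ids, delta_vmr = dv, abs_delta_vmr = abs(dv))
    out$rank <- integer(nrow(out))
    out$rank[order(-out$abs_delta_vmr, out$gene_id)] <- seq_len(nrow(out))
    structure(out, class = c("variability_table", "data.frame"))
  }
  ids <- sprintf("g%03d", 1:200)
  deg <- mk_deg(ids, seq(0.001, 1, length.out = 200), rep(1, 200))
  # deg top-100 = g001..g100; vt top-100 = g001..g003 plus g104..g200
  vt <- mk_vt(ids, c(1000, 999, 998, seq_len(197)))
  ov <- top_k_overlap(deg, vt, k = 100)
  expect_equal(ov$overlap_fraction, 0.03)
  expect_setequal(ov$both, c("g001", "g002", "g003"))
  identical_ov <- top_k_overlap(deg, mk_vt(ids, seq(200, 1)), k = 50)
  expect_equal(identical_ov$overlap_fraction, 1)
  expect_error(top_k_overlap(deg, vt, k = 500), "universe")
})

test_that("Kendall tau-b matches brute-force pair counting", {
  expect_equal(cor(1:3, 1:3, method = "kendall"), 1)
  expect_equal(cor(1:3, 3:1, method = "kendall"), -1)
  expect_equal(cor(c(1, 2, 3, 4), c(1, 3, 2, 4), method = "kendall"), 4 / 6,
               tolerance = 1e-12)
  set.seed(12)
  for (i in 1:1000) {
    n <- sample(4:12, 1)
    x <- sample(0:5, n, replace = TRUE)   # ties on both sides
    y <- sample(0:5, n, replace = TRUE)
    b <- brute_kendall(x, y)
    k <- suppressWarnings(cor(x, y, method = "kendall"))
    if (is.na(b)) expect_true(is.na(k)) else
      expect_equal(k, b, tolerance = 1e-12)
  }
})

test_that("characteristic correlations are null on independent annotation", {
  fix <- make_test_dataset(seed = 5, n_genes = 1500, n_cells = 150)
  vt <- variability_table(fix$ds, "control", "case")
  cr <- characteristic_correlations(vt, fix$study$annotation)
  expect_setequal(cr$characteristic,
                  c("transcript_level", "length_bp", "promoter_gc",
                    "phylostratum", "delta_frac", "delta_mean"))
  for (ch in c("length_bp", "promoter_gc", "phylostratum"))
    expect_lt(abs(cr$tau[cr$characteristic == ch]), 0.05)
  expect_true(all(abs(cr$tau) <= 1))
  expect_error(characteristic_correlations(vt, fix$study$annotation[1:2, ]),
               "fewer than 3")
})

test_that("null delta VMR exceeds a permutation 95th percentile ~5% of the time", {
  # two-condition data with no planted genes: split one condition in half
  sp <- dist_spec("negbinom", r = 2, p = 0.5)
  m <- sample_counts(sp, 1000, 400, seed = 31)
  row_vmr <- function(mm) apply(mm, 1, var) / rowMeans(mm)
  grp <- rep(c(TRUE, FALSE), 200)
  obs <- abs(row_vmr(m[, grp]) - row_vmr(m[, !grp]))
  set.seed(32)
  null <- replicate(12, {
    g <- sample(grp)
    abs(row_vmr(m[, g]) - row_vmr(m[, !g]))
  })
  thr <- quantile(null, 0.95)
  expect_equal(mean(obs > thr, na.rm = TRUE), 0.05, tolerance = 0.02 / 0.05)
})

test_that("ranked-list export preserves orderings", {
  fix <- make_test_dataset(seed = 7, n_genes = 150, n_cells = 30)
  vt <- variability_table(fix$ds, "control", "case")
  deg <- wilcoxon_de(fix$ds, "control", "case")
  d <- withr::local_tempdir()
  files <- export_ranked_lists(vt, deg, d, k = 20)
  rnk <- read.table(files[["variability_rnk"]], sep = "\t")
  expect_equal(nrow(rnk), nrow(vt))
  expect_true(all(diff(rnk$V2) <= 1e-12))    # signed delta VMR descending
  top <- readLines(files[["top_variability"]])
  expect_equal(top, vt$gene_id[order(vt$rank)][1:20])
  expect_error(export_ranked_lists(vt[0, ], deg, d), "empty")
})
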
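test_that("count matrices round-trip through Matrix Market with sidecars", {
  dir <- withr::local_tempdir()
  sim <- simulate_counts(n_genes = 400, n_cells = 50, n_hvg = 20, n_cc = 10,
                         n_cc_extra = 5, markers_per_group = 10,
                         n_housekeeping = 10, seed = 2)
  p <- file.path(dir, "mtx")
  write_count_matrix(sim$counts, p)
  back <- read_count_matrix(p)
  expect_equal(as.matrix(back), sim$counts)
  expect_error(read_count_matrix(file.path(dir, "nope")), "missing file")
})

test_that("cell QC applies every stated threshold rule with reasons", {
  counts <- make_qc_toy()
  qc0 <- cell_qc_metrics(counts)
  expect_true(all(qc0$total_umis >= 2500 & qc0$total_umis <= 6000))
  # plant violations
  counts2 <- counts
  # a 1500-UMI cell: scale down cell 1
  c1 <- counts[, 1]
  keep <- which(c1 > 0)[seq_len(1400)]
  x <- integer(nrow(counts)); x[keep] <- 1L
  x[keep[1:100]] <- 2L  # 1500 UMIs, 1400 genes
  counts2[, 1] <- x
  # a high-mito cell: reassign ~10% of cell 2's UMIs to a mitochondrial
  # gene without changing its library size or detected-gene count
  rownames(counts2)[1:2] <- c("MT-CO1", "MT-ND1")
  c2 <- counts2[, 2]
  shift <- min(400L, round(0.1 * sum(c2)))
  donors <- setdiff(which(c2 >= 2L), 1:2)[seq_len(shift)]
  c2[donors] <- c2[donors] - 1L
  c2["MT-CO1"] <- c2["MT-CO1"] + shift
  counts2[, 2] <- c2
  out <- filter_cells(counts2, qc_bounds())
  rep <- out$report
  expect_equal(rep$disposition[1], "low_umi")
  expect_equal(rep$disposition[2], "high_mito")
  expect_false(any(c("c01", "c02") %in% colnames(out$counts)))
  # all-pass matrix is the identity
  out0 <- filter_cells(counts, qc_bounds(max_mito = 1))
  expect_equal(out0$counts, counts)
  expect_true(all(out0$report$disposition == "pass"))
  # every input cell has exactly one disposition
  expect_equal(nrow(rep), ncol(counts2))
})

test_that("the loess residual rule removes planted gene-UMI outliers", {
  sim <- simulate_counts(n_genes = 1000, n_cells = 500, n_outliers = 3,
                         markers_per_group = 20, n_hvg = 40, n_cc = 20,
                         n_cc_extra = 10, n_housekeeping = 40, seed = 6)
  wide <- qc_bounds(min_umis = 0, max_umis = Inf, min_genes = 0,
                    max_genes = Inf, max_mito = 1)
  out <- filter_cells(sim$counts, wide)
  flagged <- out$report$barcode[out$report$disposition == "gene_umi_trend"]
  expect_true(all(sim$truth$outlier_barcodes %in% flagged))
  # few false positives under the 3 SD rule
  expect_lt(length(setdiff(flagged, sim$truth$outlier_barcodes)), 10)
})

test_that("gene filtering keeps genes with a UMI in at least two cells", {
  m <- matrix(0L, 3, 5, dimnames = list(c("one", "two", "none"),
                                        paste0("c", 1:5)))
  m["one", 1] <- 5L
  m["two", c(2, 4)] <- 1L
  out <- filter_genes(m)
  expect_equal(rownames(out), "two")
  empty <- m[integer(0), , drop = FALSE]
  expect_equal(dim(filter_genes(empty)), c(0L, 5L))
})

test_that("normalization scales to the factor and log-transforms", {
  m <- matrix(c(10L, 9990L, 50L, 4950L), 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  norm <- normalize_log(m)
  expect_equal(norm["g1", "c1"], log1p(10))  # total exactly 10,000
  # doubling a cell's counts leaves its normalized vector unchanged
  m2 <- m; m2[, 2] <- m2[, 2] * 2L
  expect_equal(normalize_log(m2)[, 2], norm[, 2])
  expect_equal(sum(norm == 0), sum(m == 0))
  m0 <- m; m0[, 1] <- 0L
  expect_error(normalize_log(m0), "zero total")
})

test_that("HVG selection recovers planted genes and applies the bounds", {
  sim <- simulate_counts(seed = 3)
  norm <- normalize_log(filter_genes(sim$counts))
  hvg <- select_hvgs(norm)
  top <- utils::head(hvg$scores$gene, 1200)
  expect_gte(sum(sim$truth$hvg_genes %in% top), 95)
  # prefix rule: all decoys that entered the top are ledgered out
  expect_true(all(!startsWith(hvg$genes, "RPL")))
  expect_true(all(!startsWith(hvg$genes, "RPS")))
  expect_true(all(!startsWith(hvg$genes, "MT")))
  expect_gte(length(hvg$ledger$ribo_mito), 1)
  # additive ledger arithmetic
  expect_equal(length(hvg$genes),
               min(1200, nrow(hvg$scores)) - length(hvg$ledger$ribo_mito))
  # a gene detected in 9 cells is excluded from candidacy
  norm9 <- norm
  g <- sim$truth$hvg_genes[1]
  x <- norm9[g, ]
  x[] <- 0
  x[seq_len(9)] <- sort(x, decreasing = TRUE)[seq_len(9)] + 2
  norm9[g, ] <- x
  hvg9 <- select_hvgs(norm9)
  expect_false(g %in% hvg9$scores$gene)
})

test_that("two-step cell-cycle removal clears planted cycle-correlated genes", {
  sim <- simulate_counts(seed = 3)
  norm <- normalize_log(filter_genes(sim$counts))
  hvg <- select_hvgs(norm)
  planted_cc <- c(sim$truth$cc_known, sim$truth$cc_extra)
  in_hvgs <- intersect(planted_cc, hvg$genes)
  expect_gte(length(in_hvgs), 5)  # the program is variable enough to enter
  out <- remove_cell_cycle(hvg, norm)
  expect_length(intersect(planted_cc, out$genes), 0)
  # step order: known genes fall in step 1 regardless of correlation
  expect_setequal(out$ledger$known_cc, intersect(sim$truth$cc_known,
                                                 hvg$genes))
  expect_true(all(intersect(sim$truth$cc_extra, hvg$genes) %in%
                    out$ledger$correlated_cc))
  # a gene orthogonal to the cycle program is retained
  orth <- intersect(sim$truth$hvg_genes, hvg$genes)
  expect_gt(length(intersect(orth, out$genes)) / length(orth), 0.9)
  # ledger additivity
  expect_equal(length(out$genes),
               length(hvg$genes) - length(out$ledger$known_cc) -
                 length(out$ledger$correlated_cc))
})

test_that("rank-sum markers match wilcox.test and recover planted markers", {
  # brute-force cross-check on a small matrix with ties
  set.seed(12)
  n <- 30
  labels <- rep(c("a", "b"), each = n / 2)
  m <- matrix(rpois(40 * n, 1.5), 40, n,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:n)))
  norm <- normalize_log(m + 1L)  # +1 avoids zero-total cells
  mk <- rank_markers(norm, labels, n_top = 10)
  for (g in sample(rownames(norm), 10)) {
    wt <- stats::wilcox.test(norm[g, labels == "a"], norm[g, labels == "b"],
                             exact = FALSE, correct = FALSE)
    row <- mk$table[["a"]][mk$table[["a"]]$gene == g, ]
    expect_equal(row$statistic, unname(wt$statistic))
    expect_equal(row$p, wt$p.value, tolerance = 1e-9)
  }
  # planted markers are recovered
  sim <- simulate_counts(seed = 3)
  normf <- normalize_log(filter_genes(sim$counts))
  mk2 <- rank_markers(normf, sim$groups)
  for (g in names(sim$truth$markers)) {
    expect_gte(sum(sim$truth$markers[[g]] %in% mk2$top_genes[[g]]), 45)
  }
  # a gene expressed only in one group tops that group's list
  m3 <- normf
  m3["G0001", ] <- 0
  m3["G0001", sim$groups == "group1"] <- 5
  mk3 <- rank_markers(m3, sim$groups)
  expect_equal(mk3$table[["group1"]]$gene[1], "G0001")
  expect_error(rank_markers(normf, rep("x", ncol(normf))), "two groups")
})

test_that("permuted labels produce no stable markers (null calibration)", {
  sim <- simulate_counts(n_genes = 600, n_cells = 200, markers_per_group = 0,
                         n_hvg = 0, n_cc = 0, n_cc_extra = 0, seed = 8)
  norm <- normalize_log(filter_genes(sim$counts))
  hits <- vapply(1:3, function(i) {
    set.seed(100 + i)
    lab <- sample(sim$groups)
    mk <- rank_markers(norm, lab)
    sum(vapply(mk$table, function(df) sum(df$p_adj < 0.05), numeric(1)))
  }, numeric(1))
  # across seeds, chance-level false discoveries only
  expect_lt(mean(hits), 0.05 * nrow(norm))
})

test_that("region gene selection follows the summed adjusted-p rule", {
  ptab <- data.frame(
    gene = paste0("g", 1:5),
    p_ctx_lge = c(1e-10, 1e-20, 0.5, 1e-3, 1),
    p_ctx_mge = c(1e-10, 0.9, 1e-8, 1e-3, 1))
  got <- select_region_genes(ptab, c("p_ctx_lge", "p_ctx_mge"), n_top = 3)
  # g1 (sum 2e-10) beats g4 (2e-3) beats g3 (0.5) beats g2 (0.9)
  expect_equal(got, c("g1", "g4", "g3"))
  expect_equal(select_region_genes(ptab, c("p_ctx_lge", "p_ctx_mge"),
                                   n_top = 99), ptab$gene[order(
                                     ptab$p_ctx_lge + ptab$p_ctx_mge)])
  expect_error(select_region_genes(ptab, "p_nope"), "missing comparison")
})

test_that("Jaccard matrix has the set-theoretic properties", {
  a100 <- paste0("g", 1:100)
  b1000 <- paste0("g", 81:1080)
  j <- jaccard_matrix(list(A = a100), list(B = b1000))
  expect_equal(j["A", "B"], 20 / 1080, tolerance = 1e-12)
  expect_equal(jaccard_matrix(list(x = a100), list(y = a100))[1, 1], 1)
  expect_equal(jaccard_matrix(list(x = a100),
                              list(y = paste0("h", 1:50)))[1, 1], 0)
  # symmetry and order invariance
  j2 <- jaccard_matrix(list(B = b1000), list(A = sample(a100)))
  expect_equal(j2["B", "A"], j["A", "B"])
  expect_warning(j0 <- jaccard_matrix(list(e = character(0)),
                                      list(f = character(0))), "empty")
  expect_equal(j0[1, 1], 0)
})

test_that("count simulation is seed-reproducible and filters never alter counts", {
  s1 <- simulate_counts(n_genes = 500, n_cells = 80, markers_per_group = 10,
                        n_hvg = 20, n_cc = 10, n_cc_extra = 5,
                        n_housekeeping = 20, seed = 5)
  s2 <- simulate_counts(n_genes = 500, n_cells = 80, markers_per_group = 10,
                        n_hvg = 20, n_cc = 10, n_cc_extra = 5,
                        n_housekeeping = 20, seed = 5)
  expect_identical(s1$counts, s2$counts)
  # filters yield submatrices of the input
  fg <- filter_genes(s1$counts)
  expect_true(all(fg == s1$counts[rownames(fg), colnames(fg)]))
  out <- filter_cells(s1$counts, qc_bounds(min_umis = 0, max_umis = Inf,
                                           min_genes = 0, max_genes = Inf,
                                           max_mito = 1))
  expect_true(all(out$counts == s1$counts[, colnames(out$counts)]))
})
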
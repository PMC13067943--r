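test_that("QC keeps cells strictly above the floors and strictly below the mito ceiling", {
  # construct cells with exact metric values: genes detected, total UMIs,
  # mito fraction
  make_cell <- function(n_genes_det, n_umi, mito_frac, total_genes = 1200) {
    x <- numeric(total_genes)
    mito_umi <- round(n_umi * mito_frac)
    x[1] <- mito_umi                       # the MT- gene
    rest <- n_umi - mito_umi
    k <- n_genes_det - (mito_umi > 0)
    x[2:(k + 1)] <- c(rest - (k - 1), rep(1, k - 1))
    x
  }
  genes <- c("MT-ND1", sprintf("G%04d", 1:1199))
  cells <- cbind(
    kept = make_cell(600, 1500, 0.05),
    at_gene_floor = make_cell(500, 1500, 0.05),
    at_umi_floor = make_cell(600, 1000, 0.05),
    at_mito_ceiling = make_cell(600, 1500, 0.10),
    just_above = make_cell(501, 1001, 0.099)
  )
  rownames(cells) <- genes
  res <- qc_filter(cells, qc_thresholds(gene_min_cells = 1))
  expect_equal(unname(res$cell_pass),
               c(TRUE, FALSE, FALSE, FALSE, TRUE))

  # relaxed CTC mode shifts the floors to 300 / 500
  ctc_cells <- cbind(kept = make_cell(400, 600, 0.05),
                     too_few = make_cell(300, 600, 0.05))
  rownames(ctc_cells) <- genes
  res_ctc <- qc_filter(ctc_cells, qc_thresholds(mode = "ctc",
                                                gene_min_cells = 1))
  expect_equal(unname(res_ctc$cell_pass), c(TRUE, FALSE))
})

test_that("gene-level QC runs after the cell filter and is order-stable", {
  set.seed(4)
  m <- matrix(rpois(300 * 40, 3), 300, 40,
              dimnames = list(sprintf("G%03d", 1:300), sprintf("c%02d", 1:40)))
  # a gene detected only in cells that fail QC must be dropped
  m["G001", ] <- 0
  bad_cells <- 1:5
  m[, bad_cells] <- 0
  m["G001", bad_cells] <- 5
  thr <- qc_thresholds(min_genes = 10, min_umis = 20, gene_min_cells = 4)
  res <- qc_filter(m, thr)
  expect_false("G001" %in% rownames(res$counts))
  expect_false(res$gene_pass[["G001"]])

  # permuting cell and gene order does not change which ids pass
  perm_g <- sample(nrow(m)); perm_c <- sample(ncol(m))
  res_p <- qc_filter(m[perm_g, perm_c], thr)
  expect_setequal(names(which(res_p$cell_pass)), names(which(res$cell_pass)))
  expect_setequal(rownames(res_p$counts), rownames(res$counts))

  # 5%-of-all-genes low-capture filter
  thr5 <- qc_thresholds(min_genes = 0, min_umis = 0, gene_min_cells = 1,
                        min_gene_fraction = 0.5)
  few <- m; few[16:300, 1] <- 0  # cell 1 detects at most 5% of genes
  res5 <- qc_filter(few, thr5)
  expect_false(res5$cell_pass[[1]])
})

test_that("rank-based signature scores hit the closed-form extremes", {
  # 10 genes; signature occupies the top ranks: score 1
  x <- matrix(c(10:1), 10, 1, dimnames = list(paste0("g", 1:10), "c1"))
  expect_equal(ucell_score(x, paste0("g", 1:3), r_max = 8)[1, 1], 1)
  # no signature gene detected: score exactly 0
  x0 <- x; x0[1:3, 1] <- 0
  expect_equal(ucell_score(x0, paste0("g", 1:3), r_max = 8)[1, 1], 0)
  # cap must exceed signature size
  expect_error(ucell_score(x, paste0("g", 1:9), r_max = 8), "r_max")
  expect_warning(ucell_score(x, c("g1", "g2", "nope"), r_max = 8), "absent")
})

test_that("signature scores equal the brute-force rank-sum oracle on random cells", {
  set.seed(77)
  for (rep in 1:200) {
    n_genes <- sample(10:60, 1)
    x <- rpois(n_genes, sample(c(0.5, 2, 10), 1))
    genes <- paste0("g", seq_len(n_genes))
    m <- matrix(x, ncol = 1, dimnames = list(genes, "c1"))
    n_sig <- sample(2:5, 1)
    sig_idx <- sample(n_genes, n_sig)
    r_max <- sample((n_sig + 1):n_genes, 1)
    got <- ucell_score(m, genes[sig_idx], r_max = r_max)[1, 1]
    want <- oracle_ucell_one(x, sig_idx, r_max)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("signature scores are invariant under monotone transforms of expression", {
  set.seed(13)
  m <- matrix(rpois(200 * 5, 2), 200, 5,
              dimnames = list(paste0("g", 1:200), paste0("c", 1:5)))
  sig <- list(s1 = paste0("g", 1:6), s2 = paste0("g", 50:57))
  base <- ucell_score(m, sig, r_max = 150)
  expect_equal(ucell_score(m * 7, sig, r_max = 150), base)
  expect_equal(ucell_score(log1p(m), sig, r_max = 150), base)
})

test_that("subtype assignment takes the argmax with the documented tie-break", {
  s <- rbind(c(0.9, 0.1, 0.1, 0.1),
             c(0.2, 0.8, 0.1, 0.0),
             c(0.5, 0.5, 0.1, 0.0))
  colnames(s) <- c("SCLC_A", "SCLC_N", "SCLC_P", "SCLC_I")
  suppressMessages(res <- assign_subtype(s))
  expect_equal(as.character(res$subtype), c("A", "N", "A"))
  expect_equal(res$tie, c(FALSE, FALSE, TRUE))
})

test_that("epitope positivity is the at-least-one-UMI rule", {
  m <- toy_counts(matrix(c(0, 1, 3, 0), 1), "DLL3")
  expect_equal(unname(call_epitope(m, "DLL3")), c(FALSE, TRUE, TRUE, FALSE))
  expect_warning(res <- call_epitope(m, "SEZ6"), "absent")
  expect_false(any(res))
})

test_that("Notch-based dropout assessment brackets the generative DLL3 fraction", {
  # all cells DLL3-positive: no negatives, candidate fraction 0
  sigs <- sclc_signatures()
  p_all <- sc_count_params(n_tumor = 200, n_reference = 0, n_genes = 400,
                           dll3_fraction = 1, dropout = 0, seed = 3L)
  sim_all <- simulate_counts(p_all)
  d_all <- dropout_assessment(sim_all$counts,
                              call_epitope(sim_all$counts, "DLL3"))
  expect_equal(d_all$candidate_fraction, 0)

  # known injected dropout with strong coregulation: the corrected bounds
  # cover the generative fraction across seeds
  covered <- vapply(1:20, function(s) {
    p <- sc_count_params(n_tumor = 600, n_reference = 0, n_genes = 400,
                         dll3_fraction = 0.4, dropout = 0.2,
                         notch_coreg = 1, seed = s)
    sim <- simulate_counts(p)
    d <- dropout_assessment(sim$counts, call_epitope(sim$counts, "DLL3"))
    d$corrected_lower <= 0.4 && 0.4 <= d$corrected_upper
  }, logical(1))
  expect_gte(mean(covered), 0.95)

  no_notch <- toy_counts(matrix(1, 1, 2), "DLL3")
  expect_warning(res <- dropout_assessment(no_notch, c(TRUE, FALSE),
                                           k_min = 2),
                 "undefined")
  expect_true(is.na(res$corrected_upper))
})

test_that("Venn regions partition the cells and match brute-force set logic", {
  genes <- c("DLL3", "SEZ6", "CD276")
  m <- toy_counts(rbind(c(1, 1, 0, 0), c(0, 1, 1, 0), c(0, 0, 1, 0)), genes)
  v <- coexpression_venn(m, genes)
  get <- function(r) v$regions$count[v$regions$region == r]
  expect_equal(get("DLL3"), 1)
  expect_equal(get("DLL3&SEZ6"), 1)
  expect_equal(get("SEZ6&CD276"), 1)
  expect_equal(sum(v$regions$count) + v$none, v$total)
  expect_equal(v$any, 3)

  # empty case: all regions zero, none = total
  m0 <- toy_counts(matrix(0, 3, 5), genes)
  v0 <- coexpression_venn(m0, genes)
  expect_equal(sum(v0$regions$count), 0)
  expect_equal(v0$none, 5)

  # random matrices: regions always partition, matching an enumeration oracle
  set.seed(19)
  for (rep in 1:20) {
    mm <- toy_counts(matrix(rbinom(3 * 30, 1, 0.4), 3, 30), genes)
    vv <- coexpression_venn(mm, genes)
    expect_equal(sum(vv$regions$count) + vv$none, 30)
    want <- table(apply(mm >= 1, 2, function(f)
      if (any(f)) paste(genes[f], collapse = "&") else "none"))
    for (r in vv$regions$region[vv$regions$count > 0])
      expect_equal(vv$regions$count[vv$regions$region == r],
                   unname(want[[r]]))
  }
})

test_that("pseudobulk sums conserve global gene totals and respect symmetry", {
  set.seed(23)
  m <- matrix(rpois(50 * 20, 2), 50, 20,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:20)))
  # single group reproduces the global totals
  pb1 <- pseudobulk(m, rep("all", 20))
  expect_equal(unname(pb1[, 1]), unname(rowSums(m)))
  # group sums always conserve totals
  g <- sample(c("x", "y", "z"), 20, replace = TRUE)
  pb <- pseudobulk(m, g)
  expect_equal(unname(rowSums(pb)), unname(rowSums(m)))
  # two identical groups of identical cells give identical profiles
  mm <- cbind(m[, c(1, 1)], m[, c(1, 1)])
  pb2 <- pseudobulk(mm, c("a", "a", "b", "b"))
  expect_equal(pb2[, "a"], pb2[, "b"])
  expect_error(pseudobulk(m, g[-1]), "cover")

  # pseudobulk DLL3 is higher in an SCLC-A tumor with a high DLL3-positive
  # fraction than in an SCLC-N tumor with a low fraction
  simA <- simulate_counts(sc_count_params(
    n_tumor = 200, n_reference = 0, n_genes = 500,
    subtype_mixture = c(A = 1, N = 0, P = 0, I = 0),
    dll3_fraction = 0.6, dropout = 0, seed = 44L))
  simN <- simulate_counts(sc_count_params(
    n_tumor = 200, n_reference = 0, n_genes = 500,
    subtype_mixture = c(A = 0, N = 1, P = 0, I = 0),
    dll3_fraction = 0.1, dropout = 0, seed = 44L))
  stopifnot(identical(rownames(simA$counts), rownames(simN$counts)))
  combined <- cbind(simA$counts, simN$counts)
  pb3 <- pseudobulk(combined, rep(c("A_tumor", "N_tumor"), each = 200))
  expect_gt(pb3["DLL3", "A_tumor"], pb3["DLL3", "N_tumor"])
})

test_that("joint DLL3/epithelial classification matches per-cell set logic", {
  genes <- c("DLL3", "EPCAM", "KRT8")
  m <- toy_counts(rbind(c(1, 1, 0, 0), c(0, 1, 1, 0), c(0, 0, 0, 0)), genes)
  res <- epithelial_origin(m, call_epitope(m, "DLL3"),
                           epithelial_genes = c("EPCAM", "KRT8"))
  expect_equal(as.character(res$class),
               c("DLL3+only", "DLL3+epith+", "epith+only", "neither"))
  # fractions match brute-force logic on a random toy matrix
  set.seed(31)
  mm <- toy_counts(matrix(rbinom(30, 1, 0.5), 3, 10), genes)
  dll3 <- mm["DLL3", ] >= 1
  epith <- colSums(mm[c("EPCAM", "KRT8"), , drop = FALSE] >= 1) > 0
  want <- c(mean(dll3 & epith), mean(dll3 & !epith),
            mean(!dll3 & epith), mean(!dll3 & !epith))
  got <- epithelial_origin(mm, call_epitope(mm, "DLL3"),
                           epithelial_genes = c("EPCAM", "KRT8"))
  expect_equal(unname(as.numeric(got$fractions[c("DLL3+epith+", "DLL3+only",
                                                 "epith+only", "neither")])),
               want)
})
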
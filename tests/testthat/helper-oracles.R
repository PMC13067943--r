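# Independent reference implementations used to cross-check the package's
# vectorized paths. These are written rule-by-rule / by definition and share
# no code with the implementation.

# scalar gating oracle: one event, literal decision order
oracle_classify_one <- function(dapi_nuc, epi_cyto, dll3_cyto, heme_cyto,
                                area, cfg) {
  if (heme_cyto > cfg$hematopoietic_threshold) return("leukocyte")
  dll3 <- dll3_cyto > cfg$dll3_threshold
  epi <- epi_cyto > cfg$epithelial_threshold
  tumor <- dll3 || epi
  if ((dapi_nuc < cfg$nucleation_threshold || area < cfg$min_area) && tumor)
    return("fragment")
  if (epi && dll3) return("CTC_dual")
  if (epi) return("CTC_epithelial_only")
  if (dll3) return("CTC_DLL3_only")
  "negative"
}

# brute-force UCell-style score for a single cell, straight from the
# definition: rank all genes by descending expression (average ties),
# undetected genes share rank r_max + 1, ranks capped at r_max + 1
oracle_ucell_one <- function(x, sig_idx, r_max) {
  r <- numeric(length(x))
  det <- which(x > 0)
  if (length(det)) {
    # average ranks by explicit tie groups, descending expression
    vals <- sort(unique(x[det]), decreasing = TRUE)
    pos <- 0
    for (v in vals) {
      ties <- which(x[det] == v)
      r[det[ties]] <- pos + (1 + length(ties)) / 2
      pos <- pos + length(ties)
    }
  }
  r[r == 0 | r > r_max] <- r_max + 1
  if (all(x[sig_idx] == 0)) return(0)
  n <- length(sig_idx)
  u <- sum(r[sig_idx]) - n * (n + 1) / 2
  max(0, 1 - u / (n * r_max))
}

# brute-force Clopper-Pearson bounds found as roots of the binomial tails
oracle_cp_bounds <- function(x, n, alpha = 0.05) {
  lower <- if (x == 0) 0 else
    uniroot(function(p) 1 - pbinom(x - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# AUROC from the rank-sum identity
auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# random single-event feature row on the 8-bit scale
random_event_row <- function(id = "e1", patient = "P1") {
  data.frame(event_id = id, patient_id = patient, timepoint = "baseline",
             dapi_nuc = runif(1, 0, 255), dapi_cyto = runif(1, 0, 255),
             epi_nuc = runif(1, 0, 255), epi_cyto = runif(1, 0, 255),
             dll3_nuc = runif(1, 0, 255), dll3_cyto = runif(1, 0, 255),
             heme_nuc = runif(1, 0, 255), heme_cyto = runif(1, 0, 255),
             area = runif(1, 5, 150),
             exp_dapi = 1, exp_epi = 1, exp_dll3 = 1, exp_heme = 1,
             stringsAsFactors = FALSE)
}

random_event_table <- function(n, patient = "P1") {
  do.call(rbind, lapply(seq_len(n), function(i)
    random_event_row(paste0("e", i), patient)))
}

# tiny dense count matrix with gene names, for epitope/venn logic
toy_counts <- function(mat, genes, cells = NULL) {
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, cells)
  mat
}
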
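#' Parameters for the synthetic single-cell UMI count simulator
#'
#' Describes a gene-by-cell UMI matrix with tumor subclones and reference
#' (immune/stromal) cells, SCLC subtype signature structure, epitope
#' positivity, chromosome-block copy-number shifts, per-gene dropout with
#' Notch--DLL3 coregulation, and log-normal library sizes. Defaults give a
#' predominantly SCLC-A tumor (mixture 0.70/0.18/0.10/0.02, the reported
#' prevalence order of the four subtypes) with a 35\% DLL3-positive
#' fraction, matching the median DLL3-positive tumor-cell fraction
#' observed in SCLC biopsies.
#'
#' @param n_tumor number of tumor cells (split over \code{n_subclones}).
#' @param n_reference number of reference (immune/stromal) cells.
#' @param n_subclones tumor subclones; each subclone belongs to one
#'   simulated sample.
#' @param n_genes total genes including the named marker genes.
#' @param n_chromosomes chromosomes over which genes are laid out in
#'   genomic order.
#' @param subtype_mixture proportions over subtypes A/N/P/I; must sum to 1.
#' @param signature_effect fold elevation of a subtype's signature genes
#'   in that subtype's cells, default 8.
#' @param offstate_factor fold applied to a signature's genes in tumor
#'   cells of \emph{other} subtypes, default 0.1: the SCLC subtype
#'   programs are driven by mutually exclusive transcription factors, so
#'   a cell of one subtype has the other programs largely silenced.
#' @param dll3_fraction proportion of tumor cells truly DLL3-positive,
#'   default 0.35.
#' @param epitope_fractions named proportions of tumor cells positive for
#'   additional epitopes, default \code{c(SEZ6 = 0.18, CD276 = 0.17)}.
#' @param epithelial_fraction proportion of tumor cells with detectable
#'   epithelial (EPCAM/keratin) transcripts, default 0.9.
#' @param dropout per-gene per-cell detection failure probability,
#'   default 0.3.
#' @param notch_coreg in [0,1]: strength of Notch-gene expression
#'   coregulation with true DLL3 positivity (0 = none), default 0.8.
#' @param cnv_blocks data frame (\code{chrom}, \code{start_gene},
#'   \code{end_gene}, \code{fold}) of copy-number blocks applied to tumor
#'   cells (gene indices are positions within the chromosome); \code{NULL}
#'   for the default single-gain-single-loss layout, or a zero-row data
#'   frame for no CNV.
#' @param lib_size_meanlog,lib_size_sdlog log-normal library-size factor
#'   parameters, defaults 0 and 0.3.
#' @param base_mean mean of the exponential baseline per-gene expression
#'   level, default 0.3 UMI.
#' @param seed integer seed.
#' @return object of class \code{sc_count_params}.
#' @export
sc_count_params <- function(n_tumor = 2000,
                            n_reference = 1000,
                            n_subclones = 2,
                            n_genes = 2000,
                            n_chromosomes = 10,
                            subtype_mixture = c(A = 0.70, N = 0.18,
                                                P = 0.10, I = 0.02),
                            signature_effect = 8,
                            offstate_factor = 0.1,
                            dll3_fraction = 0.35,
                            epitope_fractions = c(SEZ6 = 0.18, CD276 = 0.17),
                            epithelial_fraction = 0.9,
                            dropout = 0.3,
                            notch_coreg = 0.8,
                            cnv_blocks = NULL,
                            lib_size_meanlog = 0,
                            lib_size_sdlog = 0.3,
                            base_mean = 0.3,
                            seed = 1L) {
  if (abs(sum(subtype_mixture) - 1) > 1e-8)
    stop("'subtype_mixture' must sum to 1")
  if (dropout < 0 || dropout > 1) stop("'dropout' must lie in [0, 1]")
  if (dll3_fraction < 0 || dll3_fraction > 1)
    stop("'dll3_fraction' must lie in [0, 1]")
  if (signature_effect <= 0) stop("'signature_effect' must be > 0")
  if (offstate_factor <= 0) stop("'offstate_factor' must be > 0")
  if (is.null(cnv_blocks))
    cnv_blocks <- data.frame(chrom = c("chr1", "chr3"),
                             start_gene = c(1, 1),
                             end_gene = c(Inf, Inf),
                             fold = c(2, 0.5))
  if (nrow(cnv_blocks) && any(cnv_blocks$fold <= 0))
    stop("CNV fold-changes must be > 0")
  structure(list(
    n_tumor = n_tumor, n_reference = n_reference, n_subclones = n_subclones,
    n_genes = n_genes, n_chromosomes = n_chromosomes,
    subtype_mixture = subtype_mixture, signature_effect = signature_effect,
    offstate_factor = offstate_factor,
    dll3_fraction = dll3_fraction, epitope_fractions = epitope_fractions,
    epithelial_fraction = epithelial_fraction, dropout = dropout,
    notch_coreg = notch_coreg, cnv_blocks = cnv_blocks,
    lib_size_meanlog = lib_size_meanlog, lib_size_sdlog = lib_size_sdlog,
    base_mean = base_mean, seed = as.integer(seed)
  ), class = "sc_count_params")
}

#' Simulate a sparse UMI count matrix with ground truth
#'
#' Generates a genes-by-cells sparse nonnegative integer matrix. Marker
#' genes (the four SCLC subtype signatures, the epitopes DLL3/SEZ6/B7H3,
#' the Notch set and the epithelial set) are embedded among background
#' genes laid out in genomic order across synthetic chromosomes. Signature
#' genes are elevated \code{signature_effect}-fold in their subtype's
#' tumor cells before dropout; CNV blocks multiply tumor-cell expression
#' of the genes they span; epitope counts are zero-truncated Poisson in
#' truly positive cells and exactly zero otherwise (so at dropout 0 the
#' observed at-least-one-UMI fraction equals the generative fraction);
#' Notch genes are co-elevated with true DLL3 positivity with strength
#' \code{notch_coreg}. Dropout is a per-gene per-cell Bernoulli detection
#' failure applied after count generation.
#'
#' @param params an \code{\link{sc_count_params}} object.
#' @return list with \code{counts} (sparse \code{dgCMatrix}, genes x
#'   cells), \code{annotation} (data frame \code{gene}, \code{chrom},
#'   \code{start}; 0-based starts, genomic order), and \code{truth} (per
#'   cell: barcode, population, sample id, subtype, true epitope
#'   positivity flags).
#' @export
simulate_counts <- function(params) {
  stopifnot(inherits(params, "sc_count_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  sigs <- sclc_signatures()
  marker_genes <- unique(c(sigs$SCLC_A, sigs$SCLC_N, sigs$SCLC_P, sigs$SCLC_I,
                           sigs$epitopes, sigs$notch, sigs$epithelial))
  n_bg <- params$n_genes - length(marker_genes)
  if (n_bg < params$n_chromosomes)
    stop("'n_genes' too small for the marker gene sets")
  genes <- c(marker_genes, sprintf("GENE%05d", seq_len(n_bg)))
  n_genes <- length(genes)
  # shuffle genes across the genome so markers are not clustered
  ord <- sample.int(n_genes)
  genes <- genes[ord]
  chrom <- sort(rep_len(seq_len(params$n_chromosomes), n_genes))
  annotation <- data.frame(
    gene = genes,
    chrom = paste0("chr", chrom),
    # 0-based starts restarting within each chromosome
    start = (stats::ave(seq_len(n_genes), chrom, FUN = seq_along) - 1L) *
      1000L,
    stringsAsFactors = FALSE
  )

  n_cells <- params$n_tumor + params$n_reference
  barcodes <- sprintf("CELL%05d", seq_len(n_cells))
  is_tumor <- c(rep(TRUE, params$n_tumor), rep(FALSE, params$n_reference))
  subclone <- integer(n_cells)
  subclone[is_tumor] <- rep_len(seq_len(params$n_subclones), params$n_tumor)
  sample_id <- ifelse(is_tumor, paste0("S", subclone), "S_ref")
  subtype <- rep(NA_character_, n_cells)
  subtype[is_tumor] <- sample(names(params$subtype_mixture), params$n_tumor,
                              replace = TRUE, prob = params$subtype_mixture)

  # per-gene baseline expression level
  base <- stats::rexp(n_genes, rate = 1 / params$base_mean)
  names(base) <- genes
  # keep marker genes detectable at baseline
  base[marker_genes[marker_genes %in% genes]] <-
    pmax(base[marker_genes[marker_genes %in% genes]], 0.2)
  lib <- stats::rlnorm(n_cells, params$lib_size_meanlog,
                       params$lib_size_sdlog)

  # expected counts: genes x cells built column-block-wise
  mu <- matrix(base, n_genes, n_cells)
  sig_lists <- list(A = sigs$SCLC_A, N = sigs$SCLC_N, P = sigs$SCLC_P,
                    I = sigs$SCLC_I)
  for (st in names(sig_lists)) {
    idx <- which(genes %in% sig_lists[[st]])
    own <- which(!is.na(subtype) & subtype == st)
    other <- which(!is.na(subtype) & subtype != st)
    if (length(idx) && length(own))
      mu[idx, own] <- mu[idx, own] * params$signature_effect
    # mutually exclusive programs: other subtypes silence this signature
    if (length(idx) && length(other))
      mu[idx, other] <- mu[idx, other] * params$offstate_factor
  }

  # CNV blocks multiply tumor-cell expression of genes within the block
  cnv <- params$cnv_blocks
  cnv_factor <- rep(1, n_genes)
  if (nrow(cnv)) {
    for (b in seq_len(nrow(cnv))) {
      on_chr <- which(annotation$chrom == cnv$chrom[b])
      if (!length(on_chr))
        stop("CNV block references chromosome '", cnv$chrom[b],
             "' absent from the annotation")
      lo <- max(1, cnv$start_gene[b])
      hi <- min(length(on_chr), cnv$end_gene[b])
      if (lo > hi)
        stop("CNV block spans no genes on ", cnv$chrom[b])
      cnv_factor[on_chr[lo:hi]] <- cnv_factor[on_chr[lo:hi]] * cnv$fold[b]
    }
    mu[, is_tumor] <- mu[, is_tumor] * cnv_factor
  }

  # epitope positivity: zero-truncated Poisson in positive cells, 0 otherwise
  epi_frac <- c(DLL3 = params$dll3_fraction, params$epitope_fractions)
  truth_pos <- matrix(FALSE, n_cells, length(epi_frac),
                      dimnames = list(NULL, names(epi_frac)))
  for (g in names(epi_frac)) {
    gi <- match(g, genes)
    if (is.na(gi)) next
    pos <- is_tumor & stats::runif(n_cells) < epi_frac[[g]]
    truth_pos[, g] <- pos
    mu[gi, ] <- 0
  }

  # epithelial transcripts in most tumor cells, absent in reference
  epi_set_idx <- which(genes %in% sigs$epithelial)
  epith_pos <- is_tumor & stats::runif(n_cells) < params$epithelial_fraction
  mu[epi_set_idx, ] <- mu[epi_set_idx, ] *
    matrix(ifelse(epith_pos, 2, 0), length(epi_set_idx), n_cells,
           byrow = TRUE)

  # Notch genes co-elevated with true DLL3 positivity
  notch_idx <- which(genes %in% sigs$notch)
  dll3_true <- truth_pos[, "DLL3"]
  coreg <- 1 + 9 * params$notch_coreg
  mu[notch_idx, ] <- mu[notch_idx, ] *
    matrix(ifelse(dll3_true, coreg, 0.2), length(notch_idx), n_cells,
           byrow = TRUE)

  mu <- sweep(mu, 2, lib, `*`)
  counts <- matrix(stats::rpois(length(mu), mu), n_genes, n_cells)

  # zero-truncated epitope counts overwrite the Poisson draw
  for (g in names(epi_frac)) {
    gi <- match(g, genes)
    if (is.na(gi)) next
    pos <- truth_pos[, g]
    k <- sum(pos)
    if (k) counts[gi, pos] <- .rztpois(k, 1.5 * lib[pos])
    counts[gi, !pos] <- 0L
  }

  # dropout: per-gene per-cell Bernoulli detection failure
  if (params$dropout > 0) {
    keep <- matrix(stats::runif(length(counts)) >= params$dropout,
                   n_genes, n_cells)
    counts <- counts * keep
  }

  dimnames(counts) <- list(genes, barcodes)
  truth <- data.frame(
    barcode = barcodes,
    population = ifelse(is_tumor, paste0("tumor_", subclone), "reference"),
    sample_id = sample_id,
    subtype = subtype,
    stringsAsFactors = FALSE
  )
  for (g in colnames(truth_pos))
    truth[[paste0(tolower(g), "_positive")]] <- truth_pos[, g]

  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "CsparseMatrix"),
       annotation = annotation, truth = truth, seed = params$seed)
}

# zero-truncated Poisson via inverse-CDF conditioning on >= 1
.rztpois <- function(n, lambda) {
  lambda <- rep_len(lambda, n)
  u <- stats::runif(n)
  stats::qpois(stats::ppois(0, lambda) + u * (1 - stats::ppois(0, lambda)),
               lambda)
}
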
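#' SCLC marker gene sets
#'
#' Loads the signature sets shipped with the package: the four SCLC
#' molecular subtype signatures (SCLC-A/N/P/I), the targetable epitopes
#' (DLL3, SEZ6, B7H3 as CD276), the Notch pathway set used for dropout
#' assessment, and the epithelial (EPCAM + keratin) set.
#'
#' @param path optional path to a YAML file of named gene lists; defaults
#'   to the file shipped in \code{inst/extdata}.
#' @return named list of character vectors.
#' @export
sclc_signatures <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "signatures.yaml", package = "ctcDLL3",
                        mustWork = TRUE)
  sigs <- yaml::read_yaml(path)
  if (any(lengths(sigs) == 0L)) stop("empty gene list in signature file")
  lapply(sigs, as.character)
}

#' Quality-control thresholds for single-cell UMI matrices
#'
#' Cell-level floors are strict (a cell must have \emph{more than}
#' \code{min_genes} genes and \code{min_umis} UMIs) and the mitochondrial
#' ceiling is strict (\emph{less than} \code{max_mito}), matching the
#' published cutoffs (tumor mode >500 genes / >1,000 UMIs / <0.1 mito;
#' relaxed CTC mode >300 / >500). The gene-level rule excludes genes
#' detected in at most \code{gene_min_cells - 1} cells (default: genes in
#' <= 3 cells are excluded). \code{min_gene_fraction} optionally removes
#' low-capture cells detecting less than that fraction of all genes.
#'
#' @param min_genes,min_umis cell-level floors (strict \code{>}).
#' @param max_mito mitochondrial fraction ceiling (strict \code{<}).
#' @param gene_min_cells minimum number of cells a gene must be detected
#'   in to be kept, default 4.
#' @param min_gene_fraction minimum fraction of all genes a cell must
#'   detect (\code{>=}); default 0 (disabled).
#' @param mode \code{"tumor"} or \code{"ctc"}; the latter applies the
#'   relaxed floors (300 genes, 500 UMIs) unless overridden explicitly.
#' @return object of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(min_genes = NULL, min_umis = NULL, max_mito = 0.1,
                          gene_min_cells = 4, min_gene_fraction = 0,
                          mode = c("tumor", "ctc")) {
  mode <- match.arg(mode)
  if (is.null(min_genes)) min_genes <- if (mode == "tumor") 500 else 300
  if (is.null(min_umis)) min_umis <- if (mode == "tumor") 1000 else 500
  vals <- c(min_genes, min_umis, max_mito, gene_min_cells, min_gene_fraction)
  if (any(vals < 0)) stop("QC thresholds must be nonnegative")
  if (max_mito > 1 || min_gene_fraction > 1)
    stop("fraction thresholds must lie in [0, 1]")
  structure(list(min_genes = min_genes, min_umis = min_umis,
                 max_mito = max_mito, gene_min_cells = gene_min_cells,
                 min_gene_fraction = min_gene_fraction, mode = mode),
            class = "qc_thresholds")
}

#' Filter a UMI count matrix by cell- and gene-level QC
#'
#' Keeps cells with number of detected genes strictly above
#' \code{min_genes}, UMI counts strictly above \code{min_umis} and
#' mitochondrial fraction strictly below \code{max_mito} (and, when
#' enabled, detecting at least \code{min_gene_fraction} of all genes);
#' then drops genes detected in fewer than \code{gene_min_cells} of the
#' surviving cells. The gene filter is applied after the cell filter.
#' Mitochondrial genes are identified by a symbol prefix (default
#' \code{"^MT-"}).
#'
#' @param counts sparse or dense genes-by-cells integer matrix with
#'   rownames (gene symbols) and colnames (barcodes).
#' @param thresholds a \code{\link{qc_thresholds}} object.
#' @param mito_pattern regular expression identifying mitochondrial gene
#'   symbols.
#' @return list: \code{counts} (filtered matrix), \code{cell_pass} and
#'   \code{gene_pass} (named logical flags on the original dimensions,
#'   persisted for audit). Removing all cells warns rather than errors.
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds(),
                      mito_pattern = "^MT-") {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  n_genes_per_cell <- Matrix::colSums(counts > 0)
  umis <- Matrix::colSums(counts)
  mito_idx <- grepl(mito_pattern, rownames(counts))
  mito_frac <- if (any(mito_idx))
    Matrix::colSums(counts[mito_idx, , drop = FALSE]) / pmax(umis, 1)
  else rep(0, ncol(counts))
  cell_pass <- n_genes_per_cell > thresholds$min_genes &
    umis > thresholds$min_umis &
    mito_frac < thresholds$max_mito
  if (thresholds$min_gene_fraction > 0)
    cell_pass <- cell_pass &
      (n_genes_per_cell / nrow(counts)) >= thresholds$min_gene_fraction
  names(cell_pass) <- colnames(counts)
  if (!any(cell_pass)) warning("QC removed all cells")
  kept <- counts[, cell_pass, drop = FALSE]
  gene_pass <- Matrix::rowSums(kept > 0) >= thresholds$gene_min_cells
  names(gene_pass) <- rownames(counts)
  list(counts = kept[gene_pass, , drop = FALSE],
       cell_pass = cell_pass, gene_pass = gene_pass)
}

#' Rank-based per-cell signature score (capped Mann--Whitney U)
#'
#' For each cell, all genes are ranked by descending expression (average
#' ranks on ties); ranks beyond \code{r_max} are capped at
#' \code{r_max + 1}, and undetected genes share the capped rank. The
#' signature's U statistic is the sum of its (capped) ranks minus
#' n(n+1)/2, and the score is \code{1 - U/(n * r_max)}, floored at 0.
#' A cell detecting none of the signature's genes scores exactly 0.
#' Because the score depends on within-cell ranks only, it is invariant
#' under any strictly monotone transform of the cell's expression values
#' (scaling, log-transformation).
#'
#' @param counts genes-by-cells matrix (sparse or dense) with gene
#'   rownames.
#' @param signatures named list of gene vectors (or a single character
#'   vector).
#' @param r_max rank cap; must exceed every signature's size. Default
#'   1500.
#' @return matrix of scores, cells x signatures, in [0, 1].
#' @export
ucell_score <- function(counts, signatures, r_max = 1500) {
  if (!is.list(signatures)) signatures <- list(signature = signatures)
  sig_idx <- lapply(signatures, function(s) {
    idx <- match(s, rownames(counts))
    present <- s[!is.na(idx)]
    if (!length(present))
      stop("signature has no genes in the matrix")
    if (length(setdiff(s, present)))
      warning("signature genes absent from matrix: ",
              paste(setdiff(s, present), collapse = ", "))
    idx[!is.na(idx)]
  })
  for (nm in names(sig_idx))
    if (length(sig_idx[[nm]]) >= r_max)
      stop("rank cap r_max must exceed the size of signature '", nm, "'")

  counts <- as.matrix(counts)
  n_cells <- ncol(counts)
  scores <- matrix(0, n_cells, length(sig_idx),
                   dimnames = list(colnames(counts), names(sig_idx)))
  for (j in seq_len(n_cells)) {
    x <- counts[, j]
    detected <- x > 0
    r <- rep(r_max + 1, length(x))
    if (any(detected)) {
      rd <- rank(-x[detected], ties.method = "average")
      rd[rd > r_max] <- r_max + 1
      r[detected] <- rd
    }
    for (k in seq_along(sig_idx)) {
      idx <- sig_idx[[k]]
      if (!any(detected[idx])) next  # no signature gene detected: score 0
      n <- length(idx)
      u <- sum(r[idx]) - n * (n + 1) / 2
      scores[j, k] <- max(0, 1 - u / (n * r_max))
    }
  }
  scores
}

#' Assign each cell to its most enriched SCLC subtype
#'
#' Argmax over the four per-cell signature scores; exact ties are broken
#' by the fixed priority A > N > P > I (the prevalence order of the
#' subtypes) and flagged.
#'
#' @param scores cells x signatures score matrix with columns ordered (or
#'   named) A, N, P, I (prefix-matched, so \code{SCLC_A} etc. also work).
#' @return data frame: \code{subtype} (factor A/N/P/I) and logical
#'   \code{tie}.
#' @export
assign_subtype <- function(scores) {
  stopifnot(ncol(scores) == 4L)
  priority <- c("A", "N", "P", "I")
  cn <- colnames(scores)
  if (!is.null(cn)) {
    key <- sub("^SCLC[_-]?", "", cn)
    if (all(priority %in% key)) scores <- scores[, match(priority, key),
                                                 drop = FALSE]
  }
  best <- apply(scores, 1, max)
  tie <- rowSums(scores == best) > 1L
  pick <- apply(scores, 1, which.max)  # first max = priority order
  if (any(tie))
    message(sum(tie), " cell(s) with tied subtype scores broken by ",
            "A > N > P > I priority")
  data.frame(subtype = factor(priority[pick], levels = priority), tie = tie)
}

#' Per-cell epitope positivity by the UMI rule
#'
#' A cell is positive for a gene when its UMI count is at least
#' \code{min_umi} (default 1). A gene absent from the matrix yields
#' all-\code{FALSE} with a warning.
#'
#' @param counts genes-by-cells matrix.
#' @param gene gene symbol.
#' @param min_umi positivity floor, default 1.
#' @return named logical vector over cells.
#' @export
call_epitope <- function(counts, gene, min_umi = 1) {
  gi <- match(gene, rownames(counts))
  if (is.na(gi)) {
    warning("gene '", gene, "' absent from matrix; all cells negative")
    return(stats::setNames(rep(FALSE, ncol(counts)), colnames(counts)))
  }
  v <- as.numeric(counts[gi, ])
  stats::setNames(v >= min_umi, colnames(counts))
}

#' Bound the DLL3 false-negative rate using Notch coexpression
#'
#' DLL3 and the Notch pathway genes are transcriptionally coregulated, so
#' a DLL3-negative cell that nevertheless detects several Notch
#' transcripts is a candidate technical false negative (a dropout). A
#' DLL3-negative cell is flagged as a candidate when it detects at least
#' \code{k_min} genes of the Notch set. The operation reports bounds
#' rather than a single corrected value: the observed DLL3-positive
#' fraction is the lower bound and observed + candidate fraction the
#' upper bound.
#'
#' @param counts genes-by-cells matrix.
#' @param dll3_positive logical per-cell DLL3 flags
#'   (\code{\link{call_epitope}}).
#' @param notch_genes Notch gene set; default from
#'   \code{\link{sclc_signatures}}.
#' @param k_min minimum detected Notch genes for a candidate call,
#'   default 2.
#' @return list: \code{candidate} (logical per cell; \code{FALSE} for
#'   DLL3-positive cells), \code{observed_fraction},
#'   \code{candidate_fraction}, \code{corrected_lower},
#'   \code{corrected_upper}.
#' @export
dropout_assessment <- function(counts, dll3_positive,
                               notch_genes = sclc_signatures()$notch,
                               k_min = 2) {
  present <- intersect(notch_genes, rownames(counts))
  if (!length(present)) {
    warning("no Notch-set gene in matrix; dropout estimate undefined")
    return(list(candidate = rep(NA, ncol(counts)),
                observed_fraction = mean(dll3_positive),
                candidate_fraction = NA_real_,
                corrected_lower = NA_real_, corrected_upper = NA_real_))
  }
  n_notch <- Matrix::colSums(counts[present, , drop = FALSE] > 0)
  candidate <- !dll3_positive & n_notch >= k_min
  obs <- mean(dll3_positive)
  cand <- mean(candidate)
  list(candidate = candidate, observed_fraction = obs,
       candidate_fraction = cand,
       corrected_lower = obs, corrected_upper = obs + cand)
}

#' Venn partition of epitope-positive cells
#'
#' Counts every region of the k-set Venn partition of per-cell positivity
#' for up to four genes, plus the cells positive for any and for none.
#' Percentages are reported against the any-positive denominator, the
#' convention used when describing overlap of targetable epitopes.
#'
#' @param counts genes-by-cells matrix.
#' @param genes character vector of 1--4 gene symbols.
#' @param min_umi positivity floor, default 1.
#' @return list: \code{regions} (data frame with one row per nonempty
#'   membership pattern: the pattern string, \code{count}, \code{pct} of
#'   any-positive cells), \code{any}, \code{none}, \code{total}.
#' @export
coexpression_venn <- function(counts, genes, min_umi = 1) {
  if (length(genes) < 1L || length(genes) > 4L)
    stop("between 1 and 4 genes required")
  flags <- vapply(genes, function(g) call_epitope(counts, g, min_umi),
                  logical(ncol(counts)))
  if (is.null(dim(flags))) flags <- matrix(flags, ncol = length(genes),
                                           dimnames = list(NULL, genes))
  membership <- apply(flags, 1, function(f)
    if (any(f)) paste(genes[f], collapse = "&") else "none")
  any_pos <- sum(membership != "none")
  patterns <- unlist(lapply(seq_along(genes), function(k)
    utils::combn(genes, k, paste, collapse = "&")))
  counts_by <- vapply(patterns, function(p) sum(membership == p), integer(1))
  regions <- data.frame(
    region = patterns, count = unname(counts_by),
    pct = if (any_pos > 0) 100 * unname(counts_by) / any_pos else 0,
    stringsAsFactors = FALSE
  )
  list(regions = regions, any = any_pos,
       none = sum(membership == "none"), total = ncol(counts))
}

#' Aggregate single-cell counts into pseudobulk profiles
#'
#' Sums raw counts over cells within each group; sums over all groups
#' equal the global per-gene totals. Optionally rescales each group
#' profile to counts per million.
#'
#' @param counts genes-by-cells matrix.
#' @param grouping factor/character vector over cells (must cover all
#'   cells, no \code{NA}).
#' @param scale \code{"none"} (raw sums) or \code{"cpm"}.
#' @return genes x groups matrix.
#' @export
pseudobulk <- function(counts, grouping, scale = c("none", "cpm")) {
  scale <- match.arg(scale)
  if (length(grouping) != ncol(counts) || anyNA(grouping))
    stop("grouping must cover every cell")
  g <- factor(grouping)
  out <- vapply(levels(g), function(l)
    Matrix::rowSums(counts[, g == l, drop = FALSE]),
    numeric(nrow(counts)))
  if (scale == "cpm")
    out <- sweep(out, 2, pmax(colSums(out), 1), `/`) * 1e6
  out
}

#' Joint DLL3 / epithelial-marker classification of tumor cells
#'
#' Classifies each cell by the at-least-one-UMI rule into DLL3 and
#' epithelial (EPCAM/keratin) positivity: both, DLL3 only, epithelial
#' only, or neither, with cohort fractions over all cells. Used to ask
#' whether DLL3-expressing CTCs are of epithelial origin.
#'
#' @param counts genes-by-cells matrix.
#' @param dll3_positive logical per-cell DLL3 flags.
#' @param epithelial_genes epithelial set; default from
#'   \code{\link{sclc_signatures}}.
#' @param min_umi positivity floor, default 1.
#' @return list: \code{class} (factor per cell:
#'   \code{DLL3+epith+}, \code{DLL3+only}, \code{epith+only},
#'   \code{neither}) and \code{fractions} (named proportions).
#' @export
epithelial_origin <- function(counts, dll3_positive,
                              epithelial_genes = sclc_signatures()$epithelial,
                              min_umi = 1) {
  present <- intersect(epithelial_genes, rownames(counts))
  if (!length(present)) stop("no epithelial-set gene in matrix")
  epith <- Matrix::colSums(counts[present, , drop = FALSE] >= min_umi) > 0
  lv <- c("DLL3+epith+", "DLL3+only", "epith+only", "neither")
  cls <- ifelse(dll3_positive & epith, lv[1],
                ifelse(dll3_positive, lv[2],
                       ifelse(epith, lv[3], lv[4])))
  cls <- factor(cls, levels = lv)
  list(class = cls, fractions = prop.table(table(cls)))
}
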
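#' Infer a smoothed genome-ordered relative-expression (CNV) profile
#'
#' A deliberately simple expression-based copy-number inference (no HMM,
#' no subcluster tree), sufficient for total-CNV scoring and tumor-cell
#' calling: (1) library-size-normalize each cell to a fixed depth and
#' log2(1+x)-transform; (2) subtract the per-gene mean over the reference
#' (immune/stromal) cells, so the reference mean profile is 0 by
#' construction; (3) moving-average over a genomic window of
#' \code{window} genes within each chromosome (truncated windows at
#' chromosome edges); (4) re-center each cell by its own median;
#' (5) clip to \code{[-clip, +clip]} (log2 units).
#'
#' @param counts genes-by-cells matrix (sparse or dense) with gene
#'   rownames.
#' @param annotation data frame \code{gene}, \code{chrom}, \code{start}
#'   (0-based); defines the genomic order. Matrix genes missing from the
#'   annotation are excluded with a warning.
#' @param reference_cells barcodes (or logical/integer index) of the
#'   reference cell set; must be nonempty.
#' @param window odd number of genes in the smoothing window, >= 3,
#'   default 101. Must not exceed the smallest chromosome's gene count.
#' @param clip clipping bound in log2 units, default 1.
#' @param target_depth fixed depth for library-size normalization,
#'   default 10000.
#' @return object of class \code{cnv_profile}: list with \code{values}
#'   (genes x cells matrix in genomic order), \code{annotation} (ordered),
#'   \code{reference_cells}, \code{window}, \code{clip}.
#' @export
infer_cnv_profile <- function(counts, annotation, reference_cells,
                              window = 101, clip = 1,
                              target_depth = 10000) {
  if (window < 3 || window %% 2 == 0) stop("'window' must be odd and >= 3")
  if (is.logical(reference_cells)) reference_cells <-
      colnames(counts)[reference_cells]
  if (is.numeric(reference_cells)) reference_cells <-
      colnames(counts)[reference_cells]
  reference_cells <- intersect(reference_cells, colnames(counts))
  if (!length(reference_cells)) stop("reference cell set is empty")

  keep <- rownames(counts) %in% annotation$gene
  if (!all(keep)) {
    warning(sum(!keep), " matrix gene(s) missing from annotation excluded")
    counts <- counts[keep, , drop = FALSE]
  }
  ann <- annotation[match(rownames(counts), annotation$gene), ]
  ord <- order(ann$chrom, ann$start)
  ann <- ann[ord, ]
  counts <- counts[ord, , drop = FALSE]
  chrom_sizes <- table(ann$chrom)
  if (window > min(chrom_sizes))
    stop("window (", window, ") exceeds the smallest chromosome's gene ",
         "count (", min(chrom_sizes), ")")

  depth <- pmax(Matrix::colSums(counts), 1)
  norm <- log2(1 + sweep(as.matrix(counts), 2, depth / target_depth, `/`))
  ref_mean <- rowMeans(norm[, reference_cells, drop = FALSE])
  centered <- norm - ref_mean

  smoothed <- matrix(0, nrow(centered), ncol(centered),
                     dimnames = dimnames(centered))
  for (chr in unique(ann$chrom)) {
    idx <- which(ann$chrom == chr)
    smoothed[idx, ] <- .running_mean(centered[idx, , drop = FALSE], window)
  }
  values <- sweep(smoothed, 2, apply(smoothed, 2, stats::median), `-`)
  values[values > clip] <- clip
  values[values < -clip] <- -clip

  structure(list(values = values, annotation = ann,
                 reference_cells = reference_cells,
                 window = window, clip = clip),
            class = "cnv_profile")
}

# column-wise running mean along rows with truncated edge windows
.running_mean <- function(m, window) {
  half <- (window - 1) / 2
  n <- nrow(m)
  cs <- apply(m, 2, cumsum)
  if (n == 1L) cs <- matrix(cs, 1)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  upper <- cs[hi, , drop = FALSE]
  lower <- rbind(0, cs)[lo, , drop = FALSE]
  sweep(upper - lower, 1, hi - lo + 1, `/`)
}

#' Total CNV score per cell
#'
#' The per-cell sum of absolute smoothed relative-expression values of a
#' \code{\link{infer_cnv_profile}} result. Aneuploid cells, whose
#' profiles deviate from the diploid reference across chromosome blocks,
#' score high; cells with an identically zero profile score exactly 0.
#'
#' @param profile a \code{cnv_profile}.
#' @return named nonnegative numeric vector over cells.
#' @export
cnv_total_score <- function(profile) {
  stopifnot(inherits(profile, "cnv_profile"))
  colSums(abs(profile$values))
}

#' Call tumor versus normal cells from CNV scores and cluster structure
#'
#' A cluster of cells is annotated normal when (a) its median total CNV
#' score lies at or below the \code{score_quantile} quantile of all cells'
#' scores (so a degenerate all-zero input is normal), and (b) it is mixed from multiple samples: no single sample
#' contributes more than \code{mixing_threshold} of its cells. All cells
#' of every other cluster are called tumor. With a single sample in the
#' input the mixing criterion is skipped with a warning and the score
#' criterion alone applies.
#'
#' @param scores per-cell total CNV scores (\code{\link{cnv_total_score}}).
#' @param clusters per-cell cluster labels (clustering is supplied, not
#'   computed here).
#' @param samples per-cell sample ids.
#' @param score_quantile quantile of all scores below which a cluster's
#'   median counts as low, default 0.25.
#' @param mixing_threshold maximum single-sample share for a mixed
#'   cluster, default 0.75.
#' @return list: \code{tumor} (logical per cell), \code{cluster_calls}
#'   (data frame per cluster: median score, low-score flag, max sample
#'   share, normal flag).
#' @export
call_tumor_cells <- function(scores, clusters, samples,
                             score_quantile = 0.25,
                             mixing_threshold = 0.75) {
  stopifnot(length(scores) == length(clusters),
            length(scores) == length(samples))
  cutoff <- stats::quantile(scores, score_quantile, names = FALSE)
  single_sample <- length(unique(samples)) == 1L
  if (single_sample)
    warning("single sample: mixing criterion skipped, score criterion ",
            "alone applies")
  cl <- unique(clusters)
  calls <- do.call(rbind, lapply(cl, function(k) {
    in_k <- clusters == k
    med <- stats::median(scores[in_k])
    share <- max(prop.table(table(samples[in_k])))
    low <- med <= cutoff
    mixed <- single_sample || share <= mixing_threshold
    data.frame(cluster = k, median_score = med, low_score = low,
               max_sample_share = share, normal = low && mixed,
               stringsAsFactors = FALSE)
  }))
  normal_clusters <- calls$cluster[calls$normal]
  list(tumor = !(clusters %in% normal_clusters), cluster_calls = calls)
}
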
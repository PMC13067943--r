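#' Read a per-cell feature or generic delimited table
#'
#' Tab-delimited with header; column names are matched
#' case-insensitively against the documented schema and lower-cased.
#' Mixed line endings (LF/CRLF) parse identically.
#'
#' @param path file path.
#' @param sep field separator, default tab.
#' @return data frame.
#' @export
read_cell_features <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  names(df) <- tolower(names(df))
  df
}

#' Write a delimited table (values preserved to full precision)
#'
#' @param df data frame.
#' @param path file path.
#' @param sep field separator, default tab.
#' @export
write_cell_features <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a Matrix Market UMI matrix with gene/barcode sidecars
#'
#' Expects \code{matrix.mtx}, \code{genes.tsv} and \code{barcodes.tsv}
#' in \code{dir} (names configurable). Indices are 1-based on disk (the
#' Matrix Market convention) and carried as dimnames in memory.
#'
#' @param dir directory holding the three files.
#' @param matrix_file,genes_file,barcodes_file file names within
#'   \code{dir}.
#' @return sparse \code{dgCMatrix}, genes x cells.
#' @export
read_counts_mtx <- function(dir, matrix_file = "matrix.mtx",
                            genes_file = "genes.tsv",
                            barcodes_file = "barcodes.tsv") {
  m <- methods::as(Matrix::readMM(file.path(dir, matrix_file)),
                   "CsparseMatrix")
  genes <- readLines(file.path(dir, genes_file))
  barcodes <- readLines(file.path(dir, barcodes_file))
  if (length(genes) != nrow(m) || length(barcodes) != ncol(m))
    stop("sidecar lengths do not match matrix dimensions")
  dimnames(m) <- list(genes, barcodes)
  m
}

#' Write a Matrix Market UMI matrix with gene/barcode sidecars
#'
#' @param counts genes-by-cells matrix with dimnames.
#' @param dir output directory (created if absent).
#' @inheritParams read_counts_mtx
#' @return \code{dir}, invisibly.
#' @export
write_counts_mtx <- function(counts, dir, matrix_file = "matrix.mtx",
                             genes_file = "genes.tsv",
                             barcodes_file = "barcodes.tsv") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, matrix_file))
  writeLines(rownames(counts), file.path(dir, genes_file))
  writeLines(colnames(counts), file.path(dir, barcodes_file))
  invisible(dir)
}

#' Read a gene annotation table (gene, chrom, start)
#'
#' Tab-delimited, 0-based half-open starts.
#'
#' @param path file path.
#' @return data frame with \code{gene}, \code{chrom}, \code{start}.
#' @export
read_gene_annotation <- function(path) {
  df <- read_cell_features(path)
  need <- c("gene", "chrom", "start")
  if (!all(need %in% names(df)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read a run configuration from YAML or JSON
#'
#' Format chosen by extension (\code{.yaml}/\code{.yml} or \code{.json}).
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unrecognized config extension: .", ext)
}

# provenance block attached to every report: config + md5 hash + seed
.provenance <- function(config, seed) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  list(config = config,
       config_md5 = unname(tools::md5sum(tmp)),
       seed = seed,
       package_version = as.character(utils::packageVersion("ctcDLL3")))
}

#' Run the CTC DLL3 scoring pipeline end to end
#'
#' Chains the stages on either simulated or file-based inputs. The
#' immunofluorescence arm gates the per-event feature table, enumerates
#' CTCs per patient, stratifies by DLL3 fraction, and computes the
#' contingency table, exact-binomial predictive metrics and per-response
#' pooled marker totals. The single-cell arm (when count inputs are
#' given) runs QC, subtype scoring and assignment, epitope positivity,
#' the coexpression Venn partition, pseudobulk aggregation and CNV-based
#' tumor-cell calling. Every report carries a provenance block (config,
#' md5 of the serialized config, seed, package version).
#'
#' @param config named list. Recognized keys: \code{stages} (character
#'   subset of \code{c("if", "sc")}); \code{seed}; \code{features},
#'   \code{truth}, \code{volumes}, \code{clinical} (IF inputs as data
#'   frames / named vector); \code{gating} (arguments for
#'   \code{\link{gating_config}}); \code{cutoff}, \code{high_cutoff},
#'   \code{alpha}; \code{counts}, \code{annotation} (single-cell inputs);
#'   \code{qc} (arguments for \code{\link{qc_thresholds}});
#'   \code{reference_cells}, \code{clusters}, \code{samples} (CNV stage);
#'   \code{venn_genes}. Unknown keys are rejected.
#' @return named list report with one element per executed stage plus
#'   \code{provenance}.
#' @export
run_pipeline <- function(config) {
  known <- c("stages", "seed", "features", "truth", "volumes", "clinical",
             "gating", "cutoff", "high_cutoff", "alpha", "counts",
             "annotation", "qc", "reference_cells", "clusters", "samples",
             "venn_genes", "cnv_window", "cnv_clip")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  stages <- config$stages
  if (is.null(stages) || !length(stages))
    stop("config must select at least one stage ('if' and/or 'sc')")
  if (!all(stages %in% c("if", "sc")))
    stop("stages must be a subset of c('if', 'sc')")
  seed <- if (is.null(config$seed)) NA_integer_ else config$seed
  report <- list()

  if ("if" %in% stages) {
    if (is.null(config$features) || is.null(config$volumes) ||
        is.null(config$clinical))
      stop("stage 'if' requires 'features', 'volumes' and 'clinical' inputs")
    gc_args <- if (is.null(config$gating)) list() else config$gating
    gcfg <- do.call(gating_config, gc_args)
    calls <- classify_events(normalize_intensity(config$features), gcfg)
    enum <- enumerate_ctcs(calls, config$volumes, gcfg)
    summ <- patient_summaries(enum, config$clinical,
                              cutoff = config$cutoff %||% 25,
                              high_cutoff = config$high_cutoff %||% 75)
    tab <- build_contingency(summ)
    report$if_arm <- list(
      calls = calls, enumeration = enum, summaries = summ,
      contingency = tab,
      metrics = predictive_metrics(tab, alpha = config$alpha %||% 0.05),
      group_totals = group_marker_totals(summ)
    )
  }

  if ("sc" %in% stages) {
    if (is.null(config$counts))
      stop("stage 'sc' requires a 'counts' input")
    qc_args <- if (is.null(config$qc)) list() else config$qc
    thr <- do.call(qc_thresholds, qc_args)
    qc <- qc_filter(config$counts, thr)
    sigs <- sclc_signatures()
    r_max <- min(1500, nrow(qc$counts) - 1)
    scores <- ucell_score(qc$counts,
                          sigs[c("SCLC_A", "SCLC_N", "SCLC_P", "SCLC_I")],
                          r_max = r_max)
    subtype <- assign_subtype(scores)
    dll3 <- call_epitope(qc$counts, "DLL3")
    venn_genes <- config$venn_genes %||% sigs$epitopes
    sc <- list(
      qc = qc[c("cell_pass", "gene_pass")],
      scores = scores, subtype = subtype,
      dll3_positive = dll3,
      dropout = dropout_assessment(qc$counts, dll3, sigs$notch),
      venn = coexpression_venn(qc$counts, venn_genes),
      pseudobulk = pseudobulk(qc$counts,
                              rep("all", ncol(qc$counts)))
    )
    if (!is.null(config$annotation) && !is.null(config$reference_cells)) {
      prof <- infer_cnv_profile(qc$counts, config$annotation,
                                config$reference_cells,
                                window = config$cnv_window %||% 101,
                                clip = config$cnv_clip %||% 1)
      sc$cnv_scores <- cnv_total_score(prof)
      if (!is.null(config$clusters)) {
        kept <- colnames(qc$counts)
        sc$tumor_calls <- call_tumor_cells(
          sc$cnv_scores,
          config$clusters[kept],
          (config$samples %||% stats::setNames(rep("S1", length(kept)),
                                               kept))[kept])
      }
    }
    report$sc_arm <- sc
  }

  report$provenance <- .provenance(
    config[setdiff(names(config),
                   c("features", "truth", "counts", "annotation"))], seed)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline report (or any list) as JSON
#'
#' @param report named list.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
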
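#' Gating configuration for immunofluorescence CTC classification
#'
#' Bundles the intensity thresholds, morphology cutoffs and reference blood
#' volume used to classify segmented imaging events into CTC classes,
#' leukocytes and circulating tumor fragments. All intensities are on the
#' 8-bit (0--255) scale and are compared against exposure-normalized values.
#'
#' The DLL3 threshold of 20 is applied as a strict inequality (an event at
#' exactly 20 is negative); the same strictness is used for every gate. The
#' epithelial, hematopoietic and nucleation thresholds are not fixed by any
#' published consensus; the defaults here were calibrated once on synthetic
#' positive/negative control populations generated by
#' \code{\link{simulate_if_cohort}} (mimicking cell-line/WBC control
#' calibration) and sit far from both class modes.
#'
#' @param dll3_threshold DLL3 positivity threshold (strict \code{>}),
#'   default 20.
#' @param epithelial_threshold epithelial-cocktail (EpCAM/pan-CK/CK19)
#'   positivity threshold, default 20.
#' @param hematopoietic_threshold hematopoietic-cocktail (CD45/CD66b/CD16)
#'   exclusion threshold, default 30.
#' @param nucleation_threshold minimum nuclear-stain intensity for an event
#'   to count as nucleated, default 20.
#' @param min_area minimum intact-cell area in square micrometres,
#'   default 30.
#' @param reference_volume_ml blood volume (mL) to which counts are
#'   normalized, default 20.
#' @return An object of class \code{gating_config}.
#' @export
gating_config <- function(dll3_threshold = 20,
                          epithelial_threshold = 20,
                          hematopoietic_threshold = 30,
                          nucleation_threshold = 20,
                          min_area = 30,
                          reference_volume_ml = 20) {
  thresholds <- c(dll3_threshold, epithelial_threshold,
                  hematopoietic_threshold, nucleation_threshold, min_area)
  if (any(!is.finite(thresholds)) || any(thresholds < 0))
    stop("all gating thresholds must be finite and >= 0")
  if (!is.finite(reference_volume_ml) || reference_volume_ml <= 0)
    stop("'reference_volume_ml' must be > 0")
  structure(list(
    dll3_threshold = dll3_threshold,
    epithelial_threshold = epithelial_threshold,
    hematopoietic_threshold = hematopoietic_threshold,
    nucleation_threshold = nucleation_threshold,
    min_area = min_area,
    reference_volume_ml = reference_volume_ml
  ), class = "gating_config")
}

#' @export
print.gating_config <- function(x, ...) {
  cat("Gating configuration\n")
  cat(sprintf("  DLL3 > %g, epithelial > %g, hematopoietic exclusion > %g\n",
              x$dll3_threshold, x$epithelial_threshold,
              x$hematopoietic_threshold))
  cat(sprintf("  nucleation >= %g (strict >), min area %g um^2, reference volume %g mL\n",
              x$nucleation_threshold, x$min_area, x$reference_volume_ml))
  invisible(x)
}

# columns an IF feature table must carry; intensity columns are mask means per
# channel, exposure columns are ratios of actual to reference exposure
.if_intensity_cols <- c("dapi_nuc", "dapi_cyto", "epi_nuc", "epi_cyto",
                        "dll3_nuc", "dll3_cyto", "heme_nuc", "heme_cyto")
.if_exposure_cols <- c(dapi = "exp_dapi", epi = "exp_epi",
                       dll3 = "exp_dll3", heme = "exp_heme")
.if_required_cols <- c("event_id", "patient_id", "timepoint",
                       .if_intensity_cols, "area", unname(.if_exposure_cols))

.check_feature_table <- function(records) {
  missing <- setdiff(.if_required_cols, names(records))
  if (length(missing))
    stop("feature table is missing channel/column(s): ",
         paste(missing, collapse = ", "))
  invisible(records)
}

#' Exposure-normalize per-cell channel intensities
#'
#' Divides each channel's nuclear- and cytoplasmic-mask mean intensity by
#' that channel's exposure factor (ratio of actual to reference exposure),
#' so that scoring thresholds are comparable across acquisitions where
#' reduced exposure was used to avoid saturation. With all factors equal to
#' 1 the table is returned unchanged, so the operation is idempotent once
#' factors are reset.
#'
#' @param records data frame of per-event IF features (see
#'   \code{\link{simulate_if_cohort}} for the column schema).
#' @return The same data frame with intensity columns divided by their
#'   channel's exposure factor and all exposure factors set to 1.
#' @export
normalize_intensity <- function(records) {
  .check_feature_table(records)
  for (chan in names(.if_exposure_cols)) {
    f <- records[[.if_exposure_cols[[chan]]]]
    if (any(!is.finite(f)) || any(f <= 0))
      stop("nonpositive exposure factor in channel '", chan, "'")
    for (comp in c("_nuc", "_cyto")) {
      col <- paste0(chan, comp)
      records[[col]] <- records[[col]] / f
    }
    records[[.if_exposure_cols[[chan]]]] <- rep(1, nrow(records))
  }
  records
}

.event_labels <- c("CTC_DLL3_only", "CTC_epithelial_only", "CTC_dual",
                   "leukocyte", "fragment", "negative")

#' Classify imaging events into CTC classes, leukocytes and fragments
#'
#' Applies the marker-based decision rule to exposure-normalized per-event
#' intensities. Gating uses the cytoplasmic-mask mean for the membrane or
#' cytoplasmic markers (epithelial cocktail, DLL3, hematopoietic cocktail)
#' and the nuclear-mask mean for the nuclear stain. The decision order is:
#' \enumerate{
#'   \item hematopoietic signal above the exclusion threshold: leukocyte;
#'   \item nuclear signal below the nucleation threshold or area below the
#'     intact-cell minimum, with any tumor marker positive: fragment;
#'   \item otherwise by marker combination: epithelial and DLL3 positive
#'     gives \code{CTC_dual}; epithelial alone \code{CTC_epithelial_only};
#'     DLL3 alone \code{CTC_DLL3_only}; neither \code{negative}.
#' }
#' All positivity calls use a strict \code{>} of the configured threshold,
#' so an event at exactly the DLL3 threshold of 20 is negative.
#'
#' @param records normalized feature table (\code{\link{normalize_intensity}}).
#' @param config a \code{\link{gating_config}}.
#' @return data frame with one row per event: \code{event_id},
#'   \code{patient_id}, \code{timepoint}, \code{label} (factor over the six
#'   classes), \code{dll3_positive}, and the normalized gating intensities.
#' @export
classify_events <- function(records, config = gating_config()) {
  stopifnot(inherits(config, "gating_config"))
  .check_feature_table(records)
  gate_cols <- c("dapi_nuc", "epi_cyto", "dll3_cyto", "heme_cyto")
  for (col in gate_cols)
    if (any(is.na(records[[col]])))
      stop("missing intensity value in channel column '", col, "'")

  dll3_pos <- records$dll3_cyto > config$dll3_threshold
  epi_pos <- records$epi_cyto > config$epithelial_threshold
  heme_pos <- records$heme_cyto > config$hematopoietic_threshold
  tumor_pos <- dll3_pos | epi_pos
  not_intact <- records$dapi_nuc < config$nucleation_threshold |
    records$area < config$min_area

  label <- rep("negative", nrow(records))
  label[tumor_pos & dll3_pos & epi_pos] <- "CTC_dual"
  label[tumor_pos & epi_pos & !dll3_pos] <- "CTC_epithelial_only"
  label[tumor_pos & dll3_pos & !epi_pos] <- "CTC_DLL3_only"
  label[not_intact & tumor_pos] <- "fragment"
  label[heme_pos] <- "leukocyte"

  data.frame(
    event_id = records$event_id,
    patient_id = records$patient_id,
    timepoint = records$timepoint,
    label = factor(label, levels = .event_labels),
    dll3_positive = dll3_pos,
    dapi_nuc = records$dapi_nuc,
    epi_cyto = records$epi_cyto,
    dll3_cyto = records$dll3_cyto,
    heme_cyto = records$heme_cyto,
    area = records$area,
    stringsAsFactors = FALSE
  )
}

#' Enumerate CTCs per patient, normalized to a reference blood volume
#'
#' Counts gated events per patient and scales the counts to the configured
#' reference volume (default 20 mL): scaled count = raw count x
#' (reference volume / actual volume). Raw counts are integers; scaled
#' counts are reals. DLL3-positive CTCs are CTC-class events whose
#' normalized DLL3 intensity strictly exceeds the threshold
#' (\code{CTC_DLL3_only}, \code{CTC_dual}, plus any DLL3-positive
#' \code{CTC_epithelial_only} events -- impossible by construction of the
#' labels, but counted from the flag for safety).
#'
#' @param calls output of \code{\link{classify_events}}.
#' @param volumes named numeric vector (or single number) of actual blood
#'   volumes in mL per patient id.
#' @param config a \code{\link{gating_config}}.
#' @return data frame of class \code{ctc_enumeration}: one row per patient
#'   with raw and volume-scaled per-label counts, total CTCs and
#'   DLL3-positive CTCs, and the DLL3-positive fraction in percent
#'   (\code{NA} when a patient has no CTCs).
#' @export
enumerate_ctcs <- function(calls, volumes, config = gating_config()) {
  stopifnot(inherits(config, "gating_config"))
  patients <- unique(as.character(calls$patient_id))
  if (length(volumes) == 1L && is.null(names(volumes)))
    volumes <- stats::setNames(rep(volumes, length(patients)), patients)
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop("blood volumes must be positive")
  missing_vol <- setdiff(patients, names(volumes))
  if (length(missing_vol))
    stop("no blood volume for patient(s): ", paste(missing_vol, collapse = ", "))

  ctc_labels <- c("CTC_DLL3_only", "CTC_epithelial_only", "CTC_dual")
  out <- lapply(patients, function(p) {
    sub <- calls[calls$patient_id == p, , drop = FALSE]
    scale <- config$reference_volume_ml / volumes[[p]]
    tab <- table(sub$label)
    is_ctc <- sub$label %in% ctc_labels
    n_ctc <- sum(is_ctc)
    n_dll3 <- sum(is_ctc & sub$dll3_positive)
    data.frame(
      patient_id = p,
      n_events = nrow(sub),
      volume_ml = unname(volumes[[p]]),
      ctc_raw = n_ctc,
      ctc_dll3_raw = n_dll3,
      ctc_per_ref = n_ctc * scale,
      ctc_dll3_per_ref = n_dll3 * scale,
      dll3_fraction_pct = if (n_ctc > 0) 100 * n_dll3 / n_ctc else NA_real_,
      dll3_only_raw = unname(tab[["CTC_DLL3_only"]]),
      epithelial_only_raw = unname(tab[["CTC_epithelial_only"]]),
      dual_raw = unname(tab[["CTC_dual"]]),
      leukocyte_raw = unname(tab[["leukocyte"]]),
      fragment_raw = unname(tab[["fragment"]]),
      negative_raw = unname(tab[["negative"]]),
      fragment_per_ref = unname(tab[["fragment"]]) * scale,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ctc_enumeration", "data.frame")
  res
}

#' @export
print.ctc_enumeration <- function(x, ...) {
  cat(sprintf("CTC enumeration: %d patient(s), counts scaled to reference volume\n",
              nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Per-class cell-area summaries
#'
#' Summarizes the area distribution of each event class: mean, median, n,
#' and a histogram expressed as the percentage of the class's cells per
#' area bin (so classes of different sizes are comparable, as when
#' contrasting the size of DLL3-only versus epithelial-only CTCs against
#' the leukocyte average).
#'
#' @param calls output of \code{\link{classify_events}} (carries \code{area}).
#' @param binwidth histogram bin width in square micrometres, default 10.
#' @param labels classes to summarize; defaults to all six.
#' @return list with \code{summary} (data frame: label, n, mean, median) and
#'   \code{histogram} (data frame: label, bin_lo, bin_hi, pct). Classes with
#'   no events appear in \code{summary} with \code{n = 0} and \code{NA}
#'   statistics rather than raising an error.
#' @export
size_summary <- function(calls, binwidth = 10, labels = .event_labels) {
  stats_df <- do.call(rbind, lapply(labels, function(l) {
    a <- calls$area[calls$label == l]
    data.frame(label = l, n = length(a),
               mean = if (length(a)) mean(a) else NA_real_,
               median = if (length(a)) stats::median(a) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  present <- labels[stats_df$n > 0]
  hist_df <- NULL
  if (length(present)) {
    amax <- max(calls$area[calls$label %in% present])
    breaks <- seq(0, binwidth * ceiling(amax / binwidth), by = binwidth)
    hist_df <- do.call(rbind, lapply(present, function(l) {
      a <- calls$area[calls$label == l]
      h <- hist(a, breaks = breaks, plot = FALSE)
      data.frame(label = l, bin_lo = breaks[-length(breaks)],
                 bin_hi = breaks[-1], pct = 100 * h$counts / length(a),
                 stringsAsFactors = FALSE)
    }))
  }
  list(summary = stats_df, histogram = hist_df)
}
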
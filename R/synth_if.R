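#' Parameters for the synthetic immunofluorescence cohort
#'
#' Describes a cohort of patients whose CTC-enriched slides are to be
#' simulated as per-event feature tables with known ground truth. The
#' class-conditional intensity model is truncated normal per channel on
#' the 8-bit scale, with DLL3-positive and -negative classes placed well
#' above and below the positivity threshold of 20 so that gating
#' calibration is meaningful. Fragments are tumor-marker-positive events
#' with near-absent nuclear signal and sub-minimum area, injected in bulk
#' ("bursts") only at designated on-treatment timepoints, emulating the
#' transient shedding of tumor fragments after treatment (observed at up
#' to the 50,000-event scale). A small marker-positive background rate
#' (default 0.18 events/mL, the mean seen in healthy donors) is always
#' present.
#'
#' @param n_patients number of patients.
#' @param dll3_fraction per-patient true DLL3-positive CTC fraction in
#'   [0,1]; recycled to \code{n_patients}.
#' @param ctc_abundance per-patient expected CTCs per 20 mL; recycled.
#' @param leukocyte_carryover expected contaminating leukocytes per slide.
#' @param fragment_burst expected fragments per on-treatment draw (0
#'   disables bursts).
#' @param background_rate marker-positive background events per mL,
#'   default 0.18.
#' @param dual_fraction probability a DLL3-positive CTC also stains
#'   epithelial (so that DLL3-only, epithelial-only and dual classes all
#'   arise), default 0.16.
#' @param volume_ml blood volume per draw in mL; recycled per patient.
#' @param timepoint label for the draw; bursts are injected only when
#'   \code{on_treatment = TRUE}.
#' @param on_treatment logical; whether this draw is an on-treatment
#'   timepoint eligible for fragment bursts.
#' @param intensity_model list of per-class channel means/sds; see
#'   defaults in the source. Means must lie in [0,255].
#' @param area_model list of per-class mean/sd areas in square
#'   micrometres; defaults: leukocyte 61, CTC 77.7 overall (DLL3-only
#'   CTCs slightly smaller than epithelial-only, as observed), fragments
#'   well below the intact-cell minimum.
#' @param seed integer seed; identical seed and parameters give identical
#'   output.
#' @return object of class \code{if_cohort_params}.
#' @export
if_cohort_params <- function(n_patients = 20,
                             dll3_fraction = 0.5,
                             ctc_abundance = 250,
                             leukocyte_carryover = 500,
                             fragment_burst = 0,
                             background_rate = 0.18,
                             dual_fraction = 0.16,
                             volume_ml = 20,
                             timepoint = "baseline",
                             on_treatment = FALSE,
                             intensity_model = NULL,
                             area_model = NULL,
                             seed = 1L) {
  dll3_fraction <- rep_len(dll3_fraction, n_patients)
  ctc_abundance <- rep_len(ctc_abundance, n_patients)
  volume_ml <- rep_len(volume_ml, n_patients)
  if (any(dll3_fraction < 0 | dll3_fraction > 1))
    stop("'dll3_fraction' must lie in [0, 1]")
  if (dual_fraction < 0 || dual_fraction > 1)
    stop("'dual_fraction' must lie in [0, 1]")
  for (nm in c("ctc_abundance", "leukocyte_carryover", "fragment_burst",
               "background_rate")) {
    v <- get(nm)
    if (any(v < 0)) stop("'", nm, "' must be nonnegative")
  }
  if (any(volume_ml <= 0)) stop("'volume_ml' must be positive")

  if (is.null(intensity_model)) intensity_model <- default_intensity_model()
  means <- unlist(lapply(intensity_model, function(m) m$mean))
  if (any(means < 0 | means > 255))
    stop("intensity means must lie on the 8-bit scale [0, 255]")
  if (is.null(area_model))
    area_model <- list(
      leukocyte = c(mean = 61, sd = 12),
      CTC_DLL3_only = c(mean = 70, sd = 15),
      CTC_epithelial_only = c(mean = 88, sd = 18),
      CTC_dual = c(mean = 80, sd = 16),
      fragment = c(mean = 15, sd = 5)
    )
  structure(list(
    n_patients = n_patients, dll3_fraction = dll3_fraction,
    ctc_abundance = ctc_abundance, leukocyte_carryover = leukocyte_carryover,
    fragment_burst = fragment_burst, background_rate = background_rate,
    dual_fraction = dual_fraction, volume_ml = volume_ml,
    timepoint = timepoint, on_treatment = on_treatment,
    intensity_model = intensity_model, area_model = area_model,
    seed = as.integer(seed)
  ), class = "if_cohort_params")
}

#' Default class-conditional intensity model
#'
#' Per-channel mean/sd (8-bit scale) for positive and negative signal and
#' for the nuclear stain of nucleated versus anucleate events. The
#' positive modes sit far above the gating thresholds and the negative
#' modes far below, which is what makes threshold calibration on
#' synthetic control populations meaningful.
#'
#' @return named list with elements \code{positive}, \code{negative},
#'   \code{nucleated}, \code{anucleate}, each \code{list(mean, sd)}.
#' @export
default_intensity_model <- function() {
  list(positive = list(mean = 120, sd = 30),
       negative = list(mean = 5, sd = 4),
       nucleated = list(mean = 130, sd = 25),
       anucleate = list(mean = 5, sd = 4))
}

# truncated-normal draw clipped to the 8-bit range
.rintensity <- function(n, m) pmin(255, pmax(0, stats::rnorm(n, m$mean, m$sd)))

#' Simulate a per-event immunofluorescence feature table with ground truth
#'
#' Generates one row per segmented imaging event for each patient: CTCs
#' (Poisson around the patient's abundance scaled by blood volume, each
#' DLL3-positive with the patient's true fraction), contaminating
#' leukocytes, marker-positive background events, and (at on-treatment
#' timepoints) fragment bursts. Intensities are drawn from the
#' class-conditional truncated-normal model and clipped to [0, 255];
#' fragments carry near-absent nuclear signal and sub-minimum area.
#'
#' @param params an \code{\link{if_cohort_params}} object.
#' @return list with \code{features} (the per-event table; columns
#'   \code{event_id}, \code{patient_id}, \code{timepoint}, eight mask-mean
#'   intensity columns, \code{area} and four exposure-factor columns) and
#'   \code{truth} (one row per event: \code{event_id}, \code{patient_id},
#'   \code{class} over CTC_DLL3_only / CTC_epithelial_only / CTC_dual /
#'   leukocyte / fragment, \code{dll3_positive}, \code{background}).
#' @export
simulate_if_cohort <- function(params) {
  stopifnot(inherits(params, "if_cohort_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  im <- params$intensity_model
  am <- params$area_model
  per_patient <- lapply(seq_len(params$n_patients), function(i) {
    pid <- sprintf("P%02d", i)
    vol_scale <- params$volume_ml[i] / 20
    n_ctc <- stats::rpois(1, params$ctc_abundance[i] * vol_scale)
    n_wbc <- stats::rpois(1, params$leukocyte_carryover)
    n_bg <- stats::rpois(1, params$background_rate * params$volume_ml[i])
    n_frag <- if (isTRUE(params$on_treatment))
      stats::rpois(1, params$fragment_burst) else 0L

    dll3_pos <- stats::runif(n_ctc) < params$dll3_fraction[i]
    # a DLL3-negative CTC must stain epithelial to be a CTC at all;
    # DLL3-positive CTCs co-stain epithelial with the dual fraction
    epi_pos <- ifelse(dll3_pos, stats::runif(n_ctc) < params$dual_fraction,
                      TRUE)
    ctc_class <- ifelse(dll3_pos & epi_pos, "CTC_dual",
                        ifelse(dll3_pos, "CTC_DLL3_only",
                               "CTC_epithelial_only"))
    # background marker-positive events score as epithelial-only CTCs
    cls <- c(ctc_class, rep("leukocyte", n_wbc),
             rep("CTC_epithelial_only", n_bg), rep("fragment", n_frag))
    bg <- c(rep(FALSE, n_ctc + n_wbc), rep(TRUE, n_bg), rep(FALSE, n_frag))
    n <- length(cls)
    if (n == 0L) return(NULL)

    is_ctc <- startsWith(cls, "CTC")
    dll3_true <- cls %in% c("CTC_DLL3_only", "CTC_dual") |
      (cls == "fragment" & stats::runif(n) < 0.5)
    epi_true <- cls %in% c("CTC_epithelial_only", "CTC_dual") |
      cls == "fragment"
    nucleated <- cls != "fragment"

    draw <- function(flag, pos = im$positive, neg = im$negative)
      ifelse(flag, .rintensity(n, pos), .rintensity(n, neg))
    area_mean <- vapply(am, `[[`, numeric(1), "mean")[cls]
    area_sd <- vapply(am, `[[`, numeric(1), "sd")[cls]
    area <- pmax(1, stats::rnorm(n, area_mean, area_sd))

    data.frame(
      event_id = paste0(pid, "_", seq_len(n)),
      patient_id = pid,
      timepoint = params$timepoint,
      dapi_nuc = draw(nucleated, im$nucleated, im$anucleate),
      dapi_cyto = draw(nucleated, im$nucleated, im$anucleate) * 0.5,
      epi_nuc = draw(epi_true) * 0.6,
      epi_cyto = draw(epi_true),
      dll3_nuc = draw(dll3_true) * 0.6,
      dll3_cyto = draw(dll3_true),
      heme_nuc = draw(cls == "leukocyte") * 0.6,
      heme_cyto = draw(cls == "leukocyte"),
      area = unname(area),
      exp_dapi = 1, exp_epi = 1, exp_dll3 = 1, exp_heme = 1,
      class = cls, dll3_positive = dll3_true, background = bg,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, per_patient)
  truth_cols <- c("event_id", "patient_id", "class", "dll3_positive",
                  "background")
  truth <- tab[, truth_cols]
  rownames(truth) <- rownames(tab) <- NULL
  features <- tab[, setdiff(names(tab), c("class", "dll3_positive",
                                          "background"))]
  list(features = features, truth = truth,
       seed = params$seed, volumes = stats::setNames(
         params$volume_ml, sprintf("P%02d", seq_len(params$n_patients))))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
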
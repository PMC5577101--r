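# Scalar ECM-accumulation endpoints: fixed-threshold total intensity,
# viability and radioactive-count normalisation, percent inhibition, fold
# change and delta-delta-Ct.

#' Total stain intensity above a fixed threshold
#'
#' Sum of the intensities of all pixels whose value strictly exceeds the
#' threshold ("above" is read as a strict inequality; configurable
#' upstream by choosing the threshold).
#'
#' @param image a [WellImage-class].
#' @param threshold native counts, >= 0.
#' @return total intensity (counts).
#' @export
totalIntensityAboveThreshold <- function(image, threshold) {
  stopifnot(is(image, "WellImage"), threshold >= 0)
  px <- pixels(image)
  sum(px[px > threshold])
}

#' Estimate the fixed intensity threshold from control wells
#'
#' Background mode (most frequent integer count) plus three robust sigmas
#' (1.4826 x MAD about the mode), pooled over the supplied unstimulated
#' control images.
#'
#' @param images a [WellImage-class] or list of them.
#' @return threshold in native counts.
#' @export
estimateFixedThreshold <- function(images) {
  if (is(images, "WellImage")) images <- list(images)
  px <- unlist(lapply(images, function(im) as.numeric(pixels(im))))
  counts <- table(px)
  mode <- as.numeric(names(counts)[which.max(counts)])
  sigma <- mad(px, center = mode, constant = 1.4826)
  mode + 3 * sigma
}

#' Normalise ECM intensity to the viability signal
#'
#' @param ecm total ECM stain intensity (counts).
#' @param viability viability signal (arbitrary units, > 0).
#' @return `ecm / viability`.
#' @export
normalizeToViability <- function(ecm, viability) {
  if (any(viability <= 0))
    stopTyped("ecms_dead_well",
              "viability signal must be positive (dead or empty well?)")
  ecm / viability
}

#' Normalise ECM radioactivity to the total cell count
#'
#' @param ecmCpm ECM radioactivity (counts/min, >= 0).
#' @param cellCpm total cell radioactivity (counts/min, > 0).
#' @return `ecmCpm / cellCpm`.
#' @export
normalizeRadioactive <- function(ecmCpm, cellCpm) {
  if (any(cellCpm <= 0))
    stopTyped("ecms_dead_well", "cell count (cpm) must be positive")
  ecmCpm / cellCpm
}

#' Percent inhibition relative to plate controls
#'
#' `100 * (stimulated - value) / (stimulated - unstimulated)`: the
#' stimulated-control mean anchors 0% and the unstimulated-control mean
#' anchors 100%. Invariant under any positive affine rescaling of the
#' response.
#'
#' @param value normalised response for the test well(s).
#' @param stimControlMean mean of the stimulated-control wells.
#' @param unstimControlMean mean of the unstimulated-control wells.
#' @return percent inhibition.
#' @export
percentInhibition <- function(value, stimControlMean, unstimControlMean) {
  if (stimControlMean == unstimControlMean)
    stopTyped("ecms_no_window",
              "stimulated and unstimulated control means are equal: no assay window")
  100 * (stimControlMean - value) / (stimControlMean - unstimControlMean)
}

#' Fold change over control
#'
#' @param treated,control normalised responses; `control` must be > 0.
#' @return `treated / control`.
#' @export
foldChange <- function(treated, control) {
  if (any(control <= 0))
    stopTyped("ecms_bad_control", "control value must be positive")
  treated / control
}

#' A qPCR Ct record
#'
#' @param sampleId sample identifier.
#' @param targetCt target-gene Ct (cycles, finite and > 0).
#' @param housekeeperCts named numeric vector of housekeeper Cts; the
#'   default panel is B2M, HMBS and TBP.
#' @return object of class `CtRecord`.
#' @export
ctRecord <- function(sampleId, targetCt,
                     housekeeperCts = c(B2M = NA_real_, HMBS = NA_real_,
                                        TBP = NA_real_)) {
  if (!is.finite(targetCt) || targetCt <= 0)
    stop("targetCt must be finite and positive")
  if (is.null(names(housekeeperCts)) || any(names(housekeeperCts) == ""))
    stop("housekeeperCts must be a named vector")
  structure(list(sample_id = sampleId, target_ct = targetCt,
                 housekeeper_cts = housekeeperCts), class = "CtRecord")
}

#' Relative expression by the delta-delta-Ct method
#'
#' Target Ct is referenced to the housekeeper panel and to a calibrator
#' sample: `fold = 2^-((dCt_sample) - (dCt_calibrator))` with
#' `dCt = target Ct - reference Ct`. The reference Ct is the arithmetic
#' mean of the housekeeper Cts, which on the linear scale is exactly the
#' geometric-mean normalisation over the housekeeper panel.
#'
#' @param sample,calibrator [ctRecord()] objects sharing a complete
#'   housekeeper panel.
#' @return relative expression (fold).
#' @export
deltaDeltaCt <- function(sample, calibrator) {
  stopifnot(inherits(sample, "CtRecord"), inherits(calibrator, "CtRecord"))
  hk <- names(sample$housekeeper_cts)
  for (rec in list(sample, calibrator)) {
    cts <- rec$housekeeper_cts[hk]
    if (length(cts) != length(hk) || anyNA(cts) || any(!is.finite(cts)))
      stopTyped("ecms_missing_housekeeper",
                "sample '%s' lacks a complete housekeeper panel (%s)",
                rec$sample_id, paste(hk, collapse = ", "))
  }
  dctS <- sample$target_ct - mean(sample$housekeeper_cts[hk])
  dctC <- calibrator$target_ct - mean(calibrator$housekeeper_cts[hk])
  2^-(dctS - dctC)
}
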
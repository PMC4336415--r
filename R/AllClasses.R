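#' @import methods
NULL

# ---------------------------------------------------------------------------
# Synthetic-data specifications
# ---------------------------------------------------------------------------

#' Specification of a synthetic droplet-monolayer image
#'
#' Describes one brightfield field of view of an emulsion droplet monolayer to
#' be rendered by [renderMonolayer()]: image geometry, pixel scale, the normal
#' diameter distribution of the droplets, and nuisance features (touching
#' droplets, droplets crossing the image border, small satellite droplets,
#' Gaussian background noise).  Droplets are rendered as bright disks with a
#' darker rim on a mid-grey background, the contrast structure an edge-based
#' segmentation pipeline expects from brightfield emulsion images.
#'
#' Defaults emulate the droplet-generator cartridges this package was written
#' to characterise: droplets of about 117 um mean diameter with a 2.2 um
#' standard deviation, imaged at 1 um/px; eight fields of 75 droplets give the
#' roughly 600 droplets per measurement day used by the sizing protocol.
#'
#' @slot width_px,height_px image size in pixels.
#' @slot scale_um_per_px micrometres per pixel.
#' @slot diam_mean_um,diam_sd_um mean and sd of the droplet diameter (um).
#' @slot n_droplets number of full-size droplets to place.
#' @slot touching_fraction fraction of droplets placed touching another one
#'   (centre distance 0.95-1.0 times the sum of radii).
#' @slot border_fraction fraction of droplets placed crossing the image edge.
#' @slot satellite_fraction number of small satellite droplets, as a fraction
#'   of \code{n_droplets} (satellites are extra objects, not part of
#'   \code{n_droplets}).
#' @slot satellite_diam_um diameter of satellite droplets (um).
#' @slot noise_sd sd of additive Gaussian background noise (grey levels).
#' @slot rim_contrast how much darker the droplet rim is than the interior
#'   (grey levels).
#' @slot rim_width_px width of the darker rim (pixels).
#' @slot bg_level,interior_level background and droplet-interior grey levels.
#' @slot seed integer seed; rendering is bit-reproducible given the spec.
#' @seealso [renderMonolayer()], [segmentDroplets()]
#' @export
setClass("ImageSpec",
    representation(
        width_px = "numeric", height_px = "numeric",
        scale_um_per_px = "numeric",
        diam_mean_um = "numeric", diam_sd_um = "numeric",
        n_droplets = "numeric",
        touching_fraction = "numeric", border_fraction = "numeric",
        satellite_fraction = "numeric", satellite_diam_um = "numeric",
        noise_sd = "numeric", rim_contrast = "numeric",
        rim_width_px = "numeric",
        bg_level = "numeric", interior_level = "numeric",
        seed = "numeric"))

setValidity("ImageSpec", function(object) {
    msg <- character()
    if (object@width_px < 1 || object@height_px < 1)
        msg <- c(msg, "width_px and height_px must be positive")
    if (object@scale_um_per_px <= 0)
        msg <- c(msg, "scale_um_per_px must be positive")
    if (object@diam_sd_um < 0)
        msg <- c(msg, "diam_sd_um must be >= 0")
    if (object@diam_mean_um <= 3 * object@diam_sd_um)
        msg <- c(msg, "diam_mean_um must exceed 3 * diam_sd_um")
    fr <- c(object@touching_fraction, object@border_fraction,
            object@satellite_fraction)
    if (any(fr < 0 | fr > 1))
        msg <- c(msg, "fractions must lie in [0, 1]")
    if (object@n_droplets < 0)
        msg <- c(msg, "n_droplets must be >= 0")
    if (object@satellite_diam_um <= 0)
        msg <- c(msg, "satellite_diam_um must be positive")
    if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
    if (object@rim_width_px < 0) msg <- c(msg, "rim_width_px must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname ImageSpec-class
#' @param width_px,height_px,scale_um_per_px,diam_mean_um,diam_sd_um see slots.
#' @param n_droplets,touching_fraction,border_fraction,satellite_fraction see
#'   slots.
#' @param satellite_diam_um,noise_sd,rim_contrast,rim_width_px see slots.
#' @param bg_level,interior_level,seed see slots.
#' @return `ImageSpec()` returns a validated \linkS4class{ImageSpec} object.
#' @examples
#' spec <- ImageSpec(n_droplets = 10, width_px = 768, height_px = 768, seed = 7)
#' spec
#' @export
ImageSpec <- function(width_px = 2048, height_px = 1536,
                      scale_um_per_px = 1.0,
                      diam_mean_um = 117.0, diam_sd_um = 2.2,
                      n_droplets = 75,
                      touching_fraction = 0.10, border_fraction = 0.05,
                      satellite_fraction = 0.02, satellite_diam_um = 20,
                      noise_sd = 5, rim_contrast = 160, rim_width_px = 2,
                      bg_level = 128, interior_level = 200, seed = 1L) {
    new("ImageSpec", width_px = width_px, height_px = height_px,
        scale_um_per_px = scale_um_per_px,
        diam_mean_um = diam_mean_um, diam_sd_um = diam_sd_um,
        n_droplets = n_droplets,
        touching_fraction = touching_fraction,
        border_fraction = border_fraction,
        satellite_fraction = satellite_fraction,
        satellite_diam_um = satellite_diam_um,
        noise_sd = noise_sd, rim_contrast = rim_contrast,
        rim_width_px = rim_width_px,
        bg_level = bg_level, interior_level = interior_level,
        seed = seed)
}

setMethod("show", "ImageSpec", function(object) {
    cat("ImageSpec:", object@width_px, "x", object@height_px, "px @",
        object@scale_um_per_px, "um/px\n")
    cat("  droplets: n =", object@n_droplets, ", diameter ~ N(",
        object@diam_mean_um, ",", object@diam_sd_um, ") um\n")
    cat("  fractions: touching", object@touching_fraction,
        "| border", object@border_fraction,
        "| satellite", object@satellite_fraction,
        "(", object@satellite_diam_um, "um )\n")
    cat("  render: bg", object@bg_level, "interior", object@interior_level,
        "rim -", object@rim_contrast, "x", object@rim_width_px,
        "px, noise sd", object@noise_sd, ", seed", object@seed, "\n")
})

#' Specification of a simulated ddPCR partition-count experiment
#'
#' Parameters for [simulatePartitionCounts()]: a true copy-number
#' concentration, the droplet (partition) volume, the final dilution factor,
#' the number of accepted droplets per well, and a day-by-replicate design
#' with a multiplicative log-normal between-day effect on concentration.
#'
#' Defaults reproduce the design used to characterise the reference plasmid
#' at the 10^4 cp/uL level: certified concentration 10300 cp/uL, measured
#' droplet volume 0.834 nL, gravimetric dilution 2.857 (33.6 uL sample mixed
#' with 62.4 uL pre-sample mix), 16000 accepted droplets per well, 8
#' replicates on each of 3 days, and a 1 % between-day coefficient of
#' variation.
#'
#' @slot true_concentration_cp_per_ul true concentration of the undiluted
#'   sample (cp/uL).
#' @slot droplet_volume_nl partition volume (nL).
#' @slot final_dilution final dilution factor D_f (>= 1).
#' @slot n_droplets accepted droplets per well (C).
#' @slot n_replicates,n_days design size.
#' @slot between_day_cv relative sd of the multiplicative day effect.
#' @slot seed integer seed.
#' @seealso [simulatePartitionCounts()], [copyNumberConcentration()]
#' @export
setClass("PartitionSimSpec",
    representation(
        true_concentration_cp_per_ul = "numeric",
        droplet_volume_nl = "numeric",
        final_dilution = "numeric",
        n_droplets = "numeric",
        n_replicates = "numeric", n_days = "numeric",
        between_day_cv = "numeric",
        seed = "numeric"))

setValidity("PartitionSimSpec", function(object) {
    msg <- character()
    if (object@true_concentration_cp_per_ul < 0)
        msg <- c(msg, "true_concentration_cp_per_ul must be >= 0")
    if (object@droplet_volume_nl <= 0)
        msg <- c(msg, "droplet_volume_nl must be positive")
    if (object@final_dilution < 1)
        msg <- c(msg, "final_dilution must be >= 1")
    if (object@n_droplets < 1) msg <- c(msg, "n_droplets must be >= 1")
    if (object@n_replicates < 1 || object@n_days < 1)
        msg <- c(msg, "n_replicates and n_days must be >= 1")
    if (object@between_day_cv < 0)
        msg <- c(msg, "between_day_cv must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname PartitionSimSpec-class
#' @param true_concentration_cp_per_ul,droplet_volume_nl,final_dilution see
#'   slots.
#' @param n_droplets,n_replicates,n_days,between_day_cv,seed see slots.
#' @return `PartitionSimSpec()` returns a validated
#'   \linkS4class{PartitionSimSpec} object.
#' @examples
#' PartitionSimSpec(true_concentration_cp_per_ul = 815.4,
#'                  droplet_volume_nl = 0.85, final_dilution = 1,
#'                  n_droplets = 20000, n_replicates = 4, n_days = 1)
#' @export
PartitionSimSpec <- function(true_concentration_cp_per_ul = 10300,
                             droplet_volume_nl = 0.834,
                             final_dilution = 2.857,
                             n_droplets = 16000,
                             n_replicates = 8, n_days = 3,
                             between_day_cv = 0.01,
                             seed = 1L) {
    new("PartitionSimSpec",
        true_concentration_cp_per_ul = true_concentration_cp_per_ul,
        droplet_volume_nl = droplet_volume_nl,
        final_dilution = final_dilution,
        n_droplets = n_droplets,
        n_replicates = n_replicates, n_days = n_days,
        between_day_cv = between_day_cv, seed = seed)
}

setMethod("show", "PartitionSimSpec", function(object) {
    lam <- object@true_concentration_cp_per_ul / object@final_dilution *
        object@droplet_volume_nl * 1e-3
    cat("PartitionSimSpec: T =", object@true_concentration_cp_per_ul,
        "cp/uL, Vd =", object@droplet_volume_nl, "nL, Df =",
        object@final_dilution, "\n")
    cat("  design:", object@n_days, "day(s) x", object@n_replicates,
        "replicate(s), C =", object@n_droplets,
        ", between-day cv =", object@between_day_cv, "\n")
    cat("  mean copies per droplet (lambda):", signif(lam, 4), "\n")
})

# ---------------------------------------------------------------------------
# Imaging
# ---------------------------------------------------------------------------

#' Pixel-scale calibration of a micrograph
#'
#' The length scale of the microscope, as micrometres per pixel, with the
#' relative standard uncertainty of the calibration.  Produced by
#' [calibrateScale()] from an image of a stage calibration grid, or
#' constructed directly when the scale is known.
#'
#' @slot um_per_px micrometres per pixel.
#' @slot rel_uncertainty relative standard uncertainty of `um_per_px`
#'   (dimensionless); 0.0015 corresponds to the 0.15 % grid-calibration
#'   uncertainty typical of a certified stage graticule.
#' @seealso [calibrateScale()], [measureDroplets()]
#' @export
setClass("ScaleCalibration",
    representation(um_per_px = "numeric", rel_uncertainty = "numeric"))

setValidity("ScaleCalibration", function(object) {
    msg <- character()
    if (object@um_per_px <= 0) msg <- c(msg, "um_per_px must be positive")
    if (object@rel_uncertainty < 0)
        msg <- c(msg, "rel_uncertainty must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname ScaleCalibration-class
#' @param um_per_px,rel_uncertainty see slots.
#' @return `ScaleCalibration()` returns a \linkS4class{ScaleCalibration}.
#' @examples
#' ScaleCalibration(0.5, rel_uncertainty = 0.0015)
#' @export
ScaleCalibration <- function(um_per_px, rel_uncertainty = 0) {
    new("ScaleCalibration", um_per_px = um_per_px,
        rel_uncertainty = rel_uncertainty)
}

setMethod("show", "ScaleCalibration", function(object) {
    cat("ScaleCalibration:", object@um_per_px, "um/px (rel. u. =",
        paste0(format(100 * object@rel_uncertainty, digits = 3), "%"), ")\n")
})

#' @describeIn ScaleCalibration-class micrometres per pixel.
#' @param object a `ScaleCalibration`.
#' @export
umPerPx <- function(object) {
    stopifnot(is(object, "ScaleCalibration"))
    object@um_per_px
}

#' Parameters of the droplet segmentation pipeline
#'
#' Controls [segmentDroplets()].  The pipeline is: Sobel gradient magnitude
#' ("find edges") -> threshold (Otsu on the gradient image, or a fixed grey
#' level) -> median-filter despeckle -> fill holes -> one-pixel erosion
#' compensating the edge-operator dilation (optional) -> watershed separation
#' of touching droplets (optional) -> removal of border-touching components
#' (optional) -> removal of components below a minimum area.
#'
#' @slot threshold_method `"otsu"` or `"fixed"`.  Otsu is computed on the
#'   gradient-magnitude histogram and used as the strong threshold of a
#'   hysteresis rule: pixels above a fraction `hysteresis_low_frac` of it
#'   are kept when 8-connected to a pixel above it.  Edge response varies
#'   with local boundary orientation, so a single threshold either clips
#'   the weak-response arcs of a droplet rim or admits noise; hysteresis
#'   keeps the full rim while still rejecting isolated noise.
#' @slot fixed_threshold gradient threshold in grey levels, used (without
#'   hysteresis) when `threshold_method = "fixed"`.
#' @slot hysteresis_low_frac weak-threshold fraction for Otsu mode.
#' @slot despeckle_radius_px radius of the despeckling median filter (>= 1;
#'   1 gives the classical 3x3 despeckle).
#' @slot min_area_px components smaller than this (pixels) are discarded;
#'   use [minAreaForScale()] to set it to the area of a 30 um disk, which
#'   rejects satellite droplets the droplet reader would also discard.
#' @slot watershed_enabled split touching droplets via the watershed of the
#'   distance transform.
#' @slot ws_tolerance_px watershed tolerance (minimum distance-map depth
#'   separating two objects, pixels).
#' @slot exclude_border drop components whose pixels touch the image edge.
#' @slot connectivity pixel connectivity (4 or 8) used when interpreting
#'   components; the filled disk-like masks produced by this pipeline give
#'   identical components under either.
#' @slot erode_after_fill apply a single 3x3 erosion after hole filling.
#'   The 3x3 gradient operator responds one pixel on each side of a step
#'   edge, so the thresholded-and-filled object is the true object dilated
#'   by one pixel; the erosion removes that systematic (+2 px on every
#'   diameter) and is on by default.
#' @seealso [segmentDroplets()]
#' @export
setClass("SegmentationParams",
    representation(
        threshold_method = "character", fixed_threshold = "numeric",
        hysteresis_low_frac = "numeric",
        despeckle_radius_px = "numeric", min_area_px = "numeric",
        watershed_enabled = "logical", ws_tolerance_px = "numeric",
        exclude_border = "logical", connectivity = "numeric",
        erode_after_fill = "logical"))

setValidity("SegmentationParams", function(object) {
    msg <- character()
    if (!object@threshold_method %in% c("otsu", "fixed"))
        msg <- c(msg, "threshold_method must be 'otsu' or 'fixed'")
    if (object@threshold_method == "fixed" &&
        (is.na(object@fixed_threshold) || object@fixed_threshold <= 0))
        msg <- c(msg, "fixed_threshold must be a positive grey level")
    if (object@hysteresis_low_frac <= 0 || object@hysteresis_low_frac > 1)
        msg <- c(msg, "hysteresis_low_frac must be in (0, 1]")
    if (object@despeckle_radius_px < 1)
        msg <- c(msg, "despeckle_radius_px must be >= 1")
    if (object@min_area_px < 0) msg <- c(msg, "min_area_px must be >= 0")
    if (!object@connectivity %in% c(4, 8))
        msg <- c(msg, "connectivity must be 4 or 8")
    if (object@ws_tolerance_px <= 0)
        msg <- c(msg, "ws_tolerance_px must be positive")
    if (length(msg)) msg else TRUE
})

#' @rdname SegmentationParams-class
#' @param threshold_method,fixed_threshold,hysteresis_low_frac see slots.
#' @param despeckle_radius_px see slots.
#' @param min_area_px,watershed_enabled,ws_tolerance_px see slots.
#' @param exclude_border,connectivity,erode_after_fill see slots.
#' @return `SegmentationParams()` returns a validated
#'   \linkS4class{SegmentationParams}.
#' @examples
#' SegmentationParams(min_area_px = minAreaForScale(1.0))
#' @export
SegmentationParams <- function(threshold_method = c("otsu", "fixed"),
                               fixed_threshold = NA_real_,
                               hysteresis_low_frac = 0.3,
                               despeckle_radius_px = 1,
                               min_area_px = 0,
                               watershed_enabled = TRUE,
                               ws_tolerance_px = 2,
                               exclude_border = TRUE,
                               connectivity = 8,
                               erode_after_fill = TRUE) {
    new("SegmentationParams",
        threshold_method = match.arg(threshold_method),
        fixed_threshold = fixed_threshold,
        hysteresis_low_frac = hysteresis_low_frac,
        despeckle_radius_px = despeckle_radius_px,
        min_area_px = min_area_px,
        watershed_enabled = watershed_enabled,
        ws_tolerance_px = ws_tolerance_px,
        exclude_border = exclude_border,
        connectivity = connectivity,
        erode_after_fill = erode_after_fill)
}

setMethod("show", "SegmentationParams", function(object) {
    thr <- if (object@threshold_method == "otsu") "Otsu"
           else paste("fixed @", object@fixed_threshold)
    cat("SegmentationParams: edges -> threshold (", thr,
        ") -> despeckle r=", object@despeckle_radius_px,
        " -> fill holes", sep = "")
    if (object@erode_after_fill) cat(" -> erode 3x3")
    if (object@watershed_enabled)
        cat(" -> watershed (tol ", object@ws_tolerance_px, " px)", sep = "")
    cat("\n  border exclusion:", object@exclude_border,
        "| min area:", object@min_area_px, "px | connectivity:",
        object@connectivity, "\n")
})

#' @describeIn SegmentationParams-class minimum component area (pixels)
#'   corresponding to a disk of `min_diameter_um` at the given scale; the
#'   default 30 um mirrors the size below which the droplet reader discards
#'   satellite droplets.
#' @param um_per_px micrometres per pixel.
#' @param min_diameter_um smallest droplet diameter to keep (um).
#' @export
minAreaForScale <- function(um_per_px, min_diameter_um = 30) {
    pi * (min_diameter_um / 2 / um_per_px)^2
}

# ---------------------------------------------------------------------------
# Quantification
# ---------------------------------------------------------------------------

#' Gravimetric dilution record
#'
#' Masses and densities defining the gravimetric dilution of a DNA sample in
#' the assay: the assay dilution factor is
#' \deqn{D_a = \frac{m_{DNA}/\delta_{DNA} + m_{premix}/\delta_{premix}}
#'                  {m_{DNA}/\delta_{DNA}}}
#' and the final dilution is \eqn{D_f = D_s \times D_a}, where \eqn{D_s} is
#' any pre-dilution of the sample before the assay.
#'
#' @slot m_dna_sol_g mass of DNA solution pipetted into the assay (g).
#' @slot delta_dna_sol density of the DNA solution (g/mL).
#' @slot m_premix_g mass of pre-sample mix (g).
#' @slot delta_premix density of the pre-sample mix (g/mL).
#' @slot D_s sample pre-dilution factor (>= 1; 1 = undiluted).
#' @seealso [assayDilutionFactor()], [finalDilution()],
#'   [simulateDilutionRecord()]
#' @export
setClass("DilutionRecord",
    representation(m_dna_sol_g = "numeric", delta_dna_sol = "numeric",
                   m_premix_g = "numeric", delta_premix = "numeric",
                   D_s = "numeric"))

setValidity("DilutionRecord", function(object) {
    msg <- character()
    if (object@m_dna_sol_g <= 0) msg <- c(msg, "m_dna_sol_g must be > 0")
    if (object@delta_dna_sol <= 0) msg <- c(msg, "delta_dna_sol must be > 0")
    if (object@m_premix_g < 0) msg <- c(msg, "m_premix_g must be >= 0")
    if (object@delta_premix <= 0) msg <- c(msg, "delta_premix must be > 0")
    if (object@D_s < 1) msg <- c(msg, "D_s must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @rdname DilutionRecord-class
#' @param m_dna_sol_g,delta_dna_sol,m_premix_g,delta_premix,D_s see slots.
#' @return `DilutionRecord()` returns a validated
#'   \linkS4class{DilutionRecord}.
#' @examples
#' # 33.6 uL of sample (density 1.0000 g/mL) + 62.4 uL premix (1.03532 g/mL)
#' rec <- DilutionRecord(m_dna_sol_g = 0.0336, delta_dna_sol = 1.0000,
#'                       m_premix_g = 0.064604, delta_premix = 1.03532)
#' assayDilutionFactor(rec)  # 2.857
#' @export
DilutionRecord <- function(m_dna_sol_g, delta_dna_sol = 1.0000,
                           m_premix_g = 0, delta_premix = 1.03532,
                           D_s = 1) {
    new("DilutionRecord", m_dna_sol_g = m_dna_sol_g,
        delta_dna_sol = delta_dna_sol, m_premix_g = m_premix_g,
        delta_premix = delta_premix, D_s = D_s)
}

setMethod("show", "DilutionRecord", function(object) {
    cat("DilutionRecord: m_DNA =", object@m_dna_sol_g, "g @",
        object@delta_dna_sol, "g/mL; m_premix =", object@m_premix_g, "g @",
        object@delta_premix, "g/mL; D_s =", object@D_s, "\n")
    cat("  D_a =", format(assayDilutionFactor(object), digits = 6),
        "; D_f =", format(finalDilution(object@D_s,
                                        assayDilutionFactor(object)),
                          digits = 6), "\n")
})

#' Intermediate-precision summary of replicate ddPCR concentrations
#'
#' Result of [intermediatePrecision()]: the grand mean concentration over a
#' balanced day-by-replicate design, the repeatability and between-day
#' standard deviations from a one-way random-effects ANOVA, and the combined
#' and expanded (k = 2) standard uncertainties of the grand mean.
#'
#' @slot grand_mean overall mean concentration (cp/uL).
#' @slot s_repeat repeatability sd (ANOVA residual, cp/uL).
#' @slot s_between_day between-day component sd (cp/uL), truncated at zero.
#' @slot u_combined standard uncertainty of the grand mean (cp/uL).
#' @slot U_expanded expanded uncertainty, k = 2 (cp/uL).
#' @slot n_days,n_replicates design size.
#' @slot truncated `TRUE` if the between-day variance component estimate was
#'   negative and truncated at zero.
#' @seealso [intermediatePrecision()]
#' @export
setClass("PrecisionSummary",
    representation(grand_mean = "numeric", s_repeat = "numeric",
                   s_between_day = "numeric", u_combined = "numeric",
                   U_expanded = "numeric", n_days = "numeric",
                   n_replicates = "numeric", truncated = "logical"))

setValidity("PrecisionSummary", function(object) {
    msg <- character()
    if (any(c(object@s_repeat, object@s_between_day, object@u_combined,
              object@U_expanded) < 0))
        msg <- c(msg, "uncertainty components must be >= 0")
    if (abs(object@U_expanded - 2 * object@u_combined) >
        1e-8 * max(1, object@U_expanded))
        msg <- c(msg, "U_expanded must equal 2 * u_combined")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PrecisionSummary", function(object) {
    cat("PrecisionSummary (", object@n_days, "days x", object@n_replicates,
        "replicates )\n")
    cat("  grand mean :", format(object@grand_mean, digits = 6), "cp/uL\n")
    cat("  s_repeat   :", format(object@s_repeat, digits = 4),
        "| s_between_day:", format(object@s_between_day, digits = 4),
        if (object@truncated) "(truncated at 0)" else "", "\n")
    cat("  u_combined :", format(object@u_combined, digits = 4),
        "; U (k=2) =", format(object@U_expanded, digits = 4), "cp/uL\n")
})

#' @describeIn PrecisionSummary-class grand mean concentration (cp/uL).
#' @param object a `PrecisionSummary`.
#' @export
grandMean <- function(object) {
    stopifnot(is(object, "PrecisionSummary"))
    object@grand_mean
}

#' @describeIn PrecisionSummary-class expanded uncertainty (k = 2, cp/uL).
#' @export
expandedUncertainty <- function(object) {
    stopifnot(is(object, "PrecisionSummary"))
    object@U_expanded
}
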
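# Droplet sizing from brightfield micrographs: scale calibration, edge-based
# segmentation, per-droplet measurement (ellipse fit, area-equivalent and
# Feret diameters, sphere-equivalent volume) and per-well/per-day summaries.

.sobelMagnitude <- function(x) {
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
    gx <- EBImage::filter2(x, kx, boundary = "replicate")
    gy <- EBImage::filter2(x, t(kx), boundary = "replicate")
    sqrt(gx^2 + gy^2)
}

.asGreyMatrix <- function(image) {
    if (is(image, "Image")) image <- EBImage::imageData(image)
    if (!is.numeric(image) || length(dim(image)) != 2L)
        stop("image must be a 2D single-channel (grayscale) matrix")
    m <- image
    if (max(m) > 1) m <- m / 255   # accept 0-255 or 0-1 input
    m
}

#' Calibrate the pixel scale from a stage-grid image
#'
#' Detects the dark parallel lines of a stage calibration grid, measures
#' their spacing perpendicular to the line direction (so a rotated grid needs
#' no separate correction), and converts the nominal line spacing into a
#' micrometres-per-pixel scale with a relative standard uncertainty derived
#' from the scatter of the individual gap widths.
#'
#' Lines are found by Otsu-thresholding the inverted image, labelling dark
#' components, taking the principal-axis orientation of the largest component
#' as the line direction, and reading each line position as the projection of
#' its centroid onto the line normal.
#'
#' @param grid_image 2D grayscale matrix (grey levels 0-255 or 0-1) showing
#'   at least two parallel dark lines.
#' @param nominal_spacing_um certified line-to-line spacing of the grid (um).
#' @return a \linkS4class{ScaleCalibration}.
#' @examples
#' g <- renderCalibrationGrid(600, 400, spacing_px = 200)
#' calibrateScale(g, 100)   # 0.5 um/px
#' @export
calibrateScale <- function(grid_image, nominal_spacing_um) {
    stopifnot(nominal_spacing_um > 0)
    m <- .asGreyMatrix(grid_image)
    dark <- 1 - m
    th <- EBImage::otsu(EBImage::Image(dark), range = c(0, 1))
    bin <- EBImage::Image(dark > th)
    lab <- EBImage::bwlabel(bin)
    labm <- EBImage::imageData(lab)
    sizes <- tabulate(labm[labm > 0])
    keep <- which(sizes >= 0.2 * max(sizes))   # reject specks
    if (length(keep) < 2)
        stop("fewer than 2 grid lines detected")
    # orientation of the longest line (0-based x = col-1, y = row-1)
    big <- keep[which.max(sizes[keep])]
    idx <- which(labm == big, arr.ind = TRUE)
    x <- idx[, 2] - 1; y <- idx[, 1] - 1
    cv <- stats::cov(cbind(x, y))
    e <- eigen(cv, symmetric = TRUE)
    dir <- e$vectors[, 1]                       # along the line
    nrm <- c(-dir[2], dir[1])                   # line normal
    pos <- vapply(keep, function(l) {
        ij <- which(labm == l, arr.ind = TRUE)
        mean((ij[, 2] - 1) * nrm[1] + (ij[, 1] - 1) * nrm[2])
    }, numeric(1))
    gaps <- diff(sort(pos))
    mgap <- mean(gaps)
    rel_u <- if (length(gaps) >= 2)
        stats::sd(gaps) / (mgap * sqrt(length(gaps))) else 0
    ScaleCalibration(um_per_px = nominal_spacing_um / mgap,
                     rel_uncertainty = rel_u)
}

#' Segment droplets in a brightfield monolayer image
#'
#' Edge-based segmentation: Sobel gradient magnitude of the image ("find
#' edges"), thresholding of the gradient (Otsu by default), median-filter
#' despeckling, hole filling (the droplet interior, enclosed by its rim
#' edges, becomes solid), an optional one-pixel erosion compensating the
#' one-pixel dilation inherent to 3x3 edge operators, optional watershed
#' splitting of touching droplets on the distance transform, removal of
#' components touching the image border, and removal of components below the
#' minimum area (satellite rejection).
#'
#' @param image 2D grayscale matrix (grey levels 0-255 or 0-1).
#' @param params a \linkS4class{SegmentationParams}.
#' @return integer label matrix, same shape as `image`, 0 = background,
#'   1..n = droplets.
#' @examples
#' fld <- renderMonolayer(ImageSpec(n_droplets = 6, width_px = 900,
#'                                  height_px = 700, touching_fraction = 0,
#'                                  border_fraction = 0,
#'                                  satellite_fraction = 0, seed = 5))
#' lab <- segmentDroplets(fld$image, SegmentationParams())
#' max(lab)  # 6
#' @export
segmentDroplets <- function(image, params = SegmentationParams()) {
    stopifnot(is(params, "SegmentationParams"))
    validObject(params)
    m <- .asGreyMatrix(image)
    g <- .sobelMagnitude(m)
    gmax <- max(g)
    if (gmax <= 0) return(matrix(0L, nrow(m), ncol(m)))
    if (params@threshold_method == "otsu") {
        th <- EBImage::otsu(EBImage::Image(g / gmax), range = c(0, 1)) * gmax
        # hysteresis: weak edge pixels survive only when connected to a
        # strong one, so orientation-dependent weak arcs of a rim are kept
        # while isolated noise responses are not
        weak <- g > params@hysteresis_low_frac * th
        wl <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(weak * 1)))
        seeds <- unique(wl[g > th & weak])
        seeds <- seeds[seeds > 0]
        bin <- EBImage::Image(matrix(as.numeric(wl %in% seeds),
                                     nrow(g), ncol(g)))
    } else {
        # fixed threshold is expressed in grey levels (0-255) of gradient
        th <- params@fixed_threshold / 255
        bin <- EBImage::Image(ifelse(g > th, 1, 0))
    }
    # median of a binary image = majority vote over the window, computed by
    # box filtering (much faster than a generic median on megapixel fields)
    r <- params@despeckle_radius_px
    k <- matrix(1, 2 * r + 1, 2 * r + 1)
    cnt <- EBImage::filter2(bin, k, boundary = "replicate")
    bin <- EBImage::Image(ifelse(cnt > length(k) / 2, 1, 0))
    bin <- EBImage::fillHull(bin)
    if (params@erode_after_fill)
        bin <- EBImage::erode(bin, EBImage::makeBrush(3, shape = "box"))
    if (params@watershed_enabled) {
        dm <- EBImage::distmap(bin)
        lab <- EBImage::watershed(dm, tolerance = params@ws_tolerance_px,
                                  ext = 1)
    } else {
        lab <- EBImage::bwlabel(bin)
    }
    labm <- EBImage::imageData(lab)
    storage.mode(labm) <- "integer"
    if (max(labm) == 0L) return(labm)
    if (params@exclude_border) {
        edge <- unique(c(labm[1, ], labm[nrow(labm), ],
                         labm[, 1], labm[, ncol(labm)]))
        labm[labm %in% edge[edge > 0L]] <- 0L
    }
    if (params@min_area_px > 0 && max(labm) > 0L) {
        sizes <- tabulate(labm[labm > 0L])
        small <- which(sizes < params@min_area_px)
        if (length(small)) labm[labm %in% small] <- 0L
    }
    # relabel 1..n
    ids <- sort(unique(labm[labm > 0L]))
    if (length(ids)) {
        map <- integer(max(ids)); map[ids] <- seq_along(ids)
        labm[labm > 0L] <- map[labm[labm > 0L]]
    }
    labm
}

# Rotating calipers on pixel coordinates: min/max caliper width over angles.
# Widths include the +1 px pixel extent so a digital square of side s has
# feret_min ~ s.
.feretDiameters <- function(x, y, step_deg = 0.5) {
    hull <- grDevices::chull(x, y)
    hx <- x[hull]; hy <- y[hull]
    th <- seq(0, pi, by = step_deg * pi / 180)
    wmax <- 0; wmin <- Inf
    for (a in th) {
        p <- hx * cos(a) + hy * sin(a)
        wd <- max(p) - min(p) + 1
        if (wd > wmax) wmax <- wd
        if (wd < wmin) wmin <- wd
    }
    c(max = wmax, min = wmin)
}

#' Measure segmented droplets
#'
#' For every labelled region: pixel area; major and minor axes of the
#' elliptical fit from second-order region moments; the area-equivalent
#' diameter \eqn{d = \sqrt{major \times minor}} (diameter of the circle whose
#' area equals that of the fitted ellipse); maximum and minimum Feret
#' (caliper) diameters by rotating calipers over the region's convex hull
#' (0.5 degree angular resolution, no hull smoothing); and the
#' sphere-equivalent volume \eqn{(\pi/6) d^3} in nL.  Pixel quantities are
#' converted to micrometres via the scale calibration.
#'
#' A raw-pixel-area variant of the area-equivalent diameter
#' (\eqn{2\sqrt{A/\pi}}) is also reported for comparison
#' (`area_equiv_diameter_raw_um`); the ellipse-fit route is the one used for
#' volumes.
#'
#' @param label_map integer label matrix from [segmentDroplets()].
#' @param scale a \linkS4class{ScaleCalibration}.
#' @return data.frame with one row per droplet: `label`, `area_px`,
#'   `major_axis_um`, `minor_axis_um`, `area_equiv_diameter_um`,
#'   `area_equiv_diameter_raw_um`, `feret_max_um`, `feret_min_um`,
#'   `feret_mean_um`, `volume_nl`, `touches_border`.  Regions with fewer than
#'   5 pixels are skipped with a warning (the moment fit is unstable).
#' @export
measureDroplets <- function(label_map, scale) {
    stopifnot(is(scale, "ScaleCalibration"))
    labm <- label_map
    if (is(labm, "Image")) labm <- EBImage::imageData(labm)
    stopifnot(is.numeric(labm) || is.integer(labm))
    n <- max(labm)
    s <- scale@um_per_px
    h <- nrow(labm); w <- ncol(labm)
    rows <- vector("list", n)
    skipped <- 0L
    idx_all <- which(labm > 0L, arr.ind = TRUE)
    lab_of <- labm[labm > 0L]
    ord <- order(lab_of)
    idx_all <- idx_all[ord, , drop = FALSE]
    lab_of <- lab_of[ord]
    starts <- c(1L, which(diff(lab_of) > 0) + 1L, length(lab_of) + 1L)
    for (k in seq_len(length(starts) - 1L)) {
        sel <- starts[k]:(starts[k + 1L] - 1L)
        lb <- lab_of[starts[k]]
        y <- idx_all[sel, 1] - 1; x <- idx_all[sel, 2] - 1
        npx <- length(x)
        if (npx < 5L) { skipped <- skipped + 1L; next }
        cv <- stats::cov(cbind(x, y)) * (npx - 1) / npx  # population moments
        e <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
        e[e < 0] <- 0
        major_px <- 4 * sqrt(e[1]); minor_px <- 4 * sqrt(e[2])
        d_px <- sqrt(major_px * minor_px)
        fer <- .feretDiameters(x, y)
        touches <- any(x == 0 | x == w - 1 | y == 0 | y == h - 1)
        rows[[lb]] <- data.frame(
            label = lb, area_px = npx,
            major_axis_um = major_px * s, minor_axis_um = minor_px * s,
            area_equiv_diameter_um = d_px * s,
            area_equiv_diameter_raw_um = 2 * sqrt(npx / pi) * s,
            feret_max_um = fer[["max"]] * s, feret_min_um = fer[["min"]] * s,
            feret_mean_um = (fer[["max"]] + fer[["min"]]) / 2 * s,
            volume_nl = sphereVolumeNl(d_px * s),
            touches_border = touches)
    }
    if (skipped > 0L)
        warning(skipped, " region(s) with < 5 pixels skipped")
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out)) out <- data.frame(
        label = integer(0), area_px = numeric(0), major_axis_um = numeric(0),
        minor_axis_um = numeric(0), area_equiv_diameter_um = numeric(0),
        area_equiv_diameter_raw_um = numeric(0), feret_max_um = numeric(0),
        feret_min_um = numeric(0), feret_mean_um = numeric(0),
        volume_nl = numeric(0), touches_border = logical(0))
    rownames(out) <- NULL
    out
}

#' Sphere-equivalent volume of a droplet
#'
#' Volume of a perfect sphere of the given diameter, in nanolitres:
#' \eqn{V = (\pi/6) d^3} with `d` in micrometres and
#' \eqn{1\,\mu m^3 = 10^{-6}} nL.
#'
#' @param diameter_um droplet diameter (um); vectorised.
#' @return volume in nL.
#' @examples
#' round(sphereVolumeNl(117.02), 3)  # 0.839
#' round(sphereVolumeNl(116.59), 3)  # 0.830
#' @export
sphereVolumeNl <- function(diameter_um) {
    if (any(diameter_um <= 0)) stop("diameter_um must be positive")
    pi / 6 * diameter_um^3 * 1e-6
}

#' Expected sphere volume from a diameter mean and sd
#'
#' Second-moment-corrected mean sphere volume of a droplet population whose
#' diameters have mean \eqn{\bar d} and standard deviation \eqn{s}:
#' \eqn{E[(\pi/6)d^3] \approx (\pi/6)(\bar d^3 + 3 \bar d s^2)} (the skewness
#' term of the third moment is negligible for near-symmetric diameter
#' distributions).  This reconstructs a population mean volume from printed
#' per-day summary statistics.
#'
#' @param mean_diameter_um,sd_diameter_um diameter mean and sd (um);
#'   vectorised.
#' @return mean volume in nL.
#' @examples
#' round(mean(momentCorrectedVolumeNl(c(117.02, 116.59, 116.60),
#'                                    c(1.37, 2.21, 3.18))), 3)  # 0.834
#' @export
momentCorrectedVolumeNl <- function(mean_diameter_um, sd_diameter_um) {
    if (any(mean_diameter_um <= 0)) stop("mean_diameter_um must be positive")
    if (any(sd_diameter_um < 0)) stop("sd_diameter_um must be >= 0")
    pi / 6 * (mean_diameter_um^3 +
              3 * mean_diameter_um * sd_diameter_um^2) * 1e-6
}

#' Summarise droplet measurements per well and per day
#'
#' @param measurements data.frame from [measureDroplets()] (or several
#'   rbind-ed together), one row per droplet.
#' @param well character/factor vector assigning each droplet to a well;
#'   defaults to a `well_id` column of `measurements` or a single well.
#' @return list with `wells` (data.frame: `well_id`, `n_droplets`,
#'   `mean_diameter_um`, `sd_diameter_um`, `mean_volume_nl`, `sd_volume_nl`)
#'   and `day` (one-row data.frame with the same statistics pooled over all
#'   droplets of the day).  The sd of a single droplet is 0.
#' @export
summarizeDay <- function(measurements, well = NULL) {
    if (is.null(well))
        well <- if ("well_id" %in% names(measurements))
            measurements$well_id else rep("well1", nrow(measurements))
    if (nrow(measurements) < 1L) stop("no measurements to summarise")
    stopifnot(length(well) == nrow(measurements))
    sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)
    one <- function(df) data.frame(
        n_droplets = nrow(df),
        mean_diameter_um = mean(df$area_equiv_diameter_um),
        sd_diameter_um = sd0(df$area_equiv_diameter_um),
        mean_volume_nl = mean(df$volume_nl),
        sd_volume_nl = sd0(df$volume_nl))
    parts <- split(measurements, well)
    wells <- do.call(rbind, lapply(parts, one))
    wells <- cbind(well_id = names(parts), wells)
    rownames(wells) <- NULL
    list(wells = wells, day = one(measurements))
}

#' Average droplet volume over measurement days
#'
#' Combines per-day droplet summaries into one average partition volume, the
#' critical divisor of the Poisson concentration formula.  Three conventions:
#' \describe{
#'   \item{`moment_corrected`}{unweighted mean over days of the per-day
#'     expected volume \eqn{(\pi/6)(\bar d^3 + 3 \bar d s^2)} reconstructed
#'     from each day's diameter mean and sd
#'     ([momentCorrectedVolumeNl()]).  Works from printed summary tables and
#'     is the default.}
#'   \item{`pooled_droplets`}{mean of all per-droplet volumes, computed as
#'     the droplet-count-weighted mean of the per-day mean volumes.}
#'   \item{`mean_of_day_means`}{unweighted mean of the per-day mean
#'     volumes.}
#' }
#'
#' @param day_summaries data.frame with one row per day; columns
#'   `mean_diameter_um` and `sd_diameter_um` (for `moment_corrected`),
#'   `mean_volume_nl` (for the other modes) and `n_droplets` (for
#'   `pooled_droplets`).
#' @param mode averaging convention.
#' @return average droplet volume (nL).
#' @examples
#' days <- data.frame(mean_diameter_um = c(117.02, 116.59, 116.60),
#'                    sd_diameter_um = c(1.37, 2.21, 3.18))
#' round(averageDropletVolume(days), 3)  # 0.834
#' @export
averageDropletVolume <- function(day_summaries,
                                 mode = c("moment_corrected",
                                          "pooled_droplets",
                                          "mean_of_day_means")) {
    mode <- match.arg(mode)
    if (nrow(day_summaries) < 1L) stop("need at least one day")
    switch(mode,
        moment_corrected = mean(momentCorrectedVolumeNl(
            day_summaries$mean_diameter_um, day_summaries$sd_diameter_um)),
        pooled_droplets = stats::weighted.mean(
            day_summaries$mean_volume_nl, day_summaries$n_droplets),
        mean_of_day_means = mean(day_summaries$mean_volume_nl))
}
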
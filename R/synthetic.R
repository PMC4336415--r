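# Synthetic data: droplet-monolayer images with ground truth, partition-count
# simulation, fluorescence amplitudes and gravimetric dilution records.

# Draw one disk into the canvas (matrix [row = y, col = x], 0-based centres).
.drawDisk <- function(canvas, cx, cy, r_px, interior, rim, rim_w) {
    h <- nrow(canvas); w <- ncol(canvas)
    x0 <- max(0L, floor(cx - r_px)); x1 <- min(w - 1L, ceiling(cx + r_px))
    y0 <- max(0L, floor(cy - r_px)); y1 <- min(h - 1L, ceiling(cy + r_px))
    if (x0 > x1 || y0 > y1) return(canvas)
    xs <- x0:x1; ys <- y0:y1
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    sub <- canvas[ys + 1L, xs + 1L, drop = FALSE]
    inside <- d2 <= r_px^2
    core <- d2 <= max(r_px - rim_w, 0)^2
    sub[inside] <- rim
    sub[core] <- interior
    canvas[ys + 1L, xs + 1L] <- sub
    canvas
}

.placeFree <- function(w, h, r, placed, margin = 2, border = FALSE,
                       max_try = 2000) {
    for (i in seq_len(max_try)) {
        if (border) {
            # centre within r of an edge so the disk crosses it
            side <- sample.int(4L, 1L)
            off <- stats::runif(1, -r * 0.8, r * 0.8)
            cx <- switch(side, off, w - 1 + off, stats::runif(1, 0, w - 1),
                         stats::runif(1, 0, w - 1))
            cy <- switch(side, stats::runif(1, 0, h - 1),
                         stats::runif(1, 0, h - 1), off, h - 1 + off)
        } else {
            cx <- stats::runif(1, r + 1, w - r - 2)
            cy <- stats::runif(1, r + 1, h - r - 2)
        }
        ok <- TRUE
        if (nrow(placed)) {
            dmin <- sqrt((placed$cx - cx)^2 + (placed$cy - cy)^2)
            ok <- all(dmin >= placed$r + r + margin)
        }
        if (ok) return(c(cx, cy))
    }
    NULL
}

#' Render a synthetic droplet-monolayer image with ground truth
#'
#' Renders one brightfield field of view: near-circular droplets with
#' normally distributed diameters drawn as bright disks with a darker rim on
#' a noisy mid-grey background.  A requested fraction of droplets touch a
#' neighbour (centre distance 0.95-1.0 times the sum of radii, exercising the
#' watershed), a fraction crosses the image border, and small satellite
#' droplets can be sprinkled in.  The returned ground truth lists every
#' rendered droplet with the exact diameter used for rendering.
#'
#' Placement is random sequential: positions are drawn uniformly and rejected
#' on overlap, which caps the achievable packing density well below that of a
#' real close-packed emulsion monolayer; droplet counts per measurement day,
#' not per field, are the quantity to match against real protocols.
#'
#' @param spec an \linkS4class{ImageSpec}.
#' @return a list with `image` (numeric matrix, grey levels 0-255, rows = y)
#'   and `truth` (data.frame: `center_x_px`, `center_y_px` 0-based,
#'   `diameter_um`, `is_satellite`, `touches_border`).
#' @examples
#' fld <- renderMonolayer(ImageSpec(n_droplets = 5, width_px = 768,
#'                                  height_px = 768, touching_fraction = 0,
#'                                  border_fraction = 0, satellite_fraction = 0,
#'                                  seed = 3))
#' nrow(fld$truth)
#' @export
renderMonolayer <- function(spec) {
    stopifnot(is(spec, "ImageSpec"))
    validObject(spec)
    withr::with_seed(spec@seed, {
        w <- as.integer(spec@width_px); h <- as.integer(spec@height_px)
        s <- spec@scale_um_per_px
        n <- as.integer(round(spec@n_droplets))
        n_border <- as.integer(round(spec@border_fraction * n))
        n_touch <- as.integer(round(spec@touching_fraction * n))
        n_free <- n - n_border - n_touch
        n_sat <- as.integer(round(spec@satellite_fraction * n))

        placed <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0),
                             sat = logical(0), border = logical(0))
        diam <- function(k) {
            d <- stats::rnorm(k, spec@diam_mean_um, spec@diam_sd_um)
            pmax(d, spec@diam_mean_um - 3.5 * spec@diam_sd_um)
        }
        add <- function(cx, cy, d_um, sat, border) {
            placed[nrow(placed) + 1L, ] <<-
                list(cx, cy, d_um / (2 * s), sat, border)
        }

        for (d_um in diam(n_free)) {
            p <- .placeFree(w, h, d_um / (2 * s), placed)
            if (is.null(p))
                stop("packing failure: cannot place ", n,
                     " droplets in a ", w, "x", h, " field at this density")
            add(p[1], p[2], d_um, FALSE, FALSE)
        }
        for (d_um in diam(n_border)) {
            p <- .placeFree(w, h, d_um / (2 * s), placed, border = TRUE)
            if (is.null(p))
                stop("packing failure while placing border droplets")
            add(p[1], p[2], d_um, FALSE, TRUE)
        }
        for (d_um in diam(n_touch)) {
            r <- d_um / (2 * s)
            done <- FALSE
            hosts <- which(!placed$sat & !placed$border)
            for (i in seq_len(500)) {
                host <- placed[sample(hosts, 1L), ]
                ang <- stats::runif(1, 0, 2 * pi)
                gap <- stats::runif(1, 0.95, 1.0) * (host$r + r)
                cx <- host$cx + gap * cos(ang); cy <- host$cy + gap * sin(ang)
                if (cx < r + 1 || cx > w - r - 2 ||
                    cy < r + 1 || cy > h - r - 2) next
                oth <- placed[sqrt((placed$cx - host$cx)^2 +
                                   (placed$cy - host$cy)^2) > 1e-9, ]
                dmin <- sqrt((oth$cx - cx)^2 + (oth$cy - cy)^2)
                if (all(dmin >= oth$r + r + 2)) {
                    add(cx, cy, d_um, FALSE, FALSE); done <- TRUE; break
                }
            }
            if (!done)
                stop("packing failure while placing touching droplets")
        }
        for (i in seq_len(n_sat)) {
            r <- spec@satellite_diam_um / (2 * s)
            p <- .placeFree(w, h, r, placed)
            if (is.null(p)) stop("packing failure while placing satellites")
            add(p[1], p[2], spec@satellite_diam_um, TRUE, FALSE)
        }

        img <- matrix(spec@bg_level, nrow = h, ncol = w)
        rim <- max(spec@interior_level - spec@rim_contrast, 0)
        for (i in seq_len(nrow(placed)))
            img <- .drawDisk(img, placed$cx[i], placed$cy[i], placed$r[i],
                             spec@interior_level, rim, spec@rim_width_px)
        if (spec@noise_sd > 0)
            img <- img + matrix(stats::rnorm(w * h, 0, spec@noise_sd), h, w)
        img <- round(pmin(pmax(img, 0), 255))

        truth <- data.frame(
            center_x_px = placed$cx, center_y_px = placed$cy,
            diameter_um = placed$r * 2 * s,
            is_satellite = placed$sat,
            touches_border = placed$border |
                (placed$cx - placed$r < 0) | (placed$cx + placed$r > w - 1) |
                (placed$cy - placed$r < 0) | (placed$cy + placed$r > h - 1))
        list(image = img, truth = truth)
    })
}

#' Render a synthetic stage calibration grid
#'
#' Dark parallel lines at a known pixel spacing on a bright background, as
#' imaged from a stage graticule; used to exercise [calibrateScale()].
#'
#' @param width_px,height_px image size (pixels).
#' @param spacing_px line-to-line spacing measured perpendicular to the
#'   lines (pixels).
#' @param angle_deg rotation of the lines from vertical (degrees).
#' @param jitter_px sd of a random perpendicular offset per line (pixels).
#' @param line_width_px line width (pixels).
#' @param line_level,bg_level grey levels of lines and background.
#' @param noise_sd sd of additive Gaussian noise (grey levels).
#' @param seed integer seed.
#' @return numeric matrix of grey levels 0-255 (rows = y).
#' @examples
#' g <- renderCalibrationGrid(600, 400, spacing_px = 200)
#' calibrateScale(g, nominal_spacing_um = 100)
#' @export
renderCalibrationGrid <- function(width_px, height_px, spacing_px,
                                  angle_deg = 0, jitter_px = 0,
                                  line_width_px = 3, line_level = 40,
                                  bg_level = 200, noise_sd = 0, seed = 1L) {
    stopifnot(spacing_px > line_width_px)
    withr::with_seed(seed, {
        w <- as.integer(width_px); h <- as.integer(height_px)
        phi <- angle_deg * pi / 180   # line direction from vertical
        # projection of pixel coords onto the line normal:
        # proj = x*cos(phi) - y*sin(phi)
        xs <- 0:(w - 1); ys <- 0:(h - 1)
        proj <- outer(-ys * sin(phi), xs * cos(phi), "+")
        rng <- range(proj)
        # lines at half-spacing offsets so no line is clipped by the frame
        pos <- seq(rng[1] - spacing_px / 2, rng[2] + spacing_px,
                   by = spacing_px)
        if (jitter_px > 0)
            pos <- pos + stats::rnorm(length(pos), 0, jitter_px)
        img <- matrix(bg_level, h, w)
        half <- line_width_px / 2
        for (p in pos)
            img[abs(proj - p) <= half] <- line_level
        if (noise_sd > 0)
            img <- img + matrix(stats::rnorm(w * h, 0, noise_sd), h, w)
        round(pmin(pmax(img, 0), 255))
    })
}

#' Simulate ddPCR partition counts over a day-by-replicate design
#'
#' For each replicate well the number of positive droplets `H` is drawn
#' binomially with `C` trials and success probability \eqn{1 - e^{-\lambda}},
#' where \eqn{\lambda = (T / D_f) \cdot V_d} is the mean number of target
#' copies per droplet (volume converted from nL to uL).  A multiplicative
#' log-normal day effect with relative sd `between_day_cv` (unit mean) is
#' drawn once per day and applied to the concentration, giving the
#' between-day variance component of an intermediate-precision design.
#'
#' @param spec a \linkS4class{PartitionSimSpec}.
#' @return data.frame with columns `day`, `replicate`, `C`, `H`.
#' @examples
#' counts <- simulatePartitionCounts(PartitionSimSpec(seed = 42))
#' head(counts)
#' @export
simulatePartitionCounts <- function(spec) {
    stopifnot(is(spec, "PartitionSimSpec"))
    validObject(spec)
    C <- as.integer(round(spec@n_droplets))
    vol_ul <- spec@droplet_volume_nl * 1e-3
    withr::with_seed(spec@seed, {
        out <- expand.grid(replicate = seq_len(spec@n_replicates),
                           day = seq_len(spec@n_days))[, c("day", "replicate")]
        cv <- spec@between_day_cv
        if (cv > 0) {
            sdlog <- sqrt(log(1 + cv^2))
            dayfac <- stats::rlnorm(spec@n_days, -sdlog^2 / 2, sdlog)
        } else dayfac <- rep(1, spec@n_days)
        lam <- spec@true_concentration_cp_per_ul * dayfac[out$day] /
            spec@final_dilution * vol_ul
        if (any(!is.finite(lam)) || any(lam < 0))
            stop("invalid simulation spec: lambda is not a finite ",
                 "non-negative number")
        p <- -expm1(-lam)
        out$C <- C
        out$H <- stats::rbinom(nrow(out), C, p)
        out
    })
}

#' Simulate fluorescence amplitudes for one well
#'
#' Draws `C` droplet end-point fluorescence amplitudes: `H` from the positive
#' population and `C - H` from the negative population, both Gaussian with a
#' common sd, returned in random order.  With well-separated populations a
#' fixed amplitude threshold recovers `H` exactly.
#'
#' @param C,H total and positive droplet counts (0 <= H <= C).
#' @param pos_mean,neg_mean population mean amplitudes (pos_mean > neg_mean).
#' @param sd common population sd (> 0).
#' @param seed integer seed.
#' @return numeric vector of `C` amplitudes.
#' @seealso [classifyByThreshold()]
#' @examples
#' a <- simulateAmplitudes(2000, 150, pos_mean = 6000, neg_mean = 1500,
#'                         sd = 300, seed = 1)
#' classifyByThreshold(a, 4002)
#' @export
simulateAmplitudes <- function(C, H, pos_mean, neg_mean, sd, seed = 1L) {
    stopifnot(C >= 1, H >= 0, H <= C, pos_mean > neg_mean, sd > 0)
    withr::with_seed(seed, {
        amp <- c(stats::rnorm(H, pos_mean, sd),
                 stats::rnorm(C - H, neg_mean, sd))
        sample(amp)
    })
}

#' Classify droplet amplitudes by a fixed threshold
#'
#' @param amplitudes numeric vector of droplet fluorescence amplitudes.
#' @param threshold amplitudes strictly above it are called positive; 4002 is
#'   a typical discrimination threshold for a well-optimised assay.
#' @return list with `C` (total), `H` (positive count) and `positive`
#'   (logical vector).
#' @export
classifyByThreshold <- function(amplitudes, threshold = 4002) {
    pos <- amplitudes > threshold
    list(C = length(amplitudes), H = sum(pos), positive = pos)
}

#' Simulate a gravimetric dilution record
#'
#' Converts target pipetted volumes into weighed masses via the solution
#' densities, with optional relative pipetting noise; the result feeds
#' [assayDilutionFactor()].
#'
#' @param dna_volume_ul,premix_volume_ul target pipetted volumes (uL).
#' @param dna_density,premix_density solution densities (g/mL).
#' @param D_s sample pre-dilution factor.
#' @param pipette_cv relative sd of pipetted volumes (0 = exact).
#' @param seed integer seed.
#' @return a \linkS4class{DilutionRecord}.
#' @examples
#' simulateDilutionRecord(33.6, 62.4, pipette_cv = 0)
#' @export
simulateDilutionRecord <- function(dna_volume_ul, premix_volume_ul,
                                   dna_density = 1.0000,
                                   premix_density = 1.03532,
                                   D_s = 1, pipette_cv = 0, seed = 1L) {
    stopifnot(dna_volume_ul > 0, premix_volume_ul >= 0,
              dna_density > 0, premix_density > 0, pipette_cv >= 0)
    withr::with_seed(seed, {
        noise <- function(v) if (pipette_cv > 0)
            v * (1 + stats::rnorm(1, 0, pipette_cv)) else v
        DilutionRecord(
            m_dna_sol_g = noise(dna_volume_ul) * dna_density * 1e-3,
            delta_dna_sol = dna_density,
            m_premix_g = if (premix_volume_ul > 0)
                noise(premix_volume_ul) * premix_density * 1e-3 else 0,
            delta_premix = premix_density,
            D_s = D_s)
    })
}
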
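# Shared helpers: small synthetic fields and hand-built label maps.

# a clean, well-separated field: no touching/border/satellite droplets
cleanFieldSpec <- function(n = 5, diam = 117.02, sd = 0.1, noise = 0,
                           seed = 2, wh = c(900, 900)) {
    ImageSpec(n_droplets = n, width_px = wh[1], height_px = wh[2],
              touching_fraction = 0, border_fraction = 0,
              satellite_fraction = 0,
              diam_mean_um = diam, diam_sd_um = sd, noise_sd = noise,
              seed = seed)
}

defaultParams <- function(um_per_px = 1)
    SegmentationParams(min_area_px = minAreaForScale(um_per_px))

# label map containing a single axis-aligned square of side s
squareLabelMap <- function(s = 40, pad = 30) {
    m <- matrix(0L, s + 2 * pad, s + 2 * pad)
    m[pad + seq_len(s), pad + seq_len(s)] <- 1L
    m
}

# label map containing a single digital disk of diameter d (pixels)
diskLabelMap <- function(d = 101, pad = 20) {
    r <- d / 2
    n <- ceiling(d) + 2 * pad
    ctr <- (n - 1) / 2
    xs <- matrix(0:(n - 1), n, n, byrow = TRUE)
    ys <- matrix(0:(n - 1), n, n)
    m <- matrix(0L, n, n)
    m[(xs - ctr)^2 + (ys - ctr)^2 <= r^2] <- 1L
    m
}
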
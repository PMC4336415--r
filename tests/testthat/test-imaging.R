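# Droplet sizing: scale calibration, segmentation, per-droplet measurement,
# summaries and volume averaging.

test_that("sphere volume reproduces the published diameter-volume pairs", {
    expect_equal(round(sphereVolumeNl(117.02), 3), 0.839)
    expect_equal(round(sphereVolumeNl(116.59), 3), 0.830)
    # closed form: d = (6/pi)^(1/3) um encloses exactly 1 um^3 = 1e-6 nL
    expect_equal(sphereVolumeNl((6 / pi)^(1 / 3)), 1e-6)
    expect_error(sphereVolumeNl(0), "positive")
    # cubic scaling
    expect_equal(sphereVolumeNl(234.04), 8 * sphereVolumeNl(117.02))
})

test_that("moment-corrected volume reduces to the sphere volume at sd 0", {
    expect_equal(momentCorrectedVolumeNl(117.02, 0), sphereVolumeNl(117.02))
    expect_gt(momentCorrectedVolumeNl(117.02, 3), sphereVolumeNl(117.02))
})

test_that("grid calibration recovers the scale", {
    g <- renderCalibrationGrid(600, 400, spacing_px = 200)
    cal <- calibrateScale(g, 100)
    expect_equal(umPerPx(cal), 0.5, tolerance = 1e-3)

    gj <- renderCalibrationGrid(800, 600, spacing_px = 200, jitter_px = 1,
                                noise_sd = 3, seed = 4)
    calj <- calibrateScale(gj, 100)
    expect_lt(abs(umPerPx(calj) / 0.5 - 1), 0.01)
    expect_gt(calj@rel_uncertainty, 0)

    # rotated grid: spacing measured along the line normal, no bias
    gr <- renderCalibrationGrid(800, 600, spacing_px = 200, angle_deg = 5,
                                seed = 5)
    expect_lt(abs(umPerPx(calibrateScale(gr, 100)) / 0.5 - 1), 0.01)

    g1 <- renderCalibrationGrid(300, 200, spacing_px = 250)
    expect_error(calibrateScale(g1, 100), "fewer than 2")
})

test_that("segmentation finds exactly the renderable droplets", {
    fld <- renderMonolayer(cleanFieldSpec(n = 10, sd = 2, noise = 5,
                                          seed = 8, wh = c(1400, 1100)))
    lab <- segmentDroplets(fld$image, defaultParams())
    expect_equal(max(lab), 10)

    blank <- renderMonolayer(ImageSpec(n_droplets = 0, width_px = 500,
                                       height_px = 400, seed = 2))
    expect_equal(max(segmentDroplets(blank$image, defaultParams())), 0)

    expect_error(segmentDroplets(array(0, c(4, 4, 3)), defaultParams()),
                 "2D")
})

test_that("watershed separates touching droplets without changing counts", {
    spec <- ImageSpec(n_droplets = 40, touching_fraction = 0.2,
                      border_fraction = 0.05, width_px = 1600,
                      height_px = 1200, seed = 5)
    fld <- renderMonolayer(spec)
    lab <- segmentDroplets(fld$image, defaultParams())
    keep <- !fld$truth$is_satellite & !fld$truth$touches_border
    expect_equal(max(lab), sum(keep))
})

test_that("border exclusion removes every edge-touching component", {
    spec <- ImageSpec(n_droplets = 20, border_fraction = 0.3,
                      width_px = 1400, height_px = 1100, seed = 12)
    fld <- renderMonolayer(spec)
    lab <- segmentDroplets(fld$image, defaultParams())
    m <- measureDroplets(lab, ScaleCalibration(1))
    expect_false(any(m$touches_border))
    expect_equal(max(lab),
                 sum(!fld$truth$is_satellite & !fld$truth$touches_border))
})

test_that("a rendered circle is measured to its known diameter and volume", {
    fld <- renderMonolayer(cleanFieldSpec(n = 1, diam = 117.02, sd = 1e-3,
                                          noise = 0, seed = 2,
                                          wh = c(400, 400)))
    lab <- segmentDroplets(fld$image, defaultParams())
    m <- measureDroplets(lab, ScaleCalibration(1))
    expect_equal(nrow(m), 1L)
    expect_lt(abs(m$area_equiv_diameter_um / 117.02 - 1), 0.005)
    expect_lt(abs(m$volume_nl / 0.839 - 1), 0.015)
    # for a disk, mean Feret and area-equivalent diameter agree
    expect_lt(abs(m$feret_mean_um / m$area_equiv_diameter_um - 1), 0.01)
    # raw-area variant agrees closely for an isolated disk
    expect_lt(abs(m$area_equiv_diameter_raw_um / m$area_equiv_diameter_um
                  - 1), 0.01)
})

test_that("Feret diameters of a square follow the analytic values", {
    s <- 40
    m <- measureDroplets(squareLabelMap(s), ScaleCalibration(1))
    expect_lt(abs(m$feret_min_um - s), 1)
    expect_lt(abs(m$feret_max_um - s * sqrt(2)), 1)
})

test_that("mean Feret bounds the area-equivalent diameter on convex shapes", {
    shapes <- list(diskLabelMap(61), diskLabelMap(101), squareLabelMap(30),
                   squareLabelMap(55))
    for (lm in shapes) {
        m <- measureDroplets(lm, ScaleCalibration(1))
        expect_gte(m$feret_mean_um, m$area_equiv_diameter_um * 0.999)
    }
})

test_that("tiny regions are skipped with a warning", {
    lm <- squareLabelMap(20)
    lm[5, 5] <- 2L; lm[5, 6] <- 2L   # 2-pixel region
    expect_warning(m <- measureDroplets(lm, ScaleCalibration(1)),
                   "skipped")
    expect_equal(nrow(m), 1L)
})

test_that("measurements scale linearly, volumes cubically, with the scale", {
    lm <- diskLabelMap(81)
    m1 <- measureDroplets(lm, ScaleCalibration(1))
    m2 <- measureDroplets(lm, ScaleCalibration(2))
    expect_equal(m2$area_equiv_diameter_um, 2 * m1$area_equiv_diameter_um)
    expect_equal(m2$feret_max_um, 2 * m1$feret_max_um)
    expect_equal(m2$volume_nl, 8 * m1$volume_nl)
})

test_that("day summaries compute pooled means and sds", {
    m3 <- data.frame(area_equiv_diameter_um = c(116, 117, 118),
                     volume_nl = sphereVolumeNl(c(116, 117, 118)))
    s <- summarizeDay(m3)
    expect_equal(s$day$mean_diameter_um, 117)
    expect_equal(s$day$sd_diameter_um, 1)
    expect_equal(s$day$n_droplets, 3)

    s1 <- summarizeDay(m3[2, , drop = FALSE])
    expect_equal(s1$day$sd_diameter_um, 0)

    expect_error(summarizeDay(m3[0, ]), "no measurements")

    # per-well split
    sw <- summarizeDay(m3, well = c("a", "a", "b"))
    expect_equal(nrow(sw$wells), 2)
    expect_equal(sw$wells$n_droplets, c(2, 1))
})

test_that("volume-averaging conventions behave as documented", {
    days <- data.frame(mean_diameter_um = c(117.02, 116.59, 116.60),
                       sd_diameter_um = c(1.37, 2.21, 3.18))
    expect_equal(round(averageDropletVolume(days, "moment_corrected"), 3),
                 0.834)

    one <- data.frame(mean_diameter_um = 117.02, sd_diameter_um = 0,
                      mean_volume_nl = sphereVolumeNl(117.02),
                      n_droplets = 100)
    for (mode in c("moment_corrected", "pooled_droplets",
                   "mean_of_day_means"))
        expect_equal(averageDropletVolume(one, mode),
                     sphereVolumeNl(117.02))

    # pooled mean over synthetic days matches the analytic third moment
    set.seed(42)
    mu <- 116.60; sg <- 3.18
    days3 <- do.call(rbind, lapply(1:3, function(i) {
        d <- rnorm(600, mu, sg)
        data.frame(mean_volume_nl = mean(sphereVolumeNl(d)),
                   n_droplets = 600)
    }))
    analytic <- pi / 6 * (mu^3 + 3 * mu * sg^2) * 1e-6
    expect_lt(abs(averageDropletVolume(days3, "pooled_droplets") /
                  analytic - 1), 0.005)
})
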
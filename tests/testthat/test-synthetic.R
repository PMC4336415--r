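# Synthetic-data module: rendering, partition-count simulation, amplitudes,
# dilution records.

test_that("empty spec renders a blank noise image with empty truth", {
    fld <- renderMonolayer(ImageSpec(n_droplets = 0, width_px = 400,
                                     height_px = 300, seed = 3))
    expect_equal(dim(fld$image), c(300, 400))
    expect_equal(nrow(fld$truth), 0L)
    # nothing but background + noise: grey levels cluster at bg_level
    expect_lt(diff(range(fld$image)), 60)
})

test_that("rendered disk pixel areas match the requested diameters", {
    spec <- cleanFieldSpec(n = 5, sd = 2, noise = 0, seed = 4)
    fld <- renderMonolayer(spec)
    notbg <- fld$image != spec@bg_level
    for (i in seq_len(nrow(fld$truth))) {
        tr <- fld$truth[i, ]
        r_px <- tr$diameter_um / (2 * spec@scale_um_per_px)
        xs <- matrix(0:(ncol(notbg) - 1), nrow(notbg), ncol(notbg),
                     byrow = TRUE)
        ys <- matrix(0:(nrow(notbg) - 1), nrow(notbg), ncol(notbg))
        near <- (xs - tr$center_x_px)^2 + (ys - tr$center_y_px)^2 <=
            (r_px + 3)^2
        n_px <- sum(notbg & near)
        d_eq_px <- 2 * sqrt(n_px / pi)
        expect_lt(abs(d_eq_px - tr$diameter_um / spec@scale_um_per_px), 1)
    }
})

test_that("rendering is bit-reproducible and truth flags are consistent", {
    spec <- ImageSpec(n_droplets = 20, width_px = 1200, height_px = 900,
                      border_fraction = 0.2, seed = 17)
    a <- renderMonolayer(spec)
    b <- renderMonolayer(spec)
    expect_identical(a$image, b$image)
    expect_identical(a$truth, b$truth)
    expect_equal(nrow(a$truth), 20 + round(0.02 * 20))
    r <- a$truth$diameter_um / (2 * spec@scale_um_per_px)
    crosses <- (a$truth$center_x_px - r < 0) |
        (a$truth$center_x_px + r > spec@width_px - 1) |
        (a$truth$center_y_px - r < 0) |
        (a$truth$center_y_px + r > spec@height_px - 1)
    expect_equal(a$truth$touches_border, crosses)
    expect_gte(sum(crosses), 1)
})

test_that("impossible packing densities raise an explicit error", {
    spec <- ImageSpec(n_droplets = 50, width_px = 300, height_px = 300,
                      touching_fraction = 0, border_fraction = 0,
                      satellite_fraction = 0, seed = 1)
    expect_error(renderMonolayer(spec), "packing failure")
})

test_that("zero concentration yields no positive droplets", {
    sp <- PartitionSimSpec(true_concentration_cp_per_ul = 0, seed = 5)
    counts <- simulatePartitionCounts(sp)
    expect_true(all(counts$H == 0))
    expect_equal(nrow(counts), sp@n_days * sp@n_replicates)
})

test_that("positive fraction converges to 1 - exp(-lambda)", {
    # lambda = 815.4 cp/uL x 8.5e-4 uL = 0.693 -> p = 0.5 by construction
    sp <- PartitionSimSpec(true_concentration_cp_per_ul = 815.4,
                           droplet_volume_nl = 0.85, final_dilution = 1,
                           n_droplets = 20000, n_replicates = 1e4,
                           n_days = 1, between_day_cv = 0, seed = 6)
    counts <- simulatePartitionCounts(sp)
    p_hat <- mean(counts$H / counts$C)
    p_true <- -expm1(-815.4 * 0.85e-3)
    se <- sqrt(p_true * (1 - p_true) / (20000 * 1e4))
    expect_lt(abs(p_hat - p_true), 3 * se)
    # bit-reproducibility
    expect_identical(counts, simulatePartitionCounts(sp))
})

test_that("expected positives are monotone in true concentration", {
    t_grid <- c(50, 200, 800, 3200, 12800)
    mean_H <- vapply(t_grid, function(T) {
        sp <- PartitionSimSpec(true_concentration_cp_per_ul = T,
                               final_dilution = 1, n_droplets = 5000,
                               n_replicates = 200, n_days = 1,
                               between_day_cv = 0, seed = 9)
        mean(simulatePartitionCounts(sp)$H)
    }, numeric(1))
    expect_true(all(diff(mean_H) > 0))
})

test_that("no day effect means no detectable between-day component", {
    pvals <- vapply(1:50, function(s) {
        sp <- PartitionSimSpec(between_day_cv = 0, seed = s)
        counts <- simulatePartitionCounts(sp)
        counts$concentration <- copyNumberConcentration(
            counts$C, counts$H, sp@droplet_volume_nl, sp@final_dilution)
        stats::anova(stats::aov(concentration ~ factor(day),
                                data = counts))[["Pr(>F)"]][1]
    }, numeric(1))
    expect_lte(mean(pvals < 0.05), 0.2)
})

test_that("amplitude simulation respects H and separability", {
    a0 <- simulateAmplitudes(500, 0, pos_mean = 6000, neg_mean = 1500,
                             sd = 300, seed = 1)
    expect_length(a0, 500)
    expect_equal(classifyByThreshold(a0, 4002)$H, 0)

    aC <- simulateAmplitudes(500, 500, pos_mean = 6000, neg_mean = 1500,
                             sd = 300, seed = 2)
    expect_equal(classifyByThreshold(aC, 4002)$H, 500)

    # > 6 sigma separation on either side of the threshold: exact recovery
    a <- simulateAmplitudes(20000, 137, pos_mean = 6000, neg_mean = 1500,
                            sd = 300, seed = 3)
    cls <- classifyByThreshold(a, 4002)
    expect_equal(cls$H, 137)
    expect_equal(cls$C, 20000)

    expect_error(simulateAmplitudes(10, 2, pos_mean = 100, neg_mean = 200,
                                    sd = 10))
})

test_that("dilution records convert volumes to exact masses when cv = 0", {
    rec <- simulateDilutionRecord(33.6, 62.4, pipette_cv = 0)
    expect_equal(rec@m_dna_sol_g, 0.0336)          # 33.600 mg
    rec2 <- simulateDilutionRecord(100, 0, dna_density = 1.03532,
                                   pipette_cv = 0)
    expect_equal(rec2@m_dna_sol_g, 0.103532)       # 103.532 mg
})

test_that("pipetting noise produces the requested mass cv", {
    masses <- vapply(1:2000, function(s)
        simulateDilutionRecord(100, 0, pipette_cv = 0.01,
                               seed = s)@m_dna_sol_g, numeric(1))
    cv_hat <- sd(masses) / mean(masses)
    expect_lt(abs(cv_hat - 0.01), 0.001)
})

test_that("invalid specs are rejected by validity checks", {
    expect_error(ImageSpec(diam_mean_um = 5, diam_sd_um = 2), "3")
    expect_error(ImageSpec(touching_fraction = 1.2), "fractions")
    expect_error(PartitionSimSpec(final_dilution = 0.5), "final_dilution")
    expect_error(PartitionSimSpec(between_day_cv = -1), "between_day_cv")
})
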
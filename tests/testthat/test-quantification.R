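# Partition counts -> concentrations, dilution factors, precision.

test_that("assay dilution factor follows the gravimetric definition", {
    # 33.6 uL sample (1.0000 g/mL) + 62.4 uL premix (1.03532 g/mL)
    rec <- DilutionRecord(m_dna_sol_g = 0.0336, delta_dna_sol = 1.0000,
                          m_premix_g = 62.4 * 1.03532e-3,
                          delta_premix = 1.03532)
    expect_equal(round(assayDilutionFactor(rec), 3), 2.857)

    no_premix <- DilutionRecord(m_dna_sol_g = 0.03, m_premix_g = 0)
    expect_equal(assayDilutionFactor(no_premix), 1)

    equal <- DilutionRecord(m_dna_sol_g = 0.05, delta_dna_sol = 1.02,
                            m_premix_g = 0.05, delta_premix = 1.02)
    expect_equal(assayDilutionFactor(equal), 2)
})

test_that("final dilution is the product of sample and assay factors", {
    expect_equal(finalDilution(1, 2.857), 2.857)
    expect_equal(finalDilution(10, 1), 10)
    expect_equal(finalDilution(10, 2.857), 28.57)
})

test_that("the partition-count concentration formula matches hand values", {
    # worked example: half the droplets positive
    expect_equal(round(copyNumberConcentration(20000, 10000, 0.85), 1),
                 815.4)
    # H = 0: log(1) = 0
    expect_equal(copyNumberConcentration(1000, 0, 0.85), 0)
    # H = 1: log ratio is exactly 1, so T = D_f / (C Vd)
    expect_equal(copyNumberConcentration(1000, 1, 0.85, D_f = 3),
                 3 / (1000 * 0.85e-3))
    expect_error(copyNumberConcentration(1000, 1000, 0.85), "saturated")
    expect_error(copyNumberConcentration(1000, 1001, 0.85), "H must")
})

test_that("concentration is proportional to dilution and inverse in volume", {
    T1 <- copyNumberConcentration(15000, 4000, 0.834)
    expect_equal(copyNumberConcentration(15000, 4000, 0.834, D_f = 2.857),
                 2.857 * T1)
    expect_equal(copyNumberConcentration(15000, 4000, 0.417), 2 * T1)
})

test_that("discrete and continuous Poisson forms agree for large C", {
    for (C in c(1e4, 2e4, 1e5)) {
        for (frac in c(0.05, 0.5, 0.95)) {
            H <- round(C * frac)
            disc <- copyNumberConcentration(C, H, 0.85)
            cont <- -log1p(-H / C) / 0.85e-3   # -ln(1 - H/C) / Vd
            expect_lt(abs(disc / cont - 1), 1e-4)
        }
    }
})

test_that("the Wilson interval contains the estimate and degenerates", {
    ci <- concentrationCI(20000, 10000, 0.85)
    expect_lt(ci["low"], ci["estimate"])
    expect_gt(ci["high"], ci["estimate"])
    expect_equal(unname(ci["estimate"]),
                 copyNumberConcentration(20000, 10000, 0.85))

    ci0 <- concentrationCI(20000, 0, 0.85)
    expect_equal(unname(ci0["low"]), 0)

    cid <- concentrationCI(20000, 10000, 0.85, level = 0)
    expect_equal(unname(cid["low"]), unname(cid["estimate"]))
    expect_equal(unname(cid["high"]), unname(cid["estimate"]))
})

test_that("volume rescaling is exact inverse proportionality", {
    expect_equal(rescaleConcentration(9454, 0.834, 0.834), 9454)
    expect_equal(round(rescaleConcentration(9454, 0.834, 0.91)), 8664)
    expect_equal(rescaleConcentration(1000, 0.8, 0.4), 2000)
})

test_that("estimator recovers simulated truth across the dynamic range", {
    for (T_true in c(10, 1020, 108000)) {
        D_f <- max(1, T_true / 1000)
        sp <- PartitionSimSpec(true_concentration_cp_per_ul = T_true,
                               droplet_volume_nl = 0.85,
                               final_dilution = D_f, n_droplets = 20000,
                               n_replicates = 100, n_days = 1,
                               between_day_cv = 0,
                               seed = round(T_true) %% 1000 + 1)
        counts <- simulatePartitionCounts(sp)
        est <- copyNumberConcentration(counts$C, counts$H, 0.85, D_f)
        se <- sd(est) / sqrt(length(est))
        expect_lt(abs(mean(est) - T_true), 3 * se)
    }
})

test_that("intermediate precision reduces to the SEM without a day effect", {
    # three days drawn from identical populations, laid out exactly equal
    vals <- c(9300, 9400, 9500, 9600)
    d <- data.frame(day = rep(1:3, each = 4), replicate = rep(1:4, 3),
                    concentration = rep(vals, 3))
    ps <- intermediatePrecision(d)
    expect_equal(ps@s_between_day, 0)
    expect_true(ps@truncated)
    expect_equal(ps@u_combined, ps@s_repeat / sqrt(12))
    expect_equal(expandedUncertainty(ps), 2 * ps@u_combined)
})

test_that("the grand mean equals the mean of balanced day means", {
    day_means <- c(9310, 9586, 9465)
    d <- data.frame(day = rep(1:3, each = 2), replicate = rep(1:2, 3),
                    concentration = as.vector(rbind(day_means - 50,
                                                    day_means + 50)))
    ps <- intermediatePrecision(d)
    expect_equal(round(grandMean(ps)), 9454)

    ps2 <- intermediatePrecisionFromSummaries(day_means,
                                              c(196, 224, 352), n = 8)
    expect_equal(round(grandMean(ps2)), 9454)
})

test_that("unbalanced or degenerate designs are rejected", {
    d <- data.frame(day = c(1, 1, 2), replicate = c(1, 2, 1),
                    concentration = c(1, 2, 3))
    expect_error(intermediatePrecision(d), "unbalanced")
    d1 <- data.frame(day = 1, replicate = 1:4, concentration = 1:4)
    expect_error(intermediatePrecision(d1), "2 days")
})

test_that("variance components are recovered on average", {
    set.seed(11)
    p <- 3; n <- 8; sd_day <- 130; sd_rep <- 130
    est <- t(replicate(200, {
        d <- expand.grid(replicate = seq_len(n), day = seq_len(p))
        d$concentration <- 9454 + rep(rnorm(p, 0, sd_day), each = n) +
            rnorm(p * n, 0, sd_rep)
        ps <- intermediatePrecision(d)
        c(ps@s_between_day^2, ps@s_repeat^2)
    }))
    expect_lt(abs(mean(est[, 1]) / sd_day^2 - 1), 0.15)
    expect_lt(abs(mean(est[, 2]) / sd_rep^2 - 1), 0.15)
})

test_that("solution density comes from repeated weighings", {
    expect_equal(premixDensity(rep(0.103532, 10), 100), 1.03532)
    expect_equal(premixDensity(rep(0.1, 10), 100), 1)
    set.seed(3)
    noisy <- 0.103532 * (1 + rnorm(50, 0, 0.01))
    expect_lt(abs(premixDensity(noisy, 100) / 1.03532 - 1), 0.01)
    expect_error(premixDensity(numeric(0), 100), "at least one")
})
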
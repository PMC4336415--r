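# Poisson partition statistics: partition counts -> copy-number
# concentration, gravimetric dilution factors, volume rescaling and
# intermediate-precision uncertainty.

#' Assay dilution factor from a gravimetric record
#'
#' The dilution of the DNA solution in the assay, from weighed masses and
#' densities: each mass is converted to a volume by dividing by the solution
#' density, and
#' \deqn{D_a = \frac{m_{DNA}/\delta_{DNA} + m_{premix}/\delta_{premix}}
#'                  {m_{DNA}/\delta_{DNA}}.}
#'
#' @param record a \linkS4class{DilutionRecord}.
#' @return the dimensionless assay dilution factor (>= 1).
#' @examples
#' rec <- DilutionRecord(m_dna_sol_g = 0.0336, delta_dna_sol = 1.0000,
#'                       m_premix_g = 0.064604, delta_premix = 1.03532)
#' round(assayDilutionFactor(rec), 3)  # 2.857
#' @export
assayDilutionFactor <- function(record) {
    stopifnot(is(record, "DilutionRecord"))
    validObject(record)
    v_dna <- record@m_dna_sol_g / record@delta_dna_sol
    v_pre <- record@m_premix_g / record@delta_premix
    if (v_dna <= 0) stop("DNA solution volume is zero")
    (v_dna + v_pre) / v_dna
}

#' Final dilution factor
#'
#' Product of the sample pre-dilution factor and the assay dilution factor:
#' \eqn{D_f = D_s \times D_a}.
#'
#' @param D_s sample pre-dilution factor (>= 1).
#' @param D_a assay dilution factor (>= 1), e.g. from
#'   [assayDilutionFactor()].
#' @return \eqn{D_f}.
#' @export
finalDilution <- function(D_s, D_a) {
    stopifnot(D_s >= 1, D_a >= 1)
    D_s * D_a
}

.volNlToUl <- function(volume_nl) volume_nl * 1e-3

#' Copy-number concentration from partition counts
#'
#' Converts the positive/total droplet counts of one well into the
#' copy-number concentration of the undiluted sample:
#' \deqn{T_c = D_f \times \frac{1}{C \, V_d} \times
#'       \frac{\log(1 - H/C)}{\log(1 - 1/C)}}
#' with \eqn{C} analysed droplets, \eqn{H} positive droplets, droplet volume
#' \eqn{V_d} (supplied in nL, converted internally to uL so that \eqn{T_c}
#' is in cp/uL) and final dilution factor \eqn{D_f}.  The log ratio is
#' base-invariant.  For large \eqn{C} this approaches the familiar Poisson
#' form \eqn{-\ln(1 - H/C) \cdot D_f / (C V_d)}.
#'
#' @param C analysed (accepted) droplets; vectorised.
#' @param H positive droplets, `0 <= H < C`.  `H == C` is not estimable
#'   (every droplet positive) and raises an error: dilute the sample instead.
#' @param volume_nl average droplet volume \eqn{V_d} in nL (e.g. 0.834 as
#'   measured by microscopy, 0.91 or 0.85 as assumed by instrument software
#'   versions).
#' @param D_f final dilution factor (default 1).
#' @return concentration in cp/uL.
#' @examples
#' round(copyNumberConcentration(20000, 10000, 0.85), 1)  # 815.4
#' @export
copyNumberConcentration <- function(C, H, volume_nl, D_f = 1) {
    stopifnot(all(C >= 1), all(volume_nl > 0), all(D_f >= 1))
    if (any(H < 0) || any(H > C))
        stop("H must satisfy 0 <= H <= C")
    if (any(H == C))
        stop("saturated: all partitions positive; dilute the sample")
    v_ul <- .volNlToUl(volume_nl)
    D_f * (1 / (C * v_ul)) * log1p(-H / C) / log1p(-1 / C)
}

#' Confidence interval for a copy-number concentration
#'
#' Wilson score interval on the positive fraction `H/C`, mapped through the
#' monotone partition-count transform of [copyNumberConcentration()].  The
#' droplet-count formula has no printed per-well interval convention; this
#' is a convenience for plotting and sanity checks, not a certified
#' uncertainty budget.
#'
#' @inheritParams copyNumberConcentration
#' @param level confidence level (default 0.95; 0 gives a degenerate
#'   interval at the estimate).
#' @return named numeric: `low`, `estimate`, `high` (cp/uL).
#' @export
concentrationCI <- function(C, H, volume_nl, D_f = 1, level = 0.95) {
    stopifnot(length(C) == 1L, length(H) == 1L, level >= 0, level < 1)
    est <- copyNumberConcentration(C, H, volume_nl, D_f)
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- H / C
    den <- 1 + z^2 / C
    ctr <- (p + z^2 / (2 * C)) / den
    hw <- z * sqrt(p * (1 - p) / C + z^2 / (4 * C^2)) / den
    plo <- max(0, ctr - hw)
    phi <- min(ctr + hw, 1 - 1 / (2 * C))  # keep transform finite
    tr <- function(pp) {
        hh <- pp * C
        D_f * (1 / (C * .volNlToUl(volume_nl))) *
            log1p(-hh / C) / log1p(-1 / C)
    }
    c(low = tr(plo), estimate = est, high = tr(phi))
}

#' Rescale a concentration to a different droplet volume
#'
#' The estimated concentration is inversely proportional to the droplet
#' volume used in the conversion, so an estimate obtained with volume
#' `volume_old_nl` becomes `T * volume_old_nl / volume_new_nl` under
#' `volume_new_nl`.  This is how estimates produced under an instrument's
#' assumed droplet volume are corrected to a measured volume (or vice
#' versa).
#'
#' @param T_c concentration (cp/uL); vectorised.
#' @param volume_old_nl,volume_new_nl droplet volumes (nL).
#' @return rescaled concentration (cp/uL).
#' @examples
#' round(rescaleConcentration(9454, 0.834, 0.91))  # 8664
#' @export
rescaleConcentration <- function(T_c, volume_old_nl, volume_new_nl) {
    stopifnot(all(volume_old_nl > 0), all(volume_new_nl > 0))
    T_c * volume_old_nl / volume_new_nl
}

#' Intermediate-precision uncertainty from a day-by-replicate design
#'
#' One-way random-effects ANOVA with day as the random factor, on a balanced
#' table of per-well concentrations: the residual mean square gives the
#' repeatability variance \eqn{s_r^2}; the between-day component is
#' \eqn{s_b^2 = \max(0, (MS_{between} - MS_{within})/n)} for \eqn{n}
#' replicates per day (negative estimates are truncated at zero and
#' flagged); and the standard uncertainty of the grand mean over \eqn{p}
#' days is
#' \deqn{u^2 = s_b^2 / p + s_r^2 / (p n),}
#' expanded with coverage factor k = 2.
#'
#' @param concentrations data.frame with columns `day`, `replicate` and
#'   `concentration` (cp/uL), balanced with >= 2 days and >= 2 replicates
#'   per day.
#' @return a \linkS4class{PrecisionSummary}.
#' @examples
#' set.seed(1)
#' d <- expand.grid(day = 1:3, replicate = 1:8)
#' d$concentration <- 9454 + rnorm(24, 0, 130) + rep(rnorm(3, 0, 130), 8)
#' intermediatePrecision(d)
#' @export
intermediatePrecision <- function(concentrations) {
    req <- c("day", "replicate", "concentration")
    if (!all(req %in% names(concentrations)))
        stop("need columns: ", paste(req, collapse = ", "))
    day <- factor(concentrations$day)
    p <- nlevels(day)
    if (p < 2) stop("need >= 2 days")
    tab <- table(day)
    if (length(unique(tab)) != 1L)
        stop("unbalanced design: equal replicates per day required")
    n <- unname(tab[1])
    if (n < 2) stop("need >= 2 replicates per day")
    fit <- stats::aov(concentration ~ day,
                      data = data.frame(concentration =
                                            concentrations$concentration,
                                        day = day))
    an <- stats::anova(fit)
    ms_between <- an[["Mean Sq"]][1]
    ms_within <- an[["Mean Sq"]][2]
    s2_rep <- ms_within
    s2_day_raw <- (ms_between - ms_within) / n
    truncated <- s2_day_raw < 0
    s2_day <- max(0, s2_day_raw)
    u2 <- s2_day / p + s2_rep / (p * n)
    new("PrecisionSummary",
        grand_mean = mean(concentrations$concentration),
        s_repeat = sqrt(s2_rep),
        s_between_day = sqrt(s2_day),
        u_combined = sqrt(u2),
        U_expanded = 2 * sqrt(u2),
        n_days = p, n_replicates = n,
        truncated = truncated)
}

#' Solution density from repeated weighings
#'
#' Density of a solution determined gravimetrically: a fixed volume is
#' weighed repeatedly and each mass divided by the pipetted volume; the mean
#' of the individual densities is reported in g/mL.
#'
#' @param masses_g weighed masses (g), one per weighing.
#' @param volume_ul pipetted volume per weighing (uL).
#' @return density (g/mL).
#' @examples
#' premixDensity(rep(0.103532, 10), 100)  # 1.03532
#' @export
premixDensity <- function(masses_g, volume_ul) {
    if (length(masses_g) < 1L) stop("need at least one weighing")
    stopifnot(volume_ul > 0, all(masses_g > 0))
    mean(masses_g / (volume_ul * 1e-3))
}

#' Intermediate precision reconstructed from per-day summaries
#'
#' Same variance-components combination as [intermediatePrecision()], but
#' starting from per-day means and standard deviations of a balanced design
#' (as printed in summary tables) instead of raw replicate values: the
#' within mean square is the mean of the squared day sds and the between
#' mean square is `n` times the variance of the day means.
#'
#' @param day_means per-day mean concentrations (cp/uL), length p >= 2.
#' @param day_sds per-day replicate sds (cp/uL), same length.
#' @param n replicates per day (>= 2).
#' @return a \linkS4class{PrecisionSummary}.
#' @examples
#' intermediatePrecisionFromSummaries(c(9310, 9586, 9465),
#'                                    c(196, 224, 352), n = 8)
#' @export
intermediatePrecisionFromSummaries <- function(day_means, day_sds, n) {
    p <- length(day_means)
    stopifnot(p >= 2, length(day_sds) == p, n >= 2, all(day_sds >= 0))
    ms_within <- mean(day_sds^2)
    ms_between <- n * stats::var(day_means)
    s2_day_raw <- (ms_between - ms_within) / n
    truncated <- s2_day_raw < 0
    s2_day <- max(0, s2_day_raw)
    u2 <- s2_day / p + ms_within / (p * n)
    new("PrecisionSummary",
        grand_mean = mean(day_means),
        s_repeat = sqrt(ms_within),
        s_between_day = sqrt(s2_day),
        u_combined = sqrt(u2),
        U_expanded = 2 * sqrt(u2),
        n_days = p, n_replicates = n,
        truncated = truncated)
}
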
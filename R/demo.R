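# End-to-end demonstration: reproduce the packaged published tables and run
# a synthetic image -> sizing -> simulation -> quantification round trip.

#' Run the full demonstration pipeline
#'
#' Produces a report bundle with four parts:
#' \enumerate{
#'   \item \strong{Droplet sizing reproduction}: per-day sphere-equivalent
#'     volumes from the packaged printed diameters
#'     ([dropletDaySummaries()]), the 3-day average droplet volume under all
#'     three averaging conventions, the grand-mean concentration over the
#'     three days, and the intermediate-precision uncertainty reconstructed
#'     from the per-day summaries.
#'   \item \strong{CRM bias reproduction}: the six-level bias table
#'     ([biasTable()]) in both uncertainty conventions, plus the same table
#'     after rescaling the measured concentrations from the instrument
#'     software's assumed 0.91 nL droplet volume to the measured average
#'     volume.
#'   \item \strong{Volume discrepancy}: percent difference between the
#'     0.91 nL software volume and the measured average volume, and the
#'     residual percent bias of the grand mean against the certified
#'     10300 cp/uL level.
#'   \item \strong{Synthetic end-to-end run} (optional): render monolayer
#'     fields, calibrate the scale from a synthetic grid, segment and
#'     measure the droplets, simulate partition counts using the recovered
#'     volume, quantify them, and compare with the known true
#'     concentration.
#' }
#'
#' @param seed integer seed driving every random step.
#' @param synthetic run the synthetic end-to-end part (slowest part; a few
#'   seconds).
#' @param n_fields,droplets_per_field size of the synthetic imaging run.
#' @param out_dir if non-NULL, CSV outputs are written there.
#' @param config run configuration list, see [readRunConfig()].
#' @return a list of class `"dropMetricsDemo"` with elements `sizing`,
#'   `bias`, `volume_discrepancy`, `synthetic` and `meta`; printed as a
#'   short report.
#' @examples
#' \donttest{
#' demo <- runFullDemo(seed = 1, synthetic = FALSE)
#' demo
#' }
#' @export
runFullDemo <- function(seed = 1L, synthetic = TRUE, n_fields = 2,
                        droplets_per_field = 30, out_dir = NULL,
                        config = defaultRunConfig()) {
    days <- dropletDaySummaries()
    v_soft <- config$software_volumes_nl[["QuantaSoft 1.3.2.0"]]

    # -- part 1: sizing ----------------------------------------------------
    day_vols <- sphereVolumeNl(days$mean_diameter_um)
    avg_vol <- averageDropletVolume(days, "moment_corrected")
    days$mean_volume_nl <- momentCorrectedVolumeNl(days$mean_diameter_um,
                                                   days$sd_diameter_um)
    prec <- intermediatePrecisionFromSummaries(days$conc_mean_cp_per_ul,
                                               days$conc_sd_cp_per_ul,
                                               n = days$n_replicates[1])
    sizing <- list(
        day_table = data.frame(
            day = days$day,
            mean_diameter_um = days$mean_diameter_um,
            sd_diameter_um = days$sd_diameter_um,
            n_droplets = days$n_droplets,
            volume_nl = round(day_vols, 3),
            conc_mean_cp_per_ul = days$conc_mean_cp_per_ul),
        average_volume_nl = avg_vol,
        average_volume_by_mode = c(
            moment_corrected = avg_vol,
            pooled_droplets = averageDropletVolume(
                days, "pooled_droplets"),
            mean_of_day_means = averageDropletVolume(
                days, "mean_of_day_means")),
        grand_mean_cp_per_ul = grandMean(prec),
        precision = prec)

    # -- part 2: bias ------------------------------------------------------
    crm <- crmReferenceValues()
    meas <- ddpcrMeasurementSummaries()
    meas_rescaled <- meas
    fac <- v_soft / avg_vol
    meas_rescaled$mean <- meas$mean * fac
    meas_rescaled$sd <- meas$sd * fac
    bias <- list(
        as_printed = biasTable(crm, meas, "as_printed"),
        footnote = biasTable(crm, meas, "footnote"),
        rescaled_to_measured_volume = biasTable(crm, meas_rescaled,
                                                config$bias_mode))

    # -- part 3: volume discrepancy ---------------------------------------
    volume_discrepancy <- list(
        software_volume_nl = v_soft,
        measured_volume_nl = avg_vol,
        percent_smaller = 100 * (v_soft - avg_vol) / v_soft,
        residual_bias_percent = 100 *
            (crm$certified_value[crm$level_id == "c"] - grandMean(prec)) /
            crm$certified_value[crm$level_id == "c"])

    # -- part 4: synthetic end-to-end -------------------------------------
    synth <- NULL
    if (synthetic) {
        grid <- renderCalibrationGrid(800, 600, spacing_px = 200,
                                      jitter_px = 0.2, noise_sd = 3,
                                      seed = seed + 1L)
        cal <- calibrateScale(grid, nominal_spacing_um = 200)
        params <- SegmentationParams(
            min_area_px = minAreaForScale(cal@um_per_px))
        meas_all <- list()
        for (f in seq_len(n_fields)) {
            fld <- renderMonolayer(ImageSpec(
                width_px = 1280, height_px = 960,
                n_droplets = droplets_per_field, seed = seed + 10L + f))
            lab <- segmentDroplets(fld$image, params)
            m <- measureDroplets(lab, cal)
            m$well_id <- paste0("well", f)
            meas_all[[f]] <- m
        }
        meas_df <- do.call(rbind, meas_all)
        sizing_day <- summarizeDay(meas_df)
        v_meas <- sizing_day$day$mean_volume_nl
        sim <- PartitionSimSpec(true_concentration_cp_per_ul = 10300,
                                droplet_volume_nl = v_meas,
                                seed = seed + 100L)
        counts <- simulatePartitionCounts(sim)
        counts$concentration <- copyNumberConcentration(
            counts$C, counts$H, v_meas, sim@final_dilution)
        sprec <- intermediatePrecision(counts)
        synth <- list(scale = cal, n_droplets_measured = nrow(meas_df),
                      mean_diameter_um = sizing_day$day$mean_diameter_um,
                      measured_volume_nl = v_meas,
                      true_concentration = 10300,
                      recovered = sprec)
    }

    out <- list(sizing = sizing, bias = bias,
                volume_discrepancy = volume_discrepancy, synthetic = synth,
                meta = list(seed = seed, config = config,
                            package_version =
                                as.character(utils::packageVersion(
                                    "dropMetrics"))))
    class(out) <- "dropMetricsDemo"

    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(sizing$day_table,
                         file.path(out_dir, "sizing_days.csv"),
                         row.names = FALSE)
        utils::write.csv(bias$as_printed,
                         file.path(out_dir, "bias_as_printed.csv"),
                         row.names = FALSE)
        utils::write.csv(bias$rescaled_to_measured_volume,
                         file.path(out_dir, "bias_rescaled.csv"),
                         row.names = FALSE)
    }
    out
}

#' @export
print.dropMetricsDemo <- function(x, ...) {
    cat("== dropMetrics demonstration report ==\n\n")
    cat("Droplet sizing (per day):\n")
    print(x$sizing$day_table, row.names = FALSE)
    cat("\nAverage droplet volume:",
        format(round(x$sizing$average_volume_nl, 3), nsmall = 3), "nL",
        "(moment-corrected over days)\n")
    cat("Grand mean concentration:",
        round(x$sizing$grand_mean_cp_per_ul), "cp/uL, U(k=2) =",
        round(expandedUncertainty(x$sizing$precision)), "cp/uL\n")
    vd <- x$volume_discrepancy
    cat("\nSoftware droplet volume", vd$software_volume_nl,
        "nL vs measured", format(round(vd$measured_volume_nl, 3)),
        "nL: measured volume is", round(vd$percent_smaller),
        "% smaller\n")
    cat("Residual bias vs certified 10300 cp/uL:",
        round(vd$residual_bias_percent), "%\n")
    cat("\nCRM bias table (as-printed convention):\n")
    b <- x$bias$as_printed
    b$delta_m <- round(b$delta_m); b$U_delta <- round(b$U_delta)
    b$u_m <- round(b$u_m)
    b$percent_difference <- round(b$percent_difference)
    print(b, row.names = FALSE)
    nsig <- sum(x$bias$rescaled_to_measured_volume$significant)
    cat("\nAfter rescaling to the measured volume:", nsig,
        "of", nrow(b), "levels remain significantly biased\n")
    if (!is.null(x$synthetic)) {
        s <- x$synthetic
        cat("\nSynthetic end-to-end:", s$n_droplets_measured,
            "droplets sized; mean diameter",
            format(round(s$mean_diameter_um, 2)), "um; volume",
            format(round(s$measured_volume_nl, 3)), "nL\n")
        cat("  true concentration", s$true_concentration,
            "cp/uL; recovered", round(grandMean(s$recovered)),
            "+/-", round(expandedUncertainty(s$recovered)),
            "cp/uL (k=2)\n")
    }
    invisible(x)
}
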
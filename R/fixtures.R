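# Packaged reference datasets: the certified values of the ERM-AD623
# plasmid dilution series and the published ddPCR measurement summaries
# against which the pipeline's arithmetic is validated.

.extdata <- function(file) {
    path <- system.file("extdata", file, package = "dropMetrics",
                        mustWork = TRUE)
    utils::read.csv(path)
}

#' Packaged reference datasets
#'
#' Small published summary tables shipped with the package:
#' \describe{
#'   \item{`crmReferenceValues()`}{the six certified copy-number
#'     concentration levels of the ERM-AD623 plasmid series (10 to
#'     1.08e6 cp/uL) with their expanded uncertainties (k = 2).}
#'   \item{`ddpcrMeasurementSummaries()`}{mean/sd over 8 ddPCR replicates of
#'     each level, as obtained with the instrument software's assumed
#'     droplet volume of 0.91 nL.}
#'   \item{`dropletDaySummaries()`}{per-day droplet sizing summaries (mean
#'     and sd of the area-equivalent diameter, droplet count) and the
#'     corresponding per-day ddPCR concentration means/sds for the
#'     10300 cp/uL level, measured with each day's droplet volume over a
#'     3-day x 8-replicate intermediate-precision design.}
#' }
#'
#' @return a data.frame (see Details for columns).
#' @examples
#' crmReferenceValues()
#' dropletDaySummaries()
#' @export
crmReferenceValues <- function() .extdata("crm_erm_ad623.csv")

#' @rdname crmReferenceValues
#' @export
ddpcrMeasurementSummaries <- function() .extdata("ddpcr_measured_0p91nl.csv")

#' @rdname crmReferenceValues
#' @export
dropletDaySummaries <- function() .extdata("droplet_day_summaries.csv")
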
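# Bias assessment against certified reference material (CRM) values:
# difference between measured mean and certified value compared with the
# combined expanded uncertainty at 95 % confidence (k = 2).

#' Assess measurement bias against a certified value
#'
#' Compares the mean of replicate measurements with a certified reference
#' value.  The absolute difference \eqn{\Delta_m = |certified - mean|} is
#' judged significant (95 % confidence) when it exceeds the combined
#' expanded uncertainty \eqn{U_\Delta} of the measurement and the certified
#' value (strict inequality).
#'
#' Two conventions for \eqn{U_\Delta} are provided, because published
#' comparison tables of this kind are not always internally consistent:
#' \describe{
#'   \item{`as_printed`}{\eqn{U_\Delta = \sqrt{sd^2 + U_{CRM}^2}} and
#'     \eqn{u_m = \sqrt{(sd/2)^2 + (U_{CRM}/2)^2}}.  This treats the
#'     replicate sd itself as the expanded measurement uncertainty; it is
#'     the convention that reproduces typical printed CRM comparison
#'     tables, and is the default.}
#'   \item{`footnote`}{\eqn{u_m = sd/\sqrt{n}} (the standard error of the
#'     mean, as comparison-procedure write-ups usually define it) and
#'     \eqn{U_\Delta = 2\sqrt{u_m^2 + (U_{CRM}/2)^2}}.  For n >= 4 this is
#'     never larger than the `as_printed` value, so it never declares
#'     fewer biases on the same data.}
#' }
#'
#' @param certified certified value (cp/uL).
#' @param U_crm expanded uncertainty (k = 2) of the certified value (cp/uL).
#' @param mean_measured mean of the replicate measurements (cp/uL).
#' @param sd_measured sd of the replicate measurements (cp/uL).
#' @param n number of replicates (>= 2).
#' @param mode uncertainty-combination convention, see Details.
#' @return one-row data.frame: `delta_m`, `u_m`, `U_delta`, `significant`,
#'   `percent_difference` (100 * delta_m / certified).  Full precision is
#'   retained; round for display.
#' @examples
#' assessBias(10300, 1000, 8851, 669, 8)   # delta 1449 > U 1203: significant
#' @export
assessBias <- function(certified, U_crm, mean_measured, sd_measured, n,
                       mode = c("as_printed", "footnote")) {
    mode <- match.arg(mode)
    stopifnot(certified > 0, U_crm > 0, sd_measured >= 0, n >= 2)
    delta_m <- abs(certified - mean_measured)
    if (mode == "as_printed") {
        u_m <- sqrt((sd_measured / 2)^2 + (U_crm / 2)^2)
        U_delta <- sqrt(sd_measured^2 + U_crm^2)
    } else {
        u_m <- sd_measured / sqrt(n)
        U_delta <- 2 * sqrt(u_m^2 + (U_crm / 2)^2)
    }
    data.frame(delta_m = delta_m, u_m = u_m, U_delta = U_delta,
               significant = delta_m > U_delta,
               percent_difference = 100 * delta_m / certified)
}

#' Bias table over a series of CRM levels
#'
#' Applies [assessBias()] to every level of a certified reference material
#' series and returns the comparison table, ordered from the lowest to the
#' highest certified concentration (the conventional presentation for a
#' dilution series).
#'
#' @param crm data.frame with columns `level_id`, `certified_value`,
#'   `U_crm`.
#' @param measurements data.frame with columns `level_id`, `mean`, `sd`,
#'   `n`.
#' @param mode passed to [assessBias()].
#' @return data.frame with one row per level: the CRM columns, the
#'   measurement columns and the [assessBias()] results.  An attribute
#'   `mode` records the convention used.
#' @examples
#' crm <- data.frame(level_id = c("e", "f"),
#'                   certified_value = c(104, 10), U_crm = c(10, 1.5))
#' meas <- data.frame(level_id = c("e", "f"), mean = c(87, 9),
#'                    sd = c(10, 2), n = 8)
#' biasTable(crm, meas)
#' @export
biasTable <- function(crm, measurements, mode = c("as_printed", "footnote")) {
    mode <- match.arg(mode)
    if (nrow(crm) == 0L) {
        out <- data.frame(level_id = character(0),
                          certified_value = numeric(0), U_crm = numeric(0),
                          mean = numeric(0), sd = numeric(0), n = numeric(0),
                          delta_m = numeric(0), u_m = numeric(0),
                          U_delta = numeric(0), significant = logical(0),
                          percent_difference = numeric(0))
        attr(out, "mode") <- mode
        return(out)
    }
    if (!setequal(crm$level_id, measurements$level_id) ||
        anyDuplicated(crm$level_id) || anyDuplicated(measurements$level_id))
        stop("level_id mismatch between CRM and measurement tables")
    m <- measurements[match(crm$level_id, measurements$level_id), ]
    res <- do.call(rbind, lapply(seq_len(nrow(crm)), function(i)
        assessBias(crm$certified_value[i], crm$U_crm[i],
                   m$mean[i], m$sd[i], m$n[i], mode = mode)))
    out <- cbind(crm[, c("level_id", "certified_value", "U_crm")],
                 m[, c("mean", "sd", "n")], res)
    out <- out[order(out$certified_value), ]
    rownames(out) <- NULL
    attr(out, "mode") <- mode
    out
}
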
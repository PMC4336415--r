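# CSV / image / config input-output with validation.

.requireCols <- function(df, cols, path) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop("malformed table '", path, "': missing column(s) ",
             paste(miss, collapse = ", "))
}

.rowError <- function(path, bad, what) {
    # +1 for the header row so the number matches the file line
    stop("malformed row in '", path, "' (line ", bad[1] + 1L, "): ", what)
}

#' Read and write partition-count tables
#'
#' Comma-separated, UTF-8, header row required.  Columns: `day`,
#' `replicate`, `C` (total accepted droplets), `H` (positive droplets);
#' rows violating `C >= 1` or `0 <= H <= C` are rejected with the offending
#' line number.
#'
#' @param path CSV file path.
#' @return `readCountsCsv()` returns a validated data.frame.
#' @export
readCountsCsv <- function(path) {
    df <- utils::read.csv(path)
    .requireCols(df, c("day", "replicate", "C", "H"), path)
    bad <- which(!is.finite(df$C) | df$C < 1)
    if (length(bad)) .rowError(path, bad, "C must be >= 1")
    bad <- which(!is.finite(df$H) | df$H < 0 | df$H > df$C)
    if (length(bad)) .rowError(path, bad, "H must satisfy 0 <= H <= C")
    df
}

#' @rdname readCountsCsv
#' @param counts data.frame as returned by [simulatePartitionCounts()] or
#'   [readCountsCsv()].
#' @return `writeCountsCsv()` returns `path`, invisibly.
#' @export
writeCountsCsv <- function(counts, path) {
    .requireCols(counts, c("day", "replicate", "C", "H"), "counts")
    utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read CRM certified values and measurement summaries
#'
#' `readCrmCsv()` expects columns `level_id`, `certified_value`, `U_crm`;
#' `readMeasurementSummariesCsv()` expects `level_id`, `mean`, `sd`, `n`.
#' Both validate positivity and report offending line numbers.
#'
#' @param path CSV file path.
#' @return a validated data.frame.
#' @export
readCrmCsv <- function(path) {
    df <- utils::read.csv(path)
    .requireCols(df, c("level_id", "certified_value", "U_crm"), path)
    bad <- which(!is.finite(df$certified_value) | df$certified_value <= 0 |
                 !is.finite(df$U_crm) | df$U_crm <= 0)
    if (length(bad))
        .rowError(path, bad, "certified_value and U_crm must be positive")
    df
}

#' @rdname readCrmCsv
#' @export
readMeasurementSummariesCsv <- function(path) {
    df <- utils::read.csv(path)
    .requireCols(df, c("level_id", "mean", "sd", "n"), path)
    bad <- which(!is.finite(df$sd) | df$sd < 0 | !is.finite(df$n) | df$n < 2)
    if (length(bad)) .rowError(path, bad, "need sd >= 0 and n >= 2")
    df
}

#' Read and write 8-bit grayscale images
#'
#' PNG or TIFF by file extension.  Images are represented in this package as
#' numeric matrices of grey levels 0-255 (rows = y); writing quantises to
#' 8 bits and a write/read round trip preserves 8-bit values exactly.
#'
#' @param image numeric matrix, grey levels 0-255.
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return `readGrayImage()` returns a numeric matrix of grey levels 0-255;
#'   `writeGrayImage()` returns `path` invisibly.
#' @export
writeGrayImage <- function(image, path) {
    stopifnot(is.matrix(image))
    x <- pmin(pmax(image, 0), 255) / 255
    ext <- tolower(tools::file_ext(path))
    if (ext == "png") {
        png::writePNG(x, target = path)
    } else if (ext %in% c("tif", "tiff")) {
        tiff::writeTIFF(x, where = path, bits.per.sample = 8L)
    } else stop("unsupported image extension: ", ext)
    invisible(path)
}

#' @rdname writeGrayImage
#' @export
readGrayImage <- function(path) {
    ext <- tolower(tools::file_ext(path))
    x <- if (ext == "png") {
        png::readPNG(path)
    } else if (ext %in% c("tif", "tiff")) {
        tiff::readTIFF(path)
    } else stop("unsupported image extension: ", ext)
    if (length(dim(x)) == 3L) x <- x[, , 1]   # grayscale stored with channels
    round(x * 255)
}

#' Read a run configuration
#'
#' YAML configuration holding the run-level choices of the pipeline: the
#' droplet volume with a provenance tag, solution densities, segmentation
#' parameters, the bias-assessment mode and the seed.  Missing fields fall
#' back to [defaultRunConfig()].
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return a named list.
#' @export
readRunConfig <- function(path = NULL) {
    cfg <- defaultRunConfig()
    if (!is.null(path)) {
        user <- yaml::read_yaml(path)
        cfg[names(user)] <- user
    }
    if (!is.numeric(cfg$droplet_volume_nl) || cfg$droplet_volume_nl <= 0)
        stop("config: droplet_volume_nl must be a positive number")
    cfg
}

#' @rdname readRunConfig
#' @export
defaultRunConfig <- function() {
    list(
        droplet_volume_nl = 0.834,
        droplet_volume_provenance = "measured by optical microscopy",
        # assumed volumes of instrument software, kept for rescaling:
        software_volumes_nl = list("QuantaSoft 1.3.2.0" = 0.91,
                                   "QuantaSoft 1.6.6" = 0.85),
        dna_density_g_per_ml = 1.0000,
        premix_density_g_per_ml = 1.03532,
        bias_mode = "as_printed",
        amplitude_threshold = 4002,
        seed = 1L)
}
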
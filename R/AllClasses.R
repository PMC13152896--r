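#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData colData<-
NULL

#' SpectrumSet: reflectance spectra with specimen metadata
#'
#' A \linkS4class{SummarizedExperiment} holding one assay, \code{"reflectance"}
#' (percent reflectance, wavelengths in rows, spectra in columns), with the
#' wavelength grid in \code{rowData(x)$wavelength} and the specimen metadata
#' (\code{specimen_id}, \code{patch}, and typically \code{sex},
#' \code{locality}, \code{human_morph}) in \code{colData(x)}. Column names are
#' \code{"<specimen_id>:<patch>"}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; no extra slots.
#' @name SpectrumSet-class
#' @aliases SpectrumSet-class
#' @exportClass SpectrumSet
setClass("SpectrumSet", contains = "SummarizedExperiment")

setValidity("SpectrumSet", function(object) {
    msg <- character(0)
    if (!"reflectance" %in% names(assays(object)))
        msg <- c(msg, "assay 'reflectance' is required")
    wl <- rowData(object)$wavelength
    if (is.null(wl) || !is.numeric(wl))
        msg <- c(msg, "rowData must contain a numeric 'wavelength' column")
    else if (length(wl) > 1L && any(diff(wl) <= 0))
        msg <- c(msg, "wavelengths must be strictly increasing")
    cd <- colData(object)
    if (!all(c("specimen_id", "patch") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'specimen_id' and 'patch'")
    if ("reflectance" %in% names(assays(object))) {
        r <- assay(object, "reflectance")
        if (length(r) && !all(is.finite(r)))
            msg <- c(msg, "reflectance values must be finite")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SpectrumSet
#'
#' @param reflectance numeric matrix of percent reflectance, wavelengths in
#'   rows and spectra in columns.
#' @param wavelength numeric vector of wavelengths (nm), strictly increasing,
#'   one per row of \code{reflectance}.
#' @param metadata a data.frame or \code{DataFrame} with one row per spectrum
#'   column; must contain \code{specimen_id} and \code{patch}.
#' @return a \linkS4class{SpectrumSet}.
#' @examples
#' wl <- 300:700
#' m <- cbind(a = rep(50, 401), b = seq(0, 40, length.out = 401))
#' md <- data.frame(specimen_id = c("a", "b"), patch = "throat")
#' s <- SpectrumSet(m, wl, md)
#' @export
SpectrumSet <- function(reflectance, wavelength, metadata) {
    reflectance <- as.matrix(reflectance)
    storage.mode(reflectance) <- "double"
    metadata <- as(metadata, "DataFrame")
    if (nrow(metadata) != ncol(reflectance))
        stop("metadata must have one row per spectrum column")
    key <- paste(metadata$specimen_id, metadata$patch, sep = ":")
    if (anyDuplicated(key))
        stop("duplicate (specimen_id, patch): ",
             paste(unique(key[duplicated(key)]), collapse = ", "))
    colnames(reflectance) <- key
    rownames(metadata) <- key
    se <- SummarizedExperiment(
        assays = list(reflectance = reflectance),
        rowData = DataFrame(wavelength = as.numeric(wavelength)),
        colData = metadata)
    new("SpectrumSet", se)
}

#' @describeIn SpectrumSet-class wavelength grid (nm)
#' @param x a SpectrumSet
#' @export
wavelengths <- function(x) rowData(x)$wavelength

#' @describeIn SpectrumSet-class percent-reflectance matrix
#' @export
reflectance <- function(x) assay(x, "reflectance")

#' @describeIn SpectrumSet-class specimen metadata (colData)
#' @export
specimenData <- function(x) colData(x)

setMethod("show", "SpectrumSet", function(object) {
    wl <- wavelengths(object)
    cat(sprintf("SpectrumSet: %d spectra on %d wavelengths", ncol(object),
                nrow(object)))
    if (nrow(object))
        cat(sprintf(" (%g-%g nm)", min(wl), max(wl)))
    cat("\n")
    if (ncol(object)) {
        cd <- colData(object)
        cat("  patches:", paste(unique(cd$patch), collapse = ", "), "\n")
        if ("locality" %in% colnames(cd))
            cat("  localities:", length(unique(cd$locality)), "\n")
    }
    prov <- metadata(object)$cleaning
    if (!is.null(prov))
        cat("  cleaned: clip_negative=", prov$clip_negative,
            ", smooth_span=", ifelse(is.null(prov$smooth_span), "none",
                                     prov$smooth_span), "\n", sep = "")
})

#' Wavelength grids
#'
#' \code{wavelengthGrid()} builds a regular grid; \code{canonicalGrid()} is the
#' working grid all colorimetric summaries assume: 300-700 nm inclusive in
#' 1 nm steps (401 samples). Sums over this grid are plain sample sums.
#'
#' @param start,stop,step grid extent and spacing in nm.
#' @return numeric vector of wavelengths.
#' @export
wavelengthGrid <- function(start = 300, stop = 700, step = 1) {
    if (!(start < stop) || step <= 0)
        stop("need start < stop and step > 0")
    seq(start, stop, by = step)
}

#' @rdname wavelengthGrid
#' @export
canonicalGrid <- function() seq(300, 700, by = 1)
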
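#' Read reflectance spectra and specimen metadata
#'
#' The spectra file is wide delimited text: first column \code{wl}
#' (wavelength, nm), then one column per spectrum named
#' \code{"<specimen_id>:<patch>"}. The metadata file has one row per spectrum
#' with required columns \code{id}, \code{patch}, \code{sex},
#' \code{locality}, \code{human_morph} (optionally \code{svl} and others).
#' Spectra are returned on the file's native grid; no resampling or cleaning
#' is applied.
#'
#' @param spectraPath,metadataPath paths to the two CSV files.
#' @return a \linkS4class{SpectrumSet}.
#' @seealso [writeSpectra()], [resampleSpectra()], [cleanSpectra()]
#' @export
readSpectra <- function(spectraPath, metadataPath) {
    spec <- utils::read.csv(spectraPath, check.names = FALSE,
                            fileEncoding = "UTF-8")
    if (ncol(spec) < 1L || names(spec)[1L] != "wl")
        stop("spectra file must have 'wl' as its first column")
    wl <- spec[[1L]]
    if (!is.numeric(wl)) stop("wavelength column 'wl' is not numeric")
    refl <- spec[, -1L, drop = FALSE]
    bad <- !vapply(refl, is.numeric, logical(1))
    if (any(bad))
        stop("non-numeric reflectance in column(s): ",
             paste(names(refl)[bad], collapse = ", "))
    refl <- as.matrix(refl)

    meta <- utils::read.csv(metadataPath, check.names = FALSE,
                            fileEncoding = "UTF-8",
                            colClasses = "character")
    req <- c("id", "patch", "sex", "locality", "human_morph")
    miss <- setdiff(req, names(meta))
    if (length(miss))
        stop("metadata is missing required column(s): ",
             paste(miss, collapse = ", "))
    if ("svl" %in% names(meta)) meta$svl <- as.numeric(meta$svl)
    key <- paste(meta$id, meta$patch, sep = ":")
    if (anyDuplicated(key))
        stop("duplicate (id, patch) in metadata: ",
             paste(unique(key[duplicated(key)]), collapse = ", "))
    if (ncol(refl) && anyDuplicated(colnames(refl)))
        stop("duplicate (id, patch) spectrum columns: ",
             paste(unique(colnames(refl)[duplicated(colnames(refl))]),
                   collapse = ", "))
    orphanMeta <- setdiff(key, colnames(refl))
    if (length(orphanMeta))
        stop("metadata row(s) with no matching spectrum column: ",
             paste(orphanMeta, collapse = ", "))
    orphanCol <- setdiff(colnames(refl), key)
    if (length(orphanCol))
        stop("spectrum column(s) with no metadata row: ",
             paste(orphanCol, collapse = ", "))
    meta <- meta[match(colnames(refl), key), , drop = FALSE]
    names(meta)[names(meta) == "id"] <- "specimen_id"
    SpectrumSet(refl, wl, meta)
}

#' Write a SpectrumSet to delimited text
#'
#' Inverse of [readSpectra()]: values survive a round trip to within 1e-9.
#'
#' @param set a \linkS4class{SpectrumSet}.
#' @param spectraPath,metadataPath output CSV paths.
#' @return invisibly, the two paths.
#' @export
writeSpectra <- function(set, spectraPath, metadataPath) {
    stopifnot(is(set, "SpectrumSet"))
    df <- data.frame(wl = wavelengths(set), check.names = FALSE)
    r <- reflectance(set)
    for (j in seq_len(ncol(r))) df[[colnames(r)[j]]] <- r[, j]
    utils::write.csv(df, spectraPath, row.names = FALSE,
                     fileEncoding = "UTF-8")
    md <- as.data.frame(colData(set))
    names(md)[names(md) == "specimen_id"] <- "id"
    utils::write.csv(md, metadataPath, row.names = FALSE,
                     fileEncoding = "UTF-8")
    invisible(c(spectraPath, metadataPath))
}

#' Resample spectra onto a wavelength grid
#'
#' Linear interpolation onto \code{grid}. The target grid must lie within the
#' native wavelength coverage; values are never extrapolated.
#'
#' @param set a \linkS4class{SpectrumSet}.
#' @param grid numeric vector of target wavelengths (nm), e.g.
#'   [canonicalGrid()].
#' @return a \linkS4class{SpectrumSet} on \code{grid}.
#' @export
resampleSpectra <- function(set, grid = canonicalGrid()) {
    stopifnot(is(set, "SpectrumSet"))
    grid <- as.numeric(grid)
    wl <- wavelengths(set)
    if (min(grid) < min(wl) || max(grid) > max(wl))
        stop(sprintf(
            "target grid (%g-%g nm) exceeds native coverage (%g-%g nm); %s",
            min(grid), max(grid), min(wl), max(wl),
            "extrapolation is not performed"))
    r <- reflectance(set)
    out <- matrix(0, nrow = length(grid), ncol = ncol(r),
                  dimnames = list(NULL, colnames(r)))
    for (j in seq_len(ncol(r)))
        out[, j] <- stats::approx(wl, r[, j], xout = grid)$y
    res <- SpectrumSet(out, grid, colData(set))
    metadata(res) <- metadata(set)
    res
}

#' Clean reflectance spectra
#'
#' Optional local-regression (loess) smoothing followed by flooring of
#' negative reflectance at zero. Negative raw values are an instrument
#' artefact near the white standard; the pre-clip values of clipped cells are
#' retained in \code{metadata(x)$cleaning$clipped}. With
#' \code{clipNegative = FALSE} and \code{smoothSpan = NULL} the data are
#' returned unchanged.
#'
#' @param set a \linkS4class{SpectrumSet}.
#' @param clipNegative floor negative reflectance at 0 (default TRUE).
#' @param smoothSpan loess span in (0, 1], or NULL (default) for no smoothing.
#' @return a cleaned \linkS4class{SpectrumSet} with provenance in
#'   \code{metadata()}.
#' @export
cleanSpectra <- function(set, clipNegative = TRUE, smoothSpan = NULL) {
    stopifnot(is(set, "SpectrumSet"))
    if (!is.null(smoothSpan) &&
        (!is.numeric(smoothSpan) || smoothSpan <= 0 || smoothSpan > 1))
        stop("smoothSpan must be in (0, 1]")
    r <- reflectance(set)
    wl <- wavelengths(set)
    if (!is.null(smoothSpan) && ncol(r)) {
        for (j in seq_len(ncol(r)))
            r[, j] <- stats::predict(
                stats::loess(y ~ x, data.frame(x = wl, y = r[, j]),
                             span = smoothSpan, degree = 2))
    }
    clipped <- NULL
    if (clipNegative) {
        neg <- which(r < 0, arr.ind = TRUE)
        if (nrow(neg)) {
            clipped <- data.frame(wavelength = wl[neg[, 1]],
                                  spectrum = colnames(r)[neg[, 2]],
                                  raw_value = r[neg])
            r[neg] <- 0
        }
    }
    res <- SpectrumSet(r, wl, colData(set))
    metadata(res) <- metadata(set)
    metadata(res)$cleaning <- list(clip_negative = clipNegative,
                                   smooth_span = smoothSpan,
                                   clipped = clipped)
    res
}
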
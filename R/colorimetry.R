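#' Spectral cut-off location R_mid
#'
#' The wavelength at which reflectance is halfway between its minimum and
#' maximum values within a search window (default 300-450 nm). With
#' \code{scope = "window"} (default) the min and max are taken inside the
#' window; \code{scope = "global"} takes them over the whole spectrum while
#' still locating the crossing inside the window. The half-height crossing is
#' the first upward crossing, located by linear interpolation between the
#' bracketing grid samples. Flat spectra (range below \code{tol}) or spectra
#' with no upward crossing in the window return \code{NA}.
#'
#' R_mid summarizes the position of the sigmoid cut-off that separates
#' UV-reflecting from UV-absorbing white coloration; it depends only on curve
#' shape, not on overall intensity.
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param window two-element numeric, the search window in nm.
#' @param scope where min/max reflectance are taken: within the window
#'   (default) or over the full spectrum.
#' @param tol minimum reflectance range (percent) below which R_mid is
#'   undefined.
#' @return named numeric vector of R_mid (nm), \code{NA} where undefined.
#' @seealso [classifyWhite()]
#' @export
rMid <- function(x, window = c(300, 450), scope = c("window", "global"),
                 tol = 1e-6) {
    stopifnot(is(x, "SpectrumSet"), length(window) == 2L, window[1] < window[2])
    scope <- match.arg(scope)
    wl <- wavelengths(x)
    if (window[1] < min(wl) || window[2] > max(wl))
        stop("R_mid window lies outside the wavelength grid")
    inWin <- wl >= window[1] & wl <= window[2]
    r <- reflectance(x)
    out <- vapply(seq_len(ncol(r)), function(j) {
        y <- r[, j]
        ref <- if (scope == "window") y[inWin] else y
        lo <- min(ref); hi <- max(ref)
        if (hi - lo < tol) return(NA_real_)
        h <- (lo + hi) / 2
        .firstUpwardCrossing(wl[inWin], y[inWin], h)
    }, numeric(1))
    names(out) <- colnames(r)
    out
}

# first index pair (i-1, i) with y[i-1] < h <= y[i]; linear interpolation
.firstUpwardCrossing <- function(wl, y, h) {
    if (y[1] >= h) return(wl[1])
    i <- which(y >= h & c(-Inf, y[-length(y)]) < h)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    wl[i - 1] + (h - y[i - 1]) / (y[i] - y[i - 1]) * (wl[i] - wl[i - 1])
}

#' Threshold classification of white spectra
#'
#' Spectra are called UV-reflecting white (\code{"UVplus_white"}) when R_mid
#' is at or below \code{lo} (default 345 nm) and UV-absorbing white
#' (\code{"UVminus_white"}) when R_mid is at or above \code{hi} (default
#' 365 nm); both boundaries are inclusive. R_mid strictly between the
#' thresholds, or undefined, yields \code{"ambiguous"}.
#'
#' @param r numeric vector of R_mid values (nm), possibly with \code{NA}.
#' @param lo,hi classification thresholds (nm), \code{lo < hi}.
#' @return factor with levels \code{UVplus_white}, \code{UVminus_white},
#'   \code{ambiguous}.
#' @export
classifyWhite <- function(r, lo = 345, hi = 365) {
    if (!(lo < hi)) stop("need lo < hi")
    lab <- rep("ambiguous", length(r))
    lab[!is.na(r) & r <= lo] <- "UVplus_white"
    lab[!is.na(r) & r >= hi] <- "UVminus_white"
    factor(lab, levels = c("UVplus_white", "UVminus_white", "ambiguous"))
}

#' Colorimetric summary variables
#'
#' \code{luminance()} is the plain sum of percent reflectance over all grid
#' samples (on the canonical 300-700 nm, 1 nm grid: 401 samples).
#' \code{uvChroma()} is the summed reflectance at wavelengths \eqn{\le} 400 nm
#' divided by the total sum, a unitless fraction in [0, 1]. \code{huePeak()}
#' is the wavelength of maximum reflectance; ties are broken by the shortest
#' wavelength and reported in the \code{"tied"} attribute.
#'
#' @param x a \linkS4class{SpectrumSet} on the canonical grid.
#' @return named numeric vector, one value per spectrum.
#' @export
luminance <- function(x) {
    stopifnot(is(x, "SpectrumSet"))
    colSums(reflectance(x))
}

#' @rdname luminance
#' @export
uvChroma <- function(x) {
    stopifnot(is(x, "SpectrumSet"))
    r <- reflectance(x)
    tot <- colSums(r)
    uv <- colSums(r[wavelengths(x) <= 400, , drop = FALSE])
    zero <- tot == 0
    if (any(zero)) {
        warning("zero total reflectance for: ",
                paste(colnames(r)[zero], collapse = ", "),
                "; UV chroma undefined (NA)")
        tot[zero] <- NA_real_
    }
    uv / tot
}

#' @rdname luminance
#' @export
huePeak <- function(x) {
    stopifnot(is(x, "SpectrumSet"))
    r <- reflectance(x)
    wl <- wavelengths(x)
    tied <- logical(ncol(r))
    out <- vapply(seq_len(ncol(r)), function(j) {
        i <- which(r[, j] == max(r[, j]))
        tied[j] <<- length(i) > 1L
        wl[min(i)]
    }, numeric(1))
    names(out) <- names(tied) <- colnames(r)
    attr(out, "tied") <- tied
    out
}

#' Per-spectrum feature table with white-type calls
#'
#' Computes luminance, UV chroma, hue peak and R_mid for every spectrum,
#' applies the threshold classification, and joins the specimen metadata.
#' The result is a tidy table suitable for export to external mixed-model
#' analyses.
#'
#' @inheritParams rMid
#' @inheritParams classifyWhite
#' @return a \code{DataFrame} keyed by (specimen_id, patch) with columns
#'   \code{luminance}, \code{c_uv}, \code{hue_peak}, \code{hue_tied},
#'   \code{r_mid}, \code{label} plus any metadata columns.
#' @export
colourFeatures <- function(x, window = c(300, 450),
                           scope = c("window", "global"),
                           lo = 345, hi = 365, tol = 1e-6) {
    stopifnot(is(x, "SpectrumSet"))
    hp <- huePeak(x)
    rm_ <- rMid(x, window = window, scope = scope, tol = tol)
    out <- DataFrame(colData(x),
                     luminance = luminance(x),
                     c_uv = uvChroma(x),
                     hue_peak = as.numeric(hp),
                     hue_tied = attr(hp, "tied"),
                     r_mid = rm_,
                     label = classifyWhite(rm_, lo = lo, hi = hi))
    out
}

#' Group mean and SEM spectra
#'
#' Pointwise mean and standard error of the mean per group (label by patch,
#' as in split-panel mean-spectra figures). With \code{normalize = TRUE} the
#' mean spectrum is divided by its own maximum after averaging (peak = 1);
#' the SEM is scaled by the same divisor, which is recorded in the
#' \code{divisor} column.
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param labels vector/factor of group labels, one per spectrum; \code{NA}
#'   labels are dropped with a warning.
#' @param byPatch also split groups by body patch (default TRUE when a patch
#'   column exists).
#' @param normalize peak-normalize each group mean after averaging.
#' @return long data.frame: \code{wavelength}, \code{label}, (\code{patch}),
#'   \code{mean}, \code{sem}, \code{n}, (\code{divisor}).
#' @export
groupMeanSpectra <- function(x, labels, byPatch = TRUE, normalize = FALSE) {
    stopifnot(is(x, "SpectrumSet"), length(labels) == ncol(x))
    labels <- as.character(labels)
    keep <- !is.na(labels)
    if (!all(keep)) {
        warning(sum(!keep), " spectra with NA label dropped")
        x <- x[, keep]; labels <- labels[keep]
    }
    if (!ncol(x)) stop("no spectra left to average (empty group)")
    patch <- if (byPatch && "patch" %in% colnames(colData(x)))
        as.character(colData(x)$patch) else rep(NA_character_, ncol(x))
    grp <- if (all(is.na(patch))) labels else paste(labels, patch, sep = "\r")
    r <- reflectance(x)
    wl <- wavelengths(x)
    pieces <- lapply(split(seq_len(ncol(x)), grp), function(idx) {
        m <- rowMeans(r[, idx, drop = FALSE])
        sem <- if (length(idx) > 1L)
            apply(r[, idx, drop = FALSE], 1, stats::sd) / sqrt(length(idx))
        else rep(0, nrow(r))
        div <- 1
        if (normalize) {
            div <- max(m)
            if (div <= 0) stop("cannot normalize a non-positive mean spectrum")
            m <- m / div; sem <- sem / div
        }
        data.frame(wavelength = wl,
                   label = labels[idx[1]],
                   patch = patch[idx[1]],
                   mean = m, sem = sem, n = length(idx),
                   divisor = div)
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    if (all(is.na(out$patch))) out$patch <- NULL
    if (!normalize) out$divisor <- NULL
    out
}

#' Frequency tables of white types
#'
#' Counts and within-stratum proportions of each white-type label, stratified
#' by locality, sex and patch (any subset), plus the four throat-by-belly
#' combination classes per sex for specimens measured on both patches (the
#' mixed-pattern table). Strata with no specimens are omitted with a warning.
#'
#' @param features output of [colourFeatures()] (needs \code{label},
#'   \code{specimen_id}, \code{patch} and the stratifying columns).
#' @param by character vector of stratifying columns, default
#'   \code{c("locality", "sex", "patch")}.
#' @param dropAmbiguous exclude ambiguous spectra from the proportions
#'   (default FALSE: they form their own class).
#' @return list with \code{strata} (long table: strata, label, n, proportion)
#'   and \code{patchCombos} (per-sex proportions of the four
#'   throat/belly combinations).
#' @export
tabulateFrequencies <- function(features,
                                by = c("locality", "sex", "patch"),
                                dropAmbiguous = FALSE) {
    df <- as.data.frame(features)
    stopifnot("label" %in% names(df))
    by <- intersect(by, names(df))
    if (dropAmbiguous) df <- df[df$label != "ambiguous", , drop = FALSE]
    df$label <- droplevels(factor(df$label))
    if (!nrow(df)) stop("no spectra to tabulate")

    if (length(by)) {
        stratum <- interaction(df[by], drop = FALSE, sep = ":")
        empty <- setdiff(levels(stratum), unique(as.character(stratum)))
        if (length(empty))
            warning("empty strata omitted: ", paste(empty, collapse = ", "))
        tab <- as.data.frame(table(stratum = droplevels(stratum),
                                   label = df$label))
        names(tab)[3] <- "n"
        tot <- stats::ave(tab$n, tab$stratum, FUN = sum)
        tab$proportion <- ifelse(tot > 0, tab$n / tot, NA_real_)
        keyCols <- do.call(rbind, strsplit(as.character(tab$stratum),
                                           ":", fixed = TRUE))
        colnames(keyCols) <- by
        strata <- cbind(as.data.frame(keyCols), tab[c("label", "n",
                                                      "proportion")])
    } else {
        tab <- as.data.frame(table(label = df$label))
        names(tab)[2] <- "n"
        tab$proportion <- tab$n / sum(tab$n)
        strata <- tab
    }

    patchCombos <- NULL
    if (all(c("specimen_id", "patch", "sex") %in% names(df)) &&
        all(c("throat", "belly") %in% df$patch)) {
        th <- df[df$patch == "throat", c("specimen_id", "sex", "label")]
        be <- df[df$patch == "belly", c("specimen_id", "label")]
        m <- merge(th, be, by = "specimen_id",
                   suffixes = c("_throat", "_belly"))
        m <- m[m$label_throat %in% c("UVplus_white", "UVminus_white") &
               m$label_belly %in% c("UVplus_white", "UVminus_white"), ]
        if (nrow(m)) {
            m$combo <- factor(
                paste(sub("_white", "", m$label_throat), "throat /",
                      sub("_white", "", m$label_belly), "belly"),
                levels = c("UVplus throat / UVplus belly",
                           "UVminus throat / UVminus belly",
                           "UVminus throat / UVplus belly",
                           "UVplus throat / UVminus belly"))
            pc <- as.data.frame(table(sex = m$sex, combo = m$combo))
            names(pc)[3] <- "n"
            tot <- stats::ave(pc$n, pc$sex, FUN = sum)
            pc$proportion <- ifelse(tot > 0, pc$n / tot, NA_real_)
            patchCombos <- pc
        }
    }
    list(strata = strata, patchCombos = patchCombos)
}
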
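#' A1 visual-pigment absorbance template
#'
#' Govardovskii-style alpha-band template for an A1 (retinal-based) visual
#' pigment, parameterized only by the peak absorbance wavelength
#' \code{lmax}, evaluated on \code{wavelength} and scaled to a maximum of 1.
#'
#' @param lmax peak sensitivity (nm), must lie within the grid.
#' @param wavelength numeric wavelength grid (nm).
#' @return numeric sensitivity vector, peak value 1.
#' @export
pigmentTemplate <- function(lmax, wavelength = canonicalGrid()) {
    if (lmax < min(wavelength) || lmax > max(wavelength))
        stop("lmax must lie within the wavelength grid")
    x <- lmax / wavelength
    a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
    s <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
              exp(-14.9 * (1.104 - x)) + 0.674)
    s / max(s)
}

#' Tetrachromatic visual system
#'
#' Cone spectral sensitivities on a wavelength grid, relative cone
#' abundances, a reference-cone Weber fraction, and an illuminant. The
#' shipped defaults describe a diurnal lacertid lizard eye: four single-cone
#' classes (UVS, SWS, MWS, LWS) built from A1 pigment templates with
#' literature-derived peak sensitivities (367, 456, 497, 562 nm), a cone
#' abundance ratio of 1:1:1:4 and a Weber fraction of 0.05 referenced to the
#' LWS cone. The default illuminant is flat ("ideal"); a measured illuminant
#' may be supplied. An optional ocular-media transmission vector multiplies
#' all sensitivities.
#'
#' @slot coneNames ordered cone labels.
#' @slot wavelength grid (nm).
#' @slot sensitivities matrix (wavelength x cone), non-negative.
#' @slot abundances relative cone abundances n_i, positive.
#' @slot weberRef Weber fraction of the reference cone, in (0, 1).
#' @slot referenceCone which cone the Weber fraction refers to.
#' @slot illuminant irradiance spectrum over the grid.
#' @name VisualSystem-class
#' @exportClass VisualSystem
setClass("VisualSystem",
         representation(coneNames = "character",
                        wavelength = "numeric",
                        sensitivities = "matrix",
                        abundances = "numeric",
                        weberRef = "numeric",
                        referenceCone = "character",
                        illuminant = "numeric"))

setValidity("VisualSystem", function(object) {
    msg <- character(0)
    s <- object@sensitivities
    if (nrow(s) != length(object@wavelength))
        msg <- c(msg, "sensitivities rows must match the wavelength grid")
    if (ncol(s) != length(object@coneNames))
        msg <- c(msg, "one sensitivity column per cone is required")
    if (any(s < 0) || any(colSums(s) <= 0))
        msg <- c(msg, "sensitivities must be >= 0 with positive column sums")
    if (length(object@abundances) != length(object@coneNames) ||
        any(object@abundances <= 0))
        msg <- c(msg, "abundances must be positive, one per cone")
    if (object@weberRef <= 0 || object@weberRef >= 1)
        msg <- c(msg, "weberRef must be in (0, 1)")
    if (!object@referenceCone %in% object@coneNames)
        msg <- c(msg, "referenceCone must be one of coneNames")
    if (length(object@illuminant) != length(object@wavelength) ||
        any(object@illuminant < 0))
        msg <- c(msg, "illuminant must be non-negative over the grid")
    if (length(msg)) msg else TRUE
})

#' Construct a VisualSystem
#'
#' @param lmax named numeric of cone peak sensitivities (nm), in cone order.
#' @param abundances relative cone abundances, same order.
#' @param weberRef Weber fraction of the reference cone.
#' @param referenceCone name of the reference cone.
#' @param wavelength wavelength grid (nm).
#' @param illuminant irradiance over the grid; NULL (default) = flat "ideal".
#' @param sensitivities optional matrix of measured sensitivities
#'   (wavelength x cone); if NULL, built from A1 templates at \code{lmax}.
#' @param ocularTransmission optional transmission vector over the grid
#'   multiplying all sensitivities.
#' @return a \linkS4class{VisualSystem}.
#' @examples
#' vs <- visualSystem()
#' receptorNoise(vs)
#' @export
visualSystem <- function(lmax = c(UVS = 367, SWS = 456, MWS = 497,
                                  LWS = 562),
                         abundances = c(1, 1, 1, 4),
                         weberRef = 0.05,
                         referenceCone = "LWS",
                         wavelength = canonicalGrid(),
                         illuminant = NULL,
                         sensitivities = NULL,
                         ocularTransmission = NULL) {
    coneNames <- names(lmax)
    if (is.null(coneNames))
        coneNames <- paste0("cone", seq_along(lmax))
    if (is.null(sensitivities)) {
        sensitivities <- vapply(lmax, pigmentTemplate,
                                numeric(length(wavelength)),
                                wavelength = wavelength)
    }
    sensitivities <- as.matrix(sensitivities)
    colnames(sensitivities) <- coneNames
    if (!is.null(ocularTransmission))
        sensitivities <- sensitivities * as.numeric(ocularTransmission)
    if (is.null(illuminant)) illuminant <- rep(1, length(wavelength))
    new("VisualSystem", coneNames = coneNames,
        wavelength = as.numeric(wavelength),
        sensitivities = sensitivities,
        abundances = unname(as.numeric(abundances)),
        weberRef = weberRef, referenceCone = referenceCone,
        illuminant = as.numeric(illuminant))
}

setMethod("show", "VisualSystem", function(object) {
    cat(sprintf("VisualSystem: %d cones (%s) on %g-%g nm\n",
                length(object@coneNames),
                paste(object@coneNames, collapse = ", "),
                min(object@wavelength), max(object@wavelength)))
    cat("  abundances:", paste(object@abundances, collapse = ":"),
        " Weber:", object@weberRef, "on", object@referenceCone, "\n")
    flat <- length(unique(object@illuminant)) == 1L
    cat("  illuminant:", if (flat) "flat (ideal)" else "supplied", "\n")
})

#' Read a visual-system configuration file
#'
#' YAML with fields \code{cones} (name: lmax pairs, in order),
#' \code{abundances}, \code{weber_ref}, \code{reference_cone} and
#' \code{illuminant} ("ideal" or a numeric vector over the grid).
#'
#' @param path YAML file path.
#' @param wavelength wavelength grid to build the system on.
#' @return a \linkS4class{VisualSystem}.
#' @export
readVisualSystem <- function(path, wavelength = canonicalGrid()) {
    cfg <- yaml::read_yaml(path)
    lmax <- unlist(cfg$cones)
    ill <- cfg$illuminant
    if (is.null(ill) || identical(ill, "ideal")) ill <- NULL
    else ill <- as.numeric(ill)
    visualSystem(lmax = lmax,
                 abundances = as.numeric(cfg$abundances),
                 weberRef = as.numeric(cfg$weber_ref),
                 referenceCone = cfg$reference_cone,
                 wavelength = wavelength,
                 illuminant = ill)
}

#' Receptor noise per cone channel
#'
#' Channel noise scaled from the reference-cone Weber fraction by relative
#' cone abundance: \eqn{\omega_i = w \sqrt{n_{ref} / n_i}}. With the default
#' lacertid system (abundances 1:1:1:4, Weber 0.05 on LWS) this gives
#' (0.1, 0.1, 0.1, 0.05). Noise is intensity-independent ("neural"), the
#' standard assumption for bright-light discrimination with a stated Weber
#' fraction.
#'
#' @param vs a \linkS4class{VisualSystem}.
#' @return named numeric vector of Weber fractions, one per cone.
#' @export
receptorNoise <- function(vs) {
    stopifnot(is(vs, "VisualSystem"))
    nref <- vs@abundances[match(vs@referenceCone, vs@coneNames)]
    w <- vs@weberRef * sqrt(nref / vs@abundances)
    names(w) <- vs@coneNames
    w
}

#' Quantum catches under von Kries adaptation
#'
#' Raw catches \eqn{Q_i = \sum_\lambda R(\lambda) S_i(\lambda) I(\lambda)}
#' (reflectance taken as a proportion, i.e. percent / 100), normalized
#' against the catch of a perfect (100%) reflector under the same illuminant
#' (von Kries chromatic adaptation), and log-transformed:
#' \eqn{f_i = \ln q_i}. A perfect reflector therefore has \eqn{q_i = 1} and
#' \eqn{f_i = 0} in every channel regardless of the illuminant. Spectra with
#' a non-positive catch in any channel are flagged (log-catch undefined) and
#' excluded from downstream distances.
#'
#' @param x a \linkS4class{SpectrumSet} on the same grid as \code{vs}.
#' @param vs a \linkS4class{VisualSystem}.
#' @return a \linkS4class{ConeCatchSet}.
#' @export
quantumCatch <- function(x, vs) {
    stopifnot(is(x, "SpectrumSet"), is(vs, "VisualSystem"))
    if (!isTRUE(all.equal(wavelengths(x), vs@wavelength)))
        stop("spectra and visual system are on different wavelength grids; ",
             "resample first")
    si <- vs@sensitivities * vs@illuminant
    q <- t(reflectance(x) / 100) %*% si       # raw catches, spectra x cones
    k <- colSums(si)                          # perfect-reflector catches
    qn <- sweep(q, 2, k, "/")
    flagged <- apply(qn, 1, function(z) any(z <= 0))
    f <- log(qn)
    f[flagged, ] <- NA_real_
    if (any(flagged))
        warning("zero catch in >=1 channel for: ",
                paste(rownames(q)[flagged], collapse = ", "),
                "; log-catch undefined, spectra flagged")
    new("ConeCatchSet", catches = q, normCatches = qn, logCatches = f,
        flagged = flagged, coneNames = vs@coneNames)
}

#' ConeCatchSet: per-spectrum cone stimulation
#'
#' Raw catches Q (arbitrary units), von Kries-normalized catches q, and
#' log-catches f = ln(q), one row per spectrum, one column per cone.
#' \code{flagged} marks spectra with a non-positive catch.
#'
#' @slot catches,normCatches,logCatches numeric matrices (spectra x cones).
#' @slot flagged logical, per spectrum.
#' @slot coneNames cone labels.
#' @name ConeCatchSet-class
#' @exportClass ConeCatchSet
setClass("ConeCatchSet",
         representation(catches = "matrix", normCatches = "matrix",
                        logCatches = "matrix", flagged = "logical",
                        coneNames = "character"))

setMethod("show", "ConeCatchSet", function(object) {
    cat(sprintf("ConeCatchSet: %d spectra x %d cones (%s); %d flagged\n",
                nrow(object@catches), length(object@coneNames),
                paste(object@coneNames, collapse = ", "),
                sum(object@flagged)))
})

#' @describeIn ConeCatchSet-class log-catch matrix f = ln(q)
#' @param x a ConeCatchSet
#' @export
logCatches <- function(x) x@logCatches

#' @describeIn ConeCatchSet-class von Kries-normalized catch matrix q
#' @export
normCatches <- function(x) x@normCatches

#' Receptor-noise-limited chromatic distance
#'
#' Discriminability of two stimuli in just noticeable differences (JND)
#' under the receptor-noise-limited model. For a tetrachromat the closed
#' form is
#' \deqn{\Delta S^2 = \frac{\sum_{i<j} (\omega_k \omega_l)^2
#'   (\Delta f_j' - \Delta f_i')^2}{\sum_{\mathrm{triples}}
#'   (\omega_i \omega_j \omega_k)^2}}
#' over the log-catch differences \eqn{\Delta f_i = f_{A,i} - f_{B,i}}
#' (see the package vignette for the expanded form). Other cone numbers are
#' routed through the equivalent weighted-least-squares formulation:
#' \eqn{\Delta S^2 = \min_x \sum_i (\Delta f_i - x)^2 / \omega_i^2}.
#' Uniform shifts of \eqn{\Delta f} (pure intensity changes) give 0 JND.
#'
#' @param fA,fB numeric log-catch vectors, one entry per cone.
#' @param noise per-cone Weber fractions, e.g. from [receptorNoise()].
#' @return chromatic distance in JND (non-negative scalar).
#' @export
chromaticDistance <- function(fA, fB, noise) {
    df <- fA - fB
    if (any(!is.finite(df))) stop("log-catch differences must be finite")
    if (length(df) == 4L) .deltaS4(matrix(df, 1L, 4L), noise)
    else .deltaSGLS(matrix(df, 1L), noise)
}

# tetrachromatic closed form, vectorized over rows of dF
.deltaS4 <- function(dF, w) {
    w <- unname(w)
    d1 <- dF[, 1]; d2 <- dF[, 2]; d3 <- dF[, 3]; d4 <- dF[, 4]
    num <- (w[1] * w[2])^2 * (d4 - d3)^2 +
           (w[1] * w[3])^2 * (d4 - d2)^2 +
           (w[1] * w[4])^2 * (d3 - d2)^2 +
           (w[2] * w[3])^2 * (d4 - d1)^2 +
           (w[2] * w[4])^2 * (d3 - d1)^2 +
           (w[3] * w[4])^2 * (d2 - d1)^2
    den <- (w[1] * w[2] * w[3])^2 + (w[1] * w[2] * w[4])^2 +
           (w[1] * w[3] * w[4])^2 + (w[2] * w[3] * w[4])^2
    sqrt(num / den)
}

# n-cone weighted-least-squares form, vectorized over rows of dF
.deltaSGLS <- function(dF, w) {
    w <- unname(w)
    iw2 <- 1 / w^2
    xstar <- (dF %*% iw2) / sum(iw2)
    sqrt(rowSums(sweep(dF - as.vector(xstar) %o% rep(1, length(w)),
                       2, w, "/")^2))
}

#' Achromatic (luminance-channel) distance
#'
#' \eqn{\Delta L = |\Delta f_{ref}| / \omega_{ref}} using the reference
#' (long-wavelength) channel's log-catch difference and Weber fraction.
#'
#' @inheritParams chromaticDistance
#' @param vs a \linkS4class{VisualSystem}.
#' @return achromatic distance in JND.
#' @export
achromaticDistance <- function(fA, fB, vs) {
    stopifnot(is(vs, "VisualSystem"))
    i <- match(vs@referenceCone, vs@coneNames)
    abs(fA[i] - fB[i]) / vs@weberRef
}

#' Pairwise JND distance matrices
#'
#' Chromatic (and optionally achromatic) just-noticeable-difference matrices
#' over all spectra in a set. Flagged spectra (non-positive catch) are
#' excluded with a warning. Matrices are symmetric with zero diagonal.
#'
#' @param x a \linkS4class{SpectrumSet} or \linkS4class{ConeCatchSet}.
#' @param vs a \linkS4class{VisualSystem}.
#' @param achromatic also return the achromatic matrix (default TRUE).
#' @return list with elements \code{chromatic} (matrix, JND),
#'   \code{achromatic} (matrix or NULL) and \code{ids}.
#' @export
pairwiseJND <- function(x, vs, achromatic = TRUE) {
    cc <- if (is(x, "ConeCatchSet")) x else quantumCatch(x, vs)
    f <- cc@logCatches
    keep <- !cc@flagged
    if (any(!keep))
        warning(sum(!keep), " flagged spectra excluded from distance matrix")
    f <- f[keep, , drop = FALSE]
    w <- receptorNoise(vs)
    n <- nrow(f)
    nc <- ncol(f)
    d <- lapply(seq_len(nc), function(i) outer(f[, i], f[, i], "-"))
    if (nc == 4L) {
        num <- (w[1] * w[2])^2 * (d[[4]] - d[[3]])^2 +
               (w[1] * w[3])^2 * (d[[4]] - d[[2]])^2 +
               (w[1] * w[4])^2 * (d[[3]] - d[[2]])^2 +
               (w[2] * w[3])^2 * (d[[4]] - d[[1]])^2 +
               (w[2] * w[4])^2 * (d[[3]] - d[[1]])^2 +
               (w[3] * w[4])^2 * (d[[2]] - d[[1]])^2
        den <- (w[1] * w[2] * w[3])^2 + (w[1] * w[2] * w[4])^2 +
               (w[1] * w[3] * w[4])^2 + (w[2] * w[3] * w[4])^2
        chrom <- sqrt(num / den)
    } else {
        iw2 <- 1 / w^2
        xs <- Reduce(`+`, Map(function(dd, z) dd * z, d, iw2)) / sum(iw2)
        chrom <- sqrt(Reduce(`+`, Map(function(dd, ww) ((dd - xs) / ww)^2,
                                      d, w)))
    }
    diag(chrom) <- 0
    dimnames(chrom) <- list(rownames(f), rownames(f))
    achro <- NULL
    if (achromatic) {
        i <- match(vs@referenceCone, vs@coneNames)
        achro <- abs(d[[i]]) / vs@weberRef
        diag(achro) <- 0
        dimnames(achro) <- dimnames(chrom)
    }
    list(chromatic = chrom, achromatic = achro, ids = rownames(f))
}
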
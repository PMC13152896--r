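#' Configuration for a synthetic spectral cohort
#'
#' The generator emulates the statistical structure a ventral-colour
#' polymorphism analysis assumes: sigmoid (long-pass) reflectance curves
#' whose midpoint wavelength is bimodally distributed across two white
#' classes, long-pass yellow/orange morphs with midpoints well beyond the
#' near-UV, locality-varying class frequencies, sex structure, optional
#' throat/belly class discordance, and measurement noise (a per-spectrum
#' lognormal intensity factor plus per-wavelength additive noise).
#'
#' Default class midpoints: UV-reflecting white N(330, 5), UV-absorbing
#' white N(390, 5), yellow N(460, 8), orange N(520, 10) nm — the two white
#' means sit symmetric about the 345-365 nm classification gap so that, at
#' default noise, class membership is unambiguous and the midpoint
#' distribution is clearly bimodal.
#'
#' @param n number of specimens (each yields a throat and a belly spectrum).
#' @param classMix named proportions over
#'   \code{UVplus_white, UVminus_white, yellow, orange}; must sum to 1.
#' @param localities optional data.frame with columns \code{locality},
#'   \code{weight} and one frequency column per class (each row summing
#'   to 1); NULL = a single locality with \code{classMix}.
#' @param sexRatio proportion of males.
#' @param cutoff data.frame with columns \code{class}, \code{mean},
#'   \code{sd}: the per-class sigmoid midpoint distribution (nm).
#' @param slope sigmoid slope scale s (nm).
#' @param base,amplitude baseline and amplitude reflectance (percent).
#' @param multSD sdlog of the per-spectrum lognormal intensity factor.
#' @param addSD SD of per-wavelength additive Gaussian noise (percent).
#' @param discordance probability that a white specimen's belly class
#'   differs from its throat class.
#' @param grid wavelength grid.
#' @param seed integer seed (mandatory for [simulateCohort()]).
#' @return a list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(n = 400,
                         classMix = c(UVplus_white = 0.5,
                                      UVminus_white = 0.5,
                                      yellow = 0, orange = 0),
                         localities = NULL,
                         sexRatio = 0.5,
                         cutoff = data.frame(
                             class = c("UVplus_white", "UVminus_white",
                                       "yellow", "orange"),
                             mean = c(330, 390, 460, 520),
                             sd = c(5, 5, 8, 10)),
                         slope = 10, base = 5, amplitude = 50,
                         multSD = 0.05, addSD = 0.5,
                         discordance = 0.1,
                         grid = canonicalGrid(),
                         seed = NULL) {
    classes <- c("UVplus_white", "UVminus_white", "yellow", "orange")
    classMix <- classMix[classes]
    classMix[is.na(classMix)] <- 0
    names(classMix) <- classes
    if (abs(sum(classMix) - 1) > 1e-8)
        stop("classMix must sum to 1")
    if (is.null(localities)) {
        localities <- data.frame(locality = "L01", weight = 1)
        for (cl in classes) localities[[cl]] <- unname(classMix[cl])
    }
    locMix <- as.matrix(localities[classes])
    if (any(abs(rowSums(locMix) - 1) > 1e-8))
        stop("per-locality class frequencies must each sum to 1")
    if (any(cutoff$sd < 0) || amplitude <= 0 || multSD < 0 || addSD < 0)
        stop("SDs must be >= 0 and amplitude > 0")
    structure(list(n = as.integer(n), classMix = classMix,
                   localities = localities, sexRatio = sexRatio,
                   cutoff = cutoff, slope = slope, base = base,
                   amplitude = amplitude, multSD = multSD, addSD = addSD,
                   discordance = discordance, grid = as.numeric(grid),
                   seed = seed),
              class = "CohortConfig")
}

# noise-free long-pass sigmoid template (percent reflectance)
.sigmoidSpectrum <- function(wl, base, amplitude, lambda0, slope) {
    base + amplitude / (1 + exp(-(wl - lambda0) / slope))
}

#' Simulate one reflectance spectrum
#'
#' \eqn{R(\lambda) = base + amplitude / (1 + e^{-(\lambda - \lambda_0)/s})},
#' multiplied by a lognormal per-spectrum intensity factor, plus additive
#' per-wavelength Gaussian noise, floored at 0. \code{lambda0} is drawn from
#' the class's midpoint distribution unless supplied. Uses the current RNG
#' state; seed externally (or via [simulateCohort()]) for reproducibility.
#'
#' @param class one of \code{UVplus_white, UVminus_white, yellow, orange}.
#' @param config a [cohortConfig()].
#' @param lambda0 optional fixed sigmoid midpoint (nm).
#' @param noise apply measurement noise (default TRUE).
#' @return numeric vector of percent reflectance over \code{config$grid}.
#' @export
simulateSpectrum <- function(class, config = cohortConfig(), lambda0 = NULL,
                             noise = TRUE) {
    stopifnot(inherits(config, "CohortConfig"))
    row <- config$cutoff[config$cutoff$class == class, ]
    if (!nrow(row)) stop("unknown class: ", class)
    if (is.null(lambda0))
        lambda0 <- stats::rnorm(1, row$mean, row$sd)
    y <- .sigmoidSpectrum(config$grid, config$base, config$amplitude,
                          lambda0, config$slope)
    if (noise) {
        y <- y * stats::rlnorm(1, 0, config$multSD) +
            stats::rnorm(length(y), 0, config$addSD)
    }
    pmax(y, 0)
}

#' Simulate a spectral cohort
#'
#' Draws specimens (locality by weight, sex by ratio, class by the
#' locality's class frequencies), then generates a throat and a belly
#' spectrum per specimen; with probability \code{discordance} a white
#' specimen's belly is the other white class (mixed ventral pattern). The
#' true generating class of every spectrum is recorded in
#' \code{colData()$true_class}, alongside the human-visible morph
#' (\code{human_morph}: both whites read as "white") and the drawn sigmoid
#' midpoint (\code{lambda0}). Output is byte-identical for a given seed.
#'
#' @param config a [cohortConfig()] with a non-NULL integer \code{seed}.
#' @return a \linkS4class{SpectrumSet} with the truth columns in its
#'   metadata.
#' @examples
#' set <- simulateCohort(cohortConfig(n = 20, seed = 1))
#' table(colData(set)$true_class)
#' @export
simulateCohort <- function(config = cohortConfig(seed = 1)) {
    stopifnot(inherits(config, "CohortConfig"))
    if (is.null(config$seed)) stop("config$seed is required")
    set.seed(config$seed)
    n <- config$n
    classes <- c("UVplus_white", "UVminus_white", "yellow", "orange")
    loc <- config$localities
    locIdx <- sample.int(nrow(loc), n, replace = TRUE, prob = loc$weight)
    sex <- ifelse(stats::runif(n) < config$sexRatio, "male", "female")
    throatClass <- vapply(locIdx, function(i)
        sample(classes, 1, prob = as.numeric(loc[i, classes])), character(1))
    bellyClass <- throatClass
    white <- throatClass %in% classes[1:2]
    flip <- white & stats::runif(n) < config$discordance
    bellyClass[flip] <- ifelse(throatClass[flip] == "UVplus_white",
                               "UVminus_white", "UVplus_white")
    ids <- sprintf("S%04d", seq_len(n))
    k <- length(config$grid)
    refl <- matrix(0, k, 2L * n)
    md <- vector("list", 2L * n)
    col <- 0L
    for (i in seq_len(n)) {
        for (patch in c("throat", "belly")) {
            cl <- if (patch == "throat") throatClass[i] else bellyClass[i]
            row <- config$cutoff[config$cutoff$class == cl, ]
            l0 <- stats::rnorm(1, row$mean, row$sd)
            col <- col + 1L
            refl[, col] <- simulateSpectrum(cl, config, lambda0 = l0)
            md[[col]] <- data.frame(
                specimen_id = ids[i], patch = patch, sex = sex[i],
                locality = loc$locality[locIdx[i]],
                human_morph = switch(cl, UVplus_white = "white",
                                     UVminus_white = "white", cl),
                true_class = cl, lambda0 = l0)
        }
    }
    SpectrumSet(refl, config$grid, do.call(rbind, md))
}
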
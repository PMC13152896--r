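#' Bootstrapped between-group centroid colour distance
#'
#' Point estimate: the chromatic JND between the two groups' colour-space
#' centroids, each centroid being the per-cone geometric mean of the
#' normalized catches (equivalently, the arithmetic mean of the log-catches).
#' Confidence interval: percentile bootstrap, resampling specimens with
#' replacement within each group and recomputing the centroid distance.
#'
#' @param fA,fB log-catch matrices (spectra x cones) of the two groups, e.g.
#'   \code{logCatches(quantumCatch(x, vs))} split by label. Rows with
#'   non-finite entries are dropped.
#' @param noise per-cone Weber fractions from [receptorNoise()].
#' @param nBoot number of bootstrap resamples (default 1000).
#' @param seed integer seed; required, recorded in the result.
#' @param conf confidence level (default 0.95).
#' @return a \linkS4class{BootDistResult}.
#' @export
bootColDist <- function(fA, fB, noise, nBoot = 1000, seed, conf = 0.95) {
    fA <- .finiteRows(as.matrix(fA)); fB <- .finiteRows(as.matrix(fB))
    if (!nrow(fA) || !nrow(fB)) stop("both groups must be non-empty")
    if (missing(seed)) stop("a seed is required for the bootstrap")
    dist1 <- function(mA, mB) {
        df <- matrix(mA - mB, 1L)
        if (ncol(df) == 4L) .deltaS4(df, noise) else .deltaSGLS(df, noise)
    }
    est <- dist1(colMeans(fA), colMeans(fB))
    set.seed(seed)
    mA <- .bootMeans(fA, nBoot)
    mB <- .bootMeans(fB, nBoot)
    dF <- mA - mB
    boots <- if (ncol(dF) == 4L) .deltaS4(dF, noise)
             else .deltaSGLS(dF, noise)
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
    new("BootDistResult", pointEstimate = unname(est), ciLow = ci[1],
        ciHigh = ci[2], nBoot = as.integer(nBoot), seed = as.integer(seed),
        conf = conf, bootDist = as.numeric(boots))
}

.finiteRows <- function(m) m[apply(is.finite(m), 1, all), , drop = FALSE]

# nBoot bootstrap group means of the rows of f (n x k) -> nBoot x k
.bootMeans <- function(f, nBoot) {
    n <- nrow(f)
    idx <- sample.int(n, n * nBoot, replace = TRUE)
    vapply(seq_len(ncol(f)),
           function(j) colMeans(matrix(f[idx, j], n, nBoot)),
           numeric(nBoot))
}

#' BootDistResult
#'
#' Result of [bootColDist()]: centroid chromatic distance (JND) with a
#' percentile bootstrap confidence interval.
#'
#' @slot pointEstimate,ciLow,ciHigh JND.
#' @slot nBoot,seed integers.
#' @slot conf confidence level.
#' @slot bootDist the bootstrap distribution.
#' @name BootDistResult-class
#' @exportClass BootDistResult
setClass("BootDistResult",
         representation(pointEstimate = "numeric", ciLow = "numeric",
                        ciHigh = "numeric", nBoot = "integer",
                        seed = "integer", conf = "numeric",
                        bootDist = "numeric"))

setValidity("BootDistResult", function(object) {
    if (isTRUE(object@ciLow > object@ciHigh)) "ciLow must be <= ciHigh"
    else if (isTRUE(any(c(object@pointEstimate, object@ciLow) < 0)))
        "distances must be non-negative"
    else TRUE
})

setMethod("show", "BootDistResult", function(object) {
    cat(sprintf(
        "Centroid chromatic distance: %.3f JND (%.0f%% CI %.3f-%.3f; %d bootstrap resamples, seed %d)\n",
        object@pointEstimate, 100 * object@conf, object@ciLow,
        object@ciHigh, object@nBoot, object@seed))
})

#' Distance-based PERMANOVA (one-way)
#'
#' Permutational multivariate analysis of variance on a distance matrix,
#' partitioning squared interpoint distances:
#' \eqn{SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2},
#' \eqn{SS_{within} = \sum_g \frac{1}{n_g} \sum_{i<j \in g} d_{ij}^2},
#' \eqn{SS_{between} = SS_{total} - SS_{within}}, and
#' pseudo-\eqn{F = \frac{SS_{between}/(a-1)}{SS_{within}/(N-a)}}.
#' Significance is assessed by permuting group labels; the p-value uses the
#' \eqn{(1 + x)/(1 + n_{perm})} estimator, so its resolution (and floor) is
#' \eqn{1/(n_{perm}+1)}. On a Euclidean distance matrix from univariate data
#' the pseudo-F equals the classical one-way ANOVA F.
#'
#' @param D symmetric distance matrix (or \code{dist}) with zero diagonal.
#' @param labels group assignment, one per row of \code{D}; every group needs
#'   at least 2 members.
#' @param nPerm number of label permutations (default 9999).
#' @param seed integer seed; required.
#' @return a \linkS4class{PermanovaResult}. An all-zero \code{D}
#'   (\eqn{SS_{total} = 0}) yields a degenerate result with \code{NA}
#'   statistics rather than a division by zero.
#' @export
permanovaDist <- function(D, labels, nPerm = 9999, seed) {
    if (inherits(D, "dist")) D <- as.matrix(D)
    stopifnot(is.matrix(D), nrow(D) == ncol(D))
    if (max(abs(D - t(D))) > 1e-8 || any(D < 0) || any(diag(D) != 0))
        stop("D must be symmetric and non-negative with zero diagonal")
    labels <- factor(labels)
    n <- nrow(D)
    if (length(labels) != n) stop("one label per row of D is required")
    if (nlevels(labels) < 2L) stop("at least 2 groups are required")
    if (any(table(labels) < 2L)) stop("singleton group(s) not allowed")
    if (missing(seed)) stop("a seed is required for the permutation test")
    a <- nlevels(labels)
    D2 <- D^2
    ssTot <- sum(D2) / (2 * n)
    dfB <- a - 1L
    dfW <- n - a
    if (ssTot <= .Machine$double.eps * n^2) {
        return(new("PermanovaResult", pseudoF = NA_real_,
                   pValue = NA_real_, nPerm = as.integer(nPerm),
                   dfBetween = dfB, dfWithin = dfW,
                   ssBetween = 0, ssWithin = 0, ssTotal = 0,
                   seed = as.integer(seed), degenerate = TRUE))
    }
    grpRows <- split(seq_len(n), labels)
    ssW <- .ssWithin(D2, grpRows)
    Fobs <- ((ssTot - ssW) / dfB) / (ssW / dfW)
    set.seed(seed)
    sizes <- lengths(grpRows)
    count <- 0L
    for (k in seq_len(nPerm)) {
        perm <- sample.int(n)
        idx <- split(perm, rep.int(seq_along(sizes), sizes))
        ssWp <- .ssWithin(D2, idx)
        Fp <- ((ssTot - ssWp) / dfB) / (ssWp / dfW)
        if (Fp >= Fobs) count <- count + 1L
    }
    p <- (1 + count) / (1 + nPerm)
    new("PermanovaResult", pseudoF = Fobs, pValue = p,
        nPerm = as.integer(nPerm), dfBetween = dfB, dfWithin = dfW,
        ssBetween = ssTot - ssW, ssWithin = ssW, ssTotal = ssTot,
        seed = as.integer(seed), degenerate = FALSE)
}

.ssWithin <- function(D2, idxList) {
    sum(vapply(idxList,
               function(i) sum(D2[i, i]) / (2 * length(i)),
               numeric(1)))
}

#' PermanovaResult
#'
#' @slot pseudoF,pValue test statistic and permutation p-value.
#' @slot nPerm,dfBetween,dfWithin,seed integers.
#' @slot ssBetween,ssWithin,ssTotal sums of squares.
#' @slot degenerate TRUE when all distances were zero.
#' @name PermanovaResult-class
#' @exportClass PermanovaResult
setClass("PermanovaResult",
         representation(pseudoF = "numeric", pValue = "numeric",
                        nPerm = "integer", dfBetween = "integer",
                        dfWithin = "integer", ssBetween = "numeric",
                        ssWithin = "numeric", ssTotal = "numeric",
                        seed = "integer", degenerate = "logical"))

setMethod("show", "PermanovaResult", function(object) {
    if (object@degenerate) {
        cat("PERMANOVA: degenerate (all interpoint distances zero)\n")
    } else {
        cat(sprintf(
            "PERMANOVA: pseudo-F(%d,%d) = %.2f, p = %.4g (%d permutations, seed %d)\n",
            object@dfBetween, object@dfWithin, object@pseudoF,
            object@pValue, object@nPerm, object@seed))
    }
})

#' Perceptual verdict from a chromatic distance
#'
#' Interprets a JND on the standard discriminability bands: above 3 JND
#' colours are easily discriminable; between 1 and 3 JND they are
#' discriminable only under good illumination; below 1 JND they are below
#' the discrimination threshold.
#'
#' @param jnd chromatic distance (JND).
#' @return character verdict.
#' @export
jndVerdict <- function(jnd) {
    ifelse(jnd > 3, "easily discriminable",
           ifelse(jnd >= 1, "discriminable only under good illumination",
                  "below discrimination threshold"))
}

#' Two-step discriminability report
#'
#' The combined statistical-and-perceptual comparison of the two white
#' classes: (1) a distance-based PERMANOVA on the pairwise chromatic JND
#' matrix answers whether the classes differ statistically; (2) the
#' bootstrapped centroid distance with its confidence interval, read against
#' the JND discriminability bands, answers whether the difference is
#' perceptually meaningful. Ambiguous spectra are excluded. With fewer than
#' two classes present the report declines the two-class statistics and
#' explains why.
#'
#' @param catches a \linkS4class{ConeCatchSet} for all spectra.
#' @param labels factor of white-type calls aligned with the catch rows
#'   (levels as from [classifyWhite()]).
#' @param vs the \linkS4class{VisualSystem} used for the catches.
#' @param D optional precomputed chromatic distance matrix over the
#'   unambiguous spectra; computed from the catches when NULL.
#' @param nBoot,nPerm resampling sizes.
#' @param seed integer seed; required.
#' @return a \linkS4class{TwoStepReport}.
#' @export
twoStepReport <- function(catches, labels, vs, D = NULL,
                          nBoot = 1000, nPerm = 9999, seed) {
    stopifnot(is(catches, "ConeCatchSet"), is(vs, "VisualSystem"))
    if (missing(seed)) stop("a seed is required")
    labels <- factor(as.character(labels),
                     levels = c("UVplus_white", "UVminus_white"))
    keep <- !is.na(labels) & !catches@flagged
    labs <- droplevels(labels[keep])
    if (nlevels(labs) < 2L || any(table(labs) < 2L)) {
        return(new("TwoStepReport", twoClass = FALSE,
                   message = paste("two-class statistics skipped:",
                                   "fewer than two white classes with >= 2",
                                   "spectra after excluding ambiguous and",
                                   "flagged spectra"),
                   boot = new("BootDistResult", pointEstimate = NA_real_,
                              ciLow = 0, ciHigh = 0, nBoot = 0L, seed = 0L,
                              conf = NA_real_, bootDist = numeric(0)),
                   permanova = new("PermanovaResult", pseudoF = NA_real_,
                                   pValue = NA_real_, nPerm = 0L,
                                   dfBetween = NA_integer_,
                                   dfWithin = NA_integer_,
                                   ssBetween = NA_real_, ssWithin = NA_real_,
                                   ssTotal = NA_real_, seed = 0L,
                                   degenerate = FALSE),
                   verdict = NA_character_))
    }
    f <- catches@logCatches[keep, , drop = FALSE]
    noise <- receptorNoise(vs)
    boot <- bootColDist(f[labs == "UVplus_white", , drop = FALSE],
                        f[labs == "UVminus_white", , drop = FALSE],
                        noise, nBoot = nBoot, seed = seed)
    if (is.null(D)) {
        sub <- new("ConeCatchSet", catches = catches@catches[keep, ,
                                                             drop = FALSE],
                   normCatches = catches@normCatches[keep, , drop = FALSE],
                   logCatches = f, flagged = rep(FALSE, sum(keep)),
                   coneNames = catches@coneNames)
        D <- pairwiseJND(sub, vs, achromatic = FALSE)$chromatic
    }
    perm <- permanovaDist(D, labs, nPerm = nPerm, seed = seed + 1L)
    new("TwoStepReport", twoClass = TRUE, message = "",
        boot = boot, permanova = perm,
        verdict = jndVerdict(boot@pointEstimate))
}

#' TwoStepReport
#'
#' @slot twoClass whether two-class statistics were computed.
#' @slot message explanation when they were not.
#' @slot boot a \linkS4class{BootDistResult}.
#' @slot permanova a \linkS4class{PermanovaResult}.
#' @slot verdict perceptual band of the point estimate.
#' @name TwoStepReport-class
#' @exportClass TwoStepReport
setClass("TwoStepReport",
         representation(twoClass = "logical", message = "character",
                        boot = "BootDistResult",
                        permanova = "PermanovaResult",
                        verdict = "character"))

setMethod("show", "TwoStepReport", function(object) {
    cat("Two-step discriminability report\n")
    if (!object@twoClass) {
        cat(" ", object@message, "\n")
        return(invisible(NULL))
    }
    cat("  step 1 (statistical): ")
    show(object@permanova)
    cat("  step 2 (perceptual):  ")
    show(object@boot)
    cat("  verdict:", object@verdict, "\n")
})
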
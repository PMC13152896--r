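# Shared fixtures and independent oracles for the test suite.

wlGrid <- function() 300:700

# small SpectrumSet from a named list of reflectance vectors
makeSet <- function(spectra, wl = wlGrid(), patch = "throat",
                    sex = "male", locality = "Loc1", morph = "white") {
    m <- do.call(cbind, spectra)
    n <- ncol(m)
    md <- data.frame(specimen_id = names(spectra),
                     patch = rep_len(patch, n),
                     sex = rep_len(sex, n),
                     locality = rep_len(locality, n),
                     human_morph = rep_len(morph, n))
    SpectrumSet(m, wl, md)
}

# long-pass sigmoid in percent reflectance, the generator's template shape
sigmoid <- function(wl, lambda0, slope = 10, base = 5, amplitude = 50) {
    base + amplitude / (1 + exp(-(wl - lambda0) / slope))
}

# independent receptor-noise oracle: JND as the root of the minimized
# weighted least-squares objective min_x sum((df_i - x)^2 / w_i^2)
glsOracle <- function(df, w) {
    iw2 <- 1 / w^2
    xstar <- sum(df * iw2) / sum(iw2)
    sqrt(sum((df - xstar)^2 / w^2))
}

# exhaustive one-way PERMANOVA p-value: proportion of all assignments of
# the observed group sizes whose pseudo-F >= the observed pseudo-F
exhaustivePermanovaP <- function(D, labels) {
    labels <- factor(labels)
    n <- nrow(D)
    D2 <- D^2
    ssTot <- sum(D2) / (2 * n)
    a <- nlevels(labels)
    fOf <- function(lab) {
        ssW <- sum(vapply(split(seq_len(n), lab), function(i)
            sum(D2[i, i]) / (2 * length(i)), numeric(1)))
        ((ssTot - ssW) / (a - 1)) / (ssW / (n - a))
    }
    fObs <- fOf(labels)
    g1 <- which(labels == levels(labels)[1])
    combs <- utils::combn(n, length(g1))
    fAll <- apply(combs, 2, function(idx) {
        lab <- rep(levels(labels)[2], n)
        lab[idx] <- levels(labels)[1]
        fOf(factor(lab))
    })
    mean(fAll >= fObs - 1e-12)
}
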
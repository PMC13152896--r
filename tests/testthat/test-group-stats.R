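test_that("bootstrap centroid distance: degenerate case and recovery of a known separation", {
    w <- receptorNoise(visualSystem())
    f <- matrix(rnorm(4), 1, 4)
    b <- bootColDist(f, f, w, nBoot = 100, seed = 1)
    expect_equal(b@pointEstimate, 0)
    expect_equal(c(b@ciLow, b@ciHigh), c(0, 0))
    expect_error(bootColDist(f[0, , drop = FALSE], f, w, seed = 1),
                 "non-empty")
    expect_error(bootColDist(f, f, w, nBoot = 10), "seed")

    # log-normal catches with a known centroid separation
    set.seed(8)
    muA <- c(-0.5, -0.3, -0.2, -0.1)
    delta <- c(0.25, 0.05, -0.1, 0.02)
    trueDS <- glsOracle(delta, w)
    fA <- sweep(matrix(rnorm(200 * 4, 0, 0.1), 200), 2, muA, "+")
    fB <- sweep(matrix(rnorm(200 * 4, 0, 0.1), 200), 2, muA - delta, "+")
    b <- bootColDist(fA, fB, w, nBoot = 500, seed = 2)
    se <- sd(b@bootDist)
    expect_lt(abs(b@pointEstimate - trueDS), 3 * se)
    expect_true(b@ciLow <= b@pointEstimate && b@pointEstimate <= b@ciHigh)
})

test_that("bootstrap CI endpoints stabilize across seeds at large resample counts", {
    w <- receptorNoise(visualSystem())
    set.seed(12)
    fA <- sweep(matrix(rnorm(120 * 4, 0, 0.1), 120), 2,
                c(-0.4, -0.3, -0.2, -0.1), "+")
    fB <- sweep(matrix(rnorm(120 * 4, 0, 0.1), 120), 2,
                c(-0.1, -0.3, -0.2, -0.15), "+")
    b1 <- bootColDist(fA, fB, w, nBoot = 5000, seed = 101)
    b2 <- bootColDist(fA, fB, w, nBoot = 5000, seed = 202)
    expect_lt(abs(b1@ciLow - b2@ciLow), 0.05)
    expect_lt(abs(b1@ciHigh - b2@ciHigh), 0.05)
    expect_equal(b1@pointEstimate, b2@pointEstimate)   # seed-free estimand
})

test_that("PERMANOVA matches exhaustive enumeration on a 3+3 instance", {
    set.seed(4)
    pts <- c(rnorm(3, 0), rnorm(3, 1.5))
    D <- as.matrix(dist(pts))
    lab <- rep(c("A", "B"), each = 3)
    pExact <- exhaustivePermanovaP(D, lab)
    res <- permanovaDist(D, lab, nPerm = 19999, seed = 9)
    mcSE <- sqrt(pExact * (1 - pExact) / 19999)
    expect_lt(abs(res@pValue - pExact), 3 * mcSE + 2e-4)
})

test_that("pseudo-F on Euclidean univariate distances equals classical ANOVA F", {
    set.seed(10)
    y <- c(rnorm(8, 0), rnorm(7, 0.8), rnorm(9, -0.4))
    g <- factor(rep(c("a", "b", "c"), c(8, 7, 9)))
    res <- permanovaDist(as.matrix(dist(y)), g, nPerm = 99, seed = 1)
    Fclassic <- summary(aov(y ~ g))[[1]]$`F value`[1]
    expect_equal(res@pseudoF, Fclassic, tolerance = 1e-10)
    expect_equal(res@dfBetween, 2L)
    expect_equal(res@dfWithin, 21L)
})

test_that("pseudo-F agrees with an independent PERMANOVA implementation", {
    set.seed(13)
    x <- rbind(matrix(rnorm(10 * 3), 10), matrix(rnorm(12 * 3, 0.7), 12))
    g <- factor(rep(c("A", "B"), c(10, 12)))
    D <- as.matrix(dist(x))
    res <- permanovaDist(D, g, nPerm = 99, seed = 2)
    ad <- vegan::adonis2(as.dist(D) ~ g, data = data.frame(g = g),
                         permutations = 99)
    expect_equal(res@pseudoF, ad$F[1], tolerance = 1e-8)
})

test_that("PERMANOVA is invariant to relabeling and specimen order; degenerate input is explicit", {
    set.seed(14)
    x <- c(rnorm(6), rnorm(6, 2))
    D <- as.matrix(dist(x))
    g <- rep(c("A", "B"), each = 6)
    f1 <- permanovaDist(D, g, nPerm = 49, seed = 3)@pseudoF
    f2 <- permanovaDist(D, ifelse(g == "A", "zz", "aa"), nPerm = 49,
                        seed = 3)@pseudoF
    ord <- sample(12)
    f3 <- permanovaDist(D[ord, ord], g[ord], nPerm = 49, seed = 3)@pseudoF
    expect_equal(f1, f2)
    expect_equal(f1, f3, tolerance = 1e-10)

    degen <- permanovaDist(matrix(0, 6, 6), rep(c("A", "B"), each = 3),
                           nPerm = 49, seed = 1)
    expect_true(degen@degenerate)
    expect_true(is.na(degen@pseudoF))
    expect_error(permanovaDist(D, c(rep("A", 11), "B"), nPerm = 9, seed = 1),
                 "singleton")

    # maximal separation pins p at its permutation floor
    far <- c(rnorm(6), rnorm(6, 50))
    res <- permanovaDist(as.matrix(dist(far)), g, nPerm = 199, seed = 5)
    expect_equal(res@pValue, 1 / 200)
})

test_that("two-step report applies the JND discriminability bands and declines single-class input", {
    expect_equal(jndVerdict(c(5.07, 2.0, 0.4)),
                 c("easily discriminable",
                   "discriminable only under good illumination",
                   "below discrimination threshold"))

    wl <- wlGrid()
    vs <- visualSystem()
    set.seed(20)
    sp <- setNames(lapply(1:8, function(i) sigmoid(wl, rnorm(1, 330, 3))),
                   paste0("s", 1:8))
    cc <- quantumCatch(makeSet(sp), vs)
    rep1 <- twoStepReport(cc, rep("UVplus_white", 8), vs,
                          nBoot = 50, nPerm = 49, seed = 1)
    expect_false(rep1@twoClass)
    expect_match(rep1@message, "skipped")

    labs <- rep(c("UVplus_white", "UVminus_white"), each = 8)
    sp2 <- c(sp, setNames(lapply(1:8, function(i)
        sigmoid(wl, rnorm(1, 390, 3))), paste0("t", 1:8)))
    cc2 <- quantumCatch(makeSet(sp2), vs)
    rep2 <- twoStepReport(cc2, labs, vs, nBoot = 100, nPerm = 199, seed = 2)
    expect_true(rep2@twoClass)
    expect_equal(rep2@verdict, "easily discriminable")
    expect_gt(rep2@boot@pointEstimate, 3)
    expect_equal(rep2@permanova@pValue, 1 / 200)
})
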
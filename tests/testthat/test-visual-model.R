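test_that("pigment template peaks at lambda-max, is unimodal, with the expected half-max bandwidth", {
    wl <- wlGrid()
    for (lmax in c(367, 456, 497, 562)) {
        s <- pigmentTemplate(lmax, wl)
        expect_equal(max(s), 1)
        expect_lte(abs(wl[which.max(s)] - lmax), 1)
        d <- diff(s)
        flips <- sum(diff(sign(d[d != 0])) != 0)
        expect_lte(flips, 1)              # one rise, one fall

        # oracle: half-max crossings by root finding on the template itself
        f <- function(x) pigmentTemplate(lmax, c(x, lmax))[1] - 0.5
        left <- uniroot(f, c(min(wl), lmax), tol = 1e-8)$root
        right <- uniroot(f, c(lmax, max(wl)), tol = 1e-8)$root
        dense <- seq(min(wl), max(wl), by = 0.05)
        sd_ <- pigmentTemplate(lmax, dense)
        above <- dense[sd_ >= 0.5]
        expect_lt(abs((max(above) - min(above)) - (right - left)), 2)
    }
    expect_error(pigmentTemplate(250, wl), "lmax")
})

test_that("von Kries catches: perfect reflector is the fixed point; intensity scaling shifts all log-catches equally", {
    wl <- wlGrid()
    set.seed(3)
    ill <- 0.5 + runif(length(wl))
    vs <- visualSystem(illuminant = ill)
    perfect <- makeSet(list(w = rep(100, length(wl))))
    cc <- quantumCatch(perfect, vs)
    expect_equal(unname(normCatches(cc)[1, ]), rep(1, 4), tolerance = 1e-12)
    expect_equal(unname(logCatches(cc)[1, ]), rep(0, 4), tolerance = 1e-12)

    y <- sigmoid(wl, 360)
    k <- 2.8
    set <- makeSet(list(a = y, b = k * y))
    cc <- quantumCatch(set, visualSystem())
    f <- logCatches(cc)
    expect_equal(unname(f[2, ] - f[1, ]), rep(log(k), 4), tolerance = 1e-12)

    zero <- makeSet(list(z = rep(0, length(wl))))
    expect_warning(cz <- quantumCatch(zero, visualSystem()), "flagged")
    expect_true(cz@flagged[1])
})

test_that("receptor noise follows the abundance scaling law", {
    vs <- visualSystem()                 # 1:1:1:4, w = 0.05 on LWS
    expect_equal(unname(receptorNoise(vs)), c(0.1, 0.1, 0.1, 0.05))
    eq <- visualSystem(abundances = c(2, 2, 2, 2))
    expect_equal(unname(receptorNoise(eq)), rep(0.05, 4))
    expect_equal(receptorNoise(vs)[["LWS"]], vs@weberRef)
})

test_that("tetrachromatic closed form matches the least-squares oracle and kills intensity shifts", {
    set.seed(99)
    for (i in 1:200) {
        df <- rnorm(4, 0, 0.5)
        w <- runif(4, 0.02, 0.3)
        fA <- rnorm(4); fB <- fA - df
        expect_equal(chromaticDistance(fA, fB, w), glsOracle(df, w),
                     tolerance = 1e-9)
    }
    w <- receptorNoise(visualSystem())
    f <- rnorm(4)
    expect_equal(chromaticDistance(f, f, w), 0)
    expect_equal(chromaticDistance(f + 0.7, f, w), 0, tolerance = 1e-12)

    # shrinking all channel noise by c scales every distance by 1/c
    df <- c(0.2, -0.1, 0.05, 0.3)
    d1 <- chromaticDistance(df, rep(0, 4), w)
    d2 <- chromaticDistance(df, rep(0, 4), w / 4)
    expect_equal(d2, 4 * d1, tolerance = 1e-12)
})

test_that("achromatic distance is the reference-channel Weber ratio", {
    vs <- visualSystem()
    fA <- c(0, 0, 0, 0.05); fB <- rep(0, 4)
    expect_equal(achromaticDistance(fA, fB, vs), 1)
    expect_equal(achromaticDistance(fB, fB, vs), 0)
    expect_gt(achromaticDistance(c(0, 0, 0, 0.2), fB, vs),
              achromaticDistance(fA, fB, vs))
})

test_that("pairwise JND matrices are symmetric pseudometrics, invariant to illuminant intensity", {
    wl <- wlGrid()
    same <- makeSet(list(a = sigmoid(wl, 350), b = sigmoid(wl, 350)))
    vs <- visualSystem()
    expect_equal(max(pairwiseJND(same, vs)$chromatic), 0)

    set.seed(17)
    sp <- setNames(lapply(1:6, function(i)
        sigmoid(wl, runif(1, 320, 420), slope = runif(1, 6, 14))),
        paste0("s", 1:6))
    set <- makeSet(sp)
    J <- pairwiseJND(set, vs)
    D <- J$chromatic
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0) && all(D >= 0))
    expect_equal(J$achromatic, t(J$achromatic))
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
        expect_lte(D[i, k], D[i, j] + D[j, k] + 1e-12)

    bright <- visualSystem(illuminant = rep(40, length(wl)))
    expect_equal(pairwiseJND(set, bright)$chromatic, D, tolerance = 1e-9)
})

test_that("non-tetrachromatic systems route through the generalized path consistently", {
    wl <- wlGrid()
    vs3 <- visualSystem(lmax = c(SWS = 456, MWS = 497, LWS = 562),
                        abundances = c(1, 1, 4))
    w <- receptorNoise(vs3)
    set.seed(5)
    fA <- rnorm(3); fB <- rnorm(3)
    expect_equal(chromaticDistance(fA, fB, w), glsOracle(fA - fB, w),
                 tolerance = 1e-12)
    set <- makeSet(list(a = sigmoid(wl, 340), b = sigmoid(wl, 400)))
    cc <- quantumCatch(set, vs3)
    D <- pairwiseJND(cc, vs3)$chromatic
    f <- logCatches(cc)
    expect_equal(D[1, 2], glsOracle(f[1, ] - f[2, ], w), tolerance = 1e-9)
})
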
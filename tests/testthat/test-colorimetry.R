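test_that("rMid reproduces the analytic cut-off cases", {
    wl <- wlGrid()
    ramp <- pmin((wl - 300) / 150, 1)              # 0 to 1 over 300-450
    stepy <- as.numeric(wl >= 340)                 # step at 340
    flat <- rep(20, length(wl))
    set <- makeSet(list(ramp = ramp, step = stepy, flat = flat))
    r <- rMid(set)
    expect_equal(unname(r["ramp:throat"]), 375.0)
    expect_equal(unname(r["step:throat"]), 339.5)
    expect_true(is.na(r["flat:throat"]))
    expect_error(rMid(set, window = c(250, 450)), "window")
})

test_that("white classification thresholds are boundary-inclusive", {
    lab <- classifyWhite(c(345, 365, 350, 344.9, 365.1, NA))
    expect_equal(as.character(lab),
                 c("UVplus_white", "UVminus_white", "ambiguous",
                   "UVplus_white", "UVminus_white", "ambiguous"))
    expect_error(classifyWhite(350, lo = 370, hi = 360), "lo < hi")
})

test_that("classification depends only on curve shape, not intensity", {
    wl <- wlGrid()
    set.seed(7)
    for (i in 1:20) {
        l0 <- runif(1, 320, 420)
        y <- sigmoid(wl, l0, slope = runif(1, 5, 15))
        k <- exp(runif(1, -3, 3))
        s <- makeSet(list(a = y, b = k * y))
        r <- rMid(s)
        expect_equal(unname(r[1]), unname(r[2]), tolerance = 1e-9)
        expect_identical(classifyWhite(r[1]), classifyWhite(r[2]))
    }
})

test_that("luminance is the plain sum over the 401-sample grid and is linear", {
    wl <- wlGrid()
    set <- makeSet(list(a = rep(0.5, 401), b = rep(0, 401),
                        c = sigmoid(wl, 350)))
    lum <- luminance(set)
    expect_equal(unname(lum[1]), 200.5)
    expect_equal(unname(lum[2]), 0)
    scaled <- makeSet(list(c = 3.7 * sigmoid(wl, 350)))
    expect_equal(unname(luminance(scaled)), 3.7 * unname(lum[3]))
})

test_that("UV chroma is the 300-400 share of total reflectance, in [0,1]", {
    wl <- wlGrid()
    set <- makeSet(list(flat = rep(10, 401),
                        noUV = ifelse(wl <= 400, 0, 50),
                        onlyUV = ifelse(wl <= 400, 50, 0)))
    cu <- uvChroma(set)
    expect_equal(unname(cu["flat:throat"]), 101 / 401)
    expect_equal(unname(cu["noUV:throat"]), 0)
    expect_equal(unname(cu["onlyUV:throat"]), 1)

    set.seed(1)
    rnd <- makeSet(list(r1 = runif(401, 0, 80), r2 = runif(401, 0, 5)))
    expect_true(all(uvChroma(rnd) >= 0 & uvChroma(rnd) <= 1))
    zero <- makeSet(list(z = rep(0, 401)))
    expect_warning(cz <- uvChroma(zero), "zero total")
    expect_true(is.na(cz))
})

test_that("hue peak takes the global maximum with a short-wavelength tie rule", {
    wl <- wlGrid()
    single <- exp(-((wl - 550) / 40)^2)
    mono <- seq(0, 50, length.out = 401)
    plateau <- ifelse(wl >= 500 & wl <= 510, 30, 10)
    set <- makeSet(list(a = single, b = mono, c = plateau))
    hp <- huePeak(set)
    expect_equal(as.numeric(hp), c(550, 700, 500))
    expect_equal(unname(attr(hp, "tied")), c(FALSE, FALSE, TRUE))
})

test_that("group mean spectra: pointwise mean, SEM, peak normalization", {
    wl <- wlGrid()
    a <- sigmoid(wl, 330); b <- sigmoid(wl, 336)
    one <- makeSet(list(a = a))
    gm <- groupMeanSpectra(one, "UVplus_white")
    expect_equal(gm$mean, a)
    expect_true(all(gm$sem == 0))

    two <- makeSet(list(a = a, b = b))
    gm <- groupMeanSpectra(two, c("UVplus_white", "UVplus_white"))
    expect_equal(gm$mean, (a + b) / 2)
    expect_equal(gm$sem, abs(a - b) / 2)   # sd of a pair / sqrt(2)

    gm <- groupMeanSpectra(two, c("UVplus_white", "UVplus_white"),
                           normalize = TRUE)
    expect_equal(max(gm$mean), 1)
    expect_equal(unique(gm$divisor), max((a + b) / 2))
})

test_that("frequency tables give within-stratum proportions and recover a known mix", {
    wl <- wlGrid()
    feats <- data.frame(specimen_id = sprintf("s%02d", 1:10),
                        patch = "throat", sex = "male", locality = "A",
                        label = "UVplus_white")
    tab <- tabulateFrequencies(feats, by = "locality")
    expect_equal(tab$strata$proportion[tab$strata$label == "UVplus_white"], 1)

    cfg <- cohortConfig(n = 300,
                        classMix = c(UVplus_white = 0.6,
                                     UVminus_white = 0.4),
                        discordance = 0, seed = 11)
    set <- simulateCohort(cfg)
    f <- colourFeatures(set)
    tab <- tabulateFrequencies(f, by = "patch")
    p <- tab$strata$proportion[tab$strata$patch == "throat" &
                               tab$strata$label == "UVplus_white"]
    expect_lt(abs(p - 0.6), 1.96 * sqrt(0.6 * 0.4 / 300) + 0.01)

    feats2 <- rbind(feats,
                    within(feats, {sex <- "female"; label <- "UVminus_white"}))
    feats2$sex <- factor(feats2$sex, levels = c("male", "female", "juv"))
    expect_warning(tabulateFrequencies(feats2, by = "sex"), "empty strata")
})

test_that("yellow/orange morphs carry no near-UV signal: c_uv below the UV+white mean, r_mid beyond the gap", {
    cfg <- cohortConfig(n = 120,
                        classMix = c(UVplus_white = 0.5, yellow = 0.3,
                                     orange = 0.2),
                        discordance = 0, seed = 21)
    set <- simulateCohort(cfg)
    f <- colourFeatures(set)
    truth <- colData(set)$true_class
    uvplusMean <- mean(f$c_uv[truth == "UVplus_white"])
    expect_true(all(f$c_uv[truth %in% c("yellow", "orange")] < uvplusMean))
    ry <- f$r_mid[truth == "yellow"]
    expect_gt(mean(is.na(ry) | ry >= 365), 0.9)

    # the noise-free yellow template itself sits beyond the gap
    cfgNF <- cohortConfig(seed = 1)
    yt <- simulateSpectrum("yellow", cfgNF, lambda0 = 460, noise = FALSE)
    expect_gte(rMid(makeSet(list(y = yt)))[[1]], 365)
})
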
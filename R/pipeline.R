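#' Run the full polymorphism-detection pipeline
#'
#' One reproducible run of the whole analysis: obtain spectra (simulate a
#' cohort, or read and resample files), clean, extract colorimetric
#' features, classify white types, tabulate group mean spectra / the R_mid
#' histogram / frequency tables, compute the pairwise chromatic JND matrix,
#' and run the two-step discriminability analysis. All tables are written as
#' CSV under \code{outDir} together with \code{report.txt} and
#' \code{manifest.json} (package version, seed, config hash, and an MD5 per
#' output file). Every source of randomness derives from \code{config$seed},
#' so two runs with the same config are byte-identical. Any stage failure
#' aborts with a stage-named error.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   \code{seed} (required); either \code{cohort} (arguments for
#'   [cohortConfig()]) or \code{spectra}/\code{metadata} file paths;
#'   optional \code{grid} (\code{c(start, stop, step)}), \code{clipNegative},
#'   \code{smoothSpan}, \code{window}, \code{scope}, \code{lo}, \code{hi},
#'   \code{visualSystem} (YAML path), \code{nBoot}, \code{nPerm},
#'   \code{histBinwidth}.
#' @param outDir output directory, created if needed.
#' @return invisibly, a list with the in-memory results (\code{set},
#'   \code{features}, \code{meanSpectra}, \code{rmidHist}, \code{freq},
#'   \code{jnd}, \code{report}, \code{manifest}).
#' @export
runPipeline <- function(config, outDir = tempfile("uvmorph_run")) {
    if (is.character(config) && length(config) == 1L) {
        config <- yaml::read_yaml(config)
        # YAML 1.1 reads a bare "n:" key as boolean FALSE
        if (!is.null(config$cohort))
            names(config$cohort)[names(config$cohort) == "FALSE"] <- "n"
    }
    if (is.null(config$seed)) stop("config$seed is required")
    seed <- as.integer(config$seed)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
                 call. = FALSE))
    }
    cfgHash <- .hashObject(config)
    log <- function(...) message(sprintf("[uvmorph] %s", sprintf(...)))

    grid <- if (!is.null(config$grid))
        wavelengthGrid(config$grid[1], config$grid[2], config$grid[3])
    else canonicalGrid()

    set <- stage("input", {
        if (!is.null(config$spectra)) {
            s <- readSpectra(config$spectra, config$metadata)
            resampleSpectra(s, grid)
        } else {
            cc <- do.call(cohortConfig,
                          c(config$cohort, list(grid = grid, seed = seed)))
            simulateCohort(cc)
        }
    })
    log("input: %d spectra", ncol(set))

    set <- stage("clean", cleanSpectra(
        set,
        clipNegative = !isFALSE(config$clipNegative),
        smoothSpan = config$smoothSpan))

    lo <- if (is.null(config$lo)) 345 else config$lo
    hi <- if (is.null(config$hi)) 365 else config$hi
    feats <- stage("features", colourFeatures(
        set,
        window = if (is.null(config$window)) c(300, 450) else config$window,
        scope = if (is.null(config$scope)) "window" else config$scope,
        lo = lo, hi = hi))
    log("features: %d/%d unambiguous", sum(feats$label != "ambiguous"),
        nrow(feats))

    means <- stage("group_means",
                   groupMeanSpectra(set, feats$label, normalize = FALSE))
    bw <- if (is.null(config$histBinwidth)) 5 else config$histBinwidth
    rmh <- stage("rmid_hist", {
        r <- feats$r_mid[!is.na(feats$r_mid)]
        br <- seq(floor(min(r) / bw) * bw, ceiling(max(r) / bw) * bw, by = bw)
        h <- graphics::hist(r, breaks = br, plot = FALSE)
        data.frame(bin_low = h$breaks[-length(h$breaks)],
                   bin_high = h$breaks[-1], count = h$counts)
    })
    freq <- stage("frequencies", tabulateFrequencies(feats))

    vs <- stage("visual_system", {
        if (!is.null(config$visualSystem))
            readVisualSystem(config$visualSystem, wavelength = grid)
        else visualSystem(wavelength = grid)
    })
    catches <- stage("quantum_catch", quantumCatch(set, vs))
    jnd <- stage("jnd", pairwiseJND(catches, vs))
    # the two-white comparison concerns human-white patches only
    labs <- as.character(feats$label)
    if ("human_morph" %in% colnames(feats))
        labs[!feats$human_morph %in% c("white", "white-orange")] <- NA
    report <- stage("two_step", twoStepReport(
        catches, labs, vs,
        nBoot = if (is.null(config$nBoot)) 1000 else config$nBoot,
        nPerm = if (is.null(config$nPerm)) 9999 else config$nPerm,
        seed = seed + 1L))

    wcsv <- function(df, file) {
        utils::write.csv(df, file.path(outDir, file), row.names = FALSE,
                         fileEncoding = "UTF-8")
        file
    }
    files <- c(
        wcsv(as.data.frame(feats), "features.csv"),
        wcsv(means, "mean_spectra.csv"),
        wcsv(rmh, "rmid_histogram.csv"),
        wcsv(freq$strata, "frequencies_strata.csv"),
        if (!is.null(freq$patchCombos))
            wcsv(freq$patchCombos, "patch_combos.csv"),
        wcsv(data.frame(id = rownames(jnd$chromatic),
                        jnd$chromatic, check.names = FALSE),
             "jnd_chromatic.csv"))
    repPath <- file.path(outDir, "report.txt")
    writeLines(c(utils::capture.output(show(report)),
                 sprintf("config_hash: %s", cfgHash)), repPath)
    files <- c(files, "report.txt")

    manifest <- list(
        package = "uvmorph",
        version = as.character(utils::packageVersion("uvmorph")),
        seed = seed,
        config_hash = cfgHash,
        thresholds = c(lo = lo, hi = hi),
        outputs = as.list(tools::md5sum(file.path(outDir, files))))
    names(manifest$outputs) <- files
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    log("done: %s", outDir)
    invisible(list(set = set, features = feats, meanSpectra = means,
                   rmidHist = rmh, freq = freq, jnd = jnd, report = report,
                   manifest = manifest, outDir = outDir))
}

# order-stable md5 of an R object via its deparsed canonical form
.hashObject <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(deparse(x[order(names(x))]), f)
    unname(tools::md5sum(f))
}
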
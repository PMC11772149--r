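#' Write / read a recording as delimited text
#'
#' On-disk format: \code{<base>_signal.tsv} (one sample per line, uV),
#' \code{<base>_stim.csv} (stimulus times and train frequencies) and
#' \code{<base>_meta.yaml} (rate, site, path length). Plain text keeps the
#' recordings portable and diffable.
#'
#' @param rec a \linkS4class{Recording}.
#' @param base path prefix (without extension).
#' @return \code{base}, invisibly.
#' @export
writeRecording <- function(rec, base) {
    stopifnot(is(rec, "Recording"))
    utils::write.table(data.frame(signal = rec@signal),
                       paste0(base, "_signal.tsv"),
                       row.names = FALSE, col.names = TRUE, sep = "\t")
    utils::write.csv(data.frame(stim_time = rec@stimTimes,
                                stim_freq = if (length(rec@stimFreq))
                                    rec@stimFreq else
                                    rep(NA_real_, length(rec@stimTimes))),
                     paste0(base, "_stim.csv"), row.names = FALSE)
    yaml::write_yaml(list(rate = rec@rate, stim_site = rec@stimSite,
                          path_length_mm = rec@pathLength),
                     paste0(base, "_meta.yaml"))
    invisible(base)
}

#' @rdname writeRecording
#' @export
readRecording <- function(base) {
    sig <- utils::read.table(paste0(base, "_signal.tsv"), header = TRUE,
                             sep = "\t")$signal
    stim <- utils::read.csv(paste0(base, "_stim.csv"))
    meta <- yaml::read_yaml(paste0(base, "_meta.yaml"))
    freq <- stim$stim_freq
    new("Recording", signal = sig, rate = meta$rate,
        stimTimes = stim$stim_time,
        stimFreq = if (all(is.na(freq))) numeric() else freq,
        stimSite = meta$stim_site,
        pathLength = if (is.null(meta$path_length_mm)) NA_real_ else
            as.numeric(meta$path_length_mm))
}

#' Write / read an RGB image (PNG)
#'
#' @param image H x W x 3 array on the 0-255 scale.
#' @param path output path.
#' @export
writeRGBImage <- function(image, path) {
    png::writePNG(image / 255, path)
    invisible(path)
}

#' @rdname writeRGBImage
#' @export
readRGBImage <- function(path) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
    round(a[, , 1:3, drop = FALSE] * 255)
}

#' Read / write landmark tables
#'
#' Landmark CSVs are long format with columns \code{frame}, \code{point}
#' (\code{eye}, \code{shoulder}, \code{hip}, \code{ground}), \code{x},
#' \code{y}; the \code{ground} rows give the ground direction vector.
#'
#' @param scenes list of \linkS4class{LandmarkScene} objects.
#' @param path CSV path.
#' @return \code{readLandmarks} returns a list of scenes.
#' @export
writeLandmarks <- function(scenes, path) {
    rows <- lapply(scenes, function(s)
        data.frame(frame = s@frame,
                   point = c("eye", "shoulder", "hip", "ground"),
                   x = c(s@eye[1], s@shoulder[1], s@hip[1], s@ground[1]),
                   y = c(s@eye[2], s@shoulder[2], s@hip[2], s@ground[2])))
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeLandmarks
#' @export
readLandmarks <- function(path) {
    tab <- utils::read.csv(path)
    lapply(split(tab, tab$frame), function(d) {
        pt <- function(p) {
            r <- d[d$point == p, ]
            c(r$x[1], r$y[1])
        }
        new("LandmarkScene", eye = pt("eye"), shoulder = pt("shoulder"),
            hip = pt("hip"), ground = pt("ground"),
            frame = as.character(d$frame[1]))
    })
}

## ---- pipeline -----------------------------------------------------------

.defaultConfig <- function() {
    list(seed = 1,
         outdir = "cordmetrics-out",
         histology = list(width = 192, height = 192, pixel_size = 0.65,
                          fractions = c(0.4, 0.3, 0.25, 0.05), k = 16,
                          radius = 1, delta = 20, layout = "clustered"),
         ephys = list(latency_ms = 3, jitter_ms = 0.05, response_prob = 1,
                      snr = 10),
         morphometry = list(width = 192, height = 192, n_structures = 6,
                            kind = "neurite", pixel_size = 0.5,
                            length_range = c(20, 40),
                            placement = "uniform"),
         behavior = list(ctl_angles = c(100, 120, 150),
                         trunk_angles = c(10, 25, 40)))
}

.validateConfig <- function(cfg) {
    chk <- function(ok, field)
        if (!ok) stop(sprintf("invalid config field '%s'", field),
                      call. = FALSE)
    chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed")
    chk(is.character(cfg$outdir), "outdir")
    h <- cfg$histology
    chk(is.numeric(h$fractions) && length(h$fractions) == 4 &&
        abs(sum(h$fractions) - 1) < 1e-9, "histology.fractions")
    chk(h$k >= 2, "histology.k")
    chk(h$radius >= 1, "histology.radius")
    e <- cfg$ephys
    chk(e$latency_ms > 0, "ephys.latency_ms")
    chk(e$response_prob >= 0 && e$response_prob <= 1,
        "ephys.response_prob")
    m <- cfg$morphometry
    chk(m$n_structures >= 1, "morphometry.n_structures")
    b <- cfg$behavior
    chk(all(b$ctl_angles > 0 & b$ctl_angles <= 180),
        "behavior.ctl_angles")
    chk(all(b$trunk_angles >= 0 & b$trunk_angles <= 90),
        "behavior.trunk_angles")
    invisible(cfg)
}

#' Run the simulate-then-analyze pipeline
#'
#' Generates synthetic inputs for every stage (trichrome image, unit
#' recordings, structure mask, landmark scenes), analyzes them with the
#' package's operations, writes per-stage JSON outputs plus a run manifest
#' (config echo, package version, output checksums) and returns the results.
#' Reruns with an identical config give an identical manifest hash.
#'
#' @param config a config list, or the path to a YAML config file; defaults
#'   are used for missing fields.
#' @return list of per-stage results plus the manifest, invisibly.
#' @export
runPipeline <- function(config = list()) {
    if (is.character(config)) {
        if (!file.exists(config))
            stop("config file not found: ", config, call. = FALSE)
        config <- yaml::read_yaml(config)
    }
    cfg <- utils::modifyList(.defaultConfig(), config)
    .validateConfig(cfg)
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    seed <- cfg$seed

    ## histology stage
    h <- cfg$histology
    sim <- genTrichromeImage(h$width, h$height, pixelSize = h$pixel_size,
                             fractions = h$fractions,
                             collagenLayout = h$layout, seed = seed)
    model <- clusterColors(sim$image, k = h$k, seed = seed)
    cm <- classifyClusters(model, delta = h$delta,
                           pixelSize = h$pixel_size)
    areas <- quantifyAreas(cm)
    comp <- collagenCompactness(blueIntensity(sim$image, cm),
                                radius = h$radius)
    hist4 <- binCompactness(comp, pixelSize = h$pixel_size)
    histology <- list(areas_um2 = as.list(areas@areas),
                      blue_purple_ratio = areas@bluePurpleRatio,
                      compactness_fractions =
                          as.list(hist4@levelFractions))

    ## ephys stage
    e <- cfg$ephys
    study <- simulateUnitStudy("antidromic", latency = e$latency_ms,
                               jitter = e$jitter_ms, p = e$response_prob,
                               snr = e$snr, seed = seed)
    panel <- antidromicPanel(study$low$recording, study$high$recording,
                             study$coll$recording)
    ephys <- list(classification = panel$verdict@classification,
                  efficiency_pct = panel$efficiency,
                  mean_latency_ms = panel$meanLatency)

    ## morphometry stage
    m <- cfg$morphometry
    sm <- genStructureMask(m$width, m$height, m$n_structures,
                           kind = m$kind, lengthRange = m$length_range,
                           placement = m$placement,
                           pixelSize = m$pixel_size, seed = seed)
    st <- measureStructures(sm$mask, kind = m$kind)
    dh <- computeDHI(sm$mask)
    morpho <- list(totals = as.list(structureTotals(st)),
                   dhi = dhi(dh))

    ## behavior stage
    b <- cfg$behavior
    scenes <- mapply(function(c1, t1, i)
        genLandmarkScene(c1, t1, seed = seed + i, frame = as.character(i)),
        b$ctl_angles, b$trunk_angles, seq_along(b$ctl_angles),
        SIMPLIFY = FALSE)
    meas <- do.call(rbind, lapply(scenes, function(s)
        as.data.frame(as.list(sceneAngles(s)))))
    behavior <- list(angles = meas, range = angleRange(meas))

    results <- list(histology = histology, ephys = ephys,
                    morphometry = morpho,
                    behavior = list(range = as.list(behavior$range$range)))
    outFiles <- character()
    for (stage in names(results)) {
        f <- file.path(cfg$outdir, paste0(stage, ".json"))
        jsonlite::write_json(results[[stage]], f, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
        outFiles <- c(outFiles, f)
    }
    sums <- tools::md5sum(outFiles)
    manifest <- list(package = "cordmetrics",
                     version = as.character(
                         utils::packageVersion("cordmetrics")),
                     config = cfg,
                     outputs = as.list(sums),
                     hash = unname(tools::md5sum(outFiles)[1]))
    manifest$hash <- paste(unname(sums), collapse = "")
    mf <- file.path(cfg$outdir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(c(results, list(manifest = manifest)))
}
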
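## End-to-end pipeline: simulate (or load) subjects, run the correction and
## metric stages per subject with failure isolation, assemble the cohort
## table, and compute the group statistics.

#' Build a run configuration
#'
#' All defaults are the analysis' standard values: 14 annuli of 1 degree,
#' 360 azimuthal segments, a 31 x 31 pixel centre-search window, compensation
#' offsets from -5 to +5 degrees in 1-degree steps, MD cut-off 0.65, 10 x 10
#' DOPU kernel, 9 x 9 Stokes smoothing, a 5-pixel depth band for en-face
#' extraction, and the 28 x 21 degree / 1024 x 250 pixel scan geometry.
#'
#' @param nHealthy,nGlaucoma subjects per group.
#' @param seed integer master seed; all randomness derives from it.
#' @param fieldDeg,gridPx,mmPerDeg,wavelengthNm scan geometry.
#' @param mdCutoff MD cut-off for the extension estimate.
#' @param annulus correction annulus (degrees).
#' @param nSegments azimuthal segments per annulus.
#' @param centerWindow centre-search window edge (pixels, odd).
#' @param offsetGrid compensation offset candidates (degrees).
#' @param dopuKernel DOPU kernel (pixels).
#' @param smoothKernel Stokes smoothing kernel (pixels).
#' @param depthBandPx depth band for en-face extraction (pixels).
#' @param dopuCut DOPU cut for IS/OS refinement.
#' @param isosHalfWidth IS/OS search half-width (pixels).
#' @param binWidth eccentricity bin width of the retardation profile (deg).
#' @param truthConfig overrides forwarded to \code{\link{makeTruth}}.
#' @param welch use Welch's t-test instead of pooled variance.
#' @param bonferroni apply Bonferroni correction to per-annulus p-values.
#' @return a named list.
#' @export
makeRunConfig <- function(nHealthy = 20, nGlaucoma = 20, seed = 1,
                          fieldDeg = c(28, 21), gridPx = c(1024, 250),
                          mmPerDeg = 8 / 28, wavelengthNm = 860,
                          mdCutoff = 0.65, annulus = c(1, 2),
                          nSegments = 360L, centerWindow = 31L,
                          offsetGrid = -5:5, dopuKernel = c(10, 10),
                          smoothKernel = c(9, 9), depthBandPx = 5,
                          dopuCut = 0.75, isosHalfWidth = 8,
                          binWidth = 0.25, truthConfig = list(),
                          welch = FALSE, bonferroni = FALSE) {
  as.list(environment())
}

.configGeometry <- function(config) {
  sceneGeometry(config$fieldDeg, config$gridPx, config$mmPerDeg,
                config$wavelengthNm)
}

#' Process one subject
#'
#' Runs the four-step correction, estimates the HFL extension, smooths the
#' compensated Stokes map, extracts the circumferential retardation profile
#' and its scalar metrics, and estimates the SNR.
#'
#' @param subject a subject list from \code{\link{simulateCohort}}.
#' @param config a list from \code{\link{makeRunConfig}}.
#' @return list with \code{record} (one-row data.frame), \code{profile}
#'   (\linkS4class{HenleMDProfile}), \code{retProfile}
#'   (\linkS4class{RetardationProfile}) and \code{pol}.
#' @export
processSubject <- function(subject, config = makeRunConfig()) {
  fc <- fullCorrection(subject, config$annulus, config$centerWindow,
                       config$offsetGrid, config$nSegments)
  ext <- hflExtension(fc$profile, config$mdCutoff)
  sm <- smoothStokes(fc$stokes, config$smoothKernel)
  rp <- circumferentialAverage(sm, fc$center, config$binWidth)
  met <- profileMetrics(rp)
  snr <- if (!is.null(subject$scene) && subject$scene$threshold > 0)
    estimateSnr(subject$scene$isos@I, subject$scene$threshold,
                subject$scene$isos@valid)
  else NA_real_
  md <- fc$profile@md
  rec <- data.frame(id = subject$id %||% "subject",
                    group = subject$group %||% NA_character_,
                    age = subject$age %||% NA_real_,
                    snr = snr,
                    extension = as.numeric(ext),
                    extFlag = attr(ext, "flag"),
                    peak = met$peak, peakEcc = met$peakEcc, auc = met$auc,
                    rotation = fc$rotation,
                    offsetRet = fc$offsets[1], offsetAxis = fc$offsets[2],
                    centerX = fc$center[1], centerY = fc$center[2],
                    status = "ok", reason = "",
                    stringsAsFactors = FALSE)
  rec[paste0("ann_", 1:7, "_", 2:8)] <- as.list(met$annulusMeans)
  rec[paste0("md_", 0:13, "_", 1:14)] <- as.list(md)
  list(record = rec, profile = fc$profile, retProfile = rp, pol = fc$pol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-cohort pipeline
#'
#' Simulates healthy and glaucoma cohorts, processes every subject (failures
#' are isolated: failing subjects are excluded from the statistics with a
#' reason code), and computes the group comparisons: extension t-test,
#' retardation metric t-tests (peak, peak eccentricity, AUC, per-annulus
#' means), and the SNR-extension regression over healthy subjects. Fully
#' deterministic for a fixed seed.
#'
#' @param config a list from \code{\link{makeRunConfig}}.
#' @param outDir optional directory; if given, writes \code{cohort.csv},
#'   \code{stats.csv} and \code{config.yaml} there.
#' @return list with \code{cohort} (data.frame, one row per subject,
#'   including excluded ones), \code{stats} (data.frame of comparisons),
#'   \code{profiles}, \code{retProfiles}, \code{excluded} (ids).
#' @export
runPipeline <- function(config = makeRunConfig(), outDir = NULL) {
  geom <- .configGeometry(config)
  subjects <- c(
    simulateCohort(config$nHealthy, "healthy", config$seed, geom,
                   config$truthConfig),
    simulateCohort(config$nGlaucoma, "glaucoma", config$seed + 500000L, geom,
                   config$truthConfig))
  rows <- list()
  profiles <- list()
  retProfiles <- list()
  for (s in subjects) {
    res <- tryCatch(processSubject(s, config), error = function(e) e)
    if (inherits(res, "error")) {
      rec <- data.frame(id = s$id, group = s$group, age = s$age,
                        snr = NA_real_, extension = NA_real_,
                        extFlag = NA_character_, peak = NA_real_,
                        peakEcc = NA_real_, auc = NA_real_,
                        rotation = NA_real_, offsetRet = NA_real_,
                        offsetAxis = NA_real_, centerX = NA_real_,
                        centerY = NA_real_, status = "excluded",
                        reason = conditionMessage(res),
                        stringsAsFactors = FALSE)
      rec[paste0("ann_", 1:7, "_", 2:8)] <- NA_real_
      rec[paste0("md_", 0:13, "_", 1:14)] <- NA_real_
      rows[[s$id]] <- rec
    } else {
      rows[[s$id]] <- res$record
      profiles[[s$id]] <- res$profile
      retProfiles[[s$id]] <- res$retProfile
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  ok <- cohort[cohort$status == "ok", ]
  h <- ok[ok$group == "healthy", ]
  g <- ok[ok$group == "glaucoma", ]
  stats <- NULL
  if (nrow(h) >= 2 && nrow(g) >= 2) {
    cmp <- function(name, col) {
      tt <- tryCatch(twoSampleT(h[[col]], g[[col]], config$welch),
                     error = function(e) list(t = NA_real_, p = NA_real_))
      data.frame(measure = name, meanHealthy = mean(h[[col]], na.rm = TRUE),
                 meanGlaucoma = mean(g[[col]], na.rm = TRUE),
                 t = tt$t, p = tt$p, stringsAsFactors = FALSE)
    }
    stats <- rbind(cmp("extension", "extension"),
                   cmp("peak", "peak"), cmp("peakEcc", "peakEcc"),
                   cmp("auc", "auc"),
                   do.call(rbind, lapply(1:7, function(i)
                     cmp(sprintf("retardation %d-%d deg", i, i + 1),
                         sprintf("ann_%d_%d", i, i + 1)))))
    if (config$bonferroni) {
      ann <- grepl("^retardation", stats$measure)
      stats$p[ann] <- pmin(stats$p[ann] * sum(ann), 1)
    }
  }
  reg <- if (nrow(h) >= 3 && stats::sd(h$snr) > 0)
    snrExtensionRegression(h) else NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeCohortCsv(cohort, file.path(outDir, "cohort.csv"))
    if (!is.null(stats))
      utils::write.csv(stats, file.path(outDir, "stats.csv"), row.names = FALSE)
    writeRunConfig(config, file.path(outDir, "config.yaml"))
  }
  list(cohort = cohort, stats = stats, snrRegression = reg,
       profiles = profiles, retProfiles = retProfiles,
       excluded = cohort$id[cohort$status != "ok"])
}
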
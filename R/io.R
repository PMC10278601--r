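## File formats: Stokes maps as multi-page float32 TIFF (pages I, Q, U, V,
## valid) with a JSON sidecar holding the affine scale and scene metadata;
## ground truths as JSON; MD/retardation profiles and cohort tables as CSV;
## run configuration as YAML.

#' Write / read an en-face Stokes map as multi-page TIFF
#'
#' Pages are, in order, I, Q, U, V (float32) and the validity mask (0/1).
#' Float TIFF storage is defined on [0, 1], so pages are affinely rescaled;
#' the scale, surface label and geometry travel in a JSON sidecar
#' (\code{<path>.json}) written alongside.
#'
#' @param s a \linkS4class{StokesMap}.
#' @param path output path (".tif").
#' @return \code{writeStokesTiff}: the path, invisibly;
#'   \code{readStokesTiff}: a \linkS4class{StokesMap}.
#' @export
writeStokesTiff <- function(s, path) {
  stopifnot(is(s, "StokesMap"))
  scale <- max(abs(c(s@I, s@Q, s@U, s@V)), 1e-12)
  enc <- function(m) (m / scale + 1) / 2
  pages <- list(enc(s@I), enc(s@Q), enc(s@U), enc(s@V),
                matrix(as.numeric(s@valid), nrow(s@I)))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(scale = scale, surface = s@surface,
               fieldDeg = s@geometry@fieldDeg, gridPx = s@geometry@gridPx,
               mmPerDeg = s@geometry@mmPerDeg,
               wavelengthNm = s@geometry@wavelengthNm)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeStokesTiff
#' @export
readStokesTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == 5L)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dec <- function(m) (2 * m - 1) * meta$scale
  geom <- sceneGeometry(meta$fieldDeg, meta$gridPx, meta$mmPerDeg,
                        meta$wavelengthNm)
  I <- dec(pages[[1]])
  I[I < 0 & I > -1e-6 * meta$scale] <- 0   # float32 round-off guard
  .stokesMap(I, dec(pages[[2]]), dec(pages[[3]]), dec(pages[[4]]),
             pages[[5]] > 0.5, meta$surface, geom)
}

#' Write / read a ground truth as JSON
#'
#' @param truth a \linkS4class{HenleGroundTruth}.
#' @param path output path (".json").
#' @export
writeTruthJson <- function(truth, path) {
  stopifnot(is(truth, "HenleGroundTruth"))
  fields <- methods::slotNames("HenleGroundTruth")
  lst <- lapply(fields, function(nm) slot(truth, nm))
  names(lst) <- fields
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTruthJson
#' @export
readTruthJson <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(methods::new,
          c(list("HenleGroundTruth"),
            lapply(lst, function(x) if (is.character(x)) x else as.numeric(x))[
              setdiff(names(lst), "seed")],
            list(seed = as.integer(lst$seed))))
}

#' Write a cohort table as CSV
#'
#' One row per subject with the documented column schema: identifiers
#' (\code{id}, \code{group}, \code{age}, \code{snr}, \code{status}), the
#' measured extension and its flag, retardation metrics (\code{peak},
#' \code{peakEcc}, \code{auc}, \code{ann_1_2} .. \code{ann_7_8}) and the MD
#' per annulus (\code{md_0_1} .. \code{md_13_14}).
#'
#' @param cohort data.frame as produced by \code{\link{runPipeline}}.
#' @param path output path (".csv").
#' @export
writeCohortCsv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a run configuration as YAML
#'
#' @param config list as from \code{\link{makeRunConfig}}.
#' @param path output path (".yaml").
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(makeRunConfig, cfg[intersect(names(cfg),
                                       names(formals(makeRunConfig)))])
}
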
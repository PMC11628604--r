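# TIFF / CSV / JSON input-output. Channels are written as 32-bit TIFFs
# min-max scaled to [0, 1]; the physical calibration and the per-channel
# intensity scale live in a JSON sidecar so a field round-trips to within
# float precision. Matrices are [x, y]; TIFF files are row-major [y, x], so
# channels are transposed on the way in and out.

#' Write a field of view as per-channel TIFFs plus a JSON sidecar
#'
#' @param fov a [FieldOfView-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the sidecar path.
#' @export
writeFov <- function(fov, dir, prefix = "fov") {
  stopifnot(is(fov, "FieldOfView"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(pixel_size_um = fov@pixelSizeUm, fov_size_um = fov@fovSizeUm,
               channels = list())
  for (role in names(fov@channelRoles)) {
    m <- getChannel(fov, role)
    rng <- range(m)
    scaled <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
    path <- file.path(dir, paste0(prefix, "_", role, ".tif"))
    tiff::writeTIFF(t(scaled), path, bits.per.sample = 32L)
    meta$channels[[role]] <- list(file = basename(path),
                                  min = rng[1], max = rng[2])
  }
  sidecar <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a field of view written by [writeFov()]
#'
#' @param sidecar path to the JSON sidecar.
#' @return a [FieldOfView-class].
#' @export
readFov <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  chans <- lapply(names(meta$channels), function(role) {
    info <- meta$channels[[role]]
    m <- t(tiff::readTIFF(file.path(dir, info$file)))
    m * (info$max - info$min) + info$min
  })
  names(chans) <- names(meta$channels)
  FieldOfView(chans, pixelSizeUm = meta$pixel_size_um,
              fovSizeUm = meta$fov_size_um)
}

#' Write an integer label image as a 16-bit TIFF
#'
#' @param labels integer matrix (values 0..65535).
#' @param path output file.
#' @export
writeLabelTiff <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(t(labels) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label TIFF written by [writeLabelTiff()]
#' @param path file path.
#' @return integer label matrix.
#' @export
readLabelTiff <- function(path) {
  m <- t(round(tiff::readTIFF(path) * 65535))
  storage.mode(m) <- "integer"
  m
}

#' Read soma centroids from a CSV file
#'
#' Expects columns `x, y` in 0-based pixel coordinates (x = column of the
#' displayed image), which are converted to this package's 1-based `[x, y]`
#' convention.
#'
#' @param path CSV path.
#' @return n x 2 numeric matrix of (x, y) in 1-based pixels.
#' @export
readSeedsCsv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("x", "y") %in% names(df)))
  cbind(x = df$x + 1, y = df$y + 1)
}
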
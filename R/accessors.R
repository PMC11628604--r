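#' @name accessors
#' @title Accessors for gliaQuant data objects
#' @param object,fov a gliaQuant S4 object.
#' @param role channel role name.
NULL

#' @describeIn accessors pixel size in micrometres.
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setMethod("pixelSize", "FieldOfView", function(object) object@pixelSizeUm)

#' @describeIn accessors physical field size in micrometres.
#' @export
setGeneric("fovSize", function(object) standardGeneric("fovSize"))

#' @rdname accessors
#' @export
setMethod("fovSize", "FieldOfView", function(object) object@fovSizeUm)

#' @describeIn accessors channel role names.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setMethod("channelNames", "FieldOfView", function(object) names(object@channelRoles))

#' Extract one channel of a field of view
#'
#' @param fov a [FieldOfView-class].
#' @param role a channel role name (e.g. `"plaque"`) or integer index.
#' @return the channel's numeric matrix.
#' @export
getChannel <- function(fov, role) {
  stopifnot(is(fov, "FieldOfView"))
  if (is.character(role)) {
    if (!role %in% names(fov@channelRoles))
      stop("no channel with role '", role, "'; available: ",
           paste(names(fov@channelRoles), collapse = ", "))
    role <- fov@channelRoles[[role]]
  }
  fov@pixels[[role]]
}

#' @describeIn accessors number of feature planes the bank produces.
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))

#' @rdname accessors
#' @export
setMethod("nFeatures", "FeatureBankConfig", function(object) {
  per <- sum(ifelse(object@filters == "hessian_eig", 2L, 1L))
  1L + per * length(object@sigmas)
})

setMethod("show", "FieldOfView", function(object) {
  d <- dim(object@pixels[[1]])
  cat("FieldOfView:", d[1], "x", d[2], "px,",
      format(object@pixelSizeUm, digits = 3), "um/px,",
      format(object@fovSizeUm, digits = 6), "um field\n")
  cat("  channels:", paste(names(object@channelRoles), collapse = ", "), "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@plaqueTable), "plaques,",
      nrow(object@microgliaTable), "microglia,",
      nrow(object@spotPositions), "spots\n")
})

setMethod("show", "GroupSpec", function(object) {
  cat("GroupSpec", object@name,
      if (object@treatment != "none") paste0("(", object@treatment, ")") else "",
      "\n  plaques/FOV:", object@plaqueDensity,
      " microglia/FOV:", object@microgliaBaseDensity,
      " abeta slope:", object@abetaSlope,
      " spots/frame:", object@spotRate, "\n")
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", length(object@groups), "groups x",
      object@micePerGroup, "mice x", object@fovsPerMouse, "FOVs, seed",
      object@seed, "\n")
})

setMethod("show", "FeatureBankConfig", function(object) {
  cat("FeatureBankConfig:", length(object@sigmas), "scales (",
      paste(object@sigmas, collapse = ", "), "),", nFeatures(object),
      "feature planes\n")
})

setMethod("show", "PixelClassifier", function(object) {
  cat("PixelClassifier: random forest,", object@nFeatures, "features,",
      object@forest$ntree, "trees\n")
})
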
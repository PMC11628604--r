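# Trainable pixel classification over a multi-scale filter bank, the semantic
# segmentation stage for both the plaque and the microglia channel.

#' Compute the multi-scale feature stack of a channel
#'
#' Builds the classifier's feature planes: the raw image (identity) once,
#' then, filter-major and sigma-minor, per-scale Gaussian blur,
#' difference-of-gaussians (sigma vs 1.6 sigma), Gaussian gradient magnitude,
#' Laplacian-of-gaussian, the two ordered Hessian eigenvalues, and (when
#' configured) square-window mean and max filters of side `2*sigma + 1`.
#' Boundaries are handled by mirror reflection everywhere.
#'
#' @param channel numeric matrix.
#' @param config a [FeatureBankConfig-class].
#' @return numeric array `nx x ny x F` with named planes;
#'   `F == nFeatures(config)`.
#' @examples
#' st <- computeFeatureStack(matrix(runif(64 * 64), 64), featureBank("plaque"))
#' dim(st)[3] # 25
#' @export
computeFeatureStack <- function(channel, config) {
  stopifnot(is.matrix(channel), is(config, "FeatureBankConfig"))
  validObject(config)
  if (length(channel) == 0L) stop("channel is empty")
  if (max(config@sigmas) > max(dim(channel)))
    warning("largest sigma exceeds the image extent; planes computed under reflection")
  nx <- nrow(channel); ny <- ncol(channel)
  planes <- list(identity = channel)
  blurred <- lapply(config@sigmas, function(s) gaussBlur(channel, s))
  names(blurred) <- as.character(config@sigmas)
  for (f in config@filters) {
    for (i in seq_along(config@sigmas)) {
      s <- config@sigmas[i]
      b <- blurred[[i]]
      tag <- function(p) paste0(p, "_s", s)
      if (f == "gaussian") {
        planes[[tag("gaussian")]] <- b
      } else if (f == "dog") {
        planes[[tag("dog")]] <- b - gaussBlur(channel, 1.6 * s)
      } else if (f == "gradient_magnitude") {
        g <- imageGradient(b)
        planes[[tag("gradmag")]] <- sqrt(g$gx^2 + g$gy^2)
      } else if (f == "log") {
        h <- imageHessian(b)
        planes[[tag("log")]] <- h$dxx + h$dyy
      } else if (f == "hessian_eig") {
        h <- imageHessian(b)
        tr <- h$dxx + h$dyy
        disc <- sqrt(pmax((h$dxx - h$dyy)^2 + 4 * h$dxy^2, 0))
        planes[[tag("hess1")]] <- (tr + disc) / 2
        planes[[tag("hess2")]] <- (tr - disc) / 2
      } else if (f == "mean") {
        planes[[tag("mean")]] <- boxFilter(channel, s, "mean")
      } else if (f == "max") {
        planes[[tag("max")]] <- boxFilter(channel, s, "max")
      }
    }
  }
  stack <- array(unlist(planes, use.names = FALSE), dim = c(nx, ny, length(planes)),
                 dimnames = list(NULL, NULL, names(planes)))
  stack
}

labelMatrixFromSparse <- function(labels, nx, ny) {
  # labels: data.frame (x, y, class) with class in {"background", "foreground"}
  # or 0/1; returns integer matrix 0 = unlabelled, 1 = background, 2 = fg.
  lm <- matrix(0L, nx, ny)
  cls <- labels$class
  if (is.character(cls) || is.factor(cls))
    cls <- ifelse(as.character(cls) == "foreground", 2L, 1L)
  else cls <- ifelse(cls > 0, 2L, 1L)
  lm[cbind(as.integer(labels$x), as.integer(labels$y))] <- cls
  lm
}

#' Train a random-forest pixel classifier
#'
#' @param stack feature array from [computeFeatureStack()].
#' @param labels either an integer matrix of the stack's spatial dims with
#'   0 = unlabelled, 1 = background, 2 = foreground, or a sparse data.frame
#'   with columns `x, y, class` (class `"foreground"`/`"background"`).
#' @param config the [FeatureBankConfig-class] used to build `stack`.
#' @param ntree number of trees (default 100).
#' @param seed RNG seed for the forest (default 1).
#' @return a [PixelClassifier-class].
#' @export
trainPixelClassifier <- function(stack, labels, config, ntree = 100L, seed = 1L) {
  stopifnot(length(dim(stack)) == 3L)
  nx <- dim(stack)[1]; ny <- dim(stack)[2]
  if (is.data.frame(labels)) labels <- labelMatrixFromSparse(labels, nx, ny)
  stopifnot(identical(dim(labels), c(nx, ny)))
  sel <- which(labels > 0L)
  if (length(sel) < 2L) stop("need labelled pixels for both classes")
  y <- factor(ifelse(labels[sel] == 2L, "foreground", "background"),
              levels = c("background", "foreground"))
  if (length(unique(y)) < 2L)
    stop("labels contain a single class; both foreground and background are required")
  X <- matrix(stack, nx * ny, dim(stack)[3])[sel, , drop = FALSE]
  colnames(X) <- dimnames(stack)[[3]]
  forest <- withSeed(seed, randomForest::randomForest(
    x = X, y = y, ntree = as.integer(ntree)))
  new("PixelClassifier", forest = forest, bank = config,
      nFeatures = dim(stack)[3])
}

#' Predict a semantic mask with a trained pixel classifier
#'
#' @param model a [PixelClassifier-class].
#' @param channel numeric matrix (same modality the model was trained on).
#' @param config a [FeatureBankConfig-class]; must match the training bank.
#' @return logical mask (TRUE = foreground) with a `"provenance"` attribute.
#' @export
predictMask <- function(model, channel, config = model@bank) {
  stopifnot(is(model, "PixelClassifier"))
  nf <- nFeatures(config)
  if (nf != model@nFeatures)
    stop("feature bank mismatch: model expects ", model@nFeatures,
         " features, config produces ", nf)
  stack <- computeFeatureStack(channel, config)
  X <- matrix(stack, prod(dim(channel)), dim(stack)[3])
  colnames(X) <- dimnames(stack)[[3]]
  pred <- predict(model@forest, X)
  mask <- matrix(pred == "foreground", nrow(channel), ncol(channel))
  attr(mask, "provenance") <- "random_forest"
  mask
}

#' Threshold the plaque channel into a binary mask
#'
#' Otsu thresholding with a class-separation guard: after thresholding, the
#' foreground mean must exceed the background mean by at least `noiseFloorK`
#' background standard deviations, otherwise the field is declared unstained
#' and the mask is empty (Otsu splits pure noise in half; real staining
#' separates by far more). Set `noiseFloorK = 0` to disable the guard.
#'
#' @param channel numeric matrix.
#' @param method `"otsu"` (default) or a fixed numeric threshold.
#' @param noiseFloorK separation requirement in background SDs (default 5).
#' @return logical mask with a `"provenance"` attribute; a constant channel
#'   under Otsu yields an empty mask with a warning.
#' @examples
#' m <- thresholdPlaques(rbind(matrix(0, 16, 32), matrix(1, 16, 32)))
#' mean(m) # 0.5
#' @export
thresholdPlaques <- function(channel, method = "otsu", noiseFloorK = 5) {
  stopifnot(is.matrix(channel), length(channel) > 0L)
  if (is.numeric(method)) {
    mask <- channel > method
    attr(mask, "provenance") <- paste0("fixed:", method)
    return(mask)
  }
  if (!identical(method, "otsu")) stop("method must be 'otsu' or a numeric threshold")
  rng <- range(channel)
  if (diff(rng) < .Machine$double.eps) {
    warning("constant channel: Otsu threshold undefined, returning empty mask")
    mask <- matrix(FALSE, nrow(channel), ncol(channel))
    attr(mask, "provenance") <- "otsu"
    return(mask)
  }
  scaled <- (channel - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  mask <- scaled > thr
  if (noiseFloorK > 0 && any(mask) && any(!mask)) {
    sep <- mean(scaled[mask]) - mean(scaled[!mask])
    if (sep < noiseFloorK * max(sd(scaled[!mask]), .Machine$double.eps))
      mask[] <- FALSE
  }
  attr(mask, "provenance") <- "otsu"
  mask
}
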
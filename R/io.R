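# Readers and writers: 8-bit PNG/TIFF images, 16-bit TIFF label masks,
# marker CSV tables, JSON model and summary files.

#' Read an RGB image
#'
#' Decodes an 8-bit PNG or TIFF file into a height x width x 3 array with
#' values 0..255. A grayscale image is replicated to three channels with a
#' warning; an alpha channel is dropped.
#'
#' @param path file path (.png, .tif or .tiff).
#' @param pixelSizeUm physical pixel size attached as attribute
#'   "pixelSizeUm" (default 0.5 um).
#' @return RGB array, 0..255.
#' @export
readRGBImage <- function(path, pixelSizeUm = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path),
    error = function(e) stop("not a decodable ", toupper(ext),
                             " image: ", path, " (", conditionMessage(e), ")",
                             call. = FALSE))
  if (is.matrix(img)) {
    warning("grayscale input replicated to 3 channels: ", path, call. = FALSE)
    img <- array(rep(img, 3L), c(dim(img), 3L))
  }
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  out <- round(img * 255)
  attr(out, "pixelSizeUm") <- pixelSizeUm
  out
}

#' Write an RGB image
#'
#' @param image RGB array, 0..255.
#' @param path output path; extension selects PNG or TIFF.
#' @return invisibly, the path.
#' @export
writeRGBImage <- function(image, path) {
  .assertRGB(image)
  x <- image / 255
  attributes(x) <- list(dim = dim(image))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) tiff::writeTIFF(x, path, bits.per.sample = 8L)
  else png::writePNG(x, path)
  invisible(path)
}

#' Read / write point-marker tables
#'
#' Markers are CSV files with header \code{x,y[,class]}: 0-based pixel
#' coordinates (x = column, y = row) and an optional class of "positive",
#' "negative" or "unspecified" (missing class defaults to "unspecified").
#' A write followed by a read preserves every marker exactly.
#'
#' @param path CSV file path.
#' @return data.frame with columns x, y, class.
#' @export
readMarkers <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop("marker CSV needs an x,y[,class] header", call. = FALSE)
  if (nrow(df) == 0L)
    return(data.frame(x = numeric(), y = numeric(), class = character(),
                      stringsAsFactors = FALSE))
  if (!"class" %in% names(df)) df$class <- "unspecified"
  .checkMarkers(df)
  if (any(!df$class %in% c("positive", "negative", "unspecified")))
    stop("marker classes must be positive, negative or unspecified", call. = FALSE)
  df[, c("x", "y", "class")]
}

#' @rdname readMarkers
#' @param markers data.frame with x, y and optionally class.
#' @export
writeMarkers <- function(markers, path) {
  if (!"class" %in% names(markers)) markers$class <- "unspecified"
  .checkMarkers(markers)
  write.csv(markers[, c("x", "y", "class")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read / write label masks
#'
#' Label masks are stored as single-channel 16-bit TIFF with the pixel
#' value equal to the label id (0 = background); the round trip is
#' bit-exact for up to 65535 objects.
#'
#' @param path TIFF file path.
#' @return integer label matrix.
#' @export
readLabelMask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' @rdname readLabelMask
#' @param labels integer label matrix (max 65535).
#' @export
writeLabelMask <- function(labels, path) {
  stopifnot(is.matrix(labels), max(labels) <= 65535L)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Save / load a trained network as JSON
#'
#' Serialises the architecture, weights, feature standardisation, class
#' order and training metadata of an \code{\link{MLPModel}}; loading
#' reconstructs a model whose predictions are identical.
#'
#' @param model an \code{MLPModel}.
#' @param path JSON file path.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "MLPModel"))
  jsonlite::write_json(list(
    type = "ihcseg-mlp", version = 1L,
    dims = c(nrow(model@W1), ncol(model@W1), ncol(model@W2)),
    W1 = model@W1, b1 = model@b1, W2 = model@W2, b2 = model@b2,
    center = model@center, scale = model@scale, classes = model@classes,
    featureNames = model@featureNames, meta = model@meta),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @return \code{loadModel}: the reconstructed \code{MLPModel}.
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$type) || j$type != "ihcseg-mlp")
    stop("not an ihcseg model file: ", path, call. = FALSE)
  new("MLPModel",
      W1 = matrix(j$W1, j$dims[1L], j$dims[2L]),
      b1 = as.numeric(j$b1),
      W2 = matrix(j$W2, j$dims[2L], j$dims[3L]),
      b2 = as.numeric(j$b2),
      center = as.numeric(j$center), scale = as.numeric(j$scale),
      classes = as.character(j$classes),
      featureNames = as.character(j$featureNames),
      meta = as.list(j$meta))
}

#' Write a JSON result summary
#'
#' Stores the nucleus counts, positive ratio and an echo of the
#' configuration used, for downstream reporting.
#'
#' @param table a \code{\link{NucleusTable}}.
#' @param cfg the \code{\link{PipelineConfig}} used.
#' @param path JSON file path.
#' @export
writeSummary <- function(table, cfg, path) {
  stopifnot(is(table, "NucleusTable"), is(cfg, "PipelineConfig"))
  cfgList <- sapply(slotNames(cfg), function(s) slot(cfg, s),
                    simplify = FALSE)
  jsonlite::write_json(list(summary = table@summary, config = cfgList),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
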
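#' Read an image as a grayscale matrix
#'
#' Reads PNG (via the png package) or JPEG/TIFF (via EBImage) into a numeric
#' matrix in [0, 1], rows indexing image rows top-to-bottom. RGB images are
#' collapsed by an unweighted channel mean (no perceptual weighting is
#' claimed anywhere downstream).
#'
#' @param path image file path.
#' @return Numeric matrix in [0, 1].
#' @export
readImageGray <- function(path) {
  if (!file.exists(path)) {
    stop("image file not found: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg", "tif", "tiff")) {
    # EBImage images are (x, y[, c]) = (col, row); transpose to row-major
    eb <- EBImage::readImage(path)
    a <- unclass(eb@.Data)
    img <- if (length(dim(a)) == 2L) {
      t(a)
    } else {
      aperm(a, c(2, 1, 3))
    }
  } else {
    stop(
      "unsupported image format '.", ext,
      "': PNG, JPEG and TIFF are supported"
    )
  }
  toGray(img)
}

# collapse an [0,1] array to a grayscale matrix by unweighted channel mean
toGray <- function(img) {
  if (length(dim(img)) == 3L) {
    nc <- min(dim(img)[3], 3L) # drop alpha
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  img
}

#' Read a binary ground-truth mask
#'
#' Grayscale mask images are binarized at intensity > 127/255; hand-drawn
#' masks are frequently antialiased at object borders and the midpoint
#' threshold resolves border pixels deterministically.
#'
#' @param path image file path.
#' @param threshold binarization threshold on the [0, 1] intensity scale.
#' @return Logical matrix; \code{TRUE} marks target pixels.
#' @export
readMask <- function(path, threshold = 127 / 255) {
  readImageGray(path) > threshold
}

#' Read a saliency map
#'
#' Accepts 8/16-bit grayscale images (PNG/JPEG/TIFF) or plain-text numeric
#' matrices (whitespace- or comma-separated), converted to a common
#' nonnegative numeric matrix. No normalization is applied or assumed: only
#' the location of the global maximum is used downstream.
#'
#' @param path file path.
#' @return Nonnegative numeric matrix.
#' @export
readSaliencyMap <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("txt", "tsv", "csv", "dat")) {
    sep <- if (ext == "csv") "," else ""
    as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  } else {
    readImageGray(path)
  }
  if (any(!is.finite(m))) {
    stop("saliency map contains non-finite values: ", path)
  }
  if (any(m < 0)) {
    stop("saliency map contains negative values: ", path)
  }
  dimnames(m) <- NULL
  m
}

#' Write a grayscale image or binary mask as PNG
#'
#' @param image numeric matrix in [0, 1] or logical matrix.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeImagePNG <- function(image, path) {
  if (is.logical(image)) {
    image <- image * 1
  }
  stopifnot(all(is.finite(image)), min(image) >= 0, max(image) <= 1)
  png::writePNG(image, path)
  invisible(path)
}

#' Load a stimulus manifest
#'
#' Reads a UTF-8 CSV manifest with header columns \code{image}, \code{mask},
#' \code{target_present}, \code{dataset} (an \code{id} column is honoured if
#' present, otherwise ids are derived from image file names). Relative paths
#' are resolved against the manifest's directory. Every image and mask is
#' read and validated: a target-present row must have a nonempty mask of the
#' image's shape; a target-absent row must have an empty \code{mask} field.
#'
#' @param path manifest CSV path.
#' @param loadImages keep image pixel data in the returned set (needed by
#'   image-based predictors such as [contrastBaseline()]).
#' @return A [StimulusSet-class].
#' @export
loadManifest <- function(path, loadImages = FALSE) {
  if (!file.exists(path)) {
    stop("manifest not found: ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "mask", "target_present", "dataset")
  if (!all(need %in% names(df))) {
    stop(
      "manifest must have columns: ",
      paste(setdiff(need, names(df)), collapse = ", ")
    )
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(is.na(p) | p == "", NA_character_,
      ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
    )
  }
  if (nrow(df) == 0L) {
    warning("empty manifest: ", path)
    return(new("StimulusSet",
      manifest = data.frame(
        id = character(), image = character(), mask = character(),
        targetPresent = logical(), dataset = character(),
        stringsAsFactors = FALSE
      ),
      masks = list(), images = list(), imageShape = c(1L, 1L)
    ))
  }
  man <- data.frame(
    id = if ("id" %in% names(df)) {
      as.character(df$id)
    } else {
      tools::file_path_sans_ext(basename(df$image))
    },
    image = resolve(df$image),
    mask = resolve(df$mask),
    targetPresent = as.logical(df$target_present),
    dataset = as.character(df$dataset),
    stringsAsFactors = FALSE
  )
  masksList <- list()
  imagesList <- list()
  shape <- NULL
  for (i in seq_len(nrow(man))) {
    img <- readImageGray(man$image[i])
    if (is.null(shape)) {
      shape <- dim(img)
    } else if (!identical(dim(img), shape)) {
      stop(sprintf(
        "image '%s' has shape %dx%d; expected %dx%d",
        man$id[i], nrow(img), ncol(img), shape[1], shape[2]
      ))
    }
    if (man$targetPresent[i]) {
      if (is.na(man$mask[i])) {
        stop("target-present row '", man$id[i], "' has no mask path")
      }
      mk <- readMask(man$mask[i])
      if (!identical(dim(mk), dim(img))) {
        stop(sprintf(
          "mask of '%s' has shape %dx%d but its image is %dx%d",
          man$id[i], nrow(mk), ncol(mk), nrow(img), ncol(img)
        ))
      }
      if (!any(mk)) {
        stop("mask of target-present row '", man$id[i], "' is empty")
      }
      masksList[[man$id[i]]] <- mk
    } else if (!is.na(man$mask[i])) {
      stop("target-absent row '", man$id[i], "' lists a mask path")
    }
    if (loadImages) {
      imagesList[[man$id[i]]] <- img
    }
  }
  message(sprintf(
    "loaded %d records (%d target-present) from %s",
    nrow(man), sum(man$targetPresent), path
  ))
  new("StimulusSet",
    manifest = man, masks = masksList, images = imagesList,
    imageShape = as.integer(shape)
  )
}

#' Location of the global maximum of a saliency map
#'
#' The predicted first attended point P is the global maximum of the
#' conspicuity field. Ties are broken by the first occurrence in row-major
#' order (scanning rows top to bottom, columns left to right), so a
#' constant map yields (0, 0).
#'
#' @param map nonnegative numeric matrix.
#' @return Integer(2), 0-based (row, col) of the maximum.
#' @examples
#' m <- matrix(0, 5, 9)
#' m[4, 8] <- 1
#' peakLocation(m) # (3, 7)
#' @export
peakLocation <- function(map) {
  if (!is.matrix(map) || length(map) == 0L) {
    stop("map must be a nonempty matrix")
  }
  if (all(is.na(map))) {
    stop("map is all-NA")
  }
  tm <- t(map) # row-major scan of `map` = column-major scan of t(map)
  i <- which.max(tm)
  row0 <- (i - 1L) %/% nrow(tm)
  col0 <- (i - 1L) %% nrow(tm)
  c(row = row0, col = col0)
}

#' Area and centroid of a binary mask
#'
#' @param mask logical matrix.
#' @return List with \code{area} (foreground pixel count) and
#'   \code{centroid}, the mean of the foreground pixel coordinates as
#'   0-based fractional (row, col).
#' @examples
#' m <- matrix(FALSE, 10, 10)
#' m[3, 4] <- TRUE
#' maskStats(m) # area 1, centroid (2, 3)
#' @export
maskStats <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  idx <- which(mask, arr.ind = TRUE) - 1L
  if (nrow(idx) == 0L) {
    stop("mask is empty: centroid undefined")
  }
  list(
    area = nrow(idx),
    centroid = c(row = mean(idx[, 1]), col = mean(idx[, 2]))
  )
}

#' Write a StimulusSet to disk
#'
#' Writes PNG images and masks plus a manifest CSV that [loadManifest()]
#' reads back. Requires pixel data (generate with \code{images = TRUE}).
#'
#' @param set a [StimulusSet-class] with image data.
#' @param dir output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
writeStimulusSet <- function(set, dir) {
  stopifnot(is(set, "StimulusSet"))
  man <- set@manifest
  if (length(set@images) < nrow(man)) {
    stop("set has no pixel data; regenerate with images = TRUE")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rel <- data.frame(
    id = man$id,
    image = paste0(man$id, ".png"),
    mask = ifelse(man$targetPresent, paste0(man$id, "_mask.png"), ""),
    target_present = man$targetPresent,
    dataset = man$dataset,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(man))) {
    writeImagePNG(set@images[[man$id[i]]], file.path(dir, rel$image[i]))
    if (man$targetPresent[i]) {
      writeImagePNG(set@masks[[man$id[i]]], file.path(dir, rel$mask[i]))
    }
  }
  manifestPath <- file.path(dir, "manifest.csv")
  utils::write.csv(rel, manifestPath, row.names = FALSE)
  invisible(manifestPath)
}
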
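# Image and ROI input: 8-bit RGB photographs, binary mask PNGs, polygon ROIs.

#' RGB image container
#'
#' Wraps an H x W x 3 array of intensities in `[0, 1]` (stored 8-bit values
#' divided by 255). Channel order is always R, G, B.
#'
#' @param pixels numeric H x W x 3 array with all values in `[0, 1]`.
#' @return an object of class `rgb_image` with elements `pixels`, `height`,
#'   `width`.
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop("`pixels` must be an H x W x 3 array (channels R, G, B)")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("pixel intensities must lie in [0, 1]")
  }
  structure(
    list(pixels = pixels, height = dim(pixels)[1], width = dim(pixels)[2]),
    class = "rgb_image"
  )
}

#' Load an 8-bit RGB photograph
#'
#' Reads a PNG or JPEG wound photograph into an [rgb_image()]. Stored 8-bit
#' values are scaled to `[0, 1]` by division by 255; an alpha channel, if
#' present, is dropped.
#'
#' @param path path to an 8-bit RGB PNG or JPEG file.
#' @return an `rgb_image`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop("cannot decode PNG ", path, ": ",
                                             conditionMessage(e)))
    info <- attr(arr, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8) {
      stop("unsupported bit depth (", info$bit.depth, ") in ", path,
           "; only 8-bit images are accepted")
    }
    attributes(arr) <- list(dim = dim(arr))
  } else if (ext %in% c("jpg", "jpeg")) {
    img <- tryCatch(EBImage::readImage(path),
                    error = function(e) stop("cannot decode JPEG ", path, ": ",
                                             conditionMessage(e)))
    dat <- EBImage::imageData(img)
    # EBImage stores x (width) first; transpose to row-major H x W x C.
    arr <- if (length(dim(dat)) == 2) t(dat) else aperm(dat, c(2, 1, 3))
  } else {
    stop("unsupported image format '", ext, "' for ", path,
         " (PNG or JPEG required)")
  }
  if (length(dim(arr)) < 3 || dim(arr)[3] < 3) {
    stop("image ", path, " is not RGB (need 3 color channels, got ",
         if (length(dim(arr)) < 3) 1 else dim(arr)[3], ")")
  }
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE]
  rgb_image(pmin(pmax(arr, 0), 1))
}

#' Write an RGB image to PNG
#'
#' @param image an [rgb_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  write_atomic(path, function(tmp) png::writePNG(image$pixels, tmp))
}

#' Load a region-of-interest mask
#'
#' Reads an 8-bit single-channel PNG in which nonzero pixels mark the region
#' of interest, or a JSON polygon file `{"image_id": ..., "polygons":
#' [[[x, y], ...], ...]}` rasterized with [polygon_to_mask()].
#'
#' @param path mask PNG or polygon JSON path.
#' @param height,width image dimensions the mask must match (required for
#'   polygon input, checked for mask input).
#' @return logical H x W matrix.
#' @export
load_roi_mask <- function(path, height = NULL, width = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3) arr <- arr[, , 1]
    mask <- arr > 0
  } else if (ext == "json") {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(height) || is.null(width)) {
      stop("polygon ROI requires the image height and width")
    }
    polys <- spec$polygons
    if (is.array(polys) && length(dim(polys)) == 3) {
      polys <- lapply(seq_len(dim(polys)[1]), function(i) polys[i, , ])
    } else if (is.matrix(polys)) {
      polys <- list(polys)
    } else {
      polys <- lapply(polys, function(p) {
        if (is.matrix(p)) p else do.call(rbind, p)
      })
    }
    mask <- Reduce(`|`, lapply(polys, polygon_to_mask,
                               height = height, width = width))
  } else {
    stop("unsupported ROI format '", ext, "' for ", path)
  }
  if (!is.null(height) && !identical(dim(mask), c(as.integer(height),
                                                  as.integer(width)))) {
    stop("ROI mask dimensions ", paste(dim(mask), collapse = "x"),
         " do not match image ", height, "x", width)
  }
  if (!any(mask)) stop("ROI mask is empty: ", path)
  mask
}

#' Rasterize a polygon ROI
#'
#' Pixel coordinates are 0-based with the origin at the top-left; the integer
#' point (x, y) is the center of the pixel in row y, column x. A pixel is
#' included when its center falls inside the polygon under the even-odd
#' (ray-crossing) rule.
#'
#' @param vertices n x 2 matrix of (x, y) polygon vertices.
#' @param height,width output mask dimensions.
#' @return logical `height` x `width` matrix.
#' @export
polygon_to_mask <- function(vertices, height, width) {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2, nrow(v) >= 3)
  px <- rep(0:(width - 1), each = height)   # column-major over (row, col)
  py <- rep(0:(height - 1), times = width)
  inside <- rep(FALSE, length(px))
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nrow = height, ncol = width)
}

#' Mean channel intensities over regions of interest
#'
#' Averages each color channel over the union of one or more ROI masks,
#' counting every pixel once (multiple ROIs are therefore combined
#' area-weighted into a single per-image value).
#'
#' @param image an [rgb_image()].
#' @param rois a logical mask matrix or a list of them.
#' @return list with `mean` and `sem`, each a named numeric vector
#'   `(r, g, b)`, and `n_pixels`.
#' @export
roi_channel_means <- function(image, rois) {
  stopifnot(inherits(image, "rgb_image"))
  if (is.matrix(rois)) rois <- list(rois)
  if (length(rois) < 1) stop("at least one ROI is required")
  for (m in rois) {
    if (!identical(dim(m), dim(image$pixels)[1:2])) {
      stop("ROI dimensions do not match the image")
    }
    if (!any(m)) stop("degenerate ROI: no included pixels")
  }
  union <- Reduce(`|`, rois)
  idx <- which(union)
  ch <- vapply(1:3, function(c) mean(image$pixels[, , c][idx]), numeric(1))
  se <- vapply(1:3, function(c) sem(image$pixels[, , c][idx]), numeric(1))
  names(ch) <- names(se) <- c("r", "g", "b")
  list(mean = ch, sem = se, n_pixels = length(idx))
}

#' Quality-control thresholds
#'
#' @param glare_max maximum tolerated fraction of near-saturated ROI pixels.
#' @param blur_min minimum Laplacian variance of luminance (focus floor).
#' @param blood_threshold red dominance (`R - max(G, B)`) above which a pixel
#'   counts as blood.
#' @param blood_max maximum tolerated blood pixel fraction.
#' @return list of thresholds.
#' @export
qc_thresholds <- function(glare_max = 0.05, blur_min = 1e-4,
                          blood_threshold = 0.25, blood_max = 0.50) {
  list(glare_max = glare_max, blur_min = blur_min,
       blood_threshold = blood_threshold, blood_max = blood_max)
}

# 3x3 Laplacian (4-neighbour) of a matrix; returned for the interior only,
# as an (H-2) x (W-2) matrix.
laplacian3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  if (h < 3 || w < 3) return(matrix(numeric(0), 0, 0))
  c0 <- m[2:(h - 1), 2:(w - 1)]
  4 * c0 - m[1:(h - 2), 2:(w - 1)] - m[3:h, 2:(w - 1)] -
    m[2:(h - 1), 1:(w - 2)] - m[2:(h - 1), 3:w]
}

#' Screen a wound photograph for glare, blur and blood
#'
#' Computes over the ROI: the fraction of pixels with any channel at or above
#' 250/255 (glare), the variance of a 3x3 Laplacian of the luminance
#' `(R + G + B) / 3` (focus), and the fraction of pixels whose red channel
#' dominates by more than the blood threshold. The image passes when all
#' three checks meet their thresholds.
#'
#' @param image an [rgb_image()].
#' @param roi logical ROI mask.
#' @param thresholds a [qc_thresholds()] list.
#' @return list of class `qc_report`: `glare_fraction`, `blur_score`,
#'   `blood_fraction`, `pass`, `reasons`.
#' @export
qc_screen <- function(image, roi, thresholds = qc_thresholds()) {
  stopifnot(inherits(image, "rgb_image"))
  if (!identical(dim(roi), dim(image$pixels)[1:2])) {
    stop("ROI dimensions do not match the image")
  }
  px <- image$pixels
  idx <- which(roi)
  r <- px[, , 1][idx]; g <- px[, , 2][idx]; b <- px[, , 3][idx]
  glare <- mean(r >= 250 / 255 | g >= 250 / 255 | b >= 250 / 255)
  blood <- mean((r - pmax(g, b)) > thresholds$blood_threshold)
  lum <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  lap <- laplacian3(lum)
  roi_int <- roi[2:(nrow(roi) - 1), 2:(ncol(roi) - 1)]
  blur <- if (any(roi_int)) stats::var(lap[roi_int]) else 0
  if (!is.finite(blur)) blur <- 0
  reasons <- character(0)
  if (glare > thresholds$glare_max) reasons <- c(reasons, "glare")
  if (blur < thresholds$blur_min) reasons <- c(reasons, "blur")
  if (blood > thresholds$blood_max) reasons <- c(reasons, "blood")
  structure(list(glare_fraction = glare, blur_score = blur,
                 blood_fraction = blood, pass = length(reasons) == 0,
                 reasons = reasons),
            class = "qc_report")
}

# Canonical names for the 7 raw spectral indices.
raw_index_names <- function() {
  c("r", "g", "b", "r_minus_b", "r_minus_g", "rb_over_g", "rb_over_r2b2")
}

# Per-pixel value of one raw index; zero-denominator pixels -> NA.
pixel_index <- function(px, index) {
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  switch(index,
    r = r, g = g, b = b,
    r_minus_b = r - b,
    r_minus_g = r - g,
    rb_over_g = { v <- (r - b) / g; v[g == 0] <- NA_real_; v },
    rb_over_r2b2 = {
      d <- r^2 + b^2
      v <- (r - b) / d
      v[d == 0] <- NA_real_
      v
    },
    stop("unknown index '", index, "'; expected one of ",
         paste(raw_index_names(), collapse = ", "))
  )
}

#' Render a contrast-enhanced grayscale index map
#'
#' Evaluates one raw spectral index per pixel and linearly rescales it so the
#' 1st and 99th percentiles map to 0 and 1 (clipping beyond), giving the
#' contrast-enhanced grayscale rendering in which brighter regions carry
#' higher index values. Pixels where the index denominator is zero render as
#' black.
#'
#' @param image an [rgb_image()].
#' @param index one of `r`, `g`, `b`, `r_minus_b`, `r_minus_g`, `rb_over_g`,
#'   `rb_over_r2b2`.
#' @return H x W numeric matrix in `[0, 1]`.
#' @export
render_index_map <- function(image, index) {
  stopifnot(inherits(image, "rgb_image"))
  index <- match.arg(index, raw_index_names())
  v <- pixel_index(image$pixels, index)
  ok <- is.finite(v)
  q <- stats::quantile(v[ok], c(0.01, 0.99), names = FALSE)
  out <- if (q[2] > q[1]) {
    pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1)
  } else {
    # constant field: uniform mid-gray
    v * 0 + 0.5
  }
  out[!ok] <- 0
  out
}
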
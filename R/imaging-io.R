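#' Read a single image file as an 8-bit greyscale matrix
#'
#' Reads PNG or TIFF, converts RGB to greyscale with standard luminance
#' weights (0.299 R + 0.587 G + 0.114 B), and rescales to `[0, 255]`.
#'
#' @param path image file path (`.png`, `.tif`, `.tiff`).
#' @return numeric matrix (rows x cols) with intensities in `[0, 255]`.
#' @export
readGreyFrame <- function(path) {
  if (!file.exists(path))
    stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for ", path)
  )
  toGrey255(arr)
}

# array in [0,1] (matrix, or H x W x {2,3,4}) -> greyscale matrix in [0,255]
toGrey255 <- function(arr) {
  if (is.matrix(arr)) {
    g <- arr
  } else if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch >= 3L) {
      g <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      g <- arr[, , 1]  # grey + alpha
    }
  } else {
    stop("unsupported image array layout")
  }
  pmin(pmax(g * 255, 0), 255)
}

#' Load an ordered image series
#'
#' Builds a \linkS4class{FrameSeries} from image files. Timestamps derive
#' from the configured capture interval (index times `interval_s`), not from
#' file modification times, so a reloaded series is reproducible. A manifest
#' data frame (columns `path`, `t_seconds`) may instead supply explicit
#' per-frame times.
#'
#' @param paths character vector of image paths, in capture order.
#' @param interval_s capture interval in seconds (60 for the 24 h growth
#'   regime, 4 for the 1 h vein regime).
#' @param manifest optional data frame (or CSV path) with columns `path`,
#'   `t_seconds`; overrides `paths`/`interval_s`.
#' @return a \linkS4class{FrameSeries}.
#' @examples
#' f <- matrix(200, 20, 20)
#' p <- file.path(tempdir(), sprintf("f%02d.png", 1:3))
#' for (pp in p) png::writePNG(f / 255, pp)
#' fs <- loadFrameSeries(p, interval_s = 60)
#' timestamps(fs)
#' @export
loadFrameSeries <- function(paths, interval_s = 60, manifest = NULL) {
  if (!is.null(manifest)) {
    if (is.character(manifest) && length(manifest) == 1L)
      manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    stopifnot(all(c("path", "t_seconds") %in% names(manifest)))
    ord <- order(manifest$t_seconds)
    paths <- manifest$path[ord]
    times <- manifest$t_seconds[ord]
  } else {
    if (length(paths) < 1L) stop("at least one image path is required")
    times <- (seq_along(paths) - 1) * interval_s
  }
  frm <- lapply(paths, readGreyFrame)
  d <- dim(frm[[1L]])
  bad <- which(!vapply(frm, function(f) identical(dim(f), d), logical(1)))
  if (length(bad))
    stop("frame dimension mismatch at: ", paste(paths[bad], collapse = ", "))
  new("FrameSeries", frames = frm, timestamps = as.numeric(times),
      pixelPitch = NA_real_, sourcePaths = as.character(paths))
}

#' Construct a FrameSeries from in-memory rasters
#'
#' @param frames list of numeric matrices with intensities in `[0, 255]`.
#' @param interval_s capture interval in seconds, or `timestamps` directly.
#' @param timestamps optional explicit timestamps (seconds).
#' @param pixelPitch optional micrometres per pixel.
#' @return a \linkS4class{FrameSeries}.
#' @export
frameSeries <- function(frames, interval_s = 60, timestamps = NULL,
                        pixelPitch = NA_real_) {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.null(timestamps))
    timestamps <- (seq_along(frames) - 1) * interval_s
  new("FrameSeries", frames = frames, timestamps = as.numeric(timestamps),
      pixelPitch = as.numeric(pixelPitch),
      sourcePaths = rep("<memory>", length(frames)))
}

#' Non-local-means denoising of one frame
#'
#' Smooths sensor noise while preserving vein edges by averaging each pixel
#' with similar-patch pixels in a search window. Defaults follow the
#' processing configuration used for plasmodial recordings (filter strength
#' 8, 5 px template window, 21 px search window).
#'
#' @param frame numeric matrix, 8-bit greyscale.
#' @param strength filter strength h; 0 returns the input unchanged.
#' @param template_window odd patch size in pixels.
#' @param search_window search window size in pixels.
#' @return denoised matrix, same dimensions, values in `[0, 255]`.
#' @export
denoiseFrame <- function(frame, strength = 8, template_window = 5,
                         search_window = 21) {
  stopifnot(is.matrix(frame))
  if (template_window %% 2 == 0)
    stop("template_window must be odd")
  out <- nlm_denoise_cpp(frame, as.numeric(strength),
                         as.integer(template_window),
                         as.integer(search_window))
  pmin(pmax(out, 0), 255)
}

#' Calibrate the metric scale from a reference of known size
#'
#' @param known_length_px apparent length of the reference in pixels.
#' @param known_length_mm true physical length in millimetres (e.g. 92 for
#'   a standard 92 x 16 mm Petri dish diameter).
#' @param source description of the reference.
#' @return a \linkS4class{ScaleCalibration} with `pixelPitch` in um/px.
#' @examples
#' pixelPitch(calibrateScale(1000, 10))       # 10 um/px
#' pixelPitch(calibrateScale(3300, 92))       # ~27.88 um/px
#' @export
calibrateScale <- function(known_length_px, known_length_mm,
                           source = "reference object") {
  if (!is.finite(known_length_px) || known_length_px <= 0 ||
      !is.finite(known_length_mm) || known_length_mm <= 0)
    stop("calibration lengths must be positive")
  new("ScaleCalibration",
      pixelPitch = 1000 * known_length_mm / known_length_px,
      source = source)
}

sobelMagnitude <- function(frame) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::filter2(frame, kx, boundary = "replicate")
  gy <- EBImage::filter2(frame, t(kx), boundary = "replicate")
  sqrt(gx^2 + gy^2)
}

#' Detect the circular Petri-dish region of interest
#'
#' Finds the dish rim with a circle Hough transform on the gradient-edge map
#' and returns the interior disc as a boolean mask. When several centres
#' satisfy the radius bounds, the highest-voted circle wins, with ties broken
#' by proximity to the frame centre. The detected circle must also be
#' supported by rim edges along at least half its circumference; otherwise a
#' detection error advises supplying a manual ROI.
#'
#' @param frame greyscale matrix.
#' @param min_radius,max_radius admissible rim radius bounds in pixels.
#' @param min_dist minimum distance between competing circle centres (kept
#'   for interface compatibility; a single best circle is returned).
#' @param edge_threshold gradient magnitude above which a pixel is an edge.
#' @param vote_threshold minimum accumulator votes for a valid circle.
#' @param min_support minimum fraction of the circumference backed by edges.
#' @return a \linkS4class{ROIMask}.
#' @export
detectDishROI <- function(frame, min_radius, max_radius, min_dist = NULL,
                          edge_threshold = 100, vote_threshold = 30,
                          min_support = 0.5) {
  stopifnot(is.matrix(frame), min_radius >= 1, max_radius >= min_radius)
  edges <- sobelMagnitude(frame) > edge_threshold
  if (!any(edges))
    stop("no circular dish rim detected (no edges); supply a manual ROI")
  res <- hough_circle_cpp(edges, as.integer(min_radius),
                          as.integer(max_radius))
  ctr <- res[1:2]; r <- res[3]; votes <- res[4]
  if (votes < vote_threshold)
    stop("no circular dish rim detected within the radius bounds; ",
         "supply a manual ROI")
  # edge support along the fitted circumference
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  ri <- round(ctr[1] + r * sin(th)); ci <- round(ctr[2] + r * cos(th))
  supp <- mapply(function(i, j) {
    i0 <- max(1, i - 2); i1 <- min(nrow(edges), i + 2)
    j0 <- max(1, j - 2); j1 <- min(ncol(edges), j + 2)
    any(edges[i0:i1, j0:j1])
  }, ri, ci)
  if (mean(supp) < min_support)
    stop("candidate circle is poorly supported by rim edges; ",
         "supply a manual ROI")
  roiMask(center = ctr, radius = r, dim = dim(frame))
}

#' Build a circular ROI mask directly
#'
#' @param center (row, col) centre in pixels.
#' @param radius radius in pixels.
#' @param dim frame dimensions `c(rows, cols)`.
#' @return a \linkS4class{ROIMask}.
#' @export
roiMask <- function(center, radius, dim) {
  rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  mask <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
  new("ROIMask", center = as.numeric(center), radius = as.numeric(radius),
      mask = mask)
}

#' Mask a frame to the region of interest
#'
#' Pixels outside the ROI are set to the background fill (default 255, the
#' bright-agar convention, so inverse-binary thresholding never marks the
#' exterior as organism).
#'
#' @param frame greyscale matrix.
#' @param roi a \linkS4class{ROIMask}.
#' @param fill background value for pixels outside the ROI.
#' @return masked matrix, same dimensions.
#' @export
applyROI <- function(frame, roi, fill = 255) {
  if (!identical(dim(frame), dim(roi@mask)))
    stop("frame and ROI mask dimensions differ")
  frame[!roi@mask] <- fill
  frame
}
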
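#' Intensity image container
#'
#' @param pixels numeric matrix (grayscale) or H x W x 3 array (RGB) of
#'   intensities in [0, 1].
#' @param metadata named list; typically \code{box}, \code{side} (A-D) and
#'   \code{dap} parsed from the filename.
#' @return an object of class \code{intensity_image}.
#' @export
intensity_image <- function(pixels, metadata = list()) {
  d <- dim(pixels)
  if (is.null(d) || d[1] < 2 || d[2] < 2)
    stop("image must be at least 2 x 2", call. = FALSE)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  structure(list(pixels = pixels, metadata = metadata),
            class = "intensity_image")
}

#' Binary root-skeleton container
#'
#' @param mask 0/1 matrix; rows index depth downward (row 1 = gel surface).
#' @param side box face, one of "A", "B", "C", "D".
#' @param depth_calibration_mm physical depth spanned by the mask rows
#'   (default 33 mm, the gel column height).
#' @param metadata named list (box id, DAP, ...).
#' @return an object of class \code{root_skeleton}.
#' @export
root_skeleton <- function(mask, side, depth_calibration_mm = 33.0,
                          metadata = list()) {
  side <- match.arg(side, c("A", "B", "C", "D"))
  if (depth_calibration_mm <= 0)
    stop_field("depth_calibration_mm", "must be > 0")
  mask <- (mask > 0) * 1
  structure(list(mask = mask, side = side,
                 depth_calibration_mm = depth_calibration_mm,
                 metadata = metadata),
            class = "root_skeleton")
}

#' @export
print.root_skeleton <- function(x, ...) {
  cat(sprintf("<root_skeleton> side %s, %d x %d px, %d root px, depth %.1f mm\n",
              x$side, nrow(x$mask), ncol(x$mask), sum(x$mask),
              x$depth_calibration_mm))
  invisible(x)
}

#' Edge-detection and cleanup parameters
#'
#' @param gaussian_sigma Gaussian pre-smoothing sigma, pixels.
#' @param low_percentile,high_percentile hysteresis thresholds, taken as
#'   percentiles of the nonzero non-maximum-suppressed gradient magnitudes.
#' @param min_component_px connected components (8-connectivity) smaller than
#'   this are removed by \code{\link{clean_skeleton}}.
#' @param close_radius_px disk radius for morphological closing (gap
#'   bridging) before component filtering.
#' @param intensity_gate the "modified" part of the Canny stage: an edge
#'   candidate must sit on actual fluorescence, i.e. its smoothed intensity
#'   must reach this fraction of the image's bright reference level (99.9th
#'   percentile). Suppresses phantom contours on the dark outer foot of
#'   blur-merged root clusters; 0 disables the gate.
#' @return an object of class \code{canny_params}.
#' @export
canny_params <- function(gaussian_sigma = 0.6, low_percentile = 50,
                         high_percentile = 85, min_component_px = 20L,
                         close_radius_px = 2L, intensity_gate = 0.08) {
  if (gaussian_sigma < 0) stop_field("gaussian_sigma", "must be >= 0")
  if (low_percentile < 0 || high_percentile > 100 ||
      low_percentile >= high_percentile)
    stop_field("low_percentile/high_percentile",
               "need 0 <= low < high <= 100")
  if (min_component_px < 1) stop_field("min_component_px", "must be >= 1")
  if (close_radius_px < 0) stop_field("close_radius_px", "must be >= 0")
  if (intensity_gate < 0 || intensity_gate >= 1)
    stop_field("intensity_gate", "must be in [0, 1)")
  structure(list(gaussian_sigma = gaussian_sigma,
                 low_percentile = low_percentile,
                 high_percentile = high_percentile,
                 min_component_px = as.integer(min_component_px),
                 close_radius_px = as.integer(close_radius_px),
                 intensity_gate = intensity_gate),
            class = "canny_params")
}

#' Read a PNG or TIFF image
#'
#' Intensities are normalized to [0, 1] (8-bit PNGs by 255, 16-bit TIFFs by
#' 65535, as done by the underlying readers). Metadata (box id, side, DAP)
#' is parsed from filenames following \code{<box>_<side>_<DAP>.<ext>}.
#'
#' @param path file path to a .png, .tif or .tiff image.
#' @return an \code{\link{intensity_image}}.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  ext <- tolower(file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '%s' for '%s'", ext, path),
         call. = FALSE))
  if (length(dim(px)) == 3 && dim(px)[3] == 4)   # drop alpha
    px <- px[, , 1:3, drop = TRUE]
  if (length(dim(px)) == 3 && dim(px)[3] == 2)   # gray + alpha
    px <- px[, , 1, drop = TRUE]
  meta <- list(path = path)
  nm <- basename(file_path_sans_ext(path))
  m <- regmatches(nm, regexec("^(.+)_([ABCD])_([0-9]+)$", nm))[[1]]
  if (length(m) == 4)
    meta <- c(meta, list(box = m[2], side = m[3], dap = as.integer(m[4])))
  intensity_image(px, metadata = meta)
}

#' Isolate the green fluorescence channel
#'
#' For an RGB image, computes \code{G - alpha * max(R, B)} clamped at zero:
#' the GFP signal minus a fraction of the strongest competing channel, which
#' attenuates gray reflections and white-light artifacts while keeping
#' saturated green roots at full intensity. Grayscale images pass through
#' unchanged.
#'
#' @param image an \code{\link{intensity_image}}.
#' @param alpha competing-channel subtraction weight (default 0.5).
#' @return a single-channel \code{intensity_image}.
#' @export
extract_green_signal <- function(image, alpha = 0.5) {
  px <- image$pixels
  if (is.matrix(px)) return(image)
  g <- px[, , 2] - alpha * pmax(px[, , 1], px[, , 3])
  intensity_image(pmax(g, 0), metadata = image$metadata)
}

# Zero-padded shift of a matrix by (dr, dc).
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr
  cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Detect a root skeleton by Canny edge detection
#'
#' The classic Canny chain: Gaussian smoothing, Sobel gradients,
#' non-maximum suppression perpendicular to the edge, and hysteresis
#' thresholding. The two hysteresis thresholds are data-driven: the
#' \code{low_percentile} and \code{high_percentile} quantiles of the nonzero
#' gradient magnitudes that survive suppression, which makes the detector
#' insensitive to global illumination and exposure. A weak (low-threshold)
#' pixel is kept only if its 8-connected component contains a strong
#' (high-threshold) pixel. A constant image yields an empty mask.
#'
#' @param image a single-channel \code{\link{intensity_image}}.
#' @param params a \code{\link{canny_params}}.
#' @param side box face recorded on the result (taken from image metadata
#'   when present).
#' @param depth_calibration_mm depth spanned by the image rows, mm.
#' @return a \code{\link{root_skeleton}}.
#' @export
canny_skeleton <- function(image, params = canny_params(), side = NULL,
                           depth_calibration_mm = 33.0) {
  px <- image$pixels
  if (!is.matrix(px))
    stop("canny_skeleton needs a single-channel image; see extract_green_signal",
         call. = FALSE)
  if (is.null(side)) side <- image$metadata$side
  if (is.null(side)) side <- "A"
  sm <- if (params$gaussian_sigma > 0)
    EBImage::gblur(px, params$gaussian_sigma) else px

  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # varies across cols
  ky <- t(kx)                                          # varies across rows
  gx <- EBImage::filter2(sm, kx, boundary = "replicate")
  gy <- EBImage::filter2(sm, ky, boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)

  empty <- function() root_skeleton(matrix(0, nrow(px), ncol(px)), side,
                                    depth_calibration_mm, image$metadata)
  if (max(mag) < 1e-12) return(empty())

  # non-maximum suppression along the gradient direction (4 sectors)
  theta <- atan2(gy, gx) %% pi
  sector <- (floor(theta / (pi / 4) + 0.5)) %% 4
  n1 <- matrix(0, nrow(px), ncol(px)); n2 <- n1
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    o <- offs[[as.character(s)]]
    sel <- sector == s
    p1 <- shift_mat(mag, o[1], o[2])
    p2 <- shift_mat(mag, -o[1], -o[2])
    n1[sel] <- p1[sel]
    n2[sel] <- p2[sel]
  }
  ridge <- mag >= n1 & mag >= n2 & mag > 0

  nzmag <- mag[ridge]
  if (length(nzmag) == 0) return(empty())
  lo <- quantile(nzmag, params$low_percentile / 100, names = FALSE)
  hi <- quantile(nzmag, params$high_percentile / 100, names = FALSE)
  weak <- ridge & mag >= lo
  strong <- ridge & mag >= hi
  if (params$intensity_gate > 0) {
    # intensity gate: an edge must lie on fluorescence, not on the dark
    # outer foot of a blur-merged cluster (gradient offset from intensity).
    # Background-relative, so a constant offset leaves the result unchanged.
    bg <- median(sm)
    ref <- quantile(sm, 0.999, names = FALSE)
    lit <- sm >= bg + params$intensity_gate * (ref - bg)
    weak <- weak & lit
    strong <- strong & lit
  }
  if (!any(strong)) return(empty())

  lab <- label_components(weak)
  keep_labels <- unique(lab[strong])
  mask <- matrix(as.numeric(lab %in% keep_labels & lab > 0), nrow(px))
  root_skeleton(mask, side, depth_calibration_mm, image$metadata)
}

#' Clean a detected skeleton
#'
#' Automated stand-in for manual artifact removal and gap repair:
#' morphological closing with a disk of radius \code{close_radius_px}
#' bridges small breaks in the root trace and fills the interior between the
#' paired Canny contours of a root; then 8-connected components smaller than
#' \code{min_component_px} (specks, labels, reflections) are discarded.
#' When the source intensity image is supplied, closed-in pixels that carry
#' no fluorescence (smoothed intensity below the \code{intensity_gate}
#' fraction of the bright reference level) are removed again: closing cannot
#' tell the bright interior of a thick root from the dark gap between two
#' nearby roots, but the image can. The result is always a subset of the
#' closing of the input, and the operation is idempotent.
#'
#' @param skeleton a \code{\link{root_skeleton}}.
#' @param params a \code{\link{canny_params}}.
#' @param image optional \code{\link{intensity_image}} the skeleton was
#'   detected from, enabling the intensity gate.
#' @return a cleaned \code{root_skeleton}.
#' @export
clean_skeleton <- function(skeleton, params = canny_params(), image = NULL) {
  m <- skeleton$mask
  if (params$close_radius_px > 0 && any(m > 0)) {
    brush <- EBImage::makeBrush(2 * params$close_radius_px + 1, "disc")
    m <- EBImage::closing(m, brush)
  }
  if (!is.null(image) && params$intensity_gate > 0 && any(m > 0)) {
    sm <- if (params$gaussian_sigma > 0)
      EBImage::gblur(image$pixels, params$gaussian_sigma) else image$pixels
    bg <- median(sm)
    ref <- quantile(sm, 0.999, names = FALSE)
    m[sm < bg + params$intensity_gate * (ref - bg) & skeleton$mask == 0] <- 0
  }
  if (any(m > 0)) {
    lab <- label_components(m)
    sizes <- component_sizes(lab)
    small <- which(sizes < params$min_component_px)
    if (length(small) > 0) m[lab %in% small] <- 0
  }
  root_skeleton(m, skeleton$side, skeleton$depth_calibration_mm,
                skeleton$metadata)
}

#' Thin a mask to its one-pixel centerline
#'
#' Zhang-Suen morphological thinning. Edge detection outlines both flanks of
#' a bright root trace, and closing fills between them; thinning collapses
#' that band back to a centerline, so downstream pixel counts measure root
#' extent rather than trace width. Connectivity is preserved.
#'
#' @param skeleton a \code{\link{root_skeleton}}.
#' @return a thinned \code{root_skeleton}.
#' @export
thin_skeleton <- function(skeleton) {
  m <- skeleton$mask > 0
  if (any(m)) {
    repeat {
      changed <- FALSE
      for (phase in 1:2) {
        # neighbours P2..P9 clockwise from north
        p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
        p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
        p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
        p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
        b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
        a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
             (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
        cond <- m & b >= 2 & b <= 6 & a == 1
        if (phase == 1) cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
        else            cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
        if (any(cond)) {
          m[cond] <- FALSE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  root_skeleton(m * 1, skeleton$side, skeleton$depth_calibration_mm,
                skeleton$metadata)
}
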
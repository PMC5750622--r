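#' Combined view matrix
#'
#' @param values nonnegative matrix of root-pixel quantities; rows index
#'   depth downward (row 1 = gel surface).
#' @param axis_pair "XY" (sides A/C, columns index X) or "ZY" (sides B/D,
#'   columns index Z).
#' @param depth_calibration_mm physical depth spanned by the rows.
#' @return an object of class \code{view_matrix}.
#' @export
view_matrix <- function(values, axis_pair = c("XY", "ZY"),
                        depth_calibration_mm = 33.0) {
  axis_pair <- match.arg(axis_pair)
  if (any(values < 0)) stop("view matrix values must be >= 0", call. = FALSE)
  structure(list(values = values, axis_pair = axis_pair,
                 depth_calibration_mm = depth_calibration_mm),
            class = "view_matrix")
}

#' Combine two opposing box faces into one view matrix
#'
#' Cameras on opposite faces see horizontally mirrored scenes, so the back
#' mask is flipped into the front frame before the two binary masks are
#' averaged per pixel (values in {0, 0.5, 1}; fractional values are retained
#' as weights downstream). Results are always expressed in the canonical
#' frame of side A (for the XY pair) or side B (for the ZY pair), so the
#' operation is symmetric in its two arguments.
#'
#' @param front,back \code{\link{root_skeleton}}s of an opposing pair:
#'   sides \{A, C\} or \{B, D\}, same shape.
#' @return a \code{\link{view_matrix}} ("XY" for A/C, "ZY" for B/D).
#' @export
combine_opposing_views <- function(front, back) {
  pair <- sort(c(front$side, back$side))
  if (identical(pair, c("A", "C"))) axis_pair <- "XY"
  else if (identical(pair, c("B", "D"))) axis_pair <- "ZY"
  else stop(sprintf("sides %s and %s are not an opposing pair",
                    front$side, back$side), call. = FALSE)
  if (!identical(dim(front$mask), dim(back$mask)))
    stop("geometry error: opposing masks differ in shape", call. = FALSE)
  # express both in the canonical (A or B) frame
  canon <- function(s) {
    if (s$side %in% c("C", "D"))
      s$mask[, rev(seq_len(ncol(s$mask))), drop = FALSE]
    else s$mask
  }
  vals <- (canon(front) + canon(back)) / 2
  view_matrix(vals, axis_pair, front$depth_calibration_mm)
}

#' Vertical depth profile from the two combined views
#'
#' Per depth bin, the mean of the XY and ZY row sums: the average root pixel
#' count from the top to the bottom of the box.
#'
#' @param xy,zy \code{\link{view_matrix}} objects with equal row counts.
#' @return a \code{\link{depth_profile}}.
#' @export
vertical_profile <- function(xy, zy) {
  if (nrow(xy$values) != nrow(zy$values))
    stop("geometry error: row counts differ between views", call. = FALSE)
  counts <- (rowSums(xy$values) + rowSums(zy$values)) / 2
  depth_profile(counts, xy$depth_calibration_mm)
}

#' Overhead XZ matrix
#'
#' @param values nonnegative matrix, Z rows x X columns.
#' @param center hypocotyl position (x0, z0) in 1-based grid coordinates
#'   (x = column, z = row); may be fractional.
#' @param method collapse method that produced the matrix.
#' @return an object of class \code{xz_matrix}.
#' @export
xz_matrix <- function(values, center = NULL,
                      method = c("outer", "additive")) {
  method <- match.arg(method)
  if (any(values < 0)) stop("XZ values must be >= 0", call. = FALSE)
  if (!is.null(center)) {
    if (center[1] < 1 || center[1] > ncol(values) ||
        center[2] < 1 || center[2] > nrow(values))
      stop("center must lie inside the XZ grid", call. = FALSE)
  }
  structure(list(values = values, center = center, method = method),
            class = "xz_matrix")
}

#' Collapse the two views into an overhead XZ matrix
#'
#' Collapsing the vertical (Y) axis leaves two horizontal marginals: the
#' column sums \eqn{c_X} of the XY view and \eqn{c_Z} of the ZY view, each
#' rescaled to the common total \eqn{T = (\sum c_X + \sum c_Z)/2}. Two
#' reconstructions of the overhead root quantity are offered:
#' \describe{
#'   \item{outer (default)}{\eqn{XZ(x,z) = c_X(x)\, c_Z(z) / T}: the
#'     two-view independence back-projection. Both marginals are reproduced
#'     exactly, and mass is localized where both views see roots, which
#'     makes windroses meaningful.}
#'   \item{additive}{\eqn{XZ(x,z) = (c_X(x) + c_Z(z)) / 2}: the literal
#'     "average pixel count" reading; retained as an alternative.}
#' }
#'
#' @param xy,zy \code{\link{view_matrix}} objects (axis pairs XY and ZY).
#' @param method "outer" or "additive".
#' @param center optional hypocotyl (x0, z0) stored on the result.
#' @return an \code{\link{xz_matrix}} with Z rows and X columns.
#' @export
collapse_to_xz <- function(xy, zy, method = c("outer", "additive"),
                           center = NULL) {
  method <- match.arg(method)
  c_x <- colSums(xy$values)
  c_z <- colSums(zy$values)
  tot <- (sum(c_x) + sum(c_z)) / 2
  if (tot <= 0) {
    warning("both views are empty; returning an all-zero XZ matrix")
    return(xz_matrix(matrix(0, length(c_z), length(c_x)), center, method))
  }
  if (sum(c_x) > 0) c_x <- c_x * tot / sum(c_x)
  if (sum(c_z) > 0) c_z <- c_z * tot / sum(c_z)
  vals <- if (method == "outer") outer(c_z, c_x) / tot
          else (matrix(c_z, length(c_z), length(c_x)) +
                matrix(c_x, length(c_z), length(c_x), byrow = TRUE)) / 2
  xz_matrix(vals, center, method)
}

#' Locate the hypocotyl centre from the two views
#'
#' The hypocotyl sits at the gel surface, so its X coordinate is the
#' weighted centroid column of the topmost nonzero row of the XY view, and
#' its Z coordinate likewise from the ZY view. An explicit override (from a
#' run configuration) takes precedence.
#'
#' @param xy,zy \code{\link{view_matrix}} objects.
#' @param override optional (x0, z0), returned untouched when given.
#' @return numeric (x0, z0) in 1-based grid coordinates (x = XY column,
#'   z = ZY column).
#' @export
locate_center <- function(xy, zy, override = NULL) {
  if (!is.null(override)) return(as.numeric(override[1:2]))
  top_centroid <- function(vm) {
    rs <- rowSums(vm$values)
    r <- which(rs > 0)[1]
    if (is.na(r))
      stop("detection error: empty view, cannot locate the hypocotyl",
           call. = FALSE)
    weighted.mean(seq_len(ncol(vm$values)), vm$values[r, ])
  }
  c(top_centroid(xy), top_centroid(zy))
}
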
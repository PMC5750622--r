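#' Depth profile container
#'
#' Root pixel counts per depth bin. Bin \eqn{j} (1-based, top first)
#' represents the depth interval centred at
#' \eqn{(j - 1/2)/n \times} \code{depth_calibration_mm}; all statistics use
#' these bin-centre depths.
#'
#' @param counts nonnegative numeric vector (fractional counts from view
#'   averaging are allowed).
#' @param depth_calibration_mm total depth represented by the bins, mm
#'   (default 33, the gel column height).
#' @return an object of class \code{depth_profile}.
#' @export
depth_profile <- function(counts, depth_calibration_mm = 33.0) {
  counts <- as.numeric(counts)
  if (length(counts) < 1) stop("profile needs at least one bin", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("profile counts must be finite and >= 0", call. = FALSE)
  if (depth_calibration_mm <= 0)
    stop_field("depth_calibration_mm", "must be > 0")
  structure(list(counts = counts,
                 depth_calibration_mm = depth_calibration_mm),
            class = "depth_profile")
}

#' Bin-centre depths of a profile, mm
#' @param profile a \code{\link{depth_profile}}.
#' @return numeric vector of depths.
#' @export
bin_depths <- function(profile) {
  n <- length(profile$counts)
  (seq_len(n) - 0.5) / n * profile$depth_calibration_mm
}

#' Depth of maximum root density
#'
#' The bin-centre depth (mm) of the profile's maximum count; ties are broken
#' toward the shallowest bin (no within-bin interpolation: the profile is
#' the data).
#'
#' @param profile a \code{\link{depth_profile}} with at least one positive
#'   count.
#' @return depth in mm.
#' @export
location_of_max <- function(profile) {
  if (all(profile$counts <= 0))
    stop("empty profile: no positive counts", call. = FALSE)
  bin_depths(profile)[which.max(profile$counts)]
}

# Central weighted moments about the weighted mean; population convention.
wmoments <- function(x, w, orders) {
  sw <- sum(w)
  mu <- sum(w * x) / sw
  vapply(orders, function(r) sum(w * (x - mu)^r) / sw, numeric(1))
}

check_spread <- function(profile) {
  pos <- profile$counts > 0
  if (sum(pos) < 2)
    stop("undefined moment: weight on fewer than 2 distinct depths",
         call. = FALSE)
}

#' Weighted skewness of the vertical root distribution
#'
#' Population (frequency-weighted) skewness
#' \eqn{g_1 = m_3 / m_2^{3/2}} of bin-centre depth, weighted by the profile
#' counts. Negative values indicate root mass concentrated deep with a
#' shallow tail (depth increases downward).
#'
#' @param profile a \code{\link{depth_profile}} with weight on at least two
#'   distinct depths.
#' @return unitless \eqn{g_1}.
#' @export
weighted_skewness <- function(profile) {
  check_spread(profile)
  m <- wmoments(bin_depths(profile), profile$counts, c(2, 3))
  m[2] / m[1]^1.5
}

#' Weighted excess kurtosis of the vertical root distribution
#'
#' Population excess kurtosis \eqn{g_2 = m_4 / m_2^2 - 3}: 0 for a normal
#' (mesokurtic) distribution, negative for a flattened (platykurtic)
#' distribution, positive when roots concentrate at a specific depth
#' (leptokurtic).
#'
#' @inheritParams weighted_skewness
#' @return unitless \eqn{g_2}.
#' @export
weighted_excess_kurtosis <- function(profile) {
  check_spread(profile)
  m <- wmoments(bin_depths(profile), profile$counts, c(2, 4))
  m[2] / m[1]^2 - 3
}

#' All vertical distribution statistics of a profile
#'
#' @inheritParams weighted_skewness
#' @return an object of class \code{vertical_stats}: list with
#'   \code{location_of_max_mm}, \code{skewness}, \code{kurtosis} (excess) and
#'   \code{total_weight}.
#' @export
vertical_stats <- function(profile) {
  structure(list(location_of_max_mm = location_of_max(profile),
                 skewness = weighted_skewness(profile),
                 kurtosis = weighted_excess_kurtosis(profile),
                 total_weight = sum(profile$counts)),
            class = "vertical_stats")
}

#' @export
print.vertical_stats <- function(x, ...) {
  cat(sprintf(paste0("<vertical_stats> max density at %.2f mm, ",
                     "skewness %.3f, excess kurtosis %.3f (weight %.1f)\n"),
              x$location_of_max_mm, x$skewness, x$kurtosis, x$total_weight))
  invisible(x)
}
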
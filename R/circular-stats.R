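#' Weighted angle set
#'
#' The common input of all circular statistics: azimuths about the hypocotyl
#' with nonnegative weights (root pixel quantities). The compass convention
#' is theta = 0 east (+X), pi/2 north (+Z), angles counterclockwise in
#' [0, 2 pi).
#'
#' @param angles numeric, radians (reduced modulo 2 pi).
#' @param weights nonnegative weights, recycled if scalar.
#' @return an object of class \code{weighted_angles} with fields
#'   \code{angles}, \code{weights} and \code{n_eff} (= round(sum of
#'   weights), the effective sample size).
#' @export
weighted_angles <- function(angles, weights = 1) {
  angles <- as.numeric(angles)
  if (length(weights) == 1) weights <- rep(weights, length(angles))
  if (length(weights) != length(angles))
    stop("angles and weights must have equal length", call. = FALSE)
  if (any(!is.finite(angles)) || any(!is.finite(weights)) || any(weights < 0))
    stop("angles must be finite and weights finite and >= 0", call. = FALSE)
  angles <- angles %% (2 * pi)
  structure(list(angles = angles, weights = as.numeric(weights),
                 n_eff = round(sum(weights))),
            class = "weighted_angles")
}

#' Polar transform of an overhead XZ matrix
#'
#' Converts each positive cell of the XZ matrix into an (angle, weight)
#' pair about the hypocotyl centre: angle = atan2(z - z0, x - x0), weight =
#' the cell value. Cells within \code{exclusion_radius_px} of the centre
#' (including the centre cell itself, whose azimuth is undefined) are
#' excluded.
#'
#' @param xz an \code{\link{xz_matrix}} with a centre.
#' @param exclusion_radius_px cells at distance <= this (px) are dropped.
#' @return a \code{\link{weighted_angles}} set.
#' @export
polar_transform <- function(xz, exclusion_radius_px = 1) {
  if (is.null(xz$center))
    stop("XZ matrix has no centre; see locate_center", call. = FALSE)
  idx <- which(xz$values > 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop("degenerate input: XZ matrix has no positive cells", call. = FALSE)
  dx <- idx[, 2] - xz$center[1]   # columns index X
  dz <- idx[, 1] - xz$center[2]   # rows index Z
  keep <- sqrt(dx^2 + dz^2) > exclusion_radius_px
  if (!any(keep))
    stop("degenerate input: all mass within the exclusion radius",
         call. = FALSE)
  weighted_angles(atan2(dz[keep], dx[keep]),
                  xz$values[idx[keep, , drop = FALSE]])
}

trig_moments <- function(s) {
  sw <- sum(s$weights)
  if (sw <= 0) stop("degenerate input: zero total weight", call. = FALSE)
  c(C = sum(s$weights * cos(s$angles)) / sw,
    S = sum(s$weights * sin(s$angles)) / sw)
}

#' Mean resultant length (Rayleigh's statistic)
#'
#' \eqn{\bar R = \sqrt{C^2 + S^2}} with
#' \eqn{C = \sum w_i \cos\theta_i / \sum w_i},
#' \eqn{S = \sum w_i \sin\theta_i / \sum w_i}: 0 for perfect circular
#' uniformity, 1 for total concentration. Its magnitude is the package's
#' measure of horizontal root-system asymmetry.
#'
#' @param s a \code{\link{weighted_angles}} set with positive total weight.
#' @return \eqn{\bar R \in [0, 1]}.
#' @export
mean_resultant_length <- function(s) {
  m <- trig_moments(s)
  min(1, sqrt(m["C"]^2 + m["S"]^2))[[1]]
}

#' Rayleigh test of circular uniformity
#'
#' Tests departure from a uniform circular distribution via
#' \eqn{z = n \bar R^2} with the standard higher-order correction
#' \deqn{p = e^{-z}\left[1 + \frac{2z - z^2}{4n}
#'   - \frac{24z - 132z^2 + 76z^3 - 9z^4}{288 n^2}\right]}
#' clamped to [0, 1], where \eqn{n} is the effective sample size.
#'
#' @param s a \code{\link{weighted_angles}} set with \code{n_eff >= 2}.
#' @return the p-value.
#' @export
rayleigh_test <- function(s) {
  n <- s$n_eff
  if (n < 2) stop("insufficient data: effective sample size < 2",
                  call. = FALSE)
  rbar <- mean_resultant_length(s)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                  (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  clamp(p, 0, 1)
}

#' Mean direction
#'
#' \eqn{\mu = \mathrm{atan2}(S, C)} mapped to [0, 2 pi). Undefined when the
#' resultant vanishes (perfectly balanced angles), which is an error rather
#' than a silent zero.
#'
#' @param s a \code{\link{weighted_angles}} set with \eqn{\bar R > 0}.
#' @return mean direction, radians in [0, 2 pi).
#' @export
mean_direction <- function(s) {
  m <- trig_moments(s)
  if (sqrt(m["C"]^2 + m["S"]^2) < 1e-12)
    stop("undefined direction: mean resultant length is zero", call. = FALSE)
  atan2(m["S"], m["C"])[[1]] %% (2 * pi)
}

# Expand weighted angles into an (approximately) unweighted sample:
# copies_i = round(w_i * s) with s chosen so the total is ~ n_eff, capped.
expand_weights <- function(s, cap = 1e5) {
  sw <- sum(s$weights)
  target <- min(round(sw), cap)
  scale <- target / sw
  copies <- round(s$weights * scale)
  if (sum(copies) < 2) {
    warning("weight expansion degenerated; falling back to weighted resampling")
    n <- min(max(2, round(sw)), cap)
    idx <- with_local_seed(sub_seed(20201L, length(s$angles)), {
      sample.int(length(s$angles), n, replace = TRUE,
                 prob = s$weights / sw)
    })
    return(s$angles[idx])
  }
  rep(s$angles, times = copies)
}

#' Watson's U-squared statistic of circular uniformity
#'
#' The rotation-invariant goodness-of-fit statistic
#' \deqn{U^2 = \sum_i \left(u_{(i)} - \frac{2i - 1}{2n}\right)^2
#'   - n\left(\bar u - \frac{1}{2}\right)^2 + \frac{1}{12 n}}
#' with \eqn{u = \theta / 2\pi} sorted. As an order-statistic test it is
#' defined for unweighted samples; weighted sets are expanded to
#' \code{round(w_i * scale)} copies per angle, with scale chosen so the
#' expanded size is about \code{n_eff} and at most \code{cap} (integer
#' weights below the cap expand exactly). A degenerate expansion falls back
#' to weighted resampling with a warning.
#'
#' @param s a \code{\link{weighted_angles}} set with \code{n_eff >= 2}.
#' @param cap maximum expanded sample size.
#' @return \eqn{U^2 \ge 0}.
#' @export
watson_u2 <- function(s, cap = 1e5) {
  if (s$n_eff < 2) stop("insufficient data: effective sample size < 2",
                        call. = FALSE)
  theta <- expand_weights(s, cap)
  u <- sort(theta / (2 * pi))
  n <- length(u)
  i <- seq_len(n)
  sum((u - (2 * i - 1) / (2 * n))^2) - n * (mean(u) - 0.5)^2 + 1 / (12 * n)
}

# Asymptotic critical values of Watson's U2 for uniformity.
.watson_table <- data.frame(alpha = c(0.10, 0.05, 0.025, 0.01),
                            crit = c(0.152, 0.187, 0.221, 0.267))

#' Censored p-value bound for Watson's U-squared
#'
#' Compares the statistic with the standard asymptotic critical values
#' (0.152, 0.187, 0.221, 0.267 at alpha = 0.10, 0.05, 0.025, 0.01) and
#' reports a censored bound rather than extrapolating beyond the table.
#'
#' @param u2 the statistic from \code{\link{watson_u2}}.
#' @return list with \code{label} (e.g. \code{"<0.01"}, \code{"0.025-0.05"},
#'   \code{">0.10"}), \code{p_upper} (numeric upper bound, 1 when off-table
#'   low) and \code{p_lower}.
#' @export
watson_p <- function(u2) {
  tab <- .watson_table
  if (u2 > tab$crit[nrow(tab)])
    return(list(label = "<0.01", p_upper = 0.01, p_lower = 0))
  if (u2 < tab$crit[1])
    return(list(label = ">0.10", p_upper = 1, p_lower = 0.10))
  k <- max(which(tab$crit <= u2))
  list(label = sprintf("%g-%g", tab$alpha[k + 1], tab$alpha[k]),
       p_upper = tab$alpha[k], p_lower = tab$alpha[k + 1])
}

#' Windrose sector binning
#'
#' Bins the weighted angles into \code{n_sectors} equal half-open sectors;
#' sector 1 is centred on east (theta = 0), sectors proceed
#' counterclockwise, and an angle exactly on a boundary belongs to the
#' higher sector. Total weight is conserved.
#'
#' @param s a \code{\link{weighted_angles}} set.
#' @param n_sectors number of sectors (>= 2; default 16).
#' @return an object of class \code{windrose}: \code{n_sectors},
#'   \code{sector_centers_rad} and \code{sector_weights}.
#' @export
windrose <- function(s, n_sectors = 16L) {
  if (n_sectors < 2) stop_field("n_sectors", "must be >= 2")
  K <- as.integer(n_sectors)
  width <- 2 * pi / K
  sector <- (floor((s$angles + width / 2) / width)) %% K   # 0-based
  w <- vapply(0:(K - 1), function(k) sum(s$weights[sector == k]), numeric(1))
  structure(list(n_sectors = K,
                 sector_centers_rad = (0:(K - 1)) * width,
                 sector_weights = w),
            class = "windrose")
}

#' All circular statistics of a weighted angle set
#'
#' @param s a \code{\link{weighted_angles}} set with \code{n_eff >= 2}.
#' @return an object of class \code{circular_stats}: \code{rayleigh_rbar},
#'   \code{rayleigh_p}, \code{watson_u2}, \code{watson_p} (censored label),
#'   \code{mean_direction_rad} (NA when the resultant vanishes) and
#'   \code{n_eff}.
#' @export
circular_stats <- function(s) {
  rbar <- mean_resultant_length(s)
  u2 <- watson_u2(s)
  mu <- if (rbar > 1e-12) mean_direction(s) else NA_real_
  structure(list(rayleigh_rbar = rbar,
                 rayleigh_p = rayleigh_test(s),
                 watson_u2 = u2,
                 watson_p = watson_p(u2)$label,
                 mean_direction_rad = mu,
                 n_eff = s$n_eff),
            class = "circular_stats")
}

#' @export
print.circular_stats <- function(x, ...) {
  cat(sprintf(paste0("<circular_stats> Rbar %.3f (Rayleigh p %.3g), ",
                     "Watson U2 %.3f (p %s), mean direction %.2f rad, ",
                     "n_eff %d\n"),
              x$rayleigh_rbar, x$rayleigh_p, x$watson_u2, x$watson_p,
              x$mean_direction_rad, x$n_eff))
  invisible(x)
}
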
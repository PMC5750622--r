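#' Parameters of the synthetic root-system simulator
#'
#' The simulator reproduces the growth phenomenology of an
#' \emph{Arabidopsis} root system in a transparent gel-filled culture box:
#' a primary root grows essentially straight down until it reaches the gel
#' bottom; lateral (second-order) roots emerge at random positions within the
#' upper portion of the primary root, grow horizontally outward at a fixed
#' azimuth and then bend downward; a few tertiary roots emerge near the base
#' of the laterals (hence close to the primary root) late in the run. Each
#' root tip is advanced as a discrete-step biased random walk.
#'
#' @param box_width_mm inner box width (X and Z extent), mm.
#' @param box_depth_mm gel depth (Y extent, positive downward), mm. The
#'   default 33 mm matches a standard Magenta-box gel column.
#' @param n_laterals number of lateral roots.
#' @param lateral_emergence_span fraction of the primary root, measured from
#'   the top, within which laterals may emerge (default 1/3: the upper third).
#' @param lateral_outward_then_down_ratio scales the arc length over which a
#'   lateral rotates from horizontal to vertical (turn length =
#'   10 mm x ratio).
#' @param tertiary_rate expected number of tertiary roots per lateral
#'   (Poisson).
#' @param growth_days simulated observation days (days after planting, DAP).
#' @param step_mm growth-step length of the random walk, mm.
#' @param angle_jitter_sd standard deviation (radians, small-angle) of the
#'   per-step direction jitter.
#' @param primary_rate_mm_day,lateral_rate_mm_day,tertiary_rate_mm_day
#'   elongation rates. The primary default (2.5 mm/day) brings the tip to the
#'   33 mm gel bottom near 14 DAP, as observed for gel-grown
#'   \emph{Arabidopsis}.
#' @param origin_xz hypocotyl (X, Z) position at depth 0, mm; defaults to the
#'   box centre (the focal plant occupies the central planting position).
#' @param seed integer seed; identical parameters and seed give identical
#'   systems, renders and ground truths.
#' @return an object of class \code{sim_params}.
#' @export
sim_params <- function(box_width_mm = 76.2, box_depth_mm = 33.0,
                       n_laterals = 8L, lateral_emergence_span = 1 / 3,
                       lateral_outward_then_down_ratio = 1.0,
                       tertiary_rate = 1.0,
                       growth_days = c(12, 14, 19, 21, 26),
                       step_mm = 1.0, angle_jitter_sd = 0.12,
                       primary_rate_mm_day = 2.5,
                       lateral_rate_mm_day = 2.0,
                       tertiary_rate_mm_day = 1.0,
                       origin_xz = NULL, seed = 1L) {
  p <- list(box_width_mm = box_width_mm, box_depth_mm = box_depth_mm,
            n_laterals = as.integer(n_laterals),
            lateral_emergence_span = lateral_emergence_span,
            lateral_outward_then_down_ratio = lateral_outward_then_down_ratio,
            tertiary_rate = tertiary_rate,
            growth_days = as.numeric(growth_days),
            step_mm = step_mm, angle_jitter_sd = angle_jitter_sd,
            primary_rate_mm_day = primary_rate_mm_day,
            lateral_rate_mm_day = lateral_rate_mm_day,
            tertiary_rate_mm_day = tertiary_rate_mm_day,
            origin_xz = if (is.null(origin_xz))
              c(box_width_mm / 2, box_width_mm / 2) else as.numeric(origin_xz),
            seed = as.integer(seed))
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  if (!is.finite(p$box_width_mm) || p$box_width_mm <= 0)
    stop_field("box_width_mm", "must be > 0")
  if (!is.finite(p$box_depth_mm) || p$box_depth_mm <= 0)
    stop_field("box_depth_mm", "must be > 0")
  if (is.na(p$n_laterals) || p$n_laterals < 0)
    stop_field("n_laterals", "must be >= 0")
  if (!is.finite(p$lateral_emergence_span) ||
      p$lateral_emergence_span <= 0 || p$lateral_emergence_span > 1)
    stop_field("lateral_emergence_span", "must be in (0, 1]")
  if (p$lateral_outward_then_down_ratio <= 0)
    stop_field("lateral_outward_then_down_ratio", "must be > 0")
  if (p$tertiary_rate < 0) stop_field("tertiary_rate", "must be >= 0")
  if (length(p$growth_days) < 1 || any(p$growth_days <= 0) ||
      is.unsorted(p$growth_days, strictly = TRUE))
    stop_field("growth_days", "must be strictly increasing positive days")
  if (p$step_mm <= 0) stop_field("step_mm", "must be > 0")
  if (p$angle_jitter_sd < 0) stop_field("angle_jitter_sd", "must be >= 0")
  if (p$primary_rate_mm_day <= 0)
    stop_field("primary_rate_mm_day", "must be > 0")
  if (p$lateral_rate_mm_day <= 0)
    stop_field("lateral_rate_mm_day", "must be > 0")
  if (p$tertiary_rate_mm_day <= 0)
    stop_field("tertiary_rate_mm_day", "must be > 0")
  if (any(p$origin_xz < 0) || any(p$origin_xz > p$box_width_mm))
    stop_field("origin_xz", "must lie inside the box footprint")
  invisible(p)
}

# Advance one root tip as a biased random walk; returns the full vertex
# matrix. `dir_fn(s)` gives the drift direction at arc length s.
grow_path <- function(start, total_len, step, dir_fn, jitter_sd,
                      width, depth, stop_at_bottom = FALSE) {
  n_steps <- max(1L, ceiling(total_len / step))
  verts <- matrix(NA_real_, n_steps + 1L, 3L)
  verts[1L, ] <- start
  pos <- start
  k <- 1L
  for (i in seq_len(n_steps)) {
    d <- dir_fn((i - 1) * step) + rnorm(3L, 0, jitter_sd)
    nd <- sqrt(sum(d^2))
    if (nd < 1e-12) d <- c(0, 1, 0) else d <- d / nd
    pos <- pos + d * step
    pos[1] <- clamp(pos[1], 0, width)
    pos[3] <- clamp(pos[3], 0, width)
    hit_bottom <- pos[2] >= depth
    pos[2] <- clamp(pos[2], 0, depth)
    k <- k + 1L
    verts[k, ] <- pos
    if (stop_at_bottom && hit_bottom) break
  }
  verts[seq_len(k), , drop = FALSE]
}

# Arc lengths of a polyline's vertices (cumulative, from its first vertex).
arc_lengths <- function(verts) {
  if (nrow(verts) == 1L) return(0)
  seg <- sqrt(rowSums((verts[-1L, , drop = FALSE] -
                       verts[-nrow(verts), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# Truncate a polyline at arc length `len`, interpolating the final vertex.
truncate_path <- function(verts, len) {
  s <- arc_lengths(verts)
  if (len >= s[length(s)]) return(verts)
  i <- max(which(s <= len))
  out <- verts[seq_len(i), , drop = FALSE]
  if (i < nrow(verts) && len > s[i] + 1e-12) {
    f <- (len - s[i]) / (s[i + 1] - s[i])
    out <- rbind(out, verts[i, ] + f * (verts[i + 1, ] - verts[i, ]))
  }
  out
}

# Point on a polyline at arc length `len`.
point_at <- function(verts, len) {
  tail(truncate_path(verts, len), 1L)[1, ]
}

#' Simulate one root system at a given day
#'
#' Generates the full (end-of-run) growth trajectory of every root under the
#' seeded random streams, then truncates each root at the arc length it has
#' reached by \code{day}. Because per-root jitter comes from dedicated
#' substreams, the system at an earlier day is geometrically a prefix of the
#' system at a later day, and the primary tip depth is nondecreasing in day.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param day observation day; must be one of \code{params$growth_days}.
#' @return an object of class \code{root_system3d}: a list with
#'   \code{polylines} (each \code{list(order, vertices)}, order 1 = primary,
#'   2 = lateral, 3 = tertiary; vertices an n x 3 matrix of (x, y, z) mm with
#'   y positive downward), \code{origin} (hypocotyl x, z), and the box
#'   geometry.
#' @export
simulate_root_system <- function(params, day) {
  validate_sim_params(params)
  if (!any(abs(params$growth_days - day) < 1e-9))
    stop_field("day", "must be one of params$growth_days")
  W <- params$box_width_mm
  D <- params$box_depth_mm
  jit <- params$angle_jitter_sd
  step <- params$step_mm
  horizon <- max(params$growth_days)

  # structural randomness: one substream, drawn in a fixed order
  st <- with_local_seed(sub_seed(params$seed, 0L), {
    nl <- params$n_laterals
    lat_frac <- if (nl > 0) runif(nl, 0, params$lateral_emergence_span) else numeric(0)
    lat_azim <- if (nl > 0) runif(nl, 0, 2 * pi) else numeric(0)
    lat_emerge <- if (nl > 0) runif(nl, 0.38 * horizon, 0.62 * horizon) else numeric(0)
    n_tert <- if (nl > 0) rpois(nl, params$tertiary_rate) else integer(0)
    tert <- list()
    for (j in seq_len(nl)) {
      for (k in seq_len(n_tert[j])) {
        tert[[length(tert) + 1L]] <- list(
          parent = j,
          attach_mm = runif(1, 1, 4),
          azim = runif(1, 0, 2 * pi),
          emerge = runif(1, 0.70 * horizon, 0.92 * horizon))
      }
    }
    list(lat_frac = lat_frac, lat_azim = lat_azim, lat_emerge = lat_emerge,
         tert = tert)
  })

  # primary: straight-down drift, stops when it reaches the gel bottom
  primary_full <- with_local_seed(sub_seed(params$seed, 1L, 0L), {
    grow_path(c(params$origin_xz[1], 0, params$origin_xz[2]),
              total_len = params$primary_rate_mm_day * horizon,
              step = step, dir_fn = function(s) c(0, 1, 0),
              jitter_sd = jit, width = W, depth = D, stop_at_bottom = TRUE)
  })
  prim_len_day <- params$primary_rate_mm_day * day
  polylines <- list(list(order = 1L,
                         vertices = truncate_path(primary_full, prim_len_day)))

  prim_total <- arc_lengths(primary_full)[nrow(primary_full)]
  turn_len <- 10 * params$lateral_outward_then_down_ratio

  lat_full <- vector("list", params$n_laterals)
  for (j in seq_len(params$n_laterals)) {
    base <- point_at(primary_full, st$lat_frac[j] * prim_total)
    az <- st$lat_azim[j]
    dir_fn <- local({
      az0 <- az
      function(s) {
        pitch <- (pi / 2) * min(1, s / turn_len)
        c(cos(pitch) * cos(az0), sin(pitch), cos(pitch) * sin(az0))
      }
    })
    max_len <- params$lateral_rate_mm_day * max(0, horizon - st$lat_emerge[j])
    if (max_len <= 0) next
    lat_full[[j]] <- with_local_seed(sub_seed(params$seed, 2L, j), {
      grow_path(base, max_len, step, dir_fn, jit, W, D)
    })
    len_day <- params$lateral_rate_mm_day * (day - st$lat_emerge[j])
    if (len_day >= step) {
      polylines[[length(polylines) + 1L]] <-
        list(order = 2L, vertices = truncate_path(lat_full[[j]], len_day))
    }
  }

  for (tt in st$tert) {
    parent <- lat_full[[tt$parent]]
    if (is.null(parent)) next
    # tertiary only exists once its parent lateral has grown past the
    # attachment point
    parent_len_day <- params$lateral_rate_mm_day *
      (day - st$lat_emerge[tt$parent])
    if (parent_len_day <= tt$attach_mm || day <= tt$emerge) next
    base <- point_at(parent, tt$attach_mm)
    dir_fn <- local({
      az0 <- tt$azim
      function(s) {
        pitch <- (pi / 2) * min(1, s / 4)
        c(cos(pitch) * cos(az0), sin(pitch), cos(pitch) * sin(az0))
      }
    })
    len_day <- params$tertiary_rate_mm_day * (day - tt$emerge)
    if (len_day < step) next
    idx <- length(polylines) + 1L
    full <- with_local_seed(sub_seed(params$seed, 3L, tt$parent,
                                     round(tt$attach_mm * 1000)), {
      grow_path(base, params$tertiary_rate_mm_day * (horizon - tt$emerge),
                step, dir_fn, jit, W, D)
    })
    polylines[[idx]] <- list(order = 3L, vertices = truncate_path(full, len_day))
  }

  structure(list(polylines = polylines,
                 origin = params$origin_xz,
                 box_width_mm = W, box_depth_mm = D,
                 day = day),
            class = "root_system3d")
}

#' @export
print.root_system3d <- function(x, ...) {
  ords <- vapply(x$polylines, `[[`, integer(1), "order")
  cat(sprintf("<root_system3d> day %s: %d primary, %d lateral, %d tertiary roots\n",
              format(x$day), sum(ords == 1), sum(ords == 2), sum(ords == 3)))
  invisible(x)
}

#' Rasterize a root system to a voxel occupancy grid
#'
#' Each polyline segment is traced through the grid (dense supersampling at a
#' quarter voxel); every voxel a segment traverses has its occupancy count
#' incremented once per traversing segment.
#'
#' @param system a \code{root_system3d}.
#' @param voxel_size_mm voxel edge length, mm (> 0).
#' @return an object of class \code{voxel_grid}: \code{occupancy}
#'   (nx x ny x nz array of counts, y = dimension 2 indexes depth downward),
#'   \code{voxel_size_mm} and \code{dims}.
#' @export
rasterize <- function(system, voxel_size_mm = 0.5) {
  if (!is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop_field("voxel_size_mm", "must be > 0")
  W <- system$box_width_mm
  D <- system$box_depth_mm
  nx <- ceiling(W / voxel_size_mm)
  ny <- ceiling(D / voxel_size_mm)
  nz <- nx
  occ <- array(0, dim = c(nx, ny, nz))
  vox_index <- function(p) {
    c(clamp(floor(p[1] / voxel_size_mm) + 1, 1, nx),
      clamp(floor(p[2] / voxel_size_mm) + 1, 1, ny),
      clamp(floor(p[3] / voxel_size_mm) + 1, 1, nz))
  }
  for (pl in system$polylines) {
    v <- pl$vertices
    if (any(v[, 1] < -1e-9 | v[, 1] > W + 1e-9 |
            v[, 2] < -1e-9 | v[, 2] > D + 1e-9 |
            v[, 3] < -1e-9 | v[, 3] > W + 1e-9))
      stop("geometry error: polyline vertex outside the box", call. = FALSE)
    if (nrow(v) == 1L) {
      i <- vox_index(v[1, ])
      occ[i[1], i[2], i[3]] <- occ[i[1], i[2], i[3]] + 1
      next
    }
    # supersample the whole path, then count one traversal per entry into a
    # voxel (consecutive duplicates collapse; a later revisit counts again)
    pts <- NULL
    for (s in seq_len(nrow(v) - 1L)) {
      p <- v[s, ]; q <- v[s + 1L, ]
      len <- sqrt(sum((q - p)^2))
      npt <- max(2L, ceiling(len / (voxel_size_mm / 4)) + 1L)
      tfrac <- seq(0, 1, length.out = npt)
      seg <- cbind(p[1] + tfrac * (q[1] - p[1]),
                   p[2] + tfrac * (q[2] - p[2]),
                   p[3] + tfrac * (q[3] - p[3]))
      pts <- rbind(pts, if (s > 1L) seg[-1L, , drop = FALSE] else seg)
    }
    idx <- cbind(clamp(floor(pts[, 1] / voxel_size_mm) + 1, 1, nx),
                 clamp(floor(pts[, 2] / voxel_size_mm) + 1, 1, ny),
                 clamp(floor(pts[, 3] / voxel_size_mm) + 1, 1, nz))
    changed <- c(TRUE, rowSums(abs(idx[-1L, , drop = FALSE] -
                                   idx[-nrow(idx), , drop = FALSE])) > 0)
    idx <- idx[changed, , drop = FALSE]
    occ[idx] <- occ[idx] + 1
  }
  structure(list(occupancy = occ, voxel_size_mm = voxel_size_mm,
                 dims = c(nx = nx, ny = ny, nz = nz),
                 box_width_mm = W, box_depth_mm = D),
            class = "voxel_grid")
}

#' Project a voxel grid onto one box face
#'
#' Parallel binary projection: a mask pixel is set when any voxel along the
#' viewing ray is occupied (a camera sees a root once regardless of
#' thickness). Sides A and C view along the Z axis (columns index X), sides B
#' and D along the X axis (columns index Z); C is the horizontal mirror of A
#' and D of B, as seen by cameras on opposite faces. Mask rows index depth,
#' row 1 = gel surface.
#'
#' @param voxels a \code{voxel_grid}.
#' @param side one of "A", "B", "C", "D".
#' @return a \code{root_skeleton} (see \code{\link{root_skeleton}}).
#' @export
project_view <- function(voxels, side) {
  side <- match.arg(side, c("A", "B", "C", "D"))
  occ <- voxels$occupancy > 0
  if (side %in% c("A", "C")) {
    m <- t(apply(occ, c(1, 2), any)) * 1   # rows y, cols x
    if (side == "C") m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  } else {
    m <- t(apply(occ, c(3, 2), any)) * 1   # rows y, cols z
    if (side == "D") m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  }
  root_skeleton(m, side = side,
                depth_calibration_mm = voxels$box_depth_mm)
}

#' Render a noisy fluorescence image from a skeleton
#'
#' Emulates a long-exposure GFP fluorescence photograph of one box face:
#' root pixels at full intensity, an optional Gaussian point-spread blur,
#' additive Gaussian sensor noise, and a configurable number of small bright
#' artifact blobs (labels, box reflections) placed away from the root.
#'
#' @param skeleton a \code{root_skeleton}.
#' @param psf_sigma point-spread Gaussian sigma in pixels (0 = none).
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units; images are clamped to [0, 1]).
#' @param n_artifacts number of 2 x 2 bright blobs placed at least 4 px from
#'   any root pixel and 6 px from each other.
#' @param seed integer seed; rendering is bitwise reproducible.
#' @return an \code{intensity_image} (see \code{\link{read_image}}).
#' @export
render_fluorescence <- function(skeleton, psf_sigma = 0.5, noise_sd = 0.02,
                                n_artifacts = 0L, seed = 1L) {
  if (psf_sigma < 0) stop_field("psf_sigma", "must be >= 0")
  if (noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  m <- skeleton$mask
  img <- m * 1.0
  if (n_artifacts > 0) {
    forbidden <- EBImage::dilate(m, EBImage::makeBrush(9, "box"))
    placed <- matrix(numeric(0), 0, 2)
    img <- with_local_seed(sub_seed(seed, 11L), {
      ok <- which(forbidden == 0, arr.ind = TRUE)
      ok <- ok[ok[, 1] < nrow(m) & ok[, 2] < ncol(m), , drop = FALSE]
      ord <- sample.int(nrow(ok))
      n_placed <- 0L
      for (i in ord) {
        if (n_placed >= n_artifacts) break
        r <- ok[i, 1]; cc <- ok[i, 2]
        if (nrow(placed) > 0 &&
            any(pmax(abs(placed[, 1] - r), abs(placed[, 2] - cc)) < 6)) next
        img[r:(r + 1), cc:(cc + 1)] <- 1.0
        placed <- rbind(placed, c(r, cc))
        n_placed <- n_placed + 1L
      }
      if (n_placed < n_artifacts)
        warning("could not place all artifacts away from the root")
      img
    })
  }
  if (psf_sigma > 0) {
    img <- EBImage::gblur(img, psf_sigma)
    img <- img / max(img)   # keep root pixels near full scale
  }
  if (noise_sd > 0) {
    img <- with_local_seed(sub_seed(seed, 12L), {
      img + matrix(rnorm(length(img), 0, noise_sd), nrow(img))
    })
  }
  img <- clamp(img, 0, 1)
  intensity_image(img, metadata = c(skeleton$metadata,
                                    list(side = skeleton$side)))
}

#' Ground-truth vertical depth profile of a voxel grid
#'
#' Sums occupancy over each depth layer; the oracle against which the
#' image-derived \code{\link{vertical_profile}} is validated.
#'
#' @param voxels a \code{voxel_grid}.
#' @return a \code{\link{depth_profile}} whose calibration spans the grid's
#'   depth extent.
#' @export
ground_truth_vertical_profile <- function(voxels) {
  counts <- apply(voxels$occupancy, 2, sum)
  depth_profile(counts,
                depth_calibration_mm = voxels$dims["ny"] * voxels$voxel_size_mm)
}

#' Ground-truth horizontal angles of a voxel grid
#'
#' For every occupied voxel, the azimuth about a vertical axis through
#' \code{center}: \code{atan2(z - z0, x - x0)}, weighted by occupancy.
#' Voxels at the exact centre have no defined azimuth and are excluded.
#' The oracle against which the two-view \code{\link{polar_transform}}
#' statistics are validated.
#'
#' @param voxels a \code{voxel_grid}.
#' @param center (x, z) in 1-based voxel-grid coordinates; defaults to the
#'   grid position of the system origin when the grid records one.
#' @param exclusion_radius horizontal distance (voxels) below which voxels
#'   are dropped; 0 keeps everything except the exact centre. Set it to the
#'   \code{\link{polar_transform}} exclusion radius when comparing the two
#'   on the same footing.
#' @return a \code{\link{weighted_angles}} set.
#' @export
ground_truth_angles <- function(voxels, center, exclusion_radius = 0) {
  nx <- voxels$dims["nx"]; nz <- voxels$dims["nz"]
  if (center[1] < 1 || center[1] > nx || center[2] < 1 || center[2] > nz)
    stop("center must lie inside the grid footprint", call. = FALSE)
  occ <- voxels$occupancy
  idx <- which(occ > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty grid: no occupied voxels", call. = FALSE)
  dx <- idx[, 1] - center[1]
  dz <- idx[, 3] - center[2]
  r <- sqrt(dx^2 + dz^2)
  keep <- r > max(exclusion_radius, 1e-9)
  weighted_angles(atan2(dz[keep], dx[keep]), occ[idx[keep, , drop = FALSE]])
}
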
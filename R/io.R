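# TSV serialization of the pipeline's intermediate objects. All writers use
# a '#'-prefixed header so files round-trip losslessly and stay greppable.

#' Write / read a depth profile as TSV
#'
#' Two columns (\code{depth_mm}, \code{count}) after a header line carrying
#' the calibration.
#'
#' @param profile a \code{\link{depth_profile}}.
#' @param path output file.
#' @return \code{write_profile_tsv}: the path, invisibly;
#'   \code{read_profile_tsv}: the \code{depth_profile}.
#' @export
write_profile_tsv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# depth_profile\tdepth_calibration_mm=%.10g",
                     profile$depth_calibration_mm), con)
  writeLines("depth_mm\tcount", con)
  writeLines(sprintf("%.10g\t%.10g", bin_depths(profile), profile$counts),
             con)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  cal <- as.numeric(sub(".*depth_calibration_mm=", "", hdr))
  d <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1)
  depth_profile(d$count, cal)
}

#' Write / read a matrix object as TSV
#'
#' A two-line '#' header records the object class and its metadata
#' (axis pair and calibration for a \code{view_matrix}; centre and method
#' for an \code{xz_matrix}), followed by the tab-separated values.
#'
#' @param x a \code{\link{view_matrix}} or \code{\link{xz_matrix}}.
#' @param path output file.
#' @return \code{write_matrix_tsv}: the path, invisibly;
#'   \code{read_matrix_tsv}: the reconstructed object.
#' @export
write_matrix_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "view_matrix")) {
    writeLines("# view_matrix\trows=depth(top first)", con)
    writeLines(sprintf("# axis_pair=%s\tdepth_calibration_mm=%.10g",
                       x$axis_pair, x$depth_calibration_mm), con)
  } else if (inherits(x, "xz_matrix")) {
    writeLines("# xz_matrix\trows=Z\tcols=X", con)
    ctr <- if (is.null(x$center)) "NA\tNA"
           else sprintf("%.10g\t%.10g", x$center[1], x$center[2])
    writeLines(sprintf("# method=%s\tcenter=%s", x$method, ctr), con)
  } else stop("unsupported object for write_matrix_tsv", call. = FALSE)
  utils::write.table(x$values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  hdr <- readLines(path, n = 2)
  vals <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                      comment.char = "#"))
  dimnames(vals) <- NULL
  if (grepl("view_matrix", hdr[1])) {
    axis <- sub(".*axis_pair=([A-Z]+).*", "\\1", hdr[2])
    cal <- as.numeric(sub(".*depth_calibration_mm=", "", hdr[2]))
    view_matrix(vals, axis, cal)
  } else {
    method <- sub(".*method=([a-z]+).*", "\\1", hdr[2])
    ctr <- strsplit(sub(".*center=", "", hdr[2]), "\t")[[1]]
    ctr <- suppressWarnings(as.numeric(ctr))
    if (any(is.na(ctr))) ctr <- NULL
    xz_matrix(vals, ctr, method)
  }
}

#' Write a weighted angle set as TSV
#'
#' Columns \code{angle_rad} and \code{weight}.
#'
#' @param s a \code{\link{weighted_angles}} set.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_angles_tsv <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("angle_rad\tweight", con)
  writeLines(sprintf("%.10g\t%.10g", s$angles, s$weights), con)
  invisible(path)
}

#' Write a skeleton mask as a 1-bit-style PNG
#'
#' @param skeleton a \code{\link{root_skeleton}}.
#' @param path output .png path.
#' @return the path, invisibly.
#' @export
write_skeleton_png <- function(skeleton, path) {
  png::writePNG(skeleton$mask, path)
  invisible(path)
}

#' Render a windrose as a polar bar chart
#'
#' @param wr a \code{\link{windrose}}.
#' @param path output .png path.
#' @param main plot title.
#' @return the path, invisibly.
#' @export
plot_windrose <- function(wr, path, main = "windrose") {
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  par(mar = c(1, 1, 2, 1), pty = "s")
  wmax <- max(wr$sector_weights, 1e-12)
  plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), axes = FALSE,
       xlab = "", ylab = "", asp = 1)
  title(main)
  for (rr in c(0.25, 0.5, 0.75, 1)) {
    tt <- seq(0, 2 * pi, length.out = 120)
    lines(rr * cos(tt), rr * sin(tt), col = "gray80")
  }
  half <- pi / wr$n_sectors
  for (k in seq_len(wr$n_sectors)) {
    r <- wr$sector_weights[k] / wmax
    if (r <= 0) next
    ctr <- wr$sector_centers_rad[k]
    tt <- seq(ctr - half, ctr + half, length.out = 16)
    polygon(c(0, r * cos(tt)), c(0, r * sin(tt)),
            col = "forestgreen", border = "darkgreen")
  }
  invisible(path)
}

#' Render an overhead heatmap of an XZ matrix
#'
#' The hypocotyl centre is marked with a cross.
#'
#' @param xz an \code{\link{xz_matrix}}.
#' @param path output .png path.
#' @param main plot title.
#' @return the path, invisibly.
#' @export
plot_xz_heatmap <- function(xz, path, main = "overhead root density") {
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  par(mar = c(2, 2, 2, 1))
  v <- xz$values
  # image() draws x along dim 1; transpose so X is horizontal, Z vertical
  image(x = seq_len(ncol(v)), y = seq_len(nrow(v)), z = t(v),
        col = hcl.colors(64, "viridis"), xlab = "X", ylab = "Z", main = main,
        useRaster = TRUE)
  if (!is.null(xz$center))
    points(xz$center[1], xz$center[2], pch = 3, col = "red", cex = 2, lwd = 2)
  invisible(path)
}
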
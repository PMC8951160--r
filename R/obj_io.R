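# Wavefront OBJ point-cloud interchange (vertex-only dialect).
#
# Models are exchanged with external viewers as OBJ files containing one
# `v x y z [r g b]` line per point and no faces. Coordinates are written in
# µm, unscaled, so volumetric analyzability survives the round trip. The
# optional per-vertex colour triple encodes the point label with a fixed
# scheme (surface = blue, internal features = light blue, wood boundaries =
# green, interior = grey) so viewers reproduce the reconstruction colouring.

label_colors <- rbind(
  outer_surface    = c(0.0, 0.0, 1.0),
  internal_feature = c(0.4, 0.8, 1.0),
  wood_boundary    = c(0.0, 0.8, 0.0),
  interior         = c(0.6, 0.6, 0.6)
)

#' Write a labeled point cloud as an OBJ file
#'
#' @param cloud a `labeled_point_cloud`.
#' @param path output path.
#' @param precision decimal places for coordinates (1–12, default 4).
#' @param with_color append the per-vertex label colour (r g b in
#'   \[0, 1\]) to each vertex line.
#' @return the path, invisibly.
#' @export
write_obj <- function(cloud, path, precision = 4L, with_color = TRUE) {
  stopifnot(inherits(cloud, "labeled_point_cloud"))
  if (precision < 1L || precision > 12L) stop("precision must be in [1, 12]")
  header <- c(
    "# tomocloud point cloud (vertex-only OBJ, coordinates in um)",
    sprintf("# name: %s", cloud$name),
    sprintf("# points: %d", n_points(cloud)),
    sprintf("# precision: %d; colors: %s", precision,
            if (with_color) "label-rgb" else "none")
  )
  n <- n_points(cloud)
  lines <- if (n == 0L) character(0) else {
    fmt <- sprintf("%%.%df", precision)
    coords <- apply(cloud$points, 2L, function(col) sprintf(fmt, col))
    if (n == 1L) coords <- matrix(coords, 1L)
    if (with_color) {
      rgb <- label_colors[cloud$labels, , drop = FALSE]
      paste("v", coords[, 1], coords[, 2], coords[, 3],
            sprintf("%.3f", rgb[, 1]), sprintf("%.3f", rgb[, 2]),
            sprintf("%.3f", rgb[, 3]))
    } else {
      paste("v", coords[, 1], coords[, 2], coords[, 3])
    }
  }
  con <- file(path, "wb")  # binary keeps LF endings on every platform
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a point cloud from an OBJ file
#'
#' Parses `v` lines only; faces, normals, texture coordinates and comments
#' are ignored. A colour triple on a vertex line is mapped back to the label
#' scheme of [write_obj()] (nearest colour); vertices without colours become
#' `interior`.
#'
#' @param path OBJ file path.
#' @param name cloud name; defaults to the file name.
#' @return a `labeled_point_cloud`.
#' @export
read_obj <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  all_lines <- readLines(path, warn = FALSE)
  is_v <- grepl("^v( |\t)", all_lines)
  vlines <- all_lines[is_v]
  lineno <- which(is_v)
  if (length(vlines) == 0L) return(point_cloud(NULL, name = name))
  toks <- strsplit(trimws(vlines), "[ \t]+")
  nfield <- lengths(toks)
  bad <- which(!nfield %in% c(4L, 5L, 7L))
  if (length(bad) > 0L)
    stop("malformed vertex line ", lineno[bad[1]], ": '", vlines[bad[1]], "'")
  nums <- lapply(toks, function(t) suppressWarnings(as.numeric(t[-1])))
  if (any(vapply(nums, anyNA, logical(1)))) {
    bad <- which(vapply(nums, anyNA, logical(1)))[1]
    stop("malformed vertex line ", lineno[bad], ": '", vlines[bad], "'")
  }
  pts <- t(vapply(nums, function(v) v[1:3], numeric(3)))
  labels <- rep("interior", nrow(pts))
  has_col <- nfield == 7L
  if (any(has_col)) {
    rgb <- t(vapply(nums[has_col], function(v) v[4:6], numeric(3)))
    d2 <- vapply(seq_len(nrow(label_colors)), function(i)
      rowSums(sweep(rgb, 2L, label_colors[i, ])^2), numeric(nrow(rgb)))
    if (sum(has_col) == 1L) d2 <- matrix(d2, 1L)
    labels[has_col] <- rownames(label_colors)[apply(d2, 1L, which.min)]
  }
  point_cloud(pts, labels, name = name)
}
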
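# Slice stack -> 3D point cloud.
#
# Two reconstruction modes, sharing one coordinate convention:
#   x = (j - 1) * dx   (column j, 1-based)
#   y = (i - 1) * dy   (row i, 1-based; image row 1 maps to y = 0)
#   z = k * dz         (slice k, 1-based; dz = slice thickness)
# The z term is the whole point: stacking slices without the physical slice
# thickness gives a model whose length is distorted and useless for
# volumetric analysis.
#
# "direct" emits one point per (optionally grey-windowed) voxel — exhaustive,
# large, label "interior". "segmented" first finds the solid object on each
# slice (grey above the air level, largest 8-connected component), then emits
# only boundary voxels: the outer surface of the solid, the edges of the
# internal non-wood features selected by a grey window, and the wood pixels
# bordering those features.

point_labels <- c("interior", "outer_surface", "internal_feature", "wood_boundary")

#' Labeled 3-D point cloud
#'
#' @param points N x 3 numeric matrix of (x, y, z) in µm.
#' @param labels character vector (length N) over `interior`,
#'   `outer_surface`, `internal_feature`, `wood_boundary`.
#' @param greys optional integer vector (length N) of source grey values.
#' @param name free-text identifier.
#' @return a `labeled_point_cloud`.
#' @export
point_cloud <- function(points, labels = NULL, greys = NULL, name = "") {
  if (is.null(points)) points <- matrix(numeric(0), 0L, 3L)
  points <- as.matrix(points)
  if (nrow(points) > 0 && ncol(points) != 3L) stop("points must be N x 3")
  if (ncol(points) == 0L) points <- matrix(numeric(0), 0L, 3L)
  if (any(!is.finite(points))) stop("point coordinates must be finite")
  n <- nrow(points)
  if (is.null(labels)) labels <- rep("interior", n)
  if (length(labels) != n) stop("labels must have one entry per point")
  if (!all(labels %in% point_labels))
    stop("labels must be one of: ", paste(point_labels, collapse = ", "))
  if (!is.null(greys) && length(greys) != n)
    stop("greys must have one entry per point")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, labels = labels, greys = greys, name = name),
            class = "labeled_point_cloud")
}

#' @export
print.labeled_point_cloud <- function(x, ...) {
  cat(sprintf("point cloud '%s': %d points\n", x$name, nrow(x$points)))
  if (nrow(x$points) > 0) print(table(x$labels))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `labeled_point_cloud`.
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Reconstruction configuration
#'
#' @param mode `"direct"` (every foreground voxel) or `"segmented"`
#'   (boundary voxels only).
#' @param spacing a [voxel_spacing()].
#' @param foreground optional [grey_window()] restricting direct mode;
#'   `NULL` emits every voxel.
#' @param feature_window [grey_window()] selecting the internal non-wood
#'   features (required in segmented mode).
#' @param detector edge-detector name for segmented mode (see
#'   [detect_edges()]).
#' @param tilt_deg mounting inclination of the object about the slice
#'   normal, in (-180, 180]; the cloud is counter-rotated by this angle.
#' @param air_threshold grey level separating air from material in
#'   segmented mode; `NULL` = Otsu's threshold on the pooled grey histogram
#'   of the whole stack (a per-slice threshold would split pure noise on
#'   slices that contain no object at all and fabricate a solid there).
#' @param on_mask if `TRUE` (default) feature edges are detected on the
#'   binarized window mask, making them threshold-free; if `FALSE` the
#'   detector runs on raw grey values restricted to the window.
#' @return a `recon_config`.
#' @export
recon_config <- function(mode = c("direct", "segmented"), spacing,
                         foreground = NULL, feature_window = NULL,
                         detector = "roberts", tilt_deg = 0,
                         air_threshold = NULL, on_mask = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(spacing, "voxel_spacing"))
  if (mode == "segmented" && is.null(feature_window))
    stop("segmented mode requires a feature_window")
  if (!(tilt_deg > -180 && tilt_deg <= 180))
    stop("tilt_deg must lie in (-180, 180]")
  structure(list(mode = mode, spacing = spacing, foreground = foreground,
                 feature_window = feature_window, detector = detector,
                 tilt_deg = tilt_deg, air_threshold = air_threshold,
                 on_mask = on_mask),
            class = "recon_config")
}

#' z-coordinate of a slice
#'
#' The physical z position of slice k is `k * dz`: the slice index times the
#' slice thickness.
#'
#' @param k 1-based slice index (vectorized).
#' @param spacing a [voxel_spacing()].
#' @return z in µm.
#' @examples
#' assign_z(10, voxel_spacing(1, 1, 0.053))
#' @export
assign_z <- function(k, spacing) {
  stopifnot(all(k >= 1))
  k * spacing$dz
}

mask_points <- function(mask, k, spacing) {
  idx <- which(mask != 0, arr.ind = TRUE)
  cbind(x = (idx[, 2] - 1) * spacing$dx,
        y = (idx[, 1] - 1) * spacing$dy,
        z = rep(assign_z(k, spacing), nrow(idx)))
}

#' Direct reconstruction (all foreground voxels)
#'
#' Every voxel passing the optional foreground grey window becomes one
#' interior-labeled point with its grey value attached; with no window,
#' every voxel of the stack is emitted.
#'
#' @param stack a [slice_stack()].
#' @param cfg a [recon_config()] with `mode = "direct"`; defaults to one
#'   built from the stack spacing with no window.
#' @return a `labeled_point_cloud`.
#' @export
direct_reconstruct <- function(stack, cfg = recon_config("direct", stack$spacing)) {
  stopifnot(inherits(stack, "slice_stack"), cfg$mode == "direct")
  sp <- cfg$spacing
  parts <- vector("list", length(stack$slices))
  grey_parts <- vector("list", length(stack$slices))
  for (k in seq_along(stack$slices)) {
    sl <- normalize_grey(stack$slices[[k]])
    mask <- if (is.null(cfg$foreground)) {
      matrix(1L, nrow(sl$pixels), ncol(sl$pixels))
    } else {
      window_mask(sl, cfg$foreground)
    }
    parts[[k]] <- mask_points(mask, k, sp)
    grey_parts[[k]] <- sl$pixels[mask != 0]
  }
  pts <- do.call(rbind, parts)
  cloud <- point_cloud(pts, rep("interior", nrow(pts)),
                       greys = unlist(grey_parts), name = stack$name)
  apply_tilt(cloud, cfg$tilt_deg)
}

#' Stack-level air threshold
#'
#' Otsu's threshold on the pooled 0–255 grey histogram of every slice
#' (after 8-bit normalization). One consistent object definition for the
#' whole stack: slices that contain no object stay empty instead of having
#' their noise split in two.
#'
#' @param stack a [slice_stack()].
#' @return grey threshold; material is strictly above it.
#' @export
stack_air_threshold <- function(stack) {
  counts <- integer(256L)
  for (s in stack$slices) {
    pix <- normalize_grey(s)$pixels
    counts <- counts + tabulate(pix + 1L, nbins = 256L)
  }
  otsu_from_counts(counts, 0:255)
}

largest_component <- function(mask) {
  lab <- label_components(mask != 0)
  if (max(lab) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  counts <- tabulate(lab[lab > 0L])
  (lab == which.max(counts)) * 1L
}

dilate8 <- function(mask) {
  out <- mask != 0
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    out <- out | shift_logical(mask != 0, di, dj)
  }
  out
}

shift_logical <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  si <- seq_len(nr) - di; sj <- seq_len(nc) - dj
  ok_i <- si >= 1L & si <= nr; ok_j <- sj >= 1L & sj <= nc
  out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j], drop = FALSE]
  out
}

boundary_of_mask <- function(mask, detector, on_mask = TRUE, source = NULL) {
  if (on_mask || is.null(source)) {
    # edges of the binarized mask: threshold-free (any 0/1 transition in the
    # operator window exceeds 0.5)
    e <- suppressMessages(detect_edges(mask, detector, threshold = 0.5))
  } else {
    e <- suppressMessages(detect_edges(source * (mask != 0), detector))
  }
  e$mask
}

#' Segmented reconstruction (boundary voxels with labels)
#'
#' Per slice: (a) the solid object is the largest 8-connected component of
#' the above-air mask (air level from `cfg$air_threshold` or per-slice Otsu);
#' its boundary becomes `outer_surface` points. (b) Within the solid, the
#' feature grey window marks internal non-wood features (pores, cracks,
#' openings); the configured edge detector applied to that mask yields
#' `internal_feature` points. (c) Wood pixels 8-adjacent to feature pixels
#' become `wood_boundary` points. Each voxel is emitted once, with label
#' precedence internal_feature > wood_boundary > outer_surface.
#'
#' @param stack a [slice_stack()].
#' @param cfg a [recon_config()] with `mode = "segmented"`.
#' @return a `labeled_point_cloud` (empty, with a warning, if no slice
#'   contains an object).
#' @export
segmented_reconstruct <- function(stack, cfg) {
  stopifnot(inherits(stack, "slice_stack"), cfg$mode == "segmented")
  sp <- cfg$spacing
  thr <- cfg$air_threshold
  if (is.null(thr)) thr <- stack_air_threshold(stack)
  parts <- list()
  lab_parts <- list()
  grey_parts <- list()
  any_solid <- FALSE
  for (k in seq_along(stack$slices)) {
    sl <- normalize_grey(stack$slices[[k]])
    pix <- sl$pixels
    solid <- (pix > thr) * 1L
    solid <- largest_component(solid)
    if (sum(solid) == 0L) next
    any_solid <- TRUE
    surf <- boundary_of_mask(solid, cfg$detector)
    feat <- window_mask(sl, cfg$feature_window) * solid
    feat_edge <- if (sum(feat) > 0L) {
      boundary_of_mask(feat, cfg$detector, cfg$on_mask, source = pix)
    } else matrix(0L, nrow(pix), ncol(pix))
    woodb <- (solid == 1L & feat == 0L & dilate8(feat)) * 1L
    # one label per voxel, feature > wood boundary > surface
    lab <- matrix(0L, nrow(pix), ncol(pix))
    lab[surf == 1L] <- 1L
    lab[woodb == 1L] <- 2L
    lab[feat_edge == 1L] <- 3L
    for (code in 1:3) {
      m <- (lab == code) * 1L
      if (sum(m) == 0L) next
      parts[[length(parts) + 1L]] <- mask_points(m, k, sp)
      lab_parts[[length(lab_parts) + 1L]] <-
        rep(c("outer_surface", "wood_boundary", "internal_feature")[code], sum(m))
      grey_parts[[length(grey_parts) + 1L]] <- pix[m != 0]
    }
  }
  if (!any_solid) {
    warning("no object found")
    return(point_cloud(NULL, name = stack$name))
  }
  pts <- do.call(rbind, parts)
  cloud <- point_cloud(pts, unlist(lab_parts), greys = unlist(grey_parts),
                       name = stack$name)
  apply_tilt(cloud, cfg$tilt_deg)
}

#' Reconstruct a stack with a configuration
#'
#' Convenience dispatcher over [direct_reconstruct()] and
#' [segmented_reconstruct()].
#' @param stack a [slice_stack()].
#' @param cfg a [recon_config()].
#' @return a `labeled_point_cloud`.
#' @export
reconstruct <- function(stack, cfg) {
  if (cfg$mode == "direct") direct_reconstruct(stack, cfg)
  else segmented_reconstruct(stack, cfg)
}

#' Undo the mounting tilt of a cloud
#'
#' Rigid rotation by `tilt_deg` about the z axis (the slice normal) through
#' the cloud centroid; labels and greys are untouched.
#'
#' @param cloud a `labeled_point_cloud`.
#' @param tilt_deg rotation angle in degrees.
#' @return the rotated cloud.
#' @export
apply_tilt <- function(cloud, tilt_deg) {
  if (tilt_deg == 0 || n_points(cloud) == 0L) return(cloud)
  th <- tilt_deg * pi / 180
  rot <- matrix(c(cos(th), -sin(th), 0,
                  sin(th), cos(th), 0,
                  0, 0, 1), 3L, byrow = TRUE)
  ctr <- colMeans(cloud$points)
  pts <- sweep(cloud$points, 2L, ctr) %*% t(rot)
  pts <- sweep(pts, 2L, ctr, `+`)
  point_cloud(pts, cloud$labels, cloud$greys, cloud$name)
}

#' Map cloud coordinates back to voxel indices
#'
#' Inverts the coordinate convention: column `j = x/dx + 1`, row
#' `i = y/dy + 1`, slice `k = z/dz` (rounded to nearest).
#'
#' @param cloud a `labeled_point_cloud` in grid-aligned position (no tilt).
#' @param spacing the [voxel_spacing()] it was built with.
#' @return integer matrix with columns `i`, `j`, `k`.
#' @export
cloud_voxel_indices <- function(cloud, spacing) {
  p <- cloud$points
  cbind(i = as.integer(round(p[, 2] / spacing$dy)) + 1L,
        j = as.integer(round(p[, 1] / spacing$dx)) + 1L,
        k = as.integer(round(p[, 3] / spacing$dz)))
}
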
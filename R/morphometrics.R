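# Morphometrics: dimensions, volumes, change tables and distance fields.
#
# Repeated scans of one object are compared the way conservation monitoring
# does it: per-scan length/width/thickness/volume reports, percent change
# and an index (base scan = 100) against a chosen reference year, and
# cloud-to-cloud nearest-neighbour distance fields (the point-cloud
# approximation of the viewer's C2M comparison) after ICP alignment.

#' Percent change against a reference value
#'
#' `100 * (current - reference) / reference`, rounded to `digits` decimals
#' (2 by default, matching how change tables are printed). The companion
#' index is `100 + percent`.
#'
#' @param reference reference (base) value, strictly positive.
#' @param current current value.
#' @param digits decimal places (`NA` = no rounding).
#' @return percent change (vectorized over `current`).
#' @examples
#' percent_change(155606, 160958)  # +3.44
#' @export
percent_change <- function(reference, current, digits = 2) {
  if (any(reference <= 0)) stop("reference value must be strictly positive")
  p <- 100 * (current - reference) / reference
  if (!is.na(digits)) p <- round(p, digits)
  p
}

#' Change index (base = 100)
#' @inheritParams percent_change
#' @return `100 + percent_change(reference, current)`.
#' @export
change_index <- function(reference, current, digits = 2) {
  100 + percent_change(reference, current, digits)
}

#' Morphometric report of one model
#'
#' @param length,width,thickness extents in µm, `length >= width >=
#'   thickness > 0`.
#' @param volume volume in µm³, positive (`NA` allowed when not measured).
#' @param label model identifier (e.g. the scan year).
#' @return a `morph_report`.
#' @export
morph_report <- function(length, width, thickness, volume = NA_real_, label = "") {
  if (!(length >= width && width >= thickness && thickness > 0))
    stop("need length >= width >= thickness > 0")
  if (!is.na(volume) && volume <= 0) stop("volume must be positive")
  structure(list(length = length, width = width, thickness = thickness,
                 volume = volume, label = as.character(label)),
            class = "morph_report")
}

#' @export
print.morph_report <- function(x, ...) {
  cat(sprintf("model '%s': length %.1f, width %.1f, thickness %.1f um; volume %s um^3\n",
              x$label, x$length, x$width, x$thickness,
              if (is.na(x$volume)) "NA" else sprintf("%.1f", x$volume)))
  invisible(x)
}

#' Percent-change / index table across models
#'
#' For each of length, width, thickness and volume, every model is expressed
#' relative to the base model: `index = 100 + percent`, base row has index
#' 100 and percent 0. Running it twice with different bases reproduces
#' before/after-conservation baselines.
#'
#' @param reports list of [morph_report()] objects (>= 2).
#' @param base label of the reference model.
#' @return data.frame with columns `quantity`, `label`, `value`, `index`,
#'   `percent`; volume rows are dropped for models without a volume.
#' @export
change_table <- function(reports, base) {
  if (length(reports) < 2L) stop("need at least two reports")
  labels <- vapply(reports, `[[`, character(1), "label")
  if (!base %in% labels) stop("unknown base label '", base, "'")
  base_rep <- reports[[match(base, labels)]]
  rows <- list()
  for (q in c("length", "width", "thickness", "volume")) {
    ref <- base_rep[[q]]
    if (is.na(ref)) next
    for (r in reports) {
      v <- r[[q]]
      if (is.na(v)) next
      p <- percent_change(ref, v)
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = q, label = r$label, value = v,
        index = 100 + p, percent = p)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "base") <- base
  out
}

plane_rot <- function(ax, th) {
  plane <- setdiff(1:3, ax)
  r <- diag(3)
  r[plane[1], plane[1]] <- cos(th); r[plane[1], plane[2]] <- -sin(th)
  r[plane[2], plane[1]] <- sin(th); r[plane[2], plane[2]] <- cos(th)
  r
}

obb_refine <- function(p, basis, passes = 2L) {
  # PCA orientation is undefined when the scatter is (near-)isotropic — a
  # cube's covariance is a multiple of the identity. Refine the basis by
  # minimizing the in-plane bounding-box area about each axis in turn
  # (deterministic golden-section search), which recovers the tight box in
  # those degenerate cases and leaves well-conditioned clouds untouched.
  for (pass in seq_len(passes)) {
    for (ax in 1:3) {
      plane <- setdiff(1:3, ax)
      area <- function(th) {
        proj <- p %*% (basis %*% plane_rot(ax, th))[, plane]
        diff(range(proj[, 1])) * diff(range(proj[, 2]))
      }
      opt <- stats::optimize(area, c(-pi / 4, pi / 4), tol = 1e-10)
      if (opt$objective < area(0)) basis <- basis %*% plane_rot(ax, opt$minimum)
    }
  }
  basis
}

#' Length, width and thickness of a cloud
#'
#' `pca`: extents along the three principal axes of the point scatter
#' (refined by a bounding-box-area minimization, which resolves the
#' orientations plain PCA cannot — e.g. a rotated cube, whose covariance is
#' isotropic), sorted descending — the object may lie arbitrarily in the
#' scanner frame. `axis`: extents along the raw x/y/z axes, sorted
#' descending. A degenerate cloud (fewer than 4 points or coplanar) falls
#' back to `axis` with a warning.
#'
#' @param cloud a `labeled_point_cloud`.
#' @param method `"pca"` (default) or `"axis"`.
#' @return named numeric vector `c(length, width, thickness)` in µm.
#' @export
bounding_dimensions <- function(cloud, method = c("pca", "axis")) {
  method <- match.arg(method)
  p <- cloud$points
  if (nrow(p) == 0L) stop("empty cloud")
  axis_ext <- function(m) sort(apply(m, 2L, function(v) diff(range(v))),
                               decreasing = TRUE)
  if (method == "pca") {
    degenerate <- nrow(p) < 4L
    if (!degenerate) {
      cv <- cov(p)
      ev <- eigen(cv, symmetric = TRUE)
      degenerate <- ev$values[3] <= 1e-12 * max(ev$values[1], 1)
    }
    if (degenerate) {
      warning("degenerate cloud for PCA dimensions; falling back to axis extents")
      method <- "axis"
    } else {
      centred <- sweep(p, 2L, colMeans(p))
      basis <- obb_refine(centred, ev$vectors)
      ext <- axis_ext(centred %*% basis)
      return(c(length = ext[1], width = ext[2], thickness = ext[3]))
    }
  }
  ext <- axis_ext(p)
  c(length = ext[1], width = ext[2], thickness = ext[3])
}

#' Voxel-count volume
#'
#' Volume of a segmented region as (number of foreground voxels) x
#' (dx * dy * dz). Use it on solid (direct-mode) masks, never on edge
#' clouds, which are surfaces.
#'
#' @param foreground_count non-negative voxel count.
#' @param spacing a [voxel_spacing()].
#' @return volume in µm³.
#' @export
voxel_volume <- function(foreground_count, spacing) {
  stopifnot(foreground_count >= 0)
  foreground_count * spacing$dx * spacing$dy * spacing$dz
}

#' Morphometric report from a cloud and a voxel count
#'
#' @param cloud a `labeled_point_cloud`.
#' @param label model identifier.
#' @param method dimension protocol for [bounding_dimensions()].
#' @param foreground_count optional solid voxel count for the volume.
#' @param spacing required with `foreground_count`.
#' @return a [morph_report()].
#' @export
cloud_report <- function(cloud, label = cloud$name, method = "pca",
                         foreground_count = NULL, spacing = NULL) {
  dims <- bounding_dimensions(cloud, method)
  vol <- if (is.null(foreground_count)) NA_real_ else {
    stopifnot(!is.null(spacing))
    voxel_volume(foreground_count, spacing)
  }
  morph_report(dims[1], dims[2], dims[3], vol, label)
}

#' Nearest-neighbour distance field between clouds
#'
#' For every point of `compared`, the exact Euclidean distance to its
#' nearest point in `reference` (kd-tree accelerated). This is the
#' point-cloud stand-in for a cloud-to-mesh comparison: it converges to the
#' C2M distance as the reference sampling densifies.
#'
#' @param compared,reference `labeled_point_cloud`s (both non-empty).
#' @return a `distance_field`: list with `distances` (µm), `index` (matched
#'   reference point per compared point) and `summary` (mean, median, max,
#'   90/95/99th percentiles).
#' @export
nearest_distances <- function(compared, reference) {
  if (n_points(compared) == 0L) stop("empty compared cloud")
  if (n_points(reference) == 0L) stop("empty reference cloud")
  res <- nn_lookup(reference$points, compared$points)
  d <- res$dist
  structure(list(
    distances = d,
    index = res$idx,
    summary = c(mean = mean(d), median = median(d), max = max(d),
                p90 = unname(quantile(d, 0.90)),
                p95 = unname(quantile(d, 0.95)),
                p99 = unname(quantile(d, 0.99)))
  ), class = "distance_field")
}

#' @export
print.distance_field <- function(x, ...) {
  cat(sprintf("distance field over %d points (um):\n", length(x$distances)))
  print(round(x$summary, 4))
  invisible(x)
}
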
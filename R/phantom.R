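# Synthetic micro-CT phantom with ground truth.
#
# The phantom emulates what a waterlogged-wood artefact scan looks like: a
# dense solid (a tapered ellipsoid — a leaf/point-like body) at a "wood"
# grey level against a dark air background, with darker internal voids
# planted as ground truth: planar cracks carved as slabs restricted to an
# outer shell, and spherical pores. Additive i.i.d. Gaussian noise, clipped
# to [0, 255], stands in for detector noise; ring and beam-hardening
# artefacts are deliberately not simulated.
#
# Body definition, with voxel (x, y, z) relative to the grid centre,
# half-axes (a, b, c) and taper coefficient t in [0, 1):
#   u = z / c,  s(u) = 1 - t * (u + 1) / 2
#   inside  <=>  (x / (a s))^2 + (y / (b s))^2 + u^2 <= 1
# so the cross-section shrinks linearly from one end to the other (the
# "leaf" shape). Its volume has the closed form
#   V = pi a b c * (4/3 alpha^2 + 4/15 beta^2),
# with alpha = 1 - t/2, beta = -t/2 (polynomial integral of the
# cross-section area), which is the analytic ground truth for volume tests.

#' Parametric phantom specification
#'
#' @param grid integer triple `(nx, ny, n_slices)`, each >= 16.
#' @param spacing a [voxel_spacing()].
#' @param body list with half-axes `a`, `b` (in-plane, µm), `c` (along the
#'   stack, the long axis) and `taper` in \[0, 1) for the leaf shape.
#' @param cracks list of cracks, each a list with `normal` (length-3),
#'   `offset` (µm, plane offset from the centre along the normal), `width`
#'   (µm) and `depth` (fraction of the body radius the crack penetrates,
#'   from the surface inwards).
#' @param pores list with `count` and `radius` range (µm); centres are
#'   sampled inside the body (in normalized body coordinates, so the same
#'   seed yields corresponding pores after shrinkage).
#' @param grey_levels named numeric `c(air, wood, feature)` on 0–255; voids
#'   are darker than wood but brighter than air unless
#'   `bright_features = TRUE` (mineral inclusions).
#' @param noise_sd additive Gaussian sigma in grey units (>= 0).
#' @param seed RNG seed for pores and noise.
#' @param bend_deg circular-arc bend of the long axis, degrees.
#' @param bright_features allow feature grey above wood grey.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(96L, 96L, 96L),
                         spacing = voxel_spacing(20, 20, 20),
                         body = list(a = 600, b = 380, c = 850, taper = 0.35),
                         cracks = list(list(normal = c(0, 1, 0), offset = 120,
                                            width = 60, depth = 0.6)),
                         pores = list(count = 4L, radius = c(40, 80)),
                         grey_levels = c(air = 20, wood = 200, feature = 120),
                         noise_sd = 5, seed = 42L, bend_deg = 0,
                         bright_features = FALSE) {
  stopifnot(length(grid) == 3L, all(grid >= 16L), inherits(spacing, "voxel_spacing"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (body$taper < 0 || body$taper >= 1) stop("taper must be in [0, 1)")
  g <- grey_levels
  if (!all(c("air", "wood", "feature") %in% names(g)))
    stop("grey_levels needs air, wood and feature entries")
  if (!bright_features && !(g["air"] < g["feature"] && g["feature"] < g["wood"]))
    stop("need air < feature < wood grey (voids are darker than wood); ",
         "set bright_features = TRUE for bright inclusions")
  structure(list(grid = as.integer(grid), spacing = spacing, body = body,
                 cracks = cracks, pores = pores, grey_levels = g,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 bend_deg = bend_deg, bright_features = bright_features),
            class = "phantom_spec")
}

#' Analytic body volume of a phantom spec
#'
#' Exact volume of the tapered ellipsoid (see the module header): reduces to
#' `4/3 pi a b c` at taper 0. Bending shears cross-sections without changing
#' their area, so it leaves the volume unchanged.
#'
#' @param spec a [phantom_spec()].
#' @return volume in µm³.
#' @export
phantom_analytic_volume <- function(spec) {
  t <- spec$body$taper
  alpha <- 1 - t / 2
  beta <- -t / 2
  pi * spec$body$a * spec$body$b * spec$body$c *
    (4 / 3 * alpha^2 + 4 / 15 * beta^2)
}

cross_boundary <- function(f) {
  # independent 2x2 cross-difference boundary of a binary matrix: pixel
  # (i, j) is boundary when its 2x2 window is non-constant on a diagonal
  nr <- nrow(f); nc <- ncol(f)
  out <- matrix(FALSE, nr, nc)
  if (nr < 2L || nc < 2L) return(out)
  a <- f[1:(nr - 1L), 1:(nc - 1L), drop = FALSE]
  d <- f[2:nr, 2:nc, drop = FALSE]
  b <- f[1:(nr - 1L), 2:nc, drop = FALSE]
  cc <- f[2:nr, 1:(nc - 1L), drop = FALSE]
  out[1:(nr - 1L), 1:(nc - 1L)] <- (a != d) | (b != cc)
  out
}

#' Generate a synthetic slice stack with ground truth
#'
#' Voxelizes the spec's body at the wood grey, carves cracks and pores at
#' the feature grey, adds Gaussian noise (clipped to \[0, 255\]) and returns
#' both the 8-bit stack and the pre-noise ground-truth masks. Deterministic
#' given the spec's seed. Pores reaching outside the body are clipped to it
#' with a warning.
#'
#' @param spec a [phantom_spec()].
#' @return list with `stack` (a [slice_stack()]) and `truth`: logical arrays
#'   `body_mask`, `wood_mask`, `feature_mask`, `feature_boundary_mask`
#'   (dim ny x nx x n_slices), plus `analytic_volume` (µm³),
#'   `major_axis_length` (2c, µm) and `pores` (sampled centres/radii in
#'   absolute µm coordinates).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nx <- spec$grid[1]; ny <- spec$grid[2]; nz <- spec$grid[3]
  sp <- spec$spacing
  a <- spec$body$a; b <- spec$body$b; cc <- spec$body$c; taper <- spec$body$taper
  xc <- (nx - 1) / 2 * sp$dx
  yc <- (ny - 1) / 2 * sp$dy
  zc <- (nz + 1) / 2 * sp$dz
  xs <- (seq_len(nx) - 1) * sp$dx
  ys <- (seq_len(ny) - 1) * sp$dy
  s_of <- function(u) 1 - taper * (u + 1) / 2
  theta <- spec$bend_deg * pi / 180
  bend_offset <- function(z) {
    if (theta == 0) return(0)
    len <- 2 * cc
    kappa <- theta / len
    s_arc <- min(max(z - (zc - cc), 0), len)
    (1 - cos(kappa * s_arc)) / kappa
  }
  # pore centres in normalized body coordinates (deterministic via seed)
  pores <- list()
  np <- spec$pores$count
  if (np > 0L) {
    rr <- spec$pores$radius
    for (p in seq_len(np)) {
      r <- runif(1, rr[1], rr[2])
      repeat {
        q <- runif(3, -1, 1)
        s <- s_of(q[3])
        margin <- r / min(a * s, b * s, cc)
        if (sqrt(sum(q^2)) <= max(0, 1 - margin)) break
      }
      s <- s_of(q[3])
      pores[[p]] <- list(x = q[1] * a * s, y = q[2] * b * s, z = q[3] * cc, r = r)
    }
  }
  g <- spec$grey_levels
  body_mask <- array(FALSE, c(ny, nx, nz))
  feature_mask <- array(FALSE, c(ny, nx, nz))
  feature_boundary <- array(FALSE, c(ny, nx, nz))
  slices <- vector("list", nz)
  clipped <- 0L
  xm0 <- matrix(xs, ny, nx, byrow = TRUE) - xc
  ym <- matrix(ys, ny, nx) - yc
  for (k in seq_len(nz)) {
    z <- k * sp$dz
    u <- (z - zc) / cc
    xm <- xm0 - bend_offset(z)
    if (abs(u) <= 1) {
      s <- s_of(u)
      rho2 <- (xm / (a * s))^2 + (ym / (b * s))^2 + u^2
      body <- rho2 <= 1
    } else {
      body <- matrix(FALSE, ny, nx)
      rho2 <- matrix(Inf, ny, nx)
    }
    feat <- matrix(FALSE, ny, nx)
    if (any(body)) {
      rho <- sqrt(rho2)
      for (cr in spec$cracks) {
        nrm <- cr$normal / sqrt(sum(cr$normal^2))
        dist_plane <- nrm[1] * xm + nrm[2] * ym + nrm[3] * (z - zc)
        feat <- feat | (body & abs(dist_plane - cr$offset) <= cr$width / 2 &
                          rho >= 1 - cr$depth)
      }
    }
    for (po in pores) {
      if (abs(z - zc - po$z) > po$r) next
      sphere <- (xm - po$x)^2 + (ym - po$y)^2 + (z - zc - po$z)^2 <= po$r^2
      clipped <- clipped + sum(sphere & !body)
      feat <- feat | (sphere & body)
    }
    grey <- matrix(g[["air"]], ny, nx)
    grey[body] <- g[["wood"]]
    grey[feat] <- g[["feature"]]
    body_mask[, , k] <- body
    feature_mask[, , k] <- feat
    feature_boundary[, , k] <- cross_boundary(feat)
    if (spec$noise_sd > 0)
      grey <- grey + matrix(rnorm(ny * nx, sd = spec$noise_sd), ny, nx)
    grey <- matrix(as.integer(pmin(255, pmax(0, round(grey)))), ny, nx)
    slices[[k]] <- slice_image(grey, 8L, k)
  }
  if (clipped > 0L)
    warning(clipped, " feature voxels fell outside the body and were clipped")
  stack <- slice_stack(slices, sp, name = sprintf("phantom-seed%d", spec$seed))
  truth <- list(body_mask = body_mask,
                wood_mask = body_mask & !feature_mask,
                feature_mask = feature_mask,
                feature_boundary_mask = feature_boundary,
                analytic_volume = phantom_analytic_volume(spec),
                major_axis_length = 2 * spec$body$c,
                pores = lapply(pores, function(po)
                  list(x = xc + po$x, y = yc + po$y, z = zc + po$z, r = po$r)))
  list(stack = stack, truth = truth)
}

#' Deform a phantom spec (conservation-style shrinkage and bending)
#'
#' Scales the body half-axes, crack offsets/widths and pore radii by
#' `1 - shrink` and adds a circular-arc bend of the long axis, emulating
#' the shrinkage and tip bending that drying and conservation induce in
#' waterlogged wood.
#'
#' @param spec a [phantom_spec()].
#' @param shrink uniform linear shrink fraction in \[0, 0.5).
#' @param bend_deg additional bend angle in degrees.
#' @return a new [phantom_spec()].
#' @export
deform_phantom <- function(spec, shrink = 0, bend_deg = 0) {
  if (shrink < 0 || shrink >= 0.5) stop("shrink must be in [0, 0.5)")
  f <- 1 - shrink
  body <- spec$body
  body$a <- body$a * f; body$b <- body$b * f; body$c <- body$c * f
  cracks <- lapply(spec$cracks, function(cr) {
    cr$offset <- cr$offset * f
    cr$width <- cr$width * f
    cr
  })
  pores <- spec$pores
  pores$radius <- pores$radius * f
  phantom_spec(grid = spec$grid, spacing = spec$spacing, body = body,
               cracks = cracks, pores = pores,
               grey_levels = spec$grey_levels, noise_sd = spec$noise_sd,
               seed = spec$seed, bend_deg = spec$bend_deg + bend_deg,
               bright_features = spec$bright_features)
}
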
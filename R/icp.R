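# Point-to-point iterative closest point (ICP) registration.
#
# Alternates exact nearest-neighbour correspondence (kd-tree, lowest-index
# tie-break) with the closed-form least-squares rigid update (Kabsch / SVD)
# until the correspondence RMS stops improving. Initialization is centroid
# alignment plus an optional principal-axes pre-rotation: the sign-flip
# candidates of the eigenvector alignment (those with determinant +1) are
# scored by initial RMS and the best one seeds the iteration, which keeps
# the whole procedure deterministic.

kabsch <- function(moving, fixed) {
  # least-squares rigid transform mapping moving onto fixed (paired rows)
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  h <- t(sweep(moving, 2L, cm)) %*% sweep(fixed, 2L, cf)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = rot, translation = as.numeric(cf - rot %*% cm))
}

transform_points <- function(points, transform) {
  sweep(points %*% t(transform$rotation), 2L, transform$translation, `+`)
}

#' Rigid transform constructor
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 vector in µm.
#' @return a `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) || abs(det(rotation) - 1) > 1e-9 ||
      max(abs(t(rotation) %*% rotation - diag(3))) > 1e-9)
    stop("rotation must be a proper orthonormal 3x3 matrix")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to a cloud
#' @param cloud a `labeled_point_cloud`.
#' @param transform a [rigid_transform()].
#' @return the transformed cloud.
#' @export
transform_cloud <- function(cloud, transform) {
  point_cloud(transform_points(cloud$points, transform),
              cloud$labels, cloud$greys, cloud$name)
}

icp_rms <- function(pts, fixed_pts) {
  sqrt(mean(nn_lookup(fixed_pts, pts)$dist^2))
}

#' Point-to-point ICP alignment
#'
#' Finds the rigid transform that moves `moving` onto `fixed`.
#'
#' @param moving,fixed `labeled_point_cloud`s with at least 3 points each.
#' @param max_iter iteration cap (default 50).
#' @param tol stop when the RMS improvement over one iteration drops below
#'   this value, in µm (default 1e-6).
#' @param init_axes use the principal-axes pre-rotation in addition to
#'   centroid alignment (default TRUE).
#' @return list with `transform` (a [rigid_transform()]), `rms` (final
#'   correspondence RMS, µm), `rms_trace` (per-iteration RMS), `iterations`
#'   and `converged`.
#' @export
icp_align <- function(moving, fixed, max_iter = 50L, tol = 1e-6,
                      init_axes = TRUE) {
  pm <- moving$points
  pf <- fixed$points
  if (nrow(pm) < 3L || nrow(pf) < 3L) stop("ICP needs at least 3 points per cloud")
  cm <- colMeans(pm)
  cf <- colMeans(pf)
  candidates <- list(diag(3))
  if (init_axes && nrow(pm) >= 4L && nrow(pf) >= 4L) {
    vm <- eigen(cov(pm), symmetric = TRUE)$vectors
    vf <- eigen(cov(pf), symmetric = TRUE)$vectors
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      vmf <- vm %*% diag(c(s1, s2, 1))
      r0 <- vf %*% t(vmf)
      if (det(r0) < 0) r0 <- vf %*% t(vm %*% diag(c(s1, s2, -1)))
      candidates[[length(candidates) + 1L]] <- r0
    }
  }
  best <- NULL
  for (r0 in candidates) {
    tr <- list(rotation = r0, translation = as.numeric(cf - r0 %*% cm))
    rms0 <- icp_rms(transform_points(pm, tr), pf)
    if (is.null(best) || rms0 < best$rms) best <- list(tr = tr, rms = rms0)
  }
  tr <- best$tr
  rms <- best$rms
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    cur <- transform_points(pm, tr)
    nn <- nn_lookup(pf, cur)
    upd <- kabsch(pm, pf[nn$idx, , drop = FALSE])
    new_rms <- icp_rms(transform_points(pm, upd), pf)
    if (new_rms <= rms) {
      tr <- upd
      improvement <- rms - new_rms
      rms <- new_rms
      trace <- c(trace, rms)
      if (improvement < tol) { converged <- TRUE; break }
    } else {
      converged <- TRUE  # correspondence fixed point reached
      break
    }
  }
  list(transform = rigid_transform(tr$rotation, tr$translation),
       rms = rms, rms_trace = trace, iterations = iter,
       converged = converged || iter < max_iter)
}

#' Rotation angle of a rigid transform
#'
#' Total rotation angle in degrees, from the trace of the rotation matrix.
#' @param transform a [rigid_transform()].
#' @return angle in degrees.
#' @export
rotation_angle_deg <- function(transform) {
  ctheta <- (sum(diag(transform$rotation)) - 1) / 2
  acos(min(1, max(-1, ctheta))) * 180 / pi
}
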
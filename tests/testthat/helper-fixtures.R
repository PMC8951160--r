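# Shared fixtures: small phantoms and independent (brute-force) oracles.
# Phantoms are generated in code at test time; nothing is stored on disk.

tiny_spec <- function(noise_sd = 0, seed = 11L, ...) {
  phantom_spec(grid = c(48L, 48L, 48L), spacing = voxel_spacing(40, 40, 40),
               body = list(a = 600, b = 380, c = 850, taper = 0.35),
               noise_sd = noise_sd, seed = seed, ...)
}

feature_win <- function() grey_window(100, 140)

seg_cfg <- function(spacing, ...) {
  recon_config("segmented", spacing, feature_window = feature_win(), ...)
}

# independent brute-force edge oracles (double loops, no shared code with
# the package's vectorized implementations)

brute_roberts <- function(m, threshold) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr - 1L)) for (j in seq_len(nc - 1L)) {
    gx <- m[i, j] - m[i + 1L, j + 1L]
    gy <- m[i, j + 1L] - m[i + 1L, j]
    if (sqrt(gx^2 + gy^2) > threshold) out[i, j] <- 1L
  }
  out
}

brute_grad3 <- function(m, kx, ky, threshold) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  for (i in 2:(nr - 1L)) for (j in 2:(nc - 1L)) {
    win <- m[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
    gx <- sum(win * kx)
    gy <- sum(win * ky)
    if (sqrt(gx^2 + gy^2) > threshold) out[i, j] <- 1L
  }
  out
}

prewitt_kx <- matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, byrow = TRUE)
sobel_kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)

# natural-order comparator for the sorting oracle: split stem/extension,
# compare text/number runs pairwise
nat_compare <- function(a, b) {
  split_runs <- function(s) {
    if (s == "") return(list())
    runs <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    lapply(runs, function(r)
      if (grepl("^[0-9]+$", r)) list(num = TRUE, v = as.numeric(r))
      else list(num = FALSE, v = r))
  }
  key_parts <- function(name) {
    stem <- sub("\\.[^.]*$", "", name)
    ext <- if (grepl("\\.[^.]*$", name)) sub("^.*\\.", "", name) else ""
    list(split_runs(stem), split_runs(ext))
  }
  cmp_runs <- function(ra, rb) {
    for (i in seq_len(max(length(ra), length(rb)))) {
      if (i > length(ra)) return(-1L)
      if (i > length(rb)) return(1L)
      x <- ra[[i]]; y <- rb[[i]]
      if (x$num != y$num) return(if (x$num) -1L else 1L)
      if (x$num) {
        if (x$v != y$v) return(if (x$v < y$v) -1L else 1L)
      } else if (x$v != y$v) {
        return(if (x$v < y$v) -1L else 1L)
      }
    }
    0L
  }
  ka <- key_parts(a); kb <- key_parts(b)
  c1 <- cmp_runs(ka[[1]], kb[[1]])
  if (c1 != 0L) return(c1)
  cmp_runs(ka[[2]], kb[[2]])
}

brute_nat_sort <- function(names) {
  # insertion sort with the comparator
  out <- names[1]
  for (n in names[-1]) {
    pos <- length(out) + 1L
    for (i in seq_along(out)) {
      if (nat_compare(n, out[i]) < 0L) { pos <- i; break }
    }
    out <- append(out, n, after = pos - 1L)
  }
  out
}

jaccard_voxels <- function(cloud, spacing, truth_mask) {
  idx <- cloud_voxel_indices(cloud, spacing)
  a <- paste(idx[, 1], idx[, 2], idx[, 3])
  gt <- which(truth_mask, arr.ind = TRUE)
  b <- paste(gt[, 1], gt[, 2], gt[, 3])
  length(intersect(a, b)) / length(union(a, b))
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
}
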
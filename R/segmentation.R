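# Grey-window selection and per-slice edge detection.
#
# Segmentation here means restricting a slice to a grey-value window (the
# non-wood features sit in a narrow band, e.g. 110–130 on the 0–255 scale)
# and marking boundaries with an edge operator. The Roberts cross is the
# primary detector: a 2x2 mask of diagonal differences, cheap, unsmoothed,
# and good at keeping small openings. Six alternates are provided for
# side-by-side comparison.

#' Grey-value window
#'
#' @param lo,hi inclusive bounds on the 0–255 grey scale.
#' @return a `grey_window` object.
#' @export
grey_window <- function(lo, hi) {
  if (!(lo >= 0 && lo <= hi && hi <= 255)) stop("need 0 <= lo <= hi <= 255")
  structure(list(lo = lo, hi = hi), class = "grey_window")
}

#' Parse a "LO:HI" window string
#' @param text e.g. `"110:130"`.
#' @return a [grey_window()].
#' @export
parse_window <- function(text) {
  parts <- as.numeric(strsplit(text, ":", fixed = TRUE)[[1]])
  if (length(parts) != 2L || any(is.na(parts))) stop("window must be 'LO:HI'")
  grey_window(parts[1], parts[2])
}

#' Binary mask of pixels inside a grey window
#'
#' @param slice an 8-bit [slice_image()] (or a plain integer matrix).
#' @param window a [grey_window()]; both bounds inclusive.
#' @return integer matrix of 0/1, same shape as the slice.
#' @export
window_mask <- function(slice, window) {
  stopifnot(inherits(window, "grey_window"))
  pix <- if (inherits(slice, "slice_image")) {
    if (slice$bit_depth != 8L) stop("window_mask needs an 8-bit slice; see normalize_grey()")
    slice$pixels
  } else slice
  mask <- (pix >= window$lo & pix <= window$hi) * 1L
  dim(mask) <- dim(pix)
  mask
}

#' Otsu's threshold
#'
#' Maximizes between-class variance on a 256-bin histogram. For integer grey
#' images the bins are the grey levels themselves; continuous inputs (e.g.
#' gradient magnitudes) are binned over their range.
#'
#' @param values numeric vector or matrix.
#' @return threshold on the scale of `values`; pixels strictly above it are
#'   "foreground".
#' @export
otsu_threshold <- function(values) {
  v <- as.numeric(values)
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(lo)
  nb <- 256L
  idx <- pmin(nb, floor((v - lo) / (hi - lo) * nb) + 1L)
  h <- tabulate(idx, nbins = nb)
  mids <- lo + (seq_len(nb) - 0.5) * (hi - lo) / nb
  k <- otsu_split_bin(h, mids)
  lo + k * (hi - lo) / nb  # upper edge of the chosen bin
}

otsu_split_bin <- function(h, mids) {
  h <- as.numeric(h)
  mids <- as.numeric(mids)
  nb <- length(h)
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[nb]; mt <- m[nb]
  w0 <- w[-nb]; m0 <- m[-nb]
  valid <- w0 > 0 & w0 < n
  sigma_b <- rep(-Inf, nb - 1L)
  sigma_b[valid] <- (mt * w0[valid] - n * m0[valid])^2 /
    (w0[valid] * (n - w0[valid]))
  # the maximizer is a plateau when the histogram has an empty gap between
  # classes; take the plateau midpoint (the gap centre)
  best <- which(sigma_b >= max(sigma_b) * (1 - 1e-12))
  round(mean(best))
}

otsu_from_counts <- function(counts, levels) {
  if (sum(counts > 0) <= 1L) return(levels[which.max(counts)])
  levels[otsu_split_bin(counts, levels)]  # split after this level
}

edge_map <- function(mask, detector, threshold) {
  storage.mode(mask) <- "integer"
  structure(list(mask = mask, detector = detector, threshold = threshold),
            class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("edge map (%s, threshold %g): %d edge pixels of %d x %d\n",
              x$detector, x$threshold, sum(x$mask), nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

as_grey_matrix <- function(image) {
  if (inherits(image, "slice_image")) image$pixels else image
}

shift_mat <- function(m, di, dj) {
  # shifted copy padded with edge replication (used only for smoothing)
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
  cj <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
  m[ri, cj, drop = FALSE]
}

conv3_valid <- function(m, kernel) {
  # 3x3 correlation; positions without a complete window are set to 0
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  if (nr < 3L || nc < 3L) return(out)
  acc <- matrix(0, nr - 2L, nc - 2L)
  for (di in 0:2) for (dj in 0:2) {
    k <- kernel[di + 1L, dj + 1L]
    if (k != 0)
      acc <- acc + k * m[(1L + di):(nr - 2L + di), (1L + dj):(nc - 2L + dj), drop = FALSE]
  }
  out[2:(nr - 1L), 2:(nc - 1L)] <- acc
  out
}

gaussian_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  # separable filter with replicated borders
  acc <- matrix(0, nrow(m), ncol(m))
  for (d in seq(-r, r)) acc <- acc + k[d + r + 1L] * shift_mat(m, d, 0L)
  out <- matrix(0, nrow(m), ncol(m))
  for (d in seq(-r, r)) out <- out + k[d + r + 1L] * shift_mat(acc, 0L, d)
  out
}

roberts_magnitude <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- m[1:(nr - 1L), 1:(nc - 1L), drop = FALSE] - m[2:nr, 2:nc, drop = FALSE]
  gy <- m[1:(nr - 1L), 2:nc, drop = FALSE] - m[2:nr, 1:(nc - 1L), drop = FALSE]
  mag <- matrix(0, nr, nc)
  mag[1:(nr - 1L), 1:(nc - 1L)] <- sqrt(gx^2 + gy^2)
  mag
}

#' Roberts-cross edge detection
#'
#' The Roberts operator takes the two diagonal differences over each 2x2
#' window: `Gx = p(i,j) - p(i+1,j+1)`, `Gy = p(i,j+1) - p(i+1,j)`; a pixel is
#' an edge when `sqrt(Gx^2 + Gy^2)` exceeds the threshold. Positions in the
#' last row/column, which lack a complete window, are never edges.
#'
#' @param image 2-D numeric matrix (or a [slice_image()]), at least 2x2.
#' @param threshold gradient-magnitude cutoff; `NULL` picks Otsu's threshold
#'   on the magnitude histogram and reports the chosen value.
#' @return an `edge_map` (binary mask, detector name, threshold used).
#' @export
roberts_edges <- function(image, threshold = NULL) {
  m <- as_grey_matrix(image)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("image must be at least 2 x 2")
  mag <- roberts_magnitude(m)
  if (is.null(threshold)) {
    threshold <- otsu_threshold(mag)
    message(sprintf("roberts_edges: automatic (Otsu) threshold %.4g", threshold))
  }
  edge_map((mag > threshold) * 1L, "roberts", threshold)
}

grad3_edges <- function(m, kx, ky, threshold, name) {
  gx <- conv3_valid(m, kx)
  gy <- conv3_valid(m, ky)
  mag <- sqrt(gx^2 + gy^2)
  if (is.null(threshold)) {
    threshold <- otsu_threshold(mag)
    message(sprintf("%s edges: automatic (Otsu) threshold %.4g", name, threshold))
  }
  edge_map((mag > threshold) * 1L, name, threshold)
}

log_kernel <- function(sigma) {
  r <- max(2L, ceiling(3 * sigma))
  g <- expand.grid(x = seq(-r, r), y = seq(-r, r))
  k <- with(g, (x^2 + y^2 - 2 * sigma^2) / sigma^4 * exp(-(x^2 + y^2) / (2 * sigma^2)))
  k <- matrix(k, 2L * r + 1L)
  k - mean(k)  # zero-sum so flat regions give exactly zero response
}

convn_valid <- function(m, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  if (nr < nrow(kernel) || nc < ncol(kernel)) return(out)
  acc <- matrix(0, nr - 2L * r, nc - 2L * r)
  for (di in 0:(2L * r)) for (dj in 0:(2L * r)) {
    k <- kernel[di + 1L, dj + 1L]
    if (k != 0)
      acc <- acc + k * m[(1L + di):(nr - 2L * r + di), (1L + dj):(nc - 2L * r + dj), drop = FALSE]
  }
  out[(r + 1L):(nr - r), (r + 1L):(nc - r)] <- acc
  out
}

zero_crossings <- function(resp, threshold) {
  # a pixel is a zero crossing when its response changes sign against a
  # neighbour with slope above the threshold and the pixel is the
  # smaller-magnitude side of the pair (ties mark both pixels)
  nr <- nrow(resp); nc <- ncol(resp)
  out <- matrix(0L, nr, nc)
  if (nr < 3L || nc < 3L) return(out)
  cen <- resp[2:(nr - 1L), 2:(nc - 1L), drop = FALSE]
  hit <- matrix(FALSE, nr - 2L, nc - 2L)
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    a <- resp[(2L + d[1]):(nr - 1L + d[1]), (2L + d[2]):(nc - 1L + d[2]), drop = FALSE]
    b <- resp[(2L - d[1]):(nr - 1L - d[1]), (2L - d[2]):(nc - 1L - d[2]), drop = FALSE]
    hit <- hit | (cen * a < 0 & abs(cen - a) > threshold & abs(cen) <= abs(a)) |
      (cen * b < 0 & abs(cen - b) > threshold & abs(cen) <= abs(b))
  }
  out[2:(nr - 1L), 2:(nc - 1L)] <- hit * 1L
  out
}

canny_impl <- function(m, sigma, low, high, nms = TRUE, auto = "otsu") {
  sm <- gaussian_smooth(m, sigma)
  sob_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, byrow = TRUE)
  sob_y <- t(sob_x)
  gx <- conv3_valid(sm, sob_x)
  gy <- conv3_valid(sm, sob_y)
  mag <- sqrt(gx^2 + gy^2)
  if (is.null(high))
    high <- if (auto == "otsu") otsu_threshold(mag)
            else as.numeric(quantile(mag, 0.9))
  if (is.null(low)) low <- 0.4 * high
  keep <- mag
  if (nms) {
    # non-maximum suppression along the quantized gradient direction
    ang <- atan2(gy, gx)
    sector <- (round(ang / (pi / 4)) %% 4)
    nr <- nrow(m); nc <- ncol(m)
    off <- list(`0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 0L), `3` = c(1L, -1L))
    supp <- matrix(FALSE, nr, nc)
    for (s in 0:3) {
      d <- off[[as.character(s)]]
      n1 <- shift_mat(mag, d[1], d[2])
      n2 <- shift_mat(mag, -d[1], -d[2])
      supp <- supp | (sector == s & (mag < n1 | mag < n2))
    }
    keep[supp] <- 0
  }
  strong <- keep > high
  weak <- keep > low
  # hysteresis: keep weak pixels connected (8-conn) to a strong pixel
  lab <- label_components(weak)
  good <- unique(lab[strong])
  mask <- (lab > 0 & lab %in% good) * 1L
  dim(mask) <- dim(m)
  list(mask = mask, threshold = high)
}

edge_detectors <- c("roberts", "prewitt", "sobel", "log", "zerocross",
                    "canny", "approx_canny")

#' Edge detection with a named operator
#'
#' Dispatches to one of seven detectors: `roberts` (2x2 cross differences),
#' `prewitt` / `sobel` (3x3 first-difference kernels), `log`
#' (Laplacian-of-Gaussian zero crossings at `sigma`), `zerocross` (zero
#' crossings of the plain 3x3 Laplacian), `canny` (Gaussian smoothing, Sobel
#' gradients, non-maximum suppression, hysteresis) and `approx_canny`
#' (Canny with lighter smoothing and cheap fixed-percentile thresholds in
#' place of the Otsu search — a faster approximation). Border
#' positions without a complete kernel window are never edges.
#'
#' @param image 2-D numeric matrix or [slice_image()].
#' @param detector one of the seven names above (`"approx-canny"` accepted).
#' @param threshold magnitude cutoff (gradient detectors), slope cutoff
#'   (zero-crossing detectors) or high hysteresis threshold (Canny);
#'   `NULL` = automatic (Otsu).
#' @param sigma Gaussian scale for `log`, `canny`, `approx_canny`.
#' @param low low hysteresis threshold for the Canny variants
#'   (default `0.4 * threshold`).
#' @return an `edge_map`.
#' @export
detect_edges <- function(image, detector = "roberts", threshold = NULL,
                         sigma = 2, low = NULL) {
  detector <- gsub("-", "_", tolower(detector))
  if (!detector %in% edge_detectors)
    stop("unknown detector '", detector, "'; valid: ",
         paste(edge_detectors, collapse = ", "))
  m <- as_grey_matrix(image)
  if (detector == "roberts") return(roberts_edges(m, threshold))
  if (detector == "prewitt") {
    kx <- matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3L, byrow = TRUE)
    return(grad3_edges(m, kx, t(kx), threshold, "prewitt"))
  }
  if (detector == "sobel") {
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, byrow = TRUE)
    return(grad3_edges(m, kx, t(kx), threshold, "sobel"))
  }
  if (detector == "log") {
    resp <- convn_valid(m, log_kernel(sigma))
    if (is.null(threshold)) threshold <- 0.75 * mean(abs(resp))
    return(edge_map(zero_crossings(resp, threshold), "log", threshold))
  }
  if (detector == "zerocross") {
    lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3L, byrow = TRUE)
    resp <- conv3_valid(m, lap)
    if (is.null(threshold)) threshold <- 0.75 * mean(abs(resp))
    return(edge_map(zero_crossings(resp, threshold), "zerocross", threshold))
  }
  if (detector == "canny") {
    res <- canny_impl(m, sigma = sigma, low = low, high = threshold,
                      nms = TRUE, auto = "otsu")
  } else {
    # approx_canny: lighter smoothing and cheap fixed-percentile thresholds
    res <- canny_impl(m, sigma = max(1, sigma / 2), low = low,
                      high = threshold, nms = TRUE, auto = "quantile")
  }
  edge_map(res$mask, detector, res$threshold)
}

#' Run all seven edge detectors on one slice
#'
#' Produces the side-by-side comparison used to choose an operator: one row
#' per detector with its edge-pixel count, plus the masks themselves.
#'
#' @param slice [slice_image()] or matrix.
#' @param threshold,sigma passed to every detector (see [detect_edges()]).
#' @return data.frame with columns `detector`, `edge_pixels`, `threshold`;
#'   the binary masks are attached as `attr(, "masks")` (named list).
#' @export
compare_edge_detectors <- function(slice, threshold = NULL, sigma = 2) {
  maps <- lapply(edge_detectors, function(d)
    suppressMessages(detect_edges(slice, d, threshold = threshold, sigma = sigma)))
  names(maps) <- edge_detectors
  out <- data.frame(
    detector = edge_detectors,
    edge_pixels = vapply(maps, function(e) sum(e$mask), numeric(1)),
    threshold = vapply(maps, function(e) e$threshold, numeric(1)),
    row.names = NULL
  )
  attr(out, "masks") <- lapply(maps, `[[`, "mask")
  out
}
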
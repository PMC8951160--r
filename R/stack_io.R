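# Slice-stack containers and I/O.
#
# A micro-CT scan arrives as a directory of numbered 2-D grey slice images
# plus acquisition metadata. The stack is ordered by a natural (alphanumeric)
# sort of the file names — never by filesystem listing order — and each slice
# keeps its 1-based position k, from which its physical z-coordinate k * dz
# is later derived.

#' Physical voxel spacing
#'
#' @param dx,dy in-plane spacing in µm per pixel (column and row step).
#' @param dz slice thickness in µm (the distance between consecutive slices).
#' @return a `voxel_spacing` object.
#' @examples
#' voxel_spacing(10, 10, 44.2)
#' @export
voxel_spacing <- function(dx, dy, dz) {
  vals <- c(dx = dx, dy = dy, dz = dz)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("voxel spacing components must be strictly positive and finite")
  structure(list(dx = dx, dy = dy, dz = dz), class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("voxel spacing: dx = %g, dy = %g, dz = %g (um)\n", x$dx, x$dy, x$dz))
  invisible(x)
}

#' A single grey slice image
#'
#' @param pixels integer matrix of grey values (rows = image rows).
#' @param bit_depth 8 or 16.
#' @param index 1-based slice number within its stack.
#' @return a `slice_image` object.
#' @export
slice_image <- function(pixels, bit_depth = 8L, index = 1L) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("slice pixels must be a non-empty matrix")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit depth must be 8 or 16")
  maxv <- 2^bit_depth - 1
  if (min(pixels) < 0 || max(pixels) > maxv)
    stop("pixel values outside [0, ", maxv, "]")
  structure(list(pixels = pixels, bit_depth = bit_depth, index = as.integer(index)),
            class = "slice_image")
}

#' An ordered stack of slices with voxel spacing
#'
#' @param slices list of [slice_image()] objects, all the same shape and
#'   bit depth; indices are (re)assigned consecutively from 1.
#' @param spacing a [voxel_spacing()].
#' @param name free-text stack identifier.
#' @return a `slice_stack` object.
#' @export
slice_stack <- function(slices, spacing, name = "") {
  if (length(slices) == 0L) stop("a slice stack needs at least one slice")
  stopifnot(inherits(spacing, "voxel_spacing"))
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  depths <- vapply(slices, function(s) s$bit_depth, integer(1))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent slice geometry")
  if (any(depths != depths[1])) stop("inconsistent slice bit depth")
  for (k in seq_along(slices)) slices[[k]]$index <- k
  structure(list(slices = slices, spacing = spacing, name = name),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$slices[[1]]$pixels)
  cat(sprintf("slice stack '%s': %d slices of %d x %d (%d-bit)\n",
              x$name, length(x$slices), d[1], d[2], x$slices[[1]]$bit_depth))
  print(x$spacing)
  invisible(x)
}

nat_sort_key <- function(name) {
  # One sortable key per path: components compared per directory level,
  # the final component split into stem and extension, and every digit run
  # padded so numeric comparison falls out of plain string order. Separators
  # \x01 (path level) and \x02 (stem/extension) sort below all printable
  # characters, which puts shorter names before longer ones.
  pad_runs <- function(s) {
    if (s == "") return(s)
    runs <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    runs <- vapply(runs, function(r) {
      if (grepl("^[0-9]+$", r)) {
        sprintf("%024.0f", as.numeric(r))
      } else r
    }, character(1))
    paste0(runs, collapse = "")
  }
  comps <- strsplit(name, "/", fixed = TRUE)[[1]]
  last <- comps[length(comps)]
  m <- regexpr("\\.[^.]*$", last)
  if (m > 1) {
    stem <- substr(last, 1L, m - 1L)
    ext <- substr(last, m + 1L, nchar(last))
    comps[length(comps)] <- paste0(pad_runs(stem), "\x02", pad_runs(ext))
  } else {
    comps[length(comps)] <- pad_runs(last)
  }
  comps[-length(comps)] <- vapply(comps[-length(comps)], pad_runs, character(1))
  paste0(comps, collapse = "\x01")
}

#' Natural (alphanumeric) sort of slice file names
#'
#' Orders names the way slice sequences are numbered: embedded integer runs
#' compare numerically (`s2` before `s10`), the file extension compares
#' separately from the stem so shorter names sort first, and path components
#' compare per directory level.
#'
#' @param names character vector of relative paths.
#' @return the same names, naturally ordered.
#' @examples
#' natural_sort_filenames(c("s10.tif", "s2.tif", "s1.tif"))
#' @export
natural_sort_filenames <- function(names) {
  if (length(names) == 0L) stop("no slice files")
  keys <- vapply(names, nat_sort_key, character(1), USE.NAMES = FALSE)
  names[order(keys, names, method = "radix")]
}

#' Read a slice stack from a directory
#'
#' Files matching `pattern` are naturally sorted by name and read in that
#' order; each slice gets index k = its position (1-based), independent of
#' any numbering gaps in the file names.
#'
#' @param directory directory containing the slice images.
#' @param spacing a [voxel_spacing()]; taken from acquisition metadata, never
#'   inferred silently from image headers.
#' @param pattern glob pattern for slice files (default all TIFFs).
#' @param name stack name; defaults to the directory basename.
#' @return a [slice_stack()].
#' @export
read_stack <- function(directory, spacing, pattern = "*.tif", name = basename(directory)) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  files <- list.files(directory, pattern = utils::glob2rx(pattern))
  if (length(files) == 0L) stop("no slice files matching '", pattern, "' in ", directory)
  files <- natural_sort_filenames(files)
  slices <- vector("list", length(files))
  for (k in seq_along(files)) {
    img <- tryCatch(read_slice_image(file.path(directory, files[k])),
                    error = function(e) stop("failed to read slice '", files[k], "': ",
                                             conditionMessage(e)))
    slices[[k]] <- slice_image(img$pixels, img$bit_depth, k)
  }
  slice_stack(slices, spacing, name = name)
}

#' Write a slice stack as numbered image files
#'
#' @param stack a [slice_stack()].
#' @param directory output directory (created if needed).
#' @param prefix file-name prefix; files are `<prefix>_0001.tif`, ...
#' @param format "tiff" or "pgm".
#' @return the directory, invisibly.
#' @export
write_stack <- function(stack, directory, prefix = "slice", format = c("tiff", "pgm")) {
  format <- match.arg(format)
  ext <- if (format == "tiff") "tif" else "pgm"
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (s in stack$slices) {
    path <- file.path(directory, sprintf("%s_%04d.%s", prefix, s$index, ext))
    write_slice_image(s$pixels, path, s$bit_depth)
  }
  invisible(directory)
}

#' Normalize a slice to the 8-bit grey scale
#'
#' 8-bit slices pass through unchanged; 16-bit slices are mapped by the fixed
#' ratio `floor(v / 257)` so that 0 -> 0 and 65535 -> 255. The ratio is fixed
#' (not per-stack min–max) so that a grey window such as 110–130 selects the
#' same physical attenuation in every slice of every stack.
#'
#' @param slice a [slice_image()].
#' @return an 8-bit [slice_image()].
#' @export
normalize_grey <- function(slice) {
  stopifnot(inherits(slice, "slice_image"))
  if (slice$bit_depth == 8L) return(slice)
  if (slice$bit_depth != 16L) stop("unsupported bit depth: ", slice$bit_depth)
  slice_image(slice$pixels %/% 257L, 8L, slice$index)
}
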
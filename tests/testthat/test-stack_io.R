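test_that("natural sort orders numeric runs numerically", {
  expect_equal(natural_sort_filenames(c("s10.tif", "s2.tif", "s1.tif")),
               c("s1.tif", "s2.tif", "s10.tif"))
  expect_equal(natural_sort_filenames("a.tif"), "a.tif")
  expect_error(natural_sort_filenames(character(0)), "no slice files")
})

test_that("natural sort matches the brute-force comparator oracle", {
  set.seed(101)
  names50 <- sprintf("img_%d.tif", 1:50)
  shuffled <- sample(names50)
  expect_equal(natural_sort_filenames(shuffled), names50)

  # mixed stems, extensions and digit runs against the pairwise comparator
  pool <- c("a.tif", "a1.tif", "a02.tif", "a2b.tif", "a10.tif", "a2.png",
            "b.tif", "ab.tif", "a.tiff", "slice_9.tif", "slice_10.tif",
            "slice_100.tif", "x2y3.tif", "x2y10.tif", "x10y2.tif")
  for (rep in 1:5) {
    shuf <- sample(pool)
    expect_equal(natural_sort_filenames(shuf), brute_nat_sort(shuf))
  }
})

test_that("natural sort is idempotent and a bijection", {
  set.seed(7)
  names <- sample(c(sprintf("s%d.tif", sample(200, 40)), "s.tif", "s_1_2.tif"))
  once <- natural_sort_filenames(names)
  expect_equal(natural_sort_filenames(once), once)
  expect_setequal(once, names)
})

test_that("TIFF codec round-trips 8- and 16-bit slices exactly", {
  set.seed(5)
  for (depth in c(8L, 16L)) {
    m <- matrix(sample(0:(2^depth - 1), 19 * 23, TRUE), 19, 23)
    f <- withr::local_tempfile(fileext = ".tif")
    write_slice_image(m, f, depth)
    back <- read_slice_image(f)
    expect_identical(back$pixels, m)
    expect_identical(back$bit_depth, depth)
  }
})

test_that("TIFF writer agrees with an external reference reader", {
  # tifffile (Python) as the independent oracle for the baseline TIFF dialect
  set.seed(6)
  m <- matrix(sample(0:65535, 12 * 9, TRUE), 12, 9)
  f <- withr::local_tempfile(fileext = ".tif")
  out <- withr::local_tempfile(fileext = ".txt")
  write_slice_image(m, f, 16L)
  code <- sprintf(
    "import tifffile, numpy as np; a = tifffile.imread(%s); np.savetxt(%s, a, fmt='%%d')",
    shQuote(f), shQuote(out))
  status <- system2("python", c("-c", shQuote(code)))
  expect_identical(status, 0L)
  ref <- as.matrix(read.table(out))
  dimnames(ref) <- NULL
  expect_equal(ref, m)
})

test_that("read_stack orders by name, not filesystem order, and round-trips", {
  dir <- withr::local_tempdir()
  set.seed(9)
  mats <- lapply(1:12, function(k) matrix(sample(0:255, 6 * 8, TRUE), 6, 8))
  # write in scrambled creation order with non-padded numeric names
  for (k in sample(12)) write_slice_image(mats[[k]], file.path(dir, sprintf("s%d.tif", k)))
  st <- read_stack(dir, voxel_spacing(1, 2, 3))
  expect_length(st$slices, 12L)
  expect_equal(vapply(st$slices, `[[`, integer(1), "index"), 1:12)
  for (k in 1:12) expect_identical(st$slices[[k]]$pixels, mats[[k]])
  expect_equal(st$spacing$dz, 3)
})

test_that("read_stack rejects mixed geometry and missing input", {
  dir <- withr::local_tempdir()
  write_slice_image(matrix(0L, 4, 4), file.path(dir, "a1.tif"))
  write_slice_image(matrix(0L, 5, 4), file.path(dir, "a2.tif"))
  expect_error(read_stack(dir, voxel_spacing(1, 1, 1)), "inconsistent slice geometry")
  expect_error(read_stack(dir, voxel_spacing(1, 1, 1), pattern = "*.png"),
               "no slice files")
  expect_error(read_stack(file.path(dir, "nope"), voxel_spacing(1, 1, 1)),
               "no such directory")
})

test_that("write_stack -> read_stack reproduces a phantom exactly", {
  ph <- generate_phantom(tiny_spec(noise_sd = 3))
  dir <- withr::local_tempdir()
  write_stack(ph$stack, dir)
  back <- read_stack(dir, ph$stack$spacing)
  expect_length(back$slices, length(ph$stack$slices))
  for (k in seq_along(back$slices))
    expect_identical(back$slices[[k]]$pixels, ph$stack$slices[[k]]$pixels)
})

test_that("normalize_grey maps 16-bit onto 8-bit by the fixed ratio", {
  s8 <- slice_image(matrix(0:255, 16, 16), 8L)
  expect_identical(normalize_grey(s8), s8)
  const <- slice_image(matrix(65535L, 4, 4), 16L)
  expect_true(all(normalize_grey(const)$pixels == 255L))
  set.seed(3)
  v <- matrix(sample(0:65535, 64, TRUE), 8, 8)
  s16 <- slice_image(v, 16L)
  out <- normalize_grey(s16)
  expect_identical(out$pixels, matrix(as.integer(floor(v / 257)), 8, 8))
  expect_identical(out$bit_depth, 8L)
  expect_identical(dim(out$pixels), dim(v))
})

test_that("voxel_spacing and slice invariants are enforced", {
  expect_error(voxel_spacing(0, 1, 1), "strictly positive")
  expect_error(voxel_spacing(1, 1, Inf), "strictly positive")
  expect_error(slice_image(matrix(-1L, 2, 2)), "outside")
  expect_error(slice_image(matrix(256L, 2, 2), 8L), "outside")
  expect_error(slice_stack(list(), voxel_spacing(1, 1, 1)), "at least one")
})
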
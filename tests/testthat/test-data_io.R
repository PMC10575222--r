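test_that("canonicalize pads to target frame, centred, conserving values", {
  cb <- rect_cube(41, 37, 5)
  out <- canonicalize(cb, c(60, 80))
  expect_equal(dim(out$values), c(60, 80, 5))
  # nonzero support keeps original extent and total reflectance
  nz <- which(apply(out$values != 0, c(1, 2), any), arr.ind = TRUE)
  expect_equal(diff(range(nz[, 1])) + 1L, 41L)
  expect_equal(diff(range(nz[, 2])) + 1L, 37L)
  expect_identical(sum(out$values), sum(cb$values))
  # centred with floor-division margins
  expect_equal(min(nz[, 1]), (60 - 41) %/% 2 + 1)
  expect_equal(min(nz[, 2]), (80 - 37) %/% 2 + 1)
})

test_that("canonicalize is the identity at target size and idempotent", {
  cb <- rect_cube(60, 80, 4)
  expect_identical(canonicalize(cb, c(60, 80)), cb)
  once <- canonicalize(rect_cube(9, 11, 4), c(20, 30))
  expect_identical(canonicalize(once, c(20, 30)), once)
})

test_that("canonicalize rejects cubes larger than the frame", {
  expect_error(canonicalize(rect_cube(61, 10, 2), c(60, 80)),
               class = "adfs_geometry_error")
})

test_that("cube files round-trip exactly in every dialect", {
  dir <- withr::local_tempdir()
  cb <- rect_cube(6, 9, 4)
  p <- file.path(dir, "cube.rds")
  write_cube(cb, p, "rds")
  expect_equal(read_cube(p, "rds")$values, cb$values)
  for (itl in c("bsq", "bil", "bip")) {
    # float32 on disk: round-trip through single precision first
    p <- file.path(dir, paste0("cube_", itl))
    write_cube(cb, p, "envi", interleave = itl)
    back <- read_cube(p, "envi")
    expect_equal(back$values, cb$values, tolerance = 1e-7)
    expect_identical(read_cube(p, "envi")$values, back$values)
  }
})

test_that("read_cube validates files and band counts", {
  dir <- withr::local_tempdir()
  expect_error(read_cube(file.path(dir, "nope"), "rds"),
               class = "adfs_format_error")
  p <- file.path(dir, "c.rds")
  write_cube(rect_cube(6, 9, 4), p, "rds")
  expect_error(read_cube(p, "rds", n_bands = 94),
               class = "adfs_geometry_error")
  expect_silent(read_cube(p, "rds", n_bands = 4))
})

test_that("manifests validate structure and infer classes in order", {
  df <- tibble::tibble(
    sample_id = c("a", "b", "c", "d"),
    variety = c("BN4199", "JM44", "WL169", "ZM33"),
    domain = c("source", "source", "target", "target"),
    labeled = TRUE)
  man <- as_manifest(df)
  expect_identical(attr(man, "class_names"), c("BN4199", "JM44", "WL169", "ZM33"))
  expect_identical(man$variety_index, 0:3)

  expect_error(as_manifest(df[0, ]), class = "adfs_manifest_error")
  expect_error(as_manifest(dplyr::mutate(df, sample_id = "a")),
               class = "adfs_manifest_error")
  expect_error(as_manifest(dplyr::mutate(df, domain = "2019")),
               class = "adfs_manifest_error")
})

test_that("manifest CSV round-trips through load_manifest", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "manifest.csv")
  readr::write_csv(tibble::tibble(
    path = "x.rds", sample_id = c("s1", "s2"),
    variety = c("BN4199", NA), domain = c("source", "target"),
    labeled = c(TRUE, FALSE)), p)
  man <- load_manifest(p, band_count = 94)
  expect_s3_class(man, "dataset_manifest")
  expect_identical(attr(man, "band_count"), 94)
  expect_true(is.na(man$variety_index[2]))
})

test_that("cube sets load from a manifest and enforce geometry", {
  dir <- withr::local_tempdir()
  cubes <- list(rect_cube(5, 6, 3, id = "s1"),
                rect_cube(4, 5, 3, id = "s2", seed = 7))
  cubes[[2]]$domain <- "target"
  paths <- file.path(dir, c("s1.rds", "s2.rds"))
  purrr::walk2(cubes, paths, write_cube, dialect = "rds")
  man <- as_manifest(tibble::tibble(
    path = paths, sample_id = c("s1", "s2"), variety = "BN4199",
    domain = c("source", "target"), labeled = TRUE), band_count = 3)
  cs <- load_cube_set(man, "rds", target_shape = c(8, 8))
  expect_s3_class(cs, "cube_set")
  expect_true(all(vapply(cs$cubes, function(x) all(dim(x$values) == c(8, 8, 3)),
                         TRUE)))
})

test_that("band standardization uses only the ids it is given", {
  data <- tiny_data(n_per_class = 3)
  src <- data$manifest$sample_id[data$manifest$domain == "source"]
  st <- fit_band_stats(data, src)
  expect_length(st$mean, 20)
  st_all <- fit_band_stats(data)
  expect_false(isTRUE(all.equal(st$mean, st_all$mean)))
})
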
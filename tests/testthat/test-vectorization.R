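test_that("triangle function matches its closed form", {
  expect_equal(triangle_function(c(100, 200), 150), 50)  # peak (d-b)/2
  expect_equal(triangle_function(c(0, 2), 3), 0)         # outside (b, d)
  expect_equal(triangle_function(c(0, 100), 75), 25)     # falling branch -x+d
  expect_equal(triangle_function(c(0, 100), 25), 25)     # rising branch x-b
  expect_equal(triangle_function(c(5, 5), 5), 0)         # degenerate pair
  expect_error(triangle_function(c(10, 5), 7), "birth")
  # vectorized evaluation
  expect_equal(triangle_function(c(0, 10), c(-1, 0, 5, 10, 11)),
               c(0, 0, 5, 0, 0))
})

empty_diagram <- function() {
  structure(data.frame(birth = numeric(0), death = numeric(0),
                       dim = integer(0), essential = logical(0)),
            class = c("persistence_diagram", "data.frame"))
}

test_that("Betti curves count alive bars under the liveness convention", {
  grid <- threshold_grid(50)
  expect_equal(betti_curve(empty_diagram(), grid, 0L), rep(0L, 50))
  ess <- structure(data.frame(birth = 0, death = 255, dim = 0L,
                              essential = TRUE),
                   class = c("persistence_diagram", "data.frame"))
  expect_equal(betti_curve(ess, grid, 0L), rep(1L, 50))
  expect_error(betti_curve(ess, grid, 2L), "dim")
})

test_that("Betti curves equal per-threshold counting on random images", {
  set.seed(19)
  grid <- threshold_grid(10)
  for (rep in 1:8) {
    img <- as_channel_image(rand_image(8, 8))
    d <- cubical_persistence(img, grid)
    masks <- sublevel_filtration(img, grid)
    b0_oracle <- vapply(masks, count_components8, integer(1))
    chi <- vapply(masks, euler_characteristic, integer(1))
    expect_equal(betti_curve(d, grid, 0L), b0_oracle)
    expect_equal(betti_curve(d, grid, 1L), b0_oracle - chi)
  }
})

test_that("level-1 landscape is the pointwise max of tents", {
  expect_equal(landscape_level1(empty_diagram(), 0L, 100L), numeric(100))
  one <- structure(data.frame(birth = 100, death = 200, dim = 1L,
                              essential = FALSE),
                   class = c("persistence_diagram", "data.frame"))
  l <- landscape_level1(one, 1L, 100L)
  x <- landscape_bins(100L)
  binw <- 255 / 100
  expect_gte(l[which.min(abs(x - 150))], 50 - binw)  # near-peak sample
  expect_equal(l, triangle_function(c(100, 200), x))
  # two overlapping pairs: lambda1(75) = 25 for both tents
  two <- structure(data.frame(birth = c(0, 50), death = c(100, 150),
                              dim = c(1L, 1L), essential = FALSE),
                   class = c("persistence_diagram", "data.frame"))
  expect_equal(max(triangle_function(c(0, 100), 75),
                   triangle_function(c(50, 150), 75)), 25)
  l2 <- landscape_level1(two, 1L, 100L)
  brute <- pmax(triangle_function(c(0, 100), x), triangle_function(c(50, 150), x))
  expect_equal(l2, brute)
  # dominance over any single tent
  expect_true(all(l2 >= triangle_function(c(0, 100), x)))
  expect_true(all(l2 >= triangle_function(c(50, 150), x)))
})

test_that("channel vector has the documented 300-entry layout", {
  grid <- threshold_grid(50)
  img <- as_channel_image(matrix(0, 5, 5))
  d <- cubical_persistence(img, grid)
  v <- channel_vector(d, grid, 100L)
  expect_length(v, 300)
  expect_equal(unname(v[1:50]), rep(1, 50))             # Betti H0 of constant
  expect_equal(unname(v[51:100]), rep(0, 50))           # no loops
  expect_true(all(v >= 0))
  expect_equal(grep("^betti0", names(v)), 1:50)
  expect_equal(grep("^betti1", names(v)), 51:100)
  expect_equal(grep("^land0", names(v)), 101:200)
  expect_equal(grep("^land1", names(v)), 201:300)
})

test_that("image vector concatenates four channels into 1200 entries", {
  white <- array(255, c(6, 6, 3))
  v <- image_vector(white)
  expect_length(v, 1200)
  blocks <- matrix(v, ncol = 4)
  expect_equal(blocks[, 1], blocks[, 2])  # identical channels -> identical blocks
  expect_equal(blocks[, 2], blocks[, 3])
  expect_equal(blocks[, 3], blocks[, 4])
  expect_true(all(is.finite(v)))
  expect_error(image_vector(matrix(0, 4, 4)), "RGB")
})

test_that("grayscale channel uses rounded ITU-R 601 luminance", {
  rgb <- array(0, c(2, 2, 3))
  rgb[, , 1] <- 100; rgb[, , 2] <- 200; rgb[, , 3] <- 50
  ch <- split_channels(rgb)
  expect_equal(ch$gray[1, 1], as.integer(floor(0.299 * 100 + 0.587 * 200 +
                                               0.114 * 50 + 0.5)))
  expect_equal(ch$red[1, 1], 100L)
  expect_equal(attr(ch$blue, "channel"), "blue")
})

test_that("block restriction keeps only Betti or landscape features", {
  v <- image_vector(array(255, c(4, 4, 3)))
  expect_length(topo_blocks(v, "betti"), 400)
  expect_length(topo_blocks(v, "landscape"), 800)
  expect_identical(topo_blocks(v, "all"), v)
  expect_true(all(grepl("_betti", names(topo_blocks(v, "betti")))))
})

test_that("feature tables round-trip through TSV", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("a", "b", "c"), paste0("f", 1:4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(m, path)
  back <- read_feature_table(path)
  expect_equal(back, m, tolerance = 1e-12)
})
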
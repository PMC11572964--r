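test_that("the scale ladder reproduces the study unit sizes exactly", {
  lad <- make_ladder(120, 23)
  expect_identical(lad$widths_px, seq(1L, 23L, by = 2L))
  expect_identical(max(lad$sizes_m), 2760)
  expect_identical(max(make_ladder(120, 37)$sizes_m), 4440)
  expect_identical(make_ladder(120, 1)$sizes_m, 120)
  expect_error(make_ladder(120, 24), "odd")
  expect_error(make_ladder(120, 0), "w_max")
  expect_error(make_ladder(-120, 3), "base_pixel_m")
  # even widths allowed only behind the sensitivity flag
  expect_identical(make_ladder(120, 4, odd_only = FALSE)$widths_px, 1:4)
})

test_that("aggregation of constant rasters gives the obvious units", {
  px <- 120
  pair <- raster_pair(
    raster_grid(matrix(30, 9, 9), pixel_size = px),
    raster_grid(matrix(0.5, 9, 9), pixel_size = px))
  tabs <- suppressWarnings(aggregate_units(pair, make_ladder(px, 3)))
  w3 <- tabs[[2]]
  expect_identical(nrow(w3), 9L)
  expect_true(all(w3$ptree_pct == 50))
  expect_true(all(w3$lst_mean_c == 30))
  expect_true(all(w3$valid_fraction == 1))

  # partial edge tiles are dropped: floor(10/3)^2 = 9 full units
  pair10 <- raster_pair(
    raster_grid(matrix(rnorm(100, 30), 10, 10), pixel_size = px),
    raster_grid(matrix(runif(100), 10, 10), pixel_size = px))
  expect_identical(nrow(aggregate_units(pair10, make_ladder(px, 3))[[2]]),
                   9L)
})

test_that("aggregation matches the brute-force per-tile loop", {
  for (seed in c(1, 2, 3)) {
    pair <- make_test_pair(seed = seed, n = 33)
    lst <- pair$lst$values
    cover <- pair$canopy$values
    # punch nodata holes to exercise the validity threshold
    set.seed(seed + 100)
    lst[sample(length(lst), 80)] <- NA
    pair <- raster_pair(raster_grid(lst, pixel_size = 120),
                        raster_grid(cover, pixel_size = 120))
    tabs <- aggregate_units(pair, make_ladder(120, 5),
                            min_valid_fraction = 0.5)
    for (tab in tabs) {
      w <- attr(tab, "scale_m") / 120
      oracle <- brute_aggregate(lst, cover, w, 0.5)
      expect_identical(tab$unit_id, oracle$unit_id)
      expect_equal(tab$ptree_pct, oracle$ptree_pct, tolerance = 1e-12)
      expect_equal(tab$lst_mean_c, oracle$lst_mean_c, tolerance = 1e-12)
      expect_identical(tab$n_valid_px, oracle$n_valid_px)
    }
  }
})

test_that("aggregation preserves means, counts, and LST offsets", {
  pair <- make_test_pair(seed = 9, n = 45, noise_sd = 1)
  w <- 3L
  tabs <- aggregate_units(pair, make_ladder(120, 3))
  tab <- tabs[[2]]
  # valid-pixel-weighted unit mean equals the global mean (no nodata,
  # dims divisible by w)
  expect_equal(sum(tab$lst_mean_c * tab$n_valid_px) / sum(tab$n_valid_px),
               mean(pair$lst$values), tolerance = 1e-10)
  expect_equal(nrow(tab), (45 %/% w)^2)

  # adding a constant to LST shifts every unit mean by that constant
  shifted <- raster_pair(
    raster_grid(pair$lst$values + 2.5, pixel_size = 120,
                origin = pair$lst$origin),
    pair$canopy)
  tab2 <- aggregate_units(shifted, make_ladder(120, 3))[[2]]
  expect_equal(tab2$lst_mean_c, tab$lst_mean_c + 2.5, tolerance = 1e-12)
  expect_identical(tab2$ptree_pct, tab$ptree_pct)
})

test_that("boundary masks restrict units and empty scales warn", {
  vals <- matrix(30, 12, 12)
  cover <- matrix(runif(144), 12, 12)
  boundary <- raster_grid(matrix(0, 12, 12), pixel_size = 120)
  boundary$values[1:6, 1:6] <- 1
  pair <- raster_pair(raster_grid(vals, pixel_size = 120),
                      raster_grid(cover, pixel_size = 120),
                      boundary = boundary)
  # w = 9 tiles can never reach 50% in-boundary support
  expect_warning(
    tabs <- aggregate_units(pair, make_ladder(120, 9)),
    "no unit at scale 1080")
  expect_identical(nrow(tabs[[5]]), 0L)
  # w = 3: only the 4 tiles fully inside the 6x6 boundary survive
  expect_identical(nrow(tabs[[2]]), 4L)
})

test_that("zero Ptree variance at a scale is flagged", {
  pair <- raster_pair(
    raster_grid(matrix(rnorm(81, 30), 9, 9), pixel_size = 120),
    raster_grid(matrix(0.4, 9, 9), pixel_size = 120))
  expect_warning(tabs <- aggregate_units(pair, make_ladder(120, 1)),
                 "zero Ptree variance")
  expect_true(isTRUE(attr(tabs[[1]], "zero_ptree_var")))
})

test_that("unit tables round-trip through CSV with a manifest", {
  tabs <- simulate_unit_tables(tabular_sim_config(n_per_scale = 20,
                                                  scales = c(120, 360, 600),
                                                  seed = 3))
  dir <- withr::local_tempdir()
  manifest <- write_unit_tables(tabs, dir)
  expect_length(manifest$scales, 3)
  expect_identical(manifest$scales[[2]]$n_units, 20L)
  back <- read_unit_tables(dir)
  expect_equal(back[[1]]$ptree_pct, tabs[[1]]$ptree_pct, tolerance = 1e-12)
  expect_identical(attr(back[[3]], "scale_m"), 600)
})
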
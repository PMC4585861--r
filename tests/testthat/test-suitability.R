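test_that("classification boundaries follow the published intervals", {
  expect_equal(as.character(classify_ei(0)), "unsuitable")
  expect_equal(as.character(classify_ei(0.999)), "unsuitable")
  expect_equal(as.character(classify_ei(1)), "marginal")
  expect_equal(as.character(classify_ei(9.999)), "marginal")
  expect_equal(as.character(classify_ei(10)), "suitable")
  expect_equal(as.character(classify_ei(15)), "suitable")
  expect_equal(as.character(classify_ei(20)), "suitable")
  expect_equal(as.character(classify_ei(20.0001)), "highly_suitable")
  expect_equal(as.character(classify_ei(25)), "highly_suitable")
  expect_equal(as.character(classify_ei(100)), "highly_suitable")
  expect_error(classify_ei(101), "out of")
  expect_error(classify_ei(-0.5), "out of")
})

test_that("classification is monotone in EI", {
  ei <- sort(runif(200, 0, 100))
  cls <- classify_ei(ei)
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("cell areas match spherical geometry", {
  # equatorial 10-arcmin cell
  expect_equal(cell_area(0, 1 / 6), 343.3, tolerance = 1e-3)
  # ~cos(latitude) scaling at 60 degrees
  expect_equal(cell_area(60, 1 / 6) / cell_area(0, 1 / 6), cos(pi / 3),
               tolerance = 1e-3)
  # a full global grid sums to the sphere's surface
  lats <- seq(89.75, -89.75, by = -0.5)
  total <- sum(cell_area(lats, 0.5)) * 720
  expect_equal(total, 4 * pi * 6371.0088^2, tolerance = 1e-6)
  expect_error(cell_area(89.99, 0.5), "beyond")
})

make_result_with_classes <- function(codes, grid) {
  # minimal annual_result with prescribed class codes for area accounting
  ei_for <- c(0, 5, 15, 50)
  ei <- matrix(ei_for[codes + 1L], nrow = grid$n_lat)
  structure(list(grid = grid, mask = matrix(TRUE, grid$n_lat, grid$n_lon),
                 EI = ei, GIA = ei, CS = ei * 0, HS = ei * 0, DS = ei * 0,
                 WS = ei * 0, annual_dd = ei * 0 + 2000,
                 class_code = matrix(codes, nrow = grid$n_lat)),
            class = "annual_result")
}

test_that("area table sums cell areas per class and conserves the total", {
  grid <- grid_definition(100, 1, 1, 2, 2)
  lat_areas <- cell_area(grid_lats(grid), 1)

  res_one <- make_result_with_classes(rep(3L, 4), grid)
  at <- area_table(res_one, "all-high")
  expect_equal(at$highly_suitable, sum(lat_areas) * 2)
  expect_equal(at$unsuitable + at$marginal + at$suitable, 0)
  expect_equal(at$total, at$highly_suitable)

  # hand-computed 2x2: rows are latitudes 1 and 0 degrees
  codes <- matrix(c(0L, 2L, 3L, 1L), 2, 2)
  res <- make_result_with_classes(as.vector(codes), grid)
  at2 <- area_table(res, "toy")
  expect_equal(at2$unsuitable, lat_areas[1])
  expect_equal(at2$suitable, lat_areas[2])
  expect_equal(at2$highly_suitable, lat_areas[1])
  expect_equal(at2$marginal, lat_areas[2])
  expect_equal(at2$total, 2 * sum(lat_areas))
})

test_that("identical runs give zero change maps and a diagonal transition matrix", {
  p <- oil_palm_params()
  clim <- toy_climatology()
  res <- run_grid(clim, p)
  cm <- stress_change(res, res, "CS")
  expect_true(all(cm$delta[res$mask] == 0))
  tr <- class_transitions(res, res)
  expect_equal(sum(tr) - sum(diag(tr)), 0)

  # row/column sums tie back to the two scenarios' per-class areas
  warm <- run_grid(apply_scenario_delta(clim, dT = 4), p)
  tr2 <- class_transitions(res, warm)
  at_a <- area_table(res)
  at_b <- area_table(warm)
  expect_equal(unname(rowSums(tr2)),
               unname(unlist(at_a[1, suitability_levels()])))
  expect_equal(unname(colSums(tr2)),
               unname(unlist(at_b[1, suitability_levels()])))
  expect_equal(sum(tr2), at_a$total)

  shifted <- toy_climatology(n_lat = 4L)
  res_bad <- run_grid(shifted, p)
  expect_error(stress_change(res, res_bad, "HS"), "grid mismatch")
})

test_that("warming shifts heat stress up and cold stress down cellwise", {
  p <- oil_palm_params()
  tb <- make_gradient_testbed()
  base <- run_grid(tb$clim, p)
  warm <- run_grid(apply_scenario_delta(tb$clim, dT = 4), p)
  dhs <- stress_change(base, warm, "HS")$delta
  dcs <- stress_change(base, warm, "CS")$delta
  m <- base$mask
  expect_true(all(dhs[m] >= 0))
  expect_gte(sum(dhs[m] > 0), 1)  # the testbed's warm edge does heat-stress
  expect_true(all(dcs[m] <= 0))
})

test_that("occurrence overlay assigns nearest-cell classes and flags off-grid points", {
  p <- oil_palm_params()
  clim <- toy_climatology(mask_out = cbind(3, 4))
  res <- run_grid(clim, p)
  lons <- grid_lons(res$grid); lats <- grid_lats(res$grid)

  pts <- data.frame(
    lon = c(lons[1], lons[2] + 0.2, lons[4], -150),
    lat = c(lats[1], lats[1] - 0.1, lats[3], 0)
  )
  ov <- overlay_occurrences(pts, res)
  expect_equal(ov$points$off_grid, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(ov$points$EI[1], res$EI[1, 1])
  expect_equal(ov$points$EI[2], res$EI[1, 2])  # snapped to nearest center
  expect_equal(sum(ov$class_counts), 2)
})

test_that("points sampled from highly suitable cells all validate as highly suitable", {
  p <- oil_palm_params()
  tb <- make_gradient_testbed()
  res <- run_grid(tb$clim, p)
  pts <- sample_occurrences(res, 23, "highly_suitable", seed = 4)
  ov <- overlay_occurrences(pts, res)
  expect_equal(nrow(pts), 23)
  expect_equal(unname(ov$class_counts["highly_suitable"]), 23)
  expect_equal(ov$fraction_ei_pos, 1)
})
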
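test_that("cell loudness reduces to single-source values without the other", {
  only_air <- cell_loudness(75, -Inf, cst)
  expect_identical(only_air[["road"]], 0)
  # partial of the lone source equals its unmasked (total) loudness exactly
  expect_identical(only_air[["aircraft"]], only_air[["total"]])
  both <- cell_loudness(75, 70, cst)
  expect_lt(both[["aircraft"]], only_air[["aircraft"]])
  expect_gte(both[["total"]], both[["aircraft"]])
  expect_gte(both[["total"]], both[["road"]])
})

test_that("raising the background lowers the target's partial loudness", {
  partials <- vapply(c(55, 65, 75), function(r)
    cell_loudness(70, r, cst)[["aircraft"]], numeric(1))
  expect_true(all(diff(partials) < 0))
})

test_that("masking between the sources is asymmetric at unequal levels", {
  tri <- cell_loudness(83, 55, cst)
  road_alone <- cell_loudness(-Inf, 55, cst)[["road"]]
  air_alone <- cell_loudness(83, -Inf, cst)[["aircraft"]]
  # the weak road is strongly suppressed by the loud aircraft ...
  expect_lt(tri[["road"]] / road_alone, 0.35)
  # ... while the loud aircraft barely loses loudness to the weak road
  expect_gt(tri[["aircraft"]] / air_alone, 0.9)
})

test_that("indoor levels below the audibility floor contribute nothing", {
  # 14 dBA outdoors -> negative indoor level -> silent
  expect_identical(cell_loudness(14, -Inf, cst)[["aircraft"]], 0)
  expect_identical(cell_loudness(-Inf, -Inf, cst)[["total"]], 0)
})

test_that("annoyance surfaces respect shape, floor and conservation", {
  g <- receiver_grid(nx = 6, ny = 5, road_level = 72, air_level = 78)
  ag <- annoyance_surface(g, constants = cst)
  expect_equal(dim(ag$layers$pct_ha_total), dim(g$aircraft))
  expect_named(ag$layers, c("loud_aircraft", "loud_road", "loud_total",
                            "pct_ha_aircraft", "pct_ha_road", "pct_ha_total"))
  # conservation: partials sum to at most the total (plus 5 % slack)
  expect_true(all(ag$layers$loud_aircraft + ag$layers$loud_road <=
                    ag$layers$loud_total * 1.05 + 1e-9))
  expect_true(all(ag$layers$pct_ha_total >= 0 &
                    ag$layers$pct_ha_total <= 100))

  # zero-exposure grid: every cell at the zero-loudness %HA floor
  g0 <- g
  g0$aircraft[] <- -Inf
  g0$road[] <- -Inf
  ag0 <- annoyance_surface(g0, constants = cst)
  expect_true(all(abs(ag0$layers$pct_ha_total - 1 / 0.053) < 1e-9))
})

test_that("zeroing one layer reduces to the single-source map bit-for-bit", {
  g <- receiver_grid(nx = 5, ny = 4, road_level = 70, air_level = 76)
  g_no_road <- g
  g_no_road$road[] <- -Inf
  ag <- annoyance_surface(g_no_road, constants = cst)
  # single-source reference computed directly per cell
  ref <- matrix(NA_real_, nrow(g$aircraft), ncol(g$aircraft))
  for (j in seq_len(ncol(ref))) for (i in seq_len(nrow(ref)))
    ref[i, j] <- cell_loudness(g$aircraft[i, j], -Inf, cst)[["total"]]
  expect_identical(ag$layers$loud_aircraft, ref)
  expect_identical(ag$layers$loud_aircraft, ag$layers$loud_total)
})

test_that("cells near the road show suppressed aircraft annoyance", {
  # same aircraft level everywhere; road only strong near its axis
  g <- receiver_grid(nx = 3, ny = 9, road_level = 78, air_level = 78,
                     air_decay = 0)
  ag <- annoyance_surface(g, constants = cst)
  near <- which.max(g$road[, 2])
  far <- which.min(g$road[, 2])
  expect_lt(ag$layers$pct_ha_aircraft[near, 2],
            ag$layers$pct_ha_aircraft[far, 2])
})

test_that("exposure groups use half-open upward boundaries", {
  expect_equal(as.character(exposure_group(c(45, 50, 59.9, 60, 69.9, 70, 75))),
               c("less than 50 dBA", "50-60 dBA", "50-60 dBA", "60-70 dBA",
                 "60-70 dBA", "over 70 dBA", "over 70 dBA"))
  expect_error(exposure_group(NA_real_))
})
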
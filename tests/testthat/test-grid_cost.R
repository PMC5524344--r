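test_that("rasterization follows the cell-centre-in-region convention", {
  square <- cbind(c(0, 150, 150, 0, 0), c(0, 0, 150, 150, 0))
  g <- rasterize_domain(square, cell_size = 15)
  expect_equal(c(g$n_rows, g$n_cols), c(10, 10))
  expect_true(all(g$water))

  # same square as two loops with a 15 m land strip (y in [60, 75]) between
  lower <- cbind(c(0, 150, 150, 0, 0), c(0, 0, 60, 60, 0))
  upper <- cbind(c(0, 150, 150, 0, 0), c(75, 75, 150, 150, 75))
  g2 <- rasterize_domain(rbind(lower, c(NA, NA), upper), cell_size = 15)
  expect_equal(c(g2$n_rows, g2$n_cols), c(10, 10))
  # exactly the row of centres at northing 67.5 is land
  land_rows <- which(rowSums(!g2$water) == g2$n_cols)
  expect_equal(land_rows, 6)  # row 6 from the north edge has centres at 67.5
  expect_equal(sum(!g2$water), 10)

  expect_error(rasterize_domain(square, cell_size = 0), "positive")
  expect_error(rasterize_domain(cbind(c(0, 0), c(0, 0)), 15), "empty")
})

test_that("uniform open-water costs are multiples of the cell size", {
  g <- estuary_grid(matrix(TRUE, 1, 10), cell_size = 15)
  src <- list(id = "s", easting = 7.5, northing = 7.5)
  surf <- accumulate_cost(g, src)
  expect_equal(extract_cost(surf, 7.5, 7.5), 0)
  # k rook steps in open water cost 15 * k
  expect_equal(as.numeric(surf$cost), 15 * (0:9))
  expect_equal(extract_cost(surf, 7.5 + 3 * 15, 7.5), 45)
})

test_that("accumulated cost equals the brute-force shortest path exactly", {
  for (seed in 1:10) {
    g <- random_grid(seed)
    rc <- random_water_cell(g, seed + 100)
    xy <- estuaryRF:::cell_center(g, rc["row"], rc["col"])
    surf <- accumulate_cost(g, list(id = "s", easting = xy[1, 1],
                                    northing = xy[1, 2]))
    expect_equal(surf$cost, oracle_cost(g, rc["row"], rc["col"]),
                 tolerance = 1e-10)
  }
})

test_that("16-neighbourhood matches its oracle and never exceeds 8-neighbour costs", {
  for (seed in c(3, 7)) {
    g <- random_grid(seed, max_dim = 15)
    rc <- random_water_cell(g, seed + 100)
    xy <- estuaryRF:::cell_center(g, rc["row"], rc["col"])
    src <- list(id = "s", easting = xy[1, 1], northing = xy[1, 2])
    s8 <- accumulate_cost(g, src, neighborhood = 8)
    s16 <- accumulate_cost(g, src, neighborhood = 16)
    expect_equal(s16$cost, oracle_cost(g, rc["row"], rc["col"], 16),
                 tolerance = 1e-10)
    w <- g$water
    expect_true(all(s16$cost[w] <= s8$cost[w] + 1e-9))
  }
})

test_that("a land barrier forces a detour and dominates the open grid", {
  open <- estuary_grid(matrix(TRUE, 5, 5), cell_size = 15)
  wall <- matrix(TRUE, 5, 5)
  wall[1:4, 3] <- FALSE  # wall through column 3, gap at the south end
  walled <- estuary_grid(wall, cell_size = 15)
  src <- list(id = "s", easting = 7.5, northing = 15 * 5 - 7.5)  # NW corner
  so <- accumulate_cost(open, src)
  sw <- accumulate_cost(walled, src)
  rc <- which(wall, arr.ind = TRUE)
  expect_equal(sw$cost, oracle_cost(walled, 1, 1), tolerance = 1e-10)
  # barrier dominance, element-wise on shared water cells
  expect_true(all(sw$cost[wall] >= so$cost[wall] - 1e-9))
  # the detour is strictly longer for the cell across the wall
  expect_gt(sw$cost[1, 5], so$cost[1, 5])
})

test_that("accumulated cost is bounded below by straight-line distance", {
  for (seed in c(2, 5)) {
    g <- random_grid(seed, max_dim = 15, p_land = 0.2)
    rc <- random_water_cell(g, seed + 100)
    xy <- estuaryRF:::cell_center(g, rc["row"], rc["col"])
    surf <- accumulate_cost(g, list(id = "s", easting = xy[1, 1],
                                    northing = xy[1, 2]))
    wc <- which(g$water, arr.ind = TRUE)
    cen <- estuaryRF:::cell_center(g, wc[, 1], wc[, 2])
    eu <- sqrt((cen[, 1] - xy[1, 1])^2 + (cen[, 2] - xy[1, 2])^2)
    cost <- surf$cost[g$water]
    ok <- is.finite(cost)
    expect_true(all(cost[ok] >= eu[ok] - 1e-9))
  }
})

test_that("relabelling sources permutes surfaces without changing values", {
  g <- random_grid(11, max_dim = 12, p_land = 0.2)
  wc <- which(g$water, arr.ind = TRUE)
  cen <- estuaryRF:::cell_center(g, wc[1:2, 1], wc[1:2, 2])
  src <- data.frame(id = c("a", "b"), easting = cen[, 1],
                    northing = cen[, 2])
  s1 <- cost_surfaces(g, src)
  s2 <- cost_surfaces(g, src[2:1, ])
  expect_equal(s1[["a"]]$cost, s2[["a"]]$cost)
  expect_equal(s1[["b"]]$cost, s2[["b"]]$cost)
})

test_that("sources snap to nearby water and distant sources error by id", {
  water <- matrix(TRUE, 5, 5); water[, 1:2] <- FALSE
  g <- estuary_grid(water, cell_size = 15)
  # on land column 2, one cell west of water: snaps to column 3
  surf <- accumulate_cost(g, list(id = "near", easting = 1.5 * 15,
                                  northing = 2.5 * 15))
  expect_equal(min(surf$cost[water]), 0)
  g_wide <- estuary_grid(cbind(matrix(FALSE, 5, 10), matrix(TRUE, 5, 2)),
                         cell_size = 15)
  expect_error(
    accumulate_cost(g_wide, list(id = "far", easting = 7.5, northing = 7.5)),
    "far")
})

test_that("extract_cost handles land, unreachable cells and bounds", {
  water <- matrix(TRUE, 3, 3)
  water[, 2] <- FALSE  # two disconnected water columns
  g <- estuary_grid(water, cell_size = 15)
  surf <- accumulate_cost(g, list(id = "s", easting = 7.5, northing = 7.5))
  expect_equal(extract_cost(surf, 7.5, 7.5), 0)
  expect_identical(extract_cost(surf, 22.5, 22.5), Inf)  # land cell
  expect_identical(extract_cost(surf, 37.5, 7.5), Inf)   # unreachable water
  expect_error(extract_cost(surf, 100, 100), "outside")
})
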
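test_that("CSO summaries are raw min/max/mean of accumulated costs", {
  s <- cso_distance_summary(7.5, 7.5, list(const_surface(250)))
  expect_equal(unname(s), c(250, 250, 250))
  s <- cso_distance_summary(7.5, 7.5, list(const_surface(100),
                                           const_surface(200),
                                           const_surface(600)))
  expect_equal(s, c(cso_min = 100, cso_max = 600, cso_avg = 300))
  expect_error(cso_distance_summary(7.5, 7.5, list(const_surface(Inf)),
                                    id = "s9"), "s9")
})

test_that("CSO summaries agree with oracle shortest paths on a random estuary", {
  g <- random_grid(21, max_dim = 15, p_land = 0.15)
  wc <- which(g$water, arr.ind = TRUE)
  set.seed(22)
  pick <- wc[sample.int(nrow(wc), min(10, nrow(wc))), , drop = FALSE]
  cen <- estuaryRF:::cell_center(g, pick[, 1], pick[, 2])
  src <- data.frame(id = paste0("c", seq_len(nrow(pick))),
                    easting = cen[, 1], northing = cen[, 2])
  surfs <- cost_surfaces(g, src)
  # sample location: first water cell
  loc <- estuaryRF:::cell_center(g, wc[1, 1], wc[1, 2])
  d_oracle <- vapply(seq_len(nrow(pick)), function(i)
    oracle_cost(g, pick[i, 1], pick[i, 2])[wc[1, 1], wc[1, 2]], numeric(1))
  d_oracle <- d_oracle[is.finite(d_oracle)]
  s <- suppressWarnings(cso_distance_summary(loc[1, 1], loc[1, 2], surfs))
  expect_equal(unname(s),
               c(min(d_oracle), max(d_oracle), mean(d_oracle)),
               tolerance = 1e-10)
})

test_that("WWTP scores match an independent recomputation and attain bounds", {
  d <- c(1000, 2000, 4000)
  vol <- c(45, 10, 0.4)  # million gallons/day, spanning the permitted range
  surfs <- lapply(seq_along(d), function(i) const_surface(d[i]))
  s <- wwtp_weighted_summary(7.5, 7.5, surfs, vol)
  oracle <- oracle_wwtp_scores(d, vol)
  expect_equal(unname(s), c(min(oracle), max(oracle), mean(oracle)))
  # nearest plant is also highest-volume: its score attains 4
  expect_equal(unname(s["wwtp_max"]), 4)
  # farthest plant is lowest-volume: its score attains 1
  expect_equal(unname(s["wwtp_min"]), 1)
  # single-WWTP degeneracy: both factors at the upper rescale bound
  s1 <- wwtp_weighted_summary(7.5, 7.5, list(const_surface(500)), 3)
  expect_equal(unname(s1), c(4, 4, 4))
  expect_error(wwtp_weighted_summary(7.5, 7.5, surfs, c(1, NA, 2)),
               "volume")
})

test_that("the product-rescale variant stays in [1, 2] and preserves ranks", {
  d <- c(800, 1500, 3000, 6000)
  vol <- c(20, 5, 40, 1)
  surfs <- lapply(d, const_surface)
  sf <- wwtp_weighted_summary(7.5, 7.5, surfs, vol, variant = "factors")
  sp <- wwtp_weighted_summary(7.5, 7.5, surfs, vol, variant = "product")
  expect_true(sp["wwtp_min"] >= 1 && sp["wwtp_max"] <= 2)
  expect_true(sf["wwtp_min"] >= 1 && sf["wwtp_max"] <= 4)
})

test_that("WWTP scores are monotone in proximity and volume, and volume-scale invariant", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    d <- runif(k, 100, 5000)
    vol <- runif(k, 0.4, 45)
    surfs <- lapply(d, const_surface)
    base <- oracle_wwtp_scores(d, vol)
    # decreasing one plant's distance never decreases its score
    j <- sample.int(k, 1)
    d2 <- d; d2[j] <- d2[j] * 0.5
    s2 <- oracle_wwtp_scores(d2, vol)
    expect_gte(s2[j], base[j] - 1e-12)
    # increasing a plant's volume never decreases its score
    v2 <- vol; v2[j] <- v2[j] * 2
    s3 <- oracle_wwtp_scores(d, v2)
    expect_gte(s3[j], base[j] - 1e-12)
    # package agrees with oracle and is invariant to volume rescaling
    s <- wwtp_weighted_summary(7.5, 7.5, surfs, vol)
    s_scaled <- wwtp_weighted_summary(7.5, 7.5, surfs, vol * 37.5)
    expect_equal(s, s_scaled)
    expect_true(s["wwtp_min"] <= s["wwtp_avg"] &&
                s["wwtp_avg"] <= s["wwtp_max"])
  }
})

test_that("design assembly logs the response and enforces bounds", {
  cso <- list(const_surface(100), const_surface(300))
  wwtp <- list(const_surface(1000), const_surface(2000))
  smp <- data.frame(id = "a", easting = 7.5, northing = 7.5, toc = 2,
                    sand = 60, mud = 40, depth = 10, tcs = 1)
  d <- assemble_design(smp, cso, wwtp, volumes = c(5, 1))
  expect_equal(d$log_tcs, 0)
  expect_equal(names(d), c("id", "toc", "sand", "mud", "depth", "cso_min",
                           "cso_max", "cso_avg", "wwtp_min", "wwtp_max",
                           "wwtp_avg", "northing", "easting", "log_tcs"))
  smp$tcs <- -1
  expect_error(assemble_design(smp, cso, wwtp, c(5, 1)), "positive")
  smp$tcs <- 1; smp$toc <- 120
  expect_error(assemble_design(smp, cso, wwtp, c(5, 1)), "toc")
})

test_that("the synthetic training design has the reference shape", {
  fix <- synthetic_training_table(seed = 4)
  expect_equal(nrow(fix$design), 58)
  expect_equal(as.vector(table(fix$samples$survey)[c("2010-spring", "2012")]),
               c(36, 22))
  expect_equal(ncol(design_matrix(fix$design)$x), 12)
})

test_that("design tables round-trip through CSV bit-identically", {
  fix <- synthetic_training_table(seed = 2)
  path <- tempfile(fileext = ".csv")
  write_design_csv(fix$design, path)
  back <- read_design_csv(path)
  expect_equal(back, fix$design, tolerance = 0)
  # supplementary-style headers resolve through a column map
  renamed <- fix$design
  names(renamed)[names(renamed) == "toc"] <- "TOC"
  names(renamed)[names(renamed) == "cso_min"] <- "CSO_min"
  p2 <- tempfile(fileext = ".csv")
  write.csv(renamed, p2, row.names = FALSE)
  mapped <- read_design_csv(p2, column_map = c(TOC = "toc",
                                               CSO_min = "cso_min"))
  expect_equal(mapped$toc, fix$design$toc)
})
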
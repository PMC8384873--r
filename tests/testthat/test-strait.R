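# Landmass labelling, landmass distances, and the minimax crossing.

# small raster with two plateaus separated by a meridional channel and an
# optional island in the middle
plateau_raster <- function(island = FALSE) {
  g <- grid_spec(seq(43, 44, by = 0.02), seq(12, 13, by = 0.02))
  lo <- matrix(rep(g$lon, length(g$lat)), length(g$lon))
  elev <- matrix(-100, length(g$lon), length(g$lat))
  elev[lo <= 43.4] <- 100
  elev[lo >= 43.6] <- 100
  if (island) elev[which(abs(g$lon - 43.5) < 0.011), 24:27] <- 50
  climate_field(elev, g, var = "elevation")
}

seeds2 <- list(africa = c(43.1, 12.5), arabia = c(43.9, 12.5))

test_that("labelling matches a flood-fill oracle and nests with sea level", {
  b <- plateau_raster()
  lm <- label_landmasses(b, 0, seeds2)
  oracle <- flood_label(b$values > 0)
  expect_equal(lm$n, max(oracle, na.rm = TRUE))
  expect_equal(is.na(lm$labels), is.na(oracle))
  expect_false(lm$africa == lm$arabia)
  # sea level below every elevation: one landmass
  lm_low <- label_landmasses(b, -150, seeds2)
  expect_equal(lm_low$n, 1)
  expect_equal(lm_low$africa, lm_low$arabia)
  # land at higher sea level is a subset of land at lower sea level
  expect_true(all(is.na(lm_low$labels[is.na(lm$labels)]) |
                    !is.na(lm_low$labels[is.na(lm$labels)])))
  land_hi <- !is.na(lm$labels); land_lo <- !is.na(lm_low$labels)
  expect_true(all(!land_hi | land_lo))
  expect_error(label_landmasses(b, 0, list(africa = c(43.5, 12.5),
                                           arabia = c(43.9, 12.5))),
               "submarine")
})

test_that("an island splits into its own 8-connected component", {
  b <- plateau_raster(island = TRUE)
  lm <- label_landmasses(b, 0, seeds2)
  expect_equal(lm$n, 3)
  expect_equal(lm$n, max(flood_label(b$values > 0), na.rm = TRUE))
})

test_that("landmass distances are symmetric haversine minima", {
  # two single-cell masses at known coordinates
  g <- grid_spec(seq(0, 1, by = 0.5), seq(0, 1, by = 0.5))
  elev <- matrix(-10, 3, 3)
  elev[1, 1] <- 5   # (0, 0)
  elev[3, 3] <- 5   # (1, 1)
  b <- climate_field(elev, g, var = "elevation")
  lm <- label_landmasses(b, 0, list(africa = c(0, 0), arabia = c(1, 1)))
  gr <- landmass_distances(lm)
  expect_equal(gr$w, t(gr$w))
  expect_equal(gr$w[lm$africa, lm$arabia],
               gc_dist_km(0, 0, 1, 1), tolerance = 1e-9)
  # nearest cells of two masses offset by a knight's move (not 8-adjacent):
  # the weight is the haversine distance between those two cell centres
  elev2 <- matrix(-10, 3, 3)
  elev2[1, 1] <- 5; elev2[2, 3] <- 5
  lm2 <- label_landmasses(climate_field(elev2, g, var = "elevation"), 0,
                          list(africa = c(0, 0), arabia = c(0.5, 1)))
  gr2 <- landmass_distances(lm2)
  expect_equal(gr2$w[lm2$africa, lm2$arabia],
               gc_dist_km(0, 0, 0.5, 1), tolerance = 1e-9)
})

test_that("minimax crossing solves the stepping-stone problem", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 10   # A-B
  w[2, 3] <- w[3, 2] <- 3    # B-C
  w[1, 3] <- w[3, 1] <- 12   # A-C direct
  gr <- structure(list(w = w, africa = 1, arabia = 3),
                  class = "landmass_graph")
  res <- minimax_crossing(gr)
  expect_equal(res$distance_km, 10)              # via B beats 12 direct
  expect_equal(res$distance_km, brute_minimax(w, 1, 3))
  # single mass: zero
  gr1 <- structure(list(w = matrix(0, 1, 1), africa = 1, arabia = 1),
                   class = "landmass_graph")
  expect_equal(minimax_crossing(gr1)$distance_km, 0)
})

test_that("minimax equals brute force on random complete graphs and an
           island never increases it", {
  set.seed(19)
  for (rep in 1:10) {
    K <- sample(3:5, 1)
    w <- matrix(0, K, K)
    w[upper.tri(w)] <- runif(K * (K - 1) / 2, 1, 50)
    w <- w + t(w)
    gr <- structure(list(w = w, africa = 1, arabia = K),
                    class = "landmass_graph")
    got <- minimax_crossing(gr)$distance_km
    expect_equal(got, brute_minimax(w, 1, K))
    expect_lte(got, w[1, K])                       # never beyond direct edge
    # add an island: minimax cannot increase
    w2 <- rbind(cbind(w, runif(K, 1, 50)), 0)
    w2[K + 1, ] <- w2[, K + 1]
    gr2 <- structure(list(w = w2, africa = 1, arabia = K),
                     class = "landmass_graph")
    expect_lte(minimax_crossing(gr2)$distance_km, got + 1e-12)
  }
})

test_that("island stepping stones shorten the measured channel crossing", {
  b0 <- plateau_raster()
  b1 <- plateau_raster(island = TRUE)
  d0 <- minimax_crossing(landmass_distances(label_landmasses(b0, 0, seeds2)))
  d1 <- minimax_crossing(landmass_distances(label_landmasses(b1, 0, seeds2)))
  expect_lt(d1$distance_km, d0$distance_km)
  expect_equal(length(d1$path), 3)                 # A -> island -> B
})

test_that("synthetic strait: zero below the saddle, monotone in sea level,
           planted gap recovered within a cell", {
  world <- make_world(light_config(), seed = 3)
  cfg <- world$config
  cell_km <- cfg$strait_cell_deg * km_per_degree()
  cs <- crossing_series(world$bathymetry, world$sea_level, 0:21)
  # below the trench floor the land bridge closes the strait
  expect_true(all(cs$crossing_km[cs$sea_level_m < cfg$trench_floor_m] == 0))
  # monotone non-increasing as sea level falls
  ord <- order(cs$sea_level_m)
  expect_true(all(diff(cs$crossing_km[ord]) >= -1e-9))
  # analytic planted widths recovered within ~a raster cell
  want <- strait_gap_true(cs$sea_level_m, cfg)
  expect_true(all(abs(cs$crossing_km - want) <= 1.5 * cell_km))
  # present-day width ~20 km, 100 m lowstand ~4 km (the planted geometry)
  lm100 <- label_landmasses(world$bathymetry, -100)
  d100 <- minimax_crossing(landmass_distances(lm100))$distance_km
  expect_lte(abs(d100 - strait_gap_true(-100, cfg)), 1.5 * cell_km)
})
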
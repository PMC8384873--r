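# Delta methods, CO2-matched reference times, land masks, IDW infilling.

test_that("reference time minimises the CO2 difference, ties to recent", {
  co2 <- data.frame(time_ka = c(0, 5, 14, 21),
                    value = c(280, 240, 230, 190))
  expect_equal(select_reference_time(co2, 5, c(21, 14, 0)), 14)   # 240 -> 230
  expect_equal(select_reference_time(co2, 21, c(21, 14, 0)), 21)  # exact
  # exact tie: CO2(t)=255 is 25 from both 280 (0 ka) and 230 (14 ka)
  co2b <- rbind(co2, data.frame(time_ka = 7, value = 255))
  expect_equal(select_reference_time(co2b, 7, c(14, 0)), 0)
  expect_error(select_reference_time(co2, 5, numeric(0)), "empty")
})

one <- grid_spec(c(0, 1), c(0, 1))   # 2x2 grid of identical values acts as
cf <- function(v, var = "precip", t = NA) # a "single node" for arithmetic
  climate_field(matrix(v, 2, 2), one, var, t)

test_that("dynamic delta reproduces the printed arithmetic", {
  expect_equal(unique(as.numeric(
    dynamic_delta(cf(100), cf(50), cf(60))$values)), 120)
  expect_equal(unique(as.numeric(
    dynamic_delta(cf(15, "temp"), cf(12, "temp"), cf(10, "temp"),
                  "additive")$values)), 13)
})

test_that("classical delta reproduces the printed arithmetic", {
  expect_equal(unique(as.numeric(
    classical_delta(cf(80), cf(20), cf(40))$values)), 160)
})

set.seed(3)
gC <- grid_spec(seq(0, 10, 2.5), seq(0, 10, 2.5))
gF <- grid_spec(seq(0.5, 9.5, 1), seq(0.5, 9.5, 1))
rnd <- function(lo, hi, var = "precip", g = gC)
  climate_field(matrix(runif(length(g$lon) * length(g$lat), lo, hi),
                       length(g$lon)), g, var)

test_that("delta identities hold to 1e-9 relative", {
  c1 <- rnd(50, 400); f1 <- rnd(40, 500, g = gF)
  # t = t_hat: output equals the fine snapshot exactly
  out <- dynamic_delta(c1, c1, f1)
  expect_lt(max(abs(out$values - f1$values)) / max(f1$values), 1e-9)
  out_a <- dynamic_delta(c1, c1, f1, mode = "additive")
  expect_lt(max(abs(out_a$values - f1$values)) / max(f1$values), 1e-9)
  # unit correction: fine snapshot equal to the regridded coarse reference
  c2 <- rnd(50, 400)
  f_unit <- regrid(c2, gF)
  out2 <- dynamic_delta(c1, c2, f_unit)
  want <- regrid(c1, gF)$values
  expect_lt(max(abs(out2$values - want)) / max(want), 1e-9)
  # model constant in time: classical delta returns the observations
  obs <- rnd(50, 400, g = gF)
  out3 <- classical_delta(c1, c1, obs)
  expect_lt(max(abs(out3$values - obs$values)) / max(obs$values), 1e-9)
})

test_that("two-step chain with constant inputs returns the observations", {
  cst <- function(t) climate_field(
    matrix(200, length(gC$lon), length(gC$lat)), gC, "precip", t)
  cc <- cst(7); c0 <- cst(0)
  fin <- climate_field(matrix(200, length(gF$lon), length(gF$lat)), gF, "precip")
  obs <- rnd(80, 300, g = gF)
  step1_t <- dynamic_delta(cc, c0, fin)
  step1_0 <- dynamic_delta(c0, c0, fin)
  out <- classical_delta(step1_t, step1_0, obs)
  expect_lt(max(abs(out$values - obs$values)) / max(obs$values), 1e-9)
})

test_that("multiplicative outputs are non-negative with hyperarid references", {
  c1 <- rnd(0, 2); c2 <- rnd(0, 0.05)  # reference below the ratio floor
  f1 <- rnd(0, 1, g = gF)
  out <- dynamic_delta(c1, c2, f1)
  expect_true(all(out$values >= 0))
  expect_true(all(is.finite(out$values)))
})

test_that("land mask uses strict elevation > sea level and nests", {
  sea <- data.frame(time_ka = c(0, 1, 2), value = c(0, -50, -120))
  elev <- c(10, -10, 0, -60, -119.5)
  m0 <- land_mask(elev, sea, 0)
  expect_equal(as.logical(m0), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  m1 <- land_mask(elev, sea, 1)
  expect_equal(as.logical(m1), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # elevation exactly at sea level is sea
  expect_false(as.logical(land_mask(-50, sea, 1)))
  # nesting: higher sea level => subset of land
  expect_true(all(!m0 | m1))
  expect_error(land_mask(elev, sea, 5), "coverage")
})

test_that("land-mask nesting holds across a synthetic world", {
  world <- make_world(light_config(), seed = 4)
  s <- world$sea_level
  ord <- order(s$value)                 # lowest sea level first
  prev <- NULL
  for (t in s$time_ka[ord]) {
    m <- land_mask(world$elevation, world$sea_level, t)
    if (!is.null(prev)) expect_true(all(!m | prev))  # rising sea: mask shrinks
    prev <- m
  }
})

test_that("IDW infilling: constants, single donor, equidistant pair", {
  pts <- rbind(c(0, 0), c(2, 0), c(1, 1), c(1, -1), c(1, 0))
  f <- climate_field(c(10, 20, 7, 7, NA), pts, "temp")
  donors <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  target <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  # two donors at equal distance -> plain mean
  out <- fill_submarine_cells(f, donors, target, k = 2)
  expect_equal(out$values[5], 15)
  # all donors equal -> that constant for any k/power
  f2 <- climate_field(c(8, 8, 8, 8, NA), pts, "temp")
  d2 <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  expect_equal(fill_submarine_cells(f2, d2, !d2, k = 3, power = 1)$values[5], 8)
  # exactly one donor -> copied
  d1 <- c(TRUE, rep(FALSE, 4))
  out1 <- fill_submarine_cells(f, d1, target, k = 4, power = 3)
  expect_equal(out1$values[5], 10)
  # donors unchanged
  expect_equal(out$values[1:4], f$values[1:4])
  expect_error(fill_submarine_cells(f, rep(FALSE, 5), target), "donor")
})
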
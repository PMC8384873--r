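# Suitability sets, connectivity, bisection, the maximin oracle, and
# windows of opportunity.

tg <- tiny_grid()
rt <- tiny_route(tg)
n <- nrow(tg$nodes)
land_all <- rep(TRUE, n)

test_that("suitability uses an inclusive threshold and respects zones", {
  v <- rep(50, n)
  s <- suitable_set(v, tg, land_all, rt, 50)
  expect_true(all(s))                       # value exactly p is suitable
  expect_false(any(suitable_set(v, tg, land_all, rt, 50.0001)))
  expect_error(suitable_set(v, tg, land_all, rt, -1), "non-negative")
  # barriers remove, exemptions add regardless of climate and sea level
  rt2 <- rt
  rt2$barrier[3] <- TRUE
  rt2$exempt[4] <- TRUE
  s2 <- suitable_set(rep(0, n), tg, rep(FALSE, n), rt2, 10)
  expect_false(s2[3])
  expect_true(s2[4])
  expect_equal(sum(s2), 1L)
})

test_that("path_exists agrees with an independent igraph component oracle", {
  set.seed(21)
  for (rep in 1:100) {
    suit <- runif(n) < runif(1, 0.2, 0.8)
    s <- structure(suit, class = "suitability_mask")
    expect_equal(path_exists(s, tg, rt), igraph_path_exists(suit, tg, rt))
  }
})

test_that("bottleneck oracle equals exhaustive maximin on small grids", {
  tg4 <- tiny_grid(5, 4)
  rt4 <- tiny_route(tg4)
  land4 <- rep(TRUE, nrow(tg4$nodes))
  set.seed(33)
  for (rep in 1:5) {
    v <- round(runif(nrow(tg4$nodes), 0, 1000))
    got <- bottleneck_oracle(v, tg4, land4, rt4)
    want <- brute_maximin(v, tg4, rt4)
    expect_equal(got, want)
  }
})

test_that("two disjoint corridors: the wetter bottleneck wins", {
  # grid rows are 6 wide; corridor rows 1 and 5, barrier elsewhere
  v <- rep(5, n)
  v[1:6] <- c(200, 80, 200, 200, 200, 200)     # southern lane, bottleneck 80
  v[25:30] <- c(200, 200, 120, 200, 200, 200)  # northern lane, bottleneck 120
  rt2 <- rt
  rt2$start <- 1L                               # ambiguous start: connect both
  v[1] <- 200
  # join the two lanes at the west column so both are reachable
  v[c(7, 13, 19)] <- 200
  expect_equal(bottleneck_oracle(v, tg, land_all, rt2), 120)
  expect_equal(brute_maximin(v, tg, rt2), 120)
})

test_that("bisection brackets halve exactly and match the oracle", {
  set.seed(55)
  v <- round(runif(n, 0, 900))
  b <- critical_threshold(v, tg, land_all, rt)
  expect_equal(b$p_hat - b$p_check, 1000 / 2^(0:10))
  orc <- bottleneck_oracle(v, tg, land_all, rt)
  expect_lte(abs(b$p_crit - orc), 1000 / 2^10)
  expect_true(all(b$p_check <= orc & orc <= b$p_hat))
})

test_that("a complete unsuitable barrier blocks the path", {
  v <- rep(500, n)
  v[seq(4, n, by = 6)] <- 0                    # full column at 0
  s <- suitable_set(v, tg, land_all, rt, 10)
  expect_false(path_exists(s, tg, rt))
  # blocked at the lower bound -> sentinel
  land_none <- rep(FALSE, n)
  b <- critical_threshold(v, tg, land_none, rt)
  expect_true(b$blocked)
  expect_true(is.na(b$p_crit))
  expect_true(is.na(bottleneck_oracle(v, tg, land_none, rt)))
})

test_that("connected even at the upper bound collapses the bracket there", {
  v <- rep(1500, n)
  b <- critical_threshold(v, tg, land_all, rt)
  expect_gte(b$p_crit, 999)
})

test_that("raising one node's value never lowers the critical threshold", {
  set.seed(77)
  v <- round(runif(n, 0, 500))
  base <- critical_threshold(v, tg, land_all, rt)$p_crit
  for (i in sample(n, 8)) {
    v2 <- v
    v2[i] <- v2[i] + 300
    expect_gte(critical_threshold(v2, tg, land_all, rt)$p_crit, base)
  }
})

test_that("window fractions are in [0,100], monotone, and 100% at zero", {
  set.seed(88)
  dec <- matrix(round(runif(n * 20, 0, 300)), n, 20)
  wt <- window_fractions(dec, tg, land_all, rt, c(0, 50, 100, 200, 400))
  expect_true(all(wt$pct_decades >= 0 & wt$pct_decades <= 100))
  expect_true(all(diff(wt$pct_decades) <= 0))
  expect_equal(wt$pct_decades[1], 100)     # contiguous land at tolerance 0
})

test_that("planted corridors in a synthetic world are recovered exactly", {
  world <- make_world(light_config(), seed = 14)
  land <- land_mask(world$elevation, world$sea_level, 0)
  v <- world$normals[["0"]]$precip
  tr <- world$truth$corridor
  for (route in c("northern", "southern")) {
    rn <- route_nodes(world$routes[[route]], world$hex)
    planted <- tr$bottleneck_precip[tr$route == route & tr$time_ka == 0]
    expect_equal(bottleneck_oracle(v, world$hex, land, rn), planted)
    expect_lt(abs(critical_threshold(v, world$hex, land, rn)$p_crit - planted), 1)
  }
})
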
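# records giving every block the given flat speed in all four directions
flat_records <- function(ids, mbps) {
  broadband_records(ids, "p1", rep(mbps, length(ids)),
                    rep(mbps, length(ids)))
}

test_that("pair weights respect catchment membership and broadband gaps", {
  blk <- blocks(c("d", "s"), x = 0:1, y = 0, population = c(100, 0),
                supply = c(0, 1))
  far <- od_pairs("d", "s", 31)
  W <- pair_weights(blk, far, d0 = 30, mode = "distance_only")
  expect_equal(nrow(W), 0)   # 31 min > 30 min: no entry at all

  near <- od_pairs("d", "s", 10)
  bb <- aggregate_all(flat_records(c("d", "s"), 50), "min_a")
  W <- pair_weights(blk, near, 30, "stepwise_broadband", bb = bb,
                    schedule = default_schedule())
  expect_equal(W$weight, 1)

  # sub-0.6 demand: entry present with weight exactly 0
  bb2 <- aggregate_all(broadband_records(c("d", "s"), "p1", c(0.4, 50),
                                         c(0.4, 50)), "min_a")
  W2 <- pair_weights(blk, near, 30, "stepwise_broadband", bb = bb2,
                     schedule = default_schedule())
  expect_equal(nrow(W2), 1)
  expect_equal(W2$weight, 0)

  # block with no aggregated broadband row: weight 0, not an error
  bb3 <- aggregate_all(flat_records("s", 50), "min_a")
  W3 <- pair_weights(blk, near, 30, "stepwise_broadband", bb = bb3,
                     schedule = default_schedule())
  expect_equal(W3$weight, 0)

  expect_error(pair_weights(blk, near, 30, "stepwise_broadband"),
               "schedule")
  expect_error(pair_weights(blk, near, -5, "distance_only"), "d0")
})

test_that("supply-demand ratios and the accessibility step match hand computation", {
  # one supply of 2 serving one demand of 1000 at weight 1: R = 0.002
  blk <- blocks(c("d", "s"), x = 0:1, y = 0, population = c(1000, 0),
                supply = c(0, 2))
  od <- od_pairs("d", "s", 10)
  W <- pair_weights(blk, od, 30, "distance_only")
  R <- supply_demand_ratios(blk, W)
  expect_equal(unname(R["s"]), 0.002)
  A <- accessibility_step(blk, W, R)
  expect_equal(unname(A["d"]), 0.002)

  # two demands of 100 at weights 1 and 0.33: R = 1/133
  blk2 <- blocks(c("d1", "d2", "s"), x = 0:2, y = 0,
                 population = c(100, 100, 0), supply = c(0, 0, 1))
  od2 <- od_pairs(c("d1", "d2"), c("s", "s"), c(5, 5))
  bb <- aggregate_all(broadband_records(c("d1", "d2", "s"), "p1",
                                        c(100, 1, 100), c(100, 1, 100)),
                      "min_a")
  W2 <- pair_weights(blk2, od2, 30, "stepwise_broadband", bb = bb,
                     schedule = default_schedule())
  R2 <- supply_demand_ratios(blk2, W2)
  expect_equal(unname(R2["s"]), 1 / 133, tolerance = 1e-12)
  A2 <- accessibility_step(blk2, W2, R2)
  expect_equal(unname(A2["d1"]), 1 / 133, tolerance = 1e-12)
  expect_equal(unname(A2["d2"]), 0.33 / 133, tolerance = 1e-12)

  # supply with no in-catchment demand: R = 0, never NaN
  blk3 <- blocks(c("d", "s"), x = 0:1, y = 0, population = c(100, 0),
                 supply = c(0, 3))
  W3 <- pair_weights(blk3, od_pairs("d", "s", 50), 30, "distance_only")
  expect_equal(unname(supply_demand_ratios(blk3, W3)["s"]), 0)
})

test_that("a supply and demand sharing a block connect through the zero self-pair", {
  blk <- blocks("b", 0, 0, population = 1000, supply = 2)
  od <- od_pairs("b", "b", 0)
  res <- compute_accessibility(blk, od, 30, "2sfca")
  expect_equal(unname(res$scores["b"]), 0.002)
})

test_that("with universal fast broadband all three methods collapse to 2SFCA", {
  sc <- generate_scenario(scenario_config(rows = 6, cols = 6, seed = 3,
                                          divide_prob = 0))
  rec <- flat_records(sc$blocks$block_id, 50)  # all four speeds >= 3
  od <- od_matrix(sc$graph, snap_to_graph(sc$blocks, sc$graph),
                  cutoff = 30)
  base <- compute_accessibility(sc$blocks, od, 30, "2sfca")
  svca <- compute_accessibility(sc$blocks, od, 30, "2svca",
                                records = rec)
  expect_identical(svca$scores, base$scores)
  for (m in speed_metrics()) {
    e <- compute_accessibility(sc$blocks, od, 30, "e2svca", metric = m,
                               records = rec)
    expect_identical(e$scores, base$scores)
  }
})

test_that("the engine equals the triple-loop reference on random fixtures", {
  for (seed in 1:8) {
    fx <- make_random_fixture(seed, n = sample(8:20, 1))
    for (method in c("2sfca", "2svca", "e2svca")) {
      metric <- sample(speed_metrics(), 1)
      got <- compute_accessibility(fx$blocks, fx$od, 25, method,
                                   metric = metric,
                                   records = fx$broadband)
      want <- oracle_method(fx$blocks, fx$od, 25, method,
                            metric = metric, records = fx$broadband)
      expect_equal(got$scores, want$scores, tolerance = 1e-12)
      expect_equal(got$ratios, want$ratios, tolerance = 1e-12)
    }
  }
})

test_that("population-weighted totals conserve reachable supply", {
  for (seed in 11:25) {
    fx <- make_random_fixture(seed)
    for (method in c("2sfca", "2svca", "e2svca")) {
      res <- compute_accessibility(fx$blocks, fx$od, 25, method,
                                   metric = "min_f",
                                   records = fx$broadband)
      lhs <- sum(fx$blocks$population *
                 res$scores[fx$blocks$block_id])
      rhs <- sum(fx$blocks$supply[match(names(res$ratios)[res$ratios > 0],
                                        fx$blocks$block_id)])
      expect_equal(lhs, rhs, tolerance = 1e-9)
    }
  }
})

test_that("scores are linear in supply and inverse-linear in demand", {
  fx <- make_random_fixture(31)
  base <- compute_accessibility(fx$blocks, fx$od, 25, "e2svca",
                                metric = "max_f",
                                records = fx$broadband)
  up <- fx$blocks
  up$supply <- up$supply * 3
  res_s <- compute_accessibility(up, fx$od, 25, "e2svca",
                                 metric = "max_f",
                                 records = fx$broadband)
  expect_equal(res_s$scores, base$scores * 3, tolerance = 1e-12)
  dm <- fx$blocks
  dm$population <- dm$population * 4
  res_d <- compute_accessibility(dm, fx$od, 25, "e2svca",
                                 metric = "max_f",
                                 records = fx$broadband)
  expect_equal(res_d$scores, base$scores / 4, tolerance = 1e-12)
})

test_that("zero-population and zero-weight demand blocks change no score", {
  fx <- make_random_fixture(41)
  base <- compute_accessibility(fx$blocks, fx$od, 25, "e2svca",
                                metric = "min_a",
                                records = fx$broadband)
  extra <- rbind(as.data.frame(fx$blocks),
                 data.frame(block_id = c("zp", "zw"), x = 0, y = 0,
                            population = c(0, 50), supply = 0,
                            in_report_region = TRUE))
  class(extra) <- class(fx$blocks)
  # zp has zero population; zw has population but sub-0.6 broadband
  od2 <- od_pairs(c(fx$od$origin, "zp", "zw"),
                  c(fx$od$destination,
                    rep(fx$blocks$block_id[which.max(fx$blocks$supply)],
                        2)),
                  c(fx$od$minutes, 5, 5))
  bb2 <- rbind(as.data.frame(fx$broadband),
               data.frame(block_id = c("zp", "zw"), provider_id = "p",
                          download_mbps = c(100, 0.3),
                          upload_mbps = c(100, 0.3)))
  class(bb2) <- class(fx$broadband)
  res <- compute_accessibility(extra, od2, 25, "e2svca",
                               metric = "min_a", records = bb2)
  expect_equal(res$scores[fx$blocks$block_id],
               base$scores[fx$blocks$block_id], tolerance = 1e-12)
})

test_that("worst-case metric never exceeds the optimal metric in total access", {
  for (seed in 51:60) {
    fx <- make_random_fixture(seed)
    tot <- function(metric) {
      r <- compute_accessibility(fx$blocks, fx$od, 25, "e2svca",
                                 metric = metric,
                                 records = fx$broadband)
      sum(fx$blocks$population * r$scores[fx$blocks$block_id])
    }
    expect_true(tot("min_a") <= tot("max_f") + 1e-9)
  }
})
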
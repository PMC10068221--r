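fake_result <- function(scores, pop = NULL, region = NULL,
                        method = "2sfca", d0 = 30, factor = NULL) {
  ids <- names(scores)
  n <- length(ids)
  blk <- blocks(ids, x = seq_len(n), y = 0,
                population = if (is.null(pop)) rep(100, n) else pop,
                supply = rep(0, n),
                in_report_region = if (is.null(region)) TRUE else region)
  structure(list(method = method, metric = NULL, d0 = d0,
                 per_capita_factor = factor, scores = scores,
                 ratios = stats::setNames(numeric(0), character(0)),
                 blocks = blk),
            class = "accessibility_result")
}

test_that("per-capita scaling multiplies scores and records the factor", {
  r <- fake_result(c(a = 0.002, b = 0.004))
  s <- per_capita_scale(r, 1000)
  expect_equal(unname(s$scores), c(2, 4))
  expect_equal(s$per_capita_factor, 1000)
  expect_equal(per_capita_scale(r, 1)$scores, r$scores)
  back <- per_capita_scale(s, 1 / 1000)
  expect_equal(back$scores, r$scores)
  expect_error(per_capita_scale(r, 0), "positive")
})

test_that("min-max normalization maps the in-scope range onto [0,1]", {
  r <- fake_result(c(a = 2, b = 4, c = 6))
  expect_equal(unname(min_max_normalize(r)), c(0, 0.5, 1))
  expect_warning(ns <- min_max_normalize(fake_result(c(a = 3, b = 3))),
                 "equal")
  expect_equal(unname(ns), c(0, 0))
  # buffer blocks are excluded from the min/max and the output
  r2 <- fake_result(c(a = 2, b = 4, buf = 100),
                    region = c(TRUE, TRUE, FALSE))
  ns2 <- min_max_normalize(r2)
  expect_equal(names(ns2), c("a", "b"))
  expect_equal(unname(ns2), c(0, 1))
  expect_true(all(ns2 >= 0 & ns2 <= 1))
})

test_that("classification uses half-open bins with a closed top class", {
  lab <- classify(c(a = 1.5, b = 0, c = 2, d = 8),
                  breaks = c(0, 2, 3, 4, 5, 8))
  expect_equal(as.character(lab),
               c("0-2", "0-2", "2-3", "5-8"))
  norm <- classify(c(x = 0.95, y = 0.8), breaks = normalized_breaks())
  expect_equal(as.character(norm), c("0.8-1.0", "0.8-1.0"))
  expect_error(classify(c(bad = 9), breaks = c(0, 2, 3, 4, 5, 8)),
               "bad")
  # partition: every in-range score maps to exactly one class
  set.seed(2)
  x <- stats::setNames(runif(100, 0, 8), paste0("b", 1:100))
  cl <- classify(x, breaks = c(0, 2, 3, 4, 5, 8))
  expect_false(anyNA(cl))
  expect_length(cl, 100)
})

test_that("difference classifies deltas by sign and aggregates population", {
  r1 <- fake_result(c(a = 2, b = 3, c = 4), pop = c(100, 200, 50))
  same <- difference(r1, r1)
  expect_equal(same$summary$n_blocks[same$summary$diff_class == "equal"],
               3)
  expect_true(all(same$table$diff_class == "equal"))

  r2 <- fake_result(c(a = 1, b = 3, c = 5), pop = c(100, 200, 50))
  d <- difference(r1, r2)
  expect_equal(sum(d$summary$n_blocks), 3)
  expect_equal(sum(d$summary$population), 350)
  expect_equal(d$summary$n_blocks,
               c(1, 1, 1))  # one under, one equal, one over
  expect_equal(
    d$summary$population[d$summary$diff_class == "over"], 100)
  # reversing arguments swaps under and over exactly
  rev <- difference(r2, r1)
  expect_equal(rev$summary$n_blocks[rev$summary$diff_class == "under"],
               d$summary$n_blocks[d$summary$diff_class == "over"])
  expect_equal(rev$summary$n_blocks[rev$summary$diff_class == "over"],
               d$summary$n_blocks[d$summary$diff_class == "under"])

  r3 <- fake_result(c(z = 1))
  expect_error(difference(r1, r3), "block sets")
  r4 <- fake_result(c(a = 2, b = 3, c = 4), pop = c(100, 200, 50),
                    factor = 1000)
  expect_error(difference(r1, r4), "scaling")
})

test_that("binary-vs-stepwise comparison flags the overestimated blocks", {
  # demand block "slow" has 0.4 Mbps: under E2SVCA it stops competing for
  # supply, so its competitors gain and the binary model overestimates it
  blk <- blocks(c("slow", "fast", "s"), x = 0:2, y = 0,
                population = c(100, 100, 0), supply = c(0, 0, 1))
  od <- od_pairs(c("slow", "fast"), c("s", "s"), c(5, 5))
  rec <- broadband_records(c("slow", "fast", "s"), "p",
                           c(0.4, 100, 100), c(0.4, 100, 100))
  sv <- compute_accessibility(blk, od, 30, "2svca", records = rec)
  e2 <- compute_accessibility(blk, od, 30, "e2svca", metric = "min_a",
                              records = rec)
  d <- difference(sv, e2)
  cls <- stats::setNames(as.character(d$table$diff_class),
                         d$table$block_id)
  expect_identical(unname(cls["slow"]), "over")   # 0.005 vs 0
  expect_identical(unname(cls["fast"]), "under")  # 0.005 vs 0.01
})

test_that("summary statistics match an independent two-pass computation", {
  r <- fake_result(c(a = 1, b = 2, c = 3))
  s <- summarize_result(r)
  expect_equal(s$mean, 2)
  expect_equal(s$min, 1)
  expect_equal(s$max, 3)
  expect_equal(s$count, 3)
  expect_equal(summarize_result(fake_result(c(a = 5)))$std, 0)
  set.seed(13)
  x <- stats::setNames(runif(40, 0, 6), sprintf("b%02d", 1:40))
  rr <- fake_result(x)
  s2 <- summarize_result(rr)
  m <- sum(x) / length(x)
  expect_equal(s2$std, sqrt(sum((x - m)^2) / length(x)))
  s3 <- summarize_result(rr, sample_sd = TRUE)
  expect_equal(s3$std, stats::sd(x))
})
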
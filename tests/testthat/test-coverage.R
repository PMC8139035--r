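# Coverage scale-up trajectories: endpoint pinning, shape contracts,
# published-row reproduction, increments.

test_that("linear interpolation reproduces the published depression rows", {
  intensive <- coverage_interpolate(1, 30, 10, "linear", years = 2020:2030)
  expect_equal(unname(as.numeric(intensive)),
               c(1, 3.9, 6.8, 9.7, 12.6, 15.5, 18.4, 21.3, 24.2, 27.1, 30))
  expect_identical(as.numeric(intensive)[6], 15.5)  # mid-horizon checkpoint

  basic <- coverage_interpolate(40, 70, 10, "linear", years = 2020:2030)
  expect_equal(unname(as.numeric(basic)), seq(40, 70, by = 3))

  expect_equal(unname(coverage_increments(intensive)), rep(2.9, 10))
})

test_that("endpoints are pinned exactly for every pattern", {
  set.seed(7)
  for (i in 1:25) {
    b <- runif(1, 0, 60)
    tg <- b + runif(1, 0, 100 - b)
    n <- sample(1:15, 1)
    for (p in c("linear", "front_loaded", "s_shaped", "exponential")) {
      tr <- as.numeric(coverage_interpolate(b, tg, n, p))
      expect_identical(tr[1], b)
      expect_identical(tr[n + 1], tg)
      expect_true(all(diff(tr) >= -1e-9))
    }
  }
})

test_that("patterns honor their increment shape contracts", {
  set.seed(11)
  for (i in 1:25) {
    b <- runif(1, 0, 50)
    tg <- b + runif(1, 1, 100 - b)
    n <- sample(3:15, 1)
    inc <- function(p) diff(as.numeric(coverage_interpolate(b, tg, n, p)))
    expect_lt(max(abs(diff(inc("linear")))), 1e-9)
    expect_true(all(diff(inc("front_loaded")) <= 1e-9))
    expect_true(all(diff(inc("exponential")) >= -1e-9))
    d <- diff(inc("s_shaped"))
    sign_changes <- sum(diff(sign(d[abs(d) > 1e-12])) != 0)
    expect_lte(sign_changes, 1)  # increments rise then fall
  }
})

test_that("front-loaded dominates linear dominates exponential pointwise", {
  set.seed(13)
  for (i in 1:20) {
    b <- runif(1, 0, 50)
    tg <- b + runif(1, 1, 100 - b)
    n <- sample(2:15, 1)
    fl <- as.numeric(coverage_interpolate(b, tg, n, "front_loaded"))
    li <- as.numeric(coverage_interpolate(b, tg, n, "linear"))
    ex <- as.numeric(coverage_interpolate(b, tg, n, "exponential"))
    expect_true(all(fl >= li - 1e-9))
    expect_true(all(li >= ex - 1e-9))
  }
})

test_that("degenerate and invalid inputs behave as specified", {
  for (p in c("linear", "front_loaded", "s_shaped", "exponential")) {
    tr <- coverage_interpolate(35, 35, 8, p)
    expect_equal(unname(as.numeric(tr)), rep(35, 9))
    expect_equal(unname(coverage_increments(tr)), rep(0, 8))
  }
  expect_error(coverage_interpolate(50, 40, 10, "linear"),
               class = "mh_validation_error")
  expect_error(coverage_interpolate(-1, 40, 10, "linear"),
               class = "mh_validation_error")
  expect_error(coverage_interpolate(10, 120, 10, "linear"),
               class = "mh_validation_error")
  expect_error(coverage_interpolate(10, 40, 0, "linear"),
               class = "mh_validation_error")
})

test_that("explicit coverage rows are validated and authoritative", {
  row <- c(40, 43.9, 47.5, 50.9, 54.1, 57.1, 59.9, 62.6, 65.2, 67.7, 70)
  tr <- coverage_from_table(row, years = 2020:2030, intervention = "anx_basic")
  expect_identical(as.numeric(tr)[11], 70)
  expect_equal(sum(coverage_increments(tr)), 30)

  expect_error(coverage_from_table(c(40, 50, 49, 60)),
               class = "mh_validation_error")
  expect_error(coverage_from_table(c(40, 50), years = 2020:2022),
               class = "mh_validation_error")
  single <- coverage_from_table(40, years = 2020)
  expect_length(as.numeric(single), 1)
  expect_length(coverage_increments(single), 0)
})

test_that("increments telescope to target minus baseline", {
  set.seed(17)
  for (i in 1:20) {
    b <- runif(1, 0, 70)
    tg <- b + runif(1, 0, 100 - b)
    n <- sample(1:12, 1)
    p <- sample(c("linear", "front_loaded", "s_shaped", "exponential"), 1)
    tr <- coverage_interpolate(b, tg, n, p)
    inc <- coverage_increments(tr)
    expect_true(all(inc >= -1e-9))
    expect_equal(sum(inc), tg - b)
  }
})

test_that("every published coverage row passes trajectory validation", {
  cov <- iran_coverage()
  for (i in seq_len(nrow(cov))) {
    tr <- coverage_from_table(as.numeric(cov[i, paste0("y", 2020:2030)]),
                              years = 2020:2030,
                              intervention = cov$intervention[i])
    expect_s3_class(tr, "coverage_trajectory")
  }
  # the label says front-loaded: increments of the non-linear rows never grow
  anx <- as.numeric(cov[cov$intervention == "anx_basic", paste0("y", 2020:2030)])
  expect_true(all(diff(diff(anx)) <= 1e-9))
})
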
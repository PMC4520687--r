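test_that("population sampling is moment-matched and reproducible", {
  st <- population_stats()
  expect_equal(unname(st$mean),
               c(4.2, 3.8, 39.4, 15.11, 0.08))
  expect_true(min(eigen(st$cov, symmetric = TRUE)$values) > -1e-8)
  # the conversion/elimination pair carries its known strong correlation
  expect_equal(cov2cor(st$cov)["k_cm", "k_me"], 0.96, tolerance = 1e-6)

  th <- sample_population(2e4, st, seed = 1)
  expect_true(all(th > 0))
  expect_equal(unname(colMeans(th)), unname(st$mean), tolerance = 0.01)
  expect_equal(cor(th[, "k_cm"], th[, "k_me"]), 0.96, tolerance = 0.05)
  expect_equal(unname(apply(th, 2, var)), unname(diag(st$cov)),
               tolerance = 0.08)

  expect_identical(sample_population(10, st, seed = 9),
                   sample_population(10, st, seed = 9))
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(population_stats(c(k_ab = 1, k_el = 1, k_cm = 1, K = 1,
                                  k_me = 1), diag(-1, 5)))
})

test_that("activity groups use half-open 2-unit windows from 7.01", {
  expect_equal(assign_activity_group(8), 1L)
  expect_equal(assign_activity_group(9), 1L)
  expect_equal(assign_activity_group(9.005), 2L)
  expect_equal(assign_activity_group(10), 2L)
  expect_equal(assign_activity_group(29.5), 11L)
  expect_error(assign_activity_group(7), "out of modelled range")
})

test_that("genotype classes split at 10 U/ml/hr", {
  expect_equal(genotype_from_activity(9), "heterozygous")
  expect_equal(genotype_from_activity(15), "homozygous-high")
  expect_equal(genotype_from_activity(10), "homozygous-high")
})

test_that("generated datasets match the source-study shapes", {
  d1 <- generate_dataset("D1", seed = 5)
  expect_length(d1, 23)
  for (s in d1) {
    expect_true(length(s$y) >= 1 && length(s$y) <= 4)
    expect_lte(max(s$times), 56)
    expect_true(all(s$y >= 0))
    expect_false(is.unsorted(s$times))
  }

  d2 <- generate_dataset("D2", seed = 5)
  expect_length(d2, 8)
  expect_true(all(vapply(d2, function(s) max(s$times), 0) == 140))

  d3 <- generate_dataset("D3", seed = 5)
  expect_length(d3, 102)
  acts <- vapply(d3, function(s) s$activity$e, 0)
  expect_true(all(acts >= 7 & acts <= 30))
  expect_true(all(vapply(d3, function(s) length(s$y), 0L) == 1L))

  # determinism
  d1b <- generate_dataset("D1", seed = 5)
  expect_identical(vapply(d1, function(s) s$y[1], 0),
                   vapply(d1b, function(s) s$y[1], 0))

  # ground truth is attached and consistent
  truth <- attr(d3, "truth")
  expect_length(truth, 102)
  g <- vapply(truth, function(t) t$group, 0L)
  expect_identical(g, vapply(truth, function(t)
    assign_activity_group(max(t$activity$e, 7.01)), 0L))
})

test_that("zero-noise observations equal the simulated truth", {
  cfg <- synth_config(sigma_add = 0, sigma_prop = 0)
  d1 <- generate_dataset("D1", config = cfg, seed = 3)
  truth <- attr(d1, "truth")
  s <- d1[[1]]
  yh <- simulate_pk(truth[[1]]$params, s$doses,
                    sort(unique(c(0, s$times))))$x_m
  expect_equal(s$y, yh[match(s$times, sort(unique(c(0, s$times))))],
               tolerance = 1e-5)
})

test_that("6-TGN is negatively rank-correlated with TPMT activity in D3", {
  d3 <- generate_dataset("D3", seed = 11)
  acts <- vapply(d3, function(s) s$activity$e, 0)
  conc <- vapply(d3, function(s) s$y[1], 0)
  expect_lt(cor(acts, conc, method = "spearman"), 0)
})

test_that("datasets round-trip through the CSV bundle writer", {
  d <- generate_dataset("D1", seed = 2)
  dir <- tempfile()
  write_dataset(d, dir, seed = 2)
  meas <- read.csv(file.path(dir, "measurements.csv"))
  expect_equal(nrow(meas), sum(vapply(d, function(s) length(s$y), 0L)))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$design, "D1")
  unlink(dir, recursive = TRUE)
})
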
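test_that("closed-form membership values are honored", {
  s <- membership_function("s_type", "SP", "HT", list(a = 0.3, b = 150),
                           support = c(50, 250))
  expect_equal(eval_mf(s, 150), 0.5)
  g <- membership_function("quasi_gaussian", "SV", "Low_BE",
                           list(a = 60, d = 5), support = c(0, 120))
  expect_equal(eval_mf(g, 60), 1)
  expect_equal(eval_mf(g, 60 + 2 * 5), exp(-1))
  expect_equal(eval_mf(g, 60 - 2 * 5), exp(-1))
  p <- membership_function("polynomial", "X", "H", list(lambda = 1.3),
                           support = c(0, 1))
  expect_equal(eval_mf(p, 0.5), 1)  # clipped
})

test_that("grades stay in [0,1] for every family and finite input", {
  set.seed(5)
  mfs <- list(
    membership_function("polynomial", "X", "H",
                        list(lambda = rnorm(4, sd = 3)), support = c(-5, 5)),
    membership_function("s_type", "X", "H", list(a = -2, b = 0),
                        support = c(-10, 10)),
    membership_function("quasi_gaussian", "X", "H", list(a = 1, d = 0.3),
                        support = c(-4, 4)))
  xs <- c(runif(200, -50, 50), -1e6, 1e6, 0)
  for (mf in mfs) {
    gr <- eval_mf(mf, xs)
    expect_true(all(gr >= 0 & gr <= 1))
  }
  expect_error(eval_mf(mfs[[2]], Inf), "finite")
})

test_that("outside the support the boundary value is returned", {
  s <- membership_function("s_type", "X", "H", list(a = 1, b = 0),
                           support = c(-2, 2))
  expect_equal(eval_mf(s, 100), eval_mf(s, 2))
  expect_equal(eval_mf(s, -100), eval_mf(s, -2))
})

test_that("sigmoid is monotone with the sign of its slope and bell is symmetric", {
  xs <- seq(-5, 5, length.out = 101)
  up <- eval_mf(membership_function("s_type", "X", "H", list(a = 2, b = 0),
                                    support = c(-5, 5)), xs)
  expect_true(all(diff(up) > 0))
  dn <- eval_mf(membership_function("s_type", "X", "H", list(a = -2, b = 0),
                                    support = c(-5, 5)), xs)
  expect_true(all(diff(dn) < 0))
  g <- membership_function("quasi_gaussian", "X", "H", list(a = 0.7, d = 1),
                           support = c(-5, 5))
  for (d in seq(0.1, 3, by = 0.3))
    expect_equal(eval_mf(g, 0.7 + d), eval_mf(g, 0.7 - d), tolerance = 1e-12)
})

test_that("fitting recovers a narrow labeled mode inside a wide cohort", {
  set.seed(101)
  background <- runif(3000, 0, 100)
  labeled <- rnorm(400, mean = 50, sd = 4)
  all_values <- c(labeled, background)
  mf <- fit_mf(labeled, all_values, kind = "auto",
               symptom = "X", hypothesis = "H")
  expect_identical(mf$kind, "quasi_gaussian")
  bins <- max(5L, grDevices::nclass.Sturges(all_values))
  bin_width <- diff(range(all_values)) / bins
  expect_lt(abs(mf$params$a - 50), bin_width)
})

test_that("fitting recovers a monotone prevalence as a sigmoid", {
  set.seed(102)
  cohort <- runif(4000, 0, 100)
  keep <- runif(4000) < 1 / (1 + exp(-0.15 * (cohort - 60)))
  mf <- fit_mf(cohort[keep], cohort, kind = "auto",
               symptom = "X", hypothesis = "H")
  expect_identical(mf$kind, "s_type")
  bins <- max(5L, grDevices::nclass.Sturges(cohort))
  expect_lt(abs(mf$params$b - 60), diff(range(cohort)) / bins)
  expect_gt(mf$params$a, 0)
})

test_that("noise-free grade curves are reproduced within 0.05 at bin centers", {
  set.seed(103)
  centers <- seq(10, 90, by = 5)
  truth <- exp(-((centers - 45) / 30)^2)
  all_values <- c(); labeled <- c()
  for (i in seq_along(centers)) {
    pts <- centers[i] + runif(200, -2.4, 2.4)
    all_values <- c(all_values, pts)
    labeled <- c(labeled, pts[seq_len(round(truth[i] * 200))])
  }
  mf <- fit_mf(labeled, all_values, kind = "quasi_gaussian",
               bins = length(centers))
  expect_lt(max(abs(eval_mf(mf, centers) - truth)), 0.05)
})

test_that("fit guards reject unusable samples", {
  expect_error(fit_mf(c(1, 2, 3), runif(100)), "too few")
  expect_error(fit_mf(rep(1, 30), rep(1, 50)), "degenerate")
  expect_error(fit_mf(runif(30), runif(100), bins = 3), "bins")
})

test_that("family selection follows minimum residual with deterministic ties", {
  x <- seq(0, 10, length.out = 12)
  bell <- exp(-((x - 5) / 2)^2)
  expect_identical(select_kind(x, bell)$kind, "quasi_gaussian")
  sig <- 1 / (1 + exp(-2 * (x - 5)))
  expect_identical(select_kind(x, sig)$kind, "s_type")
  flat <- rep(0.4, 12)
  expect_identical(select_kind(x, flat)$kind, "polynomial")
  expect_error(select_kind(x[1:3], bell[1:3]), "5 occupied bins")
})

test_that("membership sets round-trip through YAML", {
  mfs <- list(
    membership_function("s_type", "SP", "HT", list(a = 0.25, b = 145),
                        support = c(80, 220)),
    membership_function("polynomial", "PR", "TC",
                        list(lambda = c(0.1, 0.02, -1e-4)), support = c(40, 160)))
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_mfs(mfs, tmp)
  back <- read_mfs(tmp)
  expect_length(back, 2L)
  xs <- seq(80, 220, length.out = 20)
  expect_equal(eval_mf(back[[1]], xs), eval_mf(mfs[[1]], xs))
  expect_equal(eval_mf(back[[2]], c(50, 100, 150)),
               eval_mf(mfs[[2]], c(50, 100, 150)))
})
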
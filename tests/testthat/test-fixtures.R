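test_that("logistic growth matches its closed form and an ODE oracle", {
  expect_equal(logistic_growth(0, K = 1000, r = 0.1), 10)        # N(0) = N0
  expect_equal(logistic_growth(0:50, K = 700, r = 0.2, N0 = 700),
               rep(700, 51))                                     # N0 = K fixed point
  # frozen value from an independent Runge-Kutta integration of
  # dN/dt = r N (1 - N/K) at t = 100 (K = 1000, N0 = 10, r = 0.1)
  expect_equal(logistic_growth(100, K = 1000, r = 0.1), 995.5255179295,
               tolerance = 1e-10)
  ode <- deSolve::ode(y = c(N = 10), times = c(0, 37.5),
                      func = function(t, y, p) list(0.13 * y * (1 - y / 850)),
                      parms = NULL, atol = 1e-10, rtol = 1e-10)
  expect_equal(logistic_growth(37.5, K = 850, r = 0.13),
               unname(ode[2, "N"]), tolerance = 1e-7)
  expect_error(logistic_growth(1, K = -1, r = 0.1), "> 0")
})

test_that("logistic curves are monotone toward the carrying capacity", {
  set.seed(21)
  for (i in 1:20) {
    K <- stats::runif(1, 50, 5000)
    r <- stats::runif(1, 0.01, 1)
    N0 <- stats::runif(1, 1, 2 * K)
    curve <- logistic_growth(seq(0, 200, by = 2), K = K, r = r, N0 = N0)
    # monotone toward K; increments reach exactly zero once the curve
    # saturates at the double-precision asymptote
    if (N0 < K) {
      expect_true(all(diff(curve) >= 0))
      expect_gt(curve[2], curve[1])
    } else if (N0 > K) {
      expect_true(all(diff(curve) <= 0))
      expect_lt(curve[2], curve[1])
    }
    expect_lt(abs(logistic_growth(1e6, K, r, N0) - K), 1e-6)  # asymptote
  }
})

test_that("fully biased cells follow the gradient deterministically", {
  pos <- simulate_chemotaxis(n_cells = 25, speed = 2, bias = 1,
                             duration = 120, seed = 9)
  expect_equal(pos$y, rep(10 + 2 * 120, 25))  # y0 + speed * duration
  # long enough to hit the far wall: clamped there
  pos <- simulate_chemotaxis(n_cells = 5, speed = 5, bias = 1,
                             duration = 300, seed = 9)
  expect_equal(pos$y, rep(500, 5))
})

test_that("unbiased walks have no mean drift", {
  # start mid-domain so wall clamping cannot skew the symmetry check
  pos <- simulate_chemotaxis(n_cells = 1500, speed = 2, bias = 0,
                             duration = 60, domain = c(0, 500, -1000, 1000),
                             y0 = 0, seed = 4)
  se <- stats::sd(pos$y) / sqrt(nrow(pos))
  expect_lt(abs(mean(pos$y)), 3 * se + 0.5)
})

test_that("mean final y increases with bias and with speed", {
  mean_y <- function(speed, bias)
    mean(simulate_chemotaxis(n_cells = 200, speed = speed, bias = bias,
                             duration = 60, seed = 7)$y)
  by_bias <- vapply(c(0.1, 0.5, 0.9), function(b) mean_y(2, b), 0)
  expect_true(all(diff(by_bias) > 0))
  by_speed <- vapply(c(0.5, 1, 2), function(s) mean_y(s, 0.9), 0)
  expect_true(all(diff(by_speed) > 0))
  # the calibration regime: strong bias shifts the population far-wall-ward
  shifted <- mean_y(2, 0.9) - mean_y(2, 0.1)
  expect_gt(shifted, 50)
})

test_that("chemotaxis guards its discretization and parameter ranges", {
  expect_error(simulate_chemotaxis(bias = 1.5), "\\[0, 1\\]")
  expect_error(simulate_chemotaxis(speed = -1), "> 0")
  expect_error(simulate_chemotaxis(dt = 2, persistence_time = 1),
               "must not exceed")
})

test_that("simulations are seed-reproducible and leave the caller's RNG alone", {
  a <- simulate_chemotaxis(n_cells = 30, duration = 10, seed = 42)
  b <- simulate_chemotaxis(n_cells = 30, duration = 10, seed = 42)
  expect_identical(a, b)
  set.seed(1); before <- stats::runif(1)
  set.seed(1); simulate_chemotaxis(n_cells = 5, duration = 5, seed = 99)
  expect_identical(stats::runif(1), before)
})

test_that("target generators hit the documented truths", {
  v <- generate_target("logistic", c(K = 1000, r = 0.1))
  expect_equal(v[1], 10)                      # N(0) = N0
  expect_equal(v[length(v)], 995.5255179295, tolerance = 1e-9)
  expect_length(v, 101)

  f <- withr::local_tempfile(fileext = ".csv")
  generate_target("chemotaxis", c(speed = 2, bias = 0.9), path = f, seed = 8)
  y1 <- read_target(f)
  y2 <- generate_target("chemotaxis", c(speed = 2, bias = 0.9), seed = 8)
  expect_identical(y1, y2)
  expect_length(y1, 100)
})

test_that("a sweep against its own generating parameters scores zero on-grid", {
  target <- generate_target("logistic", c(K = 1000, r = 0.1))
  lev <- run_level(fixture_black_box("logistic"),
                   list(axis1 = c(0.05, 0.1, 0.2), axis2 = c(900, 1000, 1100)),
                   target = target, param_names = c("r", "K"))
  expect_identical(lev$best$error, 0)
  expect_equal(unname(lev$best$params), c(0.1, 1000))
})

test_that("mock executables produce output every quantify operation accepts", {
  dir <- withr::local_tempdir()
  exe <- make_mock_executable("logistic", dir)
  cfg <- local_settings()
  bb <- black_box(runner = make_external_runner(exe), config = cfg,
                  processor = final_cell_count)
  n_final <- run_model(bb, c(unused = 0), seed = 0)[[1]]
  # template user_parameters: K = 1000, r = 0.1; snapshots every 10 time units
  expect_equal(n_final, round(logistic_growth(100, K = 1000, r = 0.1)))

  counts <- black_box(runner = make_external_runner(exe), config = cfg,
                      processor = function(d)
                        vapply(snapshot_files(d),
                               function(f) nrow(read_snapshot(f)$cells), 0L,
                               USE.NAMES = FALSE))
  curve <- run_model(counts, c(unused = 0), seed = 0)[[1]]
  expect_equal(curve, round(logistic_growth(seq(0, 100, 10), K = 1000, r = 0.1)))

  # determinism of the stochastic mock under a fixed seed
  dir2 <- withr::local_tempdir()
  exe2 <- make_mock_executable("chemotaxis", dir2)
  bb2 <- black_box(runner = make_external_runner(exe2), config = cfg,
                   processor = function(d) final_coordinates(d, "y"))
  y1 <- run_model(bb2, c(unused = 0), seed = 17)
  y2 <- run_model(bb2, c(unused = 0), seed = 17)
  expect_identical(y1, y2)
})
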
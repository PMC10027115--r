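# synthetic quadratic-bowl model: metric is the parameter pair itself, so
# sse against target (p*, q*) gives the error surface (p-p*)^2 + (q-q*)^2
quadratic_model <- function() {
  black_box(runner = function(workdir, params, seed) unname(params),
            name = "quadratic surface")
}

test_that("grid geometry follows the multiplicative-range rule", {
  g <- build_grid(c(0.15, 1000), percent = 0.5, n = 8)
  expect_equal(g$axis1, seq(0.075, 0.225, length.out = 8))
  expect_equal(g$axis2, seq(500, 1500, length.out = 8))
  expect_equal(range(g$axis1), c(0.075, 0.225))
  expect_equal(range(g$axis2), c(500, 1500))
  expect_equal(length(g$axis1) * length(g$axis2), 64)

  expect_equal(build_grid(c(0.15, 1000), 0.5, n = 1),
               list(axis1 = 0.15, axis2 = 1000))
})

test_that("grid values clip at the bounds and degenerate axes collapse", {
  g <- build_grid(c(0.01, 5), percent = 1.0, n = 4, lower_bounds = c(0, 0))
  expect_equal(min(g$axis1), 0)
  expect_true(all(g$axis1 >= 0))
  g <- build_grid(c(2, 0.95), percent = 0.3, n = 5, upper_bounds = c(Inf, 1))
  expect_true(all(g$axis2 <= 1))
  # center 0 spans a zero-width range: whole axis clips to one point
  expect_warning(g <- build_grid(c(0, 5), percent = 0.5, n = 4),
                 "collapsed")
  expect_equal(g$axis1, 0)
})

test_that("run_level finds an exact on-grid minimum and breaks ties row-major", {
  lev <- run_level(quadratic_model(), list(axis1 = 1:3, axis2 = 2:4),
                   target = c(2, 3), param_names = c("p", "q"))
  expect_equal(unname(lev$best$params), c(2, 3))
  expect_identical(lev$best$error, 0)
  expect_equal(nrow(lev$cells), 9)

  # (0,1) and (2,1) tie against target (1,1); row-major picks (0,1) first
  lev <- run_level(quadratic_model(), list(axis1 = c(0, 2), axis2 = 1),
                   target = c(1, 1), param_names = c("p", "q"))
  expect_equal(unname(lev$best$params), c(0, 1))
})

test_that("failed cells score +Inf; an all-failed level is an error", {
  flaky <- black_box(runner = function(workdir, params, seed) {
    if (params[["p"]] > 1.5) stop("sim exploded")
    unname(params)
  })
  expect_warning(
    lev <- suppressMessages(
      run_level(flaky, list(axis1 = 1:2, axis2 = 1), target = c(2, 1),
                param_names = c("p", "q"))),
    "sim exploded")
  expect_equal(lev$cells$error[lev$cells$p == 2], Inf)
  expect_equal(unname(lev$best$params), c(1, 1))

  broken <- black_box(runner = function(...) stop("nope"))
  expect_error(
    suppressWarnings(suppressMessages(
      run_level(broken, list(axis1 = 1, axis2 = 1), target = 1,
                param_names = c("p", "q")))),
    "all grid cells failed")
})

test_that("a single-level sweep reduces to the grid argmin", {
  cfg <- sweep_config(c("p", "q"), c(2, 3), points_per_direction = 5,
                      percent_per_direction = 0.5, n_levels = 1)
  fit <- run_sweep(quadratic_model(), cfg, target = c(2.1, 2.9))
  lev <- fit$levels[[1]]
  expect_length(fit$levels, 1)
  expect_equal(fit$estimate, lev$best$params)
  k <- which.min(lev$cells$error)
  expect_equal(unname(fit$estimate), unname(unlist(lev$cells[k, 1:2])))
})

test_that("levels recenter on the best point and shrink geometrically", {
  cfg <- sweep_config(c("p", "q"), c(1, 1), 4, 0.6, n_levels = 4,
                      shrink_factor = 0.5)
  fit <- run_sweep(quadratic_model(), cfg, target = c(1.21, 0.83))
  pct <- vapply(fit$levels, `[[`, 0, "percent")
  expect_equal(pct, 0.6 * 0.5^(0:3))
  for (k in 2:4)
    expect_equal(fit$levels[[k]]$center, fit$levels[[k - 1]]$best$params)
  expect_equal(nrow(fit$trajectory), 5)
  expect_equal(unname(fit$trajectory[1, ]), c(1, 1))
  expect_equal(fit$trajectory[5, ], fit$estimate)
  # refinement homes in on the target
  expect_lt(max(abs(fit$estimate - c(1.21, 0.83))), 0.05)
})

test_that("the same configuration and seed reproduce the sweep bitwise", {
  cfg <- sweep_config(c("speed", "bias"), c(2.5, 0.7), 3, 0.3, n_levels = 2,
                      upper_bounds = c(Inf, 1), error_metric = "sse_sorted")
  model <- fixture_black_box("chemotaxis", n_cells = 20, duration = 20)
  target <- generate_target("chemotaxis", c(speed = 2, bias = 0.9), seed = 3,
                            n_cells = 20, duration = 20)
  a <- run_sweep(model, cfg, target, seed = 5)
  b <- run_sweep(model, cfg, target, seed = 5)
  expect_identical(a$levels, b$levels)
  expect_identical(a$estimate, b$estimate)
  expect_identical(a$fitted, b$fitted)
})

test_that("replicate aggregation averages metric vectors before scoring", {
  shifted <- black_box(runner = function(workdir, params, seed) {
    unname(params) + (seed %% 2 - 0.5)  # replicate 1: -0.5, replicate 2: +0.5
  }, replicates = 2)
  lev <- run_level(shifted, list(axis1 = 2, axis2 = 3), target = c(2, 3),
                   param_names = c("p", "q"), seed = 0)
  expect_identical(lev$best$error, 0)  # mean of the two replicates is exact
})

test_that("more levels never hurt accuracy on the deterministic fixture", {
  target <- generate_target("logistic", c(K = 1000, r = 0.1))
  model <- fixture_black_box("logistic")
  err_at <- function(levels) {
    cfg <- sweep_config(c("r", "K"), c(0.15, 1000), 8, 0.5, n_levels = levels)
    est <- coef(run_sweep(model, cfg, target))
    max(abs(est - c(r = 0.1, K = 1000)) / c(0.1, 1000))
  }
  expect_lte(err_at(7), err_at(4))
  expect_lte(err_at(4), err_at(2))
})

test_that("sweep artifacts are written per level plus a final estimate", {
  out <- withr::local_tempdir()
  cfg <- sweep_config(c("p", "q"), c(2, 3), 3, 0.5, n_levels = 2)
  fit <- run_sweep(quadratic_model(), cfg, target = c(2, 3), out_dir = out)
  expect_true(all(file.exists(file.path(out,
    c("level_1_grid.csv", "level_1_best.json",
      "level_2_grid.csv", "level_2_best.json", "estimate.json")))))
  grid1 <- utils::read.csv(file.path(out, "level_1_grid.csv"))
  expect_named(grid1, c("p", "q", "error"))
  expect_equal(nrow(grid1), 9)
  est <- jsonlite::read_json(file.path(out, "estimate.json"))
  expect_equal(unlist(est$estimate), fit$estimate)
})

test_that("fit methods expose the estimate, fit quality and error surface", {
  target <- generate_target("logistic", c(K = 1000, r = 0.1))
  cfg <- sweep_config(c("r", "K"), c(0.15, 1000), 5, 0.5, n_levels = 3)
  fit <- run_sweep(fixture_black_box("logistic"), cfg, target)
  expect_named(coef(fit), c("r", "K"))
  expect_length(fitted(fit), length(target))
  expect_equal(sum(residuals(fit)^2), fit$levels[[3]]$best$error)
  s <- summary(fit)
  expect_s3_class(s, "summary.multisweep")
  expect_equal(nrow(s$table), 3)
  expect_output(print(fit), "estimate")
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.size(f) > 0)
})

test_that("sweep configurations are validated and round-trip through YAML", {
  expect_error(sweep_config(c("p", "p"), c(1, 2), 3, 0.5, 2), "distinct")
  expect_error(sweep_config(c("p", "q"), c(1, 2), 0, 0.5, 2), ">= 1")
  expect_error(sweep_config(c("p", "q"), c(1, 2), 3, 1.5, 2), "\\(0, 1\\]")
  expect_error(sweep_config(c("p", "q"), c(1, 2), 3, 0.5, 2, shrink_factor = 1),
               "\\(0, 1\\)")

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "param_names: [r, K]",
    "initial_point: [0.15, 1000.0]",
    "points_per_direction: 8",
    "percent_per_direction: 0.5",
    "n_levels: 7",
    "error_metric: sse",
    "target:",
    "  file: target.csv",
    "model:",
    "  fixture: logistic"), f)
  sc <- read_sweep_config(f)
  expect_s3_class(sc$config, "sweep_config")
  expect_equal(sc$config$param_names, c("r", "K"))
  expect_equal(sc$config$initial_point, c(0.15, 1000))
  expect_equal(sc$config$shrink_factor, 0.5)  # default applied
  expect_equal(basename(sc$target_file), "target.csv")
  expect_equal(sc$model$fixture, "logistic")
})
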
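test_that("prey energy follows the linear decay schedule", {
  expect_equal(prey_energy(0.5, 0, 100), 1.0)
  expect_equal(prey_energy(0.73, 100, 100), 0.0)
  expect_equal(prey_energy(-0.2, 50, 50), 0.0)
  expect_equal(prey_energy(-1, 25, 100), -1.5)
  expect_error(prey_energy(0.5, 101, 100), class = "hawkfs_error_bad_iteration")
})

test_that("exploration moves evaluate exactly as the update formulas state", {
  # q >= 0.5 branch: m_rand - r1 * |m_rand - 2 * r2 * m_i|
  expect_equal(
    hho_exploration(m_i = 0.4, m_rand = 0.5, m_rab = 0.9, m_avg = 0.3,
                    lower = 0, upper = 1, q = 0.9, r1 = 0.5, r2 = 0.5),
    0.5 - 0.5 * abs(0.5 - 2 * 0.5 * 0.4))
  # q < 0.5 degenerate branch: m_rab = m_avg and r1 = 0 gives 0, clipped to lower
  expect_equal(
    hho_exploration(m_i = 0.4, m_rand = 0.5, m_rab = 0.3, m_avg = 0.3,
                    lower = 0.1, upper = 1, q = 0.2, r1 = 0, r2 = 0.7),
    0.1)
  # vector positions stay within bounds
  out <- hho_exploration(runif(4), runif(4), runif(4), runif(4),
                         lower = 0, upper = 1, q = 0.3, r1 = 2, r2 = 2)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("besiege moves collapse onto the prey at zero energy and match the formula", {
  expect_equal(hho_besiege(m_i = 0.37, m_rab = 0.81, E = 0, r_e = 0.6,
                           lower = 0, upper = 1), 0.81)
  # soft besiege: (m_rab - m_i) - E * |2 * (1 - r_e) * m_rab - m_i|
  expect_equal(
    hho_besiege(m_i = 0.6, m_rab = 0.8, E = 0.6, r_e = 0.75,
                lower = -1, upper = 1),
    (0.8 - 0.6) - 0.6 * abs(2 * (1 - 0.75) * 0.8 - 0.6))
  expect_equal(
    hho_besiege(0.6, 0.8, 0.6, 0.75, lower = -1, upper = 1), 0.08)
  # clipping contract
  expect_equal(hho_besiege(m_i = 0.9, m_rab = 0.1, E = 0.99, r_e = 0.9,
                           lower = 0, upper = 1), 0)
})

test_that("rapid dives accept greedily and short-circuit the Levy candidate", {
  evals <- 0L
  sphere <- function(x) { evals <<- evals + 1L; sum(x^2) }
  # A improves: exactly one evaluation, no Levy draw
  dv <- hho_dive_step(m_i = 0.9, f_i = 0.81, base = 0.9, m_rab = 0.05,
                      E = 0.1, r_e = 0.3, objective = sphere,
                      lower = 0, upper = 1)
  expect_equal(dv$n_evals, 1L)
  expect_equal(evals, 1L)
  expect_equal(dv$position,
               hho_dive_candidate(0.9, 0.05, 0.1, 0.3, 0, 1))
  expect_lt(dv$fitness, 0.81)

  # neither candidate improves: position and fitness unchanged
  set.seed(1)
  worse <- function(x) 100
  dv2 <- hho_dive_step(m_i = 0.2, f_i = 0.04, base = 0.2, m_rab = 0.9,
                       E = 0.9, r_e = 0.2, objective = worse,
                       lower = 0, upper = 1)
  expect_equal(dv2$position, 0.2)
  expect_equal(dv2$fitness, 0.04)
  expect_equal(dv2$n_evals, 2L)

  # zero Levy scale makes B coincide with A
  set.seed(2)
  A <- hho_dive_candidate(0.2, 0.9, 0.9, 0.2, 0, 1)
  seen <- c()
  spy <- function(x) { seen <<- c(seen, x); 100 }
  hho_dive_step(0.2, -1, 0.2, 0.9, 0.9, 0.2, spy, 0, 1, levy_scale = 0)
  expect_equal(seen, c(A, A))
})

test_that("Levy flights are reproducible, correctly scaled and heavy-tailed", {
  set.seed(10); a <- levy_flight(5)
  set.seed(10); b <- levy_flight(5)
  expect_identical(a, b)

  set.seed(11)
  x <- abs(levy_flight(1e6, beta = 1.5))
  expect_gt(stats::median(x), 0.001)   # scale factor 0.01
  expect_lt(stats::median(x), 0.1)
  xs <- sort(x, decreasing = TRUE)
  k <- 1000
  hill <- 1 / mean(log(xs[1:k] / xs[k + 1]))  # Hill tail-index estimator
  expect_lt(abs(hill - 1.5), 0.2)
})

test_that("elite update moves match their closed forms", {
  # alpha: median gate draw always passes before the horizon
  expect_equal(ihho_alpha_move(0.44, t = 3, s = 10, gate_rand = 0.5,
                               step_rand = 0.9, m_m = 0.1, m_n = 0.9,
                               lower = 0, upper = 1), 0.44)
  # at the horizon the step factor vanishes, so both branches return the prey
  expect_equal(ihho_alpha_move(0.44, t = 10, s = 10, gate_rand = 0.5,
                               step_rand = 0.9, m_m = 0.1, m_n = 0.9,
                               lower = 0, upper = 1), 0.44)
  # failed gate: prey plus shrinking difference step
  expect_equal(ihho_alpha_move(0.5, t = 0, s = 10, gate_rand = 0.9,
                               step_rand = 0.5, m_m = 0.8, m_n = 0.6,
                               lower = 0, upper = 1),
               0.5 + 4 * 0.5 * (0.8 - 0.6))

  expect_equal(ihho_beta_move(0.2, 0.6, rand = 0.7, 0, 1), 0.6)   # keep
  expect_equal(ihho_beta_move(0.55, 0.55, rand = 0.1, 0, 1), 0.55) # fixed point
  expect_equal(ihho_beta_move(0.2, 0.6, rand = 0.3, 0, 1), 0.4)   # midpoint

  expect_equal(ihho_gamma_move(0.7, 0.7, 0.7, 0.7, 0.7, rand = 0.9, 0, 1), 0.7)
  expect_equal(ihho_gamma_move(0.3, 0.6, 0.9, 0.1, 0.5, rand = 0.2, 0, 1), 0.6)
  expect_equal(ihho_gamma_move(0.3, 0.6, 0.9, 0.1, 0.5, rand = 0.8, 0, 1), 0.3)
})

test_that("the optimizer loop is deterministic, monotone, bounded and elite-frugal", {
  sphere <- function(x) sum(x^2)
  cfg <- hho_config(dim = 4, n_hawks = 8, max_iters = 30,
                    lower = -2, upper = 2, variant = "ihho", seed = 13)
  r1 <- hho_optimize(sphere, cfg)
  r2 <- hho_optimize(sphere, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_position, r2$best_position)
  expect_false(is.unsorted(-r1$trace))
  expect_length(r1$trace, 30L)
  expect_true(all(r1$elite_evals <= 3L))

  # every position handed to the objective respects the box
  visited <- new.env(); visited$ok <- TRUE
  watcher <- function(x) {
    if (any(x < -2 - 1e-12) || any(x > 2 + 1e-12)) visited$ok <- FALSE
    sum(x^2)
  }
  invisible(hho_optimize(watcher, cfg))
  expect_true(visited$ok)

  # single iteration: trace of length one holding the best seen so far
  one <- hho_optimize(sphere, hho_config(dim = 2, n_hawks = 5, max_iters = 1,
                                         lower = -1, upper = 1, seed = 2))
  expect_length(one$trace, 1L)
  expect_equal(one$trace[1], one$best_fitness)

  # both variants solve small smooth problems
  hho <- hho_optimize(sphere, hho_config(dim = 4, n_hawks = 15, max_iters = 100,
                                         lower = -10, upper = 10,
                                         variant = "hho", seed = 3))
  expect_lt(hho$best_fitness, 1e-3)

  expect_error(hho_config(dim = 3, n_hawks = 3), class = "hawkfs_error_bad_config")
  expect_error(hho_config(dim = 3, n_hawks = 4, variant = "ihho"),
               class = "hawkfs_error_bad_config")
  expect_error(hho_config(dim = 3, lower = 1, upper = 0),
               class = "hawkfs_error_bad_config")
})
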
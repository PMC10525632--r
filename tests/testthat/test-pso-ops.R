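test_that("velocity update follows the linear rule and clamps elementwise", {
  v <- c(1, -2)
  x <- c(0, 0)
  p <- c(1, 1)
  g <- c(2, 2)
  vl <- c(-10, -10)
  vu <- c(10, 10)
  # zero coefficients freeze the particle
  expect_equal(update_velocity(v, x, p, g, 0, 0, 0, vl, vu), c(0, 0))
  # x = p = g leaves only the inertia term
  expect_equal(update_velocity(v, p, p, p, 0.5, 1.5, 1.7, vl, vu), 0.5 * v)
  # unclamped rule
  expect_equal(update_velocity(v, x, p, g, 0.5, 1, 2, vl, vu),
               0.5 * v + 1 * (p - x) + 2 * (g - x))
  # components beyond the bound land exactly on the bound
  out <- update_velocity(c(5, -5), x, p, g, 2, 2, 2, c(-3, -3), c(3, 3))
  expect_equal(out, c(3, -3))
  expect_error(update_velocity(1:3, x, p, g, 1, 1, 1, vl, vu), "dimension")
})

test_that("dynamic bounds narrow around the personal best", {
  st <- update_dynamic_bounds(p = 10, x = 8, alpha = 0.1, beta = 0.05,
                              lower = -100, upper = 100)
  expect_equal(st$lower, 9.8)
  expect_equal(st$upper, 10.2)
  st2 <- update_dynamic_bounds(p = 5, x = 5, alpha = 0.1, beta = 0.05,
                               lower = -100, upper = 100)
  expect_equal(st2$lower, 4.75)
  expect_equal(st2$upper, 5.25)
  # mixed elementwise branches
  st3 <- update_dynamic_bounds(p = c(10, 5), x = c(8, 5), alpha = 0.1,
                               beta = 0.05, lower = rep(-100, 2),
                               upper = rep(100, 2))
  expect_equal(st3$lower, c(9.8, 4.75))
  expect_equal(st3$upper, c(10.2, 5.25))
  expect_error(update_dynamic_bounds(1, 1, alpha = 0, beta = 0.05, -1, 1))
  expect_error(update_dynamic_bounds(1, 1, alpha = 0.1, beta = -1, -1, 1))
})

test_that("degenerate zero box is widened by the floor and recorded", {
  st <- update_dynamic_bounds(p = 0, x = 0, alpha = 0.1, beta = 0.05,
                              lower = -100, upper = 100)
  expect_true(st$floored)
  expect_true(st$upper > st$lower)
  expect_equal(st$upper - st$lower, 2 * 1e-6 * 200)
})

test_that("dynamic bounds never widen past the static box", {
  st <- update_dynamic_bounds(p = 99, x = 0, alpha = 2, beta = 0.05,
                              lower = -100, upper = 100)
  expect_equal(st$upper, 100)
  expect_gte(st$lower, -100)
})

test_that("metropolis rule always accepts non-worse states", {
  expect_true(metropolis_accept(5, 3, 0.001))
  expect_true(metropolis_accept(3, 3, 0.001))
  expect_error(metropolis_accept(1, 2, temp = 0))
  # at enormous temperature worse states are accepted almost surely
  set.seed(1)
  acc <- replicate(500, metropolis_accept(0, 2, temp = 1e9))
  expect_gte(mean(acc), 0.99)
  # fixed threshold makes the test deterministic
  expect_true(metropolis_accept(0, 2, temp = 2, eps = 0.3))   # e^-1 > 0.3
  expect_false(metropolis_accept(0, 2, temp = 2, eps = 0.4))  # e^-1 < 0.4
})

test_that("empirical acceptance rate matches exp((f_i - f_j)/T)", {
  set.seed(99)
  n <- 1e5
  acc <- logical(n)
  for (i in seq_len(n)) acc[i] <- metropolis_accept(0, 2, temp = 2)
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(acc) - p), 3 * se)
})

test_that("multi-weight proposal picks the exhaustive-argmax candidate", {
  prob <- quad_problem(c(0, 0))
  cfg <- swarm_config(m = 1, n_iter = 10, accel = list(c1 = 0.9, c2 = 1.1),
                      schedules = c("L", "E", "P"))
  particle <- list(x = c(3, 3), v = c(0.5, -0.2), p = c(2.5, 2.5),
                   lower = prob$lower, upper = prob$upper)
  g <- c(1, 1)
  out <- propose_and_select_position(particle, g, prob, cfg, n = 4)
  # oracle: recompute every candidate independently and take the best
  cand <- sapply(c("L", "E", "P"), function(s) {
    w <- compute_inertia_weight(s, 4, 10, cfg$wmin, cfg$wmax)
    v <- update_velocity(particle$v, particle$x, particle$p, g, w, 0.9, 1.1,
                         prob$vlower, prob$vupper)
    eval_objective(prob, particle$x + v)
  })
  expect_equal(out$f, max(cand))
  expect_equal(out$schedule, names(cand)[which.max(cand)])
})

test_that("degenerate proposal keeps the position and breaks ties in declared order", {
  prob <- quad_problem(c(0, 0))
  cfg <- swarm_config(m = 1, n_iter = 10, accel = list(c1 = 0, c2 = 0))
  particle <- list(x = c(1, 1), v = c(0, 0), p = c(1, 1),
                   lower = prob$lower, upper = prob$upper)
  out <- propose_and_select_position(particle, c(1, 1), prob, cfg, n = 3)
  expect_equal(out$x, c(1, 1))
  expect_equal(out$schedule, "L")  # first of the declared order L, E, P, R
})

test_that("singleton schedule reproduces a plain single-weight step", {
  prob <- quad_problem(c(0, 0))
  cfg <- swarm_config(m = 1, n_iter = 10, accel = list(c1 = 1.2, c2 = 0.8),
                      schedules = "E")
  particle <- list(x = c(2, -2), v = c(0.1, 0.1), p = c(1.5, -1.5),
                   lower = prob$lower, upper = prob$upper)
  g <- c(0.5, -0.5)
  out <- propose_and_select_position(particle, g, prob, cfg, n = 2)
  w <- compute_inertia_weight("E", 2, 10, cfg$wmin, cfg$wmax)
  v <- update_velocity(particle$v, particle$x, particle$p, g, w, 1.2, 0.8,
                       prob$vlower, prob$vupper)
  expect_equal(out$v, v)
  expect_equal(out$x, particle$x + v)
})
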
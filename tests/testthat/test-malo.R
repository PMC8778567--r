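test_that("stochastic step fires strictly above one half", {
  expect_identical(stochastic_step(0.7), 1L)
  expect_identical(stochastic_step(0.5), 0L)
  expect_identical(stochastic_step(0.0), 0L)
  expect_identical(stochastic_step(c(0.51, 0.49)), c(1L, 0L))
  expect_error(stochastic_step(1.2), "\\[0, 1\\]")
  expect_error(stochastic_step(-0.1), "\\[0, 1\\]")
})

test_that("random walk cumulates unit steps from zero", {
  expect_equal(random_walk(4, rdm = rep(0.9, 4)), c(0, 1, 2, 3, 4))
  expect_equal(random_walk(3, rdm = rep(0.2, 3)), c(0, -1, -2, -3))
  expect_error(random_walk(0), ">= 1")
  set.seed(11)
  w <- random_walk(50)
  expect_equal(w[1], 0)
  expect_true(all(diff(w) %in% c(-1, 1)))
})

test_that("walk endpoints match the +/-1 random-walk moments", {
  # 10,000 walks of 16 steps: endpoint mean ~ 0, variance ~ n
  n <- 16
  set.seed(42)
  steps <- matrix(2L * (stats::runif(10000 * n) > 0.5) - 1L, nrow = n)
  ends <- colSums(steps)
  expect_lt(abs(mean(ends)), 3 * sqrt(n) / 100)
  expect_lt(abs(stats::var(ends) - n) / n, 0.1)
  # the same law holds for the exported walk
  set.seed(42)
  ends2 <- replicate(2000, random_walk(n)[n + 1])
  expect_lt(abs(mean(ends2)), 3 * sqrt(n) / sqrt(2000))
})

test_that("trap bounds follow the omega schedule and shrink ratio", {
  cases <- list(
    list(k = 5, K = 100, omega = 1L, J = 1),
    list(k = 20, K = 100, omega = 2L, J = 100 * 0.2),
    list(k = 60, K = 100, omega = 3L, J = 1000 * 0.6),
    list(k = 76, K = 100, omega = 4L, J = 10^4 * 0.76),
    list(k = 95, K = 100, omega = 5L, J = 10^5 * 0.95),
    list(k = 96, K = 100, omega = 6L, J = 10^6 * 0.96)
  )
  for (cs in cases) {
    b <- shrink_bounds(cs$k, cs$K, -1, 1)
    expect_identical(b$omega, cs$omega)
    expect_equal(b$J, cs$J)
    expect_equal(b$r, -1 / cs$J)
    expect_equal(b$t, 1 / cs$J)
  }
  # pre-shrink regime leaves the bounds untouched
  b <- shrink_bounds(5, 100, -2, 3)
  expect_equal(c(b$r, b$t), c(-2, 3))
  expect_error(shrink_bounds(0, 100, -1, 1), "1..K")
  expect_error(shrink_bounds(101, 100, -1, 1), "1..K")
})

test_that("shrink ratio J is non-decreasing in the iteration", {
  J <- vapply(1:200, function(k) shrink_bounds(k, 200, -1, 1)$J, numeric(1))
  expect_true(all(diff(J) >= 0))
})

test_that("walk normalization maps the walk range onto the bounds", {
  expect_equal(normalize_walk(c(0, 1, 2), r = 0, t = 1), c(0, 0.5, 1))
  expect_equal(normalize_walk(c(-3, -1, 1), r = -1, t = 1), c(-1, 0, 1))
  # degenerate bounds collapse everything to the common value
  expect_equal(normalize_walk(c(-5, 2, 7), r = 3, t = 3), c(3, 3, 3))
  # constant walk lands on the bound midpoint
  expect_equal(normalize_walk(c(2, 2, 2), r = -1, t = 1), c(0, 0, 0))
  out <- normalize_walk(random_walk(30, rdm = stats::runif(30)), -0.5, 0.25)
  expect_true(all(out >= -0.5 - 1e-12 & out <= 0.25 + 1e-12))
})

test_that("Levy step honours alpha and keeps heavy tails", {
  x <- c(-1.5, 0, 2)
  expect_identical(levy_step(x, alpha = 0), x)
  expect_error(levy_step(c(1, Inf)), "finite")
  set.seed(7)
  draws <- levy_step(rep(0, 1e5), alpha = 1, lambda = 1.5)
  expect_true(all(is.finite(draws)))
  # empirical tail P(|L| > x) ~ x^(-lambda) over a decade
  xs <- seq(10, 100, length.out = 12)
  surv <- vapply(xs, function(q) mean(abs(draws) > q), numeric(1))
  slope <- stats::coef(stats::lm(log(surv) ~ log(xs)))[2]
  expect_lt(abs(slope - (-1.5)), 0.3)
})

test_that("tanh binarization has the stated acceptance probability", {
  expect_identical(binarize(c(0, 0, 0)), c(0L, 0L, 0L))
  set.seed(1)
  expect_identical(binarize(rep(50, 100)), rep(1L, 100))
  set.seed(2)
  frac <- mean(binarize(rep(1, 1e5)))
  expect_lt(abs(frac - abs(tanh(1))), 0.01)
})

test_that("roulette selection prefers low fitness but stays stochastic", {
  expect_identical(roulette_select(3.2), 1L)
  expect_error(roulette_select(numeric(0)), "nonempty")
  expect_error(roulette_select(c(1, NaN)), "finite")
  set.seed(3)
  eq <- table(replicate(20000, roulette_select(c(5, 5, 5))))
  # uniform within 3 sigma of Binomial(n, 1/3)
  expect_true(all(abs(eq - 20000 / 3) < 3 * sqrt(20000 * (1 / 3) * (2 / 3))))
  set.seed(4)
  pick <- replicate(20000, roulette_select(c(0, 1)))
  expect_gt(sum(pick == 1), sum(pick == 2))
  # max-shift weights are proportional: fitnesses (0, 1, 2) give 2:1
  # odds between the two viable candidates
  set.seed(5)
  pick2 <- replicate(30000, roulette_select(c(0, 1, 2)))
  expect_lt(abs(mean(pick2 == 1) - 2 / 3), 3 * sqrt(2 / 9 / 30000))
  expect_lt(abs(mean(pick2 == 2) - 1 / 3), 3 * sqrt(2 / 9 / 30000))
})

test_that("uniform crossover stays within the parental alleles", {
  a <- c(1L, 0L, 1L, 0L)
  expect_identical(crossover(a, a, 0.5, rdm = stats::runif(4)), a)
  expect_error(crossover(a, c(1L, 0L)), "equal length")
  set.seed(5)
  kids <- replicate(1e4, sum(crossover(rep(0L, 4), rep(1L, 4), 0.5)))
  expect_lt(abs(mean(kids) - 2), 0.15)
  set.seed(6)
  for (i in 1:50) {
    p1 <- as.integer(stats::runif(6) > 0.5)
    p2 <- as.integer(stats::runif(6) > 0.5)
    child <- crossover(p1, p2)
    expect_true(all(child == p1 | child == p2))
  }
})

test_that("the optimizer finds a hidden-target mask and stays binary", {
  target <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L)
  hits <- 0
  for (s in 0:9) {
    res <- run_malo(function(m) sum(m != target),
                    malo_config(8, n_ants = 20, max_iters = 100, seed = s))
    expect_true(all(res$best_mask %in% c(0L, 1L)))
    expect_false(is.unsorted(rev(res$elite_history)))
    expect_equal(res$best_fitness, res$elite_history[100])
    if (identical(res$best_mask, target)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("constant fitness yields a valid mask and a flat elite trace", {
  res <- run_malo(function(m) 7, malo_config(6, 5, 20, seed = 2))
  expect_true(all(res$best_mask %in% c(0L, 1L)))
  expect_equal(res$elite_history, rep(7, 20))
})

test_that("popcount minimization reaches the empty mask", {
  res <- run_malo(function(m) sum(m),
                  malo_config(10, n_ants = 20, max_iters = 200, seed = 0))
  expect_equal(res$best_fitness, 0)
  expect_equal(sum(res$best_mask), 0)
})

test_that("identical config and seed reproduce the run bit for bit", {
  fitfun <- function(m) sum(m * c(3, -1, 2, 0.5, -2)) # weighted linear
  cfg <- malo_config(5, n_ants = 8, max_iters = 30, seed = 123)
  r1 <- run_malo(fitfun, cfg)
  r2 <- run_malo(fitfun, cfg)
  expect_identical(r1, r2)
})

test_that("a non-finite fitness is reported with the offending mask", {
  expect_error(
    run_malo(function(m) if (sum(m) == 0) NaN else sum(m),
             malo_config(3, 4, 5, seed = 1)),
    "non-finite.*mask"
  )
})

test_that("malo result tidiers expose the trace and the summary", {
  res <- run_malo(function(m) sum(m), malo_config(4, 5, 12, seed = 9))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 12)
  expect_named(td, c("iteration", "elite_fitness"))
  gl <- glance(res)
  expect_equal(gl$best_fitness, res$best_fitness)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("config validation rejects out-of-domain parameters", {
  expect_error(malo_config(4, n_ants = 1), "n_ants")
  expect_error(malo_config(4, crossover_rate = 1.5), "crossover_rate")
  expect_error(malo_config(4, levy_exponent = 2.5), "levy_exponent")
  expect_error(malo_config(4, walk_lower = 1, walk_upper = -1), "bounds")
})
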
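# time-averaged phase accumulation, archaeological sampling, schedules

test_that("a phase population holds exactly N = eta * v tokens", {
  set.seed(2)
  pool <- sampling_pool(4, init = c("A", "A", "B"))
  spec <- phase_spec(n = 20, r = 1, v = 5)   # N = 20, eta = 4
  out <- accumulate_phase(pool, transmission_params(mu = 0.1, b = 0), spec)
  expect_equal(sum(out$population), 20L)
  expect_length(out$tokens, 20)

  # no innovation, single-type pool: the population is monotypic
  mono <- sampling_pool(4, init = rep("A", 3))
  out <- accumulate_phase(mono, transmission_params(mu = 0), spec)
  expect_identical(names(out$population), "A")
})

test_that("innovation tokens appear at the binomial rate", {
  set.seed(5)
  pool <- sampling_pool(10, init = c("A", "A"))
  spec <- phase_spec(n = 100, r = 1, eta = 100)  # v = 1 per event
  out <- accumulate_phase(pool, transmission_params(mu = 0.5), spec)
  # every innovation mints a distinct type, and the time-averaged
  # population keeps every produced token, so the number of distinct novel
  # types equals the number of innovation events ~ Binomial(100, 0.5)
  novel <- sum(grepl("^nov", names(out$population)))
  expect_lt(abs(novel - 50), 3 * sqrt(100 * 0.25))
})

test_that("phase sampling is a simple random sample without replacement", {
  pop <- c(A = 90L, B = 10L)
  expect_identical(sample_assemblage(pop, 100), pop)
  expect_identical(sum(sample_assemblage(pop, 0)), 0L)
  expect_error(sample_assemblage(pop, 101), "r >= 1")

  set.seed(8)
  draws <- replicate(1e4, sample_assemblage(pop, 50)[["B"]])
  expect_lt(abs(mean(draws) - 5), 3 * sqrt(2.273 / 1e4) * 10)
  hyper_var <- 50 * 0.1 * 0.9 * (100 - 50) / 99
  expect_lt(abs(stats::var(draws) - hyper_var) / hyper_var, 0.05)
})

test_that("largest-remainder schedules hit the sum constraint", {
  expect_identical(largest_remainder(rep(1, 4), 10), c(3L, 3L, 2L, 2L))
  expect_error(largest_remainder(rep(1, 10), 4), "infeasible")
  set.seed(3)
  for (i in 1:50) {
    k <- sample(2:20, 1)
    total <- k + sample(0:200, 1)
    v <- largest_remainder(stats::runif(k, 0.1, 4), total)
    expect_identical(sum(v), total)
    expect_true(all(v >= 1))
  }
})

test_that("production schedules track rho * H and conserve N", {
  # constant demography: constant v equal to N / eta
  s <- production_schedule(H = c(5, 5), rho = 2, n = c(100, 100), r = 1)
  expect_true(all(unlist(s$v) == 10))
  expect_identical(vapply(s$v, sum, integer(1)), s$N)

  # doubling houses doubles mean production per event
  s <- production_schedule(H = c(4, 8), rho = 1, n = c(100, 200), r = 1)
  m <- vapply(s$v, mean, numeric(1))
  expect_equal(m[2] / m[1], 2, tolerance = 0.1)

  # integerization never changes a phase total
  set.seed(4)
  for (i in 1:20) {
    P <- sample(2:6, 1)
    H <- stats::runif(P, 2, 20)
    n <- sample(50:400, P, replace = TRUE)
    r <- stats::runif(1, 1, 10)
    s <- production_schedule(H, stats::runif(1, 0.5, 3), n, r)
    expect_identical(vapply(s$v, sum, integer(1)), s$N)
    expect_identical(vapply(s$v, length, integer(1)), s$eta)
  }
})

test_that("phase specs validate their invariants", {
  sp <- phase_spec(n = 5, r = 2.5, v = 5)
  expect_identical(sp$N, 13L)        # round-half-up of 12.5
  expect_identical(sum(sp$v_sched), 13L)
  expect_error(phase_spec(n = 10, r = 0.5, v = 2), "r")
  expect_error(phase_spec(n = 10, r = 1, v_sched = c(3, 3)), "inconsistent")
})
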
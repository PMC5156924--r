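# priors, distances, rejection and posterior summaries

test_that("prior draws are uniform over the stated ranges", {
  ps <- prior_spec(mu = c(0.01, 0.01), b = c(0.2, 0.2))
  d <- draw_priors(ps, 5)
  expect_true(all(d$mu == 0.01) && all(d$b == 0.2))

  set.seed(10)
  d <- draw_priors(prior_spec(mu = c(0.2, 0.8)), 1e4)
  se <- (0.8 - 0.2) / sqrt(12) / sqrt(1e4)
  expect_lt(abs(mean(d$mu) - 0.5), 3 * se)
  expect_true(all(d$r >= 1))

  expect_error(prior_spec(mu = c(0.5, 0.1)), "range")
  expect_error(prior_spec(r = c(0.5, 2)), "r")
})

test_that("the memory window converts from years to events", {
  expect_identical(w_events_from_years(1, 200, 20), 10L)
  expect_identical(w_events_from_years(0.01, 200, 20), 1L)  # floor at 1
  expect_identical(w_events_from_years(2.5, 33, 20), 4L)
})

test_that("all three distances vanish on self-comparison", {
  m <- toy_counts()
  expect_identical(epsilon_fully_matched(m, m), 0)
  expect_identical(epsilon_first_phase_matched(m, m), 0)
  expect_identical(epsilon_rank_matched(m, m), 0)
})

test_that("fully matched distance handles disjoint type sets", {
  obs <- matrix(c(10, 0), 1, dimnames = list(NULL, c("A", "B")))
  sim <- matrix(c(0, 10), 1, dimnames = list(NULL, c("A", "B")))
  expect_equal(epsilon_fully_matched(obs, sim), sqrt(200))

  sim2 <- matrix(c(10, 3), 1, dimnames = list(NULL, c("A", "B")))
  expect_equal(epsilon_fully_matched(obs, sim2), 3)

  # a simulated type never observed enters as observed zero
  sim3 <- matrix(c(10, 0, 4), 1, dimnames = list(NULL, c("A", "B", "Z")))
  expect_equal(epsilon_fully_matched(obs, sim3), 4)
})

test_that("first-phase matching ignores later arrivals", {
  obs <- rbind(c(A = 10, B = 5, C = 0), c(A = 8, B = 6, C = 7))
  sim <- obs
  sim[, "C"] <- c(0, 99)          # C is absent from phase 1
  expect_identical(epsilon_first_phase_matched(obs, sim), 0)

  sim2 <- obs
  sim2[, "A"] <- obs[, "A"] + 3   # off by 3 in each of the two phases
  expect_equal(epsilon_first_phase_matched(obs, sim2), sqrt(18))
})

test_that("rank matching pairs by first-phase frequency and pads with zeros", {
  obs <- rbind(c(x = 60, y = 40), c(x = 60, y = 40))
  # consistent relabelling leaves the distance at zero
  sim <- obs[, c(2, 1)]
  colnames(sim) <- c("p", "q")
  expect_identical(epsilon_rank_matched(obs, sim), 0)

  obs1 <- matrix(c(60, 40), 1)
  sim1 <- matrix(c(70, 30), 1)
  expect_equal(epsilon_rank_matched(obs1, sim1), sqrt(0.02))

  # fewer simulated than observed types: missing ranks count as constant 0
  sim_mono <- matrix(c(100, 100), 2, 1)
  expect_equal(epsilon_rank_matched(obs, sim_mono), 0.8)
})

test_that("rejection retains exactly the smallest error levels", {
  set.seed(14)
  for (i in 1:20) {
    eps <- stats::runif(500)
    m <- sample(1:50, 1)
    keep <- transmitr:::retain_smallest(eps, m)
    expect_identical(sort(eps[keep]), sort(eps)[seq_len(m)])
  }
  # ties are broken by draw order
  expect_identical(transmitr:::retain_smallest(c(2, 1, 1, 3), 2), c(2L, 3L))
})

test_that("a full rejection fit retains the minimal-epsilon draw", {
  d <- generate_dataset(tiny_scenario(seed = 5))
  fit <- fit_transmission(d$counts, d$houses$H, "variable_population",
                          s = 100, alpha = 0.01, seed = 77,
                          fixed = list(rho = 1, r = 2), keep_eps = TRUE)
  expect_identical(nrow(fit$retained), 1L)
  expect_identical(fit$retained$eps, min(fit$eps_all))
  expect_identical(fit$n_retained, 1L)
})

test_that("the HPD interval is the shortest contiguous window", {
  expect_identical(hpdi(c(1, 2, 3, 4, 100), level = 0.8),
                   c(lower = 1, upper = 4))
  expect_identical(hpdi(rep(7, 10)), c(lower = 7, upper = 7))
  # ties resolved to the leftmost window
  expect_identical(hpdi(c(-2, -1, 0, 1, 2), level = 0.6),
                   c(lower = -2, upper = 0))
  expect_error(hpdi(1), "at least 2")

  # exhaustive window-search oracle
  brute <- function(x, level) {
    x <- sort(x); n <- length(x); m <- ceiling(level * n)
    best <- c(x[1], x[m]); width <- x[m] - x[1]
    for (i in seq_len(n - m + 1)) {
      if (x[i + m - 1] - x[i] < width) {
        width <- x[i + m - 1] - x[i]; best <- c(x[i], x[i + m - 1])
      }
    }
    best
  }
  set.seed(15)
  for (i in 1:50) {
    x <- stats::rnorm(sample(5:300, 1))^sample(1:3, 1)
    level <- stats::runif(1, 0.3, 0.99)
    expect_identical(unname(hpdi(x, level)), brute(x, level))
  }
})

test_that("fits are reproducible and parallel equals serial", {
  d <- generate_dataset(tiny_scenario(seed = 6))
  f1 <- fit_transmission(d$counts, d$houses$H, "variable_population",
                         s = 400, alpha = 0.01, seed = 123)
  f2 <- fit_transmission(d$counts, d$houses$H, "variable_population",
                         s = 400, alpha = 0.01, seed = 123)
  expect_identical(f1$retained, f2$retained)
  f4 <- fit_transmission(d$counts, d$houses$H, "variable_population",
                         s = 400, alpha = 0.01, seed = 123, cores = 2)
  expect_identical(f1$retained, f4$retained)
})

test_that("summary and coef report posterior medians with HPD intervals", {
  d <- generate_dataset(tiny_scenario(seed = 7))
  fit <- fit_transmission(d$counts, d$houses$H, "variable_population",
                          s = 300, alpha = 0.05, seed = 9)
  s <- summary(fit)
  expect_identical(s$table$parameter, c("mu", "b", "w_years", "rho", "r"))
  expect_true(all(s$table$lower <= s$table$median &
                  s$table$median <= s$table$upper))
  expect_identical(unname(coef(fit)["b"]),
                   stats::median(fit$retained$b))

  f3 <- fit_transmission(d$counts, d$houses$H, "variable_transmission",
                         s = 300, alpha = 0.05, seed = 9,
                         fixed = list(rho = 1, r = 2))
  expect_identical(sort(unique(f3$retained$phase)), 2:4)
  expect_identical(nrow(coef(f3)), 3L)
})
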
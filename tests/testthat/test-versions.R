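# the three generative regimes and the Dirichlet pool reconstruction

test_that("equilibrium drift without innovation loses diversity", {
  p <- transmission_params(mu = 0, b = 0, w_events = 10, v = 5)
  r <- run_equilibrium(p, n = c(40, 40), r = 1, burn_in = 2000, seed = 3)
  # no innovation: every surviving type is one of the v seed types
  expect_lte(ncol(r$samples), 5)
  expect_true(all(colnames(r$samples) %in% paste0("t", 1:5)))
})

test_that("pure innovation makes every produced item unique", {
  p <- transmission_params(mu = 1, b = 0, w_events = 5, v = 4)
  r <- run_equilibrium(p, n = 30, r = 1, burn_in = 50, seed = 4)
  expect_true(all(r$samples <= 1L))
  expect_identical(sum(r$samples), 30L)
})

test_that("per-phase richness increases with the innovation rate", {
  rich <- function(mu, seed) {
    p <- transmission_params(mu = mu, b = 0, w_events = 50, v = 10)
    r <- run_equilibrium(p, n = 100, r = 1, burn_in = 500, seed = seed)
    sum(r$samples[1, ] > 0)
  }
  k_lo <- vapply(1:200, function(s) rich(0.01, s), numeric(1))
  k_hi <- vapply(1:200, function(s) rich(0.05, 1000 + s), numeric(1))
  expect_gt(mean(k_hi), mean(k_lo))
})

test_that("sample totals always equal the requested n", {
  p <- transmission_params(mu = 0.02, b = 0.1, w_events = 8, v = 6)
  r <- run_equilibrium(p, n = c(30, 50, 70), r = 3.3, burn_in = 300,
                       seed = 9, retain_pop = TRUE)
  expect_identical(as.integer(rowSums(r$samples)), c(30L, 50L, 70L))
  expect_identical(as.integer(rowSums(r$populations)), r$N)
})

test_that("dirichlet pools respect the observed type constraint", {
  # monotypic observation: the pool is monotypic
  pool <- dirichlet_initial_pool(c(A = 12), w_events = 4, v1 = 3, seed = 1)
  expect_identical(unique(pool$loose), "A")
  expect_identical(pool_size(pool), 12L)

  # every observed type present in each of 100 generated pools
  set.seed(6)
  mean_A <- replicate(100, {
    pool <- dirichlet_initial_pool(c(A = 50, B = 50), 20, 5)
    cnt <- pool_counts(pool)
    expect_identical(sort(names(cnt)), c("A", "B"))
    cnt[["A"]]
  })
  expect_gt(mean(mean_A), 35)
  expect_lt(mean(mean_A), 65)

  # pool size equal to richness: the constraint forces one token per type
  pool <- dirichlet_initial_pool(c(A = 5, B = 1, C = 9), 3, 1, seed = 2)
  expect_identical(unname(pool_counts(pool)), c(1L, 1L, 1L))

  expect_error(dirichlet_initial_pool(c(A = 5, B = 1, C = 9), 1, 2),
               "infeasible")
})

test_that("without innovation no type outside the initial pool ever appears", {
  obs1 <- c(A = 30, B = 15, C = 5)
  p <- transmission_params(mu = 0, b = 0.2, w_events = 6)
  r <- run_variable_population(p, obs1, H = c(4, 6), rho = 1,
                               n = c(50, 60), r = 2, seed = 12)
  expect_true(all(colnames(r$samples) %in% names(obs1)))
})

test_that("the version chain reduces exactly under tied parameters", {
  obs1 <- c(A = 30, B = 15, C = 5)
  p <- transmission_params(mu = 0.02, b = 0.1, w_events = 6)
  H <- c(4, 6, 8); n <- c(50, 60, 70)
  v2 <- run_variable_population(p, obs1, H, 1, n, r = 2, seed = 99)
  v2_again <- run_variable_population(p, obs1, H, 1, n, r = 2, seed = 99)
  expect_identical(v2$samples, v2_again$samples)

  obs <- rbind(obs1, obs1, obs1)
  colnames(obs) <- names(obs1)
  v3 <- run_variable_population_transmission(p, obs, H, 1, n, r = 2,
                                             chain_pools = TRUE, seed = 99)
  expect_identical(unname(v3$samples), unname(v2$samples))

  # constant demography, divisible sizes: the variable population version
  # is the equilibrium version without burn-in, given the same pool
  pe <- transmission_params(mu = 0.02, b = 0.1, w_events = 6, v = 10)
  init <- list(0:9)
  ve <- run_equilibrium(pe, n = c(40, 40), r = 1, burn_in = 0, seed = 21,
                        initial_pool = init)
  vv <- run_variable_population(pe, c(A = 1), H = c(10, 10), rho = 1,
                                n = c(40, 40), r = 1, seed = 21,
                                initial_pool = list(events = init,
                                                    loose = integer(0),
                                                    next_id = 10L))
  expect_identical(unname(ve$samples), unname(vv$samples))
})

test_that("per-phase parameters act only within their phase", {
  obs <- rbind(c(A = 40, B = 20), c(A = 30, B = 30), c(A = 30, B = 30))
  H <- c(5, 5, 5); n <- c(60, 60, 60)
  p_innov <- list(NULL, transmission_params(mu = 1, b = 0, w_events = 4),
                  transmission_params(mu = 0, b = 0, w_events = 4))
  r <- run_variable_population_transmission(p_innov, obs, H, 2, n, r = 1,
                                            seed = 31)
  s2 <- r$samples["phase2", ]
  # a phase with mu = 1 contains only types absent from its predecessor
  expect_identical(sum(s2[c("A", "B")]), 0L)
  expect_identical(sum(s2), 60L)

  expect_error(
    run_variable_population_transmission(p_innov, obs, H, 2, n, r = 1,
                                         phases = 1:3, seed = 1),
    "predecessor")
})

test_that("anti-conformity preserves rare types relative to drift", {
  # paired runs: an anti-conformist phase keeps the rare type alive more
  # often than unbiased drift
  obs1 <- c(common = 90, rare = 10)
  surv <- function(b, seeds) {
    vapply(seeds, function(s) {
      p <- transmission_params(mu = 0, b = b, w_events = 5)
      r <- run_variable_population(p, obs1, H = c(10, 10), rho = 1,
                                   n = c(80, 80), r = 1, seed = s)
      sum(r$samples[2, colnames(r$samples) == "rare"]) > 0
    }, logical(1))
  }
  s_anti <- mean(surv(0.4, 1:120))
  s_drift <- mean(surv(0, 1:120))
  expect_gt(s_anti, s_drift)
})
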
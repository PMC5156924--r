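# the copying rule, production events and the sliding-window pool

test_that("unbiased copying reduces to relative frequencies", {
  cp <- copy_probabilities(c(A = 3, B = 1))
  expect_equal(cp$p, c(A = 0.75, B = 0.25))
  expect_identical(cp$innovation, 0)

  cp <- copy_probabilities(c(A = 3, B = 1), mu = 0.1)
  expect_equal(cp$p, c(A = 0.675, B = 0.225))
  expect_equal(cp$innovation, 0.1)
})

test_that("positive b boosts rare types, negative b common ones", {
  # direct evaluation of the biased-copying rule over the two types
  m <- c(3, 1) / 4
  w <- m^(1 - 0.5)
  expected_B <- w[2] / sum(w)
  cp <- copy_probabilities(c(A = 3, B = 1), b = 0.5)
  expect_gt(cp$p[["B"]], 0.25)
  expect_equal(cp$p[["B"]], expected_B, tolerance = 1e-12)

  cp_neg <- copy_probabilities(c(A = 3, B = 1), b = -0.5)
  expect_lt(cp_neg$p[["B"]], 0.25)
})

test_that("copy mass and innovation mass always sum to one", {
  set.seed(42)
  for (i in 1:1000) {
    counts <- random_pool_counts()
    b <- stats::runif(1, -3, 3)
    mu <- stats::runif(1)
    cp <- copy_probabilities(counts, b, mu)
    expect_lt(abs(sum(cp$p) + cp$innovation - 1), 1e-12)
    if (i <= 200) {
      cp0 <- copy_probabilities(counts, 0, mu)
      expect_lt(max(abs(cp0$p - (1 - mu) * counts / sum(counts))), 1e-12)
    }
  }
})

test_that("the rare-type boost is strictly increasing in b", {
  counts <- c(common = 9, rare = 1)
  m_rare <- 0.1
  ratio <- vapply(seq(-1, 1, by = 0.25), function(b)
    copy_probabilities(counts, b)$p[["rare"]] / m_rare, numeric(1))
  expect_true(all(diff(ratio) > 0))
})

test_that("degenerate pools are rejected with a helpful message", {
  expect_error(copy_probabilities(integer(0)), "seed the pool")
  expect_error(copy_probabilities(c(A = 0)), "seed the pool")
  expect_error(copy_probabilities(c(A = -1)), "non-negative")
  expect_error(copy_probabilities(c(A = 1), mu = 1.2), "mu")
})

test_that("production events mix copies and innovations as mu dictates", {
  pool <- sampling_pool(5, init = c("A", "A", "A", "B"))
  # pure innovation: all outputs are brand-new distinct ids
  set.seed(1)
  ev <- production_event(pool, transmission_params(mu = 1), 3)
  expect_length(unique(ev$variants), 3)
  expect_false(any(ev$variants %in% c("A", "B")))

  # no innovation, single-type pool: all copies of that type
  mono <- sampling_pool(5, init = rep("A", 4))
  ev <- production_event(mono, transmission_params(mu = 0), 5)
  expect_identical(ev$variants, rep("A", 5))
})

test_that("copy frequencies match the binomial expectation", {
  pool <- sampling_pool(5, init = c("A", "A", "A", "B"))
  set.seed(7)
  ev <- production_event(pool, transmission_params(mu = 0, b = 0), 1e5)
  frac_A <- mean(ev$variants == "A")
  expect_lt(abs(frac_A - 0.75), 3 * sqrt(0.75 * 0.25 / 1e5))
})

test_that("the pool window keeps exactly the last w events", {
  pool <- sampling_pool(2)
  pool <- advance_pool(pool, "A", 1)
  pool <- advance_pool(pool, "B", 2)
  pool <- advance_pool(pool, "C", 3)
  expect_equal(sort(names(pool_counts(pool))), c("B", "C"))

  # warm-up: the pool grows until w events have happened
  pool <- sampling_pool(3)
  pool <- advance_pool(pool, c("A", "B"), 1)
  pool <- advance_pool(pool, c("C", "D"), 2)
  expect_equal(pool_size(pool), 4)

  expect_error(advance_pool(pool, "E", 2), "strictly increasing")
})

test_that("pool size equals the sum of the last w event sizes", {
  set.seed(3)
  pool <- sampling_pool(5)
  sizes <- integer(0)
  for (t in 1:100) {
    v <- sample(1:4, 1)
    sizes <- c(sizes, v)
    pool <- advance_pool(pool, paste0("e", t, "_", seq_len(v)), t)
    if (t >= 5) expect_equal(pool_size(pool), sum(utils::tail(sizes, 5)))
  }
})

test_that("identical seeds give identical event sequences", {
  run_once <- function(seed) {
    set.seed(seed)
    pool <- sampling_pool(4, init = c("A", "A", "B"))
    out <- character(0)
    params <- transmission_params(mu = 0.3, b = 0.2)
    for (t in 1:20) {
      ev <- production_event(pool, params, 3)
      pool <- advance_pool(ev$pool, ev$variants, t)
      out <- c(out, ev$variants)
    }
    out
  }
  expect_identical(run_once(11), run_once(11))
  expect_false(identical(run_once(11), run_once(12)))
})
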
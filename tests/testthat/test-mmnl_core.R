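# Conditional logit kernel, simulated mixed likelihood, Choleski quadrants.

test_that("logit probabilities are a shift-invariant softmax", {
  expect_equal(logit_choice_prob(c(0, 0, 0, 0)), rep(0.25, 4))
  expect_equal(logit_choice_prob(c(log(2), 0)), c(2 / 3, 1 / 3))
  u <- c(0.3, -1.2, 2.0)
  expect_equal(logit_choice_prob(u), logit_choice_prob(u + 57),
               tolerance = 1e-12)
  expect_equal(sum(logit_choice_prob(c(700, -700, 0))), 1)  # no overflow
  expect_error(logit_choice_prob(c(0, Inf)), "finite")
})

test_that("panel log-probability multiplies situation probabilities in log space", {
  toy <- toy_panel()
  expect_equal(panel_logprob_given_beta(toy, 1, c(B = 0)), log(0.5))
  # 20 situations, all four alternatives at equal utility
  sim <- simulate_panel(sim_spec(n_individuals = 1, n_situations = 20,
                                 n_alternatives = 4, seed = 1))
  expect_equal(panel_logprob_given_beta(sim$panel, 1, c(B = 0, C = 0, D = 0)),
               20 * log(0.25))
  # random cases against a plain exp-and-multiply oracle
  set.seed(42)
  for (case in 1:50) {
    sim <- simulate_panel(sim_spec(n_individuals = 2, n_situations = 3,
                                   n_alternatives = 3,
                                   seed = 100 + case))
    beta <- c(B = rnorm(1), C = rnorm(1))
    prod_oracle <- 1
    d <- sim$panel$data
    for (t in 1:3) {
      rows <- d$individual == 1 & d$situation == t
      u <- ifelse(d$alternative[rows] == "B", beta["B"],
                  ifelse(d$alternative[rows] == "C", beta["C"], 0))
      p <- exp(u) / sum(exp(u))
      prod_oracle <- prod_oracle * p[d$chosen[rows] == 1]
    }
    expect_equal(panel_logprob_given_beta(sim$panel, 1, beta),
                 log(prod_oracle), tolerance = 1e-10)
  }
})

test_that("draw transformation is mean plus triangular factor times draw", {
  p <- mixing_params(c(B = 0.7, C = -0.2), rbind(c(1, 0), c(0.5, 2)))
  expect_equal(transform_draws(c(0, 0), p), c(B = 0.7, C = -0.2))
  expect_equal(transform_draws(c(1, 1), p), c(B = 0.7, C = -0.2) + c(1, 2.5))
  p1 <- mixing_params(c(B = 0), matrix(1.7))
  expect_equal(transform_draws(0.3, p1), c(B = 1.7 * 0.3))
})

test_that("column sign flips preserve the covariance exactly", {
  Q <- rbind(c(1, 0), c(0.5, 2))
  expect_equal(flip_factor(Q, c(-1, 1)), rbind(c(-1, 0), c(-0.5, 2)))
  expect_equal(flip_factor(diag(c(1, 2, 3)), c(-1, 1, -1)),
               diag(c(-1, 2, -3)))
  expect_equal(flip_factor(Q, c(1, 1)), Q)
  S <- quadrant_signs(3)
  Q3 <- rbind(c(1.2, 0, 0), c(-0.3, 0.8, 0), c(0.1, 0.4, 2.1))
  for (q in seq_len(nrow(S))) {
    Qf <- flip_factor(Q3, S[q, ])
    expect_identical(Qf %*% t(Qf), Q3 %*% t(Q3))  # bit-level equality
  }
})

test_that("degenerate mixing reduces to the conventional logit likelihood", {
  sim <- small_sim()
  pr <- true_params(sim)
  pr0 <- mixing_params(pr$means, matrix(0, 3, 3))
  draws <- build_draws(std_cfg(I = 30, R = 8))
  ll <- simulated_loglik(sim$panel, pr0, draws)
  conv <- sum(vapply(sim$panel$individuals, function(i)
    panel_logprob_given_beta(sim$panel, i, pr$means), numeric(1)))
  expect_equal(ll, conv, tolerance = 1e-10)
  # and the zero-dimension path gives the same number without draws
  pr_none <- mixing_params(numeric(0), matrix(0, 0, 0),
                           fixed_coeffs = pr$means)
  expect_equal(simulated_loglik(sim$panel, pr_none, NULL), conv,
               tolerance = 1e-10)
})

test_that("attribute (general) path agrees with the count-based fast path", {
  sim <- small_sim()
  pr <- true_params(sim)
  draws <- build_draws(std_cfg(I = 30, R = 16))
  ll_fast <- simulated_loglik(sim$panel, pr, draws)
  d2 <- sim$panel$data
  set.seed(9)
  d2$price <- round(runif(nrow(d2)), 2)
  p2 <- choice_panel(d2, base_alternative = "A")
  pr2 <- pr; pr2$fixed_coeffs <- c(price = 0)
  expect_equal(simulated_loglik(p2, pr2, draws), ll_fast, tolerance = 1e-10)
  # with a nonzero attribute coefficient, agree with a per-draw oracle
  pr3 <- pr; pr3$fixed_coeffs <- c(price = -0.6)
  ll3 <- simulated_loglik(p2, pr3, draws)
  oracle <- 0
  for (i in p2$individuals) {
    ii <- match(i, p2$individuals)
    lp <- vapply(seq_len(16), function(r) {
      beta <- transform_draws(draws$points[ii, r, ], pr3)
      panel_logprob_given_beta(p2, i, c(beta, price = -0.6))
    }, numeric(1))
    m <- max(lp)
    oracle <- oracle + m + log(mean(exp(lp - m)))
  }
  expect_equal(ll3, oracle, tolerance = 1e-10)
})

test_that("chunked evaluation is independent of the chunk size", {
  sim <- small_sim()
  pr <- true_params(sim)
  draws <- build_draws(std_cfg(I = 30, R = 32))
  ll <- simulated_loglik(sim$panel, pr, draws)
  expect_equal(simulated_loglik(sim$panel, pr, draws, chunk = 5), ll,
               tolerance = 1e-12)
  expect_equal(simulated_loglik(sim$panel, pr, draws, chunk = 1), ll,
               tolerance = 1e-12)
})

test_that("simulated likelihood converges to the Gauss-Hermite integral", {
  skip_if_not_installed("pracma")
  toy <- toy_panel()
  pr <- mixing_params(c(B = 0.5), 1)
  gh <- pracma::gaussHermite(64)
  p_true <- sum(gh$w * stats::plogis(0.5 + sqrt(2) * gh$x)) / sqrt(pi)
  ll_at <- function(R) {
    cfg <- draw_config(primes = c(B = 2), draws_per_individual = R,
                       n_individuals = 1, antithetic = "none")
    simulated_loglik(toy, pr, build_draws(cfg))
  }
  err2 <- abs(ll_at(100) - log(p_true))
  err4 <- abs(ll_at(10000) - log(p_true))
  expect_lt(err4, err2)
})

test_that("quadrant scan is flat under full antithetics, spread under conventional", {
  sim <- small_sim()
  pr <- true_params(sim)
  scan_f <- quadrant_scan(sim$panel, pr, build_draws(std_cfg(I = 30, R = 32)))
  expect_length(scan_f$per_quadrant_ll, 8)
  expect_lt(scan_f$max_abs_difference, 1e-8)
  scan_n <- quadrant_scan(sim$panel, pr,
                          build_draws(std_cfg(I = 30, R = 32, mode = "none")))
  expect_gt(scan_n$max_abs_difference, 0.1)
  # canonical-quadrant precondition
  pr_neg <- pr
  pr_neg$chol <- flip_factor(pr$chol, c(-1, 1, 1))
  expect_error(quadrant_scan(sim$panel, pr_neg, NULL), "canonical")
})

test_that("antithetic invariance holds at arbitrary parameter points", {
  sim <- small_sim()
  draws <- build_draws(std_cfg(I = 30, R = 32))
  set.seed(11)
  for (case in 1:3) {
    Q <- diag(abs(rnorm(3, 1, 0.3)))
    Q[lower.tri(Q)] <- rnorm(3, 0, 0.2)   # correlated mixing too
    pr <- mixing_params(stats::setNames(rnorm(3, 0.5, 0.5), c("B", "C", "D")),
                        Q)
    base_ll <- simulated_loglik(sim$panel, pr, draws)
    S <- quadrant_signs(3)
    for (q in 2:8) {
      pq <- pr; pq$chol <- flip_factor(pr$chol, S[q, ])
      expect_equal(simulated_loglik(sim$panel, pq, draws), base_ll,
                   tolerance = 1e-8)
    }
  }
})

test_that("one-dim antithetics symmetrize only the global flip", {
  sim <- simulate_panel(sim_spec(n_individuals = 20, n_situations = 5,
                                 n_alternatives = 3, seed = 8))
  pr <- true_params(sim)
  draws <- build_draws(std_cfg(I = 20, R = 10, mode = "one_dim", n = 2))
  base_ll <- simulated_loglik(sim$panel, pr, draws)
  flip_ll <- function(s) {
    pq <- pr; pq$chol <- flip_factor(pr$chol, s)
    simulated_loglik(sim$panel, pq, draws)
  }
  expect_equal(flip_ll(c(-1, -1)), base_ll, tolerance = 1e-8)
  partial <- c(abs(flip_ll(c(-1, 1)) - base_ll),
               abs(flip_ll(c(1, -1)) - base_ll))
  expect_gt(max(partial), 1e-6)
})

test_that("a symmetric kernel removes quadrant differences even with conventional draws", {
  # diagonal factor and zero means: a column flip is then exactly a
  # coordinate sign flip of beta, which a coordinate-symmetric kernel ignores
  draws <- build_draws(std_cfg(I = 5, R = 16, mode = "none", n = 2))
  pr <- mixing_params(c(B = 0, C = 0), c(1, 0.8))
  sym_kernel <- function(beta) -sum(beta^2)
  base_ll <- simulated_kernel_loglik(draws, pr, sym_kernel)
  S <- quadrant_signs(2)
  for (q in 2:4) {
    pq <- pr; pq$chol <- flip_factor(pr$chol, S[q, ])
    expect_equal(simulated_kernel_loglik(draws, pq, sym_kernel), base_ll,
                 tolerance = 1e-10)
  }
  # asymmetric kernel (a logistic choice probability): differences reappear
  asym_kernel <- function(beta) stats::plogis(sum(beta), log.p = TRUE)
  base_a <- simulated_kernel_loglik(draws, pr, asym_kernel)
  pq <- pr; pq$chol <- flip_factor(pr$chol, c(-1, 1))
  expect_gt(abs(simulated_kernel_loglik(draws, pq, asym_kernel) - base_a),
            1e-6)
})

test_that("quadrant spread shrinks from R=100 to R=1000 with conventional draws", {
  sim <- small_sim(I = 40)
  pr <- true_params(sim)
  d100 <- quadrant_scan(sim$panel, pr,
                        build_draws(std_cfg(I = 40, R = 100, mode = "none")))
  d1000 <- quadrant_scan(sim$panel, pr,
                         build_draws(std_cfg(I = 40, R = 1000, mode = "none")))
  expect_lt(d1000$max_abs_difference, d100$max_abs_difference)
})

test_that("panels round-trip through long-format CSV", {
  sim <- small_sim(I = 5, T_ = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(sim$panel, path)
  p2 <- read_panel_csv(path, base_alternative = "A")
  expect_equal(p2$data$chosen, sim$panel$data$chosen)
  expect_equal(p2$alternatives, sim$panel$alternatives)
  pr <- true_params(sim)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  write_params_yaml(pr, ypath)
  pr2 <- read_params_yaml(ypath)
  expect_equal(pr2$means, pr$means, tolerance = 1e-9)
  expect_equal(pr2$chol, pr$chol, tolerance = 1e-9)
})

test_that("malformed panels are rejected", {
  d <- data.frame(individual = 1, situation = 1,
                  alternative = c("A", "B"), chosen = c(1, 1))
  expect_error(choice_panel(d), "exactly one chosen")
  d2 <- data.frame(individual = 1, situation = c(1, 1, 2),
                   alternative = c("A", "B", "A"), chosen = c(1, 0, 1))
  expect_error(choice_panel(d2), "alternative")
})
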
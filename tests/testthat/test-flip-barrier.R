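test_that("control normalization corrects acquisition decay exactly", {
  # mother identical to the control mean -> constant 100
  t <- (0:19) * 4
  ctrl <- list(data.frame(time_s = t, intensity = 900 * 0.99^(0:19) + 10),
               data.frame(time_s = t, intensity = 1100 * 0.99^(0:19) + 10))
  mom <- data.frame(time_s = t, intensity = 1000 * 0.99^(0:19) + 10)
  bud <- data.frame(time_s = t, intensity = 500 * 0.99^(0:19) + 10)
  nd <- normalize_traces(mom, bud, ctrl, background = 10)
  expect_equal(nd$mother$percent, rep(100, 20))
  expect_equal(nd$bud$percent, rep(100, 20))  # same decay rate, rescaled
  expect_identical(nd$mother$percent[1], 100)

  # background swallowing the whole trace aborts
  expect_error(normalize_traces(mom, bud, ctrl, background = 2000),
               "non-positive")
})

test_that("normalized synthetic decay with acquisition decay matches the a = 0 latent decay", {
  base <- list(n_cells = 1, bleach_fraction = 0.05, exchange_rate = 0.01,
               noise_sd = 0, background = 40, seed = 21)
  with_a <- do.call(flip_sim_config, c(base, list(acquisition_decay = 0.003)))
  no_a <- do.call(flip_sim_config, c(base, list(acquisition_decay = 0)))
  tr <- gen_flip_traces(with_a)
  sp <- split_traces(tr)
  nd <- normalize_traces(sp$mother, sp$bud, sp$controls, background = 40)
  lat0 <- attr(gen_flip_traces(no_a), "latent")
  expect_equal(nd$mother$percent,
               100 * lat0$latent[lat0$role == "mother"] / 1000,
               tolerance = 1e-8)
  expect_equal(nd$bud$percent,
               100 * lat0$latent[lat0$role == "bud"] / 1000,
               tolerance = 1e-8)
})

test_that("pooling is a frame-wise mean with CLT-level accuracy on noisy replicates", {
  t <- (0:29) * 4
  truth <- 30 + 70 * exp(-0.03 * t)
  one <- data.frame(time_s = t, percent = truth)
  expect_equal(pool_profiles(list(one)), one, ignore_attr = TRUE)

  p <- data.frame(time_s = t, percent = truth)
  q <- data.frame(time_s = t, percent = 200 - truth)
  expect_equal(pool_profiles(list(p, q))$percent, rep(100, 30))

  set.seed(31)
  noise_sd <- 4
  reps <- lapply(1:50, function(i)
    data.frame(time_s = t, percent = truth + rnorm(30, 0, noise_sd)))
  pooled <- pool_profiles(reps)
  expect_true(all(abs(pooled$percent - truth) < 3 * noise_sd / sqrt(50)))
  expect_identical(attr(pooled, "n"), 50L)
  expect_error(pool_profiles(list()), "no profiles")
})

test_that("constrained one-phase decay fit recovers exact curves", {
  fit <- fit_one_phase_decay(exact_decay(P = 20, K = 0.05))
  expect_true(fit$converged)
  expect_equal(fit$plateau, 20, tolerance = 1e-6)
  expect_equal(fit$K, 0.05, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)

  # pure exponential to zero
  fit0 <- fit_one_phase_decay(exact_decay(P = 0, K = 0.05))
  expect_equal(fit0$K, 0.05, tolerance = 1e-6)
  expect_equal(fit0$plateau, 0, tolerance = 1e-4)

  # flat trace: either K ~ 0 or plateau ~ 100, with ~zero residual
  flat <- fit_one_phase_decay(data.frame(time_s = (0:19) * 4,
                                         percent = rep(100, 20)))
  expect_true(flat$K < 1e-6 || flat$plateau > 99.9)
  expect_lt(flat$rss, 1e-8)
})

test_that("time to threshold follows the closed form, with censoring above it", {
  # P = 0, K = ln(4/3)/10 -> t75 exactly 10 s
  r <- time_to_fraction(fixed_fit(P = 0, K = log(4 / 3) / 10))
  expect_false(r$censored)
  expect_equal(r$t, 10, tolerance = 1e-12)
  # same curve quoted at a rounded rate
  expect_equal(time_to_fraction(fixed_fit(0, 0.02877))$t, 10.0, tolerance = 1e-3)

  # P = 50, K = 0.1 -> 10 ln 2
  expect_equal(time_to_fraction(fixed_fit(50, 0.1))$t, 10 * log(2),
               tolerance = 1e-12)

  # plateau at/above threshold never reaches it
  expect_true(time_to_fraction(fixed_fit(80, 0.1))$censored)
  expect_true(time_to_fraction(fixed_fit(75, 0.1))$censored)
  # K = 0 with P < threshold is censored too
  expect_true(time_to_fraction(fixed_fit(0, 0))$censored)
})

test_that("delta-method SE of t75 matches a numeric jacobian", {
  fit <- fixed_fit(P = 30, K = 0.02, se_P = 1.5, se_K = 0.002,
                   cov_PK = -1e-3 * 1.5 * 0.002)
  r <- time_to_fraction(fit)
  tfun <- function(P, K) (1 / K) * log((100 - P) / (75 - P))
  h <- 1e-6
  dP <- (tfun(30 + h, 0.02) - tfun(30 - h, 0.02)) / (2 * h)
  dK <- (tfun(30, 0.02 + h) - tfun(30, 0.02 - h)) / (2 * h)
  var_num <- dP^2 * 1.5^2 + dK^2 * 0.002^2 + 2 * dP * dK * fit$cov_PK
  expect_equal(r$se_t, sqrt(var_num), tolerance = 1e-6)
})

test_that("closed-form t75 agrees with numeric root finding to 1e-9 relative", {
  grid <- expand.grid(P = c(-20, 0, 25, 60, 74), K = c(0.001, 0.01, 0.1))
  for (i in seq_len(nrow(grid))) {
    P <- grid$P[i]; K <- grid$K[i]
    t_closed <- time_to_fraction(fixed_fit(P, K))$t
    t_root <- uniroot(function(t) P + (100 - P) * exp(-K * t) - 75,
                      c(0, 1e7), tol = 1e-13)$root
    expect_equal(t_closed, t_root, tolerance = 1e-9)
  }
})

test_that("Barrier Index arithmetic, censoring and error propagation", {
  f <- fixed_fit(P = 0, K = 0.02877, se_K = 1e-4)
  expect_equal(barrier_index(f, f)$value, 1)

  slow <- fixed_fit(P = 0, K = 0.0028768)
  fast <- fixed_fit(P = 0, K = 0.028768)
  bi <- barrier_index(fast, slow)
  expect_equal(bi$value, 10, tolerance = 1e-6)

  # relative errors add in quadrature
  fm <- fixed_fit(0, 0.02, se_K = 0.002)    # 10% on K -> 10% on t75
  fb <- fixed_fit(0, 0.002, se_K = 0.0001)  # 5%
  b2 <- barrier_index(fm, fb)
  expect_equal(b2$se / b2$value, sqrt(0.1^2 + 0.05^2), tolerance = 1e-10)

  # bud plateau above threshold: censored, not determined
  cen <- barrier_index(fast, fixed_fit(P = 80, K = 0.1))
  expect_true(cen$censored)
  expect_true(is.na(cen$value))
  expect_output(print(cen), "n.d.")

  # bleached mother must decay
  expect_error(barrier_index(fixed_fit(P = 80, K = 0.1), slow), "mother")
})

test_that("cross-run normalization rescales over the reference ratio", {
  mk <- function(v, se) structure(list(value = v, se = se, censored = FALSE,
                                       threshold = 75),
                                  class = "barrier_index")
  expect_equal(cross_run_normalize(mk(20, 0), mk(30, 0), mk(30, 0))$value, 20)
  out <- cross_run_normalize(mk(20, 2), mk(30, 3), mk(42, 4))
  expect_equal(out$value, 28, tolerance = 1e-12)
  expect_equal(out$se / out$value,
               sqrt((2 / 20)^2 + (3 / 30)^2 + (4 / 42)^2), tolerance = 1e-12)
  cen <- mk(20, 2); cen$censored <- TRUE
  expect_error(cross_run_normalize(cen, mk(30, 3), mk(42, 4)), "censored")
})

test_that("full FLIP pipeline is deterministic and censors when exchange is off", {
  cfg <- flip_sim_config(n_cells = 8, seed = 41)
  tr <- gen_flip_traces(cfg)
  b1 <- flip_barrier_index(tr, background = cfg$background)
  b2 <- flip_barrier_index(gen_flip_traces(cfg), background = cfg$background)
  expect_identical(b1$value, b2$value)
  expect_false(b1$censored)

  # no exchange: the bud never loses signal beyond noise -> censored BI
  tr0 <- gen_flip_traces(flip_sim_config(n_cells = 8, exchange_rate = 0,
                                         noise_sd = 1, seed = 42))
  b0 <- flip_barrier_index(tr0, background = 50)
  expect_true(b0$censored)
})

test_that("estimated Barrier Index decreases with the exchange rate", {
  xs <- c(0.002, 0.005, 0.01, 0.05, 0.1)
  bis <- vapply(xs, function(x) {
    tr <- gen_flip_traces(flip_sim_config(n_cells = 30, exchange_rate = x,
                                          seed = 11))
    flip_barrier_index(tr, background = 50)$value
  }, 0)
  expect_true(all(diff(bis) < 0))
})
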
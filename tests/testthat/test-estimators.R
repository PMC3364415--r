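test_that("richness-age rate is ln(n)/t with its published worked example", {
  est <- richness_age_rate(450, 0.015)
  expect_equal(est$lambda_hat, log(450) / 0.015)
  expect_identical(signif(est$lambda_hat, 1), 400)
  expect_equal(richness_age_rate(1, 3.7)$lambda_hat, 0)
  expect_equal(richness_age_rate(100, 10)$lambda_hat, 0.4605, tolerance = 1e-4)
  expect_error(richness_age_rate(0, 1), "'n'")
  expect_error(richness_age_rate(10, 0), "'t'")
})

test_that("waiting-time conversion spans the published 5 to 200 range", {
  expect_equal(waiting_time_to_rate(5000, 1)$lambda_hat, 200)
  expect_equal(waiting_time_to_rate(1e6, 1)$lambda_hat, 1)
  expect_equal(waiting_time_to_rate(200000, 1)$lambda_hat, 5)
  expect_error(waiting_time_to_rate(0, 1), "positive")
  expect_error(waiting_time_to_rate(100, -2), "positive")
})

test_that("branching times are validated and order-invariant", {
  bt <- branching_times(c(1, 2))
  expect_equal(bt$ages, c(2, 1))
  expect_identical(bt$n, 3L)
  expect_equal(bt$T, 2)
  expect_error(branching_times(c(2, 0)), "positive")
  shuffled <- c(4.1, 0.3, 2.2, 1.7, 3.0)
  expect_equal(fit_yule(branching_times(shuffled))$lambda_hat,
               fit_yule(branching_times(sort(shuffled)))$lambda_hat)
})

test_that("Yule MLE matches the hand-computed exposure fixture", {
  # splits at ages 2 and 1: exposure 2*1 + 3*1 = 5, lambda = (3-2)/5
  est <- fit_yule(branching_times(c(2, 1)))
  expect_equal(est$lambda_hat, 0.2)
  expect_error(fit_yule(branching_times(2)), "n >= 3")
  # rescaling times by c divides the rate by c
  set.seed(51)
  for (i in 1:10) {
    ages <- sort(runif(sample(3:12, 1), 0.1, 9), decreasing = TRUE)
    c0 <- runif(1, 0.1, 20)
    expect_equal(fit_yule(branching_times(ages * c0))$lambda_hat,
                 fit_yule(branching_times(ages))$lambda_hat / c0,
                 tolerance = 1e-12)
  }
})

test_that("Yule MLE recovers the canonical 0.3 benchmark rate", {
  set.seed(52)
  lams <- replicate(200, fit_yule(sim_yule_bt(100, 0.3))$lambda_hat)
  expect_lt(abs(median(lams) / 0.3 - 1), 0.05)
})

test_that("closed-form Yule MLE equals a grid-search maximization", {
  set.seed(53)
  for (i in 1:20) {
    bt <- sim_yule_bt(sample(4:25, 1), runif(1, 0.1, 2))
    lam <- fit_yule(bt)$lambda_hat
    expect_equal(yule_grid_mle(bt), lam, tolerance = 1e-6 / max(lam, 1))
  }
})

test_that("birth-death fit is consistent with Yule on extinction-free data", {
  set.seed(54)
  ratio <- mu <- numeric(50)
  for (i in 1:50) {
    bt <- sim_yule_bt(120, 0.5)
    fy <- fit_yule(bt)
    fb <- fit_birth_death(bt)
    ratio[i] <- fb$lambda_hat / fy$lambda_hat
    mu[i] <- fb$mu_hat
    expect_gte(fb$log_likelihood, fy$log_likelihood - 1e-6)
  }
  expect_lt(abs(median(ratio) - 1), 0.1)
  expect_lt(median(mu), 0.05)
})

test_that("birth-death fit recovers lambda from supercritical simulations", {
  set.seed(55)
  lams <- c()
  while (length(lams) < 100) {
    tre <- sim_bd_tree(1, 0.5, t_max = 9, min_tips = 50)
    lams <- c(lams, fit_birth_death(as_branching_times(tre))$lambda_hat)
  }
  expect_gte(median(lams), 0.8)
  expect_lte(median(lams), 1.2)
})

test_that("richness-age behaves as a minimum bound when extinction hides events", {
  set.seed(56)
  rich <- bdml <- c()
  while (length(rich) < 100) {
    tre <- sim_bd_tree(1, 0.5, t_max = 6, min_tips = 5)
    bt <- as_branching_times(tre)
    rich <- c(rich, richness_age_rate(bt$n, bt$T)$lambda_hat)
    bdml <- c(bdml, fit_birth_death(bt)$lambda_hat)
  }
  expect_lt(median(rich), median(bdml))
})

test_that("estimates are coherent under a change of time unit", {
  set.seed(57)
  bt_myr <- as_branching_times(sim_bd_tree(1, 0.3, t_max = 7, min_tips = 10))
  bt_kyr <- branching_times(bt_myr$ages * 1000)
  fy <- fit_yule(bt_myr); fyk <- fit_yule(bt_kyr)
  expect_equal(fyk$lambda_hat * 1000, fy$lambda_hat, tolerance = 1e-9)
  fb <- fit_birth_death(bt_myr); fbk <- fit_birth_death(bt_kyr)
  expect_equal(fbk$lambda_hat * 1000, fb$lambda_hat, tolerance = 1e-9)
  expect_equal(fbk$mu_hat * 1000, fb$mu_hat, tolerance = 1e-9)
})

test_that("the birth-death log-likelihood agrees with an independent implementation", {
  set.seed(58)
  tre <- sim_bd_tree(1, 0.5, t_max = 8, min_tips = 20)
  fb <- fit_birth_death(as_branching_times(tre))
  ab <- ape::birthdeath(tre)
  expect_equal(unname(ab$para["d/b"]), fb$mu_hat / fb$lambda_hat,
               tolerance = 1e-3)
  expect_equal(unname(ab$para["b-d"]), fb$lambda_hat - fb$mu_hat,
               tolerance = 1e-3)
  expect_equal(-ab$dev / 2, fb$log_likelihood, tolerance = 1e-4)
})
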
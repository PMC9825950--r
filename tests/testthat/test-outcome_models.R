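test_that("estimating functions match their closed forms", {
  dm <- outcome_model("difference_of_means")
  # exact residual zero
  a <- c(0, 1, 0, 1)
  y <- 2 + 3 * a
  expect_equal(unname(estimating_function(dm, y, a, c(2, 3))),
               matrix(0, 4, 2))
  # binary relative-risk model at the benchmark death probabilities
  rr <- outcome_model("log_relative_risk")
  v <- estimating_function(rr, 1, 1, c(log(0.33), log(0.247 / 0.33)))
  expect_equal(as.numeric(v), c(0.753, 0.753))
  # two-category proportional odds reduces to the logistic score
  po2 <- outcome_model("proportional_odds", n_categories = 2L)
  y2 <- c(1, 2, 2, 1); a2 <- c(0, 0, 1, 1)
  th <- c(0.4, -0.7)
  got <- estimating_function(po2, y2, a2, th)
  r <- (y2 <= 1) - plogis(th[1] + th[2] * a2)
  expect_equal(unname(got), unname(cbind(r, a2 * r)))
})

test_that("proportional-odds Jacobian: analytic equals central differences", {
  cfg <- scenario_config("ordinal", beta = log(1.5), n_max = 150)
  snap <- interim_data(generate_trial(cfg, seed = 2), 150)
  cc <- which(snap$ascertained == 1L)
  y <- snap$outcome[cc]; a <- snap$arm[cc]
  po <- outcome_model("proportional_odds", n_categories = 6L)
  th <- c(qlogis(c(0.1, 0.3, 0.5, 0.6, 0.7)), 0.2)
  w <- runif(length(y), 0.5, 2)
  J_an <- model_jacobian(po, y, a, th, weights = w, n_norm = 100)
  J_num <- numeric_jacobian(function(t)
    colSums(w * estimating_function(po, y, a, t)) / 100, th)
  expect_lt(max(abs(J_an - J_num)) / max(abs(J_an)), 1e-4)
})

test_that("influence row G inverts the negated Jacobian", {
  po <- outcome_model("proportional_odds", n_categories = 4L)
  y <- c(1, 2, 3, 4, 2, 3, 1, 4); a <- c(0, 1, 0, 1, 1, 0, 1, 0)
  th <- c(-1, 0, 1, 0.3)
  G <- g_row(po, y, a, th)
  J <- model_jacobian(po, y, a, th)
  e_p <- as.numeric(G %*% (-J))
  expect_equal(e_p, c(0, 0, 0, 1), tolerance = 1e-10)
})

test_that("difference-of-means influence function has the textbook form", {
  set.seed(5)
  n <- 200
  a <- rep(c(0, 1), n / 2)                      # exactly balanced, pi = 0.5
  y <- rnorm(n) + a
  dm <- outcome_model("difference_of_means")
  sol <- solve_estimating_equation(dm, y, a)
  m <- influence_values(dm, y, a, sol$theta)
  mu1 <- mean(y[a == 1]); mu0 <- mean(y[a == 0])
  manual <- a * (y - mu1) / 0.5 - (1 - a) * (y - mu0) / 0.5
  expect_equal(m, manual, tolerance = 1e-10)
  # influence variance tracks the two-sample variance of a difference in means
  v_if <- var(m) / n
  v_txt <- var(y[a == 1]) / sum(a) + var(y[a == 0]) / sum(1 - a)
  expect_lt(abs(v_if / v_txt - 1), 0.02)
})

test_that("unweighted solutions recover the closed-form estimators", {
  set.seed(11)
  a <- rbinom(300, 1, 0.5)
  y <- rnorm(300, 1 + 0.4 * a)
  dm <- outcome_model("difference_of_means")
  sol <- solve_estimating_equation(dm, y, a)
  expect_equal(sol$beta, mean(y[a == 1]) - mean(y[a == 0]), tolerance = 1e-12)

  yb <- rbinom(300, 1, plogis(-0.5 + 0.3 * a))
  rr <- outcome_model("log_relative_risk")
  solb <- solve_estimating_equation(rr, yb, a)
  expect_equal(solb$beta, log(mean(yb[a == 1]) / mean(yb[a == 0])), tolerance = 1e-12)

  # weighted residuals vanish at the proportional-odds solution
  cfg <- scenario_config("ordinal", beta = log(1.5), n_max = 250)
  snap <- interim_data(generate_trial(cfg, seed = 7), 160)
  cc <- which(snap$ascertained == 1L)
  po <- outcome_model("proportional_odds", n_categories = 6L)
  w <- runif(length(cc), 0.5, 3)
  solp <- solve_estimating_equation(po, snap$outcome[cc], snap$arm[cc], weights = w)
  eq <- colSums(w * estimating_function(po, snap$outcome[cc], snap$arm[cc], solp$theta))
  expect_lt(max(abs(eq)), 1e-9 * length(cc))
})

test_that("full-covariance proportional odds reproduces the ML fit", {
  skip_if_not_installed("MASS")
  cfg <- scenario_config("ordinal", beta = log(1.5))
  snap <- interim_data(generate_trial(cfg, seed = 13), 330)
  y <- snap$outcome; a <- snap$arm
  po_full <- outcome_model("proportional_odds", n_categories = 6L, variance = "full")
  sol <- solve_estimating_equation(po_full, y, a)
  fit <- MASS::polr(factor(y) ~ a)
  # polr uses logit pr(Y <= j) = zeta_j - eta: alpha_j = zeta_j, beta = -coef
  expect_equal(unname(sol$alpha), unname(fit$zeta), tolerance = 1e-4)
  expect_equal(sol$beta, unname(-coef(fit)), tolerance = 1e-4)
})

test_that("estimating-function means vanish at the generative parameters", {
  # Monte Carlo unbiasedness at the truth for all three scenario models
  n <- 5000
  for (sc in c("ordinal", "binary", "continuous")) {
    beta_gen <- if (sc == "continuous") 6.24 else log(1.5)
    cfg <- scenario_config(sc, beta = beta_gen, n_max = n)
    full <- generate_trial(cfg, seed = match(sc, c("ordinal", "binary", "continuous")))
    model <- scenario_model(cfg)
    theta0 <- switch(sc,
      ordinal = c(qlogis(cumsum(ordinal_category_probs(0))[1:5]), log(1.5)),
      binary = c(log(0.33), scenario_effect(cfg)),
      continuous = {
        mu0 <- sum(cfg$x1_probs * cfg$x1_means) + cfg$xi1 * cfg$tf
        c(mu0, 6.24)
      })
    M <- estimating_function(model, full$outcome, full$arm, theta0)
    se <- apply(M, 2, sd) / sqrt(n)
    expect_true(all(abs(colMeans(M)) <= 3 * se),
                label = paste("mean-zero at truth for", sc))
  }
})

test_that("separation and degenerate inputs raise informative errors", {
  rr <- outcome_model("log_relative_risk")
  expect_error(solve_estimating_equation(rr, c(0, 0, 1, 1), c(0, 0, 1, 1)),
               "not estimable")
  dm <- outcome_model("difference_of_means")
  expect_error(solve_estimating_equation(dm, c(1, 2), c(1, 1)), "both arms")
  expect_error(estimating_function(dm, 1, 1, c(Inf, 0)), "non-finite")
  po <- outcome_model("proportional_odds", n_categories = 3L)
  expect_error(estimating_function(po, 7, 1, c(0, 1, 0)), "range")
})
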
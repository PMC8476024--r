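sim_lmm_data <- function(seed, n_groups = 40, per_group = 20, beta = 2,
                         sd_b = 1, sd_e = 1) {
  set.seed(seed)
  g <- factor(rep(seq_len(n_groups), each = per_group))
  x <- rnorm(n_groups * per_group)
  b <- rnorm(n_groups, 0, sd_b)
  data.frame(y = 1 + beta * x + b[as.integer(g)] +
               rnorm(n_groups * per_group, 0, sd_e),
             x = x, g = g)
}

test_that("the LMM covers the true slope and collapses to OLS without groups", {
  hits <- 0
  for (s in 1:100) {
    d <- sim_lmm_data(s)
    f <- fit_lmm(d, y ~ x, "g")
    ci <- f$coefficients[f$coefficients$term == "x", ]
    hits <- hits + (ci$ci_low <= 2 && 2 <= ci$ci_high)
  }
  expect_gte(hits, 90)

  ## sigma_b = 0: variance estimated at the boundary, fixed effects = OLS
  d0 <- sim_lmm_data(7, sd_b = 0)
  f0 <- fit_lmm(d0, y ~ x, "g", reml = FALSE)
  expect_lt(f0$random_intercept_variance, 1e-6)
  ols <- coef(lm(y ~ x, d0))
  expect_equal(unname(f0$coefficients$estimate), unname(ols),
               tolerance = 1e-6)

  expect_error(fit_lmm(d0[1, ], y ~ x, "g"), "2 observations|2 groups")
  d_bad <- d0; d_bad$x2 <- d_bad$x
  expect_error(fit_lmm(d_bad, y ~ x + x2, "g"), "collinear.*x2")
})

test_that("the Poisson GLMM recovers its variance and nests the plain GLM", {
  set.seed(42)
  g <- factor(rep(1:50, each = 50))
  x <- rnorm(2500)
  b <- rnorm(50, 0, 0.5)
  d <- data.frame(y = rpois(2500, exp(0.5 + 0.3 * x + b[as.integer(g)])),
                  x = x, g = g)
  fit <- fit_glmm(d, y ~ x, family = "poisson", group = "g")
  expect_lt(abs(sqrt(fit$random_intercept_variance) - 0.5), 0.1)

  set.seed(7)
  d0 <- data.frame(y = rpois(2500, exp(0.5 + 0.3 * x)), x = x, g = g)
  f0 <- fit_glmm(d0, y ~ x, family = "poisson", group = "g")
  glm0 <- glm(y ~ x, poisson, d0)
  expect_lt(abs(-2 * f0$log_likelihood - (-2 * as.numeric(logLik(glm0)))),
            1e-4)

  d_bad <- d0; d_bad$y <- d_bad$y + 0.5
  expect_error(fit_glmm(d_bad, y ~ x, family = "poisson", group = "g"),
               "integer")
})

test_that("complete separation in a binomial stratum is caught", {
  set.seed(3)
  d <- data.frame(y = rbinom(200, 1, 0.5),
                  stratum = rep(c("A", "B"), each = 100),
                  g = factor(rep(1:10, each = 20)))
  d$y[d$stratum == "B"] <- 1
  expect_error(fit_glmm(d, y ~ stratum, family = "binomial", group = "g"),
               "separation")
})

test_that("doubling the quadrature nodes barely moves the coefficients", {
  set.seed(9)
  g <- factor(rep(1:20, each = 30))
  x <- rnorm(600)
  b <- rnorm(20, 0, 0.8)
  d <- data.frame(y = rbinom(600, 1, plogis(-0.3 + 0.6 * x + b[as.integer(g)])),
                  x = x, g = g)
  f15 <- fit_glmm(d, y ~ x, family = "binomial", group = "g", nagq = 15)
  f30 <- fit_glmm(d, y ~ x, family = "binomial", group = "g", nagq = 30)
  expect_lt(max(abs(f15$coefficients$estimate - f30$coefficients$estimate)),
            1e-3)
})

test_that("the RSF front end validates its table and tilts with the data", {
  tab <- make_ua_table(1, betas = c(pasture = 1, maize = -0.8))
  fit <- fit_rsf(tab, include_road = FALSE, nagq = 1)
  co <- fit$coefficients
  expect_lt(abs(co$estimate[co$term == "land_coverpasture"] - 1), 0.35)
  expect_lt(abs(co$estimate[co$term == "land_covermaize"] + 0.8), 0.35)
  ## adding a term never decreases the maximised log-likelihood
  fit_more <- fit_rsf(tab, include_road = TRUE, nagq = 1)
  expect_gte(fit_more$log_likelihood, fit$log_likelihood - 1e-6)

  expect_error(fit_rsf(tab[tab$used == 1, ]), "no available rows")
  expect_error(fit_rsf(tab[tab$used == 0, ]), "no used rows")
  tab_miss <- tab; tab_miss$land_cover[tab_miss$land_cover == "cereal"] <- "rape"
  expect_error(fit_rsf(tab_miss), "reference class")
  tab_onesided <- tab
  tab_onesided$land_cover[tab_onesided$used == 1 &
                          tab_onesided$land_cover == "maize"] <- "cereal"
  expect_warning(fit_rsf(tab_onesided, include_road = FALSE), "unstable")
})

test_that("relative probability of use equals the closed-form null", {
  ## all-zero selection, ratio 10: every class ~ 1/11, the 0.1 reference line
  tab <- make_ua_table(11, n_used = 800)
  fit <- fit_rsf(tab, include_road = FALSE, nagq = 1)
  rp <- relative_probability_of_use(fit)
  expect_equal(attr(rp, "null_line"), 1 / 11)
  expect_true(all(abs(rp$rel_prob - 1 / 11) < 0.02))
  expect_error(relative_probability_of_use(fit, classes = "forest"),
               "absent")
  ## strong positive selection lifts the class above the reference and the
  ## null line; in the beta -> +Inf limit the value approaches 1
  tab_hi <- make_ua_table(12, betas = c(pasture = 4, maize = 0))
  fit_hi <- fit_rsf(tab_hi, include_road = FALSE, nagq = 1)
  rp_hi <- relative_probability_of_use(fit_hi)
  expect_gt(rp_hi$rel_prob[rp_hi$class == "pasture"],
            rp_hi$rel_prob[rp_hi$class == "cereal"])
  expect_gt(rp_hi$rel_prob[rp_hi$class == "pasture"], 1 / 11)
  fit_inf <- fit_hi
  fit_inf$coefficients$estimate[
    fit_inf$coefficients$term == "land_coverpasture"] <- 50
  rp_inf <- relative_probability_of_use(fit_inf)
  expect_equal(rp_inf$rel_prob[rp_inf$class == "pasture"], 1,
               tolerance = 1e-6)
})

test_that("AICc arithmetic and backward selection behave as designed", {
  ## AIC = 100 (k = 3, n = 20) gains 24/16 = 1.5
  expect_equal(aicc(-47, 3, 20), 101.5)
  expect_equal(aicc(-47, 3, 4), Inf)

  ## marginality: the interaction must leave before its main effects
  set.seed(21)
  g <- factor(rep(1:10, each = 30))
  d <- data.frame(a = rnorm(300), b = rnorm(300), g = g)
  d$y <- 0.8 * d$a + rnorm(300) + rnorm(10)[as.integer(g)] * 0.3
  res <- aicc_stepwise(d, y ~ a * b, "gaussian", "g")
  kept <- attr(terms(lme4::nobars(res$best_formula)), "term.labels")
  expect_true("a" %in% kept)
  expect_false("a:b" %in% kept)
  expect_equal(res$table$model, c("best", "full", "intercept_only"))
  expect_true(all(diff(res$table$aicc[c(2, 1)]) <= 0))

  ## a strong true effect survives selection
  expect_true("a" %in% kept)
})

test_that("Nakagawa R2 partitions variance as in the Gaussian benchmark", {
  ## sigma2_f = 1, sigma2_b = 1, sigma2_e = 2 -> R2m = 0.25, R2c = 0.5
  set.seed(14)
  g <- factor(rep(1:60, each = 25))
  x <- rnorm(1500)
  d <- data.frame(y = x + rnorm(60, 0, 1)[as.integer(g)] +
                    rnorm(1500, 0, sqrt(2)),
                  x = x, g = g)
  fit <- fit_lmm(d, y ~ x, "g")
  r2 <- nakagawa_r2(fit)
  expect_lt(abs(r2$R2_marginal - 0.25), 0.05)
  expect_lt(abs(r2$R2_conditional - 0.5), 0.05)

  ## intercept-only model explains nothing by fixed effects
  f0 <- fit_lmm(d, y ~ 1, "g")
  expect_equal(nakagawa_r2(f0)$R2_marginal, 0)

  ## sigma_b = 0 collapses conditional onto marginal
  d0 <- sim_lmm_data(5, sd_b = 0)
  fb <- fit_lmm(d0, y ~ x, "g")
  r2b <- nakagawa_r2(fb)
  expect_equal(r2b$R2_conditional, r2b$R2_marginal, tolerance = 1e-6)

  expect_error(nakagawa_r2(lm(y ~ x, d0)), "fitted model")
})

test_that("informativeness is the 95% CI excluding zero, boundary inclusive", {
  fake <- structure(list(coefficients = tibble::tibble(
    term = c("a", "b", "c"),
    estimate = c(0.5, 0, 0.25),
    se = c(0.1, 0.05, 0.13),
    ci_low = c(0.2, -0.1, 0),
    ci_high = c(0.8, 0.1, 0.5))), class = "owl_model_fit")
  flags <- informative_flags(fake)
  expect_equal(flags$informative, c(TRUE, FALSE, FALSE))
})

test_that("the collinearity screen flags duplicates and constants only", {
  set.seed(31)
  d <- data.frame(a = rnorm(10000), b = rnorm(10000), konst = 1)
  d$dup <- d$a
  res <- screen_collinearity(d, c("a", "b", "dup", "konst"))
  expect_equal(res$undefined, "konst")
  pairs <- res$pairs
  expect_true(pairs$flagged[pairs$term1 == "a" & pairs$term2 == "dup"])
  expect_equal(pairs$r[pairs$term1 == "a" & pairs$term2 == "dup"], 1)
  ab <- pairs[pairs$term1 == "a" & pairs$term2 == "b", ]
  expect_lt(abs(ab$r), 0.05)
  expect_false(ab$flagged)
})
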
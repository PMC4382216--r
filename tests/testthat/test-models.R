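# shared simulated daily-range table: 16 bats x 3 sessions
sim_daily <- function(seed = 3, beta_dist = 3, beta_day = -0.4,
                      sigma_b = 0.5, sigma_e = 0.6) {
  set.seed(seed)
  d <- data.frame(bat_id = rep(1:16, each = 3),
                  disturbance = runif(48),
                  day = rep(1:3, 16),
                  moon = runif(48),
                  sex = rep(rbinom(16, 1, 0.5), each = 3))
  b <- rnorm(16, 0, sigma_b)
  d$log_area <- 10.6 + beta_dist * d$disturbance + beta_day * d$day +
    b[d$bat_id] + rnorm(48, 0, sigma_e)
  d
}

test_that("covariate centering zeroes means and reports them", {
  d <- data.frame(bat_id = 1:3, log_area = 1:3,
                  disturbance = c(0.2, 0.4, 0.6), day = c(1, 1, 1),
                  moon = c(0, 0.5, 1), sex = c("f", "m", "f"))
  cen <- center_covariates(d)
  expect_equal(cen$data$disturbance, c(-0.2, 0, 0.2))
  expect_equal(attr(cen, "constant"), "day")
  expect_true(all(abs(colMeans(cen$data[c("disturbance", "day", "moon",
                                          "sex")])) < 1e-12))
  expect_equal(unname(cen$means["disturbance"]), 0.4)
  # already-centered data passes through unchanged
  cen2 <- center_covariates(cen$data)
  expect_equal(cen2$data$disturbance, cen$data$disturbance)
})

test_that("profiled ML fit matches lme4 maximum likelihood", {
  library(lme4)
  d <- sim_daily()
  for (terms in list(character(0), "disturbance",
                     c("disturbance", "day"),
                     c("disturbance", "day", "moon", "sex"))) {
    f <- fit_lmm(d, terms)
    form <- stats::reformulate(c(if (length(terms)) terms else "1",
                                 "(1 | bat_id)"), response = "log_area")
    m <- lmer(form, data = d, REML = FALSE)
    expect_equal(unname(f$beta), unname(fixef(m)), tolerance = 1e-6)
    expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 1e-6)
    vc <- as.data.frame(VarCorr(m))$vcov
    expect_equal(f$sigma_b2, vc[1], tolerance = 1e-5)
    expect_equal(f$sigma_e2, vc[2], tolerance = 1e-5)
  }
})

test_that("a zero-variance random intercept collapses to OLS", {
  # groups constructed with identical response patterns: the profiled
  # likelihood peaks at sigma_b^2 = 0 and the GLS solution is OLS
  set.seed(13)
  base_x <- runif(3); base_e <- rnorm(3, 0, 0.5)
  d <- data.frame(bat_id = rep(1:16, each = 3),
                  disturbance = rep(base_x, 16))
  d$log_area <- 2 + 1.5 * d$disturbance + rep(base_e, 16)
  f <- fit_lmm(d, "disturbance")
  ols <- stats::lm(log_area ~ disturbance, data = d)
  expect_lte(f$sigma_b2, 1e-6)
  expect_equal(unname(f$beta), unname(coef(ols)), tolerance = 1e-6)
})

test_that("the profiled optimum dominates the OLS boundary likelihood", {
  for (s in 1:5) {
    d <- sim_daily(seed = 100 + s)
    f <- fit_lmm(d, "disturbance")
    ols <- stats::lm(log_area ~ disturbance, data = d)
    n <- nrow(d)
    ll0 <- -n / 2 * (log(2 * pi) + log(mean(resid(ols)^2)) + 1)
    expect_gte(f$loglik, ll0 - 1e-8)
  }
})

test_that("replicating the data as fresh groups leaves the fit unchanged", {
  # doubling the data with new group labels doubles the log-likelihood
  # exactly, so every estimate is preserved
  d <- sim_daily(seed = 21)
  d2 <- rbind(d, transform(d, bat_id = bat_id + 100))
  f1 <- fit_lmm(d, c("disturbance", "day"))
  f2 <- fit_lmm(d2, c("disturbance", "day"))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
  expect_equal(f1$sigma_b2, f2$sigma_b2, tolerance = 1e-5)
  expect_equal(2 * f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("AICc counts fixed effects plus two variance parameters", {
  d <- sim_daily()
  f0 <- fit_lmm(d, character(0))
  f1 <- fit_lmm(d, "disturbance")
  expect_equal(f0$K, 3L)
  expect_equal(f1$K, 4L)
  expect_equal(aicc(f1),
               -2 * f1$loglik + 2 * 4 + 2 * 4 * 5 / (48 - 4 - 1))
  # large-n limit: the correction vanishes
  big <- list(loglik = -100, K = 4, n = 1e6)
  expect_lt(aicc(big) - (-2 * big$loglik + 2 * big$K), 1e-4)
  expect_error(aicc(list(loglik = 0, K = 5, n = 6)), "undefined")
})

test_that("Akaike weights follow the closed form and normalize", {
  w <- akaike_weights(c(69.2, 70.5))
  expect_equal(w$weight, c(1, exp(-0.65)) / (1 + exp(-0.65)))
  expect_equal(sum(w$weight), 1)
  eq <- akaike_weights(rep(42, 16))
  expect_equal(eq$weight, rep(1 / 16, 16))
  expect_equal(min(w$delta), 0)
})

test_that("the all-subset model set ranks 16 models coherently", {
  d <- sim_daily()
  cen <- center_covariates(d)
  set <- all_subsets(cen$data)
  expect_length(set$fits, 16)
  expect_equal(sum(set$table$weight), 1)
  expect_equal(set$table$delta[1], 0)
  expect_true(1 %in% set$top_set)
  expect_true(all(diff(set$table$aicc) >= 0))
  # the generating term dominates this simulation
  expect_match(set$table$model[1], "disturbance")
})

test_that("model averaging reduces to single-model estimates and obeys the
           unconditional-variance formula", {
  d <- sim_daily()
  set <- all_subsets(center_covariates(d)$data)
  one <- set
  one$top_set <- 1L
  avg <- model_average(one, scope = "delta2")
  f <- set$fits[[1]]
  expect_equal(avg$estimate[avg$term == "(Intercept)"],
               unname(f$beta["(Intercept)"]))
  # hand-computed two-model average: equal weights, beta 2 and 4, se 0
  fake <- list(
    fits = list(list(terms = "t", beta = c("(Intercept)" = 0, t = 2),
                     se = c("(Intercept)" = 0, t = 0)),
                list(terms = "t", beta = c("(Intercept)" = 0, t = 4),
                     se = c("(Intercept)" = 0, t = 0))),
    table = data.frame(weight = c(0.5, 0.5)),
    top_set = 1:2)
  class(fake) <- "model_set"
  a2 <- model_average(fake, scope = "delta2")
  expect_equal(a2$estimate[a2$term == "t"], 3)
  expect_equal(a2$unconditional_se[a2$term == "t"], 1)
  # relative importance sums weights of models containing the term
  avg_all <- model_average(set, scope = "all", mode = "full")
  imp <- avg_all$rel_importance[avg_all$term == "disturbance"]
  expect_equal(imp, sum(set$table$weight[grepl("disturbance",
                                               set$table$model)]))
})

test_that("conditional R2 follows its closed forms", {
  f_null <- list(fitted_fixed = rep(5, 10), sigma_b2 = 2, sigma_e2 = 2)
  expect_equal(conditional_r2(f_null), 0.5)
  f_perfect <- list(fitted_fixed = rnorm(10), sigma_b2 = 0, sigma_e2 = 1e-12)
  expect_gt(conditional_r2(f_perfect), 0.999)
})

test_that("variance inflation factors detect constructed collinearity", {
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  ortho <- data.frame(disturbance = x1, day = x2, moon = x3)
  v <- vif(ortho, c("disturbance", "day", "moon"))
  expect_true(all(abs(v - 1) < 0.15))
  dup <- data.frame(a = x1, b = x1)
  w <- testthat::capture_warnings(vd <- vif(dup, c("a", "b")))
  expect_true(any(grepl("collinearity", w)))
  expect_true(all(is.infinite(vd)))
  # x2 = x1 + noise scaled so that R^2 = 0.75 exactly -> VIF = 4
  x1s <- scale(x1)[, 1]
  e <- stats::resid(stats::lm(rnorm(n) ~ x1s))
  e <- e / sqrt(sum(e^2))
  y <- sqrt(0.75) * x1s / sqrt(sum(x1s^2)) + sqrt(0.25) * e
  con <- data.frame(a = x1s, b = y)
  expect_equal(unname(vif(con, c("a", "b"))["b"]), 4, tolerance = 1e-6)
})

test_that("log correlation is base-invariant with Fisher-z intervals", {
  a <- exp(seq(1, 4, length.out = 10))
  expect_equal(pearson_log_correlation(a, -log(a))$r, -1)
  set.seed(14)
  areas <- exp(rnorm(20)); ratios <- runif(20)
  r_e <- pearson_log_correlation(areas, ratios)
  expect_equal(stats::cor(log10(areas), ratios), r_e$r, tolerance = 1e-12)
  ct <- stats::cor.test(log(areas), ratios)
  expect_equal(r_e$r, unname(ct$estimate))
  expect_equal(c(r_e$ci_low, r_e$ci_high), unname(ct$conf.int),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(r_e$p, ct$p.value, tolerance = 1e-12)
})

test_that("the normality screen runs as a smoke test on model residuals", {
  d <- sim_daily()
  f <- fit_lmm(d, "disturbance")
  p <- stats::shapiro.test(d$log_area - f$fitted_fixed)$p.value
  expect_gt(p, 0.001)
})
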
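test_that("closed-form MLEs are exact for poisson and normal", {
  expect_equal(fit_mle(c(2, 4, 6), "poisson")$params[["lambda"]], 4)
  fn <- fit_mle(c(1, 2, 3), "normal")
  expect_equal(fn$params[["mean"]], 2)
  expect_equal(fn$params[["sd"]], sqrt(2 / 3))   # population sd, not sample sd
  # loglik consistency with the density
  expect_equal(fn$loglik, sum(dnorm(1:3, 2, sqrt(2 / 3), log = TRUE)))
})

test_that("numeric MLEs recover generating parameters and beat perturbations", {
  cases <- list(
    list(fam = "gamma", params = list(shape = 3, rate = 0.02)),
    list(fam = "weibull", params = list(shape = 2.2, scale = 160)),
    list(fam = "logistic", params = list(location = 150, scale = 10)))
  set.seed(77)
  for (cs in cases) {
    x <- sample_cell_counts(cs$fam, cs$params, 4000)
    # rounding can land a rare draw on 0, triggering the documented
    # positive-support adjustment; that path has its own test
    fit <- suppressWarnings(fit_mle(x, cs$fam))
    truth <- unlist(cs$params, use.names = FALSE)
    for (k in 1:2)
      expect_lt(abs(fit$params[[k]] - truth[k]) / abs(truth[k]), 0.08,
                label = paste(cs$fam, names(fit$params)[k]))
    # local optimality: +/-5% parameter nudges never beat the MLE
    ll_at <- function(par) {
      switch(cs$fam,
        gamma    = sum(dgamma(x, shape = par[1], rate = par[2], log = TRUE)),
        weibull  = sum(dweibull(x, shape = par[1], scale = par[2], log = TRUE)),
        logistic = sum(dlogis(x, par[1], par[2], log = TRUE)))
    }
    for (f1 in c(0.95, 1, 1.05)) for (f2 in c(0.95, 1, 1.05))
      expect_lte(ll_at(fit$params * c(f1, f2)), fit$loglik + 1e-6)
  }
})

test_that("zero counts are adjusted for positive-support families with warning", {
  x <- c(0, 0, 3, 5, 2, 8, 4, 6, 1, 2)
  expect_warning(f <- fit_mle(x, "gamma"), "zero count")
  expect_true(all(is.finite(f$params)) && f$loglik > -Inf)
  expect_silent(fit_mle(x, "logistic"))
})

test_that("degenerate samples are rejected with clear errors", {
  expect_error(fit_mle(c(5, 5, 5, 5, 5), "normal"), "identical")
  expect_error(fit_mle(rep(0, 10), "poisson"), "all-zero")
  expect_error(fit_mle(rep(7, 10), "weibull"), "identical")
  expect_error(fit_mle(c(1, 2), "gamma"), "at least 5")
})

test_that("KS statistic agrees with a brute-force supremum oracle", {
  set.seed(12)
  x <- sample_cell_counts("logistic", list(location = 150, scale = 10), 80)
  fit <- fit_mle(x, "logistic")
  ks <- ks_gof(x, fit)
  expect_equal(ks$D, bf_ks_D(x, fitted_cdf_for_test(fit)), tolerance = 1e-9)
  y <- sample_cell_counts("poisson", list(lambda = 6), 120, seed = 8)
  fp <- fit_mle(y, "poisson")
  kp <- ks_gof(y, fp)
  # step-vs-step sup: brute force over a fine grid between the integers
  grid <- seq(min(y) - 1.5, max(y) + 0.5, by = 0.01)
  ec <- ecdf(y)
  D_bf <- max(abs(ec(grid) - ppois(floor(grid), fp$params[["lambda"]])))
  expect_equal(kp$D, D_bf, tolerance = 1e-9)
})

test_that("single observation at the fitted median gives D = 0.5", {
  fit <- fit_mle(c(140, 150, 145, 160, 155), "logistic")
  ks <- ks_gof(fit$params[["location"]], fit)
  expect_equal(ks$D, 0.5)
})

test_that("D vanishes for large self-fitted samples and p falls with D", {
  set.seed(9)
  x <- rlogis(1e4, 150, 10)
  fit <- fit_mle(x, "logistic")
  ks <- ks_gof(x, fit)
  expect_lt(ks$D, 0.02)
  # monotonicity: at fixed n a worse fit has larger D and smaller p
  bad <- fit
  bad$params <- c(location = 170, scale = 10)
  ks_bad <- ks_gof(x, bad)
  expect_gt(ks_bad$D, ks$D)
  expect_lt(ks_bad$p_value, ks$p_value)
})

test_that("D is invariant under joint affine rescaling of sample and fit", {
  set.seed(15)
  x <- rnorm(200, 100, 12)
  f1 <- fit_mle(x, "normal")
  y <- 3 * x + 40
  f2 <- fit_mle(y, "normal")
  expect_equal(ks_gof(x, f1)$D, ks_gof(y, f2)$D, tolerance = 1e-12)
})

test_that("rejection flag follows alpha and the bootstrap p is valid", {
  set.seed(44)
  x <- sample_cell_counts("logistic", list(location = 150, scale = 10), 60)
  fit <- fit_mle(x, "logistic")
  ks <- ks_gof(x, fit, alpha = 0.05)
  expect_identical(ks$rejected, ks$p_value < 0.05)
  set.seed(45)
  kb <- ks_gof(x, fit, bootstrap = TRUE, n_boot = 49)
  expect_gte(kb$p_value, 1 / 50)
  expect_lte(kb$p_value, 1)
})

test_that("model selection reports five families per gene with verdicts", {
  x <- sample_cell_counts("logistic", list(location = 150, scale = 10), 100,
                          seed = 50)
  suppressWarnings(ms <- model_selection_table(list(ntla = x)))
  expect_identical(nrow(ms$table), 5L)
  expect_setequal(ms$table$family,
                  c("normal", "gamma", "logistic", "weibull", "poisson"))
  expect_match(ms$verdicts[["ntla"]], "logistic")
  expect_identical(unname(ms$table$rejected), ms$table$p_value < 0.05)
  empty <- model_selection_table(setNames(list(), character(0)))
  expect_identical(nrow(empty$table), 0L)
  expect_error(model_selection_table(list(g = 1:5)), "fewer than")
})

test_that("delta-delta-Ct self-normalizes calibrators and doubles per cycle", {
  flat <- data.frame(sample_id = paste0("s", 1:4),
                     group = c("test", "test", "calibrator", "calibrator"),
                     ct_target = 20, ct_reference = 16)
  r <- delta_delta_ct(flat)
  expect_true(all(r$per_sample$rel_expr == 1))
  onecycle <- data.frame(sample_id = c("t", "c"),
                         group = c("test", "calibrator"),
                         ct_target = c(19, 20), ct_reference = c(15, 15))
  expect_equal(delta_delta_ct(onecycle)$per_sample$rel_expr[1], 2)
  toy <- data.frame(sample_id = c("t", "c1", "c2"),
                    group = c("test", "calibrator", "calibrator"),
                    ct_target = c(20, 22, 22.6), ct_reference = c(15, 15, 15.6))
  rt <- delta_delta_ct(toy)
  expect_equal(rt$per_sample$rel_expr[1], 4)   # 2^(7 - 5), hand-computed
  # calibrator geometric mean is exactly 1
  cal <- rt$per_sample$rel_expr[rt$per_sample$group == "calibrator"]
  expect_equal(exp(mean(log(cal))), 1, tolerance = 1e-12)
  expect_error(delta_delta_ct(onecycle[1, ]), "calibrator")
  expect_error(delta_delta_ct(transform(onecycle, ct_target = c(-1, 20))),
               "finite and positive")
})
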
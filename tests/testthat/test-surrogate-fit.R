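test_that("OLS on a three-run toy reproduces the closed-form estimates", {
  design <- data.frame(x = c(-1, 0, 1))
  fit <- fit_response(design, c(1, 2, 4), terms = "x", select = FALSE)
  expect_equal(unname(fit$coefficients["x"]), 1.5)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 7 / 3)
})

test_that("a zero-noise campaign recovers every reference coefficient", {
  cam <- zero_noise_campaign()
  fits <- fit_all_responses(cam$design, cam$responses)
  fitted <- as_bundle(fits)
  ref <- reference_bundle()
  for (nm in names(ref)) {
    expect_equal(fitted[[nm]]$intercept, ref[[nm]]$intercept,
                 tolerance = 1e-8, info = nm)
    truth <- ref[[nm]]$coefficients
    expect_true(all(names(truth) %in% names(fitted[[nm]]$coefficients)),
                info = nm)
    expect_equal(unname(fitted[[nm]]$coefficients[names(truth)]),
                 unname(truth), tolerance = 1e-8, info = nm)
    # terms absent from the truth carry only float dust if retained
    extra <- setdiff(names(fitted[[nm]]$coefficients),
                     c(names(truth), "(Intercept)"))
    if (length(extra)) {
      expect_lt(max(abs(fitted[[nm]]$coefficients[extra])), 1e-8)
    }
    expect_gte(fits[[nm]]$r_squared, 1 - 1e-10)
  }
})

test_that("a constant response degenerates to an intercept-only model", {
  design <- data.frame(x1 = c(-1, -1, 1, 1), x2 = c(-1, 1, -1, 1))
  fit <- fit_response(design, rep(3.7, 4))
  expect_identical(fit$terms, character(0))
  expect_equal(unname(fit$coefficients), 3.7)
  expect_identical(fit$r_squared, 0)
})

test_that("rank-deficient term sets raise an aliasing error", {
  # on a two-level design a pure quadratic is confounded with the intercept
  design <- data.frame(x1 = c(-1, -1, 1, 1), x2 = c(-1, 1, -1, 1))
  expect_error(
    fit_response(design, c(1, 2, 3, 4),
                 terms = candidate_terms(names(design), quadratic = TRUE),
                 select = FALSE),
    "aliasing error")
})

test_that("error metrics match hand arithmetic and satisfy RMSE >= MAE", {
  m <- error_metrics(c(1, 2), c(2, 4))
  expect_equal(m$mae, 1.5)
  expect_equal(m$rmse, sqrt(2.5))
  expect_equal(m$mae_pct, 100)

  same <- error_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mae, 0)
  expect_equal(same$rmse, 0)
  expect_equal(same$correlation_pct, 100)

  set.seed(31)
  for (i in 1:20) {
    y <- rnorm(50)
    p <- y + rnorm(50)
    m <- error_metrics(y, p)
    expect_gte(m$rmse, m$mae)
  }

  flagged <- error_metrics(c(0, 1), c(1, 1))
  expect_true(flagged$zero_obs)
  expect_true(is.na(flagged$mae_pct))
  expect_equal(flagged$mae, 0.5)
})

test_that("OLS residuals are orthogonal and sequential ANOVA is complete", {
  cam <- zero_noise_campaign()
  noisy <- simulate_batch(cam$design, noise_sd = noise_preset(), seed = 17)
  for (nm in c("Comp_stiff", "Tors_stiff", "Flex_bulgeL")) {
    fit <- fit_response(cam$design, noisy[[nm]], response = nm)
    res <- stats::residuals(fit$fit)
    X <- stats::model.matrix(fit$fit)
    for (j in seq_len(ncol(X))) {
      expect_lt(abs(sum(res * X[, j])), 1e-8 * sqrt(sum(X[, j]^2)) *
                  sqrt(sum(res^2)) + 1e-8)
    }
    tss <- sum((noisy[[nm]] - mean(noisy[[nm]]))^2)
    expect_equal(sum(fit$anova$`Sum Sq`), tss, tolerance = 1e-8)
    # mean square = SS / Df throughout
    expect_equal(fit$anova$`Mean Sq`, fit$anova$`Sum Sq` / fit$anova$Df)
    expect_true(all(fit$anova$signif %in% c("***", "**", "*", ".", "")))
  }
})

test_that("random sparse affine truths are recovered exactly at zero noise", {
  cam <- zero_noise_campaign()
  set.seed(47)
  for (rep in 1:5) {
    support <- sample(parameter_names(), sample(2:6, 1))
    beta <- stats::setNames(rnorm(length(support), sd = 2), support)
    b0 <- rnorm(1)
    y <- b0 + as.matrix(cam$design[, support, drop = FALSE]) %*% beta
    fit <- fit_response(cam$design, drop(y))
    expect_equal(unname(fit$coefficients["(Intercept)"]), b0,
                 tolerance = 1e-8)
    expect_equal(unname(fit$coefficients[support]), unname(beta),
                 tolerance = 1e-8)
  }
})

test_that("held-out evaluation vanishes at zero noise and detects shuffling", {
  cam <- zero_noise_campaign()
  fits <- fit_all_responses(cam$design, cam$responses)
  test <- test_design(30, cam$ranges, seed = 12)
  test_resp <- simulate_batch(test)
  rep0 <- evaluate_on_test(fits, test, test_resp)
  expect_identical(nrow(rep0), 15L)
  expect_true(all(rep0$mae < 1e-8))
  expect_true(all(rep0$rmse < 1e-8))

  # permuting predictions across runs strictly worsens any non-constant fit
  bundle <- as_bundle(fits)
  pred <- simulate_batch(test, bundle)
  set.seed(3)
  shuffle <- sample(nrow(pred))
  for (nm in c("Comp_stiff", "Exte_bulgeP")) {
    base_mae <- error_metrics(test_resp[[nm]], pred[[nm]])$mae
    shuf_mae <- error_metrics(test_resp[[nm]], pred[[nm]][shuffle])$mae
    expect_gt(shuf_mae, base_mae)
  }

  # with the reference noise preset, held-out percent errors sit in the
  # single-digit-to-low-tens regime typical of surrogate validation
  noisy <- simulate_batch(cam$design, noise_sd = noise_preset(), seed = 23)
  nfits <- fit_all_responses(cam$design, noisy)
  ntest_resp <- simulate_batch(test, noise_sd = noise_preset(), seed = 24)
  nrep <- evaluate_on_test(nfits, test, ntest_resp)
  expect_true(all(nrep$mae_pct > 0))
  expect_true(all(nrep$mae_pct < 40))

  expect_error(evaluate_on_test(fits, test, test_resp[, 1:3]),
               "schema error")
})
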
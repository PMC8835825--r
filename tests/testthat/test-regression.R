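d_ref <- reference_design_matrix()

test_that("predictor encodings reproduce the documented scheme values", {
  cp1 <- d_ref[d_ref$Subset == "CP1", ]
  enc_s <- encode_predictors(cp1, "shape")
  expect_equal(unlist(enc_s), c(B = 0, C = 0, CP1 = 2, B_x_CP1 = 0))
  enc_h <- encode_predictors(cp1, "height")
  expect_true(all(unlist(enc_h) == 0))
  proto <- d_ref[d_ref$Subset == "Protoz", ]
  enc_p <- encode_predictors(proto, "support")
  expect_equal(unlist(enc_p),
               c(protozyme_n = 4, CP1_ind = 0, protozyme_x_CP1 = 0))
  expect_error(encode_predictors(d_ref, "nope"), "unknown")
})

test_that("OLS matches the closed-form normal equations and its identities", {
  set.seed(19)
  for (i in 1:5) {
    n <- 20; k <- 3
    X <- as.data.frame(matrix(rnorm(n * k), n))
    names(X) <- paste0("v", 1:k)
    y <- rnorm(n)
    fit <- fit_ols(y, X)
    Xm <- cbind(1, as.matrix(X))
    beta_hat <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
    expect_equal(unname(fit$terms$beta), as.numeric(beta_hat),
                 tolerance = 1e-8)
    # F / R^2 / df identity
    expect_equal(fit$f_ratio,
                 (fit$r_squared / k) / ((1 - fit$r_squared) / (n - k - 1)),
                 tolerance = 1e-6)
    expect_equal(fit$terms$t, fit$terms$beta / fit$terms$sigma)
    expect_equal(fit$terms$log_worth, -log10(fit$terms$p))
  }
  # noise-free data recovers exact coefficients
  x <- 1:10
  fit2 <- suppressWarnings(fit_ols(2 * x, data.frame(x = x)))
  expect_equal(unname(fit2$terms$beta), c(0, 2), tolerance = 1e-10)
  expect_equal(fit2$r_squared, 1)
  # collinearity is an error
  expect_error(fit_ols(rnorm(10), data.frame(a = 1:10, b = 2 * (1:10))),
               "collinear")
})

test_that("tidy and glance expose the regression report", {
  fit <- fit_metric_model(d_ref, "Shape", "shape")
  td <- tidy(fit)
  expect_true(all(c("term", "beta", "sigma", "t", "p", "log_worth") %in%
                    names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 11)
  expect_s3_class(td, "tbl_df")
})

test_that("the three reference models are recovered from the design matrix", {
  fit_h <- fit_metric_model(d_ref, "TreeHeight", "height")
  co_h <- setNames(fit_h$terms$beta, fit_h$terms$term)
  expect_equal(unname(co_h["(Intercept)"]), 2.17, tolerance = 0.02)
  expect_equal(unname(co_h["B"]), -1.4, tolerance = 0.05)
  expect_equal(unname(co_h["urzyme"]), 3.2, tolerance = 0.05)
  expect_equal(unname(co_h["protozyme"]), -2.7, tolerance = 0.05)
  expect_equal(unname(co_h["B_x_protozyme"]), 1.66, tolerance = 0.05)
  expect_equal(fit_h$r_squared, 0.87, tolerance = 0.01)

  fit_s <- fit_metric_model(d_ref, "Shape", "shape")
  co_s <- setNames(fit_s$terms$beta, fit_s$terms$term)
  expect_equal(unname(co_s["(Intercept)"]), 1.37, tolerance = 0.02)
  expect_equal(unname(co_s["B"]), 0.4, tolerance = 0.05)
  expect_equal(unname(co_s["C"]), -1.08, tolerance = 0.05)
  expect_equal(unname(co_s["CP1"]), 1.56, tolerance = 0.05)
  expect_equal(unname(co_s["B_x_CP1"]), -0.57, tolerance = 0.05)

  stacked <- stack_design(d_ref)
  expect_equal(nrow(stacked), 20)
  fit_S <- fit_metric_model(stacked, "S", "support")
  co_S <- setNames(fit_S$terms$beta, fit_S$terms$term)
  expect_lt(abs(co_S[["(Intercept)"]] - 0.67), 0.02)
  expect_lt(abs(co_S[["protozyme_n"]] - 0.04), 0.01)
  expect_lt(abs(co_S[["CP1_ind"]] + 0.33), 0.01)
  expect_lt(abs(co_S[["protozyme_x_CP1"]] - 0.1), 0.01)
})

test_that("stepwise AICc search recovers planted structure and rejects noise", {
  set.seed(5)
  hits <- 0L
  for (rep in 1:10) {
    n <- 40
    X <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    y <- 1 + 2 * X$a - 1.5 * X$b + 2.5 * X$a * X$b + rnorm(n, sd = 0.3)
    sel <- stepwise_select(y, X)
    if (all(c("a", "b", "a_x_b") %in% sel$selected)) hits <- hits + 1L
  }
  expect_gte(hits, 9)

  nulls <- 0L
  for (rep in 1:10) {
    X <- tibble::tibble(a = rnorm(25), b = rnorm(25))
    y <- rnorm(25)
    sel <- stepwise_select(y, X)
    if (length(sel$selected) == 0L) nulls <- nulls + 1L
  }
  expect_gte(nulls, 6)
})

test_that("stepwise on the stacked support data selects the reference term set", {
  stacked <- stack_design(d_ref)
  X <- tibble::tibble(protozyme = stacked$A,
                      CP1 = as.integer(stacked$CP1 > 0),
                      B = stacked$B, C = stacked$C)
  sel <- stepwise_select(stacked$S, X, max_terms = 4)
  expect_true(all(c("protozyme", "CP1", "protozyme_x_CP1") %in% sel$selected))
})

test_that("cross-correlations are symmetric and flag degenerate columns", {
  toy <- tibble::tibble(Subset = letters[1:4], TreeHeight = c(1, 2, 3, 4),
                        Shape = c(2, 4, 6, 8), S_WAG = c(1, 1, 1, 1))
  cc <- cross_correlation(toy, exclude = character(0))
  expect_equal(cc$r_squared[cc$metric_a == "TreeHeight" &
                              cc$metric_b == "Shape"], 1)
  expect_true(all(is.na(cc$r_squared[cc$metric_b == "S" |
                                       cc$metric_a == "S"])))
  expect_error(cross_correlation(toy[1:2, ], exclude = character(0)),
               "3 rows")
})
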
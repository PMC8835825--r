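#' Encode design-matrix predictors under a named scheme
#'
#' Three built-in encodings reconstruct the predictor sets of the reference
#' regression models (the `urzyme` and `protozyme` predictor constructions
#' are not part of the printed design matrix and were recovered by requiring
#' the fitted equations to reproduce the tabulated responses):
#'
#' * `"height"`: `B` (numeric), `urzyme` (indicator: any A/B/C content),
#'   `protozyme` (indicator: A > 0), `B_x_protozyme`.
#' * `"shape"`: `B`, `C`, `CP1` (all numeric as tabulated; the CP1 row
#'   carries the value 2), `B_x_CP1`.
#' * `"support"`: `protozyme_n` (numeric, = A), `CP1_ind` (indicator:
#'   CP1 > 0), `protozyme_x_CP1`.
#'
#' @param rows design-matrix tibble with columns `A`, `B`, `C`, `CP1` (e.g.
#'   [reference_design_matrix()] or stacked [assemble_design_row()] output).
#' @param scheme `"height"`, `"shape"`, `"support"`, or a function taking
#'   `rows` and returning a predictor tibble.
#' @return tibble of predictors (no response, no intercept).
#' @export
encode_predictors <- function(rows, scheme) {
  if (is.function(scheme)) return(as_tibble(scheme(rows)))
  urz <- as.integer(rows$A + rows$B + rows$C > 0)
  proto <- as.integer(rows$A > 0)
  cp1i <- as.integer(rows$CP1 > 0)
  switch(scheme,
    height = tibble(B = rows$B, urzyme = urz, protozyme = proto,
                    B_x_protozyme = rows$B * proto),
    shape = tibble(B = rows$B, C = rows$C, CP1 = rows$CP1,
                   B_x_CP1 = rows$B * rows$CP1),
    support = tibble(protozyme_n = rows$A, CP1_ind = cp1i,
                     protozyme_x_CP1 = rows$A * cp1i),
    abort_input(sprintf("unknown encoding scheme '%s'", scheme)))
}

#' Ordinary least squares with the regression-report statistics
#'
#' Fits `y ~ 1 + X` and reports, per term, the coefficient, its standard
#' deviation, Student t, two-sided p on `n - k - 1` df, and the log-worth
#' (-log10 p); plus R-squared, the F-ratio and its p.
#'
#' @param y numeric response.
#' @param X predictor tibble/data frame (intercept added automatically).
#' @param response_name label for reporting.
#' @return a `mosaic_ols` object; see [tidy()] and [glance()] methods.
#' @export
fit_ols <- function(y, X, response_name = "y") {
  X <- as.data.frame(X)
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  k <- ncol(X)
  if (length(y) <= k + 1L) abort_input("need n_obs > k + 1")
  qrX <- qr(cbind(`(Intercept)` = 1, as.matrix(X)))
  if (qrX$rank < k + 1L) {
    bad <- colnames(qr.X(qrX))[-seq_len(qrX$rank)]
    abort_input(paste("rank-deficient design; collinear columns:",
                      paste(bad, collapse = ", ")))
  }
  dat <- cbind(.y = y, X)
  fit <- lm(.y ~ ., data = dat)
  sm <- summary(fit)
  ct <- sm$coefficients
  terms <- tibble(
    term = rownames(ct),
    beta = ct[, "Estimate"],
    sigma = ct[, "Std. Error"],
    t = ct[, "t value"],
    p = ct[, "Pr(>|t|)"],
    log_worth = -log10(ct[, "Pr(>|t|)"]))
  n <- length(y)
  r2 <- sm$r.squared
  f <- unname(sm$fstatistic)
  structure(list(terms = terms, r_squared = r2,
                 f_ratio = f[1], f_p = pf(f[1], f[2], f[3], lower.tail = FALSE),
                 n_obs = n, df = n - k - 1L, k = k,
                 response = response_name, lm = fit),
            class = "mosaic_ols")
}

#' @export
print.mosaic_ols <- function(x, ...) {
  cat(sprintf("Regression of %s on %d terms (n = %d)\n", x$response, x$k,
              x$n_obs))
  df <- as.data.frame(x$terms)
  df[, -1] <- lapply(df[, -1], signif, 3)
  print(df, row.names = FALSE)
  cat(sprintf("R-squared %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$r_squared, x$k, x$df, x$f_ratio, x$f_p))
  invisible(x)
}

#' @rdname fit_ols
#' @param x a `mosaic_ols` object.
#' @param ... unused.
#' @export
tidy.mosaic_ols <- function(x, ...) x$terms

#' @rdname fit_ols
#' @export
glance.mosaic_ols <- function(x, ...) {
  tibble(r_squared = x$r_squared, f_ratio = x$f_ratio, f_p = x$f_p,
         n_obs = x$n_obs, df = x$df)
}

#' Fit a metric model on a design matrix with a named scheme
#'
#' Convenience wrapper: encodes predictors and fits [fit_ols()]. For the
#' support model, pass the stacked design (see [stack_design()]).
#'
#' @param design design-matrix tibble.
#' @param response response column name (`"TreeHeight"`, `"Shape"`, `"S"`,
#'   ...).
#' @param scheme encoding scheme (see [encode_predictors()]).
#' @return a `mosaic_ols`.
#' @export
fit_metric_model <- function(design, response, scheme) {
  X <- encode_predictors(design, scheme)
  fit_ols(design[[response]], X, response_name = response)
}

#' Stack WAG and LG support observations
#'
#' Duplicates the composition columns with `S = S_WAG` and `S = S_LG`,
#' dropping subsets with a missing support value row-wise (both matrices),
#' so each retained subset contributes two observations.
#'
#' @param design design tibble with `S_WAG` and `S_LG` columns.
#' @return stacked tibble with an `S` response column and a `matrix` label.
#' @export
stack_design <- function(design) {
  complete <- !is.na(design$S_WAG) & !is.na(design$S_LG)
  d <- design[complete, , drop = FALSE]
  dplyr::bind_rows(
    dplyr::mutate(d, S = .data$S_WAG, matrix = "WAG"),
    dplyr::mutate(d, S = .data$S_LG, matrix = "LG"))
}

#' Exhaustive hierarchical model selection by AICc
#'
#' Searches all subsets of the candidate main effects plus two-way
#' interactions (an interaction enters only when both parents are present),
#' up to `max_terms` terms, and returns the minimum-AICc fit. Deterministic
#' and seed-free.
#'
#' @param y response vector.
#' @param candidates predictor tibble of main effects.
#' @param interactions include all two-way interactions (default `TRUE`).
#' @param max_terms cap on the number of non-intercept terms.
#' @return list: `fit` (the winning `mosaic_ols`, or `NULL` if the
#'   intercept-only model wins), `selected` (term names), `search` (tibble
#'   of all models visited with AICc).
#' @export
stepwise_select <- function(y, candidates, interactions = TRUE,
                            max_terms = 5) {
  candidates <- as_tibble(candidates)
  mains <- names(candidates)
  pairs <- if (interactions && length(mains) > 1) utils::combn(mains, 2, simplify = FALSE) else list()
  eval_model <- function(term_mains, term_ints) {
    X <- candidates[, term_mains, drop = FALSE]
    for (pr in term_ints) {
      X[[paste(pr, collapse = "_x_")]] <- candidates[[pr[1]]] * candidates[[pr[2]]]
    }
    k <- ncol(X)
    n <- sum(!is.na(y))
    if (n <= k + 3L) return(NULL)   # AICc needs n - (k+2) - 1 > 0
    fit <- tryCatch(fit_ols(y, X), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    rss <- sum(stats::residuals(fit$lm)^2)
    p <- k + 2L                                   # + intercept + sigma
    aic <- n * log(rss / n) + 2 * p
    list(fit = fit, aicc = aic + 2 * p * (p + 1) / (n - p - 1),
         terms = names(X))
  }
  # intercept-only baseline
  n <- sum(!is.na(y))
  rss0 <- sum((y[!is.na(y)] - mean(y, na.rm = TRUE))^2)
  best <- list(fit = NULL, aicc = n * log(rss0 / n) + 2 * 2 +
                 2 * 2 * 3 / (n - 3), terms = character(0))
  search <- list(tibble(model = "(intercept)", aicc = best$aicc))
  main_sets <- unlist(lapply(0:length(mains), function(sz)
    utils::combn(mains, sz, simplify = FALSE)), recursive = FALSE)
  for (ms in main_sets) {
    if (length(ms) == 0L) next
    ok_pairs <- Filter(function(pr) all(pr %in% ms), pairs)
    int_sets <- unlist(lapply(0:length(ok_pairs), function(sz)
      utils::combn(ok_pairs, sz, simplify = FALSE)), recursive = FALSE)
    for (is_ in int_sets) {
      if (length(ms) + length(is_) > max_terms) next
      res <- eval_model(ms, is_)
      if (is.null(res)) next
      search <- c(search, list(tibble(model = paste(res$terms, collapse = "+"),
                                      aicc = res$aicc)))
      if (res$aicc < best$aicc) best <- res
    }
  }
  list(fit = best$fit, selected = best$terms,
       search = dplyr::bind_rows(search))
}

#' Pairwise squared correlations between metric columns
#'
#' @param design design tibble.
#' @param metrics metric column names (default the three phylogenetic
#'   metrics with `S = S_WAG`).
#' @param exclude `Subset` row names to drop before correlating.
#' @return tibble (`metric_a`, `metric_b`, `r_squared`); constant columns
#'   give `NA`.
#' @export
cross_correlation <- function(design,
                              metrics = c(TreeHeight = "TreeHeight",
                                          Shape = "Shape", S = "S_WAG"),
                              exclude = "CP1") {
  d <- design[!design$Subset %in% exclude, , drop = FALSE]
  if (nrow(d) < 3L) abort_input("need at least 3 rows after exclusion")
  nm <- names(metrics) %||% metrics
  prs <- utils::combn(seq_along(metrics), 2, simplify = FALSE)
  dplyr::bind_rows(lapply(prs, function(pr) {
    xa <- d[[metrics[pr[1]]]]; xb <- d[[metrics[pr[2]]]]
    r2 <- if (sd(xa) == 0 || sd(xb) == 0) NA_real_ else cor(xa, xb)^2
    tibble(metric_a = nm[pr[1]], metric_b = nm[pr[2]], r_squared = r2)
  }))
}
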
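#' Amino-acid replacement models with discrete-gamma rate heterogeneity
#'
#' Builds a reversible 20-state substitution model from symmetric
#' exchangeabilities `s` and stationary frequencies `pi`
#' (`Q[a,b] = s[a,b] * pi[b]`, diagonal fixed so rows sum to zero, scaled to
#' one expected substitution per site), plus Yang-style mean-of-category
#' discrete-gamma site rates.
#'
#' @param name `"WAG"` or `"LG"` (bundled), or a path to a PAML-format file.
#' @param alpha gamma shape for among-site rate variation (> 0).
#' @param k number of discrete rate categories (default 4).
#' @return A `mosaic_submodel`: exchangeabilities, frequencies, normalized
#'   generator `Q`, its symmetric eigendecomposition, `alpha`, `k` and the
#'   category rates.
#' @export
substitution_model <- function(name = "WAG", alpha = 1, k = 4) {
  path <- if (file.exists(name)) name else {
    system.file("extdata", paste0(tolower(name), ".paml"), package = "mosaicphy")
  }
  if (!nzchar(path) || !file.exists(path)) {
    abort_input(sprintf("unknown model '%s'", name))
  }
  dat <- read_paml_model(path)
  gen <- build_generator(dat$s, dat$freqs)
  structure(
    c(list(name = name, alpha = alpha, k = as.integer(k),
           rates = discrete_gamma_rates(alpha, k)),
      list(s = dat$s), gen),
    class = "mosaic_submodel")
}

#' @export
print.mosaic_submodel <- function(x, ...) {
  cat(sprintf("<mosaic_submodel %s: alpha=%g, k=%d>\n", x$name, x$alpha, x$k))
  invisible(x)
}

#' Read a PAML-style amino-acid model file
#'
#' Lower-triangle exchangeabilities (19 rows) followed by a blank line and
#' the 20 stationary frequencies, residues in PAML order
#' ARNDCQEGHILKMFPSTWYV.
#'
#' @param path model file.
#' @return list with `s` (symmetric 20x20 matrix) and `freqs`.
#' @export
read_paml_model <- function(path) {
  toks <- as.numeric(scan(path, what = "", quiet = TRUE))
  if (length(toks) != 190 + 20) abort_input("malformed PAML model file")
  s <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  idx <- 1
  for (i in 2:20) for (j in 1:(i - 1)) {
    s[i, j] <- s[j, i] <- toks[idx]
    idx <- idx + 1
  }
  freqs <- toks[191:210]
  freqs <- setNames(freqs / sum(freqs), AA_ALPHABET)
  list(s = s, freqs = freqs)
}

#' Build a normalized reversible rate generator
#'
#' @param s symmetric non-negative exchangeability matrix.
#' @param freqs stationary distribution (positive, sums to 1 after
#'   renormalization).
#' @return list with `Q` (rows sum to 0, mean rate 1), `freqs`, and the
#'   eigendecomposition (`eigvec`, `eigval`) of the pi-symmetrized
#'   generator used to compute transition probabilities.
#' @export
build_generator <- function(s, freqs) {
  if (!isSymmetric(unname(s))) abort_input("exchangeabilities must be symmetric")
  if (any(freqs <= 0)) abort_input("stationary frequencies must be positive")
  freqs <- freqs / sum(freqs)
  Q <- s * rep(freqs, each = nrow(s))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))        # expected rate
  Q <- Q / mu
  sq <- sqrt(freqs)
  Sy <- diag(sq) %*% Q %*% diag(1 / sq)
  Sy <- (Sy + t(Sy)) / 2             # symmetrize numerically
  e <- eigen(Sy, symmetric = TRUE)
  list(Q = Q, freqs = freqs, eigvec = e$vectors, eigval = e$values)
}

#' Discrete-gamma rate multipliers (mean-of-category)
#'
#' Rates are the conditional means of a mean-one gamma(`alpha`) distribution
#' over its `k` equal-probability quantile bins (Yang's discretization),
#' returned in ascending order with mean exactly 1.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories (>= 1).
#' @return numeric vector of `k` rates.
#' @export
discrete_gamma_rates <- function(alpha, k = 4) {
  if (alpha <= 0) abort_input("alpha must be > 0")
  if (k < 1) abort_input("k must be >= 1")
  if (k == 1L) return(1)
  b <- qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  p_upper <- pgamma(b, shape = alpha + 1, rate = alpha)
  rates <- k * diff(c(0, p_upper, 1))
  rates / mean(rates) * 1   # guard against roundoff; mean is 1 analytically
}

#' Transition probability matrices per rate category
#'
#' `P_c = exp(Q * r_c * t)` for each category rate `r_c`.
#'
#' @param model a [substitution_model()].
#' @param branch_length expected substitutions per site (>= 0).
#' @return list of `k` stochastic 20x20 matrices.
#' @export
transition_probs <- function(model, branch_length) {
  if (branch_length < 0) abort_input("branch length must be >= 0")
  sq <- sqrt(model$freqs)
  lapply(model$rates, function(r) {
    E <- model$eigvec %*% (exp(model$eigval * r * branch_length) * t(model$eigvec))
    P <- (1 / sq) * E %*% diag(sq)
    P[P < 0] <- 0
    dimnames(P) <- list(AA_ALPHABET, AA_ALPHABET)
    P / rowSums(P)
  })
}
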
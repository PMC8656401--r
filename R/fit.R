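#' Empirical state distribution of a binary state sequence
#'
#' Tabulates the empirical probability \eqn{p(\sigma) = n_\sigma / T} of every
#' state code and the frequency-based energy \eqn{-\log p(\sigma)} for the
#' observed states (defined up to an additive constant). Unobserved states get
#' `NA` energy rather than `Inf`: the landscape is always built from model
#' energies, and the empirical energies serve as a diagnostic overlay.
#'
#' @param states Integer vector of state codes, or a data frame with a
#'   `state` column (e.g. the output of [binarize()]).
#' @param n Number of channels. Required when it cannot be recovered from
#'   `states` (codes alone do not determine `n`).
#' @return A tibble with columns `state`, `count`, `probability`, `energy`
#'   covering all `2^n` codes, with attribute `kind = "empirical"`.
#' @export
empirical_distribution <- function(states, n) {
  s <- state_codes(states)
  n <- check_n(n)
  if (length(s) < 1) abort("need at least one timepoint.")
  if (any(s < 0) || any(s >= 2^n)) abort("state codes out of range for given n.")
  counts <- tabulate(s + 1L, nbins = 2^n)
  p <- counts / length(s)
  out <- tibble(
    state = 0:(2^n - 1),
    count = as.integer(counts),
    probability = p,
    energy = ifelse(p > 0, -log(p), NA_real_)
  )
  attr(out, "kind") <- "empirical"
  out
}

state_codes <- function(states) {
  if (is.data.frame(states)) {
    if (!"state" %in% names(states)) abort("data frame input must have a `state` column.")
    return(as.integer(states$state))
  }
  as.integer(states)
}

# Weighted first and second moments of the state distribution given
# probabilities/weights w over all 2^n codes. Returns list(m1, M2) where
# M2 = sum_sigma w(sigma) sigma sigma^T (diagonal = m1).
state_moments <- function(S, w) {
  m1 <- as.numeric(crossprod(S, w))
  M2 <- crossprod(S, S * w)
  list(m1 = m1, M2 = M2)
}

#' Fit the pairwise maximum entropy model by maximum likelihood
#'
#' Maximizes the average log-likelihood of a binary state sequence under the
#' Boltzmann distribution of an [ising_model()]. The gradient is the exact
#' moment gap (\eqn{\partial\ell/\partial h_i =
#' \langle\sigma_i\rangle_{data} - \langle\sigma_i\rangle_{model}} and the
#' pairwise analogue for `J`), with model moments computed by full
#' enumeration of the `2^n` states. Optimization is damped Newton on the
#' concave likelihood — the Hessian is the exact covariance matrix of the
#' sufficient statistics, also by enumeration — with a gradient-ascent
#' fallback step whenever the Newton system is ill-conditioned; iteration
#' stops once the largest absolute moment gap falls below `tol`. Because
#' Newton converges quadratically, the reported final gap typically
#' undershoots `tol` by several orders of magnitude. The likelihood is
#' concave, so the converged model is the unique moment-matching maximum
#' entropy solution.
#'
#' @param x Either a state-code vector / data frame with a `state` column, or
#'   a distribution table with `state` and `probability` columns (e.g.
#'   [empirical_distribution()] or [boltzmann_distribution()] output) to fit
#'   to exactly known probabilities.
#' @param n Number of channels; inferred from a full distribution table.
#' @param tol Convergence tolerance on the largest absolute moment gap.
#' @param max_iter Maximum gradient-ascent iterations.
#' @param step Step size of the gradient-ascent fallback used when the
#'   Newton system cannot be solved; Newton steps themselves use a halving
#'   line search starting at 1.
#' @param roi_names Optional channel names for the fitted model.
#' @return An object of class `pmem_fit`: a list with `model`
#'   ([ising_model()]), `iterations`, `max_moment_gap`,
#'   `log_likelihood_per_sample`, `kl_divergence` (empirical vs model), and
#'   `converged`. Supports [generics::tidy()] and [generics::glance()].
#' @examples
#' m <- ising_model(c(0, 0), matrix(c(0, log(3), log(3), 0), 2))
#' fit <- fit_pmem(boltzmann_distribution(m))
#' glance(fit)
#' @export
fit_pmem <- function(x, n = NULL, tol = 1e-6, max_iter = 20000L, step = 0.2,
                     roi_names = NULL) {
  if (is.data.frame(x) && "probability" %in% names(x)) {
    if (is.null(n)) n <- as.integer(round(log2(nrow(x))))
    n <- check_n(n)
    if (nrow(x) != 2^n) abort("distribution table must cover all 2^n states.")
    w <- x$probability[order(x$state)]
    if (abs(sum(w) - 1) > 1e-8 || any(w < 0)) abort("probabilities must be nonnegative and sum to 1.")
  } else {
    s <- state_codes(x)
    if (is.null(n)) abort("`n` must be supplied with raw state codes.")
    n <- check_n(n)
    w <- tabulate(s + 1L, nbins = 2^n) / length(s)
  }

  S <- state_matrix(n)
  target <- state_moments(S, w)
  if (any(target$m1 <= 0) || any(target$m1 >= 1)) {
    bad <- which(target$m1 <= 0 | target$m1 >= 1)
    abort(sprintf(
      "channel(s) %s are never or always active in the data; their h would diverge and the MLE does not exist.",
      paste(bad, collapse = ", ")
    ))
  }

  # feature matrix: sigma_i, then sigma_i * sigma_j over the upper triangle;
  # theta = (h, J_upper) parameterizes E = -F theta
  up <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  FF <- cbind(S, S[, up[, 1], drop = FALSE] * S[, up[, 2], drop = FALSE])
  d <- ncol(FF)
  target_mu <- as.numeric(crossprod(FF, w))

  theta <- c(stats::qlogis(target$m1), rep(0, d - n))
  ll_of <- function(theta) {
    e <- as.numeric(-FF %*% theta)
    lp <- -e - logsumexp(-e)
    list(lp = lp, ll = sum(w * lp))
  }

  cur <- ll_of(theta)
  gap <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p <- exp(cur$lp)
    mu <- as.numeric(crossprod(FF, p))
    g <- target_mu - mu
    gap <- max(abs(g))
    if (gap < tol) break
    H <- crossprod(FF, FF * p) - tcrossprod(mu)
    delta <- tryCatch(
      solve(H + diag(1e-10, d), g),
      error = function(e) NULL
    )
    if (is.null(delta) || !all(is.finite(delta))) delta <- step * g
    stp <- 1
    repeat {
      cand <- ll_of(theta + stp * delta)
      if (cand$ll >= cur$ll || stp < 1e-12) break
      stp <- stp / 2
    }
    theta <- theta + stp * delta
    cur <- cand
  }

  converged <- gap < tol
  if (!converged) {
    abort(sprintf(
      "fit_pmem did not converge in %d iterations (last moment gap %.3g); the data may sit near the boundary of the model family.",
      max_iter, gap
    ))
  }

  h <- theta[seq_len(n)]
  J <- matrix(0, n, n)
  J[cbind(up[, 1], up[, 2])] <- theta[-seq_len(n)]
  J <- J + t(J)
  model <- ising_model(h, J, roi_names)
  kl <- sum(ifelse(w > 0, w * (log(w) - cur$lp), 0))
  structure(
    list(
      model = model,
      iterations = iter,
      max_moment_gap = gap,
      log_likelihood_per_sample = cur$ll,
      kl_divergence = kl,
      converged = converged
    ),
    class = "pmem_fit"
  )
}

#' @export
print.pmem_fit <- function(x, ...) {
  cat(sprintf(
    "<pmem_fit> n = %d; %d iterations; moment gap %.2e; KL(empirical || model) = %.4g\n",
    x$model$n, x$iterations, x$max_moment_gap, x$kl_divergence
  ))
  invisible(x)
}

#' Goodness-of-fit diagnostics for a fitted model
#'
#' Compares a model's Boltzmann distribution against an empirical state
#' distribution: Kullback-Leibler divergence (with the `0 log 0 = 0`
#' convention), per-sample log-likelihood, and the largest absolute gap
#' between empirical and model first/second moments.
#'
#' @param model An [ising_model()].
#' @param empirical An [empirical_distribution()] table over the same `n`.
#' @return A one-row tibble with `kl_divergence`,
#'   `log_likelihood_per_sample`, `max_moment_gap`.
#' @export
fit_quality <- function(model, empirical) {
  stopifnot(inherits(model, "ising_model"))
  n <- model$n
  if (nrow(empirical) != 2^n) abort("empirical table does not match model size.")
  w <- empirical$probability[order(empirical$state)]
  S <- state_matrix(n)
  e <- state_energies(model)
  lp <- -e - logsumexp(-e)
  emp <- state_moments(S, w)
  mod <- state_moments(S, exp(lp))
  gapJ <- emp$M2 - mod$M2
  diag(gapJ) <- 0
  tibble(
    kl_divergence = sum(ifelse(w > 0, w * (log(w) - lp), 0)),
    log_likelihood_per_sample = sum(w * lp),
    max_moment_gap = max(abs(emp$m1 - mod$m1), abs(gapJ))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted pairwise maximum entropy model
#'
#' @param x A `pmem_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: columns `term` (`h[roi]` or
#'   `J[roi_i,roi_j]`, upper triangle only), `estimate`.
#' @export
tidy.pmem_fit <- function(x, ...) {
  m <- x$model
  pairs <- which(upper.tri(m$J), arr.ind = TRUE)
  bind_rows(
    tibble(term = paste0("h[", m$roi_names, "]"), estimate = unname(m$h)),
    tibble(
      term = paste0("J[", m$roi_names[pairs[, 1]], ",", m$roi_names[pairs[, 2]], "]"),
      estimate = m$J[pairs]
    )
  )
}

#' @rdname tidy.pmem_fit
#' @export
glance.pmem_fit <- function(x, ...) {
  tibble(
    n_channels = x$model$n,
    iterations = x$iterations,
    max_moment_gap = x$max_moment_gap,
    log_likelihood_per_sample = x$log_likelihood_per_sample,
    kl_divergence = x$kl_divergence,
    converged = x$converged
  )
}
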
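#' Pairwise maximum entropy (Ising) model
#'
#' The pairwise maximum entropy model (P-MEM) assigns each binary activation
#' pattern \eqn{\sigma \in \{0,1\}^n} the quadratic energy
#' \deqn{E(\sigma) = -\sum_i h_i \sigma_i - \tfrac{1}{2}\sum_{i \ne j} J_{ij} \sigma_i \sigma_j}
#' and the Boltzmann probability \eqn{P(\sigma) \propto \exp[-E(\sigma)]}.
#' `h` captures per-channel activity, the symmetric zero-diagonal `J` captures
#' pairwise interaction; lower energy means a more probable state. Note the
#' \eqn{\{0,1\}} activation convention (not \eqn{\pm 1} spins); use
#' [spin_to_activation()] to translate parameters fitted under the spin
#' convention.
#'
#' @param h Numeric vector of length `n` of activity terms.
#' @param J `n x n` symmetric numeric matrix of pairwise interactions with a
#'   zero diagonal.
#' @param roi_names Optional character vector of channel names.
#' @return An object of class `ising_model` with elements `h`, `J`,
#'   `roi_names`, `n`.
#' @examples
#' m <- ising_model(h = c(0, 0), J = matrix(c(0, log(3), log(3), 0), 2))
#' boltzmann_distribution(m)
#' @export
ising_model <- function(h, J, roi_names = NULL) {
  h <- as.numeric(h)
  J <- as.matrix(J)
  n <- length(h)
  if (!all(dim(J) == n)) abort("`J` must be an n x n matrix matching length(h).")
  if (!all(is.finite(h)) || !all(is.finite(J))) abort("model parameters must be finite.")
  if (!isTRUE(all.equal(J, t(J), tolerance = 1e-10))) abort("`J` must be symmetric.")
  if (any(abs(diag(J)) > 1e-12)) abort("`J` must have a zero diagonal.")
  J <- (J + t(J)) / 2
  diag(J) <- 0
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(n))
  if (length(roi_names) != n || anyDuplicated(roi_names)) {
    abort("`roi_names` must be n unique names.")
  }
  dimnames(J) <- list(roi_names, roi_names)
  structure(
    list(h = setNames(h, roi_names), J = J, roi_names = roi_names, n = as.integer(n)),
    class = "ising_model"
  )
}

#' @export
print.ising_model <- function(x, ...) {
  cat(sprintf("<ising_model> %d channels: %s\n", x$n, paste(x$roi_names, collapse = ", ")))
  cat("h:", format(unname(x$h), digits = 4), "\n")
  cat("mean |J| off-diagonal:", format(mean(abs(off_diagonal(x$J))), digits = 4), "\n")
  invisible(x)
}

#' Energy of specific states under a model
#'
#' @param model An [ising_model()].
#' @param states Integer state codes (see [encode_state()]).
#' @return Numeric vector of energies.
#' @export
model_energy <- function(model, states) {
  stopifnot(inherits(model, "ising_model"))
  S <- decode_state(states, model$n)
  if (!is.matrix(S)) S <- matrix(S, nrow = 1)
  as.numeric(-S %*% model$h - 0.5 * rowSums((S %*% model$J) * S))
}

# Energies of all 2^n states (index = code + 1).
state_energies <- function(model) {
  S <- state_matrix(model$n)
  as.numeric(-S %*% model$h - 0.5 * rowSums((S %*% model$J) * S))
}

#' Exact Boltzmann distribution over all states
#'
#' Enumerates all `2^n` states and returns model energies together with the
#' normalized Boltzmann probabilities
#' \eqn{P(\sigma) = \exp[-E(\sigma)] / \sum_{\sigma'} \exp[-E(\sigma')]},
#' computed with log-sum-exp stabilization.
#'
#' @inheritParams model_energy
#' @return A tibble with columns `state`, `energy`, `probability` (one row per
#'   state code, in code order), carrying attribute `kind = "model"`.
#' @export
boltzmann_distribution <- function(model) {
  stopifnot(inherits(model, "ising_model"))
  e <- state_energies(model)
  if (!all(is.finite(e))) abort("non-finite state energies; check model parameters.")
  lp <- -e - logsumexp(-e)
  out <- tibble(state = 0:(2^model$n - 1), energy = e, probability = exp(lp))
  attr(out, "kind") <- "model"
  out
}

#' Convert between spin and activation parameter conventions
#'
#' Much of the Ising literature writes the energy over spins
#' \eqn{s \in \{-1,+1\}} with fields `b` and couplings `K`. These helpers
#' translate exactly (up to an additive energy constant) to and from the
#' \eqn{\{0,1\}} activation convention used here, via \eqn{s = 2\sigma - 1}:
#' `h = 2 b - 2 rowSums(K)`, `J = 4 K`.
#'
#' @param b Spin-convention field vector.
#' @param K Spin-convention symmetric coupling matrix, zero diagonal.
#' @return For `spin_to_activation`, a list with `h` and `J`; for
#'   `activation_to_spin`, a list with `b` and `K`.
#' @export
spin_to_activation <- function(b, K) {
  K <- as.matrix(K)
  diag(K) <- 0
  list(h = 2 * as.numeric(b) - 2 * rowSums(K), J = 4 * K)
}

#' @rdname spin_to_activation
#' @param h,J Activation-convention parameters.
#' @export
activation_to_spin <- function(h, J) {
  J <- as.matrix(J)
  diag(J) <- 0
  K <- J / 4
  list(b = (as.numeric(h) + rowSums(K) * 2) / 2, K = K)
}
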
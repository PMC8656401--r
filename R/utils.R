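#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols across n
#' @importFrom stats setNames
NULL

# Enumeration guard: landscapes are tabulated over all 2^n states, so n is
# capped (networks of interest have 5-9 ROIs).
n_guard <- function() getOption("elandscape.n_guard", 20L)

check_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("`n` must be a single positive integer.")
  }
  if (n > n_guard()) {
    abort(sprintf(
      "n = %d exceeds the enumeration guard (%d states would be tabulated); refusing. Set options(elandscape.n_guard = ) to raise it.",
      n, n_guard()
    ))
  }
  as.integer(n)
}

#' Derive a child seed from a run seed
#'
#' All randomness in the package flows from one integer seed; independent
#' stages draw child seeds through this fixed multiplicative-congruential
#' scheme so cohorts are byte-reproducible while stages stay decoupled.
#'
#' @param seed Integer run seed.
#' @param k Integer stream index (stage/participant counter).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
split_seed <- function(seed, k) {
  m <- 2147483647
  x <- (as.double(seed) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + (as.double(k) * 69621)) %% m
  x <- (x * 16807) %% m
  as.integer(x)
}

# Evaluate expr with a locally set RNG seed, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

off_diagonal <- function(m) m[row(m) != col(m)]
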
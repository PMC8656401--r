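# Independent brute-force oracles for landscape operations. These deliberately
# use a different representation (explicit bit vectors and loops) from the
# package's vectorized code paths.

oracle_bits <- function(code, n) {
  b <- integer(n)
  for (i in seq_len(n)) {
    b[i] <- code %% 2
    code <- code %/% 2
  }
  b
}

oracle_code <- function(bits) {
  s <- 0
  for (i in seq_along(bits)) s <- s + bits[i] * 2^(i - 1)
  as.integer(s)
}

oracle_neighbors <- function(code, n) {
  vapply(seq_len(n), function(i) {
    b <- oracle_bits(code, n)
    b[i] <- 1 - b[i]
    oracle_code(b)
  }, integer(1))
}

# Local minima by exhaustive neighbour comparison (strict; code tie-break).
oracle_basins <- function(e) {
  n <- as.integer(log2(length(e)))
  out <- integer(0)
  for (s in 0:(length(e) - 1)) {
    ok <- TRUE
    for (t in oracle_neighbors(s, n)) {
      if (e[t + 1] < e[s + 1] || (e[t + 1] == e[s + 1] && t < s)) {
        ok <- FALSE
        break
      }
    }
    if (ok) out <- c(out, s)
  }
  out
}

# Steepest-descent assignment with memoization, recursive.
oracle_assignment <- function(e) {
  n <- as.integer(log2(length(e)))
  memo <- rep(NA_integer_, length(e))
  descend <- function(s) {
    if (!is.na(memo[s + 1])) {
      return(memo[s + 1])
    }
    nbs <- oracle_neighbors(s, n)
    best <- nbs[1]
    for (t in nbs[-1]) {
      if (e[t + 1] < e[best + 1] || (e[t + 1] == e[best + 1] && t < best)) best <- t
    }
    res <- if (e[best + 1] < e[s + 1] || (e[best + 1] == e[s + 1] && best < s)) {
      descend(best)
    } else {
      s
    }
    memo[s + 1] <<- res
    res
  }
  vapply(0:(length(e) - 1), descend, integer(1))
}

# Minimax path cost between two states over all simple paths on the
# hypercube, by depth-first search with pruning.
oracle_minimax <- function(e, from, to) {
  n <- as.integer(log2(length(e)))
  best <- Inf
  visited <- rep(FALSE, length(e))
  dfs <- function(s, cost) {
    cost <- max(cost, e[s + 1])
    if (cost >= best) {
      return(invisible(NULL))
    }
    if (s == to) {
      best <<- cost
      return(invisible(NULL))
    }
    visited[s + 1] <<- TRUE
    for (t in oracle_neighbors(s, n)) {
      if (!visited[t + 1]) dfs(t, cost)
    }
    visited[s + 1] <<- FALSE
    invisible(NULL)
  }
  dfs(from, -Inf)
  best
}

random_landscape <- function(n, seed) {
  set.seed(seed)
  stats::rnorm(2^n)
}

# Fast two-basin planted fixture shared across tests.
planted6 <- function() planted_model(c(1, 1, 1, 0, 0, 0), coupling_strength = 1.2, field_strength = 0.05)
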
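#' Find basin states of an energy landscape
#'
#' A basin state is a state whose energy is lower than that of all `n`
#' single-flip neighbours (states differing in exactly one channel). Ties are
#' broken deterministically by state code: a state tied with a neighbour
#' counts as the basin only if its code is lower, so even a perfectly flat
#' landscape yields exactly one basin (code 0).
#'
#' @param energies Either a numeric vector of length `2^n` (energy of state
#'   code `k` at index `k + 1`), a model-kind energy table (see
#'   [boltzmann_distribution()]), or an [ising_model()].
#' @return Sorted integer vector of basin state codes.
#' @export
find_basins <- function(energies) {
  e <- energy_vector(energies)
  n <- as.integer(round(log2(length(e))))
  nb <- neighbor_matrix(n)
  codes <- 0:(2^n - 1)
  is_basin <- rep(TRUE, 2^n)
  for (j in seq_len(n)) {
    en <- e[nb[, j] + 1L]
    ok <- e < en | (e == en & codes < nb[, j])
    is_basin <- is_basin & ok
  }
  codes[is_basin]
}

energy_vector <- function(energies) {
  if (inherits(energies, "ising_model")) {
    e <- state_energies(energies)
  } else if (is.data.frame(energies)) {
    if (!all(c("state", "energy") %in% names(energies))) {
      abort("energy table needs `state` and `energy` columns.")
    }
    e <- energies$energy[order(energies$state)]
  } else {
    e <- as.numeric(energies)
  }
  n <- round(log2(length(e)))
  if (2^n != length(e)) abort("energy vector length must be a power of two.")
  if (!all(is.finite(e))) {
    abort("all state energies must be finite; build the landscape from model energies, not empirical ones.")
  }
  e
}

#' Map the full energy landscape of a model
#'
#' Enumerates all `2^n` states of the model (or energy table), finds the basin
#' states, assigns every state to a basin by steepest descent (repeatedly move
#' to the lowest-energy single-flip neighbour until a basin is reached; ties
#' by lower state code), computes the pairwise saddle energies between basins
#' by minimax-path search, and marks the two lowest-energy basins as major.
#'
#' @inheritParams find_basins
#' @return An object of class `energy_landscape`: a list with
#' \describe{
#'   \item{states}{tibble `state`, `energy`, `basin` (assigned basin code) for
#'     all `2^n` states.}
#'   \item{basins}{tibble `basin`, `energy`, `size`, `fraction`, `major`,
#'     sorted by energy ascending.}
#'   \item{saddle}{symmetric basin-by-basin matrix of minimax path energies
#'     (`NULL` for a single-basin landscape).}
#'   \item{n}{channel count.}
#' }
#' Supports [tidy()] (basin table) and [autoplot()].
#' @examples
#' e <- c(-1, 0.5, 0.7, -0.8) # states 00, 01, 10, 11
#' ls <- energy_landscape(e)
#' ls$basins
#' @export
energy_landscape <- function(energies) {
  e <- energy_vector(energies)
  n <- as.integer(round(log2(length(e))))
  basins <- find_basins(e)
  assignment <- assign_to_basins(e, basins)

  sizes <- table(factor(assignment, levels = basins))
  btab <- tibble(
    basin = basins,
    energy = e[basins + 1L],
    size = as.integer(sizes),
    fraction = as.integer(sizes) / 2^n
  ) |>
    arrange(.data$energy, .data$basin)
  btab$major <- seq_len(nrow(btab)) <= min(2L, nrow(btab))

  saddle <- if (length(basins) >= 2) saddle_energies(e, basins) else NULL

  structure(
    list(
      states = tibble(state = 0:(2^n - 1), energy = e, basin = assignment),
      basins = btab,
      saddle = saddle,
      n = n
    ),
    class = "energy_landscape"
  )
}

#' Steepest-descent basin assignment
#'
#' From each state, repeatedly move to the single-flip neighbour with the
#' lowest energy (ties by lower code) while that neighbour improves on the
#' current state; the fixed point is the assigned basin. States are processed
#' in increasing (energy, code) order so each descent step lands on an
#' already-assigned state.
#'
#' @param energies Energy vector/table/model as in [find_basins()].
#' @param basins Optional precomputed basin codes.
#' @return Integer vector of length `2^n`: assigned basin code per state.
#' @export
assign_to_basins <- function(energies, basins = NULL) {
  e <- energy_vector(energies)
  n <- as.integer(round(log2(length(e))))
  if (is.null(basins)) basins <- find_basins(e)
  nb <- neighbor_matrix(n)
  assignment <- rep(NA_integer_, 2^n)
  assignment[basins + 1L] <- basins
  ord <- order(e, 0:(2^n - 1))
  for (s1 in ord) {
    if (!is.na(assignment[s1])) next
    s <- s1 - 1L
    nbs <- nb[s1, ]
    en <- e[nbs + 1L]
    # lexicographic min over (energy, code): the steepest-descent target
    best <- nbs[order(en, nbs)][1]
    stopifnot(e[best + 1L] < e[s1] || (e[best + 1L] == e[s1] && best < s))
    assignment[s1] <- assignment[best + 1L]
  }
  assignment
}

#' Minimax saddle energies between basins
#'
#' The saddle between two basins is the lowest achievable "highest energy en
#' route": over all paths on the n-hypercube graph (single-flip moves), the
#' minimum of the maximum state energy along the path, endpoints included.
#' Computed by Dijkstra's algorithm with the widest-path relaxation
#' `new_cost = max(cost_so_far, E(neighbor))`. The one-way energy barrier out
#' of basin `a` towards `b` is `saddle(a, b) - E(a)` (asymmetric).
#'
#' @inheritParams assign_to_basins
#' @param basins Basin codes (at least 2).
#' @return Symmetric numeric matrix with dimnames the basin codes;
#'   `saddle[a, a] = E(a)`.
#' @export
saddle_energies <- function(energies, basins = NULL) {
  e <- energy_vector(energies)
  n <- as.integer(round(log2(length(e))))
  if (is.null(basins)) basins <- find_basins(e)
  if (length(basins) < 2) {
    warn("fewer than two basins; returning an empty saddle matrix.")
    return(matrix(numeric(0), 0, 0))
  }
  nb <- neighbor_matrix(n)
  k <- length(basins)
  saddle <- matrix(NA_real_, k, k, dimnames = list(basins, basins))
  for (a in seq_len(k)) {
    src <- basins[a]
    dist <- rep(Inf, 2^n)
    done <- rep(FALSE, 2^n)
    dist[src + 1L] <- e[src + 1L]
    repeat {
      u <- which.min(ifelse(done, Inf, dist))
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      for (v in nb[u, ] + 1L) {
        cand <- max(dist[u], e[v])
        if (cand < dist[v]) dist[v] <- cand
      }
      if (all(done)) break
    }
    saddle[a, ] <- dist[basins + 1L]
  }
  # numerically symmetric by construction; enforce exactly
  (saddle + t(saddle)) / 2
}

#' One-way energy barriers between basins
#'
#' @param landscape An [energy_landscape()].
#' @return A tibble `from`, `to`, `saddle`, `barrier` with
#'   `barrier = saddle - E(from)` for every ordered basin pair.
#' @export
basin_barriers <- function(landscape) {
  stopifnot(inherits(landscape, "energy_landscape"))
  if (is.null(landscape$saddle)) {
    return(tibble(from = integer(), to = integer(), saddle = numeric(), barrier = numeric()))
  }
  b <- as.integer(rownames(landscape$saddle))
  eb <- setNames(landscape$basins$energy, landscape$basins$basin)
  grid <- expand.grid(from = b, to = b)
  grid <- grid[grid$from != grid$to, ]
  tibble(
    from = grid$from,
    to = grid$to,
    saddle = landscape$saddle[cbind(match(grid$from, b), match(grid$to, b))],
    barrier = landscape$saddle[cbind(match(grid$from, b), match(grid$to, b))] -
      unname(eb[as.character(grid$from)])
  )
}

#' Major basin states of a landscape
#'
#' The two lowest-energy basins (ties broken by lower state code) are the
#' major basins; all timepoint-level transition scores are defined relative
#' to them and their attraction clusters.
#'
#' @param landscape An [energy_landscape()].
#' @return Integer vector of 1 or 2 major basin codes, deepest first.
#' @export
major_basins <- function(landscape) {
  stopifnot(inherits(landscape, "energy_landscape"))
  landscape$basins$basin[landscape$basins$major]
}

#' Disconnectivity dendrogram of the basins
#'
#' Single-linkage agglomeration of basins on the saddle-energy matrix: the
#' two clusters joined by the lowest saddle merge first, at a height equal to
#' that saddle. Because minimax saddles satisfy the ultrametric-like
#' inequality `saddle(a,c) <= max(saddle(a,b), saddle(b,c))`, single linkage
#' reproduces the disconnectivity-graph merge structure exactly.
#'
#' @param landscape An [energy_landscape()] with at least two basins.
#' @return An object of class `basin_dendrogram`: list with `hclust` (the
#'   merge tree; heights are saddle energies), `labels` (basin codes as
#'   character), and `basin_energies`. Export with [dendrogram_newick()],
#'   plot with [autoplot()].
#' @export
build_dendrogram <- function(landscape) {
  stopifnot(inherits(landscape, "energy_landscape"))
  if (is.null(landscape$saddle) || nrow(landscape$saddle) < 2) {
    abort("dendrogram needs at least two basins.")
  }
  s <- landscape$saddle
  hc <- stats::hclust(stats::as.dist(s), method = "single")
  hc$labels <- rownames(s)
  b <- landscape$basins
  structure(
    list(
      hclust = hc,
      labels = rownames(s),
      basin_energies = setNames(b$energy, as.character(b$basin))
    ),
    class = "basin_dendrogram"
  )
}

#' Newick serialization of a basin dendrogram
#'
#' Leaves are basin state codes; each branch length is the energy climbed to
#' reach the parent merge level (merge saddle minus the child's level, where
#' a leaf's level is its basin energy).
#'
#' @param dend A [build_dendrogram()] result.
#' @return A single Newick string (terminated by `;`).
#' @export
dendrogram_newick <- function(dend) {
  stopifnot(inherits(dend, "basin_dendrogram"))
  hc <- dend$hclust
  leaf_level <- dend$basin_energies
  render <- function(idx) {
    # idx: row of hc$merge; negative entries are leaves
    node <- function(child, parent_h) {
      if (child < 0) {
        lab <- hc$labels[-child]
        sprintf("S%s:%.10g", lab, parent_h - leaf_level[[lab]])
      } else {
        sprintf("%s:%.10g", render(child), parent_h - hc$height[child])
      }
    }
    h <- hc$height[idx]
    sprintf("(%s,%s)", node(hc$merge[idx, 1], h), node(hc$merge[idx, 2], h))
  }
  paste0(render(nrow(hc$merge)), ";")
}

#' Concentric-circle landscape profile of a basin cluster
#'
#' Describes the shape of one basin's attraction cluster: states of the
#' cluster are grouped on concentric circles by Hamming distance (radius)
#' from the basin state, and the depth of each circle is the lowest energy
#' among its states. Radius 0 is the basin itself; `depth(0) < depth(1)`
#' always holds because the basin is a strict local minimum.
#'
#' @param landscape An [energy_landscape()].
#' @param basin A basin state code of `landscape`.
#' @return A tibble with `radius`, `depth`, `n_states`.
#' @export
landscape_profile <- function(landscape, basin) {
  stopifnot(inherits(landscape, "energy_landscape"))
  if (!basin %in% landscape$basins$basin) abort("`basin` is not a basin of this landscape.")
  cl <- landscape$states |> filter(.data$basin == !!basin)
  cl |>
    mutate(radius = hamming_to(.data$state, !!basin, landscape$n)) |>
    group_by(.data$radius) |>
    summarise(depth = min(.data$energy), n_states = dplyr::n(), .groups = "drop") |>
    arrange(.data$radius)
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf(
    "<energy_landscape> n = %d (%d states), %d basin(s)\n",
    x$n, 2^x$n, nrow(x$basins)
  ))
  print(x$basins)
  invisible(x)
}

#' Tidy the basin table of a landscape
#'
#' @param x An `energy_landscape`.
#' @param ... Unused.
#' @return The basin tibble (`basin`, `energy`, `size`, `fraction`, `major`).
#' @export
tidy.energy_landscape <- function(x, ...) x$basins

#' @rdname tidy.energy_landscape
#' @export
glance.energy_landscape <- function(x, ...) {
  tibble(
    n_channels = x$n,
    n_basins = nrow(x$basins),
    deepest_energy = min(x$basins$energy),
    major_fraction = sum(x$basins$fraction[x$basins$major])
  )
}
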
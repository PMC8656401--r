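#' Construct a planted two-basin Ising model
#'
#' Builds a model whose two lowest-energy states are a chosen activation
#' pattern and its bitwise complement — the antisynchronized major-basin pair
#' characteristic of resting-state landscapes. The couplings store the
#' pattern Hopfield-style in spin space (`K = coupling_strength *
#' outer(xi, xi) / n` with `xi = 2 * pattern - 1`) and a small spin field
#' `field_strength * xi` breaks the pattern/complement degeneracy so the
#' pattern itself is strictly deepest; parameters are then translated exactly
#' to the `{0,1}` activation convention of [ising_model()]. The construction
#' is verified by full enumeration: if the two planted states are not the two
#' lowest-energy states the function errors, signalling that
#' `coupling_strength` is too weak relative to `field_strength`.
#'
#' @param pattern 0/1 vector: the intended deep-basin activation pattern.
#' @param coupling_strength Positive scalar; larger values deepen the two
#'   planted basins relative to the rest of the landscape.
#' @param field_strength Scalar controlling the energy split between pattern
#'   (deeper) and complement; small relative to `coupling_strength`.
#' @param roi_names Optional channel names.
#' @return An [ising_model()] with attribute `pattern`.
#' @examples
#' m <- planted_model(c(1, 1, 1, 0, 0, 0), coupling_strength = 1.2)
#' head(dplyr::arrange(boltzmann_distribution(m), energy), 2)
#' @export
planted_model <- function(pattern, coupling_strength = 1.2, field_strength = 0.05,
                          roi_names = NULL) {
  if (!all(pattern %in% c(0, 1))) abort("`pattern` must be a 0/1 vector.")
  n <- check_n(length(pattern))
  if (n < 2) abort("need at least two channels.")
  if (!is.numeric(coupling_strength) || coupling_strength <= 0) {
    abort("`coupling_strength` must be > 0 (zero coupling gives a flat landscape with no planted minima).")
  }
  xi <- 2 * pattern - 1
  K <- coupling_strength * outer(xi, xi) / n
  diag(K) <- 0
  par <- spin_to_activation(field_strength * xi, K)
  model <- ising_model(par$h, par$J, roi_names)

  e <- state_energies(model)
  target <- sort(c(encode_state(pattern), encode_state(1 - pattern)))
  lowest2 <- sort(order(e)[1:2] - 1L)
  if (!identical(as.integer(target), as.integer(lowest2)) ||
      sort(e)[3] - sort(e)[2] < 1e-9) {
    abort(paste(
      "the planted pattern and its complement are not the two uniquely lowest-energy states;",
      "raise `coupling_strength` relative to `field_strength`."
    ))
  }
  attr(model, "pattern") <- as.integer(pattern)
  model
}

#' Sample binary state sequences from a model
#'
#' `sampler = "exact"` draws i.i.d. states from the fully enumerated
#' Boltzmann distribution. `sampler = "metropolis"` runs a single-flip
#' Metropolis chain, giving temporally correlated sequences like real
#' resting-state dynamics; by default it discards a burn-in of `10 * 2^n`
#' flip attempts and records one state per `n` flip attempts.
#'
#' @param model An [ising_model()].
#' @param t_len Number of timepoints to return.
#' @param sampler `"exact"` or `"metropolis"`.
#' @param seed Integer seed; the same seed and arguments reproduce the
#'   sequence exactly.
#' @param burn_in,thin Metropolis chain controls (flip attempts).
#' @return A tibble with columns `time` (1..t_len) and `state`.
#' @export
sample_states <- function(model, t_len, sampler = c("exact", "metropolis"),
                          seed = 1L, burn_in = NULL, thin = NULL) {
  stopifnot(inherits(model, "ising_model"))
  sampler <- match.arg(sampler)
  if (t_len < 1) abort("`t_len` must be >= 1.")
  n <- model$n
  if (sampler == "exact") {
    bd <- boltzmann_distribution(model)
    s <- with_local_seed(seed, sample(bd$state, t_len, replace = TRUE, prob = bd$probability))
  } else {
    if (is.null(burn_in)) burn_in <- 10L * 2^n
    if (is.null(thin)) thin <- n
    s <- with_local_seed(seed, metropolis_chain(model, t_len, burn_in, thin))
  }
  tibble(time = seq_len(t_len), state = as.integer(s))
}

metropolis_chain <- function(model, t_len, burn_in, thin) {
  n <- model$n
  h <- unname(model$h)
  J <- unname(model$J)
  sigma <- as.numeric(stats::runif(n) < 0.5)
  total <- burn_in + t_len * thin
  flips <- sample.int(n, total, replace = TRUE)
  us <- stats::runif(total)
  out <- integer(t_len)
  k <- 0L
  w <- 2^(seq_len(n) - 1)
  for (t in seq_len(total)) {
    i <- flips[t]
    # energy change of flipping channel i: E has -h_i sigma_i - sigma_i * sum_j J_ij sigma_j
    delta <- (1 - 2 * sigma[i]) * (-h[i] - sum(J[i, ] * sigma))
    if (delta <= 0 || us[t] < exp(-delta)) sigma[i] <- 1 - sigma[i]
    if (t > burn_in && (t - burn_in) %% thin == 0) {
      k <- k + 1L
      out[k] <- as.integer(sum(sigma * w))
    }
  }
  if (!all(is.finite(out))) abort("non-finite energies in Metropolis chain.")
  out[seq_len(t_len)]
}

#' Render a binary state sequence as continuous BOLD-like signals
#'
#' Inverts mean-threshold binarization: channel `i` at time `t` takes value
#' `baseline[i] + amplitude[i] * (2 * sigma_it - 1) + N(0, noise_sd)`. With
#' zero noise and balanced up/down occupancy, per-channel mean thresholding
#' recovers the binary sequence exactly; with noise the misclassification
#' rate is the Gaussian tail probability of `amplitude / noise_sd`.
#'
#' @param states A tibble from [sample_states()] (or any data frame with
#'   `time` and `state`).
#' @param n Channel count.
#' @param baseline,amplitude Per-channel scalars (recycled); `amplitude > 0`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed for the noise.
#' @param roi_names Channel names for the output columns.
#' @return A tibble with a `time` column and one numeric column per channel.
#' @export
states_to_bold <- function(states, n, baseline = 0, amplitude = 1, noise_sd = 0.3,
                           seed = 1L, roi_names = NULL) {
  n <- check_n(n)
  if (any(amplitude <= 0)) abort("`amplitude` must be positive.")
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(n))
  s <- state_codes(states)
  B <- decode_state(s, n)
  if (!is.matrix(B)) B <- matrix(B, nrow = 1)
  baseline <- rep_len(baseline, n)
  amplitude <- rep_len(amplitude, n)
  sig <- sweep(sweep(2 * B - 1, 2, amplitude, `*`), 2, baseline, `+`)
  if (noise_sd > 0) {
    sig <- sig + with_local_seed(seed, matrix(stats::rnorm(length(sig), 0, noise_sd), nrow(sig)))
  }
  colnames(sig) <- roi_names
  bind_cols(tibble(time = seq_len(nrow(sig))), as_tibble(sig))
}

#' Simulate a multi-group cohort with a planted landscape
#'
#' Generates a full synthetic study: a base planted model (see
#' [planted_model()]), per-group models obtained by adding Gaussian
#' perturbations of a group-specific scale to `h` and `J`, per-participant
#' binary state sequences sampled from their group's model, BOLD-like
#' continuous signals via [states_to_bold()], and metadata with group, site,
#' and symptom-like scores. Symptom scores are generated as a linear function
#' of the participant's true major-basin occupancy
#' (`symptom = symptom_intercept + symptom_slope * f(A1) + N(0, symptom_sd)`),
#' so downstream regression has a recoverable planted effect.
#'
#' All randomness derives from `seed` through [split_seed()]: group
#' perturbations, each participant's state sequence, BOLD noise and symptom
#' noise use separate child streams, so cohorts are byte-reproducible.
#'
#' @param groups A data frame with columns `label`, `n_participants`, and
#'   `perturbation` (Gaussian SD added to the base model's parameters for
#'   that group; 0 means the group uses the base model), and optionally
#'   `coupling_strength` to override the base coupling per group.
#' @param pattern Planted deep-basin pattern (0/1 vector).
#' @param coupling_strength,field_strength Base model parameters
#'   ([planted_model()]).
#' @param t_len Timepoints per participant.
#' @param sampler State sampler, `"metropolis"` (temporally correlated,
#'   default) or `"exact"`.
#' @param noise_sd BOLD noise SD (amplitude is 1).
#' @param n_sites Number of acquisition sites, assigned round-robin.
#' @param symptom_slope,symptom_intercept,symptom_sd Planted symptom model.
#' @param seed Integer run seed.
#' @param roi_names Optional channel names.
#' @return A list of class `ela_cohort`:
#' \describe{
#'   \item{signals}{tibble with `participant_id`, `time`, one column per ROI.}
#'   \item{states}{tibble `participant_id`, `time`, `state` — the true binary
#'     sequences before BOLD rendering.}
#'   \item{metadata}{tibble `participant_id`, `group`, `site`, `symptom`,
#'     `true_major_frequency`.}
#'   \item{models}{named list of per-group true [ising_model()]s.}
#'   \item{base_model}{the unperturbed planted model.}
#'   \item{truth}{list of generator settings (pattern, slope, ...).}
#' }
#' @export
simulate_cohort <- function(groups = tibble(
                              label = c("healthy", "non_melancholic", "melancholic"),
                              n_participants = 20L,
                              perturbation = 0.1
                            ),
                            pattern = c(1, 1, 1, 0, 0, 0),
                            coupling_strength = 1.2,
                            field_strength = 0.05,
                            t_len = 158L,
                            sampler = c("metropolis", "exact"),
                            noise_sd = 0.3,
                            n_sites = 4L,
                            symptom_slope = 2,
                            symptom_intercept = 10,
                            symptom_sd = 0.1,
                            seed = 1L,
                            roi_names = NULL) {
  sampler <- match.arg(sampler)
  groups <- as_tibble(groups)
  if (!all(c("label", "n_participants", "perturbation") %in% names(groups))) {
    abort("`groups` needs columns label, n_participants, perturbation.")
  }
  if (any(groups$n_participants < 1)) abort("each group needs at least one participant.")
  if (t_len < 2) abort("`t_len` must be >= 2.")
  n <- check_n(length(pattern))
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(n))

  base <- planted_model(pattern, coupling_strength, field_strength, roi_names)

  models <- list()
  for (g in seq_len(nrow(groups))) {
    cs <- if ("coupling_strength" %in% names(groups)) groups$coupling_strength[g] else coupling_strength
    mg <- planted_model(pattern, cs, field_strength, roi_names)
    if (groups$perturbation[g] > 0) {
      pert_seed <- split_seed(seed, 1000L + g)
      mg <- with_local_seed(pert_seed, perturb_model(mg, groups$perturbation[g]))
    }
    models[[groups$label[g]]] <- mg
  }

  signals <- list()
  states <- list()
  meta <- list()
  pid <- 0L
  for (g in seq_len(nrow(groups))) {
    lab <- groups$label[g]
    mg <- models[[lab]]
    mg_landscape <- energy_landscape(mg)
    majors <- major_basins(mg_landscape)
    cluster_of <- mg_landscape$states$basin
    for (p in seq_len(groups$n_participants[g])) {
      pid <- pid + 1L
      id <- sprintf("sub%03d", pid)
      st <- sample_states(mg, t_len, sampler, seed = split_seed(seed, 2L * pid))
      bold <- states_to_bold(st, n,
        noise_sd = noise_sd,
        seed = split_seed(seed, 2L * pid + 1L), roi_names = roi_names
      )
      f_major <- mean(cluster_of[st$state + 1L] == majors[1])
      symptom <- symptom_intercept + symptom_slope * f_major +
        with_local_seed(split_seed(seed, 100000L + pid), stats::rnorm(1, 0, symptom_sd))
      signals[[pid]] <- bind_cols(tibble(participant_id = id), bold)
      states[[pid]] <- bind_cols(tibble(participant_id = id), st)
      meta[[pid]] <- tibble(
        participant_id = id, group = lab,
        site = paste0("site", ((pid - 1L) %% n_sites) + 1L),
        symptom = symptom, true_major_frequency = f_major
      )
    }
  }

  structure(
    list(
      signals = bind_rows(signals),
      states = bind_rows(states),
      metadata = bind_rows(meta),
      models = models,
      base_model = base,
      truth = list(
        pattern = as.integer(pattern), coupling_strength = coupling_strength,
        field_strength = field_strength, sampler = sampler, noise_sd = noise_sd,
        symptom_slope = symptom_slope, symptom_intercept = symptom_intercept,
        symptom_sd = symptom_sd, seed = seed
      )
    ),
    class = "ela_cohort"
  )
}

# Gaussian parameter jitter, preserving J symmetry and zero diagonal.
perturb_model <- function(model, scale) {
  n <- model$n
  h <- unname(model$h) + stats::rnorm(n, 0, scale)
  Z <- matrix(0, n, n)
  Z[upper.tri(Z)] <- stats::rnorm(n * (n - 1) / 2, 0, scale)
  J <- unname(model$J) + Z + t(Z)
  out <- ising_model(h, J, model$roi_names)
  attr(out, "pattern") <- attr(model, "pattern")
  out
}

#' @export
print.ela_cohort <- function(x, ...) {
  cat(sprintf(
    "<ela_cohort> %d participants, %d groups, %d channels, %d timepoints each\n",
    nrow(x$metadata), length(x$models), x$base_model$n,
    max(x$signals$time)
  ))
  invisible(x)
}
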
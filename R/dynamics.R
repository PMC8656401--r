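#' Basin occurrence frequencies of a state sequence
#'
#' Maps every timepoint's state to its assigned basin on a fixed landscape
#' and reports each basin's fraction of timepoints, per participant. By
#' default occupancy counts membership of the basin's whole attraction
#' cluster (`count = "cluster"`); `count = "basin_state"` counts only exact
#' visits to the basin state itself.
#'
#' @param states A tibble with `state` (and optionally `participant_id`)
#'   or an integer vector of state codes.
#' @param landscape An [energy_landscape()].
#' @param count `"cluster"` or `"basin_state"`.
#' @return A tibble `participant_id`, `basin`, `frequency`; every basin of
#'   the landscape appears for every participant (zero rows included), so
#'   frequencies sum to 1 per participant in `"cluster"` mode.
#' @export
basin_frequency <- function(states, landscape, count = c("cluster", "basin_state")) {
  stopifnot(inherits(landscape, "energy_landscape"))
  count <- match.arg(count)
  df <- if (is.data.frame(states)) as_tibble(states) else tibble(state = as.integer(states))
  if (!"participant_id" %in% names(df)) df$participant_id <- "all"
  if (any(df$state < 0 | df$state >= 2^landscape$n)) abort("state codes out of range for this landscape.")

  if (count == "cluster") {
    df$basin <- landscape$states$basin[df$state + 1L]
  } else {
    df$basin <- ifelse(df$state %in% landscape$basins$basin, df$state, NA_integer_)
  }
  all_basins <- landscape$basins$basin
  counts <- df |> dplyr::count(.data$participant_id, .data$basin)
  totals <- df |> dplyr::count(.data$participant_id, name = "t_len")
  tidyr::expand_grid(
    participant_id = unique(df$participant_id),
    basin = all_basins
  ) |>
    left_join(counts, by = c("participant_id", "basin")) |>
    left_join(totals, by = "participant_id") |>
    mutate(frequency = dplyr::coalesce(.data$n, 0L) / .data$t_len) |>
    select("participant_id", "basin", "frequency")
}

#' Transition and staying rates on the major-basin landscape
#'
#' Computes, per participant, the four rates underlying the traveling and
#' lingering scores. Let `A1`, `A2` be the two major basins of the landscape
#' and `P1`, `P2` their attraction clusters. Writing `T` for the participant's
#' series length and counting consecutive timepoint pairs that stay within
#' one participant:
#' \describe{
#'   \item{`tr_major`}{`(n(A1 -> A2) + n(A2 -> A1)) / T`, pairs sitting
#'     exactly on the basin states.}
#'   \item{`tr_peripheral`}{cross-cluster pairs `(n(P1 -> P2) + n(P2 -> P1)) / T`.}
#'   \item{`sr_major`}{`(n(A1 -> A1) + n(A2 -> A2)) / T`, exact-state staying
#'     pairs on a major basin.}
#'   \item{`sr_peripheral`}{pairs remaining within one major cluster,
#'     excluding those already counted in `sr_major`.}
#' }
#' The traveling score is `tr_major / tr_peripheral` (undefined — `NA` with
#' `traveling_defined = FALSE` — when no cross-cluster pair occurs) and the
#' lingering score is `sr_major + sr_peripheral`.
#'
#' In `mode = "first_passage"` the two transition counts are replaced by
#' episode counts: `n(A1 -> A2)` counts visits to `A1` whose next visit to
#' `{A1, A2}` is `A2` (likewise for clusters, on the subsequence of
#' timepoints lying in a major cluster). With `first_passage_strict = TRUE`
#' an excursion through a minor cluster breaks the episode. Staying rates are
#' identical in both modes.
#'
#' @param states Tibble with `state` and optionally `participant_id`, or an
#'   integer state-code vector.
#' @param landscape An [energy_landscape()] with two major basins.
#' @param mode `"direct"` (consecutive-pair counting, default) or
#'   `"first_passage"`.
#' @param first_passage_strict Break first-passage episodes at minor-cluster
#'   states.
#' @return A tibble with one row per participant: `participant_id`, `t_len`,
#'   `tr_major`, `tr_peripheral`, `sr_major`, `sr_peripheral`, `traveling`,
#'   `traveling_defined`, `lingering`.
#' @export
transition_and_staying_rates <- function(states, landscape,
                                         mode = c("direct", "first_passage"),
                                         first_passage_strict = FALSE) {
  stopifnot(inherits(landscape, "energy_landscape"))
  mode <- match.arg(mode)
  majors <- major_basins(landscape)
  if (length(majors) < 2) abort("landscape has fewer than two major basins; scores are undefined.")
  a1 <- majors[1]
  a2 <- majors[2]
  assignment <- landscape$states$basin
  cl <- ifelse(assignment %in% majors, assignment, NA_integer_)

  df <- if (is.data.frame(states)) as_tibble(states) else tibble(state = as.integer(states))
  if (!"participant_id" %in% names(df)) df$participant_id <- "all"

  one <- function(s) {
    t_len <- length(s)
    if (t_len < 2) {
      return(tibble(
        t_len = t_len, tr_major = 0, tr_peripheral = 0, sr_major = 0,
        sr_peripheral = 0, traveling = NA_real_, traveling_defined = FALSE,
        lingering = 0
      ))
    }
    s0 <- s[-t_len]
    s1 <- s[-1]
    c0 <- cl[s0 + 1L]
    c1 <- cl[s1 + 1L]

    sA <- sum(s0 == s1 & (s0 == a1 | s0 == a2))
    same_cluster <- !is.na(c0) & !is.na(c1) & c0 == c1
    sP <- sum(same_cluster & !(s0 == s1 & (s0 == a1 | s0 == a2)))
    cross <- !is.na(c0) & !is.na(c1) & c0 != c1

    if (mode == "direct") {
      nA <- sum(s0 == a1 & s1 == a2) + sum(s0 == a2 & s1 == a1)
      nP <- sum(cross)
    } else {
      nA <- first_passage_count(s, c(a1, a2), cl, first_passage_strict)
      in_major <- !is.na(cl[s + 1L])
      w <- cl[s[in_major] + 1L]
      nP <- if (length(w) >= 2) sum(w[-length(w)] != w[-1]) else 0L
    }

    tr_major <- nA / t_len
    tr_peripheral <- nP / t_len
    defined <- tr_peripheral > 0
    tibble(
      t_len = t_len,
      tr_major = tr_major,
      tr_peripheral = tr_peripheral,
      sr_major = sA / t_len,
      sr_peripheral = sP / t_len,
      traveling = if (defined) tr_major / tr_peripheral else NA_real_,
      traveling_defined = defined,
      lingering = (sA + sP) / t_len
    )
  }

  df |>
    group_by(.data$participant_id) |>
    dplyr::group_modify(~ one(.x$state)) |>
    ungroup()
}

# Count first-passage episodes between the two exact target states: visits to
# targets[1] whose next target visit is targets[2], plus the reverse. With
# strict = TRUE, passing through a minor-cluster state voids the episode.
first_passage_count <- function(s, targets, cl, strict) {
  if (strict) {
    minor <- is.na(cl[s + 1L])
    runs <- split(s, cumsum(minor))
    runs <- lapply(runs, function(r) r[!is.na(cl[r + 1L])])
    return(sum(vapply(runs, function(r) first_passage_count(r, targets, cl, FALSE), numeric(1))))
  }
  v <- s[s %in% targets]
  if (length(v) < 2) {
    return(0L)
  }
  sum(v[-length(v)] != v[-1])
}

#' Per-participant dynamics metrics for a whole cohort
#'
#' Runs [basin_frequency()] and [transition_and_staying_rates()] for every
#' participant of a binarized cohort against one shared landscape and joins
#' the results into a single metrics table, one row per participant, with
#' major-basin frequencies spread into columns.
#'
#' @param states Tibble `participant_id`, `time`, `state` (e.g. from
#'   [binarize()] or [concatenate_group()]).
#' @param landscape The group [energy_landscape()] to evaluate against.
#' @param metadata Optional tibble keyed by `participant_id` to join
#'   (group, site, symptom scores, ...).
#' @inheritParams transition_and_staying_rates
#' @return A tibble with one row per participant: identification and
#'   metadata columns, `f_major1`, `f_major2`, `f_minor` (summed minor-basin
#'   occupancy), the four rates, `traveling`, `traveling_defined`,
#'   `lingering`.
#' @export
cohort_dynamics <- function(states, landscape, metadata = NULL,
                            mode = c("direct", "first_passage"),
                            first_passage_strict = FALSE) {
  mode <- match.arg(mode)
  freq <- basin_frequency(states, landscape)
  majors <- major_basins(landscape)
  fw <- freq |>
    mutate(role = dplyr::case_when(
      .data$basin == majors[1] ~ "f_major1",
      length(majors) > 1 & .data$basin == majors[2] ~ "f_major2",
      TRUE ~ "f_minor"
    )) |>
    group_by(.data$participant_id, .data$role) |>
    summarise(frequency = sum(.data$frequency), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "role", values_from = "frequency", values_fill = 0)
  for (col in c("f_major1", "f_major2", "f_minor")) {
    if (!col %in% names(fw)) fw[[col]] <- 0
  }
  rates <- transition_and_staying_rates(states, landscape, mode, first_passage_strict)
  out <- left_join(fw, rates, by = "participant_id")
  if (!is.null(metadata)) out <- left_join(out, as_tibble(metadata), by = "participant_id")
  select(
    out, "participant_id", dplyr::any_of(c("group", "site", "symptom")),
    "f_major1", "f_major2", "f_minor", "t_len", "tr_major", "tr_peripheral",
    "sr_major", "sr_peripheral", "traveling", "traveling_defined", "lingering",
    dplyr::everything()
  )
}
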
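#' Binarize continuous multichannel signals into state sequences
#'
#' Each channel is thresholded at its mean: timepoints strictly above the
#' threshold become active (1), all others — including values exactly equal
#' to the threshold — inactive (0). The per-timepoint activation pattern is
#' then encoded as a state code ([encode_state()]). Two thresholding
#' conventions are supported: `"participant"` computes each channel's mean
#' within each participant's own series (robust to between-participant
#' intensity offsets), `"group"` uses one mean per channel across all rows of
#' `signals` (or explicit `group_means`), matching group-concatenated
#' fitting. Binarization is invariant to positive per-channel affine
#' rescaling when thresholds are recomputed from the rescaled data.
#'
#' @param signals A data frame with one numeric column per channel, an
#'   optional `participant_id` column, and an optional `time` column (row
#'   order is used if absent).
#' @param roi_names Channels to use, in bit order (channel `i` contributes
#'   `2^(i-1)`). Defaults to every numeric column except `time`.
#' @param threshold_mode `"participant"` (default) or `"group"`.
#' @param group_means Optional named per-channel thresholds for
#'   `threshold_mode = "group"`; computed from `signals` when omitted.
#' @param strict If `TRUE`, a zero-variance channel (constant signal, so an
#'   all-0 column after thresholding) is an error; otherwise a warning.
#' @return A tibble with columns `participant_id` (if present in input),
#'   `time`, and `state`.
#' @examples
#' sig <- tibble::tibble(time = 1:4, a = c(1, 2, 3, 4))
#' binarize(sig, "a")$state # mean 2.5 -> 0 0 1 1
#' @export
binarize <- function(signals, roi_names = NULL,
                     threshold_mode = c("participant", "group"),
                     group_means = NULL, strict = FALSE) {
  threshold_mode <- match.arg(threshold_mode)
  signals <- as_tibble(signals)
  if (is.null(roi_names)) {
    roi_names <- setdiff(
      names(signals)[vapply(signals, is.numeric, logical(1))],
      c("time", "participant_id")
    )
  }
  missing_rois <- setdiff(roi_names, names(signals))
  if (length(missing_rois) > 0) {
    abort(sprintf("channel(s) not found in `signals`: %s", paste(missing_rois, collapse = ", ")))
  }
  n <- check_n(length(roi_names))
  X <- as.matrix(signals[roi_names])
  if (!all(is.finite(X))) abort("signals must be finite (no NA/Inf); scrubbed gaps are not supported.")

  has_id <- "participant_id" %in% names(signals)
  id <- if (has_id) signals$participant_id else rep("all", nrow(signals))

  if (threshold_mode == "group") {
    if (is.null(group_means)) {
      group_means <- colMeans(X)
    } else {
      if (!all(roi_names %in% names(group_means))) {
        abort("`group_means` must supply a threshold for every channel.")
      }
      group_means <- group_means[roi_names]
    }
    flat <- apply(X, 2, function(col) stats::sd(col) == 0)
    if (any(flat)) {
      msg <- sprintf(
        "zero-variance channel(s) %s: binarized column is constant.",
        paste(roi_names[flat], collapse = ", ")
      )
      if (strict) abort(msg) else warn(msg)
    }
    thr <- matrix(group_means, nrow(X), n, byrow = TRUE)
  } else {
    thr <- matrix(NA_real_, nrow(X), n)
    for (u in unique(id)) {
      rows <- id == u
      thr[rows, ] <- matrix(colMeans(X[rows, , drop = FALSE]), sum(rows), n, byrow = TRUE)
    }
  }

  bits <- (X > thr) * 1L
  out <- tibble(
    time = if ("time" %in% names(signals)) signals$time else seq_len(nrow(signals)),
    state = encode_state(bits)
  )
  if (has_id) out <- bind_cols(tibble(participant_id = signals$participant_id), out)
  out
}

#' Concatenate per-participant state sequences into a group series
#'
#' Stacks state sequences in the given order, keeping `participant_id` so
#' that downstream transition counting never pairs timepoints across a
#' participant join. Total state counts are preserved: the concatenation's
#' empirical counts are the sum of the per-participant counts.
#'
#' @param series_list A list of tibbles as returned by [binarize()] (each
#'   with `participant_id`, `time`, `state`), or a single such tibble
#'   covering several participants.
#' @param roi_names Optional channel-name vector carried by each element as
#'   the `roi_names` attribute; mismatched orders are an error.
#' @return One tibble with `participant_id`, `time`, `state`.
#' @export
concatenate_group <- function(series_list, roi_names = NULL) {
  if (is.data.frame(series_list)) series_list <- list(series_list)
  ref <- attr(series_list[[1]], "roi_names") %||% roi_names
  for (s in series_list) {
    rn <- attr(s, "roi_names") %||% roi_names
    if (!identical(rn, ref)) abort("all series must share the same channel set and order.")
    if (!all(c("time", "state") %in% names(s))) abort("each series needs `time` and `state` columns.")
  }
  out <- bind_rows(lapply(seq_along(series_list), function(i) {
    s <- as_tibble(series_list[[i]])
    if (!"participant_id" %in% names(s)) {
      s <- bind_cols(tibble(participant_id = paste0("series", i)), s)
    }
    s
  }))
  if (!is.null(ref)) attr(out, "roi_names") <- ref
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
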
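#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_segment
#'   geom_boxplot geom_jitter labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot the disconnectivity graph of a basin dendrogram
#'
#' Vertical bars drop from each merge saddle down to the basin energies
#' (leaves) or child merge levels, the standard disconnectivity-graph
#' rendering of an energy landscape.
#'
#' @param object A [build_dendrogram()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.basin_dendrogram <- function(object, ...) {
  hc <- object$hclust
  k <- length(hc$labels)
  leaf_x <- setNames(match(seq_len(k), hc$order), hc$labels)
  node_x <- numeric(nrow(hc$merge))
  segs <- list()
  for (i in seq_len(nrow(hc$merge))) {
    ch <- lapply(hc$merge[i, ], function(c) {
      if (c < 0) {
        lab <- hc$labels[-c]
        list(x = leaf_x[[lab]], level = object$basin_energies[[lab]], label = lab)
      } else {
        list(x = node_x[c], level = hc$height[c], label = NA_character_)
      }
    })
    node_x[i] <- mean(c(ch[[1]]$x, ch[[2]]$x))
    h <- hc$height[i]
    segs[[length(segs) + 1]] <- tibble(
      x = c(ch[[1]]$x, ch[[2]]$x, ch[[1]]$x),
      xend = c(ch[[1]]$x, ch[[2]]$x, ch[[2]]$x),
      y = c(ch[[1]]$level, ch[[2]]$level, h),
      yend = c(h, h, h)
    )
  }
  seg_df <- bind_rows(segs)
  leaf_df <- tibble(
    x = unname(leaf_x),
    y = unname(object$basin_energies[hc$labels]),
    label = paste0("S", hc$labels)
  )
  ggplot(seg_df, aes(x = .data$x, y = .data$y)) +
    geom_segment(aes(xend = .data$xend, yend = .data$yend)) +
    geom_point(data = leaf_df) +
    ggplot2::geom_text(data = leaf_df, aes(label = .data$label), vjust = 1.8, size = 3) +
    labs(x = NULL, y = "energy", title = "Disconnectivity graph of basin states") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot the concentric-circle profiles of the major basins
#'
#' Depth (minimum energy among equidistant cluster states) against Hamming
#' radius from each major basin state.
#'
#' @param object An [energy_landscape()].
#' @param basins Basin codes to profile; default the major basins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.energy_landscape <- function(object, basins = NULL, ...) {
  if (is.null(basins)) basins <- major_basins(object)
  prof <- purrr::map_dfr(basins, function(b) {
    mutate(landscape_profile(object, b), basin = paste0("S", b))
  })
  ggplot(prof, aes(x = .data$radius, y = .data$depth, colour = .data$basin)) +
    geom_line() +
    geom_point() +
    labs(
      x = "Hamming radius from basin state", y = "depth (minimum energy)",
      colour = "basin", title = "Landscape profile of basin clusters"
    ) +
    theme_minimal()
}

#' Boxplots of dynamics metrics by group
#'
#' @param metrics A [cohort_dynamics()] table with a `group` column.
#' @param which Metrics to show.
#' @return A ggplot object.
#' @export
plot_dynamics <- function(metrics, which = c("f_major1", "traveling", "lingering")) {
  if (!"group" %in% names(metrics)) abort("`metrics` needs a group column (join metadata).")
  long <- metrics |>
    select("participant_id", "group", dplyr::all_of(which)) |>
    tidyr::pivot_longer(dplyr::all_of(which), names_to = "metric", values_to = "value") |>
    filter(is.finite(.data$value))
  ggplot(long, aes(x = .data$group, y = .data$value)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = NULL, title = "Participant-level landscape dynamics by group") +
    theme_minimal()
}
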
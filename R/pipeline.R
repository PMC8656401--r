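#' Run the full energy-landscape analysis pipeline
#'
#' For every requested functional network and every participant group:
#' binarize the ROI signals, concatenate the group's sequences, fit the
#' pairwise maximum entropy model on the concatenation, map its energy
#' landscape, and score every participant's dynamics against their own
#' group's landscape. Group comparisons (one-way ANOVA with Bonferroni
#' pairwise tests and Kruskal-Wallis) are then run per network on the
#' major-basin frequency and the traveling and lingering scores. All
#' artifacts are written as plain-text TSV/JSON/Newick files and indexed in
#' a manifest; a re-run with identical inputs produces byte-identical
#' outputs.
#'
#' @param cohort An `ela_cohort` from [simulate_cohort()], or a list with
#'   `signals` (tibble: `participant_id`, `time`, ROI columns) and
#'   `metadata` (tibble keyed by `participant_id` with a `group` column),
#'   e.g. from [read_cohort()].
#' @param networks Named list mapping network name to an ordered character
#'   vector of ROI column names; default one network `"all"` using every ROI
#'   column. Every named ROI must exist in `signals` (validated before any
#'   fitting).
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param threshold_mode Binarization threshold convention, see [binarize()].
#' @param dynamics_mode See [transition_and_staying_rates()].
#' @param tol,max_iter Model-fit controls, see [fit_pmem()].
#' @return A list of class `ela_run`: `results` (per network x group:
#'   `fit`, `landscape`, `dendrogram`), `dynamics` (per-network metrics
#'   tables), `stats` (per-network comparison tables), `manifest` (tibble of
#'   written files plus config hash).
#' @export
run_pipeline <- function(cohort, networks = NULL, out_dir = NULL,
                         threshold_mode = c("participant", "group"),
                         dynamics_mode = c("direct", "first_passage"),
                         tol = 1e-6, max_iter = 20000L) {
  threshold_mode <- match.arg(threshold_mode)
  dynamics_mode <- match.arg(dynamics_mode)
  signals <- as_tibble(cohort$signals)
  metadata <- as_tibble(cohort$metadata)
  if (!"participant_id" %in% names(signals) || !"group" %in% names(metadata)) {
    abort("cohort needs signals$participant_id and metadata$group.")
  }
  roi_cols <- setdiff(
    names(signals)[vapply(signals, is.numeric, logical(1))],
    c("time", "participant_id")
  )
  if (is.null(networks)) networks <- list(all = roi_cols)
  for (net in names(networks)) {
    bad <- setdiff(networks[[net]], names(signals))
    if (length(bad) > 0) {
      abort(sprintf(
        "network '%s' names ROI column(s) absent from the signals: %s",
        net, paste(bad, collapse = ", ")
      ))
    }
    check_n(length(networks[[net]]))
  }

  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  files <- character(0)
  emit <- function(path, writer) {
    if (is.null(out_dir)) {
      return(invisible(NULL))
    }
    fp <- file.path(out_dir, path)
    writer(fp)
    files <<- c(files, path)
  }

  sig_meta <- left_join(signals, metadata[c("participant_id", "group")], by = "participant_id")
  groups <- sort(unique(metadata$group))
  results <- list()
  dynamics <- list()
  stats_out <- list()

  for (net in names(networks)) {
    rois <- networks[[net]]
    net_dynamics <- list()
    for (g in groups) {
      grp_sig <- filter(sig_meta, .data$group == g)
      binary <- binarize(grp_sig, rois, threshold_mode = threshold_mode)
      series <- concatenate_group(binary)
      fit <- fit_pmem(series, n = length(rois), tol = tol, max_iter = max_iter, roi_names = rois)
      ls <- energy_landscape(fit$model)
      dend <- if (nrow(ls$basins) >= 2) build_dendrogram(ls) else NULL

      key <- paste(net, g, sep = "_")
      results[[key]] <- list(network = net, group = g, fit = fit, landscape = ls, dendrogram = dend)

      metrics <- cohort_dynamics(series, ls,
        metadata = metadata, mode = dynamics_mode
      )
      net_dynamics[[g]] <- metrics

      emit(paste0("model_", key, ".json"), function(fp) write_model_json(fit$model, fp))
      emit(paste0("basins_", key, ".tsv"), function(fp) {
        readr::write_tsv(tidy(ls), fp)
      })
      emit(paste0("energies_", key, ".tsv"), function(fp) {
        readr::write_tsv(boltzmann_distribution(fit$model), fp)
      })
      if (!is.null(ls$saddle)) {
        emit(paste0("saddle_", key, ".tsv"), function(fp) {
          readr::write_tsv(as_tibble(ls$saddle, rownames = "basin"), fp)
        })
      }
      if (!is.null(dend)) {
        emit(paste0("dendrogram_", key, ".nwk"), function(fp) {
          writeLines(dendrogram_newick(dend), fp)
        })
      }
    }
    net_metrics <- bind_rows(net_dynamics)
    dynamics[[net]] <- net_metrics
    emit(paste0("dynamics_", net, ".tsv"), function(fp) {
      readr::write_tsv(net_metrics, fp, na = "")
    })

    if (length(groups) >= 2 && all(table(net_metrics$group) >= 2)) {
      comps <- purrr::map_dfr(
        c("f_major1", "traveling", "lingering"),
        function(m) {
          gc <- tryCatch(
            compare_groups(net_metrics, m, "group"),
            error = function(e) NULL
          )
          if (is.null(gc)) {
            return(tibble())
          }
          bind_cols(tibble(network = net), glance(gc))
        }
      )
      stats_out[[net]] <- comps
      emit(paste0("stats_", net, ".tsv"), function(fp) readr::write_tsv(comps, fp, na = ""))
    }
  }

  config <- list(
    networks = networks, threshold_mode = threshold_mode,
    dynamics_mode = dynamics_mode, tol = tol
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("elandscape")),
    config = config,
    config_hash = rlang::hash(config),
    n_participants = nrow(metadata),
    groups = groups,
    networks = names(networks),
    files = files
  )
  emit("manifest.json", function(fp) {
    jsonlite::write_json(manifest, fp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  structure(
    list(results = results, dynamics = dynamics, stats = stats_out, manifest = manifest),
    class = "ela_run"
  )
}

#' @export
print.ela_run <- function(x, ...) {
  cat(sprintf(
    "<ela_run> %d network x group model(s); networks: %s\n",
    length(x$results), paste(x$manifest$networks, collapse = ", ")
  ))
  invisible(x)
}

#' Serialize / read an Ising model as JSON
#'
#' @param model An [ising_model()].
#' @param path File path.
#' @return `read_model_json` returns an [ising_model()].
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "ising_model"))
  jsonlite::write_json(
    list(
      n = model$n, roi_names = model$roi_names,
      h = unname(model$h), J = unname(model$J)
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ising_model(x$h, x$J, x$roi_names)
}

#' Write / read a cohort as plain-text files
#'
#' One TSV per participant (`<participant_id>.tsv`: a `time` column plus one
#' column per ROI), a `metadata.tsv`, and when ground-truth models are known
#' (synthetic cohorts) a `truth_model_<group>.json` per group.
#'
#' @param cohort An `ela_cohort` or compatible list.
#' @param dir Directory.
#' @return `read_cohort` returns a list with `signals` and `metadata`
#'   suitable for [run_pipeline()].
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in unique(cohort$signals$participant_id)) {
    readr::write_tsv(
      filter(cohort$signals, .data$participant_id == id) |> select(-"participant_id"),
      file.path(dir, paste0(id, ".tsv"))
    )
  }
  readr::write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  if (!is.null(cohort$models)) {
    for (g in names(cohort$models)) {
      write_model_json(cohort$models[[g]], file.path(dir, paste0("truth_model_", g, ".json")))
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- readr::read_tsv(file.path(dir, "metadata.tsv"), show_col_types = FALSE)
  signals <- purrr::map_dfr(meta$participant_id, function(id) {
    bind_cols(
      tibble(participant_id = id),
      readr::read_tsv(file.path(dir, paste0(id, ".tsv")), show_col_types = FALSE)
    )
  })
  list(signals = signals, metadata = meta)
}
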
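#' Omnibus and pairwise group comparison of one metric
#'
#' The standard battery for comparing a continuous landscape metric (basin
#' frequency, traveling or lingering score, symptom score, ...) across
#' groups: one-way ANOVA for the omnibus difference, all pairwise Welch
#' t-tests with Bonferroni adjustment, and a Kruskal-Wallis test as a
#' distribution-free check. Significance flags are reported at the 0.05,
#' 0.01 and 0.005 levels.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the metric and the group
#'   label.
#' @param star_levels Decreasing significance thresholds for the flags.
#' @return An object of class `group_comparison` with elements `metric`,
#'   `summary` (per-group n/mean/sd), `anova` (one-row tibble), `pairwise`
#'   (per-pair tibble with raw and Bonferroni-adjusted p), `kruskal`.
#'   [tidy()] returns the pairwise table, [glance()] the omnibus row.
#' @examples
#' d <- data.frame(g = rep(c("a", "b", "c"), each = 3), y = c(1, 2, 3, 2, 3, 4, 3, 4, 5))
#' glance(compare_groups(d, y, g))
#' @export
compare_groups <- function(data, value, group, star_levels = c(0.05, 0.01, 0.005)) {
  val <- resolve_column(data, rlang::enquo(value))
  grp <- resolve_column(data, rlang::enquo(group))
  metric <- val$name
  d <- tibble(value = val$values, group = as.character(grp$values)) |>
    filter(is.finite(.data$value))
  groups <- sort(unique(d$group))
  if (length(groups) < 2) abort("need at least two groups.")
  counts <- table(d$group)
  if (any(counts < 2)) abort("each group needs at least two observations.")

  summary_tbl <- d |>
    group_by(.data$group) |>
    summarise(
      n = dplyr::n(), mean = mean(.data$value), sd = stats::sd(.data$value),
      .groups = "drop"
    )

  if (all(summary_tbl$sd == 0)) {
    anova_tbl <- tibble(
      statistic = NA_real_, df_between = length(groups) - 1,
      df_within = nrow(d) - length(groups), p.value = NA_real_,
      note = "zero variance everywhere; F undefined"
    )
  } else {
    fit <- stats::aov(value ~ group, data = d)
    a <- summary(fit)[[1]]
    anova_tbl <- tibble(
      statistic = a[["F value"]][1], df_between = a[["Df"]][1],
      df_within = a[["Df"]][2], p.value = a[["Pr(>F)"]][1], note = NA_character_
    )
  }

  pairs <- utils::combn(groups, 2)
  n_comp <- ncol(pairs)
  pairwise <- purrr::map_dfr(seq_len(n_comp), function(k) {
    g1 <- pairs[1, k]
    g2 <- pairs[2, k]
    x <- d$value[d$group == g1]
    y <- d$value[d$group == g2]
    tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
    p_raw <- if (is.null(tt)) NA_real_ else tt$p.value
    tibble(
      group1 = g1, group2 = g2,
      mean_diff = mean(x) - mean(y),
      statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p.value = p_raw,
      p.adjusted = pmin(1, p_raw * n_comp)
    )
  }) |>
    mutate(
      sig_0.05 = .data$p.adjusted < star_levels[1],
      sig_0.01 = .data$p.adjusted < star_levels[2],
      sig_0.005 = .data$p.adjusted < star_levels[3]
    )

  kw <- tryCatch(stats::kruskal.test(d$value, factor(d$group)), error = function(e) NULL)
  kruskal_tbl <- tibble(
    statistic = if (is.null(kw)) NA_real_ else unname(kw$statistic),
    df = if (is.null(kw)) NA_real_ else unname(kw$parameter),
    p.value = if (is.null(kw)) NA_real_ else kw$p.value
  )

  structure(
    list(
      metric = metric, summary = summary_tbl, anova = anova_tbl,
      pairwise = pairwise, kruskal = kruskal_tbl
    ),
    class = "group_comparison"
  )
}

# Accept either a bare column or a length-1 string naming one.
resolve_column <- function(data, q) {
  v <- rlang::eval_tidy(q, data = data)
  if (is.character(v) && length(v) == 1 && v %in% names(data)) {
    list(name = v, values = data[[v]])
  } else {
    list(name = rlang::as_label(q), values = v)
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s: F = %.3g (p = %.3g); Kruskal-Wallis p = %.3g\n",
    x$metric, x$anova$statistic, x$anova$p.value, x$kruskal$p.value
  ))
  print(x$pairwise)
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @rdname compare_groups
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(
    metric = x$metric,
    statistic = x$anova$statistic,
    df_between = x$anova$df_between,
    df_within = x$anova$df_within,
    p.value = x$anova$p.value,
    kruskal_statistic = x$kruskal$statistic,
    kruskal_p.value = x$kruskal$p.value
  )
}

#' Pearson chi-squared test for a contingency table
#'
#' Used for group differences in categorical factors (sex, site). No
#' continuity correction by default.
#'
#' @param x A contingency table (matrix/table of nonnegative integer counts),
#'   or a data frame whose two columns are cross-tabulated.
#' @param correct Apply Yates continuity correction (2x2 only).
#' @return A one-row tibble `statistic`, `df`, `p.value`.
#' @export
chi_squared_test <- function(x, correct = FALSE) {
  if (is.data.frame(x)) x <- table(x[[1]], x[[2]])
  x <- as.matrix(x)
  if (any(x < 0) || any(x != round(x))) abort("counts must be nonnegative integers.")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    abort("contingency table has an empty row or column marginal.")
  }
  res <- stats::chisq.test(x, correct = correct)
  tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p.value = res$p.value
  )
}

#' Two-way ANOVA with interaction (type-II sums of squares)
#'
#' Tests main effects of two crossed factors (e.g. participant group and
#' acquisition site) and their interaction on a metric, using type-II sums
#' of squares so main effects are not distorted by unbalanced cell sizes.
#'
#' @param data A data frame.
#' @param value,factor1,factor2 Columns (tidy-eval).
#' @return A tibble with one row per term (`factor1`, `factor2`,
#'   `factor1:factor2`, `Residuals`): `term`, `sumsq`, `df`, `statistic`,
#'   `p.value`.
#' @export
two_way_anova <- function(data, value, factor1, factor2) {
  d <- tibble(
    value = dplyr::pull(data, {{ value }}),
    f1 = factor(dplyr::pull(data, {{ factor1 }})),
    f2 = factor(dplyr::pull(data, {{ factor2 }}))
  )
  if (nlevels(d$f1) < 2 || nlevels(d$f2) < 2) {
    abort("both factors need at least two levels.")
  }
  cells <- table(d$f1, d$f2)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "empty design cell: %s x %s — the interaction is not estimable.",
      rownames(cells)[idx[1]], colnames(cells)[idx[2]]
    ))
  }
  fit <- stats::lm(value ~ f1 * f2, data = d)
  a <- car::Anova(fit, type = 2)
  nm <- rownames(a)
  nm <- sub("^f1:f2$", paste0(
    rlang::as_name(rlang::enquo(factor1)), ":", rlang::as_name(rlang::enquo(factor2))
  ), nm)
  nm <- sub("^f1$", rlang::as_name(rlang::enquo(factor1)), nm)
  nm <- sub("^f2$", rlang::as_name(rlang::enquo(factor2)), nm)
  tibble(
    term = nm,
    sumsq = a[["Sum Sq"]],
    df = a[["Df"]],
    statistic = a[["F value"]],
    p.value = a[["Pr(>F)"]]
  )
}

#' Regress symptom scores on landscape characteristics
#'
#' Ordinary least squares of a symptom score (e.g. depression severity or
#' anhedonia questionnaire totals) on basin characteristics — by default the
#' major-basin occupancy frequencies from [cohort_dynamics()] — with an
#' intercept and per-coefficient t-tests.
#'
#' @param data A data frame (typically a [cohort_dynamics()] table joined
#'   with metadata).
#' @param response Name of the response column (string).
#' @param predictors Character vector of predictor columns; defaults to the
#'   major-basin frequencies.
#' @return An object of class `symptom_regression` wrapping the `lm` fit;
#'   [tidy()] gives `term`, `estimate`, `std.error`, `statistic`, `p.value`;
#'   [glance()] gives `r.squared`, `adj.r.squared`, `sigma`, `df.residual`,
#'   `nobs`.
#' @export
symptom_regression <- function(data, response, predictors = c("f_major1", "f_major2")) {
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("column(s) not in data: %s", paste(missing_cols, collapse = ", ")))
  }
  d <- as_tibble(data)[c(response, predictors)]
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < length(predictors) + 2) {
    abort("need at least p + 2 complete observations for p predictors.")
  }
  form <- stats::reformulate(predictors, response = response)
  X <- stats::model.matrix(form, d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    abort(sprintf(
      "design matrix is rank deficient; collinear column(s): %s",
      paste(dropped, collapse = ", ")
    ))
  }
  fit <- stats::lm(form, data = d)
  structure(
    list(fit = fit, response = response, predictors = predictors, nobs = nrow(d)),
    class = "symptom_regression"
  )
}

#' @export
print.symptom_regression <- function(x, ...) {
  cat(sprintf(
    "<symptom_regression> %s ~ %s (n = %d, R^2 = %.3f)\n",
    x$response, paste(x$predictors, collapse = " + "), x$nobs,
    summary(x$fit)$r.squared
  ))
  invisible(x)
}

#' @rdname symptom_regression
#' @param x A `symptom_regression`.
#' @param ... Unused.
#' @export
tidy.symptom_regression <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(
    term = rownames(cf),
    estimate = unname(cf[, 1]),
    std.error = unname(cf[, 2]),
    statistic = unname(cf[, 3]),
    p.value = unname(cf[, 4])
  )
}

#' @rdname symptom_regression
#' @export
glance.symptom_regression <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    df.residual = x$fit$df.residual,
    nobs = x$nobs
  )
}
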
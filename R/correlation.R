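# Dose-metric evaluation: Pearson correlation between per-animal dose under
# a candidate metric and relative outcome values across materials, with the
# small-sample significance convention (t reference with an explicit,
# typically very small, degrees of freedom).

#' Pearson correlation with loud failure modes
#'
#' Sample Pearson correlation of two equal-length vectors. Degenerate
#' inputs that would silently produce \code{NA} in a pipeline (constant
#' vectors, length mismatch, fewer than three points) raise classed errors
#' instead.
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @return The correlation coefficient in [-1, 1].
#' @examples
#' pearson_r(c(1, 2, 3), c(2, 4, 6)) # exactly 1
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y))
    validation_error("x and y must be numeric vectors")
  if (length(x) != length(y))
    validation_error(sprintf("length mismatch: %d vs %d", length(x), length(y)))
  if (length(x) < 3L)
    validation_error("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    validation_error("x and y must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    domain_error("correlation is undefined for a constant vector")
  r <- stats::cor(x, y)
  max(-1, min(1, r))
}

#' Two-sided p-value for a correlation at fixed degrees of freedom
#'
#' Refers \eqn{t = r \sqrt{df / (1 - r^2)}} to the t distribution with
#' \code{df} degrees of freedom (two-sided). At \code{df = 1} the reference
#' is the standard Cauchy, which is what makes three-material designs so
#' conservative: |r| must exceed about 0.997 to reach p < 0.05.
#'
#' @param r correlation coefficient, |r| <= 1.
#' @param df degrees of freedom (>= 1).
#' @return p-value in [0, 1]; exactly 0 when |r| = 1.
#' @examples
#' correlation_p(0.997, df = 1) # ~0.049
#' correlation_p(0.995, df = 1) # ~0.064
#' @export
correlation_p <- function(r, df = 1) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r))
    domain_error("r must be a single finite number")
  if (abs(r) > 1) domain_error(sprintf("|r| must be <= 1 (got %g)", r))
  df <- check_count(df, "df", minimum = 1L)
  if (abs(r) == 1) return(0)
  t_stat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t_stat), df)
}

#' Significance boundary on |r| at a given alpha and df
#'
#' The smallest |r| reaching two-sided significance:
#' \eqn{t_c / \sqrt{df + t_c^2}} with \eqn{t_c} the upper
#' \eqn{\alpha/2} t quantile. At \code{alpha = 0.05}, \code{df = 1} this is
#' about 0.99692, so r = 0.995 stays above p = 0.05 while r = 0.997 falls
#' below it.
#'
#' @param alpha two-sided significance level.
#' @param df degrees of freedom (>= 1).
#' @return The critical |r|.
#' @export
critical_r <- function(alpha = 0.05, df = 1) {
  check_scalar(alpha, "alpha")
  if (alpha >= 1) domain_error("alpha must be in (0, 1)")
  df <- check_count(df, "df", minimum = 1L)
  tc <- stats::qt(1 - alpha / 2, df)
  tc / sqrt(df + tc^2)
}

relative_values <- function(panel, outcome, timepoint, normalization,
                            reference) {
  if (normalization == "reference") {
    relative_to_reference(panel, outcome, timepoint, reference)
  } else {
    cell <- panel_slice(panel, outcome, timepoint)
    if (any(is.na(cell$control_mean)) || any(cell$control_mean <= 0))
      missing_data_error(sprintf(
        "control baseline missing or non-positive for outcome '%s' at day %s",
        outcome, timepoint))
    stats::setNames(fold_change(cell$value, cell$control_mean),
                    cell$material_id)
  }
}

#' Correlate dose metrics against outcome panels
#'
#' The central fit of the package: for each candidate dose metric and each
#' (outcome, timepoint) cell, correlates the per-animal dose across
#' materials with the relative outcome value, and tests it against the
#' t reference at a fixed (small) degrees of freedom.
#'
#' Relative values are either each material's value divided by a reference
#' material's value (\code{normalization = "reference"}, the default) or
#' the fold change over the control baseline
#' (\code{normalization = "control-fold"}). Both give identical
#' correlations when every material shares a control baseline, since
#' Pearson r is scale-invariant.
#'
#' When \code{outcomes} is \code{NULL} the fit covers every
#' (outcome, timepoint) cell observed for all dosed materials; naming
#' outcomes (and optionally timepoints) instead makes coverage gaps a hard
#' error listing the missing keys.
#'
#' @param panel an [outcome_panel()].
#' @param doses a [build_dose_table()] result; its materials define the
#'   correlation sample.
#' @param metrics character vector of dose metrics to evaluate
#'   (\code{"mass"}, \code{"number"}, \code{"ssa"}, \code{"esa"}).
#' @param outcomes optional outcome names to evaluate (default: all fully
#'   covered).
#' @param timepoints optional timepoints (days) to evaluate.
#' @param reference material id used as denominator for
#'   \code{normalization = "reference"}.
#' @param normalization \code{"reference"} or \code{"control-fold"}.
#' @param alpha two-sided significance level (default 0.05).
#' @param df degrees of freedom for the t reference; \code{NULL} (default)
#'   uses n - 2 for n materials. Three-material designs give df = 1 either
#'   way, the convention under which published r values around 0.997 sit
#'   exactly at the significance boundary.
#' @param use_printed_doses prefer printed surface doses over computed ones
#'   (see [dose_ratio()]).
#' @return An object of class \code{metric_correlation}: a list with
#'   \code{$results} (one row per metric x outcome x timepoint: r, t, df,
#'   p, significance flag), the fitted data in \code{$data}, and the fit
#'   settings. Methods: \code{print}, \code{summary}, \code{plot},
#'   \code{as.data.frame}.
#' @examples
#' doses <- fixture_dose_table()
#' panel <- fixture_outcomes()
#' fit <- correlate_dose_metrics(panel, doses, metrics = c("ssa", "esa"),
#'                               outcomes = c("PMN", "protein", "4HNE"),
#'                               timepoints = 1, reference = "asbestos",
#'                               df = 1)
#' fit
#' @export
correlate_dose_metrics <- function(panel, doses, metrics = "esa",
                                   outcomes = NULL, timepoints = NULL,
                                   reference = NULL,
                                   normalization = c("reference", "control-fold"),
                                   alpha = 0.05, df = NULL,
                                   use_printed_doses = FALSE) {
  stopifnot(inherits(panel, "outcome_panel"), inherits(doses, "dose_table"))
  normalization <- match.arg(normalization)
  check_scalar(alpha, "alpha")
  if (normalization == "reference") {
    if (is.null(reference))
      validation_error("normalization = 'reference' needs a reference material")
    if (!reference %in% doses$material_id)
      lookup_error(sprintf("reference '%s' not in dose table", reference))
  }
  materials <- doses$material_id
  if (length(materials) < 3L)
    validation_error("need at least 3 dosed materials to correlate")
  df_use <- if (is.null(df)) length(materials) - 2L else
    check_count(df, "df", minimum = 1L)

  obs <- panel[panel$material_id %in% materials, , drop = FALSE]
  cells <- unique(obs[, c("outcome", "timepoint_day")])
  if (!is.null(timepoints))
    cells <- cells[cells$timepoint_day %in% timepoints, , drop = FALSE]
  named <- !is.null(outcomes)
  if (named) cells <- cells[cells$outcome %in% outcomes, , drop = FALSE]
  covered <- function(oc, tp) {
    have <- obs$material_id[obs$outcome == oc & obs$timepoint_day == tp]
    setdiff(materials, have)
  }
  keep <- logical(nrow(cells)); missing_keys <- character()
  for (i in seq_len(nrow(cells))) {
    gap <- covered(cells$outcome[i], cells$timepoint_day[i])
    keep[i] <- length(gap) == 0L
    if (!keep[i])
      missing_keys <- c(missing_keys, sprintf(
        "(%s, day %s): missing %s", cells$outcome[i], cells$timepoint_day[i],
        paste(gap, collapse = ", ")))
  }
  if (named && length(missing_keys))
    missing_data_error(paste("incomplete coverage —",
                             paste(missing_keys, collapse = "; ")))
  if (named && !nrow(cells))
    lookup_error("none of the named outcomes are present in the panel")
  cells <- cells[keep, , drop = FALSE]
  cells <- cells[order(cells$outcome, cells$timepoint_day), , drop = FALSE]

  rows <- list(); xy <- list()
  for (metric in metrics) {
    x_all <- dose_values(doses, metric, use_printed_doses)
    if (any(is.na(x_all)))
      missing_data_error(sprintf(
        "metric '%s' undefined for: %s", metric,
        paste(names(x_all)[is.na(x_all)], collapse = ", ")))
    for (i in seq_len(nrow(cells))) {
      oc <- cells$outcome[i]; tp <- cells$timepoint_day[i]
      y <- relative_values(panel, oc, tp, normalization, reference)
      y <- y[materials]
      r <- pearson_r(x_all[materials], y)
      p <- correlation_p(r, df_use)
      t_stat <- if (abs(r) == 1) Inf * sign(r) else
        r * sqrt(df_use / (1 - r^2))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, outcome = oc, timepoint_day = tp,
        n = length(materials), r = r, df = df_use, t = t_stat, p = p,
        significant = p < alpha, stringsAsFactors = FALSE)
      xy[[sprintf("%s|%s|%s", metric, oc, tp)]] <- data.frame(
        material_id = materials, dose = unname(x_all[materials]),
        relative_value = unname(y), stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metric = character(), outcome = character(),
               timepoint_day = numeric(), n = integer(), r = numeric(),
               df = integer(), t = numeric(), p = numeric(),
               significant = logical(), stringsAsFactors = FALSE)
  results <- results[order(results$metric, results$outcome,
                           results$timepoint_day), , drop = FALSE]
  rownames(results) <- NULL
  structure(list(results = results, data = xy, metrics = metrics,
                 alpha = alpha, df = df_use, normalization = normalization,
                 reference = reference, materials = materials),
            class = "metric_correlation")
}

#' @export
print.metric_correlation <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Dose-metric correlation fit: %d materials, df = %d, alpha = %g\n",
    length(x$materials), x$df, x$alpha))
  cat(sprintf("Normalization: %s%s | significance needs |r| > %.5f\n",
              x$normalization,
              if (!is.null(x$reference)) paste0(" (reference ", x$reference, ")") else "",
              critical_r(x$alpha, x$df)))
  res <- x$results
  res$sig <- ifelse(res$significant, "*", "")
  print.data.frame(
    res[, c("metric", "outcome", "timepoint_day", "r", "p", "sig")],
    digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
summary.metric_correlation <- function(object, ...) {
  res <- object$results
  counts <- vapply(object$metrics, function(m)
    sum(res$significant[res$metric == m]), integer(1))
  structure(list(
    n_materials = length(object$materials), df = object$df,
    alpha = object$alpha, critical_r = critical_r(object$alpha, object$df),
    tests_per_metric = nrow(res) / max(1L, length(object$metrics)),
    significant_per_metric = counts, results = res),
    class = "summary.metric_correlation")
}

#' @export
print.summary.metric_correlation <- function(x, ...) {
  cat(sprintf(
    "Dose-metric comparison across %d materials (df = %d, alpha = %g)\n",
    x$n_materials, x$df, x$alpha))
  cat(sprintf("Critical |r| = %.5f; %g tests per metric\n",
              x$critical_r, x$tests_per_metric))
  cat("Significant correlations per metric:\n")
  for (m in names(x$significant_per_metric))
    cat(sprintf("  %-8s %d\n", m, x$significant_per_metric[[m]]))
  invisible(x)
}

#' @export
as.data.frame.metric_correlation <- function(x, ...) x$results

#' Plot dose versus relative outcome values
#'
#' Scatter of per-animal dose (under one metric) against the relative
#' outcome values, one plotting symbol per (outcome, timepoint) series —
#' the standard way a dose-metric comparison is displayed.
#'
#' @param x a [correlate_dose_metrics()] fit.
#' @param metric which metric to display (default: first fitted).
#' @param ... passed to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plot.metric_correlation <- function(x, metric = x$metrics[[1]], ...) {
  keys <- grep(paste0("^", metric, "\\|"), names(x$data), value = TRUE)
  if (!length(keys)) lookup_error(sprintf("metric '%s' was not fitted", metric))
  all_xy <- do.call(rbind, x$data[keys])
  graphics::plot(NA, xlim = range(all_xy$dose), ylim = range(all_xy$relative_value),
                 xlab = sprintf("dose per animal (%s metric)", metric),
                 ylab = "relative outcome value", ...)
  for (i in seq_along(keys)) {
    d <- x$data[[keys[i]]]
    graphics::points(d$dose, d$relative_value, pch = i, col = i)
  }
  labs <- sub("^[^|]+\\|", "", keys)
  graphics::legend("topleft", legend = gsub("\\|", ", day ", labs),
                   pch = seq_along(keys), col = seq_along(keys), bty = "n",
                   cex = 0.8)
  invisible(x)
}

#' Tabular comparison of dose metrics
#'
#' Pivots a (multi-metric) fit into one row per (outcome, timepoint) with
#' r, p and significance under each metric, flagging the winning metric
#' (smallest p, ties broken by larger |r|).
#'
#' @param fit a [correlate_dose_metrics()] fit, or a list of fits to pool.
#' @return A data.frame of class \code{metric_report}.
#' @export
metric_report <- function(fit) {
  if (inherits(fit, "metric_correlation")) fit <- list(fit)
  if (!length(fit) || !all(vapply(fit, inherits, logical(1), "metric_correlation")))
    validation_error("fit must be one or more metric_correlation objects")
  res <- do.call(rbind, lapply(fit, `[[`, "results"))
  if (!nrow(res)) {
    out <- data.frame(outcome = character(), timepoint_day = numeric(),
                      winner = character(), stringsAsFactors = FALSE)
    class(out) <- c("metric_report", "data.frame")
    return(out)
  }
  metrics <- unique(res$metric)
  cells <- unique(res[, c("outcome", "timepoint_day")])
  cells <- cells[order(cells$outcome, cells$timepoint_day), , drop = FALSE]
  out <- cells
  for (m in metrics) {
    sub <- res[res$metric == m, ]
    idx <- match(paste(cells$outcome, cells$timepoint_day),
                 paste(sub$outcome, sub$timepoint_day))
    out[[paste0("r_", m)]] <- sub$r[idx]
    out[[paste0("p_", m)]] <- sub$p[idx]
    out[[paste0("sig_", m)]] <- sub$significant[idx]
  }
  out$winner <- vapply(seq_len(nrow(cells)), function(i) {
    sub <- res[res$outcome == cells$outcome[i] &
                 res$timepoint_day == cells$timepoint_day[i], ]
    sub <- sub[order(sub$p, -abs(sub$r)), ]
    sub$metric[1]
  }, character(1))
  rownames(out) <- NULL
  class(out) <- c("metric_report", "data.frame")
  out
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat(sprintf("Dose-metric report (%d outcome cells)\n", nrow(x)))
  print.data.frame(as.data.frame(x), digits = digits, row.names = FALSE)
  invisible(x)
}
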
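# Outcome panel: endpoint x timepoint x material toxicology values with
# control baselines, plus the transforms the dose-metric comparison
# consumes (fold changes, reference normalization) and the stereology
# estimators behind the alveolar wall thickness endpoint.

outcome_cols <- c("material_id", "outcome", "timepoint_day", "value",
                  "unit", "control_mean", "control_se", "n", "provenance")

#' Toxicology outcome panel
#'
#' A validated collection of outcome observations keyed by
#' (material, outcome, timepoint). Each row carries the observed value in
#' its outcome units plus optional control baseline (mean, SE) and group
#' size. Duplicate keys are rejected so every downstream lookup is
#' unambiguous.
#'
#' @param observations a data.frame with columns \code{material_id},
#'   \code{outcome}, \code{timepoint_day}, \code{value} and optionally
#'   \code{unit}, \code{control_mean}, \code{control_se}, \code{n},
#'   \code{provenance}.
#' @return A data.frame of class \code{outcome_panel}.
#' @export
outcome_panel <- function(observations) {
  if (!is.data.frame(observations))
    validation_error("observations must be a data.frame")
  df <- as.data.frame(observations, stringsAsFactors = FALSE)
  required <- c("material_id", "outcome", "timepoint_day", "value")
  for (col in required)
    if (!col %in% names(df))
      validation_error(sprintf("observations lack required column '%s'", col))
  for (col in setdiff(outcome_cols, names(df)))
    df[[col]] <- rep(if (col %in% c("unit", "provenance")) NA_character_
                     else NA_real_, nrow(df))
  df <- df[, outcome_cols]
  if (nrow(df)) {
    if (any(!is.finite(df$value)))
      validation_error("all outcome values must be finite")
    if (any(!is.finite(df$timepoint_day) | df$timepoint_day <= 0))
      validation_error("timepoint_day must be positive")
    bad_se <- !is.na(df$control_se) & df$control_se < 0
    if (any(bad_se)) validation_error("control_se must be >= 0")
    key <- paste(df$material_id, df$outcome, df$timepoint_day, sep = "|")
    if (anyDuplicated(key))
      validation_error(sprintf(
        "duplicate (material, outcome, timepoint) keys: %s",
        paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  rownames(df) <- NULL
  class(df) <- c("outcome_panel", "data.frame")
  df
}

#' @export
print.outcome_panel <- function(x, ...) {
  cat(sprintf(
    "Outcome panel: %d observations, %d materials, %d outcomes, days {%s}\n",
    nrow(x), length(unique(x$material_id)), length(unique(x$outcome)),
    paste(sort(unique(x$timepoint_day)), collapse = ", ")))
  invisible(x)
}

#' Fold change over a control baseline
#'
#' @param exposed observed value(s) in the exposed group.
#' @param control control baseline(s), strictly positive.
#' @return \code{exposed/control}, vectorized.
#' @examples
#' fold_change(1106e3, 1.58e3) # 700-fold neutrophil influx
#' @export
fold_change <- function(exposed, control) {
  if (!is.numeric(exposed) || !is.numeric(control))
    domain_error("exposed and control must be numeric")
  if (any(!is.finite(control)) || any(control <= 0))
    domain_error("control baseline must be > 0")
  exposed / control
}

panel_slice <- function(panel, outcome, timepoint) {
  stopifnot(inherits(panel, "outcome_panel"))
  panel[panel$outcome == outcome & panel$timepoint_day == timepoint, ,
        drop = FALSE]
}

#' Outcome values relative to a reference material
#'
#' Divides every material's value at one (outcome, timepoint) cell by the
#' reference material's value at the same cell. Scale cancels, so any
#' common rescaling of the raw values leaves the result unchanged.
#'
#' @param panel an [outcome_panel()].
#' @param outcome,timepoint the cell to normalize.
#' @param reference material id used as denominator.
#' @return Named numeric vector, one entry per material in the cell.
#' @export
relative_to_reference <- function(panel, outcome, timepoint, reference) {
  cell <- panel_slice(panel, outcome, timepoint)
  if (!nrow(cell))
    lookup_error(sprintf("no observations for outcome '%s' at day %s",
                         outcome, timepoint))
  ref <- cell$value[cell$material_id == reference]
  if (!length(ref))
    lookup_error(sprintf(
      "reference material '%s' absent for outcome '%s' at day %s",
      reference, outcome, timepoint))
  if (ref == 0)
    domain_error(sprintf(
      "reference value is zero for outcome '%s' at day %s", outcome, timepoint))
  stats::setNames(cell$value / ref, cell$material_id)
}

#' Alveolar wall thickness from stereological densities
#'
#' Mean thickness of a sheet-like structure equals twice the ratio of its
#' volume density to its surface density, \eqn{2 V_v / S_v}.
#'
#' @param volume_density point-fraction volume density \eqn{V_v} in [0, 1].
#' @param surface_density surface density \eqn{S_v} (> 0), reciprocal
#'   length; the result is in the reciprocal of its unit.
#' @return Thickness, length units of \code{1/surface_density}.
#' @examples
#' alveolar_wall_thickness(0.25, 0.05) # 10 (um when Sv is per um)
#' @export
alveolar_wall_thickness <- function(volume_density, surface_density) {
  check_scalar(volume_density, "volume_density", allow_zero = TRUE)
  if (volume_density > 1)
    domain_error("volume_density must be <= 1")
  check_scalar(surface_density, "surface_density")
  2 * volume_density / surface_density
}

#' Point-count and intercept-count stereology estimators
#'
#' Standard design-based estimators: volume density is the point fraction
#' \eqn{V_v = P / P_T}; surface density is \eqn{S_v = 2 I / L} for
#' \eqn{I} intercepts along test lines of total length \eqn{L}.
#'
#' @param points_on_structure points hitting the structure (\eqn{P}).
#' @param total_points total test points (\eqn{P_T > 0}).
#' @param intercepts intersections of the test lines with the structure
#'   boundary (\eqn{I}).
#' @param test_line_length total test line length (\eqn{L > 0}).
#' @return A list with \code{vv} and \code{sv}.
#' @examples
#' stereology_estimates(50, 200, 30, 1200) # Vv 0.25, Sv 0.05
#' @export
stereology_estimates <- function(points_on_structure, total_points,
                                 intercepts, test_line_length) {
  p <- check_count(points_on_structure, "points_on_structure")
  pt <- check_count(total_points, "total_points", minimum = 1L)
  i <- check_count(intercepts, "intercepts")
  check_scalar(test_line_length, "test_line_length")
  if (p > pt)
    domain_error("points_on_structure cannot exceed total_points")
  list(vv = p / pt, sv = 2 * i / test_line_length)
}

#' Read an outcome table
#'
#' Reads the \code{outcomes.csv} schema (\code{material_id},
#' \code{outcome}, \code{timepoint_day}, \code{value}, \code{unit},
#' \code{control_mean}, \code{control_se}, \code{n}, optional
#' \code{provenance}) into a validated [outcome_panel()]. Duplicate keys
#' are reported with their row numbers.
#'
#' @param path CSV file path.
#' @return An [outcome_panel()].
#' @export
read_outcomes <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) parse_error(conditionMessage(e)))
  required <- c("material_id", "outcome", "timepoint_day", "value")
  for (col in required)
    if (!col %in% names(df))
      parse_error(sprintf("outcomes file lacks required column '%s'", col))
  if (nrow(df)) {
    key <- paste(df$material_id, df$outcome, df$timepoint_day, sep = "|")
    dup <- which(duplicated(key))
    if (length(dup))
      parse_error(sprintf("duplicate keys at rows %s of '%s'",
                          paste(dup + 1L, collapse = ", "), path))
  }
  tryCatch(outcome_panel(df),
           esadose_validation_error = function(e) parse_error(conditionMessage(e)))
}

#' Write an outcome table
#'
#' Writes a panel back to the \code{outcomes.csv} schema. Numeric columns
#' are serialized at full double precision so a write/read round trip
#' reproduces the panel bit-for-bit.
#'
#' @param panel an [outcome_panel()].
#' @param path output CSV file path.
#' @return The path, invisibly.
#' @export
write_outcomes <- function(panel, path) {
  stopifnot(inherits(panel, "outcome_panel"))
  df <- as.data.frame(panel)
  class(df) <- "data.frame"
  for (col in c("timepoint_day", "value", "control_mean", "control_se", "n"))
    df[[col]] <- ifelse(is.na(df[[col]]), "", sprintf("%.17g", df[[col]]))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
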
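# Dose-metric bookkeeping: turn material characterization into per-animal
# doses under competing metrics (mass, structure number, BET surface,
# effective surface), with explicit provenance for values transcribed from a
# report rather than recomputed.

#' One nanomaterial's characterization
#'
#' Bundles the quantities needed to place a material on every dose metric:
#' administered mass, BET specific surface area, effective surface area
#' (either supplied per gram or derivable from a geometry object), and the
#' optional structure count and iron content. Printed per-animal doses from
#' an external report can be attached so computed and reported values travel
#' side by side.
#'
#' @param material_id unique material label.
#' @param mass_dose_ug administered mass, micrograms per animal (> 0).
#' @param bet_ssa BET specific surface area, m\eqn{^2}/g (optional).
#' @param esa effective surface area, m\eqn{^2}/g (optional; at most the
#'   graphene bound of 1315).
#' @param geometry optional [bundle_geometry()] or [cnf_geometry()] used to
#'   compute \code{esa} when not supplied.
#' @param structure_count optional number of structures (fibers or
#'   agglomerates, counted as single entities) in the administered dose.
#' @param iron_pct optional iron content, percent by weight.
#' @param ssa_dose_printed,esa_dose_printed optional externally reported
#'   per-animal surface doses, m\eqn{^2} (provenance "printed" rather than
#'   "computed").
#' @return An object of class \code{material_record}.
#' @examples
#' material_record("SWCNT", 40, bet_ssa = 1040,
#'                 geometry = bundle_geometry(3, 65))
#' @export
material_record <- function(material_id, mass_dose_ug,
                            bet_ssa = NA_real_, esa = NA_real_,
                            geometry = NULL,
                            structure_count = NA_real_,
                            iron_pct = NA_real_,
                            ssa_dose_printed = NA_real_,
                            esa_dose_printed = NA_real_) {
  if (!is.character(material_id) || length(material_id) != 1L ||
      !nzchar(material_id))
    validation_error("material_id must be a non-empty string")
  check_scalar(mass_dose_ug, "mass_dose_ug")
  if (!is.na(bet_ssa)) check_scalar(bet_ssa, "bet_ssa")
  if (!is.na(esa)) {
    check_scalar(esa, "esa")
    if (esa > GRAPHENE_SSA)
      domain_error(sprintf(
        "esa (%g m^2/g) exceeds the graphene bound of %g m^2/g",
        esa, GRAPHENE_SSA))
  }
  if (!is.null(geometry) &&
      !inherits(geometry, c("bundle_geometry", "cnf_geometry")))
    validation_error("geometry must be a bundle_geometry or cnf_geometry")
  if (!is.na(structure_count)) check_scalar(structure_count, "structure_count")
  structure(list(material_id = material_id, mass_dose_ug = mass_dose_ug,
                 bet_ssa = bet_ssa, esa = esa, geometry = geometry,
                 structure_count = structure_count, iron_pct = iron_pct,
                 ssa_dose_printed = ssa_dose_printed,
                 esa_dose_printed = esa_dose_printed),
            class = "material_record")
}

#' Per-animal surface dose
#'
#' Administered mass times per-gram surface area. Mass is given in
#' micrograms (the usual reporting unit for bolus lung exposure); the
#' conversion to grams is internal and exact.
#'
#' @param mass_ug administered mass, micrograms (> 0).
#' @param area_m2_per_g surface area per gram, m\eqn{^2}/g (> 0).
#' @return Surface dose in m\eqn{^2} per animal.
#' @examples
#' surface_dose(40, 1040) # 4.16e-2 m^2
#' @export
surface_dose <- function(mass_ug, area_m2_per_g) {
  check_scalar(mass_ug, "mass_ug")
  check_scalar(area_m2_per_g, "area_m2_per_g")
  (mass_ug * 1e-6) * area_m2_per_g
}

resolve_esa <- function(rec, esa_from) {
  from_geom <- function() {
    if (is.null(rec$geometry)) return(list(esa = NA_real_, src = NA_character_))
    esa <- if (inherits(rec$geometry, "bundle_geometry"))
      bundle_esa(rec$geometry) else cnf_esa(rec$geometry)
    list(esa = esa, src = "geometry")
  }
  from_sup <- function() {
    if (is.na(rec$esa)) list(esa = NA_real_, src = NA_character_)
    else list(esa = rec$esa, src = "supplied")
  }
  first <- if (esa_from == "geometry") from_geom() else from_sup()
  if (is.na(first$esa)) {
    second <- if (esa_from == "geometry") from_sup() else from_geom()
    if (!is.na(second$esa)) return(second)
  }
  first
}

#' Build a per-animal dose table under all metrics
#'
#' Computes, for each material, the dose expressed as mass (g), structure
#' number, BET-surface dose and effective-surface dose (m\eqn{^2} per
#' animal). Missing inputs yield \code{NA} cells, never silent zeros.
#' Effective surface area per gram is taken from the supplied value by
#' default, falling back to the geometry model (or the other way round with
#' \code{esa_from = "geometry"}); the \code{esa_source} column records which
#' route produced each value. Externally reported ("printed") surface doses
#' attached to the records are carried in \code{*_printed} columns.
#'
#' @param materials a list of [material_record()] objects (a single record
#'   is accepted), with unique ids.
#' @param esa_from \code{"supplied"} (default) or \code{"geometry"}:
#'   preferred source of the per-gram effective surface area.
#' @return A \code{data.frame} of class \code{dose_table}, one row per
#'   material.
#' @examples
#' build_dose_table(list(
#'   material_record("SWCNT", 40, bet_ssa = 1040,
#'                   geometry = bundle_geometry(3, 65))))
#' @export
build_dose_table <- function(materials, esa_from = c("supplied", "geometry")) {
  esa_from <- match.arg(esa_from)
  if (inherits(materials, "material_record")) materials <- list(materials)
  if (!is.list(materials) ||
      !all(vapply(materials, inherits, logical(1), "material_record")))
    validation_error("materials must be a list of material_record objects")
  ids <- vapply(materials, `[[`, character(1), "material_id")
  if (anyDuplicated(ids))
    validation_error(sprintf("duplicate material ids: %s",
                             paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  rows <- lapply(materials, function(rec) {
    mass_g <- rec$mass_dose_ug * 1e-6
    esa <- resolve_esa(rec, esa_from)
    data.frame(
      material_id = rec$material_id,
      mass_ug = rec$mass_dose_ug,
      mass_g = mass_g,
      number = rec$structure_count,
      bet_ssa = rec$bet_ssa,
      esa = esa$esa,
      esa_source = esa$src,
      ssa_dose = if (is.na(rec$bet_ssa)) NA_real_ else mass_g * rec$bet_ssa,
      esa_dose = if (is.na(esa$esa)) NA_real_ else mass_g * esa$esa,
      iron_pct = rec$iron_pct,
      ssa_dose_printed = rec$ssa_dose_printed,
      esa_dose_printed = rec$esa_dose_printed,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(material_id = character(), mass_ug = numeric(),
               mass_g = numeric(), number = numeric(), bet_ssa = numeric(),
               esa = numeric(), esa_source = character(),
               ssa_dose = numeric(), esa_dose = numeric(),
               iron_pct = numeric(), ssa_dose_printed = numeric(),
               esa_dose_printed = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("dose_table", "data.frame")
  out
}

dose_metric_column <- function(metric) {
  switch(metric,
         mass = "mass_g", number = "number",
         ssa = "ssa_dose", esa = "esa_dose",
         lookup_error(sprintf(
           "unknown dose metric '%s' (use mass, number, ssa or esa)", metric)))
}

# Dose vector under a metric; printed values take precedence when asked for
# and available, with computed values as fallback.
dose_values <- function(table, metric, use_printed = FALSE) {
  col <- dose_metric_column(metric)
  v <- table[[col]]
  if (use_printed && metric %in% c("ssa", "esa")) {
    printed <- table[[paste0(col, "_printed")]]
    v <- ifelse(is.na(printed), v, printed)
  }
  names(v) <- table$material_id
  v
}

#' Between-material dose ratio under a metric
#'
#' Ratio of two materials' per-animal doses under a named metric. With
#' \code{use_printed = TRUE}, externally reported surface doses are used
#' where available (falling back to computed values), which is how published
#' ratios with a reported denominator are reproduced.
#'
#' @param table a [build_dose_table()] result.
#' @param metric one of \code{"mass"}, \code{"number"}, \code{"ssa"},
#'   \code{"esa"}.
#' @param material,reference material ids (numerator, denominator).
#' @param use_printed prefer printed surface doses over computed ones.
#' @return The positive ratio dose(material)/dose(reference).
#' @export
dose_ratio <- function(table, metric, material, reference,
                       use_printed = FALSE) {
  stopifnot(inherits(table, "dose_table"))
  v <- dose_values(table, metric, use_printed)
  for (id in c(material, reference))
    if (!id %in% names(v))
      lookup_error(sprintf("material '%s' not present in dose table", id))
  num <- v[[material]]; den <- v[[reference]]
  if (is.na(num) || is.na(den))
    lookup_error(sprintf(
      "metric '%s' is undefined for %s", metric,
      paste(c(material, reference)[is.na(c(num, den))], collapse = " and ")))
  num / den
}

#' @export
print.dose_table <- function(x, digits = 4, ...) {
  cat(sprintf("Per-animal dose table (%d materials)\n", nrow(x)))
  show <- x[, c("material_id", "mass_ug", "number", "ssa_dose", "esa_dose")]
  print.data.frame(show, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Read a materials characterization table
#'
#' Reads the \code{materials.csv} schema: \code{material_id},
#' \code{mass_dose_ug}, optional \code{bet_ssa_m2_per_g},
#' \code{esa_m2_per_g}, geometry columns (\code{d_swcnt_nm} +
#' \code{d_bundle_nm} for bundles, \code{d_od_nm} + \code{d_hc_nm} for
#' nanofibers, optional \code{interlayer_nm}), \code{structure_count},
#' \code{iron_pct}, and optional printed per-animal doses
#' (\code{ssa_dose_printed_m2}, \code{esa_dose_printed_m2}).
#'
#' @param path CSV file path (UTF-8, comma separated, header row).
#' @return A list of [material_record()] objects.
#' @export
read_materials <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) parse_error(conditionMessage(e)))
  for (col in c("material_id", "mass_dose_ug"))
    if (!col %in% names(df))
      parse_error(sprintf("materials file lacks required column '%s'", col))
  get_num <- function(row, col) {
    if (!col %in% names(df)) return(NA_real_)
    v <- suppressWarnings(as.numeric(df[[col]][row]))
    if (length(v) != 1L || is.na(v)) NA_real_ else v
  }
  lapply(seq_len(nrow(df)), function(i) {
    geom <- NULL
    ds <- get_num(i, "d_swcnt_nm"); db <- get_num(i, "d_bundle_nm")
    dod <- get_num(i, "d_od_nm"); dhc <- get_num(i, "d_hc_nm")
    il <- get_num(i, "interlayer_nm")
    if (!is.na(ds) && !is.na(db)) geom <- bundle_geometry(ds, db)
    else if (!is.na(dod) && !is.na(dhc))
      geom <- cnf_geometry(dod, dhc, if (is.na(il)) 0.34 else il)
    material_record(
      material_id = as.character(df$material_id[i]),
      mass_dose_ug = get_num(i, "mass_dose_ug"),
      bet_ssa = get_num(i, "bet_ssa_m2_per_g"),
      esa = get_num(i, "esa_m2_per_g"),
      geometry = geom,
      structure_count = get_num(i, "structure_count"),
      iron_pct = get_num(i, "iron_pct"),
      ssa_dose_printed = get_num(i, "ssa_dose_printed_m2"),
      esa_dose_printed = get_num(i, "esa_dose_printed_m2"))
  })
}
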
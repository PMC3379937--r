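# Synthetic data: log-normal geometry samples (right-skewed, positive, the
# shape measured size distributions of fibrous carbon materials show) and
# outcome panels whose expected relative value is affine in surface dose
# with multiplicative log-normal noise. Seeds are explicit; the global RNG
# state is restored after each call.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

geometry_defaults <- function(kind) {
  switch(kind,
    # rope diameters observed around 65 nm (up to ~150 nm); SWCNT 1-3 um long
    bundle = list(diameter_meanlog = log(65), diameter_sdlog = 0.2,
                  hollow_meanlog = NA_real_, hollow_sdlog = NA_real_,
                  length_meanlog = log(1.7), length_sdlog = 0.3),
    # CNF outer diameters 80-160 nm around ~109, cores ~53 nm; 5-30 um long
    cnf = list(diameter_meanlog = log(109), diameter_sdlog = 0.15,
               hollow_meanlog = log(53), hollow_sdlog = 0.15,
               length_meanlog = log(12), length_sdlog = 0.4),
    # plain fiber (asbestos-like): widths 160-800 nm, lengths 2-30 um
    fiber = list(diameter_meanlog = log(360), diameter_sdlog = 0.4,
                 hollow_meanlog = NA_real_, hollow_sdlog = NA_real_,
                 length_meanlog = log(8), length_sdlog = 0.5))
}

#' Simulate geometry samples
#'
#' Draws diameters and lengths from log-normal distributions for one of
#' three material archetypes: \code{"bundle"} (SWCNT rope around a fixed
#' constituent tube diameter), \code{"cnf"} (concentric-layer nanofiber
#' with outer and hollow-core diameters) or \code{"fiber"} (plain solid
#' fiber). Draws violating the geometric invariants (e.g. a sampled core
#' wider than the sampled outer diameter) are rejected and redrawn up to
#' \code{max_retries} rounds; parameter settings under which valid draws
#' are unreachable raise a config error.
#'
#' @param n sample size (>= 1).
#' @param kind material archetype.
#' @param diameter_meanlog,diameter_sdlog log-normal location/scale of the
#'   outer (rope/fiber) diameter, nm.
#' @param hollow_meanlog,hollow_sdlog log-normal location/scale of the
#'   hollow-core diameter, nm (\code{"cnf"} only).
#' @param length_meanlog,length_sdlog log-normal location/scale of the
#'   structure length, micrometers.
#' @param d_swcnt constituent tube diameter for bundles, nm.
#' @param interlayer graphene interlayer spacing for nanofibers, nm.
#' @param seed integer seed; the global RNG state is left untouched.
#' @param max_retries resampling rounds before declaring the configuration
#'   unreachable.
#' @return A data.frame of valid geometries (columns depend on
#'   \code{kind}) plus \code{length_um}, with the archetype in
#'   \code{attr(, "kind")}. Every row satisfies the corresponding geometry
#'   constructor's invariants.
#' @examples
#' head(simulate_geometry(5, "cnf", seed = 1))
#' @export
simulate_geometry <- function(n, kind = c("bundle", "cnf", "fiber"),
                              diameter_meanlog = NULL, diameter_sdlog = NULL,
                              hollow_meanlog = NULL, hollow_sdlog = NULL,
                              length_meanlog = NULL, length_sdlog = NULL,
                              d_swcnt = 3, interlayer = 0.34,
                              seed = NULL, max_retries = 1000L) {
  kind <- match.arg(kind)
  n <- check_count(n, "n", minimum = 1L)
  def <- geometry_defaults(kind)
  pick <- function(x, d) if (is.null(x)) d else x
  dm <- pick(diameter_meanlog, def$diameter_meanlog)
  ds <- pick(diameter_sdlog, def$diameter_sdlog)
  hm <- pick(hollow_meanlog, def$hollow_meanlog)
  hs <- pick(hollow_sdlog, def$hollow_sdlog)
  lm_ <- pick(length_meanlog, def$length_meanlog)
  ls <- pick(length_sdlog, def$length_sdlog)
  for (s in list(ds, ls)) check_scalar(s, "sdlog", allow_zero = TRUE)
  if (kind == "cnf") check_scalar(hs, "hollow_sdlog", allow_zero = TRUE)
  check_scalar(d_swcnt, "d_swcnt")
  check_scalar(interlayer, "interlayer")

  valid <- function(df) {
    switch(kind,
           bundle = df$d_bundle >= d_swcnt,
           cnf = (df$d_od - df$d_hc) >= 2 * interlayer & df$d_od > df$d_hc,
           fiber = rep(TRUE, nrow(df)))
  }
  draw <- function(m) {
    out <- data.frame(length_um = stats::rlnorm(m, lm_, ls))
    if (kind == "bundle") {
      out$d_swcnt <- rep(d_swcnt, m)
      out$d_bundle <- stats::rlnorm(m, dm, ds)
    } else if (kind == "cnf") {
      out$d_od <- stats::rlnorm(m, dm, ds)
      out$d_hc <- stats::rlnorm(m, hm, hs)
      out$interlayer <- rep(interlayer, m)
    } else {
      out$diameter <- stats::rlnorm(m, dm, ds)
    }
    out
  }
  with_seed(seed, {
    sample <- draw(n)
    ok <- valid(sample)
    tries <- 0L
    while (any(!ok)) {
      tries <- tries + 1L
      if (tries > max_retries)
        config_error(sprintf(
          "geometry invariants unreachable for kind '%s' after %d resampling rounds",
          kind, max_retries))
      redraw <- draw(sum(!ok))
      sample[!ok, names(redraw)] <- redraw
      ok <- valid(sample)
    }
    sample <- sample[, c(setdiff(names(sample), "length_um"), "length_um")]
    attr(sample, "kind") <- kind
    sample
  })
}

#' Simulate an outcome panel affine in surface dose
#'
#' Generates relative outcome values with expectation
#' \eqn{a + b \cdot dose} under a chosen dose metric and multiplicative
#' log-normal noise: \eqn{value = (a + b x) \exp(\epsilon - \sigma^2/2)},
#' \eqn{\epsilon \sim N(0, \sigma^2)} (the half-variance shift keeps the
#' expectation exactly affine). With \code{sigma = 0} the panel is exactly
#' affine in dose, so the generating metric correlates perfectly.
#'
#' @param doses a [build_dose_table()] result naming the materials.
#' @param metric dose metric driving the response.
#' @param outcomes outcome names to generate (independent noise per
#'   outcome).
#' @param timepoints days to generate (independent noise per timepoint).
#' @param intercept baseline relative value \eqn{a} (control level is 1).
#' @param slope response per m\eqn{^2} of surface dose, \eqn{b}. The
#'   default (1000 per m\eqn{^2}) gives roughly the day-one neutrophil
#'   response magnitude over surface doses of a few 10\eqn{^{-3}}
#'   m\eqn{^2}.
#' @param sigma log-normal noise scale (>= 0).
#' @param seed integer seed.
#' @return An [outcome_panel()] with \code{control_mean = 1} and unit
#'   "relative value".
#' @examples
#' simulate_outcome_panel(fixture_dose_table(), sigma = 0, seed = 1)
#' @export
simulate_outcome_panel <- function(doses, metric = "esa", outcomes = "PMN",
                                   timepoints = 1, intercept = 1,
                                   slope = 1000, sigma = 0.1, seed = NULL) {
  stopifnot(inherits(doses, "dose_table"))
  check_scalar(intercept, "intercept", positive = FALSE)
  check_scalar(slope, "slope", positive = FALSE)
  check_scalar(sigma, "sigma", allow_zero = TRUE)
  x <- dose_values(doses, metric)
  if (any(is.na(x)))
    lookup_error(sprintf("metric '%s' undefined for: %s", metric,
                         paste(names(x)[is.na(x)], collapse = ", ")))
  mu <- intercept + slope * x
  if (any(mu <= 0))
    config_error("intercept + slope * dose must stay positive for every material")
  grid <- expand.grid(material_id = names(x), outcome = outcomes,
                      timepoint_day = timepoints,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  with_seed(seed, {
    noise <- exp(stats::rnorm(nrow(grid), 0, sigma) - sigma^2 / 2)
    grid$value <- mu[grid$material_id] * noise
    grid$unit <- "relative value"
    grid$control_mean <- 1
    grid$control_se <- NA_real_
    grid$n <- NA_real_
    grid$provenance <- "simulated"
    outcome_panel(grid)
  })
}

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "esadose")
  if (!nzchar(path)) lookup_error(sprintf("packaged fixture '%s' not found", file))
  path
}

#' Packaged three-material characterization fixture
#'
#' The materials table for the bundled reference study of three fibrous
#' carbon materials in mice: HiPco SWCNT (40 ug/animal, BET 1040
#' m\eqn{^2}/g, 3 nm tubes roped into 65 nm bundles), Pyrograf CNF (120
#' ug/animal, BET 45 m\eqn{^2}/g, 109/53 nm outer/core diameters) and UICC
#' crocidolite asbestos (120 ug/animal, BET 8.3 m\eqn{^2}/g; well
#' dispersed, so its effective surface area is taken equal to its BET
#' value). Per-gram effective surface areas are stored at their reported
#' precision (138.2, 21, 8.3 m\eqn{^2}/g); the SWCNT and CNF records also
#' carry geometry, so the full-precision model route is available via
#' \code{build_dose_table(esa_from = "geometry")}. Reported per-animal
#' surface doses ride along as printed provenance (including the asbestos
#' 9.6e-4 m\eqn{^2}, which disagrees slightly with 120 ug x 8.3
#' m\eqn{^2}/g = 9.96e-4; both are kept).
#'
#' @return A list of [material_record()] objects.
#' @export
fixture_materials <- function() read_materials(fixture_path("materials.csv"))

#' Packaged outcome panel fixture
#'
#' Relative pulmonary outcome values for the three fixture materials at 1,
#' 7 and 28 days. Day-one PMN values are the asbestos-normalized vector
#' (1, 2.8, 5.7); most other series are fold-of-control values as
#' reported. A \code{provenance} column separates reported numbers from
#' the two reconstructed day-one asbestos baselines (protein and 4-HNE at
#' control level), and the separately reported control-fold PMN series
#' (700/150/675/25), which is mutually inconsistent with the
#' asbestos-normalized vector, is kept as its own outcome
#' (\code{PMN_fold_control}) without reconciliation.
#'
#' @return An [outcome_panel()].
#' @export
fixture_outcomes <- function() read_outcomes(fixture_path("outcomes.csv"))

#' Dose table of the packaged fixture
#'
#' @param esa_from passed to [build_dose_table()]; the default uses the
#'   reported per-gram effective surface areas, \code{"geometry"} uses the
#'   full-precision geometric model.
#' @return A [build_dose_table()] result for the three fixture materials.
#' @export
fixture_dose_table <- function(esa_from = c("supplied", "geometry")) {
  build_dose_table(fixture_materials(), esa_from = match.arg(esa_from))
}
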
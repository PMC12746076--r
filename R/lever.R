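#' Third-class lever geometry of the ankle dorsiflexion mechanism
#'
#' In the avian ankle, the m. tibialis cranialis inserts on a tubercle on the
#' dorsal tarsometatarsus, forming a third-class lever about the
#' intertarsal joint: the force arm FA runs from the joint (fulcrum) to the
#' tubercle, the resistance arm RA from the joint to the point where prey
#' resistance acts (taken as the distal tarsometatarsus). Arms are stored in
#' meters; [geometry_from_morphometrics()] converts from millimetre skeletal
#' metrics (RA = tarsometatarsus length, FA = tubercle distance).
#'
#' @param species Species label.
#' @param FA Force arm (inlever), m, > 0.
#' @param RA Resistance arm (outlever), m, > 0. For a third-class lever
#'   FA < RA; a violation warns but is kept (odd fossils may do odd things).
#' @param group Optional family label.
#' @return A one-row tibble of class `lever_geometry`.
#' @examples
#' lever_geometry("Bubo virginianus", FA = 0.0213, RA = 0.0626)
#' @export
lever_geometry <- function(species, FA, RA, group = NA_character_) {
  if (any(FA <= 0) || any(RA <= 0)) abort("`FA` and `RA` must be positive.")
  if (any(FA >= RA)) {
    warn("FA >= RA: not a third-class lever configuration for these rows.")
  }
  out <- tibble(species = species, group = group, FA = FA, RA = RA)
  class(out) <- c("lever_geometry", class(out))
  out
}

#' Convert millimetre skeletal metrics to lever arms in meters
#'
#' @param summaries Per-species summaries (see [summarize_all_species()])
#'   with `tmt_length_mean` and `tubercle_distance_mean` in mm.
#' @return A `lever_geometry` tibble (arms in m).
#' @export
geometry_from_morphometrics <- function(summaries) {
  lever_geometry(species = summaries$species,
                 FA = summaries$tubercle_distance_mean / 1000,
                 RA = summaries$tmt_length_mean / 1000,
                 group = summaries$group %||% NA_character_)
}

#' Lever arms of the six focal raptors
#'
#' Species-representative force and resistance arms (m) for the three focal
#' accipitrids and three focal strigids, as used in the worked lever tables.
#' RA is the averaged tarsometatarsus length and FA the averaged tubercle
#' distance, both converted from mm.
#'
#' @return A `lever_geometry` tibble with six rows.
#' @export
focal_lever_geometries <- function() {
  lever_geometry(
    species = c("Accipiter striatus", "Astur cooperii", "Buteo jamaicensis",
                "Megascops asio", "Asio otus", "Bubo virginianus"),
    group = rep(c("accipitrid", "strigid"), each = 3L),
    FA = c(0.0072, 0.0127, 0.0181, 0.0089, 0.0119, 0.0213),
    RA = c(0.0514, 0.0669, 0.0823, 0.0312, 0.0411, 0.0626))
}

#' Prey scenarios
#'
#' A scenario is a prey item with a mass; its resistance is its weight force.
#' `standard_prey_scenarios()` returns the two common-prey scenarios used for
#' cross-species comparison: a 140 g chipmunk (Tamias striatus) and a 3.6 kg
#' Virginia opossum (Didelphis virginiana).
#'
#' @param prey Prey label.
#' @param mass_kg Prey mass in kg, > 0.
#' @param g Gravitational acceleration, m s^-2 (default 9.81).
#' @return A one-row tibble of class `prey_scenario`.
#' @export
prey_scenario <- function(prey, mass_kg, g = 9.81) {
  if (any(mass_kg <= 0)) abort("`mass_kg` must be positive.")
  if (any(g <= 0)) abort("`g` must be positive.")
  out <- tibble(prey = prey, mass_kg = mass_kg, g = g)
  class(out) <- c("prey_scenario", class(out))
  out
}

#' @rdname prey_scenario
#' @export
standard_prey_scenarios <- function(g = 9.81) {
  prey_scenario(prey = c("Tamias striatus", "Didelphis virginiana"),
                mass_kg = c(0.140, 3.6), g = g)
}

#' Resistance of prey
#'
#' The weight force a prey item exerts on the pes: `RP = mass * g` (N).
#'
#' @param scenario A [prey_scenario()] tibble (or any data frame with
#'   `mass_kg` and `g` columns).
#' @return Resistance force(s) in N.
#' @examples
#' resistance_force(prey_scenario("Tamias striatus", 0.140))  # 1.3734 N
#' @export
resistance_force <- function(scenario) {
  if (any(scenario$mass_kg <= 0)) abort("Prey mass must be positive.")
  scenario$mass_kg * scenario$g
}

#' Required muscle force to lift a resistance
#'
#' Solves the lever balance `F * FA = RP * RA` for the muscle force:
#' `F = RP * RA / FA` (N). Because FA < RA in a third-class lever, F always
#' exceeds RP.
#'
#' @param RP Resistance of prey (N).
#' @param geometry A [lever_geometry()] row (recycled against `RP`).
#' @return Muscle force in N.
#' @examples
#' muscle_force(1.3734, lever_geometry("A. striatus", FA = 0.0072, RA = 0.0514))
#' @export
muscle_force <- function(RP, geometry) {
  if (any(geometry$FA <= 0)) abort("`FA` must be positive.")
  RP * geometry$RA / geometry$FA
}

#' Mechanical advantage of the dorsiflexion lever
#'
#' `MA = FA / RA`, the inlever divided by the outlever. Higher MA means less
#' muscle force is needed per unit prey resistance.
#'
#' @param geometry A [lever_geometry()] tibble.
#' @return Dimensionless MA value(s).
#' @examples
#' mechanical_advantage(focal_lever_geometries())
#' @export
mechanical_advantage <- function(geometry) {
  if (any(geometry$RA <= 0)) abort("`RA` must be positive.")
  geometry$FA / geometry$RA
}

#' Torque required to lift a prey item
#'
#' Two conventions are offered. `"muscle-outlever"` (the default, used in the
#' reference tables this package reproduces) multiplies the required muscle
#' force by the resistance arm: `torque = F * RA`. `"joint"` is the standard
#' quasi-static joint moment balance, `torque = RP * RA` (identically
#' `F * FA`). The two differ by the factor 1/MA.
#'
#' @param F Required muscle force (N), >= 0.
#' @param geometry A [lever_geometry()] tibble.
#' @param convention `"muscle-outlever"` or `"joint"`.
#' @param RP Resistance of prey (N); required for the `"joint"` convention.
#' @return Torque in N m.
#' @examples
#' g <- lever_geometry("Megascops asio", FA = 0.0089, RA = 0.0312)
#' required_torque(123.8, g)                       # 3.86 N m
#' required_torque(123.8, g, "joint", RP = 35.316) # 1.10 N m
#' @export
required_torque <- function(F, geometry,
                            convention = c("muscle-outlever", "joint"),
                            RP = NULL) {
  convention <- match.arg(convention)
  if (any(F < 0)) abort("`F` must be non-negative.")
  switch(convention,
    "muscle-outlever" = F * geometry$RA,
    "joint" = {
      if (is.null(RP)) RP <- F * geometry$FA / geometry$RA
      RP * geometry$RA
    })
}

#' Full lever table across species and prey scenarios
#'
#' Crosses every lever geometry with every prey scenario (or pairs them row
#' by row with `paired = TRUE`) and computes resistance of prey, mechanical
#' advantage, required muscle force and torque. All values are kept at full
#' precision; use [format_lever_table()] for a report rounded to the usual
#' printed precision.
#'
#' @param geometries A [lever_geometry()] tibble.
#' @param scenarios A [prey_scenario()] tibble.
#' @param convention Torque convention, see [required_torque()].
#' @param paired If `TRUE`, `geometries` and `scenarios` must have equal row
#'   counts and are matched row by row (species-specific prey); otherwise the
#'   full cross is computed.
#' @return A tibble of class `lever_table` with columns `species`, `prey`,
#'   `RP_N`, `RA_m`, `FA_m`, `MA`, `muscle_force_N`, `torque_Nm`.
#' @examples
#' lever_table(focal_lever_geometries(), standard_prey_scenarios())
#' @export
lever_table <- function(geometries, scenarios,
                        convention = c("muscle-outlever", "joint"),
                        paired = FALSE) {
  convention <- match.arg(convention)
  if (nrow(geometries) < 1L || nrow(scenarios) < 1L) {
    abort("`geometries` and `scenarios` must be non-empty.")
  }
  if (paired && nrow(geometries) != nrow(scenarios)) {
    abort("`paired = TRUE` needs equal row counts.")
  }
  grid <- if (paired) {
    dplyr::bind_cols(as_tibble(geometries), as_tibble(scenarios))
  } else {
    dplyr::cross_join(as_tibble(geometries), as_tibble(scenarios))
  }
  out <- grid |>
    mutate(RP_N = .data$mass_kg * .data$g,
           MA = .data$FA / .data$RA,
           muscle_force_N = .data$RP_N * .data$RA / .data$FA,
           torque_Nm = if (convention == "muscle-outlever")
             .data$muscle_force_N * .data$RA else .data$RP_N * .data$RA) |>
    select(any_of(c("species", "group")), "prey", "RP_N",
           RA_m = "RA", FA_m = "FA", "MA", "muscle_force_N", "torque_Nm") |>
    arrange(.data$prey)
  attr(out, "convention") <- convention
  class(out) <- c("lever_table", class(out))
  out
}

#' @rdname lever_table
#' @param x A `lever_table`.
#' @param digits Named list of decimal places per column.
#' @export
format_lever_table <- function(x, digits = list(RP_N = 2, RA_m = 4, FA_m = 4,
                                                MA = 2, muscle_force_N = 2,
                                                torque_Nm = 2)) {
  out <- as_tibble(x)
  for (nm in names(digits)) {
    if (nm %in% names(out)) out[[nm]] <- round(out[[nm]], digits[[nm]])
  }
  out
}

#' Write a lever table as CSV
#'
#' @param x A `lever_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lever_csv <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}
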
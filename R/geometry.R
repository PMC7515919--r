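#' Particle and adsorption-site geometry
#'
#' Geometric quantities entering the bound-state partition function and the
#' density-to-count mapping. The binding range L is set equal to the ligand
#' tether's gyration radius R_g; the effective particle radius is
#' R = R_np + h (core plus brush). Derived quantities:
#' binding volume v_bind = pi R^2 L; interacting area on the particle
#' A_int^np = 2 pi R_np R_g (all ligands grafted within 2 R_g of the binding
#' site); its projection on the flat surface
#' A_int^surf = pi (R_np^2 - (R_np - R_g)^2).
#'
#' @param core_radius Nanoparticle core radius R_np (nm).
#' @param gyration_radius Ligand gyration radius R_g (nm); also the binding
#'   range L.
#' @param brush_height_on_particle Brush height h on the particle (nm);
#'   default 0 for a bare core.
#'
#' @return Object of class `particle_geometry` with fields `core_radius`,
#'   `gyration_radius`, `brush_height_on_particle`, `effective_radius`,
#'   `binding_volume`, `area_particle`, `area_surface`.
#' @examples
#' particle_geometry(core_radius = 50, gyration_radius = 9)
#' @export
particle_geometry <- function(core_radius, gyration_radius,
                              brush_height_on_particle = 0) {
  stopifnot(core_radius > 0, gyration_radius > 0,
            brush_height_on_particle >= 0)
  if (gyration_radius >= 2 * core_radius) {
    stop("`gyration_radius` must be below 2 * core_radius for a positive surface interaction area",
         call. = FALSE)
  }
  r_eff <- core_radius + brush_height_on_particle
  structure(
    list(
      core_radius = core_radius,
      gyration_radius = gyration_radius,
      brush_height_on_particle = brush_height_on_particle,
      effective_radius = r_eff,
      binding_volume = pi * r_eff^2 * gyration_radius,
      area_particle = 2 * pi * core_radius * gyration_radius,
      area_surface = pi * (core_radius^2 - (core_radius - gyration_radius)^2)
    ),
    class = "particle_geometry"
  )
}

#' @export
print.particle_geometry <- function(x, ...) {
  cat(sprintf(
    paste0("<particle_geometry> R_np = %g nm, R_g = %g nm, h = %g nm\n",
           "  R = %g nm, v_bind = %.4g nm^3, A_int^np = %.4g nm^2, ",
           "A_int^surf = %.4g nm^2\n"),
    x$core_radius, x$gyration_radius, x$brush_height_on_particle,
    x$effective_radius, x$binding_volume, x$area_particle, x$area_surface
  ))
  invisible(x)
}

#' Convert a molar concentration to a number density in nm^-3
#'
#' The Langmuir activity z must carry units inverse to the binding volume
#' (nm^3), so bulk concentrations quoted in mol/L are converted via
#' Avogadro's number: 1 M = 0.6022 nm^-3.
#'
#' @param concentration Concentration in mol/L (>= 0). Vectorised.
#' @return Number density in nm^-3.
#' @examples
#' molar_to_number_density(1e-9)
#' @export
molar_to_number_density <- function(concentration) {
  stopifnot(all(concentration >= 0))
  concentration * 6.02214076e23 * 1e-24
}

#' Mean interacting counts from grafting densities
#'
#' Maps surface densities to the mean numbers of ligands and receptors in
#' the contact region: mean N_L = sigma_L * A_int^np and
#' mean N_R = rho_R * A_int^surf.
#'
#' @param ligand_density Ligand grafting density on the particle (nm^-2).
#' @param receptor_density Receptor density on the target surface (nm^-2).
#' @param geometry A [particle_geometry()].
#' @return Named list with `n_ligands` and `n_receptors` (real means).
#' @export
counts_from_densities <- function(ligand_density, receptor_density, geometry) {
  stopifnot(inherits(geometry, "particle_geometry"),
            ligand_density >= 0, receptor_density >= 0)
  list(
    n_ligands = ligand_density * geometry$area_particle,
    n_receptors = receptor_density * geometry$area_surface
  )
}
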
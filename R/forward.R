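#' Forward adsorption model for density-resolved datasets
#'
#' Fixes everything about the adsorption model except the two grafting
#' densities that are fitted: single-bond energy, ligand gyration radius,
#' brush height on the particle, the two repulsion coefficients, the bulk
#' activity, and the averaging resolution. Each dataset row carries its own
#' particle-size distribution, so the interacting areas, the binding volume
#' and both Poisson count means are recomputed per size grid point.
#'
#' Defaults describe a polymersome-like system: a strong peptide-receptor
#' bond (beta*dG = -9), a 5 nm ligand tether whose confinement against the
#' target membrane costs B = B(R_g) = 0.40 kT per ligand, an 8 nm protective
#' brush entering only through the effective radius, and a 1 nM bulk
#' concentration.
#'
#' @param bond_energy Single-bond free energy (kT).
#' @param gyration_radius Ligand gyration radius R_g (nm); also the binding
#'   range.
#' @param brush_height Brush height on the particle (nm), enlarging the
#'   effective radius.
#' @param rep_receptor Per-receptor insertion coefficient A (kT); see
#'   [repulsion_coefficient()].
#' @param rep_ligand Per-ligand confinement coefficient B (kT); see
#'   [wall_coefficient()].
#' @param activity_molar Bulk particle concentration (mol/L).
#' @param size_points Size-grid resolution for polydispersity averaging.
#' @param truncation_mass Poisson truncation mass.
#' @return Object of class `forward_model`.
#' @export
forward_model <- function(bond_energy = -9, gyration_radius = 5,
                          brush_height = 8, rep_receptor = 0,
                          rep_ligand = wall_coefficient(gyration_radius,
                                                        gyration_radius),
                          activity_molar = 1e-9, size_points = 15,
                          truncation_mass = 1 - 1e-10) {
  stopifnot(is.finite(bond_energy), gyration_radius > 0, brush_height >= 0,
            rep_receptor >= 0, rep_ligand >= 0, activity_molar > 0)
  structure(
    list(bond_energy = bond_energy, gyration_radius = gyration_radius,
         brush_height = brush_height, rep_receptor = rep_receptor,
         rep_ligand = rep_ligand, activity_molar = activity_molar,
         activity = molar_to_number_density(activity_molar),
         size_points = as.integer(size_points),
         truncation_mass = truncation_mass),
    class = "forward_model"
  )
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf(
    paste0("<forward_model> beta*dG = %g, R_g = %g nm, h = %g nm,\n",
           "  A = %g kT, B = %g kT, z = %g M, %d size points\n"),
    x$bond_energy, x$gyration_radius, x$brush_height, x$rep_receptor,
    x$rep_ligand, x$activity_molar, x$size_points
  ))
  invisible(x)
}

# double-Poisson + polydispersity averaged theta for one dataset row,
# mean-field radial attraction (fast compiled path)
theta_forward_row <- function(ligand_density, receptor_density, model,
                              size_mean, size_sd) {
  theta_forward_row_cpp(
    ligand_density, receptor_density, model$bond_energy,
    model$gyration_radius, model$brush_height, size_mean, size_sd,
    model$size_points, model$rep_receptor, model$rep_ligand,
    model$activity, model$truncation_mass,
    0.55 * model$gyration_radius
  )
}

#' Predict normalised adsorption for a loading-resolved dataset
#'
#' Runs the forward model at each row's ligand loading and size
#' distribution: mean ligand count = `ligand_density_ref * loading *
#' A_int^np`, mean receptor count = `receptor_density * A_int^surf`, both
#' Poisson-averaged together with the row's size distribution. The
#' resulting thetas are normalised by their maximum across rows, mirroring
#' the experimental normalisation.
#'
#' @param dataset Data frame with columns `loading`, `size_mean`,
#'   `size_sd` (see [read_adsorption_dataset()]).
#' @param ligand_density_ref Ligand grafting density at loading = 1
#'   (nm^-2).
#' @param receptor_density Receptor surface density (nm^-2).
#' @param model A [forward_model()].
#' @return The dataset tibble with `theta_model` and `theta_norm_model`
#'   columns appended.
#' @export
predict_adsorption <- function(dataset, ligand_density_ref, receptor_density,
                               model = forward_model()) {
  stopifnot(inherits(model, "forward_model"),
            all(c("loading", "size_mean", "size_sd") %in% names(dataset)),
            ligand_density_ref > 0, receptor_density > 0)
  theta <- purrr::pmap_dbl(
    dataset[c("loading", "size_mean", "size_sd")],
    function(loading, size_mean, size_sd) {
      theta_forward_row(ligand_density_ref * loading, receptor_density,
                        model, size_mean, size_sd)
    }
  )
  dplyr::mutate(
    tibble::as_tibble(dataset),
    theta_model = theta,
    theta_norm_model = if (max(theta) > 0) theta / max(theta) else theta
  )
}
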
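#' Polymer-brush model for receptor insertion repulsion
#'
#' Parameters of the protective polymer brush grafted on the nanoparticle
#' core, from which the per-receptor insertion penalty A is computed. The
#' brush height on a flat surface is \eqn{h_0 = N (\nu a^2 / 3\sigma_0)^{1/3}}
#' and the curvature exponent is \eqn{\gamma = 3} for
#' \eqn{h_0/R_{np} > \sqrt{3} - 1}, else \eqn{\gamma = (1 + h_0/R_{np})^2}.
#'
#' @param area_per_chain Average area per grafted chain sigma_0 (nm^2).
#' @param degree_of_polymerisation Number of monomers per chain N.
#' @param monomer_size Monomer size a (nm).
#' @param core_radius Nanoparticle core radius R_np (nm).
#' @param receptor_volume Receptor volume V_R (nm^3).
#' @param insertion_ratio delta = z / h_0 in \[0, 1\]: particle-surface
#'   distance scaled by the unperturbed brush height (1 = particle at the
#'   brush edge, no compression).
#' @param monomer_volume Monomer volume nu (nm^3); defaults to a^3.
#'
#' @return An object of class `brush_model` with the supplied fields plus
#'   derived `brush_height` (h_0, nm) and `curvature_exponent` (gamma).
#' @examples
#' brush_model(area_per_chain = 1.95, degree_of_polymerisation = 113,
#'             monomer_size = 0.35, core_radius = 50,
#'             receptor_volume = 110, insertion_ratio = 0.9)
#' @export
brush_model <- function(area_per_chain, degree_of_polymerisation,
                        monomer_size, core_radius, receptor_volume,
                        insertion_ratio,
                        monomer_volume = monomer_size^3) {
  vals <- c(area_per_chain, degree_of_polymerisation, monomer_size,
            core_radius, receptor_volume, monomer_volume)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all brush lengths, counts and volumes must be positive", call. = FALSE)
  }
  if (!is.finite(insertion_ratio) || insertion_ratio < 0 || insertion_ratio > 1) {
    stop("`insertion_ratio` (delta) must lie in [0, 1]", call. = FALSE)
  }
  h0 <- brush_height(degree_of_polymerisation, monomer_size, area_per_chain,
                     monomer_volume)
  structure(
    list(
      area_per_chain = area_per_chain,
      degree_of_polymerisation = degree_of_polymerisation,
      monomer_size = monomer_size,
      monomer_volume = monomer_volume,
      core_radius = core_radius,
      receptor_volume = receptor_volume,
      insertion_ratio = insertion_ratio,
      brush_height = h0,
      curvature_exponent = gamma_exponent(h0, core_radius)
    ),
    class = "brush_model"
  )
}

#' @export
print.brush_model <- function(x, ...) {
  cat(sprintf(
    paste0("<brush_model> sigma0 = %g nm^2, N = %g, a = %g nm, R_np = %g nm\n",
           "  h0 = %.4g nm, gamma = %.4g, V_R = %g nm^3, delta = %g\n"),
    x$area_per_chain, x$degree_of_polymerisation, x$monomer_size,
    x$core_radius, x$brush_height, x$curvature_exponent,
    x$receptor_volume, x$insertion_ratio
  ))
  invisible(x)
}

#' Unperturbed brush height
#'
#' \eqn{h_0 = N (\nu a^2 / 3 \sigma_0)^{1/3}} for a brush grafted on a
#' planar surface (Alexander-de Gennes scaling).
#'
#' @inheritParams brush_model
#' @return Brush height in nm.
#' @export
brush_height <- function(degree_of_polymerisation, monomer_size,
                         area_per_chain, monomer_volume = monomer_size^3) {
  vals <- c(degree_of_polymerisation, monomer_size, area_per_chain,
            monomer_volume)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("brush height inputs must be positive", call. = FALSE)
  }
  degree_of_polymerisation *
    (monomer_volume * monomer_size^2 / (3 * area_per_chain))^(1 / 3)
}

#' Curvature exponent of the brush insertion penalty
#'
#' gamma = 3 when the brush is tall relative to the core
#' (h0/R_np > sqrt(3) - 1), otherwise gamma = (1 + h0/R_np)^2. The two
#' branches meet continuously at the boundary ratio, where
#' (1 + (sqrt(3) - 1))^2 = 3.
#'
#' @param brush_height h_0 (nm).
#' @param core_radius R_np (nm).
#' @return Dimensionless gamma between 1 and 3.
#' @export
gamma_exponent <- function(brush_height, core_radius) {
  stopifnot(brush_height > 0, core_radius > 0)
  ratio <- brush_height / core_radius
  if (ratio > sqrt(3) - 1) 3 else (1 + ratio)^2
}

#' Per-receptor brush insertion coefficient A
#'
#' Free-energy cost, in kT, for one receptor to insert into the compressed
#' polymer brush of a particle held at scaled distance delta from the
#' surface:
#' \deqn{A = V_R \left[\sigma_0 \left(1 + \delta\left[\left(1 +
#'   \frac{(\gamma+2)N}{3R_{np}}\left(\frac{\nu a^2}{3\sigma_0}\right)^{1/3}
#'   \right)^{3/(\gamma+2)} - 1\right]\right)^{\gamma-1}\right]^{-3/2}
#'   (1-\delta^2)^{9/4}.}
#' A vanishes at delta = 1 (particle at the brush edge, no compression) and
#' is largest at full compression.
#'
#' @param brush A [brush_model()].
#' @return Non-negative dimensionless coefficient A.
#' @export
repulsion_coefficient <- function(brush) {
  stopifnot(inherits(brush, "brush_model"))
  g <- brush$curvature_exponent
  delta <- brush$insertion_ratio
  blob <- (brush$monomer_volume * brush$monomer_size^2 /
             (3 * brush$area_per_chain))^(1 / 3)
  inner <- (1 + (g + 2) * brush$degree_of_polymerisation /
              (3 * brush$core_radius) * blob)^(3 / (g + 2)) - 1
  a_val <- brush$receptor_volume *
    (brush$area_per_chain * (1 + delta * inner)^(g - 1))^(-3 / 2) *
    (1 - delta^2)^(9 / 4)
  stopifnot(is.finite(a_val), a_val >= 0)
  a_val
}

#' Receptor-side repulsive free energy
#'
#' Linear in the receptor count: \eqn{\beta F_{rep}^{rec} = A N_R}. Once any
#' receptor is bound, every receptor in the contact region compresses the
#' brush, so the penalty is per receptor present, not per bond.
#'
#' @param coefficient Per-receptor insertion coefficient A (>= 0).
#' @param n_receptors Receptor count (>= 0).
#' @return Dimensionless beta*F_rep.
#' @export
receptor_repulsion <- function(coefficient, n_receptors) {
  stopifnot(coefficient >= 0, n_receptors >= 0)
  coefficient * n_receptors
}

#' Gaussian-chain-near-wall ligand repulsion coefficient B
#'
#' Confinement penalty, per ligand, for a Gaussian-chain ligand held at
#' distance r from an impenetrable flat wall:
#' \eqn{B(r) = a\,e^{-b(r/R_g - c)}} with fitted constants
#' a = 3.1995, b = 4.1662, c = 0.4996 (calibrated against exact Monte Carlo
#' data up to 10 kT). At r = R_g this gives B = 0.40.
#'
#' @param distance Distance r from the wall (nm).
#' @param gyration_radius Ligand tether gyration radius R_g (nm).
#' @param fit_a,fit_b,fit_c Fit constants; override only to explore.
#' @return Dimensionless coefficient B >= 0.
#' @examples
#' wall_coefficient(distance = 6, gyration_radius = 6)  # 0.40
#' @export
wall_coefficient <- function(distance, gyration_radius,
                             fit_a = 3.1995, fit_b = 4.1662, fit_c = 0.4996) {
  stopifnot(distance > 0, gyration_radius > 0)
  fit_a * exp(-fit_b * (distance / gyration_radius - fit_c))
}

#' Ligand-side repulsive free energy
#'
#' Linear in the ligand count: \eqn{\beta F_{rep}^{lig} = B N_L}.
#'
#' @param coefficient Per-ligand confinement coefficient B (>= 0).
#' @param n_ligands Ligand count (>= 0).
#' @return Dimensionless beta*F_rep.
#' @export
ligand_repulsion <- function(coefficient, n_ligands) {
  stopifnot(coefficient >= 0, n_ligands >= 0)
  coefficient * n_ligands
}
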
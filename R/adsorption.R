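#' Total adsorption free energy
#'
#' beta*F_tot = beta*F_att + beta*F_rep^rec + beta*F_rep^lig. Attraction is
#' negative (bond formation), repulsion positive (brush compression and
#' ligand confinement); their different scaling with the receptor count is
#' what produces range selectivity.
#'
#' @param f_att Attractive free energy (kT units, usually <= 0).
#' @param f_rep_receptors Receptor-side repulsion (>= 0).
#' @param f_rep_ligands Ligand-side repulsion (>= 0).
#' @return Dimensionless beta*F_tot.
#' @export
total_free_energy <- function(f_att, f_rep_receptors = 0, f_rep_ligands = 0) {
  stopifnot(is.finite(f_att), is.finite(f_rep_receptors),
            is.finite(f_rep_ligands))
  f_att + f_rep_receptors + f_rep_ligands
}

#' Bound-state partition function
#'
#' q = v_bind * exp(-beta F_tot), the configurational weight of the bound
#' particle over one adsorption site. Computed through its logarithm so
#' strongly attractive systems do not overflow; use [log_bound_weight()]
#' directly when feeding [adsorption_probability()].
#'
#' @param geometry A [particle_geometry()] supplying v_bind (nm^3).
#' @param f_tot Total adsorption free energy (kT units).
#' @return q in nm^3 (positive; may be `Inf` if exp overflows — prefer the
#'   log form in that regime).
#' @export
bound_partition_function <- function(geometry, f_tot) {
  exp(log_bound_weight(geometry, f_tot))
}

#' @rdname bound_partition_function
#' @return `log_bound_weight()`: ln q = ln v_bind - beta F_tot.
#' @export
log_bound_weight <- function(geometry, f_tot) {
  stopifnot(inherits(geometry, "particle_geometry"), is.finite(f_tot))
  log(geometry$binding_volume) - f_tot
}

#' Langmuir-like adsorption probability
#'
#' theta = z q / (1 + z q), the probability that an adsorption site is
#' occupied, for bulk activity z (nm^-3) and bound-state weight q (nm^3).
#' Evaluated as a logistic in ln(zq) for numerical stability at both
#' extremes.
#'
#' @param activity Bulk number density z in nm^-3 (>= 0); see
#'   [molar_to_number_density()].
#' @param q Bound-state partition function (nm^3). Alternatively supply
#'   `log_q`.
#' @param log_q ln q; overrides `q` when given.
#' @return Probability in \[0, 1).
#' @examples
#' adsorption_probability(2, 0.5)  # z*q = 1 -> 0.5
#' @export
adsorption_probability <- function(activity, q = NULL, log_q = NULL) {
  stopifnot(all(activity >= 0))
  if (is.null(log_q)) {
    stopifnot(!is.null(q), all(q > 0))
    log_q <- log(q)
  }
  ifelse(activity == 0, 0, stats::plogis(log(activity) + log_q))
}

#' Averaging specification for the adsorption probability
#'
#' Describes the average taken inside the Langmuir expression over the
#' numbers of interacting receptors and ligands (spatial inhomogeneity of
#' grafting) and optionally over the particle-size distribution
#' (polydispersity).
#'
#' Count distributions: `"none"` evaluates at the mean (real-valued, only
#' meaningful with the mean-field scenario for fractional means);
#' `"poisson"` sums the exact Poisson pmf up to the quantile retaining
#' `truncation_mass`; `"gaussian"` uses a discretized normal on the
#' non-negative integers (sd defaults to sqrt(mean), matching the Poisson
#' variance) with renormalised weights.
#'
#' @param receptor,ligand Distribution for each count: `"none"`,
#'   `"poisson"` or `"gaussian"`.
#' @param receptor_sd,ligand_sd Gaussian sd override (defaults to
#'   sqrt(mean)).
#' @param size_mean,size_sd Particle core-radius distribution (nm); when
#'   given, theta is additionally averaged over a truncated-normal size
#'   grid.
#' @param size_points Number of grid points for the size average.
#' @param truncation_mass Minimum probability mass the truncated count
#'   support must retain.
#' @return Object of class `averaging_spec`.
#' @export
averaging_spec <- function(receptor = c("poisson", "gaussian", "none"),
                           ligand = c("none", "poisson", "gaussian"),
                           receptor_sd = NULL, ligand_sd = NULL,
                           size_mean = NULL, size_sd = NULL,
                           size_points = 15,
                           truncation_mass = 1 - 1e-10) {
  receptor <- match.arg(receptor)
  ligand <- match.arg(ligand)
  stopifnot(truncation_mass > 0, truncation_mass < 1, size_points >= 3)
  if (!is.null(size_mean)) {
    stopifnot(size_mean > 0, !is.null(size_sd), size_sd >= 0)
  }
  structure(
    list(receptor = receptor, ligand = ligand,
         receptor_sd = receptor_sd, ligand_sd = ligand_sd,
         size_mean = size_mean, size_sd = size_sd,
         size_points = as.integer(size_points),
         truncation_mass = truncation_mass),
    class = "averaging_spec"
  )
}

#' @rdname averaging_spec
#' @export
no_averaging <- function() averaging_spec(receptor = "none", ligand = "none")

# integer support and weights for one count distribution
count_support <- function(distribution, mean, sd = NULL, truncation_mass) {
  if (mean < 0) stop("count means must be non-negative", call. = FALSE)
  switch(distribution,
    none = list(n = mean, w = 1),
    poisson = {
      if (mean == 0) return(list(n = 0, w = 1))
      upper <- stats::qpois(truncation_mass, mean) + 1L
      n <- 0:upper
      w <- stats::dpois(n, mean)
      if (sum(w) < truncation_mass) {
        stop("Poisson truncation could not retain the requested mass",
             call. = FALSE)
      }
      list(n = n, w = w)
    },
    gaussian = {
      if (is.null(sd)) sd <- sqrt(mean)
      if (sd == 0) return(list(n = round(mean), w = 1))
      upper <- max(1, ceiling(mean + 6 * sd))
      n <- 0:upper
      w <- stats::dnorm(n, mean, sd)
      s <- sum(w)
      if (s <= 0) stop("degenerate Gaussian count support", call. = FALSE)
      list(n = n, w = w / s)
    },
    stop(sprintf("unknown count distribution '%s'", distribution),
         call. = FALSE)
  )
}

# truncated-normal size grid, renormalised weights; `min_radius` keeps the
# grid inside the validity region of the projected-area geometry
size_support <- function(size_mean, size_sd, size_points, min_radius = 1e-3) {
  if (is.null(size_mean) || is.null(size_sd) || size_sd == 0) {
    return(list(r = size_mean %||% NA_real_, w = 1))
  }
  lo <- max(size_mean - 3 * size_sd, 0.25 * size_sd, 1e-3, min_radius)
  hi <- size_mean + 3 * size_sd
  if (hi <= lo) return(list(r = size_mean, w = 1))
  r <- seq(lo, hi, length.out = size_points)
  w <- stats::dnorm(r, size_mean, size_sd)
  list(r = r, w = w / sum(w))
}

f_att_for <- function(scenario, n_ligands, n_receptors, bond_energy, cache) {
  key <- paste(n_ligands, n_receptors, sep = ",")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- switch(scenario,
    radial_exact = f_att_exact(n_ligands, n_receptors, bond_energy),
    radial_meanfield = f_att_mean_field(n_ligands, n_receptors, bond_energy),
    indifferent = f_att_indifferent(n_ligands, n_receptors, bond_energy),
    stop(sprintf("unknown binding scenario '%s'", scenario), call. = FALSE)
  )
  cache[[key]] <- val
  val
}

theta_fixed_counts <- function(n_ligands, n_receptors, bond_energy,
                               scenario, rep_receptor, rep_ligand,
                               geometry, activity, cache) {
  f_att <- f_att_for(scenario, n_ligands, n_receptors, bond_energy, cache)
  f_tot <- f_att + rep_receptor * n_receptors + rep_ligand * n_ligands
  adsorption_probability(activity,
                         log_q = log_bound_weight(geometry, f_tot))
}

#' Averaged adsorption probability
#'
#' Evaluates the Langmuir-like adsorption probability, averaging over the
#' distributions named in `averaging`:
#' \deqn{\theta = \left\langle \frac{z q(N_L, N_R)}{1 + z q(N_L, N_R)}
#'   \right\rangle_{N_L, N_R, R_{np}}.}
#' The average is a finite convex combination over the truncated joint
#' support of the (independent) count and size distributions. When a size
#' distribution is present, the geometry and both count means are recomputed
#' at each size grid point: the ligand mean scales with the particle
#' interacting area and the receptor mean with its surface projection.
#'
#' @param n_ligands,n_receptors Mean interacting counts. When `averaging`
#'   carries a size distribution these are reinterpreted via the grafting
#'   densities implied at the reference geometry.
#' @param bond_energy Single-bond free energy (kT).
#' @param geometry A [particle_geometry()].
#' @param activity Bulk activity z (nm^-3).
#' @param scenario Attraction model: `"radial_meanfield"` (default),
#'   `"radial_exact"`, or `"indifferent"`.
#' @param rep_receptor Per-receptor repulsion coefficient A (kT).
#' @param rep_ligand Per-ligand repulsion coefficient B (kT).
#' @param averaging An [averaging_spec()]; default Poisson over receptors
#'   only.
#' @param cache Optional environment memoising f_att per (N_L, N_R) pair
#'   across calls.
#' @return theta in \[0, 1\].
#' @examples
#' geom <- particle_geometry(50, 9)
#' adsorption_theta(3, 100, -9, geom, molar_to_number_density(1e-9),
#'                  rep_receptor = 0.1)
#' @export
adsorption_theta <- function(n_ligands, n_receptors, bond_energy, geometry,
                             activity,
                             scenario = c("radial_meanfield", "radial_exact",
                                          "indifferent"),
                             rep_receptor = 0, rep_ligand = 0,
                             averaging = averaging_spec(),
                             cache = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(geometry, "particle_geometry"),
            inherits(averaging, "averaging_spec"),
            n_ligands >= 0, n_receptors >= 0, activity >= 0,
            rep_receptor >= 0, rep_ligand >= 0)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())

  sizes <- size_support(averaging$size_mean, averaging$size_sd,
                        averaging$size_points,
                        min_radius = 0.55 * geometry$gyration_radius)
  use_sizes <- !is.null(averaging$size_mean)

  theta <- 0
  n_size <- length(sizes$w)
  for (s in seq_len(n_size)) {
    if (use_sizes) {
      geom_s <- particle_geometry(sizes$r[s], geometry$gyration_radius,
                                  geometry$brush_height_on_particle)
      scale_l <- geom_s$area_particle / geometry$area_particle
      scale_r <- geom_s$area_surface / geometry$area_surface
      mu_l <- n_ligands * scale_l
      mu_r <- n_receptors * scale_r
      cache_s <- new.env(parent = emptyenv())  # f_att reuse is per-size
    } else {
      geom_s <- geometry
      mu_l <- n_ligands
      mu_r <- n_receptors
      cache_s <- cache
    }
    lig <- count_support(averaging$ligand, mu_l, averaging$ligand_sd,
                         averaging$truncation_mass)
    rec <- count_support(averaging$receptor, mu_r, averaging$receptor_sd,
                         averaging$truncation_mass)
    th_s <- 0
    for (i in seq_along(lig$n)) {
      for (j in seq_along(rec$n)) {
        th_s <- th_s + lig$w[i] * rec$w[j] *
          theta_fixed_counts(lig$n[i], rec$n[j], bond_energy, scenario,
                             rep_receptor, rep_ligand, geom_s, activity,
                             cache_s)
      }
    }
    theta <- theta + sizes$w[s] * th_s
  }
  theta
}

#' Sweep the adsorption probability along one parameter
#'
#' Evaluates [adsorption_theta()] over a grid of one sweep variable and
#' returns a tidy curve. Supported sweep variables: `"n_receptors"`,
#' `"n_ligands"`, `"bond_energy"`, `"activity"`.
#'
#' @param values Ordered numeric grid for the sweep variable.
#' @param sweep Which parameter `values` refers to.
#' @inheritParams adsorption_theta
#' @return A tibble of class `adsorption_curve` with columns `x`, `theta`,
#'   `theta_normalized` (theta / max theta over the curve); the full
#'   parameter snapshot is stored in `attr(, "parameters")`.
#' @examples
#' geom <- particle_geometry(50, 9)
#' crv <- adsorption_curve(10^seq(0, 4, length.out = 21),
#'                         sweep = "n_receptors", n_ligands = 3,
#'                         bond_energy = -9, geometry = geom,
#'                         activity = molar_to_number_density(1e-9),
#'                         rep_receptor = 0.1)
#' @export
adsorption_curve <- function(values, sweep = c("n_receptors", "n_ligands",
                                               "bond_energy", "activity"),
                             n_ligands = NULL, n_receptors = NULL,
                             bond_energy = NULL, geometry, activity = NULL,
                             scenario = "radial_meanfield",
                             rep_receptor = 0, rep_ligand = 0,
                             averaging = averaging_spec()) {
  sweep <- match.arg(sweep)
  stopifnot(is.numeric(values), length(values) >= 2,
            !is.unsorted(values, strictly = TRUE))
  cache <- new.env(parent = emptyenv())
  theta <- vapply(values, function(v) {
    args <- list(n_ligands = n_ligands, n_receptors = n_receptors,
                 bond_energy = bond_energy, activity = activity)
    args[[sweep]] <- v
    adsorption_theta(args$n_ligands, args$n_receptors, args$bond_energy,
                     geometry, args$activity, scenario = scenario,
                     rep_receptor = rep_receptor, rep_ligand = rep_ligand,
                     averaging = averaging, cache = cache)
  }, numeric(1))
  out <- tibble::tibble(
    x = values,
    theta = theta,
    theta_normalized = if (max(theta) > 0) theta / max(theta) else theta
  )
  attr(out, "sweep") <- sweep
  attr(out, "parameters") <- list(
    n_ligands = n_ligands, n_receptors = n_receptors,
    bond_energy = bond_energy, activity = activity, scenario = scenario,
    rep_receptor = rep_receptor, rep_ligand = rep_ligand,
    geometry = unclass(geometry), averaging = unclass(averaging)
  )
  class(out) <- c("adsorption_curve", class(out))
  out
}

#' @export
print.adsorption_curve <- function(x, ...) {
  cat(sprintf("# Adsorption curve: theta vs %s (%d points, peak theta %.3g)\n",
              attr(x, "sweep"), nrow(x), max(x$theta)))
  NextMethod()
}
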
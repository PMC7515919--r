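# rebuild the theta(x) function a curve was sampled from, for edge refinement
curve_theta_fun <- function(curve) {
  p <- attr(curve, "parameters")
  sweep <- attr(curve, "sweep")
  if (is.null(p) || is.null(sweep)) return(NULL)
  geometry <- do.call(particle_geometry, p$geometry[
    c("core_radius", "gyration_radius", "brush_height_on_particle")])
  averaging <- do.call(averaging_spec, p$averaging[
    c("receptor", "ligand", "receptor_sd", "ligand_sd", "size_mean",
      "size_sd", "size_points", "truncation_mass")])
  cache <- new.env(parent = emptyenv())
  function(v) {
    args <- list(n_ligands = p$n_ligands, n_receptors = p$n_receptors,
                 bond_energy = p$bond_energy, activity = p$activity)
    args[[sweep]] <- v
    adsorption_theta(args$n_ligands, args$n_receptors, args$bond_energy,
                     geometry, args$activity, scenario = p$scenario,
                     rep_receptor = p$rep_receptor,
                     rep_ligand = p$rep_ligand,
                     averaging = averaging, cache = cache)
  }
}

bisect_crossing <- function(f, lo, hi, threshold, rising, tol = 1e-3) {
  # f(lo), f(hi) bracket the threshold; log-scale bisection when positive
  logscale <- lo > 0
  for (it in 1:60) {
    mid <- if (logscale) sqrt(lo * hi) else (lo + hi) / 2
    above <- f(mid) >= threshold
    if (above == rising) hi <- mid else lo <- mid
    rel <- if (logscale) log(hi / lo) else (hi - lo)
    if (rel < tol) break
  }
  if (logscale) sqrt(lo * hi) else (lo + hi) / 2
}

#' Locate the binding window of an adsorption curve
#'
#' The binding window is the range of the sweep variable over which the
#' adsorption probability exceeds a threshold: range selectivity manifests
#' as a finite window, bounded both below (too few receptors to pay the
#' translational-entropy cost) and above (repulsion outgrowing the
#' logarithmic attraction). Edges are refined by bisection on the
#' reconstructed model between the bracketing grid points; when the curve
#' carries no parameter snapshot, log-linear interpolation is used instead.
#'
#' @param curve An [adsorption_curve()] (ordered grid).
#' @param threshold Absolute probability threshold in (0, 1); default half
#'   the curve's peak theta.
#' @return One-row tibble of class `binding_window`: `threshold`,
#'   `lower_edge`, `upper_edge`, `peak_location`, `peak_theta`,
#'   `width_decades` (log10(upper/lower)), `exists`, `upper_unbounded`
#'   (TRUE when theta never descends below threshold before the grid ends,
#'   e.g. a classical saturating isotherm). Absent windows have all edge
#'   fields `NA` and `exists = FALSE`.
#' @export
binding_window <- function(curve, threshold = NULL) {
  stopifnot(is.data.frame(curve), all(c("x", "theta") %in% names(curve)))
  if (is.unsorted(curve$x, strictly = TRUE)) {
    stop("curve grid must be strictly increasing", call. = FALSE)
  }
  x <- curve$x
  th <- curve$theta
  peak_i <- which.max(th)
  if (is.null(threshold)) threshold <- 0.5 * th[peak_i]
  stopifnot(threshold > 0, threshold < 1)

  absent <- tibble::tibble(
    threshold = threshold, lower_edge = NA_real_, upper_edge = NA_real_,
    peak_location = x[peak_i], peak_theta = th[peak_i],
    width_decades = NA_real_, exists = FALSE, upper_unbounded = FALSE
  )
  class(absent) <- c("binding_window", class(absent))
  if (th[peak_i] < threshold) return(absent)

  f <- curve_theta_fun(curve)
  interp <- function(i, j, rising) {
    # log-linear fallback when the generating model is unavailable
    if (x[i] > 0) {
      exp(log(x[i]) + (threshold - th[i]) / (th[j] - th[i]) *
            (log(x[j]) - log(x[i])))
    } else {
      x[i] + (threshold - th[i]) / (th[j] - th[i]) * (x[j] - x[i])
    }
  }

  above <- th >= threshold
  first_above <- which(above)[1]
  last_above <- max(which(above))

  lower <- if (first_above == 1L) {
    x[1]
  } else if (is.null(f)) {
    interp(first_above - 1L, first_above, rising = TRUE)
  } else {
    bisect_crossing(f, x[first_above - 1L], x[first_above], threshold,
                    rising = TRUE)
  }
  upper_unbounded <- last_above == length(x)
  upper <- if (upper_unbounded) {
    x[length(x)]
  } else if (is.null(f)) {
    interp(last_above, last_above + 1L, rising = FALSE)
  } else {
    bisect_crossing(f, x[last_above], x[last_above + 1L], threshold,
                    rising = FALSE)
  }
  out <- tibble::tibble(
    threshold = threshold, lower_edge = lower, upper_edge = upper,
    peak_location = x[peak_i], peak_theta = th[peak_i],
    width_decades = log10(upper / lower), exists = TRUE,
    upper_unbounded = upper_unbounded
  )
  class(out) <- c("binding_window", class(out))
  out
}

#' Upper bound on the optimal number of interacting ligands
#'
#' With a linear ligand repulsion B per ligand, adding ligands beyond
#' \deqn{N_L^{opt} = N_R / B - \chi^{-1}} can only weaken binding: the
#' logarithmic growth of the multivalent attraction is outpaced by the
#' linear repulsion. A negative value (weak bonds, chi < B/N_R) means the
#' binding strength decreases monotonically with ligand number from the
#' start. In the strong-bond limit chi -> Inf the bound tends to N_R / B.
#'
#' @param n_receptors Receptor count N_R (> 0).
#' @param rep_ligand Per-ligand repulsion B (> 0).
#' @param bond_strength Single-bond strength chi (> 0).
#' @return Real-valued bound (may be negative).
#' @examples
#' optimal_ligand_number(10, 0.5, 1)  # 19
#' @export
optimal_ligand_number <- function(n_receptors, rep_ligand, bond_strength) {
  stopifnot(n_receptors > 0, bond_strength > 0)
  if (rep_ligand <= 0) {
    stop("`rep_ligand` must be positive: without ligand repulsion there is no interior optimum",
         call. = FALSE)
  }
  n_receptors / rep_ligand - 1 / bond_strength
}

#' Golden-section maximiser of the binding strength over the ligand number
#'
#' Finds the real N_L maximising -beta*F_tot(N_L) with mean-field radial
#' attraction and linear ligand repulsion B, at fixed N_R. Used to verify
#' numerically that [optimal_ligand_number()] is an upper bound.
#'
#' @inheritParams optimal_ligand_number
#' @param bond_energy Single-bond free energy (kT); overrides
#'   `bond_strength`.
#' @param upper Search interval upper end (default 10 * N_R / B).
#' @param tol Interval-width tolerance.
#' @return List with `n_ligands` (argmax) and `objective` (max of
#'   -beta F_tot).
#' @export
argmax_binding_strength <- function(n_receptors, rep_ligand,
                                    bond_energy = NULL, bond_strength = NULL,
                                    upper = NULL, tol = 1e-8) {
  if (is.null(bond_energy)) bond_energy <- -log(bond_strength)
  stopifnot(n_receptors > 0, rep_ligand > 0)
  if (is.null(upper)) upper <- 10 * n_receptors / rep_ligand
  obj <- function(nl) {
    -(f_att_mean_field(nl, n_receptors, bond_energy) + rep_ligand * nl)
  }
  gr <- (sqrt(5) - 1) / 2
  lo <- 0; hi <- upper
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- obj(x1); f2 <- obj(x2)
  while (hi - lo > tol * max(1, hi)) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- obj(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- obj(x1)
    }
  }
  xm <- (lo + hi) / 2
  list(n_ligands = xm, objective = obj(xm))
}

#' Compare binding windows along a parameter grid
#'
#' Computes one adsorption curve per grid value via `curve_fun`, locates
#' each binding window, and reports how the window width and peak
#' probability move along the grid — e.g. smaller receptor volume or a
#' sparser protective brush widens the window, weaker bonds narrow it, and
#' peak theta co-varies with width.
#'
#' @param values Numeric grid of the swept parameter.
#' @param curve_fun Function of one value returning an
#'   [adsorption_curve()].
#' @param threshold Passed to [binding_window()]; `NULL` = half-peak per
#'   curve.
#' @param label Name of the swept parameter (for the output).
#' @return Tibble of class `trend_report`: one row per value with the
#'   window fields, plus attributes `width_direction` and `peak_direction`
#'   in `c("increasing", "decreasing", "mixed", "constant")` (absent
#'   windows make the direction `"incomparable"`).
#' @export
trend_report <- function(values, curve_fun, threshold = NULL,
                         label = "parameter") {
  stopifnot(is.numeric(values), length(values) >= 2, is.function(curve_fun))
  rows <- purrr::map(values, function(v) {
    w <- binding_window(curve_fun(v), threshold = threshold)
    dplyr::mutate(w, value = v, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, parameter = label, .before = 1)
  direction <- function(z) {
    if (anyNA(z)) return("incomparable")
    d <- diff(z)
    if (all(d > 0)) "increasing"
    else if (all(d < 0)) "decreasing"
    else if (all(d == 0)) "constant"
    else "mixed"
  }
  attr(out, "width_direction") <- direction(out$width_decades)
  attr(out, "peak_direction") <- direction(out$peak_theta)
  class(out) <- c("trend_report", class(out))
  out
}

#' @export
print.trend_report <- function(x, ...) {
  cat(sprintf("# Trend report for %s: width %s, peak theta %s\n",
              x$parameter[1], attr(x, "width_direction"),
              attr(x, "peak_direction")))
  NextMethod()
}
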
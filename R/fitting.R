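#' Weighted least-squares objective for adsorption fits
#'
#' \deqn{E = \frac{\sum_i w_i (\theta'_{exp,i} - \theta'_{model,i})^2}
#'   {\sum_i w_i}} with weights the inverse of each row's mean-square-root
#' deviation. Rows with zero spread (e.g. noiseless synthetic data) fall
#' back to the largest finite weight, or to equal weights when every row is
#' degenerate.
#'
#' @param dataset Adsorption dataset: columns `loading`, `theta_norm`,
#'   `msrd`, `size_mean`, `size_sd`.
#' @param ligand_density_ref,receptor_density Trial parameters (nm^-2).
#' @param model A [forward_model()].
#' @return Non-negative scalar E; zero iff the model reproduces the data
#'   exactly.
#' @export
fit_objective <- function(dataset, ligand_density_ref, receptor_density,
                          model = forward_model()) {
  stopifnot(all(c("loading", "theta_norm", "msrd") %in% names(dataset)))
  w <- dataset_weights(dataset$msrd)
  pred <- predict_adsorption(dataset, ligand_density_ref, receptor_density,
                             model)
  sum(w * (dataset$theta_norm - pred$theta_norm_model)^2) / sum(w)
}

dataset_weights <- function(msrd) {
  if (any(msrd < 0)) stop("`msrd` must be non-negative", call. = FALSE)
  pos <- msrd > 0
  if (!any(pos)) return(rep(1, length(msrd)))
  w <- ifelse(pos, 1 / msrd, max(1 / msrd[pos]))
  w
}

#' Annealing schedule
#'
#' Geometric cooling: effective temperature starts at `t0`, is multiplied
#' by `factor` after every `sweeps_per_step` Monte Carlo sweeps (one
#' proposal per fitted parameter per sweep), and the run stops once the
#' temperature drops below `floor`. The defaults perform
#' ceil(log(1e-7)/log(0.95)) = 315 cooling steps, i.e. 31,500 sweeps.
#'
#' @param t0 Initial effective temperature.
#' @param factor Cooling factor per step.
#' @param sweeps_per_step Sweeps between cooling events.
#' @param floor Stop once temperature < floor.
#' @return Object of class `anneal_schedule` with derived `n_steps`.
#' @export
anneal_schedule <- function(t0 = 1, factor = 0.95, sweeps_per_step = 100,
                            floor = 1e-7) {
  stopifnot(t0 > 0, factor > 0, factor < 1, sweeps_per_step >= 1,
            floor > 0, floor < t0)
  structure(
    list(t0 = t0, factor = factor,
         sweeps_per_step = as.integer(sweeps_per_step), floor = floor,
         n_steps = as.integer(ceiling(log(floor / t0) / log(factor)))),
    class = "anneal_schedule"
  )
}

#' Fit grafting densities by Monte Carlo simulated annealing
#'
#' Minimises [fit_objective()] over the two grafting densities
#' (reference ligand density and receptor density) with Metropolis
#' acceptance under a geometric cooling schedule. Proposals are independent
#' multiplicative log-normal steps (sd `step_sd` in log space) on each
#' parameter, rejected outside `bounds`. The best-ever parameters are
#' returned; the run is fully determined by `seed`.
#'
#' @inheritParams fit_objective
#' @param schedule An [anneal_schedule()].
#' @param seed Integer RNG seed (stored in the result).
#' @param bounds List with `ligand` and `receptor` ranges (nm^-2); the
#'   defaults bracket typical nanocarrier ligand and cell-surface receptor
#'   densities.
#' @param init Optional starting values `c(ligand, receptor)`; default the
#'   geometric mean of each bound.
#' @param step_sd Proposal standard deviation in log space.
#' @return Object of class `anneal_fit`: fitted densities, final objective,
#'   per-step trace (temperature, best objective, acceptance rate), seed,
#'   schedule, model.
#' @examples
#' \donttest{
#' ds <- simulate_adsorption(generator_config(seed = 1))
#' fit <- anneal_fit(ds, seed = 7,
#'                   schedule = anneal_schedule(sweeps_per_step = 5))
#' tidy(fit)
#' }
#' @export
anneal_fit <- function(dataset, model = forward_model(),
                       schedule = anneal_schedule(), seed = 1,
                       bounds = list(ligand = c(1e-4, 1),
                                     receptor = c(1e-6, 1e-2)),
                       init = NULL, step_sd = 0.1) {
  stopifnot(inherits(schedule, "anneal_schedule"),
            all(bounds$ligand > 0), all(bounds$receptor > 0))
  set.seed(as.integer(seed))
  lb <- log(c(bounds$ligand[1], bounds$receptor[1]))
  ub <- log(c(bounds$ligand[2], bounds$receptor[2]))
  x <- if (is.null(init)) (lb + ub) / 2 else log(init)
  stopifnot(all(x >= lb), all(x <= ub))

  w <- dataset_weights(dataset$msrd)
  loading <- dataset$loading
  size_mean <- dataset$size_mean
  size_sd <- dataset$size_sd
  theta_norm_exp <- dataset$theta_norm
  w_sum <- sum(w)
  # lean re-statement of fit_objective(): called tens of thousands of times
  obj <- function(p) {
    th <- vapply(seq_along(loading), function(i) {
      theta_forward_row(exp(p[1]) * loading[i], exp(p[2]), model,
                        size_mean[i], size_sd[i])
    }, numeric(1))
    m <- max(th)
    if (!is.finite(m) || m <= 0) return(NA_real_)
    sum(w * (theta_norm_exp - th / m)^2) / w_sum
  }

  e <- obj(x)
  if (is.na(e)) stop("forward model failed at the initial parameters",
                     call. = FALSE)
  best_x <- x
  best_e <- e
  n_par <- 2L
  failed_proposals <- 0L
  trace <- vector("list", schedule$n_steps)
  temp <- schedule$t0
  for (step in seq_len(schedule$n_steps)) {
    accepted <- 0L
    n_prop <- 0L
    for (sw in seq_len(schedule$sweeps_per_step)) {
      for (k in seq_len(n_par)) {
        n_prop <- n_prop + 1L
        cand <- x
        cand[k] <- cand[k] + stats::rnorm(1, 0, step_sd)
        if (cand[k] < lb[k] || cand[k] > ub[k]) next
        e_new <- obj(cand)
        if (is.na(e_new)) {
          failed_proposals <- failed_proposals + 1L
          next
        }
        if (e_new <= e || stats::runif(1) < exp((e - e_new) / temp)) {
          x <- cand
          e <- e_new
          accepted <- accepted + 1L
          if (e < best_e) {
            best_e <- e
            best_x <- x
          }
        }
      }
    }
    trace[[step]] <- c(temperature = temp, best_objective = best_e,
                       acceptance_rate = accepted / n_prop)
    temp <- temp * schedule$factor
  }
  trace <- tibble::as_tibble(do.call(rbind, trace))
  trace$step <- seq_len(nrow(trace))

  structure(
    list(
      ligand_density_ref = exp(best_x[1]),
      receptor_density = exp(best_x[2]),
      objective = best_e,
      trace = trace,
      seed = as.integer(seed),
      schedule = schedule,
      bounds = bounds,
      step_sd = step_sd,
      failed_proposals = failed_proposals,
      model = model,
      dataset = tibble::as_tibble(dataset)
    ),
    class = "anneal_fit"
  )
}

#' @export
print.anneal_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<anneal_fit> sigma_L,ref = %.4g nm^-2, rho_R = %.4g nm^-2\n",
           "  E = %.4g after %d cooling steps (seed %d)\n"),
    x$ligand_density_ref, x$receptor_density, x$objective,
    x$schedule$n_steps, x$seed
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an annealing fit
#'
#' @param x An [anneal_fit()] result.
#' @param ... Unused.
#' @return One row per fitted parameter with `term` and `estimate` (nm^-2).
#' @method tidy anneal_fit
#' @export
tidy.anneal_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ligand_density_ref", "receptor_density"),
    estimate = c(x$ligand_density_ref, x$receptor_density),
    unit = "nm^-2"
  )
}

#' One-row fit summary
#'
#' @param x An [anneal_fit()] result.
#' @param ... Unused.
#' @return Tibble with the final objective, schedule length and seed.
#' @method glance anneal_fit
#' @export
glance.anneal_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    n_cooling_steps = x$schedule$n_steps,
    n_sweeps = x$schedule$n_steps * x$schedule$sweeps_per_step,
    failed_proposals = x$failed_proposals,
    seed = x$seed
  )
}
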
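#' Configuration for the synthetic adsorption-data generator
#'
#' Describes a simulated measurement campaign: particles prepared at a
#' series of relative ligand loadings, each batch with its own measured
#' size distribution, incubated at fixed bulk activity, with adsorption
#' read out in replicate. The default loadings and size distributions
#' mirror a typical polymersome preparation series in which the mean radius
#' varies with ligand loading; default truths sit at the centre of the
#' plausible grafting-density range for such systems.
#'
#' @param ligand_density_ref True reference ligand grafting density
#'   (nm^-2) at loading = 1.
#' @param receptor_density True receptor surface density (nm^-2).
#' @param loadings Relative ligand loadings sigma_L / sigma_ref (distinct
#'   non-negative values).
#' @param size_mean,size_sd Per-loading particle core radius mean and
#'   spread (nm); recycled if length 1.
#' @param noise `"none"` or `"gaussian_relative"`.
#' @param noise_sd Relative noise sd applied per replicate when
#'   `noise = "gaussian_relative"`.
#' @param replicates Measurements per loading.
#' @param model A [forward_model()] used as the data-generating truth.
#' @param seed Integer RNG seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(ligand_density_ref = 2e-2,
                             receptor_density = 2e-4,
                             loadings = c(0, 0.5, 1, 5, 10),
                             size_mean = c(26.6, 10.0, 11.5, 19.3, 20.4),
                             size_sd = c(10.9, 4.7, 5.8, 10.1, 8.6),
                             noise = c("none", "gaussian_relative"),
                             noise_sd = 0.1, replicates = 3,
                             model = forward_model(), seed = 1) {
  noise <- match.arg(noise)
  stopifnot(ligand_density_ref > 0, receptor_density > 0,
            !anyDuplicated(loadings), all(loadings >= 0),
            all(size_sd >= 0), all(size_mean > 0),
            replicates >= 1, noise_sd >= 0,
            inherits(model, "forward_model"))
  n <- length(loadings)
  size_mean <- rep_len(size_mean, n)
  size_sd <- rep_len(size_sd, n)
  structure(
    list(ligand_density_ref = ligand_density_ref,
         receptor_density = receptor_density,
         loadings = loadings, size_mean = size_mean, size_sd = size_sd,
         noise = noise, noise_sd = noise_sd,
         replicates = as.integer(replicates), model = model,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Simulate a normalised adsorption-versus-loading dataset
#'
#' Runs the forward model (mean-field radial attraction, double Poisson
#' count averaging, per-row size polydispersity) at the configured true
#' densities, then emulates the measurement pipeline: optional relative
#' Gaussian noise per replicate (clipped at zero), replicate means
#' normalised by their maximum across loadings, and per-row uncertainty as
#' the mean-square-root deviation of the normalised replicates. The truths
#' and seed are kept in the `provenance` attribute so parameter-recovery
#' studies can score themselves.
#'
#' @param config A [generator_config()].
#' @return Tibble of class `adsorption_dataset` with columns `loading`,
#'   `theta_norm`, `msrd`, `size_mean`, `size_sd`; attributes `provenance`
#'   (truths, noise, seed) and `replicates` (normalised replicate matrix).
#' @examples
#' ds <- simulate_adsorption(generator_config(seed = 42))
#' @export
simulate_adsorption <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- length(config$loadings)
  theta_true <- vapply(seq_len(n), function(i) {
    theta_forward_row(config$ligand_density_ref * config$loadings[i],
                      config$receptor_density, config$model,
                      config$size_mean[i], config$size_sd[i])
  }, numeric(1))
  if (all(theta_true == 0)) {
    stop("degenerate configuration: theta is zero at every loading",
         call. = FALSE)
  }
  reps <- matrix(theta_true, nrow = n, ncol = config$replicates)
  if (config$noise == "gaussian_relative" && config$noise_sd > 0) {
    eps <- matrix(stats::rnorm(n * config$replicates, 0, config$noise_sd),
                  nrow = n)
    reps <- pmax(reps * (1 + eps), 0)
  }
  row_means <- rowMeans(reps)
  norm <- max(row_means)
  reps_norm <- reps / norm
  theta_norm <- row_means / norm
  msrd <- sqrt(rowMeans((reps_norm - theta_norm)^2))

  out <- tibble::tibble(
    loading = config$loadings,
    theta_norm = theta_norm,
    msrd = msrd,
    size_mean = config$size_mean,
    size_sd = config$size_sd
  )
  attr(out, "provenance") <- list(
    ligand_density_ref = config$ligand_density_ref,
    receptor_density = config$receptor_density,
    noise = config$noise, noise_sd = config$noise_sd,
    replicates = config$replicates, seed = config$seed,
    theta_true = theta_true,
    model = unclass(config$model)
  )
  attr(out, "replicates") <- reps_norm
  class(out) <- c("adsorption_dataset", class(out))
  out
}

#' Summarise a particle-radius sample
#'
#' Mean radius, mean-square-root deviation (population RMS deviation from
#' the mean) and polydispersity index. The PDI is the squared coefficient
#' of variation, (sd/mean)^2 — e.g. a sample with mean 26.6 nm and spread
#' 10.9 nm has PDI 0.17.
#'
#' @param radii Positive numeric sample of particle radii (nm).
#' @return One-row tibble with `mean`, `msrd`, `pdi`, `n`.
#' @export
summarize_sizes <- function(radii) {
  if (length(radii) == 0 || !is.numeric(radii) || any(radii <= 0)) {
    stop("`radii` must be a non-empty sample of positive radii", call. = FALSE)
  }
  m <- mean(radii)
  msrd <- sqrt(mean((radii - m)^2))
  tibble::tibble(mean = m, msrd = msrd, pdi = (msrd / m)^2,
                 n = length(radii))
}

#' Polydispersity index from summary statistics
#'
#' @param mean_radius Mean radius (nm).
#' @param spread Mean-square-root deviation (nm).
#' @return (spread / mean_radius)^2.
#' @examples
#' polydispersity_index(26.6, 10.9)  # 0.17
#' @export
polydispersity_index <- function(mean_radius, spread) {
  stopifnot(mean_radius > 0, spread >= 0)
  (spread / mean_radius)^2
}
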
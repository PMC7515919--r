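#' Read / write adsorption datasets
#'
#' Datasets are plain comma-separated text with a header row and columns
#' `loading` (relative ligand density sigma_L/sigma_ref), `theta_norm`
#' (adsorption normalised by its maximum), `msrd` (per-row uncertainty),
#' `size_mean`, `size_sd` (particle radius distribution, nm). A JSON
#' provenance sidecar (written next to the CSV as `<path>.json`) records
#' generator truths and the RNG seed when the dataset is synthetic.
#'
#' @param path CSV file path.
#' @return `read_adsorption_dataset()`: tibble of class
#'   `adsorption_dataset` (provenance attached when the sidecar exists).
#' @export
read_adsorption_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("dataset '%s' not found", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("loading", "theta_norm", "msrd", "size_mean", "size_sd")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("dataset is missing columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  validate_dataset(df)
  out <- tibble::as_tibble(df)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(out, "provenance") <- jsonlite::read_json(sidecar,
                                                   simplifyVector = TRUE)
  }
  class(out) <- c("adsorption_dataset", class(out))
  out
}

validate_dataset <- function(df) {
  stopifnot(nrow(df) >= 2)
  if (any(df$theta_norm < 0 | df$theta_norm > 1 + 1e-12)) {
    stop("`theta_norm` must lie in [0, 1]", call. = FALSE)
  }
  if (abs(max(df$theta_norm) - 1) > 1e-8) {
    stop("`theta_norm` must be normalised: its maximum row must equal 1",
         call. = FALSE)
  }
  if (any(df$msrd < 0)) stop("`msrd` must be non-negative", call. = FALSE)
  if (any(df$loading < 0) || anyDuplicated(df$loading)) {
    stop("loadings must be non-negative and distinct", call. = FALSE)
  }
  invisible(df)
}

#' @rdname read_adsorption_dataset
#' @param dataset An adsorption dataset (e.g. from
#'   [simulate_adsorption()]).
#' @param provenance Write the JSON sidecar (default: yes when the dataset
#'   carries provenance).
#' @export
write_adsorption_dataset <- function(dataset, path,
                                     provenance = !is.null(attr(dataset, "provenance"))) {
  cols <- c("loading", "theta_norm", "msrd", "size_mean", "size_sd")
  utils::write.csv(as.data.frame(dataset)[cols], path, row.names = FALSE,
                   quote = FALSE)
  if (provenance) {
    jsonlite::write_json(attr(dataset, "provenance"), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write an adsorption curve with its parameter snapshot
#'
#' The curve goes to CSV (`x`, `theta`, `theta_normalized`); the full
#' parameter snapshot goes to a JSON sidecar so the curve can be
#' regenerated from the sidecar alone.
#'
#' @param curve An [adsorption_curve()].
#' @param path Output CSV path; the sidecar is `<path>.json`.
#' @export
write_adsorption_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(sweep = attr(curve, "sweep"), parameters = attr(curve, "parameters")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Load and validate a run configuration
#'
#' Configurations are YAML with up to four blocks: `model` (required for
#' curve/sweep runs), `sweep`, `fit`, `output`. The model block supplies
#' either explicit interacting `counts` (`n_ligands`, `n_receptors`) or
#' grafting `densities` (`ligand`, `receptor`) to be mapped through the
#' geometry — exactly one of the two. Repulsion coefficients may be given
#' directly (`rep_receptor`, `rep_ligand`) or computed from a `brush`
#' sub-block (receptor side) / `wall` sub-block (ligand side). Unknown keys
#' are reported with their field paths; defaults that were filled in are
#' recorded in the `defaults_used` attribute.
#'
#' @param path YAML file path.
#' @return Validated list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config '%s' not found", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || length(raw) == 0) {
    stop("empty config: at least a `model` block with `bond_energy`, `geometry` and one of `counts`/`densities` is required",
         call. = FALSE)
  }
  known_top <- c("model", "sweep", "fit", "output")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config block(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  # YAML scalars like "1.0e5" (no sign in the exponent) arrive as strings
  as_num <- function(x, field) {
    if (is.null(x)) return(NULL)
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop(sprintf("`%s` must be numeric", field), call. = FALSE)
    v
  }
  defaults <- character(0)
  note_default <- function(field, value) {
    defaults <<- c(defaults, sprintf("%s = %s", field,
                                     paste(format(value), collapse = ",")))
  }

  model <- raw$model
  if (is.null(model)) stop("config must contain a `model` block", call. = FALSE)
  known_model <- c("scenario", "counts", "densities", "bond_energy",
                   "bond_strength", "geometry", "brush", "wall",
                   "rep_receptor", "rep_ligand", "activity_molar",
                   "averaging")
  unknown <- setdiff(names(model), known_model)
  if (length(unknown) > 0) {
    stop(sprintf("unknown key(s) in model block: %s",
                 paste(paste0("model.", unknown), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(model$counts) == is.null(model$densities)) {
    stop("model block must contain exactly one of `counts` or `densities`",
         call. = FALSE)
  }
  if (is.null(model$bond_energy) && is.null(model$bond_strength)) {
    stop("model block must give `bond_energy` (kT) or `bond_strength`",
         call. = FALSE)
  }
  if (is.null(model$bond_energy)) {
    model$bond_energy <- -log(as_num(model$bond_strength,
                                     "model.bond_strength"))
  }
  model$bond_energy <- as_num(model$bond_energy, "model.bond_energy")
  geom <- model$geometry
  if (is.null(geom$core_radius) || is.null(geom$gyration_radius)) {
    stop("model.geometry must give `core_radius` and `gyration_radius` (nm)",
         call. = FALSE)
  }
  if (is.null(geom$brush_height)) {
    geom$brush_height <- 0
    note_default("model.geometry.brush_height", 0)
  }
  geometry <- particle_geometry(as_num(geom$core_radius, "model.geometry.core_radius"),
                                as_num(geom$gyration_radius, "model.geometry.gyration_radius"),
                                as_num(geom$brush_height, "model.geometry.brush_height"))
  if (!is.null(model$counts)) {
    counts <- list(
      n_ligands = as_num(model$counts$n_ligands, "model.counts.n_ligands"),
      n_receptors = as_num(model$counts$n_receptors,
                           "model.counts.n_receptors")
    )
  } else {
    counts <- counts_from_densities(
      as_num(model$densities$ligand, "model.densities.ligand"),
      as_num(model$densities$receptor, "model.densities.receptor"), geometry
    )
  }

  if (is.null(model$rep_receptor)) {
    if (!is.null(model$brush)) {
      b <- model$brush
      brush <- brush_model(
        area_per_chain = b$area_per_chain,
        degree_of_polymerisation = b$degree_of_polymerisation,
        monomer_size = b$monomer_size,
        core_radius = b$core_radius %||% geom$core_radius,
        receptor_volume = b$receptor_volume,
        insertion_ratio = b$insertion_ratio %||%
          (geom$gyration_radius / brush_height(b$degree_of_polymerisation,
                                               b$monomer_size,
                                               b$area_per_chain))
      )
      model$rep_receptor <- repulsion_coefficient(brush)
    } else {
      model$rep_receptor <- 0
      note_default("model.rep_receptor", 0)
    }
  }
  if (is.null(model$rep_ligand)) {
    if (!is.null(model$wall)) {
      model$rep_ligand <- wall_coefficient(
        model$wall$distance %||% geom$gyration_radius,
        model$wall$gyration_radius %||% geom$gyration_radius
      )
    } else {
      model$rep_ligand <- 0
      note_default("model.rep_ligand", 0)
    }
  }
  if (is.null(model$activity_molar)) {
    model$activity_molar <- 1e-9
    note_default("model.activity_molar", 1e-9)
  }
  model$activity_molar <- as_num(model$activity_molar,
                                 "model.activity_molar")
  model$rep_receptor <- as_num(model$rep_receptor, "model.rep_receptor")
  model$rep_ligand <- as_num(model$rep_ligand, "model.rep_ligand")
  if (is.null(model$scenario)) {
    model$scenario <- "radial_meanfield"
    note_default("model.scenario", "radial_meanfield")
  }
  model$scenario <- match.arg(model$scenario,
                              c("radial_meanfield", "radial_exact",
                                "indifferent"))
  avg_args <- model$averaging %||% list()
  averaging <- do.call(averaging_spec, avg_args)

  sweep <- raw$sweep
  if (!is.null(sweep)) {
    if (is.null(sweep$variable)) sweep$variable <- "n_receptors"
    sweep$scale <- sweep$scale %||% "log"
    sweep$points <- as_num(sweep$points %||% 61, "sweep.points")
    if (is.null(sweep$from) || is.null(sweep$to)) {
      stop("sweep block must give `from` and `to`", call. = FALSE)
    }
    sweep$from <- as_num(sweep$from, "sweep.from")
    sweep$to <- as_num(sweep$to, "sweep.to")
  }
  fit <- raw$fit
  if (!is.null(fit) && is.null(fit$dataset)) {
    stop("fit block must give `dataset` (CSV path)", call. = FALSE)
  }

  structure(
    list(model = model, counts = counts, geometry = geometry,
         averaging = averaging, sweep = sweep, fit = fit,
         output = raw$output),
    class = "run_config",
    defaults_used = defaults
  )
}
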
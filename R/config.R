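#' Default pipeline configuration
#'
#' The configuration is a flat key-value list (serialized as YAML,
#' `config_version` 1) holding the assay design, the loss thresholds used by
#' the classifier, scoring options, the model-simplification alpha and the
#' synthetic-generator parameters (keys prefixed `sim_`). [read_config()]
#' merges a user file over these defaults, so a config file only needs the
#' keys it changes.
#'
#' @return A named list of configuration values.
#' @seealso [read_config()], [write_config()], [as_design()],
#'   [as_sim_config()]
#' @export
default_config <- function() {
  design <- default_design()
  list(
    config_version = 1L,
    ancestor = design$ancestor,
    genotypes = design$genotypes,
    carbons = design$carbons,
    temperatures = design$temperatures,
    replicates = design$replicates,
    thresholds = c(0.99, 0.95, 0.90),
    score_then_average = FALSE,
    clamp_negative_net = TRUE,
    alpha = 0.05,
    seed = 1L,
    sim_a_max = c(1400, 1250, 1100, 950, 800, 700),
    sim_t_opt = c(34, 35, 36, 36, 37, 38),
    sim_breadth = c(10, 10.5, 11, 11, 11.5, 12),
    sim_d0 = 0.5,
    sim_d2 = 5e-4,
    sim_t_mid = 31,
    sim_sigma_delta = 0.30,
    sim_sigma_eta = 1,
    sim_psi0 = 0.02,
    sim_psi1 = 0.006,
    sim_omega0 = 0.008,
    sim_omega1 = 0.0015,
    sim_sigma_rep = 5,
    sim_blank_mean = 40,
    sim_blank_sd = 3
  )
}

#' Read a pipeline configuration file
#'
#' @param path YAML file of configuration keys; unknown keys are an error so
#'   typos never silently fall back to defaults.
#' @return The merged configuration list (defaults overridden by the file).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(user$config_version) && user$config_version != 1L)
    stop("unsupported config_version: ", user$config_version, call. = FALSE)
  cfg <- utils::modifyList(defaults, user)
  as_design(cfg)      # validates the design keys
  as_sim_config(cfg)  # validates the simulator keys
  cfg
}

#' Write a pipeline configuration file
#'
#' @param config A configuration list as returned by [default_config()] or
#'   [read_config()].
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Extract the assay design from a configuration
#'
#' @param config A configuration list.
#' @return An [experiment_design()] object.
#' @export
as_design <- function(config) {
  experiment_design(genotypes = config$genotypes, carbons = config$carbons,
                    temperatures = config$temperatures,
                    replicates = config$replicates,
                    ancestor = config$ancestor)
}

#' Extract the simulator configuration from a configuration list
#'
#' @param config A configuration list.
#' @return An [simulation_config()] object.
#' @export
as_sim_config <- function(config) {
  simulation_config(
    design = as_design(config),
    a_max = config$sim_a_max, t_opt = config$sim_t_opt,
    breadth = config$sim_breadth,
    d0 = config$sim_d0, d2 = config$sim_d2, t_mid = config$sim_t_mid,
    sigma_delta = config$sim_sigma_delta, sigma_eta = config$sim_sigma_eta,
    psi0 = config$sim_psi0, psi1 = config$sim_psi1,
    omega0 = config$sim_omega0, omega1 = config$sim_omega1,
    sigma_rep = config$sim_sigma_rep,
    blank_mean = config$sim_blank_mean, blank_sd = config$sim_blank_sd
  )
}
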
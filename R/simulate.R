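#' Configure the synthetic plate-reader data generator
#'
#' The generator emulates a mutation-accumulation growth-yield assay with a
#' known, exact ground truth. Its parts:
#'
#' * **Ancestor thermal performance.** The ancestor's net yield on carbon
#'   `c` follows a unimodal (Gaussian) thermal performance curve
#'   `A_c(T) = a_max_c * exp(-(T - t_opt_c)^2 / (2 * breadth_c^2))` in mOD.
#' * **Deleterious load.** Each MA genotype carries a deleterious magnitude
#'   `delta_g ~ |Normal(0, sigma_delta)|` on the log10 score scale, scaled
#'   by the deficit multiplier `lambda(T) = d0 + d2 * (T - t_mid)^2`:
#'   mutational yield loss is smallest at intermediate temperatures.
#' * **Responsiveness knob.** Genotypes differ in sensitivity
#'   `eta_g ~ Normal(0, sigma_eta)` to a fixed centred, unit-variance carbon
#'   axis `x_c`, scaled by `psi(T) = psi0 + psi1 * (T - T_min)`: the spread
#'   of environmental variances (hence responsiveness) grows with
#'   temperature.
#' * **Inconsistency knob.** Idiosyncratic genotype-by-carbon effects
#'   `eps_gc ~ Normal(0, 1)` scaled by
#'   `omega(T) = omega0 + omega1 * (T - T_min)` decorrelate genotype
#'   profiles increasingly with temperature.
#' * **Measurement layer.** A blank offset per (carbon, temperature) and
#'   additive truncated-Normal replicate noise on the mOD scale.
#'
#' The noiseless score surface is
#' `s_gc(T) = -delta_g * lambda(T) + eta_g * x_c * psi(T) +
#' eps_gc * omega(T)`, and measurements are generated by inverting the score
#' formula, so ground-truth variance components are exact by construction.
#'
#' @param design The [experiment_design()] to emulate (default
#'   [default_design()]).
#' @param a_max Peak ancestor net yield per carbon, mOD (recycled to E).
#' @param t_opt Thermal optimum per carbon, Celsius.
#' @param breadth Thermal niche breadth per carbon, Celsius.
#' @param d0,d2,t_mid Deficit multiplier baseline, curvature and
#'   mid-temperature.
#' @param sigma_delta Scale of deleterious magnitudes (log10 score units).
#' @param sigma_eta Scale of carbon-axis sensitivities.
#' @param psi0,psi1 Responsiveness ramp: value at the lowest design
#'   temperature and slope per degree.
#' @param omega0,omega1 Inconsistency ramp, same parameterization.
#' @param sigma_rep Replicate noise standard deviation, mOD.
#' @param blank_mean,blank_sd Mean and sd of the per-environment blank
#'   offset, mOD.
#' @return A `ma_sim_config` list.
#' @export
simulation_config <- function(design = default_design(),
                              a_max = c(1400, 1250, 1100, 950, 800, 700),
                              t_opt = c(34, 35, 36, 36, 37, 38),
                              breadth = c(10, 10.5, 11, 11, 11.5, 12),
                              d0 = 0.5, d2 = 5e-4, t_mid = 31,
                              sigma_delta = 0.30, sigma_eta = 1,
                              psi0 = 0.02, psi1 = 0.006,
                              omega0 = 0.008, omega1 = 0.0015,
                              sigma_rep = 5, blank_mean = 40, blank_sd = 3) {
  stopifnot(inherits(design, "ma_design"))
  e <- length(design$carbons)
  recycle <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, e)
    if (length(x) != e)
      stop(sQuote(what), " must have length 1 or E = ", e, call. = FALSE)
    x
  }
  a_max <- recycle(a_max, "a_max")
  t_opt <- recycle(t_opt, "t_opt")
  breadth <- recycle(breadth, "breadth")
  scalars <- c(d0 = d0, d2 = d2, sigma_delta = sigma_delta,
               sigma_eta = sigma_eta, sigma_rep = sigma_rep,
               blank_mean = blank_mean, blank_sd = blank_sd)
  if (any(scalars < 0))
    stop("negative scale parameter(s): ",
         paste(names(scalars)[scalars < 0], collapse = ", "), call. = FALSE)
  if (any(a_max <= 0) || any(breadth <= 0))
    stop("'a_max' and 'breadth' must be positive", call. = FALSE)
  tt <- design$temperatures
  cfg <- structure(list(design = design, a_max = a_max, t_opt = t_opt,
                        breadth = breadth, d0 = d0, d2 = d2, t_mid = t_mid,
                        sigma_delta = sigma_delta, sigma_eta = sigma_eta,
                        psi0 = psi0, psi1 = psi1,
                        omega0 = omega0, omega1 = omega1,
                        sigma_rep = sigma_rep, blank_mean = blank_mean,
                        blank_sd = blank_sd),
                   class = "ma_sim_config")
  if (any(deficit_multiplier(cfg, tt) < 0) ||
      any(sensitivity_ramp(cfg, tt) < 0) ||
      any(idiosyncrasy_ramp(cfg, tt) < 0))
    stop("lambda, psi and omega must be non-negative over the design ",
         "temperatures", call. = FALSE)
  cfg
}

deficit_multiplier <- function(config, t)
  config$d0 + config$d2 * (t - config$t_mid)^2
sensitivity_ramp <- function(config, t)
  config$psi0 + config$psi1 * (t - min(config$design$temperatures))
idiosyncrasy_ramp <- function(config, t)
  config$omega0 + config$omega1 * (t - min(config$design$temperatures))

# Fixed, centred, unit-sample-variance carbon axis: gives "sensitivity to
# the carbon spectrum" a stable meaning across seeds.
carbon_axis <- function(e) {
  x <- seq_len(e)
  (x - mean(x)) / stats::sd(x)
}

#' Ancestor thermal performance surface
#'
#' @param config A [simulation_config()].
#' @return An E x T matrix of ancestor net yields `A_c(T)` in mOD
#'   (rows carbons, columns design temperatures).
#' @export
ancestor_yield <- function(config) {
  tt <- config$design$temperatures
  out <- outer(seq_along(config$a_max), seq_along(tt), function(ci, ti)
    config$a_max[ci] *
      exp(-(tt[ti] - config$t_opt[ci])^2 / (2 * config$breadth[ci]^2)))
  dimnames(out) <- list(config$design$carbons, format(tt))
  out
}

run_seeded <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr()
}

#' Draw genotype and genotype-by-carbon effects
#'
#' Draws, for the G MA genotypes: deleterious magnitudes
#' `delta_g ~ |Normal(0, sigma_delta)|`, carbon-axis sensitivities
#' `eta_g ~ Normal(0, sigma_eta)` and idiosyncratic effects
#' `eps_gc ~ Normal(0, 1)` (a G x E matrix). The ancestor has all effects
#' zero by definition. Reproducible: the same config and seed give the same
#' draws, and the caller's RNG state is left untouched.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return An `ma_effects` list with `delta`, `eta` (named vectors) and
#'   `eps` (G x E matrix).
#' @export
draw_effects <- function(config, seed) {
  run_seeded(seed, function() draw_effects_impl(config))
}

draw_effects_impl <- function(config) {
  d <- config$design
  g <- length(d$genotypes)
  e <- length(d$carbons)
  delta <- abs(stats::rnorm(g, 0, config$sigma_delta))
  eta <- stats::rnorm(g, 0, config$sigma_eta)
  eps <- matrix(stats::rnorm(g * e), g, e,
                dimnames = list(d$genotypes, d$carbons))
  names(delta) <- names(eta) <- d$genotypes
  structure(list(delta = delta, eta = eta, eps = eps),
            class = "ma_effects")
}

#' Noiseless relative growth score surface
#'
#' Evaluates `s_gc(T) = -delta_g * lambda(T) + eta_g * x_c * psi(T) +
#' eps_gc * omega(T)` over the whole design.
#'
#' @param effects An [draw_effects()] result.
#' @param config The matching [simulation_config()].
#' @return A G x E x T array of scores with genotype, carbon and
#'   temperature dimnames.
#' @export
score_surface <- function(effects, config) {
  d <- config$design
  tt <- d$temperatures
  g <- length(d$genotypes)
  e <- length(d$carbons)
  x <- carbon_axis(e)
  out <- array(NA_real_, c(g, e, length(tt)),
               dimnames = list(d$genotypes, d$carbons, format(tt)))
  for (ti in seq_along(tt)) {
    out[, , ti] <- -effects$delta * deficit_multiplier(config, tt[ti]) +
      outer(effects$eta, x) * sensitivity_ramp(config, tt[ti]) +
      effects$eps * idiosyncrasy_ramp(config, tt[ti])
  }
  out
}

#' Ground-truth variance components of a simulated experiment
#'
#' Runs the variance partition on the noiseless score matrices, giving the
#' exact per-temperature components (and the surface itself) that the noisy
#' pipeline should recover.
#'
#' @inheritParams score_surface
#' @return A `ma_ground_truth` list with `surface` (the
#'   [score_surface()] array) and `components` (one
#'   [partition_components()] row per design temperature).
#' @export
ground_truth_components <- function(effects, config) {
  surf <- score_surface(effects, config)
  tt <- config$design$temperatures
  comp <- do.call(rbind, lapply(seq_along(tt), function(ti) {
    m <- surf[, , ti]
    attr(m, "temperature_c") <- tt[ti]
    partition_components(m)
  }))
  rownames(comp) <- NULL
  structure(list(surface = surf, components = comp),
            class = "ma_ground_truth")
}

#' Emit synthetic plate-reader measurements
#'
#' Converts a score surface into raw measurement records by inverting the
#' score formula. For every (carbon, temperature): the ancestor's true net
#' yield is `A_c(T)`; each MA genotype's true net yield is
#' `(A_c(T) + 1) * 10^s_gc(T) - 1`; a blank offset
#' `B ~ Normal(blank_mean, blank_sd)` (truncated at 0) is drawn once and
#' added to every well; each replicate reading adds
#' `Normal(0, sigma_rep)` noise and is truncated at 0; one matching blank
#' row (the offset plus its own replicate noise) is emitted per
#' environment. Row order is deterministic: temperature, then carbon, then
#' blank, ancestor and MA genotypes, then replicate.
#'
#' @param effects An [draw_effects()] result.
#' @param config The matching [simulation_config()].
#' @param seed Integer seed for the measurement noise.
#' @return A measurement-record data frame (schema of
#'   [read_measurements()]). A configuration that drives a true MA net mean
#'   negative is permitted; such means are clamped at zero and a warning
#'   reports the clamp rate.
#' @export
emit_measurements <- function(effects, config, seed) {
  run_seeded(seed, function() emit_measurements_impl(effects, config))
}

emit_measurements_impl <- function(effects, config) {
  d <- config$design
  tt <- d$temperatures
  reps <- d$replicates
  surf <- score_surface(effects, config)
  anc <- ancestor_yield(config)            # E x T
  genos <- c(d$ancestor, d$genotypes)
  n_env <- length(tt) * length(d$carbons)
  rows_per_env <- 1L + length(genos) * reps
  n <- n_env * rows_per_env
  genotype <- character(n); carbon <- character(n)
  temperature_c <- numeric(n); replicate <- integer(n)
  mOD <- numeric(n); is_blank <- logical(n)
  k <- 0L
  clamped <- 0L
  for (ti in seq_along(tt)) {
    for (ci in seq_along(d$carbons)) {
      B <- max(stats::rnorm(1, config$blank_mean, config$blank_sd), 0)
      k <- k + 1L
      genotype[k] <- ""; carbon[k] <- d$carbons[ci]
      temperature_c[k] <- tt[ti]; replicate[k] <- 1L
      mOD[k] <- max(B + stats::rnorm(1, 0, config$sigma_rep), 0)
      is_blank[k] <- TRUE
      a <- anc[ci, ti]
      for (gi in seq_along(genos)) {
        net <- if (gi == 1L) a
               else (a + 1) * 10^surf[gi - 1L, ci, ti] - 1
        if (net < 0) { clamped <- clamped + 1L; net <- 0 }
        reads <- pmax(net + B + stats::rnorm(reps, 0, config$sigma_rep), 0)
        idx <- k + seq_len(reps)
        genotype[idx] <- genos[gi]; carbon[idx] <- d$carbons[ci]
        temperature_c[idx] <- tt[ti]; replicate[idx] <- seq_len(reps)
        mOD[idx] <- reads; is_blank[idx] <- FALSE
        k <- k + reps
      }
    }
  }
  if (clamped > 0L)
    warning(sprintf("%d of %d true culture means were negative and clamped",
                    clamped, length(genos) * n_env), call. = FALSE)
  data.frame(genotype = genotype, carbon = carbon,
             temperature_c = temperature_c, replicate = replicate,
             mOD = mOD, is_blank = is_blank)
}

#' Simulate a complete assay with ground truth
#'
#' Draws effects, generates the measurement table and computes the exact
#' ground-truth components, all from one RNG stream, so the result is fully
#' reproducible from the (config, seed) pair.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return An `ma_simulation` list: `records` (measurement table),
#'   `effects`, `truth` (see [ground_truth_components()]), `config`, `seed`.
#' @export
simulate_experiment <- function(config = simulation_config(), seed = 1L) {
  run_seeded(seed, function() {
    effects <- draw_effects_impl(config)
    records <- emit_measurements_impl(effects, config)
    truth <- ground_truth_components(effects, config)
    structure(list(records = records, effects = effects, truth = truth,
                   config = config, seed = seed),
              class = "ma_simulation")
  })
}

#' @export
print.ma_simulation <- function(x, ...) {
  d <- x$config$design
  cat("Simulated MA assay (seed ", x$seed, "): ",
      length(d$genotypes), " MA genotypes + ancestor, ",
      length(d$carbons), " carbons, ", length(d$temperatures),
      " temperatures, ", d$replicates, " replicates = ",
      nrow(x$records), " records\n", sep = "")
  invisible(x)
}
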
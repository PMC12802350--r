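#' Simulation design for synthetic rate grids
#'
#' Describes the substrate-by-inhibitor measurement design, replicate
#' count, noise model and seed used by [simulate_rate_grid()]. The default
#' design mirrors the GC7/BSAO study conditions: substrate 20-1000 µM and
#' inhibitor 0.1-2 µM (plus the uninhibited zero level), six roughly
#' log-spaced levels of each, three replicates, and proportional Gaussian
#' noise with a 2% coefficient of variation — typical spectrophotometric
#' repeatability.
#'
#' @param substrate_levels substrate levels, µM; all positive.
#' @param inhibitor_levels inhibitor levels, µM; must include 0.
#' @param replicates replicates per (S, I) combination; at least 1.
#' @param noise_type `"none"`, `"additive"` (Gaussian, sd `noise_sd` in
#'   nmol/min) or `"proportional"` (Gaussian, sd = `noise_cv` times the
#'   true rate).
#' @param noise_sd additive noise standard deviation, nmol/min.
#' @param noise_cv proportional noise coefficient of variation.
#' @param seed integer RNG seed; `NULL` uses the current RNG stream.
#' @return An object of class `"sim_design"`.
#' @export
simulation_design <- function(substrate_levels = c(20, 50, 100, 200, 500,
                                                   1000),
                              inhibitor_levels = c(0, 0.1, 0.25, 0.5, 1, 2),
                              replicates = 3,
                              noise_type = c("proportional", "additive",
                                             "none"),
                              noise_sd = 0.1, noise_cv = 0.02,
                              seed = NULL) {
  noise_type <- match.arg(noise_type)
  stopifnot(all(substrate_levels > 0), all(inhibitor_levels >= 0),
            replicates >= 1, noise_sd >= 0, noise_cv >= 0)
  structure(list(substrate_levels = sort(unique(substrate_levels)),
                 inhibitor_levels = sort(unique(inhibitor_levels)),
                 replicates = as.integer(replicates),
                 noise_type = noise_type, noise_sd = noise_sd,
                 noise_cv = noise_cv, seed = seed),
            class = "sim_design")
}

#' Simulate a rate grid from the tight-binding model
#'
#' Generates replicated initial rates on the design's (S, I) grid from
#' [predict_rate()] plus the design's noise. Negative noisy rates are kept
#' (the grid is flagged noisy), so fitters are exercised against realistic
#' data. All randomness flows through the design's single seed and the
#' global RNG state is left untouched, so two calls with the same seed
#' agree bit-exactly. The generating truth is recorded in the grid
#' metadata for recovery studies.
#'
#' @param params a [tb_params] (or compatible list): the generating truth.
#' @param mode generating inhibition mode.
#' @param design a [simulation_design()]; must include the zero-inhibitor
#'   level.
#' @param enzyme_nominal_uM optional nominal enzyme concentration recorded
#'   in the metadata (used to initialize `E` in fits when present).
#' @return A [rate_grid] with `design`, `truth` and `mode` in its
#'   metadata.
#' @examples
#' g <- simulate_rate_grid(gc7_reference_params(), "noncompetitive",
#'                         simulation_design(seed = 1))
#' head(g)
#' @export
simulate_rate_grid <- function(params, mode, design = simulation_design(),
                               enzyme_nominal_uM = NULL) {
  params <- as_tb_params(params)
  stopifnot(inherits(design, "sim_design"))
  if (!any(design$inhibitor_levels == 0)) {
    stop("design must include the zero-inhibitor level")
  }
  df <- expand.grid(replicate = seq_len(design$replicates),
                    inhibitor_uM = design$inhibitor_levels,
                    substrate_uM = design$substrate_levels)
  df <- df[, c("substrate_uM", "inhibitor_uM", "replicate")]
  mu <- predict_rate(df$substrate_uM, df$inhibitor_uM, params, mode)
  noise <- with_seed(design$seed, switch(
    design$noise_type,
    none = rep(0, length(mu)),
    additive = stats::rnorm(length(mu), 0, design$noise_sd),
    proportional = stats::rnorm(length(mu), 0, 1) * design$noise_cv * mu
  ))
  df$rate <- mu + noise
  rate_grid(df,
            metadata = list(truth = unclass(params), mode = mode,
                            design = unclass(design),
                            enzyme_nominal_uM = enzyme_nominal_uM,
                            substrate_name = "spermidine",
                            inhibitor_name = "GC7"),
            noisy = design$noise_type != "none")
}

#' Simulate a linear-phase absorbance trace
#'
#' Inverse of the Beer-Lambert rate conversion: produces an absorbance
#' time course whose slope corresponds to the requested chemical rate
#' through [absorbance_to_rate()], plus optional Gaussian reading noise.
#' Seeded like [simulate_rate_grid()].
#'
#' @param rate chemical rate, nmol/min.
#' @param spec an [extinction_spec()].
#' @param volume reaction volume, mL.
#' @param duration trace duration, minutes.
#' @param sampling number of equally spaced points (>= 3).
#' @param noise_sd Gaussian absorbance noise, AU.
#' @param baseline absorbance offset at time zero, AU.
#' @param seed RNG seed.
#' @return An [absorbance_trace()].
#' @examples
#' q <- extinction_spec("quinonimine adduct", 26000, 515)
#' tr <- simulate_absorbance_trace(1, q, duration = 5, sampling = 30)
#' estimate_initial_rate(tr)$slope  # 0.026 AU/min
#' @export
simulate_absorbance_trace <- function(rate, spec, volume = 1, duration = 10,
                                      sampling = 60, noise_sd = 0,
                                      baseline = 0, seed = NULL) {
  stopifnot(inherits(spec, "extinction_spec"), duration > 0, sampling >= 3)
  times <- seq(0, duration, length.out = sampling)
  slope <- rate * spec$epsilon * spec$path_length /
    (spec$stoichiometry * volume * 1e6)
  a <- baseline + slope * times
  if (noise_sd > 0) {
    a <- a + with_seed(seed, stats::rnorm(length(a), 0, noise_sd))
  }
  absorbance_trace(times, a, wavelength = spec$wavelength,
                   reaction_volume = volume)
}
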
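#' Figure-level experiment runners
#'
#' Orchestrates the protocols of the main experiments at full or reduced
#' scale:
#' \describe{
#'   \item{1}{full optogenetic stimulation (all excitatory neurons) of
#'     the discrete network, with theory comparison and gain fit;}
#'   \item{2}{partial stimulation of a seeded random fraction q of the
#'     excitatory population (imbalanced amplification and suppression);}
#'   \item{3}{two-layer chain: the partially stimulated network drives a
#'     downstream layer through freshly sampled feedforward
#'     connectivity;}
#'   \item{4}{weak-stimulus variant at four times the neuron count
#'     (mean-field-preserving rescaling, epsilon halved); the stimulus
#'     amplitude \code{S} must be supplied -- no canonical value
#'     exists;}
#'   \item{5}{spatial network mean-field solution for a broad and a
#'     narrow stimulus, with balanced-width fits where balance is
#'     feasible;}
#'   \item{6}{size-tuning scans of center rates versus stimulus width,
#'     for Gaussian and sharp-edged disc stimuli and several lateral
#'     excitatory widths;}
#'   \item{7}{deconvolution demo: edge sharpness of input versus output
#'     for a disc (or user-supplied contrast-map) stimulus at several
#'     ratios of lateral to interlaminar excitatory width.}
#' }
#'
#' @param figure integer 1--7.
#' @param scale linear factor on network size for the spiking protocols
#'   (1 = reference scale, N = 5000).
#' @param seed integer seed; sub-seeds for graph sampling, external
#'   drive, target choice and initial conditions are derived from it.
#' @param duration simulated time, ms (spiking protocols).
#' @param S stimulus current, mV/ms (required for figure 4).
#' @param gain rectified-linear gain used by mean-field-only analyses;
#'   when \code{NULL}, spiking runners fit it from their own simulation
#'   and mean-field runners use \code{default_gain()}.
#' @param out_dir optional directory; when given, summary tables and a
#'   provenance record are written as CSV/JSON.
#' @param ... overrides passed to the underlying runner (e.g.
#'   \code{grid}, \code{sigma_X_values}, \code{contrast}).
#' @return A result bundle (list); contents depend on the figure.
#' @export
run_figure <- function(figure, scale = 1, seed = 1, duration = 10000,
                       S = NULL, gain = NULL, out_dir = NULL, ...) {
  res <- switch(as.character(figure),
    "1" = fig_discrete(q = 1, scale, seed, duration, S %||% 2, gain, ...),
    "2" = fig_discrete(q = 0.2, scale, seed, duration, S %||% 2, gain, ...),
    "3" = fig_chain(scale, seed, duration, S %||% 2, gain, ...),
    "4" = {
      if (is.null(S)) stop("figure 4 requires an explicit stimulus amplitude S")
      fig_discrete(q = 0.2, scale * 4, seed, duration, S, gain, ...)
    },
    "5" = fig_spatial(gain %||% default_gain(), ...),
    "6" = fig_size_tuning(gain %||% default_gain(), ...),
    "7" = fig_deconvolution(gain %||% default_gain(), ...),
    stop("unknown figure id: ", figure))
  res$provenance <- list(figure = figure, scale = scale, seed = seed,
                         duration = duration, S = S, gain = gain,
                         package_version = as.character(utils::packageVersion("imbalnet")),
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(out_dir)) write_bundle(res, out_dir)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default rectified-linear gain for mean-field-only analyses
#'
#' A representative value of the gain of the rectified-linear f-I fit
#' obtained from the reference discrete-network simulation (the fitted
#' value is close to 15 Hz per mV/ms at reference scale); mean-field
#' figure runners use it when no simulation is available to fit from.
#'
#' @return Gain in Hz per (mV/ms).
#' @export
default_gain <- function() 15

## Discrete-network protocol shared by figures 1, 2 and 4.
fig_discrete <- function(q, scale, seed, duration, S, gain,
                         r_X = 5, record = integer(0), config = NULL) {
  obj <- config_objects()
  net <- list(coupling = obj$coupling, sizes = obj$sizes)
  N_target <- round(5000 * scale)
  if (N_target != 5000)
    net <- scale_network(obj$coupling, obj$sizes, N_target)
  net$sizes$q <- q
  graph <- sample_graph(net$coupling, net$sizes, seed = seed)
  external <- poisson_drive(net$sizes$N_X, r_X, duration, seed = seed + 1000L)
  targets <- choose_targets(net$sizes, q, seed = seed + 2000L)
  protocol <- stim_protocol(S = S, onset = duration / 2, targets = targets)
  cfg <- config %||% sim_config(duration = duration, seed = seed + 3000L,
                                record = record)
  sim <- simulate_network(graph, external, protocol, cfg,
                          obj$neuron, obj$kinetics)
  NE <- net$sizes$N_E
  masks <- if (q < 1)
    list(exp = targets, nexp = setdiff(seq_len(NE), targets),
         I = NE + seq_len(net$sizes$N_I))
  else list(E = seq_len(NE), I = NE + seq_len(net$sizes$N_I))
  rates <- estimate_rates(sim$raster, masks, sim$epochs)
  currents <- mean_currents(sim, masks)
  fit <- fit_gain(gain_points(sim)$I, gain_points(sim)$rate)
  g <- gain %||% fit$g
  eps <- compute_epsilon(net$coupling, net$sizes)
  mf2 <- build_meanfield(net$coupling, net$sizes,
                         if (q < 1) "global" else "EI")
  theory <- list(
    off = corrected_rates(mf2$W, external_drive(mf2, r_X), eps, g),
    on = corrected_rates(mf2$W, external_drive(mf2, r_X, S), eps, g))
  if (q < 1) {
    mf3 <- build_meanfield(net$coupling, net$sizes, "expressing")
    theory$off3 <- corrected_rates(mf3$W, external_drive(mf3, r_X), eps, g)
    theory$on3 <- corrected_rates(mf3$W, external_drive(mf3, r_X, S), eps, g)
  }
  summary <- data.frame(population = rownames(rates$mean),
                        rate_pre = rates$mean[, 1], rate_stim = rates$mean[, 2],
                        X_pre = currents$X[, 1], X_stim = currents$X[, 2],
                        R_pre = currents$R[, 1], R_stim = currents$R[, 2],
                        I_pre = currents$I[, 1], I_stim = currents$I[, 2])
  list(sim = sim, rates = rates, currents = currents, gain_fit = fit,
       theory = theory, epsilon = eps, masks = masks, summary = summary,
       network = net, graph_seed = seed)
}

fig_chain <- function(scale, seed, duration, S, gain, upstream = NULL, ...) {
  up <- upstream %||% fig_discrete(q = 0.2, scale, seed, duration, S, gain, ...)
  net <- up$network
  down <- chain_layers(list(raster = up$sim$raster, NE = net$sizes$N_E),
                       net$coupling,
                       population_sizes(N = net$sizes$N, q = net$sizes$q,
                                        N_X = net$sizes$N_E),
                       seed = seed + 4000L)
  cfg <- sim_config(duration = duration, seed = seed + 5000L,
                    epochs = up$sim$epochs)
  obj <- config_objects()
  sim <- simulate_network(down$graph, down$external, NULL, cfg,
                          obj$neuron, obj$kinetics)
  NE <- net$sizes$N_E
  masks <- list(E = seq_len(NE), I = NE + seq_len(net$sizes$N_I))
  rates <- estimate_rates(sim$raster, masks, sim$epochs)
  list(upstream = up, sim = sim, rates = rates,
       currents = mean_currents(sim, masks),
       summary = data.frame(population = rownames(rates$mean),
                            rate_pre = rates$mean[, 1],
                            rate_stim = rates$mean[, 2]))
}

fig_spatial <- function(gain, grid = c(64, 64, 32), sigmas = c(0.2, 0.06),
                        kernels = spatial_kernels()) {
  out <- list(kernels = kernels)
  for (sx in sigmas) {
    key <- paste0("sigma_", sx)
    stim <- build_stimulus(stimulus_spec(sigma_X = sx), grid)
    sol <- spatial_corrected_rates(kernels, stim, gain = gain)
    wm <- gaussian_widths(sx, kernels$alpha["X"], kernels$alpha["E"],
                          kernels$alpha["I"])
    bal <- if (wm$feasible) spatial_balanced_rates(kernels, stim) else NULL
    fits <- if (!is.null(bal))
      list(E = fit_profile_width(bal$rE, "x"), I = fit_profile_width(bal$rI, "x"))
    else NULL
    out[[key]] <- list(stimulus = stim, corrected = sol, balanced = bal,
                       widths = wm, width_fits = fits)
  }
  out
}

fig_size_tuning <- function(gain, sigma_X_values = seq(0.02, 0.3, by = 0.02),
                            alpha_E_values = c(0.02, 0.05, 0.1, 0.15),
                            kernels = spatial_kernels(), grid = c(64, 64, 1)) {
  base <- size_tuning_scan(kernels, sigma_X_values, gain = gain, grid = grid)
  sweep_E <- lapply(alpha_E_values, function(aE) {
    k <- kernels; k$alpha["E"] <- aE
    size_tuning_scan(k, sigma_X_values, gain = gain, grid = grid)
  })
  names(sweep_E) <- paste0("alpha_E_", alpha_E_values)
  disc_k <- kernels; disc_k$alpha["E"] <- 0.02
  disc <- size_tuning_scan(disc_k, sigma_X_values, gain = gain,
                           template = "disc", grid = grid)
  list(gaussian = base, alpha_E_sweep = sweep_E, disc = disc,
       extrema = list(gaussian_E = length(base$maxima_E),
                      gaussian_I = length(base$maxima_I),
                      disc_E = length(disc$maxima_E)))
}

fig_deconvolution <- function(gain, kernels = spatial_kernels(),
                              ratios = c(0.85, 1, 1.1), radius = 0.25,
                              blur = 0.01, grid = c(128, 128, 1),
                              contrast = NULL) {
  spec <- if (is.null(contrast))
    stimulus_spec("disc", sigma_X = radius, blur = blur)
  else stimulus_spec("contrast_map", contrast = contrast, blur = blur)
  stim <- build_stimulus(spec, grid)
  aX <- kernels$alpha["X"]
  runs <- lapply(ratios, function(rr) {
    k <- kernels; k$alpha["E"] <- rr * aX
    sol <- spatial_corrected_rates(k, stim, gain = gain)
    list(ratio = rr, sol = sol,
         sharp_input = sharpness_index(sol$IE),
         sharp_output = sharpness_index(sol$rE))
  })
  names(runs) <- paste0("alpha_E_", ratios, "aX")
  list(stimulus = stim, sharp_stimulus = sharpness_index(stim), runs = runs)
}

write_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$summary))
    utils::write.csv(res$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  if (!is.null(res$rates))
    utils::write.csv(res$rates$timecourse, file.path(out_dir, "rates_timecourse.csv"),
                     row.names = FALSE)
  jsonlite::write_json(res$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
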
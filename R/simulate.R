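#' Simulation configuration
#'
#' @param dt integration time step, ms.
#' @param duration total simulated time, ms.
#' @param seed RNG seed for the membrane-potential initial condition.
#' @param burn_in initial interval excluded from rate/current averages, ms.
#' @param settle interval after stimulus onset excluded from the
#'   during-stimulation epoch, ms.
#' @param record indices of neurons whose current traces are recorded.
#' @param record_stride trace sampling stride in steps (default: every
#'   1 ms at dt = 0.1).
#' @param epochs optional explicit epoch matrix (rows of start, end in
#'   ms); by default one epoch after burn-in, split at the stimulus onset
#'   when a protocol is present.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(dt = 0.1, duration = 10000, seed = NULL,
                       burn_in = 500, settle = 250,
                       record = integer(0), record_stride = 10,
                       epochs = NULL) {
  stopifnot(dt > 0, duration >= dt)
  structure(list(dt = dt, duration = duration, seed = seed,
                 burn_in = burn_in, settle = settle,
                 record = as.integer(record),
                 record_stride = as.integer(record_stride), epochs = epochs),
            class = "sim_config")
}

#' Construct a spike raster
#'
#' A time-sorted table of spike times (ms) and neuron ids with the
#' covered duration and the neuron count attached as attributes; the
#' common currency between \code{\link{poisson_drive}},
#' \code{\link{simulate_network}}, \code{\link{chain_layers}} and
#' \code{\link{estimate_rates}}.
#'
#' @param time spike times, ms.
#' @param id neuron indices (1-based).
#' @param duration covered duration, ms.
#' @param count number of neurons in the population.
#' @return An object of classes \code{"spike_raster"} and
#'   \code{"data.frame"}.
#' @export
spike_raster <- function(time, id, duration, count) {
  o <- order(time, id)
  structure(data.frame(time = time[o], id = id[o]),
            duration = duration, count = count, class = c("spike_raster", "data.frame"))
}

#' Poisson external spike trains
#'
#' Independent homogeneous Poisson spike trains, one per external neuron,
#' at a common or per-neuron rate.
#'
#' @param count number of neurons.
#' @param rate firing rate(s), Hz (scalar or length \code{count}).
#' @param duration ms.
#' @param seed optional RNG seed.
#' @return A \code{"spike_raster"}: data frame (time ms, id) sorted by
#'   time, with the duration and neuron count attached as attributes.
#' @export
poisson_drive <- function(count, rate, duration, seed = NULL) {
  if (any(rate < 0)) stop("rates must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  rate <- rep_len(rate, count)
  n <- stats::rpois(count, rate * duration / 1000)
  spike_raster(stats::runif(sum(n), 0, duration), rep(seq_len(count), n),
               duration, count)
}

#' Optogenetic-style stimulation protocol
#'
#' An extra inward current \code{S} added to the external input of a
#' targeted subset of excitatory neurons from \code{onset} onward.
#'
#' @param S injected current, mV/ms.
#' @param onset stimulation onset, ms.
#' @param targets integer indices of targeted excitatory neurons.
#' @return An object of class \code{"stim_protocol"}.
#' @export
stim_protocol <- function(S = 2, onset, targets) {
  stopifnot(onset >= 0)
  structure(list(S = S, onset = onset, targets = as.integer(targets)),
            class = "stim_protocol")
}

#' Choose a seeded random expressing subset
#'
#' @param sizes a \code{\link{population_sizes}}.
#' @param q fraction of excitatory neurons to target.
#' @param seed optional RNG seed.
#' @return Sorted integer indices into the excitatory population.
#' @export
choose_targets <- function(sizes, q = sizes$q, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (q >= 1) return(seq_len(sizes$N_E))
  sort(sample.int(sizes$N_E, round(q * sizes$N_E)))
}

#' Apply a stimulation protocol to external current traces
#'
#' Adds the protocol current to the columns of a time-by-neuron external
#' current matrix for targeted neurons at times at or after onset.
#'
#' @param protocol a \code{\link{stim_protocol}}.
#' @param traces numeric matrix, rows = time points, columns = neurons.
#' @param times time stamps of the rows, ms.
#' @param ids neuron indices of the columns (default \code{1:ncol}).
#' @return The modified matrix.
#' @export
apply_stimulation <- function(protocol, traces, times, ids = seq_len(ncol(traces))) {
  hit <- ids %in% protocol$targets
  traces[times >= protocol$onset, hit] <- traces[times >= protocol$onset, hit] + protocol$S
  traces
}

## Flatten pair blocks into CSR adjacency over presynaptic neurons.
## Presyn populations listed in `pres`; postsynaptic targets get a global
## index with I offset by N_E.
build_csr <- function(graph, pres, n_pre_each, NE) {
  pre_l <- list(); post_l <- list(); w_l <- list()
  offset <- 0
  for (i in seq_along(pres)) {
    b <- pres[i]
    for (a in c("E", "I")) {
      blk <- graph$blocks[[paste0(b, "->", a)]]
      if (nrow(blk)) {
        pre_l[[length(pre_l) + 1]] <- blk$pre + offset
        post_l[[length(post_l) + 1]] <- blk$post + if (a == "I") NE else 0
        w_l[[length(w_l) + 1]] <- blk$weight
      }
    }
    offset <- offset + n_pre_each[i]
  }
  n_pre <- sum(n_pre_each)
  if (!length(pre_l))
    return(list(ptr = integer(n_pre + 1), post = integer(0), w = numeric(0)))
  pre <- unlist(pre_l); post <- unlist(post_l); w <- unlist(w_l)
  o <- order(pre)
  list(ptr = c(0L, cumsum(tabulate(pre, n_pre))),
       post = as.integer(post[o] - 1L), w = as.numeric(w[o]))
}

#' Simulate the spiking network
#'
#' Forward-Euler integration (compiled core) of the recurrent AdEx
#' network defined by a sampled synaptic graph, driven by an external
#' spike raster and an optional stimulation protocol. Membrane potentials
#' are initialised uniformly between the reset and the soft threshold
#' (seeded via the configuration); adaptation and synaptic filter states
#' start at zero.
#'
#' @param graph a \code{\link{sample_graph}} result.
#' @param external a \code{"spike_raster"} for the external population
#'   (its neuron count must equal \code{graph$sizes$N_X}).
#' @param protocol optional \code{\link{stim_protocol}}.
#' @param config a \code{\link{sim_config}}.
#' @param neuron,kinetics model constants.
#' @return An object of class \code{"sim_result"}: the spike raster,
#'   per-neuron per-epoch sums of external and recurrent current and
#'   spike counts, recorded current traces for the configured subset,
#'   and the epoch matrix.
#' @export
simulate_network <- function(graph, external, protocol = NULL,
                             config = sim_config(),
                             neuron = neuron_params(),
                             kinetics = synapse_kinetics()) {
  sizes <- graph$sizes
  if (attr(external, "count") != sizes$N_X)
    stop("external raster count does not match N_X of the graph")
  if (attr(external, "duration") < config$duration)
    stop("external raster does not cover the simulation duration")
  NE <- sizes$N_E; NI <- sizes$N_I; N <- NE + NI
  rec <- build_csr(graph, c("E", "I"), c(NE, NI), NE)
  ext <- build_csr(graph, "X", sizes$N_X, NE)
  if (!is.null(config$seed)) set.seed(config$seed)
  Vinit <- stats::runif(N, neuron$V_re, neuron$V_T)
  S <- 0; onset <- config$duration; mask <- logical(NE)
  if (!is.null(protocol)) {
    S <- protocol$S; onset <- protocol$onset
    mask[protocol$targets] <- TRUE
  }
  epochs <- config$epochs
  if (is.null(epochs)) {
    epochs <- if (!is.null(protocol) && onset < config$duration)
      rbind(c(config$burn_in, onset),
            c(onset + config$settle, config$duration))
    else matrix(c(config$burn_in, config$duration), 1)
  }
  out <- .adex_sim(NE, NI, Vinit, unclass(neuron), unclass(kinetics),
                   rec$ptr, rec$post, rec$w, ext$ptr, ext$post, ext$w,
                   external$time, as.integer(external$id) - 1L,
                   S, onset, mask, config$dt, config$duration,
                   epochs, as.integer(config$record - 1L),
                   config$record_stride)
  structure(list(
    raster = spike_raster(out$spike_time, out$spike_id, config$duration, N),
    NE = NE, NI = NI, epochs = epochs,
    sums = list(X = out$sumX, R = out$sumR, nspike = out$nspike,
                steps = out$epoch_steps),
    traces = if (length(config$record))
      list(X = out$trX, R = out$trR, I = out$trX + out$trR,
           time = out$trT, index = config$record) else NULL,
    protocol = protocol, config = config,
    neuron = neuron, kinetics = kinetics, sizes = sizes),
    class = "sim_result")
}

#' Chain a downstream layer onto an upstream simulation
#'
#' Uses the excitatory spikes of an upstream simulation as the external
#' population of a new (downstream) network, whose external-block
#' connectivity is freshly sampled with the usual feedforward
#' probabilities and strengths. The upstream excitatory count must equal
#' the downstream external count.
#'
#' @param upstream a \code{"sim_result"}.
#' @param coupling,sizes downstream network parameters.
#' @param seed optional RNG seed for the downstream graph.
#' @return List with \code{external} (spike raster of upstream E spikes)
#'   and \code{graph} (downstream synaptic graph).
#' @export
chain_layers <- function(upstream, coupling, sizes, seed = NULL) {
  if (sizes$N_X != upstream$NE)
    stop("downstream N_X must equal the upstream excitatory count")
  r <- upstream$raster
  keep <- r$id <= upstream$NE
  external <- spike_raster(r$time[keep], r$id[keep],
                           attr(r, "duration"), upstream$NE)
  list(external = external, graph = sample_graph(coupling, sizes, seed))
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("AdEx network simulation: N = %d (E %d / I %d), %d spikes in %g ms\n",
              x$NE + x$NI, x$NE, x$NI, nrow(x$raster), x$config$duration))
  invisible(x)
}
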
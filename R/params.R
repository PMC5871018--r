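#' Neuron model constants
#'
#' Parameters of the adaptive exponential integrate-and-fire (AdEx) neuron.
#' All currents in the package are expressed per membrane capacitance, so
#' they carry units of mV/ms and no explicit capacitance constant appears:
#' the leak is parameterised by the membrane time constant
#' \code{tau_m = C_m/g_L} and the adaptation increment \code{B} is the jump
#' of the adaptation variable (itself a current per capacitance) at each
#' spike.
#'
#' @param tau_m membrane time constant, ms.
#' @param E_L leak reversal potential, mV.
#' @param V_T soft spike-initiation threshold, mV.
#' @param V_th hard threshold at which a spike is recorded, mV.
#' @param Delta_T spike-initiation sharpness, mV.
#' @param V_re reset potential, mV.
#' @param V_lb lower bound on the membrane potential, mV.
#' @param tau_ref absolute refractory period, ms.
#' @param tau_w adaptation time constant, ms.
#' @param B adaptation increment per spike, mV/ms.
#' @return An object of class \code{"neuron_params"}.
#' @export
neuron_params <- function(tau_m = 15, E_L = -72, V_T = -60, V_th = -15,
                          Delta_T = 1.5, V_re = -72, V_lb = -100,
                          tau_ref = 1, tau_w = 150, B = 0.267) {
  stopifnot(tau_m > 0, tau_ref > 0, tau_w > 0, Delta_T > 0)
  if (!(V_lb < V_re && V_re <= E_L && E_L < V_T && V_T < V_th))
    stop("potentials must satisfy V_lb < V_re <= E_L < V_T < V_th")
  structure(list(tau_m = tau_m, E_L = E_L, V_T = V_T, V_th = V_th,
                 Delta_T = Delta_T, V_re = V_re, V_lb = V_lb,
                 tau_ref = tau_ref, tau_w = tau_w, B = B),
            class = "neuron_params")
}

#' Synaptic kinetics
#'
#' Decay constants of the exponential synaptic kernels
#' \code{eta_b(t) = exp(-t/tau_b)/tau_b}, one kernel per presynaptic class
#' (recurrent excitatory, recurrent inhibitory, external). Each kernel
#' integrates to one, so time constants do not affect time-averaged
#' currents.
#'
#' @param tau_E,tau_I,tau_X decay constants, ms.
#' @return An object of class \code{"synapse_kinetics"}.
#' @export
synapse_kinetics <- function(tau_E = 8, tau_I = 4, tau_X = 10) {
  stopifnot(tau_E > 0, tau_I > 0, tau_X > 0)
  structure(list(tau_E = tau_E, tau_I = tau_I, tau_X = tau_X),
            class = "synapse_kinetics")
}

#' Population sizes
#'
#' The recurrent network holds \code{N} neurons split 4:1 into excitatory
#' and inhibitory populations; an external population of \code{N_X}
#' Poisson neurons drives it. \code{q} is the fraction of excitatory
#' neurons targeted by partial (optogenetic-style) stimulation.
#'
#' @param N total recurrent neuron count.
#' @param N_X external population count.
#' @param q stimulated fraction of the excitatory population, in [0, 1].
#' @param N_E,N_I optional explicit excitatory/inhibitory counts
#'   (default 0.8 N and 0.2 N).
#' @return An object of class \code{"population_sizes"}.
#' @export
population_sizes <- function(N = 5000, N_X = 4000, q = 0.2,
                             N_E = round(0.8 * N), N_I = N - N_E) {
  stopifnot(N > 0, N_X > 0, q >= 0, q <= 1, N_E + N_I == N)
  structure(list(N = N, N_E = N_E, N_I = N_I, N_X = N_X, q = q),
            class = "population_sizes")
}

#' Microscopic coupling table
#'
#' Connection probabilities \code{p[a, b]} and strengths \code{J[a, b]}
#' (mV) for postsynaptic populations a in {E, I} and presynaptic
#' populations b in {E, I, X}. Defaults are the dense-network values used
#' throughout: \code{p_EE = p_IE = p_IX = 0.1}, \code{p_EI = p_II = p_EX =
#' 0.2}, \code{J_EE = 0.4}, \code{J_IE = 0.83}, \code{J_EI = J_II =
#' -1.67}, \code{J_EX = J_IX = 0.47}.
#'
#' @param p 2 x 3 matrix of connection probabilities with dimnames
#'   \code{list(c("E","I"), c("E","I","X"))}.
#' @param J 2 x 3 matrix of connection strengths, mV; inhibitory columns
#'   must be non-positive, others non-negative.
#' @return An object of class \code{"coupling_table"}.
#' @export
coupling_table <- function(p = NULL, J = NULL) {
  dn <- list(c("E", "I"), c("E", "I", "X"))
  if (is.null(p))
    p <- matrix(c(0.1, 0.1, 0.2, 0.2, 0.2, 0.1), 2, 3, dimnames = dn)
  if (is.null(J))
    J <- matrix(c(0.4, 0.83, -1.67, -1.67, 0.47, 0.47), 2, 3, dimnames = dn)
  storage.mode(p) <- "double"; storage.mode(J) <- "double"
  dimnames(p) <- dn; dimnames(J) <- dn
  if (any(p < 0) || any(p > 1)) stop("connection probabilities must lie in [0, 1]")
  if (any(J[, "I"] > 0)) stop("inhibitory strengths J[, 'I'] must be <= 0")
  if (any(J[, c("E", "X")] < 0)) stop("excitatory strengths must be >= 0")
  structure(list(p = p, J = J), class = "coupling_table")
}

#' Mean in-degrees K[a, b] = p[a, b] * N_b
#'
#' @param coupling a \code{\link{coupling_table}}.
#' @param sizes a \code{\link{population_sizes}}.
#' @return 2 x 3 matrix of mean in-degrees.
#' @export
in_degrees <- function(coupling, sizes) {
  Nb <- c(E = sizes$N_E, I = sizes$N_I, X = sizes$N_X)
  sweep(coupling$p, 2, Nb, "*")
}

#' Balance parameter
#'
#' \code{epsilon = 1/(K_EX * J_EX)}, the reciprocal of the total synaptic
#' current (mV) a neuron in E would receive if every external neuron fired
#' once. Small \code{epsilon} means strong feedforward coupling; the
#' classical balanced limit is \code{epsilon -> 0}. The stored number
#' carries units of 1/mV.
#'
#' @inheritParams in_degrees
#' @return The balance parameter (numeric scalar).
#' @export
compute_epsilon <- function(coupling, sizes) {
  K_EX <- coupling$p["E", "X"] * sizes$N_X
  J_EX <- coupling$J["E", "X"]
  if (!(K_EX > 0) || !(J_EX > 0))
    stop("K_EX * J_EX must be positive to define the balance parameter")
  1 / (K_EX * J_EX)
}

#' Rescale a network while preserving its mean field
#'
#' Changes the total recurrent count to \code{N_new}, scaling all
#' population sizes proportionally (rounded, preserving the 4:1 E:I split)
#' and multiplying every connection probability and strength by
#' \code{(5000/N_new)^(1/4)}. At \code{N_new = 5000} the input is returned
#' unchanged. Because \code{K * J} then scales as \code{sqrt(1/N)}, the
#' balance parameter scales as \code{epsilon ~ N^(-1/2)} under this
#' recipe, while every mean-field ratio \code{w_ab} is unchanged.
#'
#' @inheritParams in_degrees
#' @param N_new new total recurrent neuron count.
#' @return List with elements \code{coupling} and \code{sizes}.
#' @export
scale_network <- function(coupling, sizes, N_new) {
  stopifnot(N_new > 0)
  f <- (5000 / N_new)^0.25
  ratio <- N_new / 5000
  N_E <- round(sizes$N_E * ratio)
  N_I <- round(sizes$N_I * ratio)
  N_X <- round(sizes$N_X * ratio)
  p <- coupling$p * f
  if (any(p > 1))
    stop("scaled connection probability exceeds 1; network not realizable at N_new = ",
         N_new)
  list(coupling = coupling_table(p = p, J = coupling$J * f),
       sizes = population_sizes(N = N_E + N_I, N_X = N_X, q = sizes$q,
                                N_E = N_E, N_I = N_I))
}

#' Peak postsynaptic potential of a passive membrane
#'
#' Peak deflection of a passive membrane (time constant \code{tau_m})
#' responding from rest to a single presynaptic spike delivered through
#' the unit-integral exponential kernel \code{J * exp(-t/tau_s)/tau_s}.
#' The closed form is the classic double-exponential peak
#' \deqn{|J| \frac{\tau_m}{\tau_m - \tau_s}
#'   \left(e^{-t^*/\tau_m} - e^{-t^*/\tau_s}\right),\quad
#'   t^* = \frac{\tau_m \tau_s}{\tau_m - \tau_s}\log(\tau_m/\tau_s),}
#' signed by \code{J}. At \code{tau_s == tau_m} the alpha-function limit
#' \code{J * exp(-1)} is used (continuity).
#'
#' With the default coupling table and \code{tau_m = 15} ms this spans
#' the range of unitary postsynaptic potentials from about 0.19 mV
#' (weakest, J = 0.4 mV through the 8 ms kernel) to about 1.0 mV in
#' magnitude (strongest, |J| = 1.67 mV through the 4 ms kernel).
#'
#' @param J connection strength, mV (may be a vector).
#' @param tau_s synaptic decay constant, ms.
#' @param tau_m membrane time constant, ms.
#' @return Peak deflection in mV, same sign as \code{J}.
#' @export
psp_peak <- function(J, tau_s, tau_m) {
  stopifnot(tau_s > 0, tau_m > 0)
  if (isTRUE(all.equal(tau_s, tau_m))) return(J * exp(-1))
  tstar <- (tau_m * tau_s / (tau_m - tau_s)) * log(tau_m / tau_s)
  J * (tau_m / (tau_m - tau_s)) * (exp(-tstar / tau_m) - exp(-tstar / tau_s))
}

#' @export
print.coupling_table <- function(x, ...) {
  cat("Coupling table (rows: postsynaptic, cols: presynaptic)\n")
  cat("Connection probabilities p:\n"); print(x$p)
  cat("Connection strengths J (mV):\n"); print(x$J)
  invisible(x)
}

#' @export
print.population_sizes <- function(x, ...) {
  cat(sprintf("Populations: N = %d (E %d / I %d), external N_X = %d, q = %g\n",
              x$N, x$N_E, x$N_I, x$N_X, x$q))
  invisible(x)
}
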
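# Shared fixtures and independent oracle implementations used across the
# suite. Oracles deliberately avoid the package's own computational paths.

fig_coupling <- function() coupling_table()
fig_sizes <- function() population_sizes()

# Fine-step Euler integration of a passive membrane driven by one
# synaptic kernel event (oracle for the closed-form PSP peak).
psp_numeric <- function(J, tau_s, tau_m, dt = 0.001, Tmax = 300) {
  t <- seq(0, Tmax, by = dt)
  V <- 0
  peak <- 0
  eta <- exp(-t / tau_s) / tau_s
  for (i in seq_along(t)) {
    V <- V + dt * (-V / tau_m + J * eta[i])
    if (abs(V) > abs(peak)) peak <- V
  }
  peak
}

# Plain-R forward Euler of a single AdEx neuron under constant input
# (oracle for the compiled network core at one-neuron scale).
adex_single_R <- function(I0, neuron, dt, duration) {
  V <- neuron$V_re; w <- 0; refr <- 0
  nsteps <- round(duration / dt)
  ref_steps <- max(1, round(neuron$tau_ref / dt))
  nsp <- 0
  for (n in seq_len(nsteps)) {
    if (refr > 0) {
      refr <- refr - 1
      V <- neuron$V_re
    } else {
      arg <- min((V - neuron$V_T) / neuron$Delta_T,
                 (neuron$V_th - neuron$V_T) / neuron$Delta_T + 5)
      V <- V + dt * ((-(V - neuron$E_L) + neuron$Delta_T * exp(arg)) / neuron$tau_m
                     + I0 - w)
      if (V < neuron$V_lb) V <- neuron$V_lb
      if (V > neuron$V_th) {
        nsp <- nsp + 1
        V <- neuron$V_re
        refr <- ref_steps
        w <- w + neuron$B
      }
    }
    w <- w * exp(-dt / neuron$tau_w)
  }
  nsp / (duration / 1000)
}

# Dense real-space circular-convolution solve of the corrected spatial
# rate equation (oracle for the Fourier-domain solver). Builds the full
# block-circulant operator from the inverse transform of the analytic
# kernel coefficients and solves it with dense linear algebra.
dense_spatial_solve <- function(kernels, rX, epsilon, gain) {
  grid <- dim(rX); M <- prod(grid)
  freq <- function(n) { i <- seq_len(n) - 1; ifelse(i <= n %/% 2, i, i - n) }
  N2 <- outer(outer(freq(grid[1])^2, freq(grid[2])^2, "+"), rep(1, grid[3]))
  K2 <- outer(array(1, grid[1:2]), freq(grid[3]))^2
  w <- kernels$wbar; a <- kernels$alpha; at <- kernels$alpha_theta
  dec <- function(b) exp(-2 * pi^2 * (N2 * a[b]^2 + K2 * at[b]^2))
  kreal <- function(wt) Re(stats::fft(wt, inverse = TRUE)) / M
  ix <- rep(0:(grid[1] - 1), times = grid[2] * grid[3])
  iy <- rep(rep(0:(grid[2] - 1), each = grid[1]), times = grid[3])
  it <- rep(0:(grid[3] - 1), each = grid[1] * grid[2])
  circ <- function(k3) {
    dx <- outer(ix, ix, "-") %% grid[1]
    dy <- outer(iy, iy, "-") %% grid[2]
    dtt <- outer(it, it, "-") %% grid[3]
    matrix(k3[cbind(as.vector(dx) + 1, as.vector(dy) + 1, as.vector(dtt) + 1)], M, M)
  }
  g2 <- rep_len(gain, 2)
  A <- rbind(
    cbind(diag(1000 * epsilon / g2[1], M) - circ(kreal(w["E", "E"] * dec("E"))),
          -circ(kreal(w["E", "I"] * dec("I")))),
    cbind(-circ(kreal(w["I", "E"] * dec("E"))),
          diag(1000 * epsilon / g2[2], M) - circ(kreal(w["I", "I"] * dec("I")))))
  x <- as.vector(unclass(rX))
  b <- c(circ(kreal(w["E", "X"] * dec("X"))) %*% x,
         circ(kreal(w["I", "X"] * dec("X"))) %*% x)
  sol <- solve(A, b)
  list(rE = array(sol[1:M], grid), rI = array(sol[M + 1:M], grid))
}

# Smooth random positive stimulus field for oracle comparisons.
random_smooth_field <- function(grid, seed = 7, base = 5, width = 0.12) {
  set.seed(seed)
  vals <- array(0, grid)
  gx <- (seq_len(grid[1]) - 1) / grid[1]
  gy <- (seq_len(grid[2]) - 1) / grid[2]
  gt <- (seq_len(grid[3]) - 1) / grid[3]
  for (i in 1:4) {
    vals <- vals + runif(1, 0.5, 2) *
      outer(outer(wrapped_gaussian(gx - runif(1), width),
                  wrapped_gaussian(gy - runif(1), width)),
            wrapped_gaussian(gt - runif(1), 1.25 * width))
  }
  imbalnet:::rate_field(base + vals, grid)
}

# Small discrete-network simulation shared by simulator tests.
small_sim <- function(N = 1000, duration = 1500, seed = 42, S = 0, q = 1,
                      record = integer(0)) {
  net <- scale_network(fig_coupling(), fig_sizes(), N)
  graph <- sample_graph(net$coupling, net$sizes, seed = seed)
  ext <- poisson_drive(net$sizes$N_X, 5, duration, seed = seed + 1)
  protocol <- if (S != 0)
    stim_protocol(S = S, onset = duration / 2,
                  targets = choose_targets(net$sizes, q, seed = seed + 2))
  else NULL
  sim <- simulate_network(graph, ext, protocol,
                          sim_config(duration = duration, seed = seed + 3,
                                     record = record))
  list(sim = sim, net = net, graph = graph, ext = ext)
}
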
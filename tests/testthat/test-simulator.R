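# A one-neuron "network": empty recurrent graph, constant stimulus as the
# only input.
single_neuron_sim <- function(I0, duration, dt = 0.1) {
  cp <- coupling_table(p = matrix(0, 2, 3), J = coupling_table()$J)
  cp$p["E", "X"] <- 0.5; cp$J["E", "X"] <- 1  # keep epsilon definable
  sz <- population_sizes(N = 2, N_X = 2, N_E = 1, N_I = 1)
  g <- sample_graph(cp, sz, seed = 1)
  ext <- spike_raster(numeric(0), integer(0), duration, 2)
  simulate_network(g, ext,
                   stim_protocol(S = I0, onset = 0, targets = 1),
                   sim_config(duration = duration, seed = 1, dt = dt,
                              epochs = matrix(c(0, duration), 1)))
}

test_that("a resting network without drive stays silent", {
  sim <- single_neuron_sim(0, 500)
  expect_equal(nrow(sim$raster), 0)
})

test_that("suprathreshold firing matches a fine-step reference integration", {
  # constant input at 1.5x the exponential-IF rheobase
  # (rheobase/C_m = (V_T - E_L - Delta_T)/tau_m = 0.7 mV/ms), with
  # adaptation disabled to make the rate stationary
  neuron0 <- neuron_params(B = 0, tau_w = 1e9)
  I0 <- 1.5 * (neuron0$V_T - neuron0$E_L - neuron0$Delta_T) / neuron0$tau_m
  cp <- coupling_table(p = matrix(0, 2, 3), J = coupling_table()$J)
  cp$p["E", "X"] <- 0.5; cp$J["E", "X"] <- 1
  sz <- population_sizes(N = 2, N_X = 2, N_E = 1, N_I = 1)
  g <- sample_graph(cp, sz, seed = 1)
  ext <- spike_raster(numeric(0), integer(0), 2000, 2)
  sim <- simulate_network(g, ext, stim_protocol(S = I0, onset = 0, targets = 1),
                          sim_config(duration = 2000, seed = 1,
                                     epochs = matrix(c(0, 2000), 1)),
                          neuron = neuron0)
  rate_sim <- nrow(sim$raster) / 2
  rate_ref <- adex_single_R(I0, neuron0, dt = 0.001, duration = 2000)
  expect_gt(rate_sim, 0)
  expect_equal(rate_sim, rate_ref, tolerance = 0.02)
})

test_that("simulation is deterministic and respects its invariants", {
  a <- small_sim(N = 600, duration = 800, seed = 21)
  b <- small_sim(N = 600, duration = 800, seed = 21)
  expect_identical(a$sim$raster, b$sim$raster)

  # refractory floor on inter-spike intervals
  r <- a$sim$raster
  isi <- unlist(tapply(r$time, r$id, function(t) diff(sort(t))))
  expect_gt(nrow(r), 100)
  expect_true(all(isi >= neuron_params()$tau_ref - 1e-9))
  expect_true(all(r$time >= 0 & r$time <= 800))
})

test_that("current bookkeeping: total = external + recurrent identically", {
  res <- small_sim(N = 600, duration = 800, seed = 5, record = c(1, 10, 550))
  tr <- res$sim$traces
  expect_equal(tr$I, tr$X + tr$R)
  # trace average agrees with the per-neuron epoch accumulator
  ep <- res$sim$epochs
  sel <- tr$time >= ep[1, 1] & tr$time < ep[1, 2]
  acc <- res$sim$sums$X[1, 1] / res$sim$sums$steps[1]
  expect_equal(mean(tr$X[sel, 1]), acc, tolerance = 0.05)
})

test_that("Poisson drive has Poisson statistics", {
  expect_equal(nrow(poisson_drive(10, 0, 1000, seed = 1)), 0)
  r <- poisson_drive(4000, 5, 10000, seed = 2)
  expect_lt(abs(nrow(r) - 200000), 5 * sqrt(200000))
  counts <- tabulate(r$id, 4000)
  fano <- stats::var(counts) / mean(counts)
  expect_lt(abs(fano - 1), 0.1)
  expect_error(poisson_drive(10, -1, 100), "non-negative")
  # per-neuron rates
  r2 <- poisson_drive(3, c(0, 50, 100), 20000, seed = 3)
  expect_equal(sum(r2$id == 1), 0)
  expect_lt(abs(sum(r2$id == 3) - 2000), 5 * sqrt(2000))
})

test_that("stimulation adds exactly S to targeted external currents", {
  # protocol applied to plain traces
  tr <- matrix(1, 4, 3)
  out <- apply_stimulation(stim_protocol(S = 2, onset = 10, targets = c(1, 3)),
                           tr, times = c(0, 5, 10, 15))
  expect_equal(out[, 2], rep(1, 4))
  expect_equal(out[3:4, c(1, 3)], matrix(3, 2, 2))
  expect_equal(out[1:2, 1], c(1, 1))
  # S = 0 is the identity
  expect_equal(apply_stimulation(stim_protocol(0, 0, 1), tr, 1:4), tr)

  # in simulation: same seed with and without stimulus, targeted traces
  # differ by exactly S after onset
  on <- small_sim(N = 600, duration = 600, seed = 13, S = 2, q = 1,
                  record = c(2, 590))
  off <- small_sim(N = 600, duration = 600, seed = 13, S = 0, q = 1,
                   record = c(2, 590))
  tr_on <- on$sim$traces; tr_off <- off$sim$traces
  pre <- tr_on$time < 300
  expect_equal(tr_on$X[pre, 1], tr_off$X[pre, 1])
  dX <- tr_on$X[!pre, 1] - tr_off$X[!pre, 1]
  expect_equal(dX, rep(2, sum(!pre)))
  # inhibitory neuron (column 2, index 590 > N_E = 480): never stimulated
  expect_equal(tr_on$X[, 2], tr_off$X[, 2])
})

test_that("layer chaining feeds upstream excitatory spikes downstream", {
  up <- small_sim(N = 600, duration = 600, seed = 31)
  NE <- up$net$sizes$N_E
  down_sizes <- population_sizes(N = 600, N_X = NE,
                                 N_E = NE, N_I = 600 - NE)
  ch <- chain_layers(list(raster = up$sim$raster, NE = NE),
                     up$net$coupling, down_sizes, seed = 32)
  expect_true(all(ch$external$id <= NE))
  expect_equal(attr(ch$external, "count"), NE)

  # silent upstream propagates zero drive
  silent <- list(raster = spike_raster(numeric(0), integer(0), 600, 600),
                 NE = NE)
  ch0 <- chain_layers(silent, up$net$coupling, down_sizes, seed = 33)
  sim0 <- simulate_network(ch0$graph, ch0$external, NULL,
                           sim_config(duration = 600, seed = 34))
  expect_equal(nrow(sim0$raster), 0)

  # population mismatch is an error
  expect_error(chain_layers(list(raster = up$sim$raster, NE = NE),
                            up$net$coupling, population_sizes(N = 600, N_X = 99)),
               "must equal")
})

test_that("the small network operates in the balanced regime", {
  res <- small_sim(N = 2000, duration = 2000, seed = 77)
  NE <- res$net$sizes$N_E
  masks <- list(E = seq_len(NE), I = NE + seq_len(res$net$sizes$N_I))
  cur <- mean_currents(res$sim, masks)
  # net-inhibitory recurrent input canceling most of the external drive
  expect_lt(cur$R["E", 1], 0)
  expect_lt(abs(cur$I["E", 1]), abs(cur$X["E", 1]))
  expect_lt(abs(cur$I["E", 1]), abs(cur$R["E", 1]))
  # external drive magnitude matches K_EX J_EX r_X
  KJ <- in_degrees(res$net$coupling, res$net$sizes)["E", "X"] *
    res$net$coupling$J["E", "X"]
  expect_equal(unname(cur$X["E", 1]), KJ * 5 / 1000, tolerance = 0.05)
})
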
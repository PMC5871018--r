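test_that("balanced rates solve the cancellation condition", {
  # W = -identity passes the drive straight through
  sol <- balanced_rates(-diag(2), c(3, 2))
  expect_equal(sol$r, c(3, 2))
  expect_lt(sol$residual, 1e-10)

  # reference parameters, hand-solved 2x2 system
  cp <- fig_coupling(); sz <- fig_sizes()
  mf <- build_meanfield(cp, sz)
  sol <- balanced_rates(mf$W, external_drive(mf, 5))
  expect_equal(sol$r, c(5.465116, 8.246762), tolerance = 1e-6)
  expect_lt(sol$residual, 1e-10 * sqrt(sum(external_drive(mf, 5)^2)))
  expect_true(sol$positive)

  # the partial-stimulation matrix is singular: no balanced state
  mf3 <- build_meanfield(cp, sz, "expressing")
  err <- tryCatch(balanced_rates(mf3$W, external_drive(mf3, 5, 2)),
                  error = function(e) e)
  expect_s3_class(err, "imbalnet_singular")
  expect_match(conditionMessage(err), "finite")
})

test_that("corrected rates converge to balance and match a generic solver", {
  cp <- fig_coupling(); sz <- fig_sizes()
  mf <- build_meanfield(cp, sz)
  X <- external_drive(mf, 5)
  bal <- balanced_rates(mf$W, X)$r
  errs <- vapply(10^-(2:6), function(e)
    sqrt(sum((corrected_rates(mf$W, X, e, 15)$r - bal)^2)), numeric(1))
  # error shrinks linearly in epsilon: err/eps ratio stable across decades
  ratio <- errs / 10^-(2:6)
  expect_lt(max(ratio) / min(ratio), 1.5)

  # W = 0: pure feedforward gain r = gain * X / (1000 * epsilon)
  r0 <- corrected_rates(matrix(0, 2, 2), c(1, 2), 0.01, 15)$r
  expect_equal(r0, 15 * c(1, 2) / (1000 * 0.01))

  # singular three-population system: finite rates equal to an
  # independent QR-based dense solve
  mf3 <- build_meanfield(cp, sz, "expressing")
  X3 <- external_drive(mf3, 5, 2)
  got <- corrected_rates(mf3$W, X3, mf3$epsilon, 15)
  A <- mf3$epsilon * diag(1000 / 15, 3) - mf3$W
  expect_equal(got$r, unname(qr.solve(A, X3)), tolerance = 1e-12)
  expect_true(all(is.finite(got$I)))
})

test_that("nullspace decomposition reproduces the partial-stimulation algebra", {
  cp <- fig_coupling(); sz <- fig_sizes()
  mf3 <- build_meanfield(cp, sz, "expressing")
  S <- 2
  s <- 1000 * mf3$epsilon * S
  X <- external_drive(mf3, 5, S)
  nd <- nullspace_decompose(mf3$W, X)
  expect_equal(nd$dim, 1L)
  # X0 = [s/2, -s/2, 0]; v0 ~ [1-q, -q, 0] normalized; v2 ~ [1, -1, 0]/sqrt(2)
  expect_equal(nd$X0, c(s / 2, -s / 2, 0))
  q <- sz$q
  expect_equal(nd$v0, c(1 - q, -q, 0) / sqrt(q^2 + (1 - q)^2))
  expect_equal(nd$v2, c(1, -1, 0) / sqrt(2))
  # exactness of the split
  expect_equal(nd$X0 + nd$X1, unname(X))
  expect_lt(abs(sum(nd$v2 * nd$X1)), 1e-12)

  # invertible W: nothing to amplify
  mf <- build_meanfield(cp, sz)
  nd2 <- nullspace_decompose(mf$W, external_drive(mf, 5))
  expect_equal(nd2$dim, 0L)
  expect_equal(nd2$X0, c(0, 0))
  expect_equal(amplified_component(mf$W, external_drive(mf, 5), 15), c(0, 0))
})

test_that("decomposition is exact on random rank-deficient matrices", {
  set.seed(11)
  for (i in 1:10) {
    P <- matrix(rnorm(20), 5, 4); Q <- matrix(rnorm(20), 4, 5)
    W <- P %*% Q                      # planted rank 4
    X <- rnorm(5)
    nd <- nullspace_decompose(W, X)
    expect_equal(nd$dim, 1L)
    expect_equal(nd$X0 + nd$X1, X)
    expect_lt(abs(sum(nd$v2 * nd$X1)), 1e-10)
    expect_lt(max(abs(W %*% nd$v0)), 1e-8)
    r0 <- amplified_component(W, X, 15)
    expect_lt(max(abs(W %*% r0)), 1e-8 * max(1, max(abs(r0))))
  }
})

test_that("amplified component equals the vanishing-epsilon limit", {
  cp <- fig_coupling(); sz <- fig_sizes()
  mf3 <- build_meanfield(cp, sz, "expressing")
  X <- external_drive(mf3, 5, 2)
  gain <- 15
  r0 <- amplified_component(mf3$W, X, gain)
  # printed closed form: r0 = g s [1-q, -q, 0] (in consistent units
  # g_mf * s = gain * S * epsilon)
  expect_equal(r0, gain * 2 * mf3$epsilon * c(1 - sz$q, -sz$q, 0))

  eps_seq <- 10^-(2:6)
  errs <- vapply(eps_seq, function(e)
    max(abs(e * corrected_rates(mf3$W, X, e, gain)$r - r0)), numeric(1))
  # linear convergence of eps * r(eps) to r0
  expect_true(all(diff(log(errs)) < 0))
  ratio <- errs / eps_seq
  expect_lt(max(ratio) / min(ratio), 2)

  # s = 0 leaves the drive in the column space: no amplified component
  expect_equal(amplified_component(mf3$W, external_drive(mf3, 5), gain),
               c(0, 0, 0), tolerance = 1e-12)
})

test_that("partial-stimulation expansion has the predicted structure", {
  cp <- fig_coupling(); sz <- fig_sizes()
  pe <- partial_stim_expansion(cp, sz, gain = 15, S = 2)
  expect_equal(pe$c, 332 / 334, tolerance = 1e-12)  # |w_IE / w_II|
  # sign pattern of the stimulated shift: (+, -, +) over (exp, nexp, I)
  d <- pe$r_exact$r - pe$r_off
  expect_true(d[1] > 0 && d[2] < 0 && d[3] > 0)
  # leading-order shift is gain * S * [1-q, -q, 0]
  expect_equal(unname(pe$r_on - pe$r_off), 15 * 2 * c(0.8, -0.2, 0))
  # no stimulus: on = off
  pe0 <- partial_stim_expansion(cp, sz, gain = 15, S = 0)
  expect_equal(pe0$r_on, pe0$r_off)
})

test_that("expansion remainder stays bounded and global balance holds", {
  cp <- fig_coupling(); sz <- fig_sizes()
  mf3 <- build_meanfield(cp, sz, "expressing")
  mf2 <- build_meanfield(cp, sz, "global")
  gain <- 15; q <- sz$q
  bal2 <- balanced_rates(mf2$W, external_drive(mf2, 5))$r
  r_off <- c(bal2[1], bal2[1], bal2[2])
  s <- 1000 * mf3$epsilon * 2              # rescaled stimulus held fixed
  rem <- vapply(10^-(3:6), function(e) {
    rc <- corrected_rates(mf3$W, external_drive(mf3, 5, s = c(s, 0, 0)), e, gain)$r
    max(abs(rc - r_off - (gain / 1000) * (s / e) * c(1 - q, -q, 0)))
  }, numeric(1))
  # the O(s) + O(eps) remainder does not blow up as eps -> 0 at fixed s
  expect_lt(max(rem) / min(rem), 3)

  # algebraic identity: q-weighted average of exp/nexp corrected rates
  # equals the global two-population solution with stimulus weight q
  eps <- mf3$epsilon
  r3 <- corrected_rates(mf3$W, external_drive(mf3, 5, 2), eps, gain)$r
  r2 <- corrected_rates(mf2$W, external_drive(mf2, 5, 2), eps, gain)$r
  expect_equal(q * r3[1] + (1 - q) * r3[2], r2[1], tolerance = 1e-10)
  expect_equal(r3[3], r2[2], tolerance = 1e-10)
})

test_that("near-singular scale generalizes the singular analysis", {
  cp <- fig_coupling(); sz <- fig_sizes()
  mf3 <- build_meanfield(cp, sz, "expressing")
  eps <- mf3$epsilon
  # exactly singular: delta = epsilon
  ns <- near_singular_scale(mf3$W, eps)
  expect_equal(ns$delta, eps, tolerance = 1e-10)

  # shift by eta * I moves the small eigenvalue to eta, matching a direct
  # eigen-decomposition oracle
  for (eta in c(1e-3, 1e-2, 0.1)) {
    Wp <- mf3$W + eta * diag(3)
    nsp <- near_singular_scale(Wp, eps)
    ev <- eigen(Wp, only.values = TRUE)$values
    expect_equal(nsp$delta, min(Mod(ev)) + eps, tolerance = 1e-10)
    expect_equal(Mod(nsp$lambda), eta, tolerance = 1e-8)
  }
  # far from singular: no strong amplification
  big <- near_singular_scale(-diag(c(2, 3)), eps)
  expect_equal(big$amplification, 1 / (2 + eps))
})
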
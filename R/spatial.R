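#' Spatial kernel set for a continuously indexed network
#'
#' Describes the wrapped-Gaussian connectivity of the spatial network:
#' total kernel weights \code{wbar_ab = J_ab pbar_ab N_b / (J_EX pbar_EX
#' N_X)} (identical to the discrete mean-field ratios, since any common
#' scaling of J cancels), outgoing projection widths \code{alpha_b} on
#' the unit square and \code{alpha_btheta} on the orientation circle
#' [0, 1), and the balance parameter of the spatial network. The default
#' widths and sizes are those of the visual-cortex model: \code{alpha_E =
#' 0.15}, \code{alpha_I = alpha_X = 0.04}, orientation widths 0.1 (E, I)
#' and 0.125 (X), 2e5 recurrent and 1.6e5 external neurons, and synaptic
#' strengths scaled by 1.2 relative to the discrete-network table.
#'
#' @inheritParams in_degrees
#' @param alpha named spatial projection widths, populations E, I, X.
#' @param alpha_theta named orientation projection widths.
#' @param j_factor common multiplier on all connection strengths (enters
#'   the balance parameter only).
#' @return An object of class \code{"spatial_kernels"}.
#' @export
spatial_kernels <- function(coupling = coupling_table(),
                            sizes = population_sizes(N = 2e5, N_X = 1.6e5),
                            alpha = c(E = 0.15, I = 0.04, X = 0.04),
                            alpha_theta = c(E = 0.1, I = 0.1, X = 0.125),
                            j_factor = 1.2) {
  stopifnot(all(alpha > 0), all(alpha_theta > 0))
  eps <- compute_epsilon(coupling, sizes) / j_factor
  wbar <- in_degrees(coupling, sizes) * coupling$J * compute_epsilon(coupling, sizes)
  structure(list(wbar = wbar, alpha = alpha[c("E", "I", "X")],
                 alpha_theta = alpha_theta[c("E", "I", "X")],
                 epsilon = eps, pbar = coupling$p),
            class = "spatial_kernels")
}

#' Fourier coefficients of the connectivity kernels
#'
#' The wrapped-Gaussian kernels have Fourier coefficients
#' \deqn{\tilde w_{ab}(n, k) = \bar w_{ab}
#'   \exp[-2\pi^2(\|n\|^2 \alpha_b^2 + k^2 \alpha_{b,\theta}^2)]}
#' under the transform convention
#' \code{u~(n,k) = integral of u(x, theta) exp(-2 pi i (x.n + k theta))}.
#'
#' @param kernels a \code{\link{spatial_kernels}} object.
#' @param n1,n2 integer spatial mode indices (vectors, recycled).
#' @param k integer orientation mode indices.
#' @return List with per-mode coefficient vectors \code{EE}, \code{EI},
#'   \code{IE}, \code{II}, \code{EX}, \code{IX} and the per-population
#'   decay factors \code{decay} (a 3-column matrix).
#' @export
kernel_fourier <- function(kernels, n1, n2 = 0, k = 0) {
  N2 <- n1^2 + n2^2
  len <- max(length(N2), length(k))
  dec1 <- function(b)
    rep_len(unname(exp(-2 * pi^2 * (N2 * kernels$alpha[[b]]^2 +
                                    k^2 * kernels$alpha_theta[[b]]^2))), len)
  dE <- dec1("E"); dI <- dec1("I"); dX <- dec1("X")
  w <- kernels$wbar
  list(EE = w[["E", "E"]] * dE, EI = w[["E", "I"]] * dI,
       IE = w[["I", "E"]] * dE, II = w[["I", "I"]] * dI,
       EX = w[["E", "X"]] * dX, IX = w[["I", "X"]] * dX,
       decay = matrix(c(dE, dI, dX), ncol = 3,
                      dimnames = list(NULL, c("E", "I", "X"))))
}

#' Gaussian width calculus for balanced spatial profiles
#'
#' Synaptic divergence broadens a Gaussian rate profile of width
#' \code{sigma_a} into an input profile of width \code{beta_a} with
#' \code{beta_a^2 = sigma_a^2 + alpha_a^2}. Balance forces all input
#' profiles to share the external width \code{beta_X}, which pins the
#' recurrent rate-profile widths to
#' \code{sigma_E^2 = beta_X^2 - alpha_E^2} and
#' \code{sigma_I^2 = beta_X^2 - alpha_I^2}. These solutions exist only
#' when \code{alpha_E < beta_X} and \code{alpha_I < beta_X}: input
#' sharper than the recurrent kernels cannot be cancelled and balance is
#' infeasible, in which case the widths are returned as \code{NA} with
#' \code{feasible = FALSE}.
#'
#' @param sigma_X width of the external rate profile.
#' @param alpha_X,alpha_E,alpha_I projection widths.
#' @return An object of class \code{"width_model"}: list with
#'   \code{beta_X}, \code{sigma_E}, \code{sigma_I}, \code{feasible}.
#' @export
gaussian_widths <- function(sigma_X, alpha_X, alpha_E, alpha_I) {
  stopifnot(sigma_X > 0, alpha_X >= 0, alpha_E >= 0, alpha_I >= 0)
  beta_X <- sqrt(sigma_X^2 + alpha_X^2)
  feasible <- (alpha_E < beta_X) && (alpha_I < beta_X)
  structure(list(beta_X = beta_X,
                 sigma_E = if (alpha_E < beta_X) sqrt(beta_X^2 - alpha_E^2) else NA_real_,
                 sigma_I = if (alpha_I < beta_X) sqrt(beta_X^2 - alpha_I^2) else NA_real_,
                 feasible = feasible),
            class = "width_model")
}

## Signed FFT mode indices for an n-point grid.
fft_freq <- function(n) {
  i <- seq_len(n) - 1
  ifelse(i <= n %/% 2, i, i - n)
}

## 3-D arrays of squared spatial mode norm and orientation mode.
mode_arrays <- function(grid) {
  f1 <- fft_freq(grid[1]); f2 <- fft_freq(grid[2]); f3 <- fft_freq(grid[3])
  N2 <- outer(outer(f1^2, f2^2, "+"), rep(1, grid[3]))
  K <- outer(array(1, grid[1:2]), f3)
  list(N2 = N2, K2 = K^2, rho2 = N2 + K^2)
}

rate_field <- function(values, grid) {
  structure(values, grid = grid, class = "rate_field")
}

#' Stimulus specification for the external layer
#'
#' Describes the firing-rate field imposed on the external (input) layer
#' over position and orientation. Three variants:
#' \describe{
#'   \item{\code{"gaussian"}}{\code{r_X(x, theta) = rbar_X * [c + (1-c)
#'     G(x - x0; sigma_X)] * [c_theta + (1-c_theta) g(theta - theta0;
#'     sigma_X_theta)]} with wrapped Gaussians;}
#'   \item{\code{"disc"}}{the spatial factor is an indicator of radius
#'     \code{sigma_X} around \code{x0}, convolved with a Gaussian blur of
#'     width \code{blur} (slightly soft edges), floored at \code{c};}
#'   \item{\code{"contrast_map"}}{an arbitrary non-negative contrast
#'     matrix (matching the spatial grid), blurred, scaled to peak 1 and
#'     floored at \code{c}; the orientation factor is uniform.}
#' }
#' When \code{calibrate} is a two-vector \code{c(lo, hi)}, the floor
#' \code{c} and the scale \code{rbar_X} are solved so that the minimum
#' and maximum of the spatial factor over the grid equal \code{lo} and
#' \code{hi} Hz (default 10 and 20 Hz).
#'
#' @param variant one of \code{"gaussian"}, \code{"disc"},
#'   \code{"contrast_map"}.
#' @param sigma_X spatial stimulus width (Gaussian) or disc radius.
#' @param sigma_X_theta orientation stimulus width.
#' @param rbar_X overall rate scale, Hz (ignored when calibrating).
#' @param c,c_theta baseline floors in [0, 1].
#' @param x0 stimulus center on the unit square.
#' @param theta0 stimulus orientation center on [0, 1).
#' @param blur edge-blur width for the disc and contrast-map variants.
#' @param contrast contrast matrix for \code{"contrast_map"}.
#' @param calibrate \code{c(lo, hi)} spatial-factor bounds in Hz, or
#'   \code{NULL} to use \code{rbar_X} and \code{c} as given.
#' @return An object of class \code{"stimulus_spec"}.
#' @export
stimulus_spec <- function(variant = c("gaussian", "disc", "contrast_map"),
                          sigma_X = 0.2, sigma_X_theta = 0.1,
                          rbar_X = 1, c = 0.5, c_theta = 0.75,
                          x0 = c(0.5, 0.5), theta0 = 0.5, blur = 0.01,
                          contrast = NULL, calibrate = c(10, 20)) {
  variant <- match.arg(variant)
  if (variant == "contrast_map") {
    if (is.null(contrast)) stop("contrast_map variant requires a contrast matrix")
    if (any(contrast < 0)) stop("contrasts must be non-negative")
  }
  structure(list(variant = variant, sigma_X = sigma_X,
                 sigma_X_theta = sigma_X_theta, rbar_X = rbar_X, c = c,
                 c_theta = c_theta, x0 = x0, theta0 = theta0, blur = blur,
                 contrast = contrast, calibrate = calibrate),
            class = "stimulus_spec")
}

## Periodic Gaussian blur of a 2-D spatial pattern via the FFT.
blur_spatial <- function(mat, width) {
  if (width <= 0) return(mat)
  n <- dim(mat)
  N2 <- outer(fft_freq(n[1])^2, fft_freq(n[2])^2, "+")
  d <- exp(-2 * pi^2 * N2 * width^2)
  Re(stats::fft(stats::fft(mat) * d, inverse = TRUE)) / prod(n)
}

#' Build the external rate field from a stimulus specification
#'
#' Evaluates the stimulus on a regular periodic grid over the unit square
#' and the orientation circle (grid points \code{(i-1)/n}).
#'
#' @param spec a \code{\link{stimulus_spec}}.
#' @param grid integer vector \code{c(nx, ny, ntheta)}; use
#'   \code{ntheta = 1} for an orientation-averaged (untuned) stimulus.
#' @return A \code{"rate_field"} array of external rates in Hz.
#' @export
build_stimulus <- function(spec, grid = c(64, 64, 32)) {
  if (any(grid[1:2] < 4)) stop("need at least 4 grid points per spatial dimension")
  gx <- (seq_len(grid[1]) - 1) / grid[1]
  gy <- (seq_len(grid[2]) - 1) / grid[2]
  gt <- (seq_len(grid[3]) - 1) / grid[3]
  base <- switch(spec$variant,
    gaussian = outer(wrapped_gaussian(gx - spec$x0[1], spec$sigma_X),
                     wrapped_gaussian(gy - spec$x0[2], spec$sigma_X)),
    disc = {
      dx <- gx - spec$x0[1]; dx <- dx - round(dx)
      dy <- gy - spec$x0[2]; dy <- dy - round(dy)
      ind <- outer(dx^2, dy^2, "+") <= spec$sigma_X^2
      blur_spatial(ind * 1, spec$blur)
    },
    contrast_map = {
      if (!all(dim(spec$contrast) == grid[1:2]))
        stop("contrast matrix must match the spatial grid")
      m <- blur_spatial(spec$contrast, spec$blur)
      m / max(m)
    })
  if (!is.null(spec$calibrate)) {
    lo <- spec$calibrate[1]; hi <- spec$calibrate[2]
    A <- max(base); B <- min(base)
    rho <- hi / lo
    cc <- (A - rho * B) / (A - rho * B + rho - 1)
    if (is.na(cc) || cc < 0 || cc >= 1)
      stop("stimulus too flat to calibrate to the requested bounds")
    rbar <- hi / (cc + (1 - cc) * A)
    spat <- rbar * (cc + (1 - cc) * base)
  } else {
    spat <- spec$rbar_X * (spec$c + (1 - spec$c) * base)
  }
  ftheta <- if (grid[3] == 1 || spec$variant == "contrast_map") rep(1, grid[3])
            else spec$c_theta + (1 - spec$c_theta) *
                 wrapped_gaussian(gt - spec$theta0, spec$sigma_X_theta)
  vals <- outer(spat, ftheta)
  if (any(vals < 0)) stop("stimulus produced negative rates")
  rate_field(array(vals, grid), grid)
}

## Forward transform with 1/M normalization (integral convention).
field_fft <- function(field) {
  stats::fft(unclass(field)) / length(field)
}

field_ifft <- function(ft, grid, what = "field") {
  v <- stats::fft(ft, inverse = TRUE)
  resid <- max(abs(Im(v))) / max(abs(v), 1e-300)
  if (resid > 1e-8)
    warning(sprintf("%s has imaginary residue %.2e after inverse transform", what, resid))
  rate_field(array(Re(v), grid), grid)
}

spatial_solution <- function(rE, rI, IE, II, rX, method, kernels, epsilon, gain) {
  structure(list(rE = rE, rI = rI, IE = IE, II = II, rX = rX,
                 method = method, kernels = kernels, epsilon = epsilon,
                 gain = gain),
            class = "spatial_solution")
}

#' Linearly corrected rates of the spatial network
#'
#' Solves the finite-coupling rate equation mode by mode in the Fourier
#' domain: \code{rt(n, k) = solve(epsilon D - Wt(n, k), Xt(n, k))} with
#' \code{Xt = Wt_X * rt_X}, then inverts the transform. Also returns the
#' mean-input fields \code{I = (W r + X) / epsilon} (in mV/ms) by the
#' same mode-wise algebra. Finite for any input, including inputs
#' narrower than the recurrent kernels where the balanced solution does
#' not exist -- the regime of imbalanced amplification and surround
#' suppression.
#'
#' @param kernels a \code{\link{spatial_kernels}}.
#' @param rX external rate field from \code{\link{build_stimulus}}.
#' @param epsilon balance parameter (default: the kernel set's own).
#' @param gain rectified-linear gain, Hz per (mV/ms); scalar or
#'   \code{c(E, I)}.
#' @return A \code{"spatial_solution"} with rate fields \code{rE},
#'   \code{rI} (Hz) and input fields \code{IE}, \code{II} (mV/ms).
#' @export
spatial_corrected_rates <- function(kernels, rX, epsilon = kernels$epsilon, gain) {
  grid <- attr(rX, "grid")
  m <- mode_arrays(grid)
  a <- kernels$alpha; at <- kernels$alpha_theta; w <- kernels$wbar
  dec <- function(b) exp(-2 * pi^2 * (m$N2 * a[b]^2 + m$K2 * at[b]^2))
  dE <- dec("E"); dI <- dec("I"); dX <- dec("X")
  rtX <- field_fft(rX)
  XtE <- w["E", "X"] * dX * rtX
  XtI <- w["I", "X"] * dX * rtX
  g2 <- rep_len(gain, 2)
  if (any(g2 <= 0)) stop("gain must be positive")
  eE <- 1000 * epsilon / g2[1]; eI <- 1000 * epsilon / g2[2]
  m11 <- eE - w["E", "E"] * dE; m12 <- -w["E", "I"] * dI
  m21 <- -w["I", "E"] * dE;     m22 <- eI - w["I", "I"] * dI
  det <- m11 * m22 - m12 * m21
  if (min(abs(det)) < 1e-14 * max(abs(det)))
    stop("a Fourier mode of epsilon*D - Wt is singular (non-generic coincidence)")
  rtE <- (m22 * XtE - m12 * XtI) / det
  rtI <- (m11 * XtI - m21 * XtE) / det
  ItE <- (w["E", "E"] * dE * rtE + w["E", "I"] * dI * rtI + XtE) / (1000 * epsilon)
  ItI <- (w["I", "E"] * dE * rtE + w["I", "I"] * dI * rtI + XtI) / (1000 * epsilon)
  spatial_solution(field_ifft(rtE, grid, "rE"), field_ifft(rtI, grid, "rI"),
                   field_ifft(ItE, grid, "IE"), field_ifft(ItI, grid, "II"),
                   rX, "corrected", kernels, epsilon, gain)
}

#' Balanced-limit rates of the spatial network
#'
#' Solves the spatial balance condition mode by mode,
#' \code{rt = -solve(Wt, Xt)}. Because the kernel matrix factors as
#' \code{Wt(n,k) = Wbar \%*\% diag(decay_E, decay_I)}, the solution is
#' evaluated stably as \code{rt_a = u_a * exp(E_X - E_a) * rt_X} with
#' \code{u = -solve(Wbar, Wbar_X)} and log-domain exponents. Modes where
#' the input has no resolvable power (relative amplitude below
#' \code{mode_tol}) are dropped before amplification: the balanced
#' inverse grows exponentially with frequency, so amplifying the numeric
#' noise floor would be meaningless. The solution is refused (error of
#' class \code{"imbalnet_infeasible"}) when the retained mode amplitudes
#' fail to decay -- operationally, when the energy of \code{rt} over the
#' top octave of retained mode radii is not smaller than over the
#' previous octave -- which happens exactly when the input is sharper
#' than the recurrent kernels (\code{beta_X < alpha_E} or
#' \code{beta_X < alpha_I}).
#'
#' @inheritParams spatial_corrected_rates
#' @param mode_tol relative input-amplitude floor below which a mode is
#'   treated as unresolvable and dropped.
#' @return A \code{"spatial_solution"} (input fields are \code{NULL}: in
#'   the balanced limit the residual input vanishes by construction).
#' @export
spatial_balanced_rates <- function(kernels, rX, mode_tol = 1e-13) {
  grid <- attr(rX, "grid")
  m <- mode_arrays(grid)
  a <- kernels$alpha; at <- kernels$alpha_theta
  Wbar <- kernels$wbar[, c("E", "I")]
  u <- -solve(Wbar, kernels$wbar[, "X"])
  rtX <- field_fft(rX)
  keep <- Mod(rtX) >= mode_tol * max(Mod(rtX))
  rt <- list()
  for (pop in c("E", "I")) {
    expo <- -2 * pi^2 * (m$N2 * (a["X"]^2 - a[pop]^2) +
                         m$K2 * (at["X"]^2 - at[pop]^2))
    v <- u[pop] * exp(pmin(expo, 700)) * rtX
    v[!keep] <- 0
    rt[[pop]] <- v
  }
  rho <- sqrt(m$rho2)
  rmax <- max(rho[keep])
  if (rmax >= 4) {
    amp2 <- Mod(rt$E)^2 + Mod(rt$I)^2
    top <- sum(amp2[keep & rho > rmax / 2])
    prev <- sum(amp2[keep & rho > rmax / 4 & rho <= rmax / 2])
    if (!is.finite(top) || top >= prev) {
      cond <- simpleError(paste0(
        "balance cannot be realized: the external input is sharper than the ",
        "recurrent connectivity, so the balanced mode series does not decay"))
      class(cond) <- c("imbalnet_infeasible", class(cond))
      stop(cond)
    }
  }
  spatial_solution(field_ifft(rt$E, grid, "rE"), field_ifft(rt$I, grid, "rI"),
                   NULL, NULL, rX, "balanced", kernels, kernels$epsilon, NA)
}

#' Size-tuning scan of center firing rates
#'
#' Computes the corrected-rate solution for a sequence of stimulus widths
#' and records the excitatory and inhibitory rates at the stimulus
#' center, reproducing size-tuning curves: non-monotonic (rise then fall)
#' for a population whose lateral projections are broader than the
#' feedforward ones, monotonic otherwise, and oscillatory for sharp-edged
#' disc stimuli with narrow lateral excitation.
#'
#' @inheritParams spatial_corrected_rates
#' @param sigma_X_values stimulus widths (Gaussian width or disc radius).
#' @param template \code{"gaussian"} or \code{"disc"}.
#' @param grid spatial grid; the default drops the orientation dimension
#'   (untuned stimulus, modes k = 0 only).
#' @param calibrate per-stimulus calibration bounds in Hz.
#' @param blur disc edge blur.
#' @return List with \code{curve} (data frame sigma_X, rE, rI) and the
#'   indices of interior local maxima \code{maxima_E}, \code{maxima_I}.
#' @export
size_tuning_scan <- function(kernels, sigma_X_values, epsilon = kernels$epsilon,
                             gain, template = c("gaussian", "disc"),
                             grid = c(64, 64, 1), calibrate = c(10, 20),
                             blur = 0.01) {
  template <- match.arg(template)
  ctr <- c(grid[1] / 2 + 1, grid[2] / 2 + 1, 1)
  res <- vapply(sigma_X_values, function(sx) {
    sp <- stimulus_spec(variant = template, sigma_X = sx, blur = blur,
                        calibrate = calibrate)
    sol <- spatial_corrected_rates(kernels, build_stimulus(sp, grid),
                                   epsilon, gain)
    c(sol$rE[ctr[1], ctr[2], ctr[3]], sol$rI[ctr[1], ctr[2], ctr[3]])
  }, numeric(2))
  curve <- data.frame(sigma_X = sigma_X_values, rE = res[1, ], rI = res[2, ])
  list(curve = curve,
       maxima_E = interior_maxima(curve$rE),
       maxima_I = interior_maxima(curve$rI))
}

interior_maxima <- function(y) which(diff(sign(diff(y))) == -2) + 1

#' Edge sharpness of a field
#'
#' Maximum finite-difference slope magnitude along the horizontal center
#' line of a field (orientation-averaged for 3-D fields), in units of
#' field value per unit length. Used to compare the edge sharpness of a
#' network's output rate profile with that of its blurred feedforward
#' input.
#'
#' @param field a \code{"rate_field"} or numeric vector/matrix.
#' @return Maximum absolute slope (scalar).
#' @export
sharpness_index <- function(field) {
  if (is.array(field) && length(dim(field)) == 3)
    field <- apply(unclass(field), c(1, 2), mean)
  if (is.matrix(field)) field <- field[, ncol(field) %/% 2 + 1]
  n <- length(field)
  if (n < 2) return(0)
  max(abs(diff(c(field, field[1])))) * n
}

#' @export
print.spatial_solution <- function(x, ...) {
  g <- attr(x$rE, "grid")
  cat(sprintf("Spatial rate solution (%s) on a %d x %d x %d grid\n",
              x$method, g[1], g[2], g[3]))
  cat(sprintf("mean rates: E %.3f Hz, I %.3f Hz\n", mean(x$rE), mean(x$rI)))
  invisible(x)
}

#' @export
print.width_model <- function(x, ...) {
  if (x$feasible)
    cat(sprintf("Balanced widths: beta_X = %.4f, sigma_E = %.4f, sigma_I = %.4f\n",
                x$beta_X, x$sigma_E, x$sigma_I))
  else
    cat(sprintf("Balance infeasible: beta_X = %.4f is narrower than a recurrent kernel\n",
                x$beta_X))
  invisible(x)
}
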
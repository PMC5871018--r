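#' Population firing-rate summary from a spike raster
#'
#' Epoch-mean rates (spike count / neuron count / epoch length) and
#' time-resolved rates through a centered sliding window for each
#' population mask.
#'
#' @param raster a \code{"spike_raster"}.
#' @param masks named list of neuron index vectors.
#' @param epochs matrix with rows (start, end) in ms.
#' @param window sliding-window width, ms.
#' @param step grid spacing for the time-resolved curve, ms.
#' @return List with \code{mean} (populations x epochs matrix, Hz) and
#'   \code{timecourse} (data frame: time plus one rate column per
#'   population).
#' @export
estimate_rates <- function(raster, masks, epochs, window = 100,
                           step = window / 5) {
  if (is.null(dim(epochs))) epochs <- matrix(epochs, ncol = 2)
  if (any(lengths(masks) == 0)) stop("empty population mask")
  duration <- attr(raster, "duration")
  if (any(epochs < 0) || any(epochs > duration))
    stop("epochs must lie within [0, duration]")
  mean_rate <- matrix(0, length(masks), nrow(epochs),
                      dimnames = list(names(masks), NULL))
  grid <- seq(window / 2, duration - window / 2, by = step)
  tc <- data.frame(time = grid)
  for (p in seq_along(masks)) {
    tm <- sort(raster$time[raster$id %in% masks[[p]]])
    n <- length(masks[[p]])
    for (e in seq_len(nrow(epochs))) {
      cnt <- sum(tm >= epochs[e, 1] & tm < epochs[e, 2])
      mean_rate[p, e] <- cnt / n / ((epochs[e, 2] - epochs[e, 1]) / 1000)
    }
    cnt <- findInterval(grid + window / 2, tm) - findInterval(grid - window / 2, tm)
    tc[[names(masks)[p]]] <- cnt / n / (window / 1000)
  }
  list(mean = mean_rate, timecourse = tc)
}

#' Epoch-averaged synaptic currents by population
#'
#' Averages the per-neuron external (X), recurrent (R) and total (I = X
#' + R) currents accumulated during simulation over each population mask
#' and epoch. Values are returned in mV/ms and, divided by the display
#' constant \code{rheobase}, in rheobase units.
#'
#' @param sim a \code{"sim_result"}.
#' @param masks named list of neuron index vectors.
#' @param rheobase display divisor, mV/ms.
#' @return List of populations-x-epochs matrices \code{X}, \code{R},
#'   \code{I} (mV/ms) and their \code{*_rheo} counterparts.
#' @export
mean_currents <- function(sim, masks, rheobase = 10.5) {
  steps <- sim$sums$steps
  out <- list()
  for (comp in c("X", "R")) {
    m <- vapply(masks, function(idx)
      colSums(sim$sums[[comp]][idx, , drop = FALSE]) /
        (length(idx) * steps), numeric(length(steps)))
    m <- t(matrix(m, nrow = length(steps),
                  dimnames = list(NULL, names(masks))))
    out[[comp]] <- m
  }
  out$I <- out$X + out$R
  for (comp in c("X", "R", "I")) out[[paste0(comp, "_rheo")]] <- out[[comp]] / rheobase
  out
}

#' Per-neuron rate/current points for the gain fit
#'
#' One point per neuron per epoch: its epoch-mean total input current
#' (mV/ms) and epoch-mean firing rate (Hz), the scatter to which the
#' rectified-linear f-I curve is fitted.
#'
#' @param sim a \code{"sim_result"}.
#' @param neurons neuron indices to include (default: all).
#' @return Data frame with columns \code{I} and \code{rate}.
#' @export
gain_points <- function(sim, neurons = seq_len(sim$NE + sim$NI)) {
  steps <- sim$sums$steps
  dt <- sim$config$dt
  I <- sweep(sim$sums$X[neurons, , drop = FALSE] +
             sim$sums$R[neurons, , drop = FALSE], 2, steps, "/")
  rate <- sweep(sim$sums$nspike[neurons, , drop = FALSE], 2,
                steps * dt / 1000, "/")
  data.frame(I = as.numeric(I), rate = as.numeric(rate))
}

#' Rectified-linear gain fit
#'
#' Least-squares fit of \code{rate = g * pmax(I - I0, 0)} to a scatter of
#' mean input currents and firing rates, by a one-dimensional search over
#' the threshold \code{I0} with the slope profiled out in closed form.
#'
#' @param I mean input currents, mV/ms.
#' @param rate firing rates, Hz.
#' @return An object of class \code{"gain_fit"}: \code{g} (Hz per
#'   mV/ms), \code{I0}, \code{residual} (root-mean-square), \code{n}.
#' @export
fit_gain <- function(I, rate) {
  ok <- is.finite(I) & is.finite(rate)
  I <- I[ok]; rate <- rate[ok]
  if (length(I) < 2 || diff(range(I)) < 1e-12)
    stop("gain unidentifiable: input currents do not span a range")
  if (all(rate == 0)) stop("gain unidentifiable: all rates are zero")
  sse <- function(I0) {
    a <- pmax(I - I0, 0)
    s2 <- sum(a^2)
    g <- if (s2 > 0) sum(rate * a) / s2 else 0
    sum((rate - g * a)^2)
  }
  opt <- stats::optimize(sse, range(I), tol = 1e-10)
  I0 <- opt$minimum
  a <- pmax(I - I0, 0)
  g <- sum(rate * a) / sum(a^2)
  if (!is.finite(g) || g <= 0)
    stop("gain fit degenerate: no increasing rate-current relationship")
  structure(list(g = g, I0 = I0,
                 residual = sqrt(opt$objective / length(I)), n = length(I)),
            class = "gain_fit")
}

#' Fit a wrapped-Gaussian profile width
#'
#' Least-squares fit of \code{baseline + amplitude * g(x - center;
#' sigma)} (wrapped Gaussian) to a one-dimensional periodic profile,
#' e.g. an axis marginal of a rate field. For a \code{"rate_field"}, the
#' marginal along the requested axis (mean over the other dimensions) is
#' fitted.
#'
#' @param profile numeric profile on an even grid over [0, 1), or a
#'   \code{"rate_field"}.
#' @param axis for fields: \code{"x"}, \code{"y"} or \code{"theta"}.
#' @return An object of class \code{"profile_fit"}: \code{sigma},
#'   \code{center}, \code{baseline}, \code{amplitude}, \code{rss}.
#' @export
fit_profile_width <- function(profile, axis = c("x", "y", "theta")) {
  axis <- match.arg(axis)
  if (is.array(profile) && length(dim(profile)) == 3) {
    d <- match(axis, c("x", "y", "theta"))
    profile <- apply(unclass(profile), d, mean)
  }
  y <- as.numeric(profile)
  n <- length(y)
  x <- (seq_len(n) - 1) / n
  span <- max(y) - min(y)
  if (span < 1e-10 * max(abs(y), 1))
    stop("profile is flat: no dominant peak to fit")
  x0 <- x[which.max(y)]
  above <- sum(y > min(y) + span / 2)
  s0 <- max(above / n / 2.355, 1 / n)
  obj <- function(p) {
    g <- wrapped_gaussian(x - p[3], exp(p[4]))
    sum((y - p[1] - p[2] * g)^2)
  }
  fit <- stats::optim(c(min(y), span / wrapped_gaussian(0, s0), x0, log(s0)),
                      obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$convergence != 0)
    stop("profile width fit did not converge (code ", fit$convergence, ")")
  structure(list(sigma = exp(fit$par[4]), center = fit$par[3] %% 1,
                 baseline = fit$par[1], amplitude = fit$par[2],
                 rss = fit$value),
            class = "profile_fit")
}

#' @export
print.gain_fit <- function(x, ...) {
  cat(sprintf("Rectified-linear gain fit: g = %.3f Hz/(mV/ms), threshold I0 = %.4f mV/ms (rms %.3f, n = %d)\n",
              x$g, x$I0, x$residual, x$n))
  invisible(x)
}
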
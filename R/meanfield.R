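#' Mean-field connectivity matrices
#'
#' Builds the dimensionless recurrent matrix \code{W} with entries
#' \code{w_ab = K_ab J_ab / (K_EX J_EX)} and the feedforward column
#' \code{W_X}, for one of three population partitions:
#' \describe{
#'   \item{\code{"EI"}}{the two-population (E, I) partition;}
#'   \item{\code{"expressing"}}{the three-population partition
#'     (expressing, non-expressing, I) in which the excitatory population
#'     is split by the stimulated fraction \code{q}: rows for the two
#'     excitatory subpopulations are identical (local connectivity is
#'     blind to expression) and the E columns carry factors \code{q} and
#'     \code{1 - q}. This matrix is exactly singular, with a
#'     one-dimensional nullspace for any \code{q} in (0, 1);}
#'   \item{\code{"global"}}{the (E, I) partition used to describe partial
#'     stimulation globally: identical to \code{"EI"} except that the
#'     stimulus current is weighted by \code{q} in
#'     \code{\link{external_drive}}.}
#' }
#'
#' @inheritParams in_degrees
#' @param partition one of \code{"EI"}, \code{"expressing"},
#'   \code{"global"}.
#' @return An object of class \code{"meanfield"} with elements \code{W},
#'   \code{W_X}, \code{epsilon}, \code{partition}, \code{labels},
#'   \code{stim_weight} (per-population weighting of the stimulus
#'   current) and \code{q}.
#' @export
build_meanfield <- function(coupling, sizes, partition = c("EI", "expressing", "global")) {
  partition <- match.arg(partition)
  K <- in_degrees(coupling, sizes)
  KJ <- K * coupling$J
  eps <- compute_epsilon(coupling, sizes)
  w <- KJ * eps                      # w_ab = K_ab J_ab / (K_EX J_EX)
  q <- sizes$q
  if (partition == "EI" || partition == "global") {
    W <- w[, c("E", "I")]
    W_X <- w[, "X"]
    labels <- c("E", "I")
    sw <- if (partition == "global") c(q, 0) else c(1, 0)
  } else {
    if (!(q > 0 && q < 1)) stop("'expressing' partition requires q in (0, 1)")
    W <- rbind(c(q * w["E", "E"], (1 - q) * w["E", "E"], w["E", "I"]),
               c(q * w["E", "E"], (1 - q) * w["E", "E"], w["E", "I"]),
               c(q * w["I", "E"], (1 - q) * w["I", "E"], w["I", "I"]))
    W_X <- c(w["E", "X"], w["E", "X"], w["I", "X"])
    labels <- c("exp", "nexp", "I")
    sw <- c(1, 0, 0)
  }
  dimnames(W) <- list(labels, labels)
  names(W_X) <- labels
  structure(list(W = W, W_X = W_X, epsilon = eps, partition = partition,
                 labels = labels, stim_weight = sw, q = q),
            class = "meanfield")
}

#' Rescaled external drive
#'
#' Assembles the drive vector \code{X = W_X * r_X + s} entering the
#' mean-field equations, in the same (Hz) units as the rates. The
#' stimulus is given either as a raw injected current \code{S} in mV/ms,
#' rescaled internally to \code{s = 1000 * epsilon * S} and placed
#' according to the partition's stimulus weighting (the factor 1000
#' converts mV/ms to the mV/s current unit implied by rates in Hz), or as
#' an explicit pre-scaled per-population vector \code{s}.
#'
#' @param mf a \code{\link{build_meanfield}} object.
#' @param r_X external population rate, Hz.
#' @param S injected stimulus current, mV/ms (scalar; ignored when
#'   \code{s} is given).
#' @param s optional explicit rescaled stimulus vector (Hz units), one
#'   entry per population.
#' @return Numeric drive vector, one entry per population.
#' @export
external_drive <- function(mf, r_X, S = 0, s = NULL) {
  if (r_X < 0) stop("external rate r_X must be non-negative")
  if (is.null(s)) s <- mf$stim_weight * 1000 * mf$epsilon * S
  if (length(s) != length(mf$W_X))
    stop("stimulus vector length does not match the partition")
  drv <- mf$W_X * r_X + s
  names(drv) <- mf$labels
  drv
}

## D = diag(1/g) in mean-field current units (mV/s); user-facing gains are
## Hz per (mV/ms), hence the factor 1000.
gain_matrix <- function(gain, n) {
  if (any(gain <= 0)) stop("gain must be positive")
  diag(1000 / rep_len(gain, n), n)
}

rate_solution <- function(r, I, W, X, method) {
  structure(list(r = as.numeric(r), I = I,
                 residual = sqrt(sum((W %*% r + X)^2)),
                 positive = all(r >= 0), method = method,
                 labels = rownames(W)),
            class = "rate_solution")
}

#' Balanced-limit firing rates
#'
#' Solves the balance condition \code{W r + X = 0} for the population
#' rates, \code{r = -solve(W, X)}, valid in the strong-coupling limit
#' \code{epsilon -> 0}. When \code{W} is singular (or numerically close
#' to it) no finite-rate balanced state exists -- the mean input could
#' not remain finite -- and an error of class
#' \code{"imbalnet_singular"} is thrown naming the obstruction. Negative
#' solution entries are reported, not clipped: the balanced solution is
#' only meaningful when strictly positive, and \code{$positive} flags
#' this.
#'
#' @param W square mean-field matrix.
#' @param X drive vector from \code{\link{external_drive}}.
#' @param tol relative singularity threshold on the smallest singular
#'   value.
#' @return A \code{"rate_solution"} with rates \code{r} (Hz), the balance
#'   residual and a positivity flag. The mean-input field \code{I} is
#'   \code{NULL}: in the balanced limit the residual input is zero by
#'   construction.
#' @export
balanced_rates <- function(W, X, tol = 1e-8) {
  stopifnot(nrow(W) == ncol(W), length(X) == nrow(W))
  sv <- svd(W, nu = 0, nv = 0)$d
  if (min(sv) < tol * max(sv)) {
    cond <- simpleError(paste0(
      "W is singular: balance cannot be realized because no rate vector ",
      "cancels the external drive, so the mean input cannot remain finite ",
      "in the strong-coupling limit"))
    class(cond) <- c("imbalnet_singular", class(cond))
    stop(cond)
  }
  r <- solve(W, -X)
  if (any(r < 0))
    warning("balanced solution has negative entries; the balanced state requires strictly positive rates")
  rate_solution(r, NULL, W, X, "balanced")
}

#' Linearly corrected firing rates at finite coupling
#'
#' Solves \code{r = solve(epsilon D - W, X)} with \code{D = diag(1/g)},
#' the rate solution of the rectified-linear rate model at finite
#' \code{epsilon}. Unlike the balanced solution this is finite even when
#' \code{W} is singular, which is exactly the regime of imbalanced
#' amplification.
#'
#' @inheritParams balanced_rates
#' @param epsilon balance parameter, from \code{\link{compute_epsilon}}.
#' @param gain population gain(s) of the rectified-linear f-I curve, Hz
#'   per (mV/ms); scalar or one per population.
#' @return A \code{"rate_solution"}; \code{$I} holds the mean input per
#'   population in mV/ms, \code{I = (W r + X)/(1000 epsilon)}.
#' @export
corrected_rates <- function(W, X, epsilon, gain) {
  stopifnot(nrow(W) == ncol(W), length(X) == nrow(W), epsilon > 0)
  A <- epsilon * gain_matrix(gain, nrow(W)) - W
  if (rcond(A) < 1e-14)
    stop("epsilon*D - W is numerically singular (non-generic parameter coincidence)")
  r <- solve(A, X)
  I <- as.numeric(W %*% r + X) / (1000 * epsilon)
  names(I) <- rownames(W)
  rate_solution(r, I, W, X, "corrected")
}

## Sign convention: first nonzero entry positive (reproducible outputs).
fix_sign <- function(v) {
  nz <- which(abs(v) > 1e-12)
  if (length(nz) && v[nz[1]] < 0) -v else v
}

#' Nullspace decomposition of the external drive
#'
#' Computes the quantities behind imbalanced amplification: unit vectors
#' \code{v0} spanning the nullspace of \code{W} and \code{v2} spanning
#' the nullspace of \code{t(W)} (from the singular triplet(s) of smallest
#' singular value), the smallest-magnitude eigenvalue \code{lambda} of
#' \code{W}, and the split \code{X = X0 + X1} of the drive into its
#' component \code{X0} along the nullspace of \code{t(W)} -- which the
#' recurrent connectivity cannot cancel, so the mean input grows as
#' \code{X0/epsilon} -- and its cancellable column-space component
#' \code{X1}.
#'
#' If the nullspace has dimension above one, orthonormal bases are
#' returned as matrix columns and the scalar amplification formula
#' (\code{\link{amplified_component}}) is not applicable.
#'
#' @inheritParams balanced_rates
#' @return An object of class \code{"nullspace_decomposition"} with
#'   elements \code{v0}, \code{v2}, \code{lambda}, \code{X0}, \code{X1},
#'   \code{dim} (nullspace dimension) and the singular values \code{sv}.
#' @export
nullspace_decompose <- function(W, X, tol = 1e-8) {
  stopifnot(nrow(W) == ncol(W), length(X) == nrow(W))
  X <- unname(as.numeric(X))
  s <- svd(W)
  ns <- which(s$d < tol * max(s$d))
  dim_null <- length(ns)
  ev <- eigen(W, only.values = TRUE)$values
  lambda <- ev[which.min(Mod(ev))]
  if (abs(Im(lambda)) < 1e-12) lambda <- Re(lambda)
  if (dim_null == 0) {
    v0 <- v2 <- NULL
    X0 <- rep(0, length(X)); X1 <- X
  } else if (dim_null == 1) {
    v0 <- fix_sign(s$v[, ns]); v2 <- fix_sign(s$u[, ns])
    X0 <- drop(crossprod(v2, X)) * v2
    X1 <- X - X0
  } else {
    v0 <- s$v[, ns, drop = FALSE]; v2 <- s$u[, ns, drop = FALSE]
    X0 <- drop(v2 %*% crossprod(v2, X))
    X1 <- X - X0
  }
  structure(list(v0 = v0, v2 = v2, lambda = lambda, X0 = X0, X1 = X1,
                 dim = dim_null, sv = s$d),
            class = "nullspace_decomposition")
}

#' Amplified rate component for a one-dimensional nullspace
#'
#' The leading, order-\code{1/epsilon} component of the corrected rates
#' when \code{W} has a one-dimensional nullspace:
#' \deqn{r_0 = \frac{v_2 \cdot X}{v_2 \cdot D v_0} v_0,}
#' which satisfies \code{W r0 = 0}. The full rates expand as
#' \code{r = r0/epsilon + r1} with \code{r1} of order one.
#'
#' @inheritParams corrected_rates
#' @return Numeric vector \code{r0} (units Hz * epsilon).
#' @export
amplified_component <- function(W, X, gain) {
  nd <- nullspace_decompose(W, X)
  if (nd$dim == 0) return(rep(0, length(X)))
  if (nd$dim > 1)
    stop("nullspace of W is multi-dimensional; the scalar amplification formula does not apply")
  D <- gain_matrix(gain, nrow(W))
  denom <- drop(crossprod(nd$v2, D %*% nd$v0))
  if (abs(denom) < 1e-14)
    stop("degenerate geometry: v2 . D v0 = 0, amplified component undefined")
  drop(crossprod(nd$v2, X)) / denom * nd$v0
}

#' Rate expansion under partial stimulation
#'
#' For the three-population (expressing, non-expressing, inhibitory)
#' system with stimulated fraction \code{q}, returns the pre-stimulation
#' balanced rates \code{r_off} (the two-population balanced solution
#' replicated across the expressing split, which exists because the
#' unstimulated drive lies in the column space of the singular
#' three-population \code{W}), the leading-order prediction during
#' stimulation
#' \deqn{r_{on} \approx r_{off} + \frac{g s}{\epsilon}[1-q, -q, 0],}
#' and, for comparison, the exact corrected-rate solution. In these units
#' \code{g s / epsilon = gain * S}, so the leading stimulated shift is
#' \code{gain * S * c(1-q, -q, 0)}. The omitted remainder is an O(s) term
#' with population pattern \code{[q, q, q c]}, \code{c = |w_IE/w_II|},
#' plus O(epsilon): only its sign pattern and \code{c} are determined.
#'
#' Entries of the leading-order prediction that fall below zero are
#' flagged: there the linear expansion has left its domain of validity
#' (non-expressing neurons cease firing and amplification saturates).
#'
#' @inheritParams in_degrees
#' @param q stimulated fraction (overrides \code{sizes$q} if given).
#' @param gain rectified-linear gain, Hz per (mV/ms).
#' @param S stimulus current, mV/ms.
#' @param r_X external rate, Hz.
#' @return List with \code{r_off}, \code{r_on} (leading order),
#'   \code{r_exact} (corrected solve), \code{c}, \code{epsilon} and
#'   \code{valid} (TRUE when the leading-order rates are all
#'   non-negative).
#' @export
partial_stim_expansion <- function(coupling, sizes, q = sizes$q, gain, S, r_X = 5) {
  stopifnot(q > 0, q < 1)
  sizes$q <- q
  mf2 <- build_meanfield(coupling, sizes, "EI")
  mf3 <- build_meanfield(coupling, sizes, "expressing")
  eps <- mf2$epsilon
  bal2 <- balanced_rates(mf2$W, external_drive(mf2, r_X))
  r_off <- c(bal2$r[1], bal2$r[1], bal2$r[2])
  names(r_off) <- mf3$labels
  shift <- gain * S * c(1 - q, -q, 0)
  r_on <- r_off + shift
  r_exact <- corrected_rates(mf3$W, external_drive(mf3, r_X, S), eps, gain)
  cc <- abs(mf2$W["I", "E"] / mf2$W["I", "I"])
  list(r_off = r_off, r_on = r_on, r_exact = r_exact, c = cc,
       epsilon = eps, valid = all(r_on >= 0))
}

#' Near-singular amplification scale
#'
#' For a matrix that is only approximately singular, the amplification
#' analysis survives with the eigenvalue of smallest magnitude,
#' \code{lambda}, replacing exact singularity: the rates along the
#' associated left eigenvector \code{v} scale as \code{1/delta} with
#' \code{delta = |lambda| + epsilon}. Exactly singular \code{W} recovers
#' \code{delta = epsilon}; when \code{|lambda|} is much larger than
#' \code{epsilon} the factor \code{1/delta} is order one and no strong
#' amplification occurs.
#'
#' @inheritParams corrected_rates
#' @return List with \code{lambda}, \code{delta}, the unit left
#'   eigenvector \code{v}, and \code{amplification = 1/delta}.
#' @export
near_singular_scale <- function(W, epsilon) {
  stopifnot(nrow(W) == ncol(W), epsilon >= 0)
  e <- eigen(t(W))
  i <- which.min(Mod(e$values))
  lambda <- e$values[i]
  v <- e$vectors[, i]
  if (max(abs(Im(v))) < 1e-10) { v <- Re(v); v <- fix_sign(v) }
  if (abs(Im(lambda)) < 1e-12) lambda <- Re(lambda)
  v <- v / sqrt(sum(Mod(v)^2))
  delta <- Mod(lambda) + epsilon
  list(lambda = lambda, delta = delta, v = v, amplification = 1 / delta)
}

#' @export
print.rate_solution <- function(x, ...) {
  cat(sprintf("Rate solution (%s)\n", x$method))
  r <- x$r; names(r) <- x$labels
  print(round(r, 4))
  cat(sprintf("balance residual %.3e%s\n", x$residual,
              if (x$positive) "" else "  [negative entries: outside model validity]"))
  invisible(x)
}

#' @export
print.meanfield <- function(x, ...) {
  cat(sprintf("Mean-field matrices, partition '%s' (epsilon = %.4g)\nW:\n",
              x$partition, x$epsilon))
  print(round(x$W, 4))
  cat("W_X:\n"); print(round(x$W_X, 4))
  invisible(x)
}
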
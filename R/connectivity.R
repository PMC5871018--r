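#' Wrapped Gaussian density on the unit circle
#'
#' \deqn{g(u; \alpha) = \sum_j \frac{1}{\sqrt{2\pi\alpha^2}}
#'   e^{-(u+j)^2/(2\alpha^2)},}
#' the Gaussian density summed over integer shifts so that it is periodic
#' with period 1 and integrates to one over any unit interval. The sum is
#' truncated once the next term falls below 1e-12 of the running total.
#'
#' @param u displacement(s) on the unit circle.
#' @param alpha width parameter (> 0).
#' @return Density values, same length as \code{u}.
#' @export
wrapped_gaussian <- function(u, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  u <- u - round(u)                  # principal displacement in [-1/2, 1/2]
  norm <- 1 / sqrt(2 * pi * alpha^2)
  tot <- norm * exp(-u^2 / (2 * alpha^2))
  j <- 1
  repeat {
    term <- norm * (exp(-(u + j)^2 / (2 * alpha^2)) +
                    exp(-(u - j)^2 / (2 * alpha^2)))
    tot <- tot + term
    if (max(term) < 1e-12 * min(tot)) break
    j <- j + 1
    if (j > 1e4) break               # unreachable for sane alpha
  }
  tot
}

#' Regular grid layout with random orientation preferences
#'
#' Places \code{count} neurons at the cell centers of the most-square
#' regular grid covering the unit square (offset by half a spacing so
#' that periodic distances are symmetric) and assigns each a preferred
#' orientation drawn uniformly from [0, 1) (fractions of 180 degrees).
#'
#' @param count number of neurons.
#' @param seed optional RNG seed for the orientation draw.
#' @return An object of class \code{"spatial_layout"} with fields
#'   \code{x}, \code{y}, \code{theta}, \code{nx}, \code{ny}.
#' @export
grid_layout <- function(count, seed = NULL) {
  stopifnot(count > 0)
  if (!is.null(seed)) set.seed(seed)
  nx <- floor(sqrt(count))
  while (count %% nx != 0) nx <- nx - 1
  ny <- count / nx
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  structure(list(x = (ix - 0.5) / nx, y = (iy - 0.5) / ny,
                 theta = stats::runif(count), nx = nx, ny = ny,
                 count = count),
            class = "spatial_layout")
}

## Aggregate repeated draws into integer multiplicities.
#' @importFrom data.table data.table setorderv .N
aggregate_edges <- function(pre, post, J) {
  dt <- data.table::data.table(pre = pre, post = post)
  dt <- dt[, .N, by = c("pre", "post")]
  data.table::setorderv(dt, c("pre", "post"))
  data.frame(pre = dt$pre, post = dt$post, weight = dt$N * J)
}

#' Sample a random synaptic graph with fixed out-degree
#'
#' For each presynaptic neuron in population b and each postsynaptic
#' population a, draws exactly \code{round(p_ab * N_a)} targets from a,
#' uniformly and with replacement; repeated draws accumulate so that the
#' realized weight is \code{(number of contacts) * J_ab}. Sampling order
#' over pair blocks is fixed, so identical seeds give identical graphs.
#' Self-connections are permitted.
#'
#' @inheritParams in_degrees
#' @param seed optional RNG seed.
#' @return An object of class \code{"synaptic_graph"}: a list of pair
#'   blocks named \code{"E->E"}, \code{"E->I"}, ... (presynaptic ->
#'   postsynaptic), each a data frame (pre, post, weight), with the
#'   coupling, sizes and seed attached.
#' @export
sample_graph <- function(coupling, sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Na <- c(E = sizes$N_E, I = sizes$N_I)
  Nb <- c(E = sizes$N_E, I = sizes$N_I, X = sizes$N_X)
  blocks <- list()
  for (b in c("E", "I", "X")) for (a in c("E", "I")) {
    m <- round(coupling$p[a, b] * Na[a])
    if (m < 0) stop("negative out-degree requested")
    key <- paste0(b, "->", a)
    if (m == 0 || Nb[b] == 0) {
      blocks[[key]] <- data.frame(pre = integer(0), post = integer(0),
                                  weight = numeric(0))
      next
    }
    pre <- rep(seq_len(Nb[b]), each = m)
    post <- sample.int(Na[a], m * Nb[b], replace = TRUE)
    blocks[[key]] <- aggregate_edges(pre, post, coupling$J[a, b])
  }
  structure(list(blocks = blocks, coupling = coupling, sizes = sizes,
                 seed = seed, out_degree = round(sweep(
                   coupling$p, 1, Na, "*"))),
            class = "synaptic_graph")
}

#' Sample one pair block of a distance- and tuning-dependent graph
#'
#' Each presynaptic neuron draws \code{round(pbar * N_post)} targets with
#' replacement, each target chosen with probability proportional to the
#' product of wrapped Gaussians in periodic physical distance (width
#' \code{alpha}, per dimension) and orientation distance (width
#' \code{alpha_theta}). The categorical draw is exact (no rejection), and
#' by construction the connection probability averaged over all distances
#' equals \code{pbar}.
#'
#' @param layout_pre,layout_post \code{\link{grid_layout}} objects for the
#'   pre- and postsynaptic populations.
#' @param pbar mean connection probability.
#' @param J connection strength, mV.
#' @param alpha spatial projection width (unit square).
#' @param alpha_theta orientation projection width ([0,1) circle).
#' @param seed optional RNG seed.
#' @return A data frame (pre, post, weight) of aggregated contacts.
#' @export
sample_spatial_graph <- function(layout_pre, layout_post, pbar, J,
                                 alpha, alpha_theta, seed = NULL) {
  if (alpha <= 0 || alpha_theta <= 0) stop("projection widths must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_pre <- layout_pre$count
  n_post <- layout_post$count
  m <- round(pbar * n_post)
  pre_l <- vector("list", n_pre)
  post_l <- vector("list", n_pre)
  for (i in seq_len(n_pre)) {
    pr <- wrapped_gaussian(layout_post$x - layout_pre$x[i], alpha) *
          wrapped_gaussian(layout_post$y - layout_pre$y[i], alpha) *
          wrapped_gaussian(layout_post$theta - layout_pre$theta[i], alpha_theta)
    post_l[[i]] <- sample.int(n_post, m, replace = TRUE, prob = pr)
    pre_l[[i]] <- rep.int(i, m)
  }
  aggregate_edges(unlist(pre_l), unlist(post_l), J)
}

#' Export a synaptic graph as edge-list CSVs
#'
#' Writes one three-column CSV (pre, post, weight) per pair block plus a
#' JSON sidecar of metadata (seed, sizes, coupling).
#'
#' @param graph a \code{\link{sample_graph}} result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_graph_csv <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(graph$blocks)) {
    fn <- file.path(dir, paste0(gsub("->", "_to_", key, fixed = TRUE), ".csv"))
    utils::write.csv(graph$blocks[[key]], fn, row.names = FALSE)
  }
  meta <- list(seed = graph$seed, sizes = unclass(graph$sizes),
               p = split_rows(graph$coupling$p), J = split_rows(graph$coupling$J))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.synaptic_graph <- function(x, ...) {
  cat("Synaptic graph (fixed out-degree, sampled with replacement)\n")
  for (key in names(x$blocks))
    cat(sprintf("  %-7s %d edges\n", key, nrow(x$blocks[[key]])))
  invisible(x)
}
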
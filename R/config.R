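#' Default model configuration
#'
#' A nested list with sections \code{neuron}, \code{synapse},
#' \code{sizes}, \code{coupling} and \code{stimulus} whose defaults
#' reproduce the reference parameter set of the discrete-network
#' simulations (see \code{\link{neuron_params}},
#' \code{\link{synapse_kinetics}}, \code{\link{population_sizes}} and
#' \code{\link{coupling_table}}). The stimulus section holds the external
#' rate \code{r_X} (Hz), the injected current \code{S} (mV/ms), the
#' stimulated fraction \code{q} and the onset as a fraction of the
#' simulation duration.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  cp <- coupling_table()
  list(
    neuron = unclass(neuron_params()),
    synapse = unclass(synapse_kinetics()),
    sizes = unclass(population_sizes()),
    coupling = list(p = cp$p, J = cp$J),
    stimulus = list(r_X = 5, S = 2, q = 0.2, onset_fraction = 0.5)
  )
}

#' Read / write a configuration file
#'
#' Configurations are stored as JSON mirroring the structure of
#' \code{\link{default_config}}; missing entries are filled from the
#' defaults, so a file may specify only the values it overrides. The
#' coupling matrices are stored row-major with rows (E, I) and columns
#' (E, I, X).
#'
#' @param path file path.
#' @return \code{read_config} returns the nested configuration list with
#'   coupling matrices restored; \code{write_config} returns \code{path}
#'   invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(default_config(), raw)
  dn <- list(c("E", "I"), c("E", "I", "X"))
  for (m in c("p", "J")) {
    v <- cfg$coupling[[m]]
    if (is.list(v)) v <- do.call(rbind, lapply(v, as.numeric))
    cfg$coupling[[m]] <- matrix(as.numeric(v), 2, 3, dimnames = dn)
  }
  cfg
}

#' @rdname read_config
#' @param config nested configuration list.
#' @export
write_config <- function(config, path) {
  config$coupling$p <- split_rows(config$coupling$p)
  config$coupling$J <- split_rows(config$coupling$J)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

split_rows <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))

#' Assemble typed parameter objects from a configuration
#'
#' @param config nested configuration list (see
#'   \code{\link{default_config}}).
#' @return List with \code{neuron}, \code{kinetics}, \code{sizes},
#'   \code{coupling} objects and the \code{stimulus} section.
#' @export
config_objects <- function(config = default_config()) {
  list(neuron = do.call(neuron_params, config$neuron),
       kinetics = do.call(synapse_kinetics, config$synapse),
       sizes = do.call(population_sizes,
                       config$sizes[c("N", "N_X", "q", "N_E", "N_I")]),
       coupling = coupling_table(config$coupling$p, config$coupling$J),
       stimulus = config$stimulus)
}
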
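# Plain-text serialization: long-format CSV for panels, YAML for draw
# configurations and mixing parameters.

#' Write a choice panel to long-format CSV
#'
#' Columns `individual`, `situation`, `alternative`, `chosen`, then any
#' attribute columns; alternative labels are preserved.
#'
#' @param panel A [choice_panel()].
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel$data, path, row.names = FALSE)
  invisible(path)
}

#' Read a choice panel from long-format CSV
#'
#' @param path CSV file with the layout of [write_panel_csv()].
#' @param base_alternative Base alternative label (default: first).
#' @return A [choice_panel()].
#' @export
read_panel_csv <- function(path, base_alternative = NULL) {
  choice_panel(utils::read.csv(path), base_alternative = base_alternative)
}

#' Serialize a draw configuration to YAML
#'
#' @param config A [draw_config()].
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_draw_config <- function(config, path) {
  yaml::write_yaml(list(
    primes = as.list(config$primes),
    draws_per_individual = config$draws_per_individual,
    n_individuals = config$n_individuals,
    drop = config$drop,
    antithetic_mode = config$antithetic_mode,
    seed = if (is.na(config$seed)) NULL else config$seed), path)
  invisible(path)
}

#' Read a draw configuration from YAML
#'
#' @param path YAML file written by [write_draw_config()].
#' @return A [draw_config()].
#' @export
read_draw_config <- function(path) {
  y <- yaml::read_yaml(path)
  draw_config(primes = unlist(y$primes),
              draws_per_individual = y$draws_per_individual,
              n_individuals = y$n_individuals,
              antithetic = y$antithetic_mode,
              drop = if (is.null(y$drop)) 10L else y$drop,
              seed = if (is.null(y$seed)) NA_integer_ else y$seed)
}

#' Serialize mixing parameters to YAML
#'
#' Parameter ordering (dimension names) is written explicitly so the
#' prime-to-dimension assignment survives the round trip.
#'
#' @param params A [mixing_params()].
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(params, path) {
  yaml::write_yaml(list(
    order = as.list(names(params$means)),
    means = as.list(params$means),
    chol = apply(params$chol, 1, as.list, simplify = FALSE),
    fixed_coeffs = as.list(params$fixed_coeffs)), path, precision = 15)
  invisible(path)
}

#' Read mixing parameters from YAML
#'
#' @param path YAML file written by [write_params_yaml()].
#' @return A [mixing_params()].
#' @export
read_params_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ord <- unlist(y$order)
  n <- length(ord)
  Q <- matrix(0, n, n)
  for (k in seq_len(n)) Q[k, ] <- unlist(y$chol[[k]])
  mixing_params(stats::setNames(unlist(y$means), ord), Q,
                unlist(y$fixed_coeffs) %||% numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the moments sidecar of a simulated panel
#'
#' YAML record of the generating specification, seed and realized moments,
#' written next to the panel CSV by the `simulate` CLI subcommand.
#'
#' @param sim A `simulated_panel`.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_sim_sidecar <- function(sim, path) {
  yaml::write_yaml(list(
    spec = list(n_individuals = sim$spec$n_individuals,
                n_situations = sim$spec$n_situations,
                n_alternatives = sim$spec$n_alternatives,
                base_alternative = sim$spec$base_alternative,
                mixing_means = as.list(sim$spec$mixing_means),
                mixing_cov = apply(sim$spec$mixing_cov, 1, as.list,
                                   simplify = FALSE),
                seed = sim$spec$seed),
    realized_means = as.list(sim$realized_means),
    realized_cov = apply(sim$realized_cov, 1, as.list, simplify = FALSE)),
    path, precision = 15)
  invisible(path)
}
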
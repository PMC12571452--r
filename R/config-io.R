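.config_to_nested <- function(config) {
  list(
    cheb = list(layers = config$cheb_layers,
                orders = as.list(config$cheb_orders),
                halve_k0 = config$cheb_halve_k0,
                residual = config$residual),
    gated = list(layers = config$gated_layers,
                 seq_len = config$gated_seq_len,
                 residual = config$residual,
                 self_message = config$gated_self_message),
    hidden_dim = config$hidden_dim,
    learning_rate = config$learning_rate,
    weight_decay = config$weight_decay,
    dropout = config$dropout,
    epochs = config$epochs,
    variant = config$variant,
    seed = config$seed
  )
}

#' Read a model configuration from YAML
#'
#' Any key omitted from the file keeps its [model_config()] default, so a
#' partial file overrides only what it mentions.
#'
#' @param path YAML file path.
#' @param base Configuration supplying defaults (default [model_config()]).
#' @return A `cgsda_config`.
#' @export
read_run_config <- function(path, base = model_config()) {
  raw <- yaml::read_yaml(path)
  pick <- function(x, nm, default) if (!is.null(x[[nm]])) x[[nm]] else default
  model_config(
    cheb_layers = pick(raw$cheb, "layers", base$cheb_layers),
    cheb_orders = unlist(pick(raw$cheb, "orders",
                              as.list(base$cheb_orders))),
    cheb_halve_k0 = pick(raw$cheb, "halve_k0", base$cheb_halve_k0),
    gated_layers = pick(raw$gated, "layers", base$gated_layers),
    gated_seq_len = pick(raw$gated, "seq_len", base$gated_seq_len),
    gated_self_message = pick(raw$gated, "self_message",
                             base$gated_self_message),
    hidden_dim = pick(raw, "hidden_dim", base$hidden_dim),
    learning_rate = pick(raw, "learning_rate", base$learning_rate),
    weight_decay = pick(raw, "weight_decay", base$weight_decay),
    dropout = pick(raw, "dropout", base$dropout),
    epochs = pick(raw, "epochs", base$epochs),
    variant = pick(raw, "variant", base$variant),
    residual = pick(raw$cheb, "residual", base$residual),
    seed = pick(raw, "seed", base$seed)
  )
}

#' Write the effective configuration beside run outputs
#'
#' Serializes the fully resolved configuration (defaults plus any overrides)
#' as YAML; reloading it with [read_run_config()] reproduces the run given
#' the same inputs and seed.
#'
#' @param config A `cgsda_config`.
#' @param out_dir Output directory (created if needed).
#' @param filename File name (default `"config.yaml"`).
#' @return The written path, invisibly.
#' @export
write_effective_config <- function(config, out_dir,
                                   filename = "config.yaml") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  path <- file.path(out_dir, filename)
  yaml::write_yaml(.config_to_nested(config), path)
  invisible(path)
}
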
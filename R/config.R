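# YAML configuration and checkpoint plumbing for the CLI.

#' Read a YAML experiment configuration
#'
#' Sections `arch`, `train`, `loss`, `canny` and `phantom` mirror the
#' corresponding constructor arguments field for field; missing sections or
#' fields fall back to the constructor defaults.
#'
#' @param path YAML file path.
#' @return list with `arch`, `train`, `loss`, `canny`, `phantom` objects.
#' @export
read_config <- function(path) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  build <- function(ctor, section) do.call(ctor, as.list(y[[section]] %||% list()))
  canny <- build(canny_params, "canny")
  tr_args <- as.list(y[["train"]] %||% list())
  tr_args$canny <- canny
  list(arch = build(arch_config, "arch"),
       train = do.call(train_config, tr_args),
       loss = build(loss_config, "loss"),
       canny = canny,
       phantom = build(phantom_config, "phantom"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a trained network checkpoint
#'
#' Checkpoints store the full parameter set, architecture configuration and
#' seed.
#'
#' @param net a `msca_network`.
#' @param path checkpoint file path (`.rds`).
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "msca_network")) stop("not a network checkpoint", call. = FALSE)
  net
}
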
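#' Load an experiment configuration from YAML
#'
#' Reads a YAML file with optional `model`, `train` and `augment` blocks
#' and materialises them into [network_config()], [train_config()] and
#' [augment_config()] objects; omitted fields take the package defaults.
#'
#' @param path YAML file path.
#' @return List with elements `model`, `train`, `augment`.
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines(c("model:", "  num_classes: 8", "  bilinear: true",
#'              "train:", "  epochs: 5"), cfg_file)
#' cfg <- load_experiment_config(cfg_file)
#' cfg$model$num_classes
#' @export
load_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  take <- function(block, fn) {
    if (is.null(block)) block <- list()
    block <- block[names(block) %in% names(formals(fn))]
    do.call(fn, block)
  }
  model <- take(raw$model, network_config)
  train <- take(raw$train, train_config)
  augment <- if (!is.null(raw$augment)) take(raw$augment, augment_config)
  train$augment <- augment
  list(model = model, train = train, augment = augment)
}

#' Describe the defaults in effect
#'
#' One-line-per-setting description of the architecture and training
#' defaults a run will use; intended for run logs so that every choice
#' not pinned by a config file is visible.
#'
#' @param model A [network_config()].
#' @param train A [train_config()].
#' @return Character vector of `key = value` lines, invisibly (also
#'   printed).
#' @export
describe_defaults <- function(model = network_config(),
                              train = train_config()) {
  lines <- c(
    sprintf("stage_depths = %s", paste(model$stage_depths, collapse = ",")),
    sprintf("stage_widths = %s", paste(model$stage_widths, collapse = ",")),
    sprintf("num_classes = %d", model$num_classes),
    sprintf("input_size = %d", model$input_size),
    sprintf("bilinear = %s, use_sa = %s, fusion = %s, sa_groups = %d",
            model$bilinear, model$use_sa, model$fusion, model$sa_groups),
    sprintf("optimizer = adam, lr0 = %g (cosine annealed), batch_size = %d, epochs = %d",
            train$lr0, train$batch_size, train$epochs),
    sprintf("seed = %d", train$seed)
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
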
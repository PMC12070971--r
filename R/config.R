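# Run configuration: YAML schema with strict key validation, defaults
# mirroring the published training recipe (AdamW, lr 2e-3, weight decay
# 5e-4, 3 warm-up epochs, momentum 0.9, batch 16, 200 epochs, 7:1:2 split).

default_run_config <- function() {
  list(
    model = list(variant = "s", input_size = 256L,
                 weconv = list(enabled = TRUE, levels = 1L, kernel = 5L,
                               stages = 2:5),
                 opam = list(enabled = TRUE, reduction = 16L,
                             shared_gate = FALSE, gate_kernel = 7L),
                 head = list(ls = TRUE, middle_channel = 128L,
                             use_dfl = TRUE, reg_max = 16L)),
    loss = list(alpha = 0.4, beta = 0.6, sigma_repgt = 0.5, sigma_repbox = 0.5,
                epsilon = 1e-7, box_gain = 7.5, cls_gain = 0.5, dfl_gain = 1.5),
    train = list(lr = 2e-3, weight_decay = 5e-4, warmup_epochs = 3L,
                 momentum = 0.9, batch = 16L, epochs = 200L, seed = 0L),
    data = list(dir = NULL, split = c(0.7, 0.1, 0.2)),
    eval = list(conf_thr = 0.001, nms_iou = 0.65)
  )
}

# Recursive strict merge: unknown keys are an error.
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) return(user)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ", paste0(path, bad, collapse = ", "))
  for (nm in names(user)) {
    val <- if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      merge_config(defaults[[nm]], user[[nm]], paste0(path, nm, "."))
    else user[[nm]]
    defaults[nm] <- list(val)  # keeps NULL values instead of deleting the key
  }
  defaults
}

validate_run_config <- function(cfg) {
  if (cfg$loss$alpha < 0 || cfg$loss$beta < 0)
    stop("loss weights alpha/beta must be nonnegative")
  if (cfg$loss$sigma_repgt < 0 || cfg$loss$sigma_repgt >= 1 ||
      cfg$loss$sigma_repbox < 0 || cfg$loss$sigma_repbox >= 1)
    stop("sigma values must lie in [0, 1)")
  if (abs(sum(cfg$data$split) - 1) > 1e-9)
    stop("data split ratios must sum to 1")
  if (cfg$model$input_size %% 32L != 0L)
    stop("model input_size must be divisible by 32")
  if (!cfg$model$variant %in% c("n", "s", "m"))
    stop("model variant must be one of n/s/m")
  cfg
}

#' Load a YAML run configuration
#'
#' Missing keys take documented defaults; unknown keys are rejected with an
#' error naming them.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated configuration list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  # YAML 1.1 reads a bare `n` as FALSE; the "n" variant is a legitimate value
  if (is.logical(user$model$variant) && !isTRUE(user$model$variant))
    user$model$variant <- "n"
  cfg <- validate_run_config(merge_config(default_run_config(), user))
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Optional output path; when `NULL` the YAML text is returned.
#' @export
dump_config <- function(cfg, path = NULL) {
  txt <- yaml::as.yaml(unclass(cfg))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Stable hash of a configuration (provenance stamp for reports)
#' @param cfg A `run_config`.
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  txt <- yaml::as.yaml(unclass(cfg))
  # polynomial rolling hash mod a Mersenne prime; stays exact in doubles
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Model config from a run config
#' @param cfg A `run_config`.
#' @param seed Build seed.
#' @return A [model_config].
#' @export
as_model_config <- function(cfg, seed = cfg$train$seed) {
  model_config(variant = cfg$model$variant, input_size = cfg$model$input_size,
               weconv = cfg$model$weconv, opam = cfg$model$opam,
               head = cfg$model$head, seed = seed)
}

#' Deterministic train/validation/test split
#'
#' Shuffles with the given seed and partitions: validation and test sizes
#' are the rounded shares, the remainder goes to training.
#'
#' @param manifest Data frame (or anything with rows) to split.
#' @param ratios Length-3 ratios summing to 1 (train, val, test).
#' @param seed Shuffle seed.
#' @return List of three row-subsets named train/val/test.
#' @export
split_dataset <- function(manifest, ratios = c(0.7, 0.1, 0.2), seed = 0L) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  n <- nrow(manifest)
  idx <- with_seed(seed, sample(n))
  n_val <- round(n * ratios[2])
  n_test <- round(n * ratios[3])
  n_train <- n - n_val - n_test
  list(train = manifest[sort(idx[seq_len(n_train)]), , drop = FALSE],
       val = manifest[sort(idx[n_train + seq_len(n_val)]), , drop = FALSE],
       test = manifest[sort(idx[n_train + n_val + seq_len(n_test)]), , drop = FALSE])
}
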
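# YAML run configuration with a strict (fail-closed) schema, canonical config
# hashing, and the per-run reproducibility manifest.

config_schema <- function() {
  # path -> c(run_config argument, type)
  list(
    "train.lr" = c("lr", "numeric"),
    "train.weight_decay" = c("weight_decay", "numeric"),
    "train.batch_size" = c("batch_size", "integer"),
    "train.epochs" = c("epochs", "integer"),
    "train.schedule" = c("schedule", "character"),
    "train.split" = c("split", "character"),
    "train.seed" = c("seed", "integer"),
    "train.modality" = c("modality", "character"),
    "train.augmentation" = c("augmentation", "character_vector"),
    "train.augment_prob" = c("augment_prob", "numeric"),
    "encoder.image.backbone" = c("image_backbone", "character"),
    "encoder.image.channels" = c("cnn_channels", "integer_vector"),
    "encoder.sensor.bins" = c("sensor_bins", "integer"),
    "encoder.sensor.layers" = c("sensor_layers", "integer"),
    "encoder.sensor.dim" = c("fusion_dim", "integer"),
    "fusion.mode" = c("fusion_mode", "character"),
    "fusion.dim" = c("fusion_dim", "integer"),
    "fusion.alpha_init" = c("fusion_alpha_init", "numeric"),
    "attention.kind" = c("attention_kind", "character"),
    "attention.layers" = c("attention_layers", "integer"),
    "loss.kind" = c("loss_kind", "character"),
    "loss.lambda_align" = c("lambda_align", "numeric"),
    "loss.lambda_box" = c("lambda_box", "numeric"),
    "loss.focal_gamma" = c("focal_gamma", "numeric"),
    "loss.focal_alpha" = c("focal_alpha", "numeric"),
    "loss.class_weights" = c("class_weights", "any"),
    "head.dim" = c("head_dim", "integer"),
    "data.image_size" = c("image_size", "integer_vector")
  )
}

flatten_yaml <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    v <- x[[nm]]
    if (is.list(v) && !is.null(names(v))) {
      out <- c(out, flatten_yaml(v, key))
    } else {
      out[[key]] <- v
    }
  }
  out
}

check_type <- function(key, value, type) {
  ok <- switch(type,
    numeric = is.numeric(value) && length(value) == 1,
    integer = is.numeric(value) && length(value) == 1 &&
      abs(value - round(value)) < 1e-9,
    character = is.character(value) && length(value) == 1,
    character_vector = is.character(value) || length(value) == 0,
    integer_vector = is.numeric(value),
    any = TRUE)
  if (!ok) {
    stop("config key '", key, "': expected ", type, ", got ",
         class(value)[1], " value '", paste(value, collapse = ", "), "'")
  }
  invisible(TRUE)
}

#' Load and validate a YAML run configuration
#'
#' Strict mode: unknown keys are rejected with the offending key name, and
#' every value is type-checked against the schema before being passed to
#' [run_config()]. An empty (or missing-section) file yields all defaults.
#'
#' @param path YAML file path.
#' @return validated [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  flat <- flatten_yaml(raw)
  schema <- config_schema()
  unknown <- setdiff(names(flat), names(schema))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  args <- list()
  for (key in names(flat)) {
    spec <- schema[[key]]
    check_type(key, flat[[key]], spec[2])
    val <- flat[[key]]
    if (spec[2] %in% c("integer", "integer_vector")) val <- as.integer(val)
    args[[spec[1]]] <- val
  }
  backbone <- args$image_backbone
  args$image_backbone <- NULL
  if (!is.null(backbone) && backbone != "tinycnn") {
    stop("config key 'encoder.image.backbone': only 'tinycnn' is runnable ",
         "offline")
  }
  do.call(run_config, args)
}

#' Write a run configuration as YAML
#'
#' Inverse of [load_config()]: dumping then loading reproduces the
#' configuration exactly.
#'
#' @param cfg a [run_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  schema <- config_schema()
  out <- list()
  for (key in names(schema)) {
    field <- schema[[key]][1]
    if (field %in% c("image_backbone")) next
    v <- cfg[[field]]
    if (is.null(v)) next
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    out <- insert_path(out, parts, v)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

insert_path <- function(lst, parts, value) {
  if (length(parts) == 1) {
    lst[[parts]] <- value
    return(lst)
  }
  head_part <- parts[1]
  if (is.null(lst[[head_part]])) lst[[head_part]] <- list()
  lst[[head_part]] <- insert_path(lst[[head_part]], parts[-1], value)
  lst
}

#' Canonical configuration hash
#'
#' SHA-256 of the canonicalized (recursively key-sorted) JSON serialization,
#' so the hash is stable under key reordering.
#'
#' @param cfg a list (typically a [run_config()]).
#' @return hex digest string.
#' @export
config_hash <- function(cfg) {
  canonical <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canonical)
    } else x
  }
  digest::digest(jsonlite::toJSON(canonical(unclass(cfg)), digits = NA,
                                  auto_unbox = TRUE),
                 algo = "sha256", serialize = FALSE)
}

#' Write a reproducibility manifest for a run
#'
#' Records the canonical config hash, the named RNG substream seeds derived
#' from the master seed, timestamps and artifact paths as JSON.
#'
#' @param cfg the run configuration (any list).
#' @param seed master seed.
#' @param artifacts named character vector/list of artifact paths.
#' @param path output JSON path.
#' @param started POSIXct start time.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(cfg, seed, artifacts, path,
                           started = Sys.time()) {
  streams <- c("data", "split", "init", "trainloop", "bayes",
               "cutmix", "mosaic", "gridmask")
  manifest <- list(
    config_hash = config_hash(cfg),
    seeds = c(list(master = as.integer(seed)),
              setNames(lapply(streams, function(s) derive_seed(seed, s)),
                       streams)),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    ended = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    artifacts = as.list(artifacts),
    package_version = as.character(utils::packageVersion("phytofuse"))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Save / load a model checkpoint
#'
#' Single-file container (RDS) with a version field.
#'
#' @param model a `pf_model`.
#' @param path checkpoint path.
#' @return `path` (save) or the restored `pf_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(version = 1L, config = model$cfg, params = model$params,
               stats = model$stats, class_weights = model$class_weights,
               log = model$log), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$version) || ck$version != 1L) {
    stop("unsupported checkpoint version in ", path)
  }
  structure(list(params = ck$params, cfg = ck$config, stats = ck$stats,
                 class_weights = ck$class_weights, log = ck$log,
                 split = NULL),
            class = "pf_model")
}
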
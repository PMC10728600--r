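# YAML run configuration and the command layer behind the dcsanet CLI script
# (inst/cli/dcsanet.R). Every command validates its configuration up front,
# derives all randomness from the global `seed`, and writes a provenance
# record (config hash, seed, versions) beside its outputs.

RUN_CONFIG_SCHEMA <- list(
  version = "scalar", seed = "scalar", output_dir = "scalar",
  model = list(stem_channels = "scalar", kernel_N = "scalar",
               kernel_small = "scalar", use_shuffle = "scalar",
               use_attention = "scalar", decoder_variant = "scalar",
               decoder_widths = "vector", num_classes = "scalar"),
  train = list(initial_lr = "scalar", batch_size = "scalar",
               epochs = "scalar", val_every = "scalar",
               miou_every = "scalar", target_miou = "scalar",
               verbose = "scalar"),
  scene = list(size = "scalar", target_fractions = "vector",
               occlusion_rate = "scalar"),
  data = list(images_dir = "scalar", annotations_dir = "scalar",
              dataset_dir = "scalar", checkpoint = "scalar",
              crop_size = "scalar", crops_per_image = "scalar",
              n_scenes = "scalar", subset = "scalar")
)

check_keys <- function(x, schema, path = "") {
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown) > 0) {
    stop("unknown config key", if (length(unknown) > 1) "s", " at ",
         if (nzchar(path)) path else "top level", ": ",
         paste(unknown, collapse = ", "))
  }
  for (nm in names(x)) {
    if (is.list(schema[[nm]])) {
      if (!is.list(x[[nm]])) stop("config section '", nm, "' must be a mapping")
      check_keys(x[[nm]], schema[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(x)
}

#' Validate a run configuration
#'
#' Checks the configuration (a nested list, typically from
#' [yaml::read_yaml()]) against the versioned schema; unknown keys are
#' rejected. Missing values fall back to package defaults.
#'
#' @param config nested list.
#' @return the validated configuration with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.null(config)) config <- list()
  check_keys(config, RUN_CONFIG_SCHEMA)
  if (!is.null(config$version) && config$version != 1) {
    stop("unsupported config version: ", config$version)
  }
  config$version <- 1L
  config$seed <- as.integer(config$seed %||% 1L)
  config$output_dir <- config$output_dir %||% "."
  config
}

#' @rdname validate_run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

config_model <- function(config) {
  m <- config$model %||% list()
  do.call(dcsa_config, m)
}

config_train <- function(config) {
  t <- config$train %||% list()
  do.call(train_config, c(t, list(seed = config$seed)))
}

config_scene <- function(config) {
  s <- config$scene %||% list()
  s$target_fractions <- unlist(s$target_fractions)
  s$seed <- config$seed
  do.call(scene_spec, s[!vapply(s, is.null, TRUE)])
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_provenance <- function(config, dir, command) {
  rec <- list(command = command, config_hash = config_hash(config),
              seed = config$seed,
              package = as.character(utils::packageVersion("dcsanet")),
              r_version = R.version.string)
  jsonlite::write_json(rec, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(rec)
}

ensure_dir <- function(d) {
  if (!dir.exists(d) && !dir.create(d, recursive = TRUE)) {
    stop("cannot create output directory: ", d)
  }
  d
}

# ---- commands -----------------------------------------------------------------

#' Pipeline commands
#'
#' The command layer behind the `dcsanet` CLI script: `cmd_synth` writes a
#' synthetic fixture dataset, `cmd_prepare` runs the preprocessing pipeline
#' (rasterize, crop, augment, split), `cmd_train`/`cmd_eval` train and score a
#' model, `cmd_summary` prints the analytic cost report, and `cmd_ablate`
#' writes the decoder-ablation table. All take a validated run configuration
#' and return their main artifact invisibly.
#'
#' @param config a [validate_run_config()] result.
#' @name commands
NULL

#' @rdname commands
#' @export
cmd_synth <- function(config) {
  config <- validate_run_config(config)
  n <- config$data$n_scenes %||% 8L
  if (n < 1) stop("data.n_scenes must be >= 1")
  dir <- ensure_dir(config$output_dir)
  spec <- config_scene(config)
  samples <- generate_dataset(n, spec, seed = config$seed)
  man <- attr(samples, "manifest")
  man$image <- sprintf("scene_%03d.png", man$scene)
  man$mask <- sprintf("scene_%03d_mask.png", man$scene)
  for (i in seq_len(n)) {
    write_sample(samples[[i]], file.path(dir, man$image[i]),
                 file.path(dir, man$mask[i]))
  }
  jsonlite::write_json(
    list(seed = config$seed,
         spec = list(size = spec$size,
                     target_fractions = as.list(spec$target_fractions),
                     occlusion_rate = spec$occlusion_rate),
         scenes = man),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_provenance(config, dir, "synth")
  invisible(samples)
}

read_image_file <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
    return(img[, , 1:3, drop = FALSE])
  }
  if (requireNamespace("EBImage", quietly = TRUE)) {
    img <- EBImage::readImage(path)
    return(aperm(img@.Data, c(2, 1, 3))[, , 1:3, drop = FALSE])
  }
  stop("cannot read ", path, ": only PNG is supported natively ",
       "(install EBImage for JPG)")
}

#' @rdname commands
#' @export
cmd_prepare <- function(config) {
  config <- validate_run_config(config)
  dir <- ensure_dir(config$output_dir)
  img_dir <- config$data$images_dir %||% stop("data.images_dir is required")
  ann_dir <- config$data$annotations_dir %||% img_dir
  crop_size <- config$data$crop_size %||% 512L
  crops_per <- config$data$crops_per_image %||% 1L
  files <- list.files(img_dir, pattern = "\\.(png|jpg|jpeg)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L) stop("no images found in ", img_dir)
  skipped <- 0L
  samples <- list()
  with_seed(config$seed, {
    for (f in files) {
      ann <- file.path(ann_dir,
                       paste0(tools::file_path_sans_ext(basename(f)), ".json"))
      if (!file.exists(ann)) {
        warning("no annotation for ", basename(f), "; skipped")
        skipped <- skipped + 1L
        next
      }
      rec <- tryCatch(read_labelme(ann), error = function(e) {
        warning("corrupt annotation ", basename(ann), ": ",
                conditionMessage(e), "; skipped")
        NULL
      })
      if (is.null(rec)) {
        skipped <- skipped + 1L
        next
      }
      img <- read_image_file(f)
      msk <- rasterize_annotation(rec, nrow(img), ncol(img))
      src <- seg_sample(img, msk)
      for (k in seq_len(crops_per)) {
        samples[[length(samples) + 1L]] <- random_crop(src, crop_size)
      }
    }
  })
  if (length(samples) == 0L) stop("no usable image/annotation pairs")
  aug <- with_seed(config$seed + 1L, augment_dataset(samples))
  split <- split_dataset(aug, seed = config$seed)
  prov <- attr(aug, "provenance")
  subset <- character(length(aug))
  for (s in c("train", "val", "test")) subset[split$indices[[s]]] <- s
  man <- data.frame(path = sprintf("sample_%05d", seq_along(aug)),
                    subset = subset, transform = prov,
                    stringsAsFactors = FALSE)
  for (i in seq_along(aug)) {
    write_sample(aug[[i]], file.path(dir, paste0(man$path[i], ".png")),
                 file.path(dir, paste0(man$path[i], "_mask.png")))
  }
  utils::write.csv(man, file.path(dir, "split_manifest.csv"),
                   row.names = FALSE)
  write_provenance(config, dir, "prepare")
  if (skipped > 0L) message(skipped, " image(s) skipped")
  invisible(split)
}

load_prepared <- function(dataset_dir, subset = NULL) {
  man <- utils::read.csv(file.path(dataset_dir, "split_manifest.csv"),
                         stringsAsFactors = FALSE)
  if (!is.null(subset)) man <- man[man$subset == subset, , drop = FALSE]
  lapply(man$path, function(p) {
    read_sample(file.path(dataset_dir, paste0(p, ".png")),
                file.path(dataset_dir, paste0(p, "_mask.png")))
  })
}

load_synth <- function(dataset_dir) {
  man <- jsonlite::fromJSON(file.path(dataset_dir, "manifest.json"))
  lapply(seq_len(nrow(man$scenes)), function(i) {
    read_sample(file.path(dataset_dir, man$scenes$image[i]),
                file.path(dataset_dir, man$scenes$mask[i]))
  })
}

load_dataset_dir <- function(dataset_dir, subset = NULL) {
  if (file.exists(file.path(dataset_dir, "split_manifest.csv"))) {
    load_prepared(dataset_dir, subset)
  } else if (file.exists(file.path(dataset_dir, "manifest.json"))) {
    load_synth(dataset_dir)
  } else {
    stop("no dataset manifest found in ", dataset_dir)
  }
}

#' @rdname commands
#' @export
cmd_train <- function(config) {
  config <- validate_run_config(config)
  dir <- ensure_dir(config$output_dir)
  dd <- config$data$dataset_dir %||% stop("data.dataset_dir is required")
  train <- load_dataset_dir(dd, subset = "train")
  val <- tryCatch(load_dataset_dir(dd, subset = "val"),
                  error = function(e) NULL)
  if (length(val) == 0L) val <- NULL
  model <- dcsanet(config_model(config), seed = config$seed)
  model <- train_dcsanet(model, train, val, config_train(config))
  saveRDS(model, file.path(dir, "checkpoint.rds"))
  jsonlite::write_json(unclass(model$config),
                       file.path(dir, "checkpoint_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  write_provenance(config, dir, "train")
  invisible(model)
}

#' @rdname commands
#' @export
cmd_eval <- function(config) {
  config <- validate_run_config(config)
  dir <- ensure_dir(config$output_dir)
  ckpt <- config$data$checkpoint %||% stop("data.checkpoint is required")
  if (!file.exists(ckpt)) stop("checkpoint not found: ", ckpt)
  model <- readRDS(ckpt)
  dd <- config$data$dataset_dir %||% stop("data.dataset_dir is required")
  samples <- load_dataset_dir(dd, subset = config$data$subset %||% "test")
  rep <- evaluate_model(model, samples)
  jsonlite::write_json(
    list(miou = rep$miou,
         per_class_iou = as.list(stats::setNames(rep$per_class_iou,
                                                 CLASS_NAMES))),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_provenance(config, dir, "eval")
  invisible(rep)
}

#' @rdname commands
#' @export
cmd_summary <- function(config) {
  config <- validate_run_config(config)
  dir <- ensure_dir(config$output_dir)
  model <- dcsanet(config_model(config), seed = config$seed)
  cost <- model_summary(model, 512L)
  jsonlite::write_json(list(params_millions = cost$params_millions,
                            flops_billions = cost$flops_billions,
                            input_size = cost$input_size),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_provenance(config, dir, "summary")
  invisible(cost)
}

#' @rdname commands
#' @export
cmd_ablate <- function(config) {
  config <- validate_run_config(config)
  dir <- ensure_dir(config$output_dir)
  tab <- run_ablation(base_config = config_model(config), seed = config$seed)
  utils::write.csv(tab, file.path(dir, "ablation.csv"), row.names = FALSE)
  write_provenance(config, dir, "ablate")
  invisible(tab)
}
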
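# End-to-end pipeline: synth -> train -> segment -> evaluate -> quantify ->
# score -> report, driven by a single YAML/list config with per-stage
# sections. Every run writes a manifest capturing the effective
# configuration, seeds and output hashes so deterministic stages reproduce
# byte-identical artifacts.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = c("synth", "train", "segment", "evaluate", "quantify", "score",
               "report"),
    synth = list(n_good = 8L, n_poor = 8L, image_size = c(128L, 128L)),
    train = list(preset = "tiny", max_epochs = 30L, batch_size = 8L,
                 augment = FALSE),
    segment = list(model = NULL, threshold = NULL),
    quantify = list(masks = "predicted", connectivity = 8L,
                    min_patch_size = 5L, pixels_per_mm = NULL),
    score = list(cutoff = 45, invert_t = TRUE),
    report = list()
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    abort_if(!file.exists(config), paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  abort_if(!is.list(config), "config must be a list or a YAML path")
  cfg <- modifyList(default_pipeline_config(), config)
  unknown <- setdiff(cfg$stages,
                     c("synth", "train", "segment", "evaluate", "quantify",
                       "score", "report"))
  abort_if(length(unknown) > 0,
           paste0("unknown stage(s) in config$stages: ",
                  paste(unknown, collapse = ", ")))
  cfg
}

#' Run the evaluation pipeline
#'
#' Executes the configured stages in order, each stage feeding the next:
#' synthetic cohort generation, MEM-ViT training, segmentation of the test
#' split, segmentation evaluation, melanin quantification, composite
#' scoring, and the cohort agreement report. A `manifest.json` capturing the
#' effective configuration and output files is always written.
#'
#' @param config Path to a YAML config or a named list; unset keys fall back
#'   to defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of stage outputs (`cohort`, `split`, `model`,
#'   `pred_masks`, `seg_metrics`, `metrics`, `scores`, `report`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  t0 <- Sys.time()

  if ("synth" %in% cfg$stages) {
    sy <- cfg$synth
    res$cohort <- generate_cohort(sy$n_good, sy$n_poor, base_seed = cfg$seed,
                                  image_size = sy$image_size)
    write_cohort(res$cohort, file.path(out_dir, "synth"))
    ids <- seq_along(res$cohort)
    res$split <- split_dataset(ids, seed = cfg$seed)
    write_split(res$split, file.path(out_dir, "split.json"))
  }

  model <- NULL
  if ("train" %in% cfg$stages) {
    abort_if(is.null(res$cohort), "train stage needs the synth stage")
    tr <- cfg$train
    model_cfg <- if (identical(tr$preset, "tiny")) {
      memvit_tiny(image_size = cfg$synth$image_size)
    } else {
      memvit_config(image_size = cfg$synth$image_size)
    }
    tcfg <- train_config(
      max_epochs = tr$max_epochs, batch_size = tr$batch_size,
      augmentations = if (isTRUE(tr$augment)) default_augmentations() else list(),
      seed = cfg$seed)
    model <- train(res$cohort[res$split$train_ids],
                   res$cohort[res$split$val_ids], model_cfg, tcfg)
    save_model(model, file.path(out_dir, "model.rds"))
    write.csv(tidy(model), file.path(out_dir, "curves.csv"),
              row.names = FALSE)
    res$model <- model
  }

  if ("segment" %in% cfg$stages) {
    if (is.null(model)) {
      mp <- cfg$segment$model
      abort_if(is.null(mp), "segment stage needs a trained model or segment$model path")
      abort_if(!file.exists(mp), paste0("model checkpoint not found: ", mp))
      model <- load_model(mp)
    }
    abort_if(is.null(res$cohort), "segment stage needs images (synth stage)")
    test_samples <- res$cohort[res$split$test_ids]
    pred_dir <- file.path(out_dir, "pred")
    dir.create(pred_dir, showWarnings = FALSE)
    res$pred_masks <- purrr::imap(test_samples, function(s, i) {
      m <- segment(s$image, model, threshold = cfg$segment$threshold)
      write_mask(m, file.path(pred_dir, sprintf("pred_%03d.png", i)))
      m
    })
  }

  if ("evaluate" %in% cfg$stages) {
    abort_if(is.null(res$pred_masks), "evaluate stage needs the segment stage")
    truth <- lapply(res$cohort[res$split$test_ids], `[[`, "mask")
    res$seg_metrics <- evaluate_masks(res$pred_masks, truth)
    write.csv(res$seg_metrics, file.path(out_dir, "seg_metrics.csv"),
              row.names = FALSE)
  }

  if ("quantify" %in% cfg$stages) {
    abort_if(is.null(res$cohort), "quantify stage needs samples")
    q <- cfg$quantify
    test_idx <- res$split$test_ids
    samples <- res$cohort[test_idx]
    if (identical(q$masks, "predicted")) {
      abort_if(is.null(res$pred_masks), "quantify over predicted masks needs the segment stage")
      samples <- purrr::map2(samples, res$pred_masks, function(s, m) {
        s$mask <- m
        s
      })
    }
    res$metrics <- quantify_cohort(samples, connectivity = q$connectivity,
                                   min_patch_size = q$min_patch_size,
                                   pixels_per_mm = q$pixels_per_mm)
    write.csv(res$metrics, file.path(out_dir, "metrics.csv"),
              row.names = FALSE)
  }

  if ("score" %in% cfg$stages) {
    abort_if(is.null(res$metrics), "score stage needs the quantify stage")
    res$scores <- score_samples(res$metrics, cutoff = cfg$score$cutoff,
                                invert_t = cfg$score$invert_t)
    write.csv(res$scores, file.path(out_dir, "scores.csv"),
              row.names = FALSE)
  }

  if ("report" %in% cfg$stages) {
    abort_if(is.null(res$scores), "report stage needs the score stage")
    abort_if(!"label" %in% names(res$scores), "report stage needs manual labels")
    res$report <- cohort_analysis(res$scores, res$scores$label)
    jsonlite::write_json(
      list(confusion = as.data.frame(res$report$confusion),
           agreement_pct = res$report$agreement_pct,
           pearson = res$report$pearson),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    command = "run_pipeline",
    tool_version = as.character(packageVersion("melachip")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seeds = list(root = cfg$seed),
    effective_config = cfg,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
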
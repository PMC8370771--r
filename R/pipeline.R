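#' Pipeline configuration
#'
#' One nested list drives every stage of the pipeline; it serialises to
#' YAML and round-trips losslessly. Defaults follow the pipeline's standard
#' practice: 0.85 trimming and replicate-QC thresholds, a k grid of 5 to
#' 150, and the classifier defaults of [classifier_config()].
#'
#' @param outdir directory where stages read and write their artifacts.
#' @param seed global seed; each stage derives its own with [stage_seed()].
#' @param simulate list: n_samples, n_events, doublet_rate, debris_rate,
#'   conditions.
#' @param channels channel names expected on the images, in TIFF page order.
#' @param trim_threshold,outlier_threshold preprocessing thresholds in
#'   (0, 1].
#' @param fluorescence_features feature columns to logicle-transform
#'   (`NULL`: every `_intensity`/`_max_pixel` feature on non-BF/SSC
#'   channels).
#' @param dna_feature DNA intensity feature used for landmark alignment.
#' @param k_grid clustering grid.
#' @param fdl list: cap, knn_k.
#' @param conditions named list mapping sample id patterns to condition
#'   labels for the stats stage (`NULL`: conditions are taken from the
#'   simulation truth).
#' @param classifier a [classifier_config()].
#' @return an `image3c_config` list.
#' @export
pipeline_config <- function(outdir = "image3c_run", seed = 1L,
                            simulate = list(n_samples = 4L, n_events = 200L,
                                            doublet_rate = 0.03, debris_rate = 0.03),
                            channels = c("BF", "SSC", "DNA", "FL1"),
                            trim_threshold = 0.85, outlier_threshold = 0.85,
                            fluorescence_features = NULL,
                            dna_feature = "DNA_intensity",
                            k_grid = seq(5L, 150L, by = 5L),
                            fdl = list(cap = 200L, knn_k = 10L),
                            conditions = NULL,
                            classifier = classifier_config()) {
  cfg <- structure(list(outdir = outdir, seed = as.integer(seed),
                        simulate = simulate, channels = channels,
                        trim_threshold = trim_threshold,
                        outlier_threshold = outlier_threshold,
                        fluorescence_features = fluorescence_features,
                        dna_feature = dna_feature, k_grid = as.integer(k_grid),
                        fdl = fdl, conditions = conditions,
                        classifier = classifier),
                   class = "image3c_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!is_number(trim_threshold) || trim_threshold <= 0 || trim_threshold > 1)
      stop("trim_threshold must be in (0, 1]")
    if (!is_number(outlier_threshold) || outlier_threshold <= 0 || outlier_threshold > 1)
      stop("outlier_threshold must be in (0, 1]")
    if (length(k_grid) < 4) stop("k_grid needs at least 4 values")
    if (!is.numeric(seed) || length(seed) != 1) stop("seed must be one integer")
  })
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @param cfg an `image3c_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cls <- raw$classifier %||% list()
  if (!is.null(cls$splits)) cls$splits <- unlist(cls$splits)
  if (!is.null(cls$transitions)) cls$transitions <- as.integer(unlist(cls$transitions))
  raw$classifier <- do.call(classifier_config, cls)
  raw$k_grid <- as.integer(raw$k_grid %||% seq(5L, 150L, by = 5L))
  cfg <- structure(raw, class = "image3c_config")
  validate_config(cfg)
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$classifier <- unclass(out$classifier)
  out$classifier$splits <- as.list(out$classifier$splits)
  yaml::write_yaml(out, path)
  invisible(path)
}

stage_files <- list(
  simulate  = c("manifest.csv"),
  features  = c("events.csv"),
  preprocess = c("processed.csv"),
  cluster   = c("master.csv", "cluster_means.csv", "counts.csv"),
  stats     = c("diff.csv", "volcano.csv"),
  train     = c("classifier.rds"),
  classify  = c("probabilities.csv"))

require_upstream <- function(stage, outdir, upstream) {
  for (up in upstream) {
    f <- file.path(outdir, stage_files[[up]][1])
    if (!file.exists(f))
      stop(sprintf("stage '%s' needs '%s' from stage '%s'; run that stage first",
                   stage, f, up), call. = FALSE)
  }
}

write_run_manifest <- function(stage, cfg, outdir, seed, inputs, t0) {
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, force = TRUE,
                               digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    stage = stage, seed = seed,
    config_hash = unname(tools::md5sum(tmp)),
    input_hashes = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    package_version = as.character(utils::packageVersion("image3c")),
    r_version = R.version.string,
    wall_time_s = round(as.numeric(Sys.time()) - t0, 2),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(outdir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Run one pipeline stage
#'
#' Orchestrates the pipeline as restartable stages communicating through
#' CSV artifacts in `cfg$outdir`: `simulate` (synthetic images + manifest),
#' `features` (segmentation, feature panel, gating), `preprocess`
#' (trimming, replicate QC, logicle, DNA landmark alignment, scaling),
#' `cluster` (elbow k selection, density-ascent clusters, layout, count
#' matrix), `stats` (NB differential abundance + volcano table), `train`
#' (classifier on the cluster labels) and `classify` (probability vectors
#' for the manifest's images). Each stage writes a JSON run manifest with
#' config hash, seed, input hashes and wall time.
#'
#' @param stage one of simulate, features, preprocess, cluster, stats,
#'   train, classify.
#' @param cfg an [pipeline_config()] (or path to its YAML).
#' @param seed override of the global seed.
#' @param outdir override of the output directory.
#' @return invisibly, the stage's main artifact (tibble or model).
#' @export
run_stage <- function(stage, cfg, seed = NULL, outdir = NULL) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stage <- match.arg(stage, names(stage_files))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  sseed <- stage_seed(cfg$seed, stage)
  out <- switch(stage,
    simulate = stage_simulate(cfg, sseed),
    features = stage_features(cfg, sseed),
    preprocess = stage_preprocess(cfg, sseed),
    cluster = stage_cluster(cfg, sseed),
    stats = stage_stats(cfg, sseed),
    train = stage_train(cfg, sseed),
    classify = stage_classify(cfg, sseed))
  inputs <- file.path(cfg$outdir, unlist(stage_files))
  write_run_manifest(stage, cfg, cfg$outdir, sseed, inputs, t0)
  invisible(out)
}

stage_simulate <- function(cfg, seed) {
  sim <- cfg$simulate
  pops <- demo_populations()
  conds <- sim$conditions %||% "control"
  out <- lapply(seq_len(sim$n_samples), function(s) {
    spec <- sample_spec(sprintf("s%02d", s),
                        condition = conds[(s - 1) %% length(conds) + 1],
                        n_events = sim$n_events, populations = pops,
                        doublet_rate = sim$doublet_rate %||% 0,
                        debris_rate = sim$debris_rate %||% 0,
                        seed = stage_seed(seed, sprintf("sample%02d", s)))
    simulate_sample(spec)
  })
  events <- do.call(c, lapply(out, `[[`, "events"))
  truth <- dplyr::bind_rows(lapply(out, `[[`, "truth"))
  message("simulate: writing ", length(events), " events to ", cfg$outdir)
  write_event_images(events, cfg$outdir, truth)
}

stage_features <- function(cfg, seed) {
  require_upstream("features", cfg$outdir, "simulate")
  io <- read_event_images(cfg$outdir)
  spill_path <- file.path(cfg$outdir, "spillover.csv")
  spill <- if (file.exists(spill_path))
    spillover_matrix(as.matrix(readr::read_csv(spill_path, show_col_types = FALSE)[, -1]))
  events <- lapply(io$events, function(ev) {
    if (!is.null(spill)) ev <- compensate(ev, spill)
    ev <- segment_masks(ev)
    if (!isTRUE(ev$flags$unsegmentable)) ev <- subtract_background(ev)
    ev
  })
  tbl <- compute_features(events)
  gated <- gate_events(tbl, gate_config())
  rep <- attr(gated, "gate_report")
  for (g in names(rep))
    message(sprintf("features: gate '%s' removed %d events", g, rep[[g]]$removed))
  readr::write_csv(gated, file.path(cfg$outdir, "events.csv"))
  gated
}

stage_preprocess <- function(cfg, seed) {
  require_upstream("preprocess", cfg$outdir, "features")
  tbl <- readr::read_csv(file.path(cfg$outdir, "events.csv"),
                         show_col_types = FALSE)
  trim <- spearman_trim(tbl, threshold = cfg$trim_threshold)
  message("preprocess: trimmed ", length(trim$dropped), " redundant feature(s)")
  qc <- replicate_outlier_check(trim$table, threshold = cfg$outlier_threshold)
  if (length(qc$dropped))
    message("preprocess: dropped replicate(s) ", paste(qc$dropped, collapse = ", "))
  tbl <- qc$table
  fluor <- cfg$fluorescence_features %||%
    grep("^(?!BF|SSC).*_(intensity|max_pixel)$", names(tbl),
         perl = TRUE, value = TRUE)
  fluor <- intersect(fluor, names(tbl))
  if (length(fluor)) tbl <- logicle_transform_features(tbl, fluor)
  if (!is.null(attr(tbl, "transform_spec")))
    write_transform_spec(tbl, file.path(cfg$outdir, "transform_spec.json"))
  if (cfg$dna_feature %in% names(tbl))
    tbl <- normalize_dna_peaks(tbl, cfg$dna_feature)
  tbl <- scale_features(tbl)
  if (!is.null(qc$matrix))
    readr::write_csv(tibble::as_tibble(qc$matrix, rownames = "sample_id"),
                     file.path(cfg$outdir, "replicate_qc.csv"))
  readr::write_csv(tbl, file.path(cfg$outdir, "processed.csv"))
  tbl
}

stage_cluster <- function(cfg, seed) {
  require_upstream("cluster", cfg$outdir, "preprocess")
  tbl <- readr::read_csv(file.path(cfg$outdir, "processed.csv"),
                         show_col_types = FALSE)
  res <- cluster_events(tbl, k_grid = cfg$k_grid,
                        fdl_cap = cfg$fdl$cap %||% 200L,
                        fdl_knn_k = cfg$fdl$knn_k %||% 10L, seed = seed)
  message("cluster: k = ", res$k_used, ", ", max(res$table$cluster_id),
          " clusters")
  readr::write_csv(tidy(res), file.path(cfg$outdir, "master.csv"))
  readr::write_csv(res$feature_means, file.path(cfg$outdir, "cluster_means.csv"))
  readr::write_csv(res$counts, file.path(cfg$outdir, "counts.csv"))
  if (!is.null(res$fdl))
    write_graphml(res$fdl, file.path(cfg$outdir, "fdl.graphml"))
  res
}

stage_stats <- function(cfg, seed) {
  require_upstream("stats", cfg$outdir, "cluster")
  counts <- readr::read_csv(file.path(cfg$outdir, "counts.csv"),
                            show_col_types = FALSE)
  names(counts)[names(counts) == "cluster_id"] <- "cluster"
  names(counts)[names(counts) == "sample_id"] <- "sample"
  counts$cluster <- as.character(counts$cluster)
  cond_map <- cfg$conditions
  if (is.null(cond_map)) {
    man <- readr::read_csv(file.path(cfg$outdir, "manifest.csv"),
                           show_col_types = FALSE)
    if (!"condition" %in% names(man))
      stop("no condition map in config and none in the manifest")
    cm <- dplyr::distinct(man, .data$sample_id, .data$condition)
    counts$condition <- cm$condition[match(counts$sample, cm$sample_id)]
  } else {
    counts$condition <- NA_character_
    for (pat in names(cond_map))
      counts$condition[grepl(pat, counts$sample)] <- cond_map[[pat]]
  }
  if (length(unique(counts$condition)) < 2) {
    message("stats: only one condition; skipping the differential test")
    return(invisible(NULL))
  }
  diff <- nb_test(counts)
  message("stats: dispersion ", signif(attr(diff, "dispersion"), 3), ", ",
          sum(diff$fdr <= 0.05), " cluster(s) at FDR <= 0.05")
  readr::write_csv(tidy(diff), file.path(cfg$outdir, "diff.csv"))
  volcano_export(diff, file.path(cfg$outdir, "volcano.csv"))
  diff
}

stage_train <- function(cfg, seed) {
  require_upstream("train", cfg$outdir, c("simulate", "cluster"))
  io <- read_event_images(cfg$outdir)
  master <- readr::read_csv(file.path(cfg$outdir, "master.csv"),
                            show_col_types = FALSE)
  keep <- match(master$event_id, io$manifest$event_id)
  events <- io$events[keep]
  labels <- as.character(master$cluster_id)
  cfg_cls <- cfg$classifier
  cfg_cls$seed <- seed
  split <- split_dataset(labels, cfg_cls$splits, seed)
  model <- build_network(length(unique(labels)), cfg_cls)
  model <- train_classifier(model, events[split$train], labels[split$train],
                            events[split$test], labels[split$test])
  ev <- evaluate_classifier(model, events[split$validate], labels[split$validate])
  message("train: validation accuracy ", round(ev$accuracy, 3),
          ", weighted f1 ", round(ev$weighted_f1, 3))
  saveRDS(model, file.path(cfg$outdir, "classifier.rds"))
  jsonlite::write_json(list(classes = model$classes,
                            preprocess = model$preprocess,
                            config = unclass(model$config),
                            log = model$log),
                       file.path(cfg$outdir, "classifier_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(ev$metrics, file.path(cfg$outdir, "validation_metrics.csv"))
  model
}

stage_classify <- function(cfg, seed) {
  require_upstream("classify", cfg$outdir, c("simulate", "train"))
  model <- readRDS(file.path(cfg$outdir, "classifier.rds"))
  io <- read_event_images(cfg$outdir)
  out <- classify(model, io$events,
                  path = file.path(cfg$outdir, "probabilities.csv"))
  out$event_id <- io$manifest$event_id
  out
}
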
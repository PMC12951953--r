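# Workflow orchestration: a resolved run configuration plus verb-driven
# stages (synth -> encode -> dfs -> train -> predict -> evaluate -> cross ->
# ablate -> enrich) writing a deterministic artifact layout (data/,
# models/, reports/, logs/). Every stage writes the resolved configuration
# and package version beside its outputs so a run is reconstructible from
# its output directory alone.

#' Resolve and validate a run configuration
#'
#' @param config A list, or path to a YAML file, with (all optional except
#'   `species`): `seed`, `out_dir`, `species` (name -> either a
#'   `synthetic` spec list or `fasta`/`labels` paths), `dfs`
#'   (`model`, `candidates`), `protocol` (folds/epochs/batch_size/seed),
#'   `ensemble` (`oof`, `tier2`, `meta`), `train_frac`.
#' @return A validated `run_config` list with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "out_dir", "species", "dfs", "protocol", "ensemble",
             "train_frac")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    abort(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")),
          class = "stack4mc_config_error")
  }
  if (is.null(config$species) || !length(config$species)) {
    abort("config must define at least one species", class = "stack4mc_config_error")
  }
  cfg <- list(
    seed = 7L, out_dir = "stack4mc_run", train_frac = 0.75,
    dfs = list(model = "surrogate", candidates = as.list(ENCODER_NAMES)),
    protocol = list(folds = 5L, epochs = 30L, batch_size = 256L),
    ensemble = list(oof = TRUE, tier2 = list(), meta = list())
  )
  for (k in names(config)) {
    if (k %in% c("dfs", "protocol", "ensemble") && is.list(config[[k]])) {
      for (kk in names(config[[k]])) cfg[[k]][[kk]] <- config[[k]][[kk]]
    } else {
      cfg[[k]] <- config[[k]]
    }
  }
  bad_enc <- setdiff(unlist(cfg$dfs$candidates), ENCODER_NAMES)
  if (length(bad_enc)) {
    abort(sprintf("invalid encoder name(s) in dfs.candidates: %s",
                  paste(bad_enc, collapse = ", ")),
          class = "stack4mc_config_error")
  }
  for (sp in names(cfg$species)) {
    s <- cfg$species[[sp]]
    if (is.null(s$synthetic) && is.null(s$fasta)) {
      abort(sprintf("species '%s' needs either a 'synthetic' spec or a 'fasta' path",
                    sp), class = "stack4mc_config_error")
    }
  }
  structure(cfg, class = "run_config")
}

pipeline_paths <- function(cfg) {
  root <- cfg$out_dir
  list(root = root,
       data = file.path(root, "data"),
       models = file.path(root, "models"),
       reports = file.path(root, "reports"),
       logs = file.path(root, "logs"))
}

log_stage <- function(paths, stage, seed, t0) {
  line <- sprintf("[%s] stage=%s seed=%d elapsed=%.2fs",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, seed,
                  as.numeric(Sys.time()) - t0)
  message(line)
  cat(line, "\n", file = file.path(paths$logs, "run.log"), append = TRUE)
}

write_resolved_config <- function(cfg, paths) {
  res <- unclass(cfg)
  res$package_version <- as.character(utils::packageVersion("stack4mc"))
  yaml::write_yaml(res, file.path(paths$root, "resolved_config.yaml"))
}

load_species_windows <- function(cfg, sp) {
  s <- cfg$species[[sp]]
  if (!is.null(s$synthetic)) {
    args <- s$synthetic
    args$seed <- args$seed %||% derive_seed(cfg$seed, sp)
    args$species_tag <- sp
    synth_generate(do.call(synthetic_spec, args))
  } else {
    labels <- if (!is.null(s$labels)) read_label_sidecar(s$labels) else NULL
    recs <- read_fasta(s$fasta, labels = labels)
    extract_windows(recs)
  }
}

split_train_test <- function(windows, frac, seed) {
  old <- .Random.seed_exists(); on.exit(restore_rng(old), add = TRUE)
  set.seed(derive_seed(seed, "split"))
  n <- nrow(windows)
  idx <- sample.int(n, floor(frac * n))
  list(train = windows[idx, , drop = FALSE],
       test = windows[-idx, , drop = FALSE])
}

pipeline_protocol <- function(cfg) {
  do.call(training_protocol,
          utils::modifyList(list(seed = cfg$seed), cfg$protocol))
}

#' Run one pipeline stage
#'
#' @param config A [run_config()] (or list/YAML path coercible to one).
#' @param verb One of "synth", "encode", "dfs", "train", "predict",
#'   "evaluate", "cross", "ablate", "enrich".
#' @return Invisibly, a list of the artifacts produced (also written under
#'   the configured output directory).
#' @export
run_pipeline <- function(config,
                         verb = c("synth", "encode", "dfs", "train",
                                  "predict", "evaluate", "cross", "ablate",
                                  "enrich")) {
  verb <- match.arg(verb)
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  paths <- pipeline_paths(cfg)
  for (p in paths) dir.create(p, recursive = TRUE, showWarnings = FALSE)
  write_resolved_config(cfg, paths)
  t0 <- as.numeric(Sys.time())
  out <- switch(verb,
    synth = stage_synth(cfg, paths),
    encode = stage_encode(cfg, paths),
    dfs = stage_dfs(cfg, paths),
    train = stage_train(cfg, paths),
    predict = stage_predict(cfg, paths),
    evaluate = stage_evaluate(cfg, paths),
    cross = stage_cross(cfg, paths),
    ablate = stage_ablate(cfg, paths),
    enrich = stage_enrich(cfg, paths)
  )
  log_stage(paths, verb, cfg$seed, t0)
  invisible(out)
}

stage_synth <- function(cfg, paths) {
  out <- list()
  for (sp in names(cfg$species)) {
    w <- load_species_windows(cfg, sp)
    fa <- file.path(paths$data, paste0(sp, ".fa"))
    tsv <- file.path(paths$data, paste0(sp, ".labels.tsv"))
    write_windows(w, fa, tsv)
    out[[sp]] <- fa
  }
  out
}

stage_encode <- function(cfg, paths) {
  out <- list()
  for (sp in names(cfg$species)) {
    w <- load_species_windows(cfg, sp)
    X <- encode_windows(w, unlist(cfg$dfs$candidates))
    f <- file.path(paths$data, paste0(sp, ".features.tsv"))
    write_feature_matrix(X, f)
    out[[sp]] <- f
  }
  out
}

stage_dfs <- function(cfg, paths) {
  prot <- pipeline_protocol(cfg)
  out <- list()
  for (sp in names(cfg$species)) {
    w <- load_species_windows(cfg, sp)
    sel <- dfs_select(w, model = cfg$dfs$model,
                      candidates = unlist(cfg$dfs$candidates),
                      protocol = prot, species = sp)
    f <- file.path(paths$reports, paste0(sp, ".dfs.json"))
    jsonlite::write_json(list(species = sel$species, model = sel$model,
                              n_star = sel$n_star, f_opt = sel$f_opt,
                              trace = sel$trace),
                         f, auto_unbox = TRUE, digits = NA)
    utils::write.table(attr(sel, "cells")[, c("species", "model", "encoding", "acc")],
                       file.path(paths$reports, paste0(sp, ".cells.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out[[sp]] <- sel
  }
  out
}

stage_train <- function(cfg, paths) {
  prot <- pipeline_protocol(cfg)
  out <- list()
  for (sp in names(cfg$species)) {
    w <- load_species_windows(cfg, sp)
    split <- split_train_test(w, cfg$train_frac, cfg$seed)
    dfs_file <- file.path(paths$reports, paste0(sp, ".dfs.json"))
    sets <- NULL
    if (file.exists(dfs_file)) {
      f_opt <- jsonlite::read_json(dfs_file, simplifyVector = TRUE)$f_opt
      sets <- stats::setNames(rep(list(f_opt), 3), BASE_KIND_ORDER)
    }
    model <- fit_stacked(
      split$train, encoder_sets = sets, protocol = prot,
      tier2 = do.call(tier2_config, cfg$ensemble$tier2 %||% list()),
      meta = do.call(meta_config, cfg$ensemble$meta %||% list()),
      oof = cfg$ensemble$oof %||% TRUE, species = sp)
    bundle <- file.path(paths$models, paste0(sp, ".rds"))
    saveRDS(list(model = model, test = split$test, seed = cfg$seed), bundle)
    out[[sp]] <- bundle
  }
  out
}

require_model <- function(paths, sp) {
  bundle <- file.path(paths$models, paste0(sp, ".rds"))
  if (!file.exists(bundle)) {
    abort(sprintf("missing model for species '%s': run the 'train' verb first", sp),
          class = "stack4mc_dependency_error")
  }
  readRDS(bundle)
}

stage_predict <- function(cfg, paths) {
  out <- list()
  for (sp in names(cfg$species)) {
    b <- require_model(paths, sp)
    preds <- stats::predict(b$model, b$test)
    f <- file.path(paths$reports, paste0(sp, ".predictions.tsv"))
    utils::write.table(preds, f, sep = "\t", quote = FALSE, row.names = FALSE)
    out[[sp]] <- f
  }
  out
}

stage_evaluate <- function(cfg, paths) {
  out <- list()
  for (sp in names(cfg$species)) {
    b <- require_model(paths, sp)
    mets <- evaluate_stacked(b$model, b$test)
    f <- file.path(paths$reports, paste0(sp, ".metrics.json"))
    jsonlite::write_json(as.list(mets[1, c("ACC", "SN", "SP", "MCC", "AUC", "F1")]),
                         f, auto_unbox = TRUE, digits = NA)
    out[[sp]] <- mets
  }
  if (length(out) == 1) {
    jsonlite::write_json(
      as.list(out[[1]][1, c("ACC", "SN", "SP", "MCC", "AUC", "F1")]),
      file.path(paths$reports, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

stage_cross <- function(cfg, paths) {
  models <- list(); datasets <- list()
  for (sp in names(cfg$species)) {
    b <- require_model(paths, sp)
    models[[sp]] <- b$model
    datasets[[sp]] <- b$test
  }
  grid <- cross_prediction_grid(models, datasets)
  utils::write.table(grid[, c("source", "target", "AUC", "ACC")],
                     file.path(paths$reports, "cross_predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  grid
}

stage_ablate <- function(cfg, paths) {
  out <- list()
  for (sp in names(cfg$species)) {
    b <- require_model(paths, sp)
    w <- load_species_windows(cfg, sp)
    split <- split_train_test(w, cfg$train_frac, cfg$seed)
    rows <- purrr::map(b$model$base_kinds, function(kind) {
      d <- ablate_base_model(b$model, split$train, split$test, kind)
      dplyr::mutate(d, excluded = kind, species = sp)
    }) |> dplyr::bind_rows()
    f <- file.path(paths$reports, paste0(sp, ".ablation.tsv"))
    utils::write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
    out[[sp]] <- rows
  }
  out
}

stage_enrich <- function(cfg, paths) {
  sps <- names(cfg$species)
  if (length(sps) < 2) {
    abort("enrich needs at least two species", class = "stack4mc_config_error")
  }
  g1 <- load_species_windows(cfg, sps[1])
  g2 <- load_species_windows(cfg, sps[2])
  rows <- kmer_enrichment(dplyr::filter(g1, .data$label == 1),
                          dplyr::filter(g2, .data$label == 1))
  f <- file.path(paths$reports, "kmer_enrichment.tsv")
  utils::write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
  rows
}
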
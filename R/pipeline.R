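# End-to-end workflow: synthesize (or load) knowledgebases, standardize,
# featurize, build the pair dataset, train/evaluate, and persist manifests.

#' Tuned model configurations for the packaged study conditions
#'
#' The model hyperparameters used by the packaged analyses, tuned once on
#' the default synthetic study conditions (the counterpart of the published
#' pipeline's per-dataset hyperparameter search): strong proximal L1 so the
#' network selects sparse color rules instead of memorizing dense rows,
#' validation-based early stopping with best-epoch weights, and a
#' validation-calibrated decision threshold.
#'
#' @param role `"cv"` (cross-validation quality configuration),
#'   `"analysis"` (faster configuration for the cross-reference
#'   comparisons, which are relative contrasts), or `"transfer"`
#'   (small-batch configuration for the per-knowledgebase models of the
#'   cross-KB analysis, whose single-KB datasets are an order of magnitude
#'   smaller).
#' @param seed RNG seed.
#' @return An [mlp_config()].
#' @export
study_mlp_config <- function(role = c("cv", "analysis", "transfer"), seed = 1L) {
  role <- match.arg(role)
  switch(role,
    cv = mlp_config(hidden_sizes = c(128L, 64L), learning_rate = 3e-3, l1 = 0.1,
                    weight_decay = 0, batch_size = 512L, max_epochs = 90L,
                    early_stop_patience = 20L, validation_fraction = 0.1,
                    calibrate_threshold = TRUE, seed = seed),
    analysis = mlp_config(hidden_sizes = c(64L, 32L), learning_rate = 3e-3, l1 = 0.1,
                          weight_decay = 0, batch_size = 512L, max_epochs = 20L,
                          early_stop_patience = Inf, validation_fraction = 0.1,
                          calibrate_threshold = TRUE, seed = seed),
    transfer = mlp_config(hidden_sizes = c(64L, 32L), learning_rate = 3e-3, l1 = 0.1,
                          weight_decay = 0, batch_size = 128L, max_epochs = 200L,
                          early_stop_patience = 30L, validation_fraction = 0.15,
                          calibrate_threshold = TRUE, seed = seed))
}

#' Pipeline run configuration
#'
#' @param synthetic A [synthetic_config()] to generate inputs, or `NULL` to
#'   load real knowledgebases.
#' @param kbs When `synthetic` is `NULL`: named list of
#'   `list(structures, annotations)` paths per knowledgebase.
#' @param std A [std_config()].
#' @param coloring A [coloring_config()].
#' @param model An [mlp_config()].
#' @param cv_iterations,cv_folds Cross-validation settings.
#' @param do_cross_kb Run the cross-knowledgebase evaluation.
#' @param do_crossref Run the cross-reference analysis (requires a crossref
#'   table: synthetic corpora provide one).
#' @param out_dir Output directory for the run manifest, metrics JSON and
#'   stage cache; `NULL` keeps everything in memory.
#' @param seed Global seed for CV splits and model training.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), kbs = NULL,
                            std = std_config("inchi"),
                            coloring = coloring_config(),
                            model = mlp_config(),
                            cv_iterations = 5L, cv_folds = 10L,
                            do_cross_kb = FALSE, do_crossref = FALSE,
                            out_dir = NULL, seed = 1L) {
  structure(list(synthetic = synthetic, kbs = kbs, std = std,
                 coloring = coloring, model = model,
                 cv_iterations = as.integer(cv_iterations),
                 cv_folds = as.integer(cv_folds),
                 do_cross_kb = isTRUE(do_cross_kb),
                 do_crossref = isTRUE(do_crossref),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(state, name, deps, fun) {
  hash <- rlang::hash(deps)
  if (!is.null(state$cache_dir)) {
    f <- file.path(state$cache_dir, paste0(name, ".rds"))
    if (file.exists(f)) {
      cached <- readRDS(f)
      if (identical(cached$hash, hash)) {
        state$log(sprintf("stage %-10s cache hit", name))
        state$manifest[[name]] <- list(status = "cached", hash = hash)
        return(cached$value)
      }
    }
  }
  t0 <- Sys.time()
  value <- tryCatch(fun(), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  state$log(sprintf("stage %-10s done in %.1fs", name, dt))
  state$manifest[[name]] <- list(status = "computed", hash = hash, seconds = dt)
  if (!is.null(state$cache_dir)) {
    saveRDS(list(hash = hash, value = value),
            file.path(state$cache_dir, paste0(name, ".rds")))
  }
  value
}

#' Build a pair dataset from records
#'
#' Convenience wrapper chaining [build_compound_matrix()],
#' [aggregate_pathway_features()], [dedup()], [normalize_features()] and
#' [cross_join()]. The original (pre-standardization) graphs are attached as
#' the dataset's graph registry so the cross-reference analysis can
#' recompute raw feature vectors.
#'
#' @param compounds,pathways Record lists (e.g. from [load_knowledgebase()]
#'   or a [generate_synthetic_kb()] corpus).
#' @param coloring A [coloring_config()].
#' @param std A [std_config()].
#' @param on_error Standardization failure policy.
#' @return A `pair_dataset`.
#' @export
build_pair_dataset <- function(compounds, pathways,
                               coloring = coloring_config(),
                               std = std_config("none"),
                               on_error = c("fail", "skip")) {
  cm_raw <- build_compound_matrix(compounds, coloring, std, on_error = on_error)
  pm_raw <- aggregate_pathway_features(pathways, cm_raw)
  cm <- normalize_features(dedup(cm_raw))
  pm <- normalize_features(dedup(pm_raw))
  pd <- cross_join(cm, pm)
  pd$graphs <- stats::setNames(
    lapply(compounds, function(r) r$graph),
    vapply(compounds, function(r) paste(r$source_kb, r$compound_id, sep = ":"),
           character(1)))
  pd
}

#' Run the full pipeline
#'
#' Executes the stages in order (synthesize/load -> dataset -> CV ->
#' optional cross-KB evaluation -> optional cross-reference analysis),
#' skipping cached stages whose configuration hashes match a previous run in
#' the same `out_dir`. Writes `manifest.json` and `report.json` under
#' `out_dir` when given.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A `pipeline_result` list: `dataset`, `cv`, `cross_kb`,
#'   `crossref`, `manifest`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  state <- new.env()
  state$manifest <- list()
  state$cache_dir <- NULL
  state$log <- if (quiet) function(...) invisible() else function(msg) message(msg)
  if (!is.null(config$out_dir)) {
    state$cache_dir <- file.path(config$out_dir, "cache")
    dir.create(state$cache_dir, recursive = TRUE, showWarnings = FALSE)
  }

  corpus <- .stage(state, "inputs", list(config$synthetic, config$kbs), function() {
    if (!is.null(config$synthetic)) {
      generate_synthetic_kb(config$synthetic)
    } else {
      if (is.null(config$kbs) || length(config$kbs) == 0L) {
        stop("no synthetic config and no knowledgebase paths given")
      }
      comp <- list(); path <- list()
      for (kb in names(config$kbs)) {
        spec <- config$kbs[[kb]]
        if (!dir.exists(spec$structures) && !file.exists(spec$structures)) {
          stop(sprintf("structures path does not exist: %s", spec$structures))
        }
        loaded <- load_knowledgebase(spec$structures, spec$annotations, kb)
        comp <- c(comp, loaded$compounds)
        path <- c(path, loaded$pathways)
      }
      crossref <- NULL
      if (!is.null(config$crossref_table) && file.exists(config$crossref_table)) {
        crossref <- utils::read.delim(config$crossref_table, stringsAsFactors = FALSE)
      }
      list(compounds = comp, pathways = path, crossref = crossref)
    }
  })

  pd <- .stage(state, "dataset",
               list(config$synthetic, config$kbs, config$std, config$coloring),
               function() {
    build_pair_dataset(corpus$compounds, corpus$pathways,
                       coloring = config$coloring, std = config$std,
                       on_error = "skip")
  })

  cv <- .stage(state, "cv",
               list(state$manifest$dataset$hash, config$model,
                    config$cv_iterations, config$cv_folds, config$seed),
               function() {
    run_cv(pd, config$model, n_iterations = config$cv_iterations,
           k = config$cv_folds, seed = config$seed)
  })

  cross_kb <- NULL
  if (config$do_cross_kb) {
    cross_kb <- .stage(state, "cross_kb",
                       list(state$manifest$dataset$hash, config$model, config$seed),
                       function() {
      cross_kb_eval(pd, config$model, seed = config$seed)
    })
  }

  crossref <- NULL
  if (config$do_crossref) {
    crossref <- .stage(state, "crossref",
                       list(state$manifest$dataset$hash, config$model, config$seed),
                       function() {
      xtab <- corpus$crossref
      if (is.null(xtab) || nrow(xtab) == 0L) {
        stop("cross-reference analysis requested but the corpus has no crossref table")
      }
      model <- train_mlp(pd, oversample_positives(pd, seq_len(nrow(pd$pairs))),
                         config$model)
      cross_reference_analysis(model, pd, xtab, pd$graphs)
    })
  }

  result <- structure(list(dataset = pd, cv = cv, cross_kb = cross_kb,
                           crossref = crossref, manifest = state$manifest,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(
      lapply(state$manifest, function(s) s[setdiff(names(s), "value")]),
      file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)
    report <- list(aggregate = cv$aggregate, per_kb = cv$per_kb_aggregate)
    if (!is.null(cross_kb)) report$cross_kb <- as.data.frame(as.table(cross_kb))
    if (!is.null(crossref)) {
      report$crossref <- crossref[c("train_mcc", "crossref_mcc", "mcc_difference",
                                    "n_pairs", "n_identical_feature_pairs")]
    }
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(cv$per_iteration,
                     file.path(config$out_dir, "cv_iterations.csv"),
                     row.names = FALSE)
  }
  result
}

#' Sweep the four atom/bond stereo configurations
#'
#' Runs CV (and, when the corpus has cross-references, the cross-reference
#' analysis) under the four on/off combinations of atom and bond stereo in
#' the atom coloring, holding everything else fixed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Data frame with one row per stereo combination: CV MCC
#'   aggregates plus (when available) the cross-reference MCCs and
#'   identical-feature pair count.
#' @export
stereo_sweep <- function(config = pipeline_config(), quiet = FALSE) {
  combos <- expand.grid(atom_stereo = c(TRUE, FALSE),
                        bond_stereo = c(TRUE, FALSE))
  combos <- combos[order(-combos$atom_stereo, -combos$bond_stereo), ]
  rows <- list()
  for (r in seq_len(nrow(combos))) {
    cfg <- config
    cfg$coloring$atom_stereo <- combos$atom_stereo[r]
    cfg$coloring$bond_stereo <- combos$bond_stereo[r]
    if (!is.null(cfg$out_dir)) {
      cfg$out_dir <- file.path(config$out_dir,
                               sprintf("stereo_%d%d", combos$atom_stereo[r],
                                       combos$bond_stereo[r]))
    }
    res <- run_pipeline(cfg, quiet = quiet)
    agg <- res$cv$aggregate
    row <- data.frame(atom_stereo = combos$atom_stereo[r],
                      bond_stereo = combos$bond_stereo[r],
                      mean_mcc = agg$mean[agg$metric == "mcc"],
                      median_mcc = agg$median[agg$metric == "mcc"],
                      sd_mcc = agg$sd[agg$metric == "mcc"])
    if (!is.null(res$crossref)) {
      row$train_mcc <- res$crossref$train_mcc
      row$crossref_mcc <- res$crossref$crossref_mcc
      row$mcc_difference <- res$crossref$mcc_difference
      row$n_identical <- res$crossref$n_identical_feature_pairs
    }
    rows[[r]] <- row
  }
  do.call(rbind, rows)
}
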
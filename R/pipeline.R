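#' Default pipeline configuration
#'
#' @return named list of configuration defaults; see [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    design = list(),                # overrides passed to panel_design()
    cells = NULL,                   # precomputed feature table (or CSV path)
    time_h = 48,                    # viability / profile snapshot
    include_dead = FALSE,           # include dead cells in the mixture fit?
    alpha = 0.05,                   # feature-selection and MANOVA level
    permutations = 100,             # label permutations for the filter
    k_range = 1:12,
    pair_threshold = NULL,          # dendrogram cut (default 25% of max height)
    out_dir = NULL,
    stages = c("simulate", "viability", "synergy", "select", "gmm",
               "profiles", "cluster", "map")
  )
}

run_stage <- function(name, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(fun(), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          parent = e)
  })
  list(result = res, seconds = proc.time()[["elapsed"]] - t0,
       checksum = rlang::hash(res))
}

#' Run the analysis pipeline end to end
#'
#' Orchestrates: synthetic panel generation (or a user-supplied feature
#' table) -> per-condition viability -> interaction matrix -> SVM feature
#' selection -> mixture fitting with component-number selection ->
#' heterogeneity profiles -> dendrogram clustering -> pathway mapping.
#' Every random draw derives from `config$seed`; rerunning with the same
#' configuration reproduces the per-stage checksums in the manifest.
#'
#' @param config named list (or path to a YAML file) overriding
#'   [default_pipeline_config()]. Supplying `cells` (a feature table or CSV
#'   path) skips the `simulate` stage and starts at `viability`.
#' @return object of class `sl_pipeline_run`: `$config`, `$results` (one
#'   entry per executed stage) and `$manifest` (stage, seconds, checksum,
#'   seed).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_pipeline_config(), config)
  stages <- cfg$stages
  if (!is.null(cfg$cells)) stages <- setdiff(stages, "simulate")
  results <- list()
  manifest <- list()

  record <- function(name, fun) {
    st <- run_stage(name, fun)
    results[[name]] <<- st$result
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = name, seconds = st$seconds, checksum = st$checksum,
      seed = cfg$seed
    )
  }

  design <- do.call(panel_design, modifyList(cfg$design, list(seed = cfg$seed)))

  if ("simulate" %in% stages) {
    record("simulate", function() generate_feature_panel(design))
    cells <- results$simulate$cells
  } else {
    cells <- cfg$cells
    if (is.character(cells)) {
      cells <- as_tibble(utils::read.csv(cells, check.names = FALSE))
    }
    cells <- as_tibble(cells)
  }

  if ("viability" %in% stages) {
    record("viability", function() viability_table(cells, time_h = cfg$time_h))
  }
  if ("synergy" %in% stages) {
    record("synergy", function() build_interaction_matrix(results$viability))
  }

  snapshot <- if ("time_h" %in% names(cells)) {
    filter(cells, .data$time_h == cfg$time_h)
  } else cells
  if (!cfg$include_dead && "alive" %in% names(snapshot)) {
    snapshot <- filter(snapshot, .data$alive)
  }

  if ("select" %in% stages) {
    record("select", function() {
      std <- standardize_features(snapshot)
      ranking <- rank_features_svm(std)
      select_features(ranking, std, alpha = cfg$alpha, B = cfg$permutations,
                      seed = cfg$seed)
    })
  }
  if ("gmm" %in% stages) {
    record("gmm", function() {
      std <- standardize_features(snapshot)
      keep <- if (!is.null(results$select)) {
        attr(results$select, "selected")
      } else feature_cols(std)
      std <- std[, c(setdiff(names(std), feature_cols(std)), keep)]
      select_component_number(std, k_range = cfg$k_range, seed = cfg$seed,
                              alpha = cfg$alpha)
    })
  }
  if ("profiles" %in% stages) {
    record("profiles", function() {
      sel <- results$gmm
      x <- snapshot[, c(setdiff(names(snapshot), feature_cols(snapshot)),
                        character(0)), drop = FALSE]
      std <- standardize_features(snapshot)
      keep <- sel$model$feature_names
      a <- assign_cells(sel$model, std[, c(setdiff(names(std), feature_cols(std)), keep)])
      heterogeneity_profile(a$component, snapshot$condition, sel$k)
    })
  }
  if ("cluster" %in% stages) {
    record("cluster", function() {
      dend <- cluster_perturbations(results$profiles)
      list(dendrogram = dend,
           groups = extract_pairs(dend, height = cfg$pair_threshold))
    })
  }
  if ("map" %in% stages) {
    record("map", function() {
      graph <- build_default_topology()
      known <- intersect(default_drug_panel()$sl_inhibitors,
                         unique(graph$inhibitors$inhibitor))
      all_labels <- unique(results$profiles$condition)
      mapping <- map_to_pathway(results$cluster$groups, graph, known = known,
                                unknown = setdiff(all_labels, known))
      list(mapping = mapping,
           graph = annotate_drug_mapping(graph, mapping))
    })
  }

  run <- structure(
    list(config = cfg, results = results, manifest = bind_rows(manifest)),
    class = "sl_pipeline_run"
  )
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(run, cfg$out_dir)
  run
}

#' @export
print.sl_pipeline_run <- function(x, ...) {
  cat("<sl_pipeline_run>\n")
  print(x$manifest)
  invisible(x)
}

# write standard per-stage outputs under a directory
write_pipeline_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- run$results
  if (!is.null(r$viability)) {
    utils::write.csv(as.data.frame(r$viability),
                     file.path(dir, "viability.csv"), row.names = FALSE)
  }
  if (!is.null(r$synergy)) write_interaction_matrix(r$synergy, dir)
  if (!is.null(r$select)) {
    utils::write.csv(as.data.frame(r$select),
                     file.path(dir, "feature_selection.csv"), row.names = FALSE)
  }
  if (!is.null(r$gmm)) write_gmm_json(r$gmm, file.path(dir, "gmm_model.json"))
  if (!is.null(r$profiles)) {
    write_profiles_csv(r$profiles, file.path(dir, "profiles.csv"))
  }
  if (!is.null(r$cluster)) {
    write_dendrogram_newick(r$cluster$dendrogram,
                            file.path(dir, "dendrogram.nwk"))
  }
  if (!is.null(r$map)) {
    write_mapping_json(r$map$mapping, file.path(dir, "mapping.json"))
    export_pathway_graph(r$map$graph, "json",
                         file.path(dir, "pathway_annotated.json"))
  }
  utils::write.csv(as.data.frame(run$manifest),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
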
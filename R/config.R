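#' Run configuration
#'
#' Bundles every tunable of the pipeline. `lambda_lower` drives the
#' compound-level walk kernel, `lambda_upper` the reaction-level one;
#' 0.9 is the default at both levels. `mode` selects the reaction-graph
#' variant, `non_tottering` toggles the non-tottering walk transform
#' (default on), `min_score` is the rejection threshold of the predictor
#' (0 = never abstain).
#'
#' @param lambda_lower,lambda_upper walk continuation probabilities,
#'   each in (0, 1).
#' @param tol,max_iter fixed-point controls, see [walk_params()].
#' @param mode reaction-graph variant.
#' @param non_tottering logical.
#' @param top_k candidates reported per query (>= 1).
#' @param min_score rejection threshold in \[0, 1\].
#' @param seed integer seed recorded in manifests and used by commands
#'   that generate data.
#' @return an object of class `run_config`.
#' @export
run_config <- function(lambda_lower = 0.9, lambda_upper = 0.9,
                       tol = 1e-9, max_iter = 100L,
                       mode = c("full_edge", "rpair", "main_pair"),
                       non_tottering = TRUE, top_k = 5L,
                       min_score = 0, seed = 1L) {
  mode <- match.arg(mode)
  walk_params(lambda_lower, lambda_lower, tol, max_iter)  # validate
  walk_params(lambda_upper, lambda_upper, tol, max_iter)
  top_k <- as.integer(top_k)
  if (is.na(top_k) || top_k < 1L) stop("top_k must be >= 1")
  if (min_score < 0 || min_score > 1) stop("min_score must be in [0, 1]")
  structure(list(lambda_lower = lambda_lower, lambda_upper = lambda_upper,
                 tol = tol, max_iter = as.integer(max_iter), mode = mode,
                 non_tottering = isTRUE(non_tottering), top_k = top_k,
                 min_score = min_score, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose keys override the defaults.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

.lower_params <- function(config) {
  walk_params(config$lambda_lower, config$lambda_lower,
              config$tol, config$max_iter)
}

.upper_params <- function(config) {
  walk_params(config$lambda_upper, config$lambda_upper,
              config$tol, config$max_iter)
}

#' Run manifest
#'
#' Records everything needed to reproduce a pipeline run: the full
#' configuration, MD5 digests of the input files, package and R
#' versions, convergence diagnostics, and a timestamp. Two runs with the
#' same config and inputs produce identical manifests modulo the
#' timestamp field.
#'
#' @param config a [run_config()].
#' @param inputs character vector of input file paths.
#' @param outputs character vector of output file paths.
#' @param diagnostics list, e.g. `non_converged` kernel-evaluation count.
#' @param path where to write the JSON manifest.
#' @return the manifest list, invisibly; written as JSON to `path`.
#' @export
run_manifest <- function(config, inputs, outputs, diagnostics = list(),
                         path) {
  digests <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  manifest <- list(
    config = unclass(config),
    inputs = digests,
    outputs = as.list(outputs),
    diagnostics = diagnostics,
    versions = list(
      rgk = as.character(utils::packageVersion("rgk")),
      R = paste(R.version$major, R.version$minor, sep = ".")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

# load fixture-style inputs: an SDF of compounds and a reaction list
.load_inputs <- function(reaction_file, compound_file) {
  list(records = read_reaction_list(reaction_file),
       compounds = read_sdf(compound_file))
}

.build_graphs <- function(records, mode) {
  lapply(records, build_reaction_graph, mode = mode)
}

#' Pipeline commands
#'
#' High-level entry points mirroring the `rgk` command-line interface
#' (`inst/exec/rgk`). Each reads a reaction list plus compound SDF,
#' runs the corresponding computation, writes plain-text outputs into
#' `out_dir`, and drops a JSON run manifest next to them. Outputs are
#' deterministic: re-running with identical inputs and config yields
#' byte-identical TSVs.
#'
#' `rgk_gram_run` writes the normalized compound- and reaction-level
#' Gram matrices. `rgk_loo_run` performs leave-one-out EC prediction
#' (per-query TSV + summary JSON). `rgk_predict_run` predicts EC
#' candidates for every unannotated reaction (EC `"?"`) from the
#' annotated ones. `rgk_fixtures_run` materializes a synthetic benchmark.
#' `rgk_sweep_run` repeats the leave-one-out evaluation over a grid of
#' walk parameters.
#'
#' @param reaction_file reaction-list file (see [read_reaction_list()]).
#' @param compound_file SDF with every participating compound.
#' @param out_dir output directory, created if needed.
#' @param config a [run_config()].
#' @param filter apply [filter_reactions()] before evaluation.
#' @return the main result of each command, invisibly.
#' @name pipeline
NULL

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "NA", format(x, digits = 12, trim = TRUE,
                                  scientific = FALSE))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline
#' @export
rgk_gram_run <- function(reaction_file, compound_file, out_dir,
                         config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- .load_inputs(reaction_file, compound_file)
  cgram <- compound_gram_matrix(inp$compounds, .lower_params(config),
                                config$non_tottering)
  graphs <- .build_graphs(inp$records, config$mode)
  rgram <- reaction_gram_matrix(graphs, cgram, .upper_params(config),
                                config$non_tottering)
  write_gram_tsv(cgram, file.path(out_dir, "compound_gram.tsv"))
  write_gram_tsv(rgram, file.path(out_dir, "reaction_gram.tsv"))
  diag <- list(non_converged = sum(attr(cgram, "non_converged"),
                                   attr(rgram, "non_converged")))
  run_manifest(config, c(reaction_file, compound_file),
               file.path(out_dir, c("compound_gram.tsv",
                                    "reaction_gram.tsv")),
               diag, file.path(out_dir, "manifest.json"))
  invisible(list(compound_gram = cgram, reaction_gram = rgram))
}

#' @rdname pipeline
#' @export
rgk_loo_run <- function(reaction_file, compound_file, out_dir,
                        config = run_config(), filter = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- .load_inputs(reaction_file, compound_file)
  records <- inp$records
  if (filter) {
    records <- filter_reactions(
      records, has_structure = function(id) id %in% names(inp$compounds),
      verbose = FALSE)
  }
  if (length(records) < 2L) {
    stop("fewer than 2 reactions remain after filtering")
  }
  cgram <- compound_gram_matrix(inp$compounds, .lower_params(config),
                                config$non_tottering)
  graphs <- .build_graphs(records, config$mode)
  res <- loo_evaluate(graphs, cgram, .upper_params(config),
                      config$non_tottering, k = config$top_k,
                      min_score = config$min_score)
  .write_tsv(res$table, file.path(out_dir, "loo_per_query.tsv"))
  jsonlite::write_json(
    list(accuracy = as.list(res$accuracy), coverage = res$coverage,
         n_reactions = length(graphs), mode = config$mode),
    file.path(out_dir, "loo_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  run_manifest(config, c(reaction_file, compound_file),
               file.path(out_dir, c("loo_per_query.tsv",
                                    "loo_summary.json")),
               list(n_reactions = length(graphs)),
               file.path(out_dir, "manifest.json"))
  invisible(res)
}

#' @rdname pipeline
#' @export
rgk_predict_run <- function(reaction_file, compound_file, out_dir,
                            config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- .load_inputs(reaction_file, compound_file)
  ecs <- vapply(inp$records, function(r) r$ec, character(1))
  if (!any(is.na(ecs))) stop("no unannotated (ec: ?) query reactions")
  if (!any(!is.na(ecs))) stop("no annotated database reactions")
  cgram <- compound_gram_matrix(inp$compounds, .lower_params(config),
                                config$non_tottering)
  db <- .build_graphs(inp$records[!is.na(ecs)], config$mode)
  queries <- .build_graphs(inp$records[is.na(ecs)], config$mode)
  rows <- list()
  for (q in queries) {
    pred <- knn_predict(q, db, cgram, k = config$top_k,
                        params = .upper_params(config),
                        non_tottering = config$non_tottering,
                        min_score = config$min_score)
    if (nrow(pred$candidates) > 0L) {
      rows[[length(rows) + 1L]] <- cbind(query = pred$query,
                                         pred$candidates)
    }
  }
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(query = character(0))
  .write_tsv(tab, file.path(out_dir, "predictions.tsv"))
  run_manifest(config, c(reaction_file, compound_file),
               file.path(out_dir, "predictions.tsv"), list(),
               file.path(out_dir, "manifest.json"))
  invisible(tab)
}

#' @rdname pipeline
#' @param spec a [fixture_spec()]; its seed is taken from `config$seed`
#'   when `NULL`.
#' @export
rgk_fixtures_run <- function(out_dir, spec = NULL, config = run_config()) {
  if (is.null(spec)) spec <- fixture_spec(seed = config$seed)
  fixture <- generate_reaction_classes(spec)
  write_fixture_set(fixture, out_dir)
  run_manifest(config, character(0),
               file.path(out_dir, c("compounds.sdf", "reactions.txt",
                                    "truth.tsv")),
               list(spec = unclass(spec)),
               file.path(out_dir, "manifest.json"))
  invisible(fixture)
}

#' @rdname pipeline
#' @param lambdas numeric grid of walk parameters applied at both levels.
#' @export
rgk_sweep_run <- function(reaction_file, compound_file, out_dir,
                          lambdas = c(0.9, 0.8, 0.7, 0.6),
                          config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(lambdas, function(lam) {
    cfg <- run_config(lambda_lower = lam, lambda_upper = lam,
                      tol = config$tol, max_iter = config$max_iter,
                      mode = config$mode,
                      non_tottering = config$non_tottering,
                      top_k = config$top_k, min_score = config$min_score,
                      seed = config$seed)
    res <- rgk_loo_run(reaction_file, compound_file,
                       file.path(out_dir, sprintf("lambda_%g", lam)),
                       cfg)
    data.frame(lambda = lam, level1 = res$accuracy[["level1"]],
               level2 = res$accuracy[["level2"]],
               level3 = res$accuracy[["level3"]],
               coverage = res$coverage)
  })
  tab <- do.call(rbind, rows)
  .write_tsv(tab, file.path(out_dir, "sweep.tsv"))
  invisible(tab)
}
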
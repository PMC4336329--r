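default_pipeline_config <- function() {
  list(
    seed = 1L,
    paths = list(library = NULL, edge_list = NULL),
    network = list(threshold = 0.7),
    chc = list(thresholds = NULL, n_perm = 1000L),
    ensemble = list(k = 5L, families = c("winnow", "svm"),
                    alpha = 2, theta = NULL, n_epochs = 1L,
                    C = NULL, gamma = NULL, n_bins = 10L),
    summary = list(convention = "as-printed"),
    labels = list(threshold = 50),
    synthetic = NULL)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration
#'
#' YAML file (or list) with the keys of the default configuration: `seed`,
#' `paths` (library CSV, optional precomputed edge list), `network`
#' (Tanimoto threshold), `chc` (threshold grid, permutations), `ensemble`
#' (folds, families, Winnow and kernel parameters), `summary` (density
#' convention), `labels` (blocker threshold), `synthetic` (a
#' [synthetic_config()] field list used when no library path is given).
#' Unspecified keys keep their defaults.
#'
#' @param config a YAML path or a (possibly partial) config list.
#' @return the resolved config list.
#' @export
read_pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop2("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop2("config must be a list or a YAML path")
  merge_config(default_pipeline_config(), config)
}

#' Run the full screen-analysis pipeline
#'
#' Sequences the stages: load (or simulate) the library, QC-filter on the
#' patch-clamp well metadata, binarize labels, build the 2D similarity
#' network (optionally merged with an imported edge list), compute the
#' chemical-club profile with its permutation null, fit the balanced-batch
#' ensemble, and assemble the six-class summary network.  All stage
#' outputs are written as CSV into `out_dir` together with the resolved
#' configuration (YAML) and a log; re-running with the same configuration
#' reproduces identical files.
#'
#' @param config a config list or YAML path (see
#'   [read_pipeline_config()]).
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the in-memory stage results and the
#'   output paths.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- read_pipeline_config(config)
  if (missing(out_dir) || !is.character(out_dir))
    stop2("out_dir is required")
  if (is.null(cfg$paths$library) && is.null(cfg$synthetic))
    stop2("config must give either paths$library or a synthetic section")
  if (!is.null(cfg$paths$library) && !file.exists(cfg$paths$library))
    stop2("library file not found: %s", cfg$paths$library)
  if (!is.null(cfg$paths$edge_list) && !file.exists(cfg$paths$edge_list))
    stop2("edge list file not found: %s", cfg$paths$edge_list)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- file(log_path, open = "wt")
  on.exit(close(logf))
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(msg, logf)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop2("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  say("master seed: %d", cfg$seed)
  lib <- stage("load", {
    if (!is.null(cfg$paths$library)) read_library(cfg$paths$library)
    else {
      sc <- do.call(synthetic_config,
                    cfg$synthetic[names(cfg$synthetic) != "kind"])
      generate_library(sc)
    }
  })
  say("library: %d compounds", nrow(lib))

  if (all(c("tail_nA", "seal_MOhm", "drop_pct") %in% names(lib))) {
    qc <- stage("qc_filter", qc_filter(lib))
    say("qc: retained %d, rejected %d", nrow(qc$retained), nrow(qc$rejected))
    write_library(qc$rejected, file.path(out_dir, "qc_rejected.csv"))
    lib <- qc$retained
  } else say("qc: no well metadata; skipped")

  lib <- stage("binarize", binarize_labels(lib, cfg$labels$threshold))
  say("labels: %d blockers / %d nonblockers (threshold %g)",
      sum(lib$label == "blocker"), sum(lib$label == "nonblocker"),
      cfg$labels$threshold)
  write_library(lib, file.path(out_dir, "library.csv"))

  net <- stage("network",
               build_similarity_network(lib, threshold = cfg$network$threshold))
  if (!is.null(cfg$paths$edge_list)) {
    net3d <- stage("network", read_edge_list(cfg$paths$edge_list,
                                             nodes = lib$id))
    net <- stage("network", merge_networks(net, net3d))
    say("network: merged 2D + imported edges")
  }
  say("network (%s): %d edges at threshold %g", net$metric, n_edges(net),
      cfg$network$threshold)
  write_edge_list(net, file.path(out_dir, "network_edges.tsv"))

  act <- stats::setNames(lib$inhib_10uM, lib$id)
  prof <- stage("chc", permutation_null(net, act,
                                        thresholds = cfg$chc$thresholds,
                                        n_perm = cfg$chc$n_perm,
                                        seed = cfg$seed))
  utils::write.csv(as.data.frame(prof), file.path(out_dir, "chc_profile.csv"),
                   row.names = FALSE)
  say("chc: %d thresholds, %d permutations", nrow(prof), cfg$chc$n_perm)

  ens <- stage("ensemble", herg_ensemble(
    lib, k = cfg$ensemble$k, seed = cfg$seed,
    families = cfg$ensemble$families, alpha = cfg$ensemble$alpha,
    theta = cfg$ensemble$theta, n_epochs = cfg$ensemble$n_epochs,
    C = cfg$ensemble$C, gamma = cfg$ensemble$gamma,
    n_bins = cfg$ensemble$n_bins, threshold = cfg$labels$threshold))
  say("ensemble: votes per family per fold: %s",
      paste(ens$batch_counts, collapse = ", "))
  utils::write.csv(ens$results, file.path(out_dir, "ensemble_results.csv"),
                   row.names = FALSE)

  sn <- stage("summary", build_summary_network(ens, net,
                                               convention = cfg$summary$convention))
  utils::write.csv(sn$groups, file.path(out_dir, "summary_groups.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(class = rownames(sn$between), sn$between),
                   file.path(out_dir, "summary_between_density.csv"),
                   row.names = FALSE)
  say("summary: %s",
      paste(sprintf("%s=%d", sn$groups$class, sn$groups$V), collapse = ", "))

  cfg_out <- cfg
  cfg_out$ensemble$families <- as.list(cfg$ensemble$families)
  yaml::write_yaml(cfg_out, file.path(out_dir, "resolved_config.yaml"))
  invisible(list(library = lib, network = net, chc = prof, ensemble = ens,
                 summary = sn, out_dir = out_dir))
}
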
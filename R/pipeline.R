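#' Pipeline configuration
#'
#' A declarative configuration for the end-to-end workflow (descriptor
#' computation, correlation filtering, GA + MLR fitting, similarity
#' screening). Round-trips losslessly through YAML; every pipeline run
#' writes its resolved configuration next to its outputs.
#'
#' @param structures Path to the modelling structures (SMILES/SDF).
#' @param activity Path to the activity CSV.
#' @param library Path to the screening library (SMILES/SDF), or NULL.
#' @param descriptors Character vector of canonical descriptor names.
#' @param filter_threshold Correlation pre-filter cutoff.
#' @param ga List of [ga_config()] fields (merged over its defaults).
#' @param fs_threshold Fingerprint similarity cutoff for enrichment.
#' @param cluster_k Mini-batch k-means cluster count.
#' @param top_n Ranked hits to keep (NULL = all).
#' @param out_dir Output directory.
#' @param seed Integer seed for every stochastic stage.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(structures = NULL, activity = NULL,
                            library = NULL,
                            descriptors = reference_descriptor_names(),
                            filter_threshold = 0.9, ga = list(),
                            fs_threshold = 0.8, cluster_k = 40,
                            top_n = NULL, out_dir = ".", seed = 20230807) {
  cfg <- list(structures = structures, activity = activity,
              library = library, descriptors = descriptors,
              filter_threshold = filter_threshold, ga = ga,
              fs_threshold = fs_threshold, cluster_k = cluster_k,
              top_n = top_n, out_dir = out_dir, seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param cfg A \code{pipeline_config} (for the writer).
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(pipeline_config, lst)
}

#' Pipeline stage: compute a descriptor CSV from structures
#'
#' Thin wrapper over [compute_descriptor_matrix()] for file-based use: reads
#' structures, computes the requested descriptors, writes the CSV (masked
#' cells as empty fields) and logs per-compound failures.
#'
#' @param structures Path to a SMILES or SDF file.
#' @param out Output CSV path.
#' @param descriptors Canonical descriptor names.
#' @return The descriptor matrix, invisibly.
#' @export
run_descriptor_stage <- function(structures, out,
                                 descriptors = reference_descriptor_names()) {
  mols <- read_structures(structures)
  m <- compute_descriptor_matrix(mols, descriptors)
  fails <- attr(m, "failures")
  for (r in seq_len(nrow(fails)))
    message(sprintf("descriptors: compound '%s', %s masked: %s",
                    fails$id[r], fails$descriptor[r], fails$reason[r]))
  write_descriptor_csv(m, out)
  invisible(m)
}

#' Pipeline stage: filter, select and fit a pIC50 model
#'
#' Reads a descriptor CSV and an activity CSV, drops highly correlated
#' descriptor columns, selects a subset by GA on the training partition,
#' fits the OLS model, and writes the model JSON plus train/test validation
#' reports.
#'
#' @param descriptor_csv Path to the descriptor CSV.
#' @param activity_csv Path to the activity CSV.
#' @param out_dir Output directory (created if missing).
#' @param cfg A [pipeline_config()]; its \code{ga} entry parameterizes
#'   [ga_config()].
#' @return List with \code{selection} ([ga_select()] result), \code{train}
#'   and \code{test} validation reports (test NULL without test rows),
#'   invisibly.
#' @export
run_fit_stage <- function(descriptor_csv, activity_csv, out_dir,
                          cfg = pipeline_config()) {
  x <- read_descriptor_csv(descriptor_csv)
  act <- read_activity_table(activity_csv)
  missing <- setdiff(act$id, rownames(x))
  if (length(missing))
    stopf("no descriptor row for id(s): %s", paste(missing, collapse = ", "))
  masked <- rownames(x)[apply(is.na(x), 1L, any)]
  if (length(masked)) {
    message("fit: excluding compounds with masked descriptors: ",
            paste(masked, collapse = ", "))
    act <- act[!act$id %in% masked, , drop = FALSE]
  }
  xf <- correlation_filter(x[act$id, , drop = FALSE],
                           threshold = cfg$filter_threshold)
  rem <- attr(xf, "removed")
  for (r in seq_len(nrow(rem)))
    message(sprintf("filter: dropped %s (%s)", rem$dropped[r],
                    rem$reason[r]))
  tr <- act$partition == "train"
  gcfg <- do.call(ga_config, utils::modifyList(list(seed = cfg$seed),
                                               cfg$ga))
  sel <- ga_select(xf[tr, , drop = FALSE], act$pic50[tr], gcfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_model_json(sel$model, file.path(out_dir, "model.json"),
                   extra = list(ga = unclass(gcfg), selected = sel$names,
                                fitness = sel$fitness))
  train_rep <- qsar_validate(act$pic50[tr], predict(sel$model),
                             p = length(sel$names))
  write_validation_report(train_rep, file.path(out_dir,
                                               "validation_train.json"))
  test_rep <- NULL
  if (any(!tr)) {
    test_rep <- qsar_validate(act$pic50[!tr],
                              predict(sel$model, xf[!tr, , drop = FALSE]),
                              p = length(sel$names))
    write_validation_report(test_rep, file.path(out_dir,
                                                "validation_test.json"))
  }
  write_pipeline_config(cfg, file.path(out_dir, "config_resolved.yaml"))
  invisible(list(selection = sel, train = train_rep, test = test_rep))
}

#' Pipeline stage: similarity screening and candidate ranking
#'
#' Fingerprints the seed set and the candidate library, clusters the
#' library, retains compounds whose best-seed Tanimoto similarity exceeds
#' the threshold, predicts their pIC50 with the supplied model and writes
#' the ranked hits CSV.
#'
#' @param model A [qsar_model()] or path to a model JSON.
#' @param seeds Path to the seed structures (SMILES/SDF).
#' @param library Path to the library structures.
#' @param out Output hits CSV path.
#' @param fs_threshold Strict FS cutoff (default 0.8).
#' @param cluster_k Cluster count (default \code{min(40, n)}).
#' @param top_n Optional row cap after ranking.
#' @param seed Integer seed for clustering.
#' @return The ranked hits data frame, invisibly.
#' @export
run_screen_stage <- function(model, seeds, library, out,
                             fs_threshold = 0.8, cluster_k = 40,
                             top_n = NULL, seed = 20230807) {
  if (is.character(model)) model <- read_model_json(model)
  seed_mols <- read_structures(seeds)
  lib_mols <- read_structures(library)
  seed_fps <- lapply(seed_mols, morgan_fingerprint)
  lib_fps <- lapply(lib_mols, morgan_fingerprint)
  cl <- cluster_library(lib_fps, k = min(cluster_k, length(lib_fps)),
                        seed = seed)
  hits <- enrich_library(seed_fps, lib_fps, threshold = fs_threshold,
                         clustering = cl)
  if (nrow(hits)) {
    lib_keep <- lib_mols[vapply(lib_mols, function(g)
      g$id %in% hits$id, logical(1))]
    desc <- compute_descriptor_matrix(lib_keep,
                                      names(model$coefficients))
    hits <- rank_candidates(hits, model, desc, top_n = top_n)
    dropped <- attr(hits, "dropped")
    for (r in seq_len(nrow(dropped)))
      message(sprintf("screen: dropped %s (%s)", dropped$id[r],
                      dropped$reason[r]))
  } else {
    hits$pic50_pre <- numeric(0)
    hits$ic50_pre_uM <- numeric(0)
  }
  write_hits(hits, out)
  invisible(hits)
}
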
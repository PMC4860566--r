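# Whole-pipeline orchestration: simulate (or load) a cohort, denoise, segment,
# smooth, flatten, extract the VOI and features, leave-one-out classify,
# post-process, and evaluate — reproducibly from one config and master seed.

take_args <- function(block, fn, name) {
  if (is.null(block)) return(list())
  allowed <- names(formals(fn))
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop(sprintf("unknown key(s) in config block '%s': %s",
                 name, paste(bad, collapse = ", ")))
  block
}

#' Pipeline configuration
#'
#' Collects every stage's parameter block plus the master seed. Unknown keys
#' in any block are rejected. Each block holds overrides for the matching
#' constructor defaults ([phantom_config()], [bilateral_params()],
#' [graph_search_params()], [vessel_detector_config()], ...).
#'
#' @param simulate list with `n_trauma` and `n_normal` to generate a phantom
#'   cohort, or `NULL` when `inputs` is given.
#' @param inputs optional data frame (columns `id`, `group`, `volume`,
#'   `truth`) naming volume and ground-truth mask files readable by
#'   [read_volume()] / [read_mask()].
#' @param phantom,bilateral,graph_search,tps,features,pca,adaboost,vessel,morphology
#'   per-stage parameter blocks (lists of overrides).
#' @param seed master integer seed for every source of randomness.
#' @param out_dir optional output directory for reports and the manifest.
#' @param verbose emit one structured log line per stage per eye.
#' @return A list of class `ez_pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(n_trauma = 4L, n_normal = 2L),
                            inputs = NULL,
                            phantom = list(), bilateral = list(),
                            graph_search = list(),
                            tps = list(regularization = 0.1),
                            features = list(n_levels = 8L),
                            pca = list(n_components = 10L),
                            adaboost = list(n_rounds = 100L),
                            vessel = list(),
                            morphology = list(element = "disk2d", radius = 5L),
                            seed = 1L, out_dir = NULL, verbose = FALSE) {
  if (is.null(simulate) && is.null(inputs))
    stop("config needs either a simulate block or inputs")
  if (!is.null(simulate))
    stopifnot(is.numeric(simulate$n_trauma), is.numeric(simulate$n_normal))
  take_args(phantom, phantom_config, "phantom")
  take_args(bilateral, bilateral_params, "bilateral")
  take_args(graph_search, graph_search_params, "graph_search")
  take_args(tps, smooth_surfaces_tps, "tps")
  take_args(features, extract_features, "features")
  take_args(pca, fit_pca, "pca")
  take_args(adaboost, train_adaboost, "adaboost")
  take_args(vessel, vessel_detector_config, "vessel")
  bad <- setdiff(names(morphology), c("element", "radius"))
  if (length(bad))
    stop(sprintf("unknown key(s) in config block 'morphology': %s",
                 paste(bad, collapse = ", ")))
  structure(list(simulate = simulate, inputs = inputs, phantom = phantom,
                 bilateral = bilateral, graph_search = graph_search,
                 tps = tps, features = features, pca = pca,
                 adaboost = adaboost, vessel = vessel,
                 morphology = morphology, seed = as.integer(seed),
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "ez_pipeline_config")
}

#' Read a pipeline config from JSON
#'
#' @param path JSON file with (a subset of) the [pipeline_config()] fields.
#' @return An `ez_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop(sprintf("unknown top-level config key(s): %s", paste(bad, collapse = ", ")))
  do.call(pipeline_config, raw)
}

#' Digest of a pipeline config
#'
#' MD5 of the canonical JSON serialisation of the scientific parameters;
#' embedded in every output so artifacts can be traced to the exact
#' configuration. Fields that only steer I/O (`out_dir`, `verbose`) are
#' excluded, so reruns of one analysis into different directories share a
#' digest.
#'
#' @param cfg an `ez_pipeline_config`.
#' @return Hex digest string.
#' @export
config_digest <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  core <- unclass(cfg)
  core$out_dir <- NULL
  core$verbose <- NULL
  jsonlite::write_json(core, tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}

plog <- function(cfg, stage, eye, ...) {
  if (cfg$verbose)
    message(sprintf("stage=%s eye=%s %s", stage, eye,
                    paste(sprintf("%s=%s", names(list(...)), list(...)),
                          collapse = " ")))
}

# Shift each A-scan of a logical array by the integer shifts used to flatten
# its volume (FALSE padding).
shift_columns_mask <- function(arr, shifts) {
  d <- dim(arr)
  out <- arr
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    s <- shifts[i, j]
    if (s == 0) next
    src <- seq_len(d[3]) + s
    ok <- src >= 1L & src <= d[3]
    col <- rep(FALSE, d[3])
    col[ok] <- arr[i, j, src[ok]]
    out[i, j, ] <- col
  }
  out
}

# Run preprocessing and feature extraction for one eye.
process_eye <- function(eye, cfg) {
  id <- eye$id
  bp <- do.call(bilateral_params, cfg$bilateral)
  gp <- do.call(graph_search_params, cfg$graph_search)
  den <- bilateral_filter_volume(eye$volume, bp)
  plog(cfg, "denoise", id)
  surf <- segment_surfaces(den, gp)
  plog(cfg, "segment", id)
  surf <- do.call(smooth_surfaces_tps,
                  c(list(s = surf, nz = den$nz), cfg$tps))
  fl <- flatten(den, surf)
  plog(cfg, "flatten", id, ref = median(round(surf$z_of[11, , ])))
  voi <- extract_voi(fl$volume, fl$surfaces)
  truth_flat <- if (!is.null(eye$truth))
    voxel_mask(shift_columns_mask(eye$truth$disruption_mask$values, fl$shifts),
               "ground_truth")
  else NULL
  fm <- do.call(extract_features, c(list(vol = fl$volume, voi = voi),
                                    cfg$features))
  y <- if (!is.null(truth_flat)) truth_flat$values[voi$values] else NULL
  plog(cfg, "features", id, voxels = nrow(fm$X),
       disrupted = if (is.null(y)) NA else sum(y))
  list(id = id, group = eye$group, volume_flat = fl$volume,
       surfaces = fl$surfaces, voi = voi, truth_flat = truth_flat,
       features = fm, X = fm$X, y = y)
}

labels_to_mask <- function(labels, fm, role = "disruption") {
  m <- array(FALSE, fm$dim)
  m[fm$voxels[labels, , drop = FALSE]] <- TRUE
  voxel_mask(m, role)
}

# Post-process one eye's raw predicted labels into the final disruption mask.
postprocess_eye <- function(pe, pred, cfg) {
  vcfg <- do.call(vessel_detector_config, cfg$vessel)
  raw <- labels_to_mask(pred, pe$features)
  proj <- en_face_projection(pe$volume_flat, pe$surfaces, vcfg$band)
  vessels <- detect_vessels(proj, vcfg)
  # drop detections wholly explained by a vessel, clean up, and only then
  # clear the remaining vessel-overlapping columns: a vessel crossing a real
  # lesion must not fragment its footprint before the size filtering
  m <- remove_vessel_detections(raw, vessels, clear_overlap = FALSE)
  m <- morphological_cleanup(m, element = cfg$morphology$element,
                             radius = cfg$morphology$radius, voi = pe$voi)
  m <- remove_vessel_detections(m, vessels, rule = "columns")
  plog(cfg, "postprocess", pe$id, raw = sum(raw$values), final = sum(m$values))
  list(mask = m, vessels = vessels, raw = raw)
}

#' Run the full EZ disruption detection pipeline
#'
#' Executes simulate (or load) -> denoise -> segment -> smooth -> flatten ->
#' VOI -> features -> leave-one-out (PCA + under-sample + AdaBoost) ->
#' post-process -> evaluate. Fully reproducible given the master seed. When
#' the cohort contains no disrupted ground-truth voxels at all (e.g. a
#' normal-only cohort), the supervised classifier cannot be trained and a
#' fixed low-intensity rule (normalized intensity below 0.25) stands in, so
#' specificity is still measured.
#'
#' @param cfg an `ez_pipeline_config`.
#' @return A list of class `ez_pipeline_result`: `report` (an
#'   `ez_eval_report`), per-eye artifacts (`masks`, `vessel_maps`), the
#'   `config_digest`, and (when `out_dir` is set) the paths written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "ez_pipeline_config"))
  digest <- config_digest(cfg)

  cohort <- if (!is.null(cfg$simulate)) {
    pc <- do.call(phantom_config, cfg$phantom)
    generate_cohort(cfg$simulate$n_trauma, cfg$simulate$n_normal, pc,
                    seed = cfg$seed)
  } else {
    lapply(seq_len(nrow(cfg$inputs)), function(i) {
      row <- cfg$inputs[i, ]
      vol <- read_volume(row$volume)
      truth <- if (!is.null(row$truth) && nzchar(row$truth))
        list(disruption_mask = read_mask(row$truth, role = "ground_truth"))
      else list(disruption_mask = voxel_mask(array(FALSE, dim(vol$intensities)),
                                             "ground_truth"))
      list(id = row$id, group = row$group, volume = vol, truth = truth)
    })
  }

  eyes <- lapply(cohort, process_eye, cfg = cfg)

  any_disrupted <- any(vapply(eyes, function(e) sum(e$y) > 0, TRUE))
  preds <- if (any_disrupted) {
    folds <- loo_cv(eyes,
                    n_rounds = if (!is.null(cfg$adaboost$n_rounds))
                      cfg$adaboost$n_rounds else 100L,
                    seed = cfg$seed,
                    n_components = if (!is.null(cfg$pca$n_components))
                      cfg$pca$n_components else 10L)
    lapply(folds, `[[`, "pred")
  } else {
    lapply(eyes, function(e) e$X[, 1] < 0.25)
  }

  per_eye <- vector("list", length(eyes))
  masks <- vessel_maps <- vector("list", length(eyes))
  for (i in seq_along(eyes)) {
    pe <- eyes[[i]]
    pp <- postprocess_eye(pe, preds[[i]], cfg)
    masks[[i]] <- pp$mask; vessel_maps[[i]] <- pp$vessels
    cc <- confusion(pp$mask, pe$truth_flat, pe$voi)
    vs <- cohort[[i]]$volume$voxel_size_um
    per_eye[[i]] <- list(
      id = pe$id, group = pe$group,
      tp = cc[["tp"]], fp = cc[["fp"]], tn = cc[["tn"]], fn = cc[["fn"]],
      detected_volume = disruption_volume(pp$mask, vs),
      truth_volume = disruption_volume(pe$truth_flat, vs),
      ez_volume = disruption_volume(pe$voi, vs))
  }
  report <- eval_report(per_eye)

  paths <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- write_report(report, cfg$out_dir, digest)
  }
  structure(list(report = report, masks = masks, vessel_maps = vessel_maps,
                 eyes = lapply(eyes, function(e)
                   e[c("id", "group", "surfaces", "voi")]),
                 config_digest = digest, paths = paths),
            class = "ez_pipeline_result")
}

#' Write an evaluation report as JSON and per-eye CSV
#'
#' @param report an `ez_eval_report`.
#' @param out_dir output directory.
#' @param digest config digest embedded in the JSON and the manifest.
#' @return Named character vector of the files written.
#' @export
write_report <- function(report, out_dir, digest = "") {
  json_path <- file.path(out_dir, "evaluation.json")
  csv_path <- file.path(out_dir, "per_eye.csv")
  payload <- list(config_digest = digest,
                  per_eye = report$per_eye,
                  summaries = report$summaries)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  utils::write.csv(report$per_eye, csv_path, row.names = FALSE)
  manifest <- file.path(out_dir, "manifest.json")
  files <- c(evaluation = json_path, per_eye = csv_path)
  jsonlite::write_json(
    list(config_digest = digest,
         artifacts = data.frame(name = names(files), path = unname(files),
                                md5 = unname(tools::md5sum(files)))),
    manifest, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  c(files, manifest = manifest)
}

#' @export
print.ez_pipeline_result <- function(x, ...) {
  cat(sprintf("<ez_pipeline_result> config %s\n", substr(x$config_digest, 1, 8)))
  print(x$report)
  invisible(x)
}
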
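#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis (generate or load data and
#' network, record states, binarize, search, attribute, knockout, report)
#' into one validated list. All randomness in a run flows from `seed`.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param mode `"planted"` (analytic composite, no training) or `"trained"`
#'   (one-versus-rest sub-networks trained and composed).
#' @param n_classes,n_features,n_samples,noise Pattern-dataset parameters
#'   (see [generate_pattern_dataset()]).
#' @param n_inert Inert hidden nodes appended to the planted network.
#' @param method Binarization method, `"kmeans"` or `"median"`.
#' @param epsilon Minimal-set threshold (see [minimal_set()]).
#' @param classes Classes to analyse (default all).
#' @param network_path,dataset_path Optional paths to a network JSON and a
#'   dataset CSV; when both are given they replace the generated fixtures.
#' @param train Optional [train_config()] overrides for `mode = "trained"`,
#'   as a named list.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, mode = c("planted", "trained"),
                            n_classes = 4L, n_features = 16L,
                            n_samples = 2000L, noise = 0.02, n_inert = 2L,
                            method = c("kmeans", "median"), epsilon = 0.05,
                            classes = NULL, network_path = NULL,
                            dataset_path = NULL, train = list()) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), mode = mode,
         n_classes = as.integer(n_classes), n_features = as.integer(n_features),
         n_samples = as.integer(n_samples), noise = noise,
         n_inert = as.integer(n_inert), method = method, epsilon = epsilon,
         classes = classes, network_path = network_path,
         dataset_path = dataset_path, train = train),
    class = "pipeline_config"
  )
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the full relay-analysis pipeline
#'
#' Executes, in order: fixture generation (or loading), network construction
#' (planted composite or trained sub-networks composed), state recording,
#' binarization, per-class greedy search, minimal sets, attribution,
#' knockout panel and regression, and writes every artifact to
#' `config$out_dir`:
#' \itemize{
#'   \item `dataset.csv`, `network.json`, `discrete_states.csv`,
#'     `binarizer.json`
#'   \item `trace_class<i>.csv` (step, node, I_R before/after, delta)
#'   \item `attribution_delta.csv`, `attribution_aggregated.csv`,
#'     `attribution_essentiality.csv`, `attribution_rank.csv`
#'     (nodes x classes)
#'   \item `minimal_sets.json`, `knockout_panel.csv`, `regression.json`
#'   \item `manifest.json` (config echo, package version, per-stage wall
#'     time, md5 checksums of every output file)
#' }
#' Re-running with an identical configuration and seed reproduces every
#' numeric output byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  path <- function(f) file.path(config$out_dir, f)

  # --- fixtures -------------------------------------------------------------
  fixtures <- clock("fixtures", {
    if (!is.null(config$network_path) && !is.null(config$dataset_path)) {
      net <- read_network_json(config$network_path)
      dataset <- read_dataset_csv(config$dataset_path)
      list(network = net, dataset = dataset,
           relay_map = attr(net, "relay_map"))
    } else {
      dataset <- generate_pattern_dataset(
        config$n_classes, config$n_features, config$n_samples,
        noise = config$noise, seed = config$seed
      )
      if (config$mode == "planted") {
        planted <- make_planted_relay_network(
          config$n_classes, config$n_features, n_inert = config$n_inert
        )
        list(network = planted$network, dataset = dataset,
             relay_map = planted$relay_map)
      } else {
        cfg_args <- utils::modifyList(
          list(target_accuracy = 0.98, max_epochs = 200L, seed = config$seed),
          config$train
        )
        subnets <- lapply(0:(config$n_classes - 1L), function(cl) {
          cfg_args$seed <- cfg_args$seed + cl
          train_subnetwork(dataset, cl, n_hidden = 2L,
                           cfg = do.call(train_config, cfg_args))$network
        })
        net <- compose_networks(subnets)
        list(network = net, dataset = dataset,
             relay_map = attr(net, "relay_map"))
      }
    }
  })
  write_dataset_csv(fixtures$dataset, path("dataset.csv"))
  write_network_json(fixtures$network, path("network.json"))

  # --- states and discretization -------------------------------------------
  disc <- clock("discretize", {
    states <- record_states(fixtures$network, fixtures$dataset)
    binarizer <- fit_binarizer(states, method = config$method)
    list(table = binarize(states, binarizer), binarizer = binarizer)
  })
  table <- disc$table
  write_discrete_csv(table, path("discrete_states.csv"))
  .write_json(unclass(disc$binarizer), path("binarizer.json"))

  # --- search and attribution ----------------------------------------------
  classes <- config$classes
  if (is.null(classes)) classes <- 0:(table$n_classes - 1L)
  report <- clock("attribution", attribution_report(table, classes = classes))
  for (cl in names(report$traces)) {
    utils::write.csv(report$traces[[cl]]$steps,
                     path(sprintf("trace_class%s.csv", cl)), row.names = FALSE)
  }
  for (m in c("delta", "aggregated", "essentiality", "rank")) {
    utils::write.csv(data.frame(node = seq_len(nrow(report[[m]])), report[[m]],
                                check.names = FALSE),
                     path(sprintf("attribution_%s.csv", m)), row.names = FALSE)
  }
  minimal <- clock("minimal_sets", {
    lapply(report$traces, function(tr) {
      ms <- minimal_set(tr, epsilon = config$epsilon)
      list(nodes = as.integer(ms), ir = attr(ms, "ir"),
           ir_full = attr(ms, "ir_full"))
    })
  })
  .write_json(list(epsilon = config$epsilon, minimal_sets = minimal),
              path("minimal_sets.json"))

  # --- knockout validation --------------------------------------------------
  panel <- clock("knockout", {
    build_knockout_panel(fixtures$network, fixtures$dataset, report$traces)
  })
  utils::write.csv(panel, path("knockout_panel.csv"), row.names = FALSE)
  regression <- regression_analysis(panel)
  .write_json(unclass(regression), path("regression.json"))

  # --- manifest -------------------------------------------------------------
  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    package = "relaytrace",
    version = as.character(utils::packageVersion("relaytrace")),
    config = unclass(config),
    relay_map = fixtures$relay_map,
    timings_seconds = timings,
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(path(f))),
           bytes = file.size(path(f)))
    })
  )
  .write_json(manifest, path("manifest.json"))
  invisible(manifest)
}

#' Read a pipeline configuration from JSON
#'
#' @param path Path to a JSON file with [pipeline_config()] fields.
#' @param ... Overrides applied after reading.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  obj <- utils::modifyList(obj, list(...))
  do.call(pipeline_config, obj)
}
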
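#' Run configuration
#'
#' A declarative description of a complete generation run - policy, search
#' settings, objective set and output locations - as a plain nested list
#' that round-trips losslessly through YAML.  Unknown keys are errors, so a
#' typo in a configuration file fails loudly instead of being silently
#' ignored.
#'
#' Sections (all optional except `objectives`):
#' \describe{
#'   \item{seed}{integer master seed; overrides the per-section seeds.}
#'   \item{policy}{`kind` (`"ngram"`, `"recurrent"` or `"file"`), plus
#'     `corpus` (path or inline character vector) for the trainable kinds,
#'     `path` for `"file"`, `order`/`alpha` for `"ngram"`, and the
#'     [policy_config()] fields for `"recurrent"`.}
#'   \item{search}{the [search_config()] fields (`c`, `z`,
#'     `max_iterations`, `max_length`, `expansion_prob_floor`,
#'     `checkpoint_schedule`, `max_seconds`, `seed`).}
#'   \item{objectives}{`components`, a list of entries each with a `kind`
#'     (`"qed"`, `"toxicity"`, `"docking"`, `"mock_docking"`,
#'     `"mock_toxicity"` or `"constant"`) and kind-specific fields
#'     (`name`, `baseline`, `value`, and for `"docking"` the `receptor`,
#'     `center`, `size`, `exhaustiveness` of a [docking_config()]);
#'     plus `validity` (`"chem"`/`"all"`), `sa` (`"chem"`/`"mock"`/
#'     `"none"`) and `sa_threshold`.}
#'   \item{output}{`dir` plus optional file names `log`, `front`,
#'     `metrics`, `manifest`, `policy`.}
#' }
#'
#' @param x nested list (e.g. parsed YAML).
#' @return a validated list of class `momcts_run_config`.
#' @export
run_config <- function(x = list()) {
  check_keys(x, c("seed", "policy", "search", "objectives", "output"), "config")
  check_keys(x$policy, c("kind", "corpus", "path", "order", "alpha",
                         "embedding_dim", "hidden_dim", "num_recurrent_layers",
                         "learning_rate", "batch_size", "epochs",
                         "max_length", "seed"), "policy")
  check_keys(x$search, c("c", "z", "max_iterations", "max_length",
                         "expansion_prob_floor", "checkpoint_schedule",
                         "max_seconds", "seed"), "search")
  check_keys(x$objectives, c("components", "validity", "sa", "sa_threshold"),
             "objectives")
  for (comp in x$objectives$components) {
    check_keys(comp, c("kind", "name", "baseline", "value", "receptor",
                       "center", "size", "exhaustiveness", "vina", "obabel"),
               "objective component")
    if (is.null(comp[["kind"]])) {
      momcts_error("every objective component needs a 'kind'",
                   "momcts_config_error")
    }
  }
  if (!length(x$objectives$components)) {
    momcts_error("config needs objectives$components with at least one entry",
                 "momcts_config_error")
  }
  check_keys(x$output, c("dir", "log", "front", "metrics", "manifest",
                         "policy"), "output")
  structure(x, class = "momcts_run_config")
}

check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible(NULL))
  if (!is.list(x)) {
    momcts_error(sprintf("'%s' section must be a mapping", where),
                 "momcts_config_error")
  }
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    momcts_error(sprintf("unknown %s key(s): %s", where,
                         paste(bad, collapse = ", ")),
                 "momcts_config_error")
  }
  invisible(NULL)
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    momcts_error(sprintf("config file not found: %s", path),
                 "momcts_config_error")
  }
  run_config(yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config a `momcts_run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.momcts_run_config <- function(x, ...) {
  cat("<run config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

# ---------------------------------------------------------------------------

policy_from_config <- function(config, quiet = TRUE) {
  pc <- config$policy %||% list()
  kind <- pc[["kind"]] %||% "ngram"
  seed <- config$seed %||% pc[["seed"]] %||% 1L
  if (kind == "file") {
    if (is.null(pc[["path"]])) momcts_error("policy kind 'file' needs 'path'",
                                       "momcts_config_error")
    return(load_policy(pc[["path"]]))
  }
  if (is.null(pc[["corpus"]])) {
    momcts_error(sprintf("policy kind '%s' needs a 'corpus'", kind),
                 "momcts_config_error")
  }
  if (kind == "ngram") {
    ngram_policy(pc[["corpus"]], order = pc[["order"]] %||% 3L, alpha = pc[["alpha"]] %||% 0)
  } else if (kind == "recurrent") {
    cfg <- policy_config(
      embedding_dim = pc[["embedding_dim"]] %||% 81L,
      hidden_dim = pc[["hidden_dim"]] %||% 256L,
      num_recurrent_layers = pc[["num_recurrent_layers"]] %||% 2L,
      learning_rate = pc[["learning_rate"]] %||% 0.01,
      batch_size = pc[["batch_size"]] %||% 256L,
      epochs = pc[["epochs"]] %||% 100L,
      max_length = pc[["max_length"]] %||% 100L,
      seed = seed)
    train_policy(pc[["corpus"]], cfg, verbose = !quiet)
  } else {
    momcts_error(sprintf("unknown policy kind '%s'", kind),
                 "momcts_config_error")
  }
}

objectives_from_config <- function(config) {
  oc <- config$objectives
  specs <- lapply(oc[["components"]], function(comp) {
    switch(comp[["kind"]],
      qed = objective_qed(name = comp[["name"]] %||% "qed"),
      toxicity = ,
      mock_toxicity = objective_mock_toxicity(name = comp[["name"]] %||% "toxicity"),
      mock_docking = objective_mock_docking(baseline = comp[["baseline"]] %||% 0,
                                            name = comp[["name"]] %||% "docking"),
      docking = {
        args <- list(receptor = comp[["receptor"]], center = unlist(comp[["center"]]),
                     size = unlist(comp[["size"]]),
                     exhaustiveness = comp[["exhaustiveness"]] %||% 1L)
        if (!is.null(comp[["vina"]])) args$vina <- comp[["vina"]]
        if (!is.null(comp[["obabel"]])) args$obabel <- comp[["obabel"]]
        objective_docking(do.call(docking_config, args),
                          baseline = comp[["baseline"]] %||% 0,
                          name = comp[["name"]] %||% "docking")
      },
      constant = objective_constant(value = comp[["value"]] %||% 1,
                                    name = comp[["name"]] %||% "constant"),
      momcts_error(sprintf("unknown objective kind '%s'", comp[["kind"]]),
                   "momcts_config_error"))
  })
  objective_set(specs,
                validity = oc[["validity"]] %||% "chem",
                sa = oc[["sa"]] %||% "chem",
                sa_threshold = oc[["sa_threshold"]] %||% 3.5)
}

search_from_config <- function(config) {
  sc <- config$search %||% list()
  search_config(
    c = sc[["c"]] %||% 1,
    z = if (!is.null(sc[["z"]])) unlist(sc[["z"]]) else NULL,
    max_iterations = sc[["max_iterations"]] %||% 1000L,
    max_length = sc[["max_length"]] %||% 60L,
    expansion_prob_floor = sc[["expansion_prob_floor"]] %||% 1e-3,
    checkpoint_schedule = unlist(sc[["checkpoint_schedule"]] %||% c(100L, 500L, 1000L)),
    max_seconds = sc[["max_seconds"]] %||% Inf,
    seed = config$seed %||% sc[["seed"]] %||% 1L)
}

#' Run a full generation experiment from a configuration
#'
#' Builds (or loads) the rollout policy, assembles the objective set and
#' search settings, runs the tree search, and - when an output directory is
#' configured - writes the generation log (CSV), Pareto front (CSV),
#' generation metrics (JSON) and run manifest (JSON).
#'
#' @param config a [run_config()], a nested list, or a YAML file path.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `run` (the `momcts_run`), `policy`,
#'   `metrics`, and `paths` (named vector of files written, possibly empty).
#' @export
run_from_config <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  } else if (!inherits(config, "momcts_run_config")) {
    config <- run_config(config)
  }
  say <- function(...) if (!quiet) message(sprintf(...))

  say("building policy ...")
  policy <- policy_from_config(config, quiet = quiet)
  objset <- objectives_from_config(config)
  scfg <- search_from_config(config)

  say("searching (%d iterations) ...", scfg$max_iterations)
  run <- run_search(scfg, policy, objset)

  corpus <- config$policy[["corpus"]] %||% character(0)
  metrics <- compute_metrics(run, training_corpus = corpus)

  paths <- character(0)
  out <- config$output
  if (!is.null(out[["dir"]])) {
    dir.create(out[["dir"]], recursive = TRUE, showWarnings = FALSE)
    p <- function(name, default) file.path(out[["dir"]], out[[name]] %||% default)
    paths <- c(
      log = write_generation_log(run, p("log", "generation_log.csv")),
      front = write_front(run$front, p("front", "pareto_front.csv"),
                          component_names = vapply(objset$specs, `[[`, "", "name")),
      metrics = write_metrics(metrics, p("metrics", "metrics.json")),
      manifest = write_run_manifest(run, policy, p("manifest", "manifest.json")))
    if (!is.null(out[["policy"]])) {
      paths <- c(paths, policy = save_policy(policy, file.path(out[["dir"]], out[["policy"]])))
    }
    say("wrote %d output files to %s", length(paths), out[["dir"]])
  }
  invisible(list(run = run, policy = policy, metrics = metrics, paths = paths))
}
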
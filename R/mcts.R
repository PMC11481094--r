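#' Search configuration
#'
#' @param c exploration constant(s): either a scalar applied to every reward
#'   component or a vector with one constant per component.
#' @param z hypervolume reference point; default the origin (all rewards are
#'   shaped into `[0, 1]`, so the origin is always dominated).
#' @param max_iterations number of selection/expansion/simulation/
#'   backpropagation cycles.
#' @param max_length maximum sequence length in tokens (sentinels included).
#' @param expansion_prob_floor minimum policy probability for a token to be
#'   an expansion candidate (prevents a full vocabulary-wide branch at every
#'   node).
#' @param checkpoint_schedule molecule counts at which Pareto-front
#'   snapshots are recorded.
#' @param max_seconds optional wall-clock budget; the iteration budget is
#'   the default so runs are reproducible.
#' @param seed seed fixing selection tie-breaks and rollout sampling.
#' @return a list of class `momcts_search_config`.
#' @export
search_config <- function(c = 1, z = NULL, max_iterations = 1000L,
                          max_length = 60L, expansion_prob_floor = 1e-3,
                          checkpoint_schedule = c(100L, 500L, 1000L),
                          max_seconds = Inf, seed = 1L) {
  if (any(c <= 0)) momcts_error("exploration constants must be positive", "momcts_domain_error")
  if (!is_count(max_iterations)) momcts_error("max_iterations must be >= 1", "momcts_domain_error")
  if (!is_count(max_length) || max_length < 3) {
    momcts_error("max_length must be an integer >= 3", "momcts_domain_error")
  }
  structure(list(c = as.numeric(c), z = z,
                 max_iterations = as.integer(max_iterations),
                 max_length = as.integer(max_length),
                 expansion_prob_floor = expansion_prob_floor,
                 checkpoint_schedule = sort(unique(as.integer(checkpoint_schedule))),
                 max_seconds = max_seconds,
                 seed = as.integer(seed)),
            class = "momcts_search_config")
}

# ---------------------------------------------------------------------------
# Tree nodes are environments (mutable, parent/child references).

new_node <- function(token, parent = NULL) {
  node <- new.env(parent = emptyenv())
  node$token <- token
  node$parent <- parent
  node$children <- list()
  node$n <- 0L
  node$n_end <- 0L          # simulations whose path ended at this node
  node$mean <- NULL         # running mean reward vector, set on first visit
  node$candidates <- NULL   # not-yet-instantiated expansion tokens
  node$expanded <- FALSE    # TRUE once no expansion candidates remain
  node$terminal <- !is.null(token) && token == END_TOKEN
  node$depth <- if (is.null(parent)) 1L else parent$depth + 1L
  node
}

node_tokens <- function(node) {
  toks <- character(node$depth)
  cur <- node
  for (i in seq(node$depth, 1L)) {
    toks[i] <- cur$token
    cur <- cur$parent
  }
  toks
}

#' Component-wise vector UCB
#'
#' `mean_reward_i + c_i * sqrt(2 * log(parent_visits) / n_s)`: the running
#' mean reward plus a per-component UCB1 exploration bonus.
#'
#' @param mean_reward node mean reward vector.
#' @param n_s node visit count (>= 1).
#' @param parent_visits visit count of the parent (>= `n_s`).
#' @param c exploration constant(s), scalar or per-component.
#' @return numeric vector of the same dimension as `mean_reward`.
#' @export
ucb_vector <- function(mean_reward, n_s, parent_visits, c = 1) {
  if (n_s < 1L) momcts_error("n_s must be >= 1", "momcts_domain_error")
  if (parent_visits < n_s) momcts_error("parent_visits must be >= n_s", "momcts_domain_error")
  mean_reward + c * sqrt(2 * log(parent_visits) / n_s)
}

#' Hypervolume-scalarized node value
#'
#' The scalar value used to rank children during selection: the UCB vector
#' is clipped into the unit box, then scored as the hypervolume of the
#' Pareto front with the clipped vector added when it is nondominated, or
#' the front hypervolume minus the Euclidean projection-distance penalty
#' when a front point dominates it.
#'
#' @param mean_reward,n_s,parent_visits,c as in [ucb_vector()].
#' @param front the current `momcts_pareto_front` (may be empty).
#' @param z reference point (default origin).
#' @return scalar value `W(s)`.
#' @export
node_value <- function(mean_reward, n_s, parent_visits, c, front,
                       z = rep(0, length(mean_reward))) {
  u <- unname(pmin(1, pmax(0, ucb_vector(mean_reward, n_s, parent_visits, c))))
  if (front_size(front) == 0L) return(prod(u - z))
  if (is_dominated_by_any(u, front$points)) {
    hypervolume(front, z) - projection_distance(u, front)
  } else {
    unname(hypervolume(rbind(front$points, u, deparse.level = 0), z))
  }
}

select_path <- function(root, front, cfg, z) {
  node <- root
  path <- list(node)
  while (node$expanded && length(node$children) && !node$terminal) {
    w <- vapply(node$children, function(ch) {
      if (ch$n == 0L) return(Inf)
      node_value(ch$mean, ch$n, node$n, cfg$c, front, z)
    }, 0)
    best <- which(w == max(w))
    pick <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
    node <- node$children[[pick]]
    path[[length(path) + 1L]] <- node
  }
  path
}

expand_node <- function(node, policy, cfg) {
  if (node$terminal) momcts_error("cannot expand a terminal node", "momcts_domain_error")
  vocab <- policy$vocabulary
  if (is.null(node$candidates)) {
    if (node$depth >= cfg$max_length - 1L) {
      node$candidates <- END_TOKEN
    } else {
      p <- next_token_distribution(policy, node_tokens(node))
      keep <- p >= cfg$expansion_prob_floor & names(p) != START_TOKEN
      cand <- names(p)[keep][order(p[keep], decreasing = TRUE)]
      if (!length(cand)) cand <- names(p)[which.max(p)]
      node$candidates <- cand
    }
  }
  if (!length(node$candidates)) {
    momcts_error("no expandable token remains", "momcts_no_expandable_token_error")
  }
  tok <- node$candidates[1L]
  node$candidates <- node$candidates[-1L]
  if (!length(node$candidates)) node$expanded <- TRUE
  child <- new_node(tok, parent = node)
  node$children[[length(node$children) + 1L]] <- child
  child
}

backpropagate <- function(path, r) {
  for (node in path) {
    node$n <- node$n + 1L
    if (is.null(node$mean)) node$mean <- numeric(length(r))
    node$mean <- node$mean + (r - node$mean) / node$n
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Simulation: complete the prefix, sanitize, filter, evaluate, archive.

simulate_node <- function(node, policy, objset, state, cfg, iteration) {
  toks <- node_tokens(node)
  truncated <- FALSE
  if (node$terminal) {
    full <- toks
  } else {
    rolled <- rollout(policy, toks, max_length = cfg$max_length)
    truncated <- isTRUE(attr(rolled, "truncated"))
    full <- rolled$tokens
  }
  smiles <- detokenize_chr(full)
  d <- length(objset$specs)
  zero <- numeric(d)
  rec <- list(iteration = iteration, smiles = smiles,
              canonical = NA_character_, valid = FALSE, passed_filter = FALSE,
              truncated = truncated, sascore = NA_real_,
              raw = rep(NA_real_, d), reward = zero, cached = FALSE)

  if (!nzchar(smiles)) return(list(record = rec, reward = zero))

  canonical <- if (exists(smiles, envir = state$raw2can, inherits = FALSE)) {
    get(smiles, envir = state$raw2can)
  } else {
    can <- tryCatch(obj_validity(objset, smiles)$canonical,
                    error = function(e) NA_character_)
    assign(smiles, can, envir = state$raw2can)
    can
  }
  if (is.na(canonical)) return(list(record = rec, reward = zero))

  rec$valid <- TRUE
  rec$canonical <- canonical
  key <- canonical
  if (exists(key, envir = state$evals, inherits = FALSE)) {
    ev <- get(key, envir = state$evals)
    rec$cached <- TRUE
    rec$sascore <- ev$sascore
    rec$passed_filter <- ev$passed_filter
    rec$raw <- ev$raw
    rec$reward <- ev$reward
    return(list(record = rec, reward = ev$reward))
  }

  sascore <- tryCatch(obj_sa(objset, canonical), error = function(e) NA_real_)
  passed <- if (objset$sa == "none") TRUE
            else if (is.na(sascore)) FALSE
            else sa_filter(sascore, objset$sa_threshold)
  rec$sascore <- sascore
  rec$passed_filter <- passed
  if (!passed) {
    assign(key, list(sascore = sascore, passed_filter = FALSE,
                     raw = rec$raw, reward = zero), envir = state$evals)
    return(list(record = rec, reward = zero))
  }

  ev <- evaluate_objectives(canonical, objset)
  if (isTRUE(ev$failed)) {
    # adapter failure: scored as invalid, not archived
    rec$valid <- FALSE
    rec$passed_filter <- FALSE
    return(list(record = rec, reward = zero))
  }
  rec$raw <- ev$raw
  rec$reward <- ev$reward
  assign(key, list(sascore = sascore, passed_filter = TRUE,
                   raw = ev$raw, reward = ev$reward), envir = state$evals)
  state$front <- update_front(state$front, ev$reward, canonical)
  state$n_molecules <- state$n_molecules + 1L
  list(record = rec, reward = ev$reward)
}

# ---------------------------------------------------------------------------

#' Run the multiobjective tree search
#'
#' Iterates selection (hypervolume-scalarized vector UCB), expansion (one
#' child per visit, candidates ordered by policy probability), simulation
#' (policy rollout, sanitization, synthetic-accessibility filter, objective
#' evaluation, Pareto-archive update) and vector backpropagation
#' (incremental mean).  Invalid or filtered rollouts backpropagate the zero
#' vector and count as visits.  Fully reproducible under a fixed seed with
#' deterministic objectives; an interrupt flushes partial results.
#'
#' @param cfg a [search_config()].
#' @param policy a trained policy ([train_policy()] or [ngram_policy()]).
#' @param objectives an [objective_set()].
#' @return an object of class `momcts_run`: list with `records` (one row
#'   per iteration), `front` (final `momcts_pareto_front`), `snapshots`
#'   (front copies at the checkpoint schedule), `config`, and counters.
#' @export
run_search <- function(cfg, policy, objectives) {
  if (!inherits(objectives, "momcts_objective_set")) {
    objectives <- objective_set(objectives, validity = "chem", sa = "chem")
  }
  d <- length(objectives$specs)
  z <- cfg$z %||% rep(0, d)
  if (length(z) != d) momcts_error("reference point dimension mismatch",
                                   "momcts_dimension_mismatch_error")
  cvec <- if (length(cfg$c) == 1L) rep(cfg$c, d) else cfg$c
  if (length(cvec) != d) momcts_error("exploration constant dimension mismatch",
                                      "momcts_dimension_mismatch_error")
  cfg$c <- cvec

  set.seed(cfg$seed)
  root <- new_node(START_TOKEN)
  state <- new.env(parent = emptyenv())
  state$front <- new_front(d)
  state$evals <- new.env(parent = emptyenv())
  state$raw2can <- new.env(parent = emptyenv())
  state$n_molecules <- 0L
  records <- vector("list", cfg$max_iterations)
  snapshots <- list()
  pending_checkpoints <- cfg$checkpoint_schedule
  t0 <- Sys.time()
  interrupted <- FALSE
  iter_done <- 0L

  tryCatch({
    for (iter in seq_len(cfg$max_iterations)) {
      if (as.numeric(Sys.time() - t0, units = "secs") > cfg$max_seconds) break
      path <- select_path(root, state$front, cfg, z)
      leaf <- path[[length(path)]]
      if (!leaf$terminal && leaf$depth < cfg$max_length) {
        child <- expand_node(leaf, policy, cfg)
        path[[length(path) + 1L]] <- child
        leaf <- child
      }
      sim <- simulate_node(leaf, policy, objectives, state, cfg, iter)
      leaf$n_end <- leaf$n_end + 1L
      backpropagate(path, sim$reward)
      records[[iter]] <- sim$record
      iter_done <- iter
      while (length(pending_checkpoints) &&
             state$n_molecules >= pending_checkpoints[1L]) {
        snapshots[[length(snapshots) + 1L]] <-
          list(molecules = pending_checkpoints[1L], iteration = iter,
               front = state$front,
               hypervolume = hypervolume(state$front, z))
        pending_checkpoints <- pending_checkpoints[-1L]
      }
    }
  }, interrupt = function(e) interrupted <<- TRUE)

  records <- records[seq_len(iter_done)]
  df <- records_to_df(records, objectives)
  if (nrow(df)) {
    on_front <- rep(FALSE, nrow(df))
    if (front_size(state$front)) {
      members <- unique(unlist(state$front$members))
      on_front <- !is.na(df$canonical) & df$canonical %in% members
    }
    df$on_front <- on_front
  }
  structure(list(records = df, front = state$front, snapshots = snapshots,
                 config = cfg, root = root, interrupted = interrupted,
                 n_molecules = state$n_molecules,
                 hypervolume = hypervolume(state$front, z), z = z),
            class = "momcts_run")
}

records_to_df <- function(records, objset) {
  if (!length(records)) {
    return(data.frame(iteration = integer(0), smiles = character(0)))
  }
  nm <- vapply(objset$specs, `[[`, "", "name")
  base <- data.frame(
    iteration = vapply(records, `[[`, 0L, "iteration"),
    smiles = vapply(records, `[[`, "", "smiles"),
    canonical = vapply(records, `[[`, "", "canonical"),
    valid = vapply(records, `[[`, TRUE, "valid"),
    passed_filter = vapply(records, `[[`, TRUE, "passed_filter"),
    truncated = vapply(records, `[[`, TRUE, "truncated"),
    cached = vapply(records, `[[`, TRUE, "cached"),
    sascore = vapply(records, `[[`, 0, "sascore"),
    stringsAsFactors = FALSE)
  for (j in seq_along(nm)) {
    base[[paste0("raw_", nm[j])]] <- vapply(records, function(r) r$raw[j], 0)
    base[[paste0("reward_", nm[j])]] <- vapply(records, function(r) r$reward[j], 0)
  }
  base
}

#' @export
print.momcts_run <- function(x, ...) {
  cat(sprintf(paste0("<momcts run: %d iterations, %d unique molecules, ",
                     "front size %d, hypervolume %.4f%s>\n"),
              nrow(x$records), x$n_molecules, front_size(x$front),
              x$hypervolume, if (x$interrupted) " (interrupted)" else ""))
  invisible(x)
}

#' Write the generation log
#'
#' One CSV row per search iteration with the completed SMILES, validity and
#' filter flags, raw objective values, shaped rewards and final-front
#' membership.
#'
#' @param run a `momcts_run`.
#' @param path output CSV path.
#' @export
write_generation_log <- function(run, path) {
  utils::write.csv(run$records, path, row.names = FALSE)
  invisible(path)
}

#' Write the run manifest
#'
#' Configuration, seed and policy fingerprint as JSON, so a run can be
#' attributed and repeated.
#'
#' @param run a `momcts_run`.
#' @param policy the policy used.
#' @param path output JSON path.
#' @export
write_run_manifest <- function(run, policy, path) {
  manifest <- list(
    config = unclass(run$config),
    n_iterations = nrow(run$records),
    n_molecules = run$n_molecules,
    hypervolume = run$hypervolume,
    policy = list(kind = policy$kind,
                  vocabulary_size = length(policy$vocabulary$tokens),
                  checksum = policy_checksum(policy)))
  manifest$config$max_seconds <- NULL
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

policy_checksum <- function(policy) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(policy$kind, policy$vocabulary$tokens,
               if (!is.null(policy$params)) policy$params else ls(policy$counts)),
          f)
  unname(tools::md5sum(f))
}
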
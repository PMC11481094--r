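test_that("the vector UCB matches the closed form", {
  u <- ucb_vector(c(0.5, 0.2), n_s = 2, parent_visits = 10, c = 1)
  bonus <- sqrt(2 * log(10) / 2)
  expect_equal(u, c(0.5, 0.2) + bonus, tolerance = 1e-12)
  u2 <- ucb_vector(c(0.5, 0.2), n_s = 2, parent_visits = 10, c = c(1, 2))
  expect_equal(u2, c(0.5 + bonus, 0.2 + 2 * bonus), tolerance = 1e-12)
  expect_error(ucb_vector(0.5, 0, 10), class = "momcts_domain_error")
  expect_error(ucb_vector(0.5, 5, 3), class = "momcts_domain_error")
})

test_that("node value adds hypervolume for nondominated UCB vectors", {
  front <- pareto_front(rbind(c(1, 0)))
  # parent_visits = n_s = 1 makes the exploration bonus exactly zero
  w <- node_value(c(0.5, 0.5), 1, 1, c = 1, front = front, z = c(0, 0))
  expect_equal(w, hypervolume(rbind(c(1, 0), c(0.5, 0.5)), c(0, 0)))
  expect_equal(w, 0.25)
})

test_that("node value penalizes dominated UCB vectors by projection distance", {
  front <- pareto_front(rbind(c(0.9, 0.9)))
  w <- node_value(c(0.1, 0.1), 1, 1, c = 1, front = front, z = c(0, 0))
  expect_equal(w, 0.81 - sqrt(2) * 0.8, tolerance = 1e-12)
})

test_that("UCB vectors are clipped into the unit box before scoring", {
  front <- pareto_front(rbind(c(0.5, 0.5)))
  # enormous bonus would push u far above 1 without clipping
  w <- node_value(c(0.9, 0.9), 1, 1000, c = 5, front = front, z = c(0, 0))
  expect_equal(w, 1)  # clipped to (1,1), hypervolume of the unit box
})

test_that("backpropagation keeps every node mean equal to the routed average", {
  root <- momcts:::new_node("&")
  a <- momcts:::new_node("C", root); root$children <- list(a)
  b <- momcts:::new_node("O", a); a$children <- list(b)
  paths <- list(list(root, a), list(root, a, b), list(root, a, b),
                list(root, a))
  set.seed(6)
  rewards <- replicate(length(paths), stats::runif(2), simplify = FALSE)
  seen <- list(root = list(), a = list(), b = list())
  for (i in seq_along(paths)) {
    momcts:::backpropagate(paths[[i]], rewards[[i]])
    for (node in paths[[i]]) {
      key <- if (identical(node, root)) "root" else if (identical(node, a)) "a" else "b"
      seen[[key]] <- c(seen[[key]], list(rewards[[i]]))
    }
  }
  for (key in names(seen)) {
    node <- switch(key, root = root, a = a, b = b)
    expect_equal(node$n, length(seen[[key]]))
    expect_equal(node$mean, Reduce(`+`, seen[[key]]) / length(seen[[key]]),
                 tolerance = 1e-12)
  }
})

test_that("ties between equal-valued children break uniformly at random", {
  cfg <- search_config(seed = 1)
  cfg$c <- c(1, 1)
  front <- new_front(2)
  root <- momcts:::new_node("&")
  for (tok in c("C", "O")) {
    ch <- momcts:::new_node(tok, root)
    ch$n <- 5L; ch$mean <- c(0.5, 0.5)
    root$children <- c(root$children, list(ch))
  }
  root$n <- 10L; root$expanded <- TRUE
  set.seed(123)
  picks <- replicate(1000, {
    path <- momcts:::select_path(root, front, cfg, c(0, 0))
    path[[2]]$token
  })
  frac <- mean(picks == "C")
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
})

test_that("with a constant second objective, ranking reduces to scalar UCB1", {
  # one informative objective plus a constant reward of 1: the
  # hypervolume-scalarized value of a clipped UCB vector (u1, 1) is exactly
  # u1, so child ranking must coincide with single-objective UCB1.
  front <- pareto_front(rbind(c(0.6, 1)))
  set.seed(8)
  for (trial in 1:20) {
    k <- sample(2:5, 1)
    means <- stats::runif(k)
    ns <- sample(1:20, k, replace = TRUE)
    parent <- sum(ns)
    w <- vapply(seq_len(k), function(i)
      node_value(c(means[i], 1), ns[i], parent, c = c(1, 1),
                 front = front, z = c(0, 0)), 0)
    scalar <- vapply(seq_len(k), function(i)
      min(1, ucb_vector(means[i], ns[i], parent, c = 1)), 0)
    expect_equal(order(w), order(scalar))
    expect_equal(w, scalar, tolerance = 1e-12)
  }
})

test_that("search visit counts are conserved across the tree", {
  sp <- toy_space()
  cfg <- search_config(max_iterations = 300, max_length = 8, seed = 3)
  run <- run_search(cfg, toy_policy(sp), toy_objective_set(sp))
  check <- function(node) {
    if (length(node$children)) {
      child_n <- sum(vapply(node$children, function(ch) ch$n, 0L))
      expect_equal(node$n, child_n + node$n_end)
      for (ch in node$children) check(ch)
    } else {
      expect_equal(node$n, node$n_end)
    }
  }
  check(run$root)
  expect_equal(run$root$n, nrow(run$records))
})

test_that("repeat molecules reuse cached evaluations", {
  sp <- toy_space()
  cfg <- search_config(max_iterations = 400, max_length = 8, seed = 4)
  run <- run_search(cfg, toy_policy(sp), toy_objective_set(sp))
  df <- run$records
  expect_true(any(df$cached))
  rc <- grep("^reward_", names(df), value = TRUE)
  for (can in unique(df$canonical[df$cached])) {
    rows <- df[!is.na(df$canonical) & df$canonical == can, rc, drop = FALSE]
    expect_true(all(vapply(rows, function(col) all(col == col[1]), TRUE)))
  }
  expect_equal(run$n_molecules,
               length(unique(df$canonical[df$valid & df$passed_filter])))
})

test_that("runs are reproducible under a fixed seed", {
  sp <- toy_space()
  cfg <- search_config(max_iterations = 200, max_length = 8, seed = 11)
  r1 <- run_search(cfg, toy_policy(sp), toy_objective_set(sp))
  r2 <- run_search(cfg, toy_policy(sp), toy_objective_set(sp))
  expect_identical(r1$records, r2$records)
  expect_identical(r1$front$points, r2$front$points)
  expect_identical(r1$hypervolume, r2$hypervolume)
})

test_that("checkpoints fire at the configured molecule counts", {
  sp <- toy_space()
  cfg <- search_config(max_iterations = 600, max_length = 8, seed = 5,
                       checkpoint_schedule = c(20, 50, 100))
  run <- run_search(cfg, toy_policy(sp), toy_objective_set(sp))
  got <- vapply(run$snapshots, `[[`, 0L, "molecules")
  expect_equal(got, c(20L, 50L, 100L)[seq_along(got)])
  expect_true(length(got) >= 1L)
})

test_that("invalid rollouts count visits but contribute zero reward", {
  sp <- toy_space(max_length = 2L)  # long rollouts fall outside the universe
  cfg <- search_config(max_iterations = 150, max_length = 8, seed = 2)
  run <- run_search(cfg, toy_policy(toy_space()), toy_objective_set(sp))
  df <- run$records
  expect_true(any(!df$valid))
  rc <- grep("^reward_", names(df), value = TRUE)
  for (col in rc) expect_true(all(df[[col]][!df$valid] == 0))
  expect_equal(run$root$n, nrow(df))
})

test_that("generation log and manifest are written faithfully", {
  sp <- toy_space()
  pol <- toy_policy(sp)
  cfg <- search_config(max_iterations = 100, max_length = 8, seed = 9)
  run <- run_search(cfg, pol, toy_objective_set(sp))
  log <- withr::local_tempfile(fileext = ".csv")
  man <- withr::local_tempfile(fileext = ".json")
  write_generation_log(run, log)
  df <- utils::read.csv(log, stringsAsFactors = FALSE)
  expect_equal(nrow(df), nrow(run$records))
  expect_true(all(c("iteration", "smiles", "valid", "on_front") %in% names(df)))
  write_run_manifest(run, pol, man)
  m <- jsonlite::fromJSON(man)
  expect_equal(m$config$seed, 9)
  expect_equal(m$n_molecules, run$n_molecules)
  expect_match(m$policy$checksum, "^[0-9a-f]{32}$")
})
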
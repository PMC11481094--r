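test_that("dominance follows the weak/strict definition", {
  expect_true(dominates(c(1, 1), c(0, 1)))
  expect_true(dominates(c(1, 1), c(0, 0)))
  expect_false(dominates(c(1, 1), c(1, 1)))   # equality never dominates
  expect_false(dominates(c(0, 1), c(1, 0)))   # incomparable
  expect_false(dominates(c(0, 1), c(1, 1)))
  expect_error(dominates(c(1, 1), c(1, 1, 1)),
               class = "momcts_dimension_mismatch_error")
})

test_that("pareto_front keeps exactly the nondominated points", {
  pts <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(0.2, 0.2))
  f <- pareto_front(pts, ids = c("a", "b", "c", "d"))
  expect_equal(nrow(f$points), 3L)
  expect_false("d" %in% unlist(f$members))
  # points with identical values are merged into one front point
  f2 <- pareto_front(rbind(c(1, 0), c(1, 0)), ids = c("x", "y"))
  expect_equal(nrow(f2$points), 1L)
  expect_setequal(f2$members[[1]], c("x", "y"))
})

test_that("pareto_front matches the all-pairs oracle on random sets", {
  set.seed(1)
  for (trial in 1:60) {
    d <- sample(2:3, 1)
    n <- sample(3:60, 1)
    pts <- matrix(round(stats::runif(n * d), 2), n, d)
    f <- pareto_front(pts)
    expect_equal(nrow(unique(f$points)),
                 nrow(unique(pts[oracle_front_indices(pts), , drop = FALSE])))
    for (i in seq_len(nrow(f$points))) {
      expect_true(any(apply(pts[oracle_front_indices(pts), , drop = FALSE], 1,
                            function(p) all(p == f$points[i, ]))))
    }
  }
})

test_that("incremental archive updates equal batch recomputation", {
  set.seed(2)
  for (trial in 1:20) {
    d <- sample(2:3, 1)
    n <- sample(2:40, 1)
    pts <- matrix(stats::runif(n * d), n, d)
    batch <- pareto_front(pts)
    inc <- new_front(d)
    for (i in sample(n)) inc <- update_front(inc, pts[i, ])
    expect_equal(inc$points[order(inc$points[, 1]), , drop = FALSE],
                 batch$points[order(batch$points[, 1]), , drop = FALSE])
  }
})

test_that("2-D hypervolume matches closed forms and inclusion-exclusion", {
  expect_equal(hypervolume(rbind(c(1, 1)), z = c(0, 0)), 1)
  expect_equal(hypervolume(rbind(c(1, 0.5), c(0.5, 1)), z = c(0, 0)), 0.75)
  set.seed(3)
  for (trial in 1:50) {
    n <- sample(1:4, 1)
    pts <- matrix(stats::runif(2 * n, 0.1, 1), n, 2)
    expect_equal(hypervolume(pts, z = c(0, 0)),
                 oracle_hv_incl_excl(pts, c(0, 0)), tolerance = 1e-12)
  }
})

test_that("d >= 3 hypervolume matches inclusion-exclusion exactly", {
  set.seed(4)
  for (d in 3:4) {
    for (trial in 1:20) {
      n <- sample(1:5, 1)
      pts <- matrix(stats::runif(d * n, 0.1, 1), n, d)
      expect_equal(hypervolume(pts, z = rep(0, d)),
                   oracle_hv_incl_excl(pts, rep(0, d)), tolerance = 1e-12)
    }
  }
})

test_that("hypervolume is monotone under point insertion", {
  set.seed(5)
  d <- 3
  f <- new_front(d)
  prev <- 0
  for (i in 1:40) {
    f <- update_front(f, stats::runif(d))
    h <- hypervolume(f, z = rep(0, d))
    expect_gte(h, prev - 1e-12)
    prev <- h
  }
})

test_that("hypervolume validates the reference point", {
  expect_error(hypervolume(rbind(c(0.5, 0.5)), z = c(0.6, 0)),
               class = "momcts_reference_not_dominated_error")
  expect_error(hypervolume(rbind(c(1, 1)), z = c(0, 0, 0)),
               class = "momcts_dimension_mismatch_error")
  expect_equal(hypervolume(new_front(2), z = c(0, 0)), 0)
})

test_that("projection distance is zero iff nondominated, else nearest-front", {
  f1 <- pareto_front(rbind(c(0.9, 0.9)))
  expect_equal(projection_distance(c(0.1, 0.1), f1),
               sqrt(2) * 0.8, tolerance = 1e-12)
  f <- pareto_front(rbind(c(1, 0), c(0, 1), c(0.9, 0.9)))
  expect_equal(projection_distance(c(0.95, 0.95), f), 0)
  expect_equal(projection_distance(c(0.9, 0.9), f), 0)
  # nearest front point wins: (1,0) is closer to (0.1,0.1) than (0.9,0.9)
  expect_equal(projection_distance(c(0.1, 0.1), f),
               sqrt(0.9^2 + 0.1^2), tolerance = 1e-12)
})

test_that("front export writes CSV and JSON with member lists", {
  f <- pareto_front(rbind(c(1, 0), c(0, 1)), ids = c("CCO", "CCN"))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_front(f, csv, component_names = c("a", "b"))
  write_front(f, js, component_names = c("a", "b"))
  df <- utils::read.csv(csv)
  expect_equal(names(df), c("a", "b", "members"))
  expect_setequal(df$members, c("CCO", "CCN"))
  expect_equal(nrow(jsonlite::fromJSON(js)), 2L)
})
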
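#' Pareto dominance between reward vectors
#'
#' Under the maximization convention, `x` dominates `y` when every component
#' of `x` is at least the corresponding component of `y` and at least one is
#' strictly larger.  A point never dominates itself.
#'
#' @param x,y numeric reward vectors of equal dimension.
#' @return logical.
#' @export
dominates <- function(x, y) {
  if (length(x) != length(y)) {
    momcts_error(sprintf("dimension mismatch: %d vs %d", length(x), length(y)),
                 "momcts_dimension_mismatch_error")
  }
  all(x >= y) && any(x > y)
}

#' Nondominated front of a set of reward vectors
#'
#' @param points a numeric matrix (one reward vector per row) or a list of
#'   numeric vectors of common dimension.
#' @param ids optional record identifiers, one per row; identical reward
#'   vectors from different records are merged into one front point carrying
#'   all their ids.
#' @return an object of class `momcts_pareto_front`: a list with `points`
#'   (matrix of distinct nondominated vectors, one per row) and `members`
#'   (list of character vectors of record ids per point, possibly empty).
#' @export
pareto_front <- function(points, ids = NULL) {
  pts <- as_reward_matrix(points)
  if (!nrow(pts)) momcts_error("empty point set", "momcts_domain_error")
  if (is.null(ids)) ids <- rep(NA_character_, nrow(pts))
  keep <- !vapply(seq_len(nrow(pts)), function(i) {
    is_dominated_by_any(pts[i, ], pts[-i, , drop = FALSE])
  }, logical(1))
  front <- empty_front(ncol(pts))
  for (i in which(keep)) front <- front_add_point(front, pts[i, ], ids[i])
  front
}

as_reward_matrix <- function(points) {
  if (is.list(points) && !is.data.frame(points)) {
    dims <- unique(vapply(points, length, 1L))
    if (length(dims) > 1L) {
      momcts_error("reward vectors have differing dimensions",
                   "momcts_dimension_mismatch_error")
    }
    points <- do.call(rbind, points)
  }
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (anyNA(pts) || any(!is.finite(pts))) {
    momcts_error("reward vectors must be finite", "momcts_domain_error")
  }
  pts
}

is_dominated_by_any <- function(x, pts) {
  if (!nrow(pts)) return(FALSE)
  ge <- pts >= rep(x, each = nrow(pts))
  gt <- pts > rep(x, each = nrow(pts))
  any(rowSums(ge) == ncol(pts) & rowSums(gt) > 0L)
}

empty_front <- function(d) {
  structure(list(points = matrix(numeric(0), 0, d), members = list()),
            class = "momcts_pareto_front")
}

front_size <- function(front) nrow(front$points)

front_add_point <- function(front, p, id = NA_character_) {
  # exact-duplicate vector: merge membership
  if (nrow(front$points)) {
    same <- which(apply(front$points, 1, function(q) all(q == p)))
    if (length(same)) {
      front$members[[same[1L]]] <- unique(c(front$members[[same[1L]]],
                                            id[!is.na(id)]))
      return(front)
    }
  }
  front$points <- rbind(front$points, p, deparse.level = 0)
  front$members[[nrow(front$points)]] <- id[!is.na(id)]
  front
}

#' Incrementally insert a reward vector into a nondominated archive
#'
#' If the new vector is dominated by (or equal to) an existing front point,
#' the front is unchanged apart from membership bookkeeping; otherwise the
#' vector joins the front and any points it dominates are evicted.  At every
#' moment the archive equals `pareto_front()` of all vectors ever inserted.
#'
#' @param front a `momcts_pareto_front` (use `empty_front` via
#'   [pareto_front()] of the first point, or insert into the front returned
#'   here).
#' @param r a numeric reward vector.
#' @param record_id optional identifier of the molecule achieving `r`.
#' @return the updated `momcts_pareto_front`.
#' @export
update_front <- function(front, r, record_id = NA_character_) {
  r <- as.numeric(r)
  if (anyNA(r) || any(!is.finite(r))) {
    momcts_error("reward vector must be finite", "momcts_domain_error")
  }
  if (!inherits(front, "momcts_pareto_front")) {
    momcts_error("front must be a momcts_pareto_front", "momcts_domain_error")
  }
  if (ncol(front$points) != length(r)) {
    momcts_error("dimension mismatch between front and reward vector",
                 "momcts_dimension_mismatch_error")
  }
  if (nrow(front$points) && is_dominated_by_any(r, front$points)) return(front)
  # evict points dominated by r
  if (nrow(front$points)) {
    dom <- vapply(seq_len(nrow(front$points)),
                  function(i) dominates(r, front$points[i, ]), logical(1))
    if (any(dom)) {
      front$points <- front$points[!dom, , drop = FALSE]
      front$members <- front$members[!dom]
    }
  }
  front_add_point(front, r, record_id)
}

#' @export
print.momcts_pareto_front <- function(x, ...) {
  cat(sprintf("<Pareto front: %d points, d = %d>\n", nrow(x$points), ncol(x$points)))
  if (nrow(x$points)) print(utils::head(x$points, 10))
  invisible(x)
}

#' New empty nondominated archive
#'
#' @param d reward dimension.
#' @export
new_front <- function(d) {
  if (!is_count(d)) momcts_error("d must be a positive integer", "momcts_domain_error")
  empty_front(as.integer(d))
}

#' Hypervolume indicator of a front
#'
#' The Lebesgue measure of the union of axis-aligned boxes spanned between
#' the reference point `z` and each front point (maximization convention).
#' Computed exactly: in one dimension the best improvement over `z`, in two
#' dimensions by the sorted staircase, in three or more by dimension-sweep
#' recursion over slabs of the last coordinate.
#'
#' @param front a `momcts_pareto_front`, matrix of points (rows) or list of
#'   vectors.  Dominated points may be present; they do not change the value.
#' @param z reference point, component-wise no larger than every point.
#' @return non-negative scalar.
#' @export
hypervolume <- function(front, z = NULL) {
  pts <- if (inherits(front, "momcts_pareto_front")) front$points else as_reward_matrix(front)
  d <- ncol(pts)
  if (is.null(z)) z <- rep(0, d)
  if (length(z) != d) {
    momcts_error("reference point dimension mismatch", "momcts_dimension_mismatch_error")
  }
  if (!nrow(pts)) return(0)
  if (any(pts < rep(z, each = nrow(pts)))) {
    momcts_error("every point must dominate the reference point component-wise",
                 "momcts_reference_not_dominated_error")
  }
  hv_rec(pts, z)
}

hv_rec <- function(pts, z) {
  d <- ncol(pts)
  if (d == 1L) return(max(pts[, 1]) - z[1])
  if (d == 2L) return(hv_staircase2d(pts, z))
  # dimension sweep on the last coordinate: integrate the (d-1)-dimensional
  # hypervolume of the points alive above each slab level
  o <- order(pts[, d], decreasing = TRUE)
  pts <- pts[o, , drop = FALSE]
  levels <- pts[, d]
  hv <- 0
  for (i in seq_len(nrow(pts))) {
    lower <- if (i < nrow(pts)) levels[i + 1L] else z[d]
    thick <- levels[i] - lower
    if (thick > 0) {
      alive <- pts[seq_len(i), -d, drop = FALSE]
      hv <- hv + thick * hv_rec(alive, z[-d])
    }
  }
  hv
}

# Staircase sweep: with points sorted by decreasing x, each point whose y
# improves on the running maximum contributes a rectangle of width (x - z1)
# and height (y - best_y so far).  Dominated points never improve best_y.
hv_staircase2d <- function(pts, z) {
  o <- order(pts[, 1], decreasing = TRUE)
  pts <- pts[o, , drop = FALSE]
  hv <- 0
  best_y <- z[2]
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, 1]; y <- pts[i, 2]
    if (y > best_y) {
      hv <- hv + (y - best_y) * (x - z[1])
      best_y <- y
    }
  }
  hv
}

#' Euclidean projection-distance penalty
#'
#' Distance from a reward vector to the Pareto front: zero when the vector is
#' nondominated with respect to the front, otherwise the Euclidean distance
#' to the nearest front point.  Used to discriminate among dominated
#' candidates without recomputing hypervolumes.
#'
#' @param r numeric reward vector.
#' @param front a `momcts_pareto_front` or matrix of front points.
#' @return non-negative scalar.
#' @export
projection_distance <- function(r, front) {
  pts <- if (inherits(front, "momcts_pareto_front")) front$points else as_reward_matrix(front)
  if (!nrow(pts)) momcts_error("front must be non-empty", "momcts_domain_error")
  if (ncol(pts) != length(r)) {
    momcts_error("dimension mismatch", "momcts_dimension_mismatch_error")
  }
  if (!is_dominated_by_any(r, pts)) return(0)
  sqrt(min(rowSums((pts - rep(r, each = nrow(pts)))^2)))
}

#' Export a Pareto front
#'
#' One row/object per front point: the reward components and the identifiers
#' of the molecules achieving that point.
#'
#' @param front a `momcts_pareto_front`.
#' @param path output file; format chosen by extension (`.csv` or `.json`).
#' @param component_names optional column names for the reward components.
#' @export
write_front <- function(front, path, component_names = NULL) {
  d <- ncol(front$points)
  if (is.null(component_names)) component_names <- paste0("reward_", seq_len(d))
  df <- as.data.frame(front$points)
  names(df) <- component_names
  df$members <- vapply(front$members, function(m) paste(m, collapse = ";"), "")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
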
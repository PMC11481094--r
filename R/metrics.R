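#' Generation-quality metrics
#'
#' Standard metrics for molecular generative models, computed over a
#' generation log:
#' \describe{
#'   \item{validity}{valid molecules / generated molecules.}
#'   \item{uniqueness}{unique canonical SMILES / valid molecules; duplicates
#'     are detected on canonical SMILES, so the same molecule written two
#'     ways counts once.}
#'   \item{duplication_ratio}{`1 - uniqueness`.}
#'   \item{novelty}{unique valid molecules absent from the training corpus /
#'     unique valid molecules.}
#'   \item{internal_diversity}{one minus the mean pairwise Tanimoto
#'     similarity of Morgan fingerprints (radius 2, 2048 bits) over the
#'     unique valid molecules; unordered pairs counted once, self-pairs
#'     excluded.  Fewer than two distinct molecules give zero diversity.}
#' }
#'
#' @param log a `momcts_run`, its `records` data.frame, or a data.frame with
#'   at least columns `valid` and `canonical` (e.g. read back from a
#'   generation log CSV).
#' @param training_corpus character vector of training SMILES (canonicalized
#'   internally), or a path to a SMILES line file.  Empty by default, which
#'   makes every molecule novel.
#' @return a list of class `momcts_metrics_report`.
#' @export
compute_metrics <- function(log, training_corpus = character(0)) {
  df <- if (inherits(log, "momcts_run")) log$records else as.data.frame(log)
  if (!nrow(df)) momcts_error("empty generation log", "momcts_empty_log_error")
  if (length(training_corpus) == 1L && !grepl("[&\n]", training_corpus) &&
      file.exists(training_corpus)) {
    training_corpus <- read_smiles_file(training_corpus)
  }
  n_generated <- nrow(df)
  valid <- df$valid & !is.na(df$canonical)
  n_valid <- sum(valid)
  uniq <- unique(df$canonical[valid])
  n_unique <- length(uniq)
  validity <- n_valid / n_generated
  uniqueness <- if (n_valid) n_unique / n_valid else 0
  duplication_ratio <- 1 - uniqueness
  novelty <- if (n_unique) {
    train_can <- if (length(training_corpus)) {
      can <- canonical_smiles(training_corpus)
      can[!is.na(can)]
    } else character(0)
    sum(!uniq %in% train_can) / n_unique
  } else 0
  internal_diversity <- internal_diversity(uniq)
  structure(list(n_generated = n_generated, n_valid = n_valid,
                 n_unique = n_unique, validity = validity,
                 uniqueness = uniqueness,
                 duplication_ratio = duplication_ratio, novelty = novelty,
                 internal_diversity = internal_diversity),
            class = "momcts_metrics_report")
}

#' Internal diversity of a molecule set
#'
#' @param smiles character vector of (ideally canonical, distinct) SMILES.
#' @return `1 - mean(pairwise Tanimoto)` over Morgan fingerprints; 0 when
#'   fewer than two molecules carry a fingerprint.
#' @export
internal_diversity <- function(smiles) {
  smiles <- unique(smiles[!is.na(smiles)])
  if (length(smiles) < 2L) return(0)
  fps <- morgan_fingerprints(smiles)
  fps <- fps[!vapply(fps, is.null, TRUE)]
  m <- length(fps)
  if (m < 2L) return(0)
  total <- 0
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) total <- total + tanimoto(fps[[i]], fps[[j]])
  }
  1 - total / (m * (m - 1L) / 2L)
}

#' @export
print.momcts_metrics_report <- function(x, ...) {
  cat(sprintf("generated: %d   valid: %d   unique: %d\n",
              x$n_generated, x$n_valid, x$n_unique))
  cat(sprintf("validity            %.4f\n", x$validity))
  cat(sprintf("uniqueness          %.4f\n", x$uniqueness))
  cat(sprintf("duplication ratio   %.4f\n", x$duplication_ratio))
  cat(sprintf("novelty             %.4f\n", x$novelty))
  cat(sprintf("internal diversity  %.4f\n", x$internal_diversity))
  invisible(x)
}

#' @rdname compute_metrics
#' @param report a `momcts_metrics_report`.
#' @param path output JSON path.
#' @export
write_metrics <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
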
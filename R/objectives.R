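#' Reward shaping for the search objectives
#'
#' Every objective produces a raw value (docking score in kcal/mol, QED,
#' toxicity probability, ...) and a reward transform mapping it into `[0, 1]`
#' under the maximization convention, so that the origin is always a valid
#' hypervolume reference point.  Transforms are deliberately isolated in
#' small exported functions.
#'
#' @name objectives
NULL

#' Docking-score reward
#'
#' `max(0, (baseline - ds) / (1 + |baseline - ds|))`: zero for scores at or
#' above the baseline, strictly decreasing in the docking score below it and
#' saturating toward 1 for strongly negative binding energies.  Monotone, so
#' it preserves the ordering of docking scores.
#'
#' @param ds docking score(s) in kcal/mol (lower is better binding).
#' @param baseline per-target base score; the default 0 treats any predicted
#'   binding as rewarding.
#' @return reward(s) in `[0, 1]`.
#' @export
reward_docking <- function(ds, baseline = 0) {
  if (any(!is.finite(ds))) momcts_error("docking score must be finite", "momcts_domain_error")
  impr <- baseline - ds
  pmax(0, impr / (1 + abs(impr)))
}

#' QED reward
#'
#' The QED desirability is already a `[0, 1]` drug-likeness score under the
#' maximization convention, so the reward is the QED value itself (clipped
#' defensively).
#'
#' @param qed QED value(s).
#' @return reward(s) in `[0, 1]`.
#' @export
reward_qed <- function(qed) {
  pmin(1, pmax(0, qed))
}

#' Toxicity reward
#'
#' The predictor returns the probability that the molecule is toxic; the
#' reward inverts it (`1 - p`) so that safer molecules score higher.
#'
#' @param p toxicity probability in `[0, 1]`.
#' @return reward(s) in `[0, 1]`.
#' @export
reward_toxicity <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    momcts_error("toxicity probability must lie in [0, 1]", "momcts_domain_error")
  }
  1 - p
}

#' Synthetic-accessibility filter
#'
#' Hard pass/fail on the synthetic accessibility score (1 easy .. 10 hard):
#' molecules pass if the score does not exceed the threshold (3.5, boundary
#' inclusive).  The score is a filter, not an objective.
#'
#' @param sascore score(s) in `[1, 10]`.
#' @param threshold filter threshold.
#' @return logical vector, `TRUE` = pass.
#' @export
sa_filter <- function(sascore, threshold = 3.5) {
  if (any(!is.finite(sascore)) || any(sascore < 1) || any(sascore > 10)) {
    momcts_error("SAscore must lie in [1, 10]", "momcts_domain_error")
  }
  sascore <= threshold
}

# ---------------------------------------------------------------------------
# Objective specifications

new_objective <- function(name, kind, compute, transform, params = list()) {
  structure(list(name = name, kind = kind, compute = compute,
                 transform = transform, params = params),
            class = "momcts_objective")
}

#' @export
print.momcts_objective <- function(x, ...) {
  cat(sprintf("<objective '%s' (%s)>\n", x$name, x$kind))
  invisible(x)
}

#' Objective constructors
#'
#' Each constructor returns an objective specification holding a `compute`
#' function (canonical SMILES -> raw value) and the reward transform.
#'
#' `objective_qed()` scores drug-likeness via the native QED model over
#' chemistry-backend descriptors.  `objective_toxicity()` wraps a pluggable
#' toxicity predictor (SMILES -> probability); the default is the
#' deterministic mock.  `objective_docking()` wraps an external docking
#' engine configured by [docking_config()]; when the engine binary is
#' absent the deterministic mock is substituted with a warning.
#' `objective_constant()` always returns the given value - with the value 1
#' it is the single-objective mode, where the vector search provably reduces
#' to scalar UCB1.  `objective_mock_docking()` and
#' `objective_mock_toxicity()` are deterministic, chemistry-free functions
#' of heavy-atom and ring counts for fully offline runs.
#'
#' @param name objective name used in logs.
#' @param baseline docking baseline score (kcal/mol).
#' @param predict function mapping a SMILES string to a toxicity probability.
#' @param config a [docking_config()].
#' @param value constant reward value in `[0, 1]`.
#' @return a `momcts_objective`.
#' @export
objective_qed <- function(name = "qed") {
  new_objective(name, "qed", compute = function(smiles) qed_score(smiles),
                transform = reward_qed)
}

#' @rdname objective_qed
#' @export
objective_toxicity <- function(predict = mock_toxicity_probability,
                               name = "toxicity") {
  new_objective(name, "toxicity", compute = function(smiles) predict(smiles),
                transform = reward_toxicity)
}

#' @rdname objective_qed
#' @export
objective_docking <- function(config, baseline = 0, name = "docking") {
  if (is.null(config$vina) || !nzchar(config$vina)) {
    warning("docking engine binary not found; substituting the deterministic mock")
    return(objective_mock_docking(baseline = baseline, name = name))
  }
  new_objective(name, "docking",
                compute = function(smiles) dock_molecule(smiles, config),
                transform = function(ds) reward_docking(ds, baseline),
                params = list(baseline = baseline, config = config))
}

#' @rdname objective_qed
#' @export
objective_constant <- function(value = 1, name = "constant") {
  stopifnot_scalar_prob(value, "constant objective value")
  new_objective(name, "constant", compute = function(smiles) value,
                transform = function(x) x, params = list(value = value))
}

#' @rdname objective_qed
#' @export
objective_mock_docking <- function(baseline = 0, name = "docking") {
  new_objective(name, "mock",
                compute = function(smiles) mock_docking_score(smiles),
                transform = function(ds) reward_docking(ds, baseline),
                params = list(baseline = baseline))
}

#' @rdname objective_qed
#' @export
objective_mock_toxicity <- function(name = "toxicity") {
  new_objective(name, "mock",
                compute = function(smiles) mock_toxicity_probability(smiles),
                transform = reward_toxicity)
}

# ---------------------------------------------------------------------------
# Deterministic mocks: smooth functions of coarse structural counts obtained
# by a vocabulary-free token scan, so offline runs need no chemistry backend.

smiles_structure_counts <- function(smiles) {
  toks <- scan_smiles_tokens(smiles)
  atom_like <- grepl("^\\[.*\\]$", toks) |
    toks %in% c("C", "c", "N", "n", "O", "o", "S", "s", "P", "F", "I", "Br", "Cl", "B", "p")
  atoms <- toks[atom_like]
  carbon <- atoms %in% c("C", "c") | grepl("^\\[[Cc][^l]", atoms)
  ringdig <- sum(toks %in% as.character(1:9)) + sum(grepl("^%[0-9]{2}$", toks))
  list(heavy = sum(atom_like),
       hetero_frac = if (any(atom_like)) mean(!carbon) else 0,
       rings = ringdig / 2)
}

#' Deterministic mock docking score
#'
#' A smooth, hash-free function of heavy-atom and ring counts: larger and
#' more cyclic molecules "dock" better, saturating around -12 kcal/mol.
#'
#' @param smiles character vector.
#' @return numeric docking scores (kcal/mol).
#' @export
mock_docking_score <- function(smiles) {
  vapply(smiles, function(s) {
    cc <- smiles_structure_counts(s)
    -12 * (1 - exp(-(0.35 * cc$heavy + 1.5 * cc$rings) / 8))
  }, 0, USE.NAMES = FALSE)
}

#' Deterministic mock toxicity probability
#'
#' A logistic function of heavy-atom count and heteroatom fraction standing
#' in for an external toxicity predictor in offline runs.
#'
#' @param smiles character vector.
#' @return probabilities in `[0, 1]`.
#' @export
mock_toxicity_probability <- function(smiles) {
  vapply(smiles, function(s) {
    cc <- smiles_structure_counts(s)
    stats::plogis(2.5 * cc$hetero_frac + 0.08 * cc$heavy - 2)
  }, 0, USE.NAMES = FALSE)
}

#' Deterministic mock synthetic-accessibility score
#'
#' @param smiles character vector.
#' @return scores in `[1, 10]`.
#' @export
mock_sa_score <- function(smiles) {
  vapply(smiles, function(s) {
    cc <- smiles_structure_counts(s)
    min(10, 1 + 0.14 * cc$heavy + 0.5 * cc$rings)
  }, 0, USE.NAMES = FALSE)
}

# ---------------------------------------------------------------------------
# Objective sets: the full evaluation context used by the search.

#' Bundle objectives with validity checking and the synthetic filter
#'
#' @param specs list of `momcts_objective`s (declared order fixes the reward
#'   vector component order).
#' @param validity `"chem"` for chemistry-toolkit sanitization, `"all"` to
#'   treat every completed string as valid, or a function mapping a string
#'   to its canonical form (`NA_character_` for invalid) for custom
#'   universes such as enumerable toy spaces.
#' @param sa `"chem"` for the fragment-based score, `"mock"` for the
#'   deterministic offline stand-in, `"none"` to disable the filter.
#' @param sa_threshold filter threshold (pass when score `<= threshold`).
#' @return an object of class `momcts_objective_set`.
#' @export
objective_set <- function(specs, validity = c("chem", "all"),
                          sa = c("chem", "mock", "none"), sa_threshold = 3.5) {
  if (!is.function(validity)) validity <- match.arg(validity)
  sa <- match.arg(sa)
  if (!length(specs)) momcts_error("at least one objective is required", "momcts_domain_error")
  if (inherits(specs, "momcts_objective")) specs <- list(specs)
  for (s in specs) {
    if (!inherits(s, "momcts_objective")) {
      momcts_error("specs must be momcts_objective objects", "momcts_domain_error")
    }
  }
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) momcts_error("objective names must be unique", "momcts_domain_error")
  structure(list(specs = specs, validity = validity, sa = sa,
                 sa_threshold = sa_threshold),
            class = "momcts_objective_set")
}

#' @export
print.momcts_objective_set <- function(x, ...) {
  cat(sprintf("<objective set: [%s]; validity=%s, sa=%s (<= %.2f)>\n",
              paste(vapply(x$specs, `[[`, "", "name"), collapse = ", "),
              if (is.function(x$validity)) "custom" else x$validity,
              x$sa, x$sa_threshold))
  invisible(x)
}

obj_validity <- function(objset, smiles) {
  if (is.function(objset$validity)) {
    can <- objset$validity(smiles)
    return(list(valid = !is.na(can), canonical = can))
  }
  if (objset$validity == "all") {
    return(list(valid = TRUE, canonical = smiles))
  }
  res <- check_validity(smiles)
  list(valid = res$valid[1L], canonical = res$canonical[1L])
}

obj_sa <- function(objset, smiles) {
  switch(objset$sa,
         none = NA_real_,
         mock = mock_sa_score(smiles),
         chem = sa_score(smiles))
}

#' Evaluate a molecule against an objective set
#'
#' @param smiles a single canonical SMILES string (already validated and
#'   filter-passing).
#' @param objset a [objective_set()] (or bare list of objectives).
#' @return list with `raw` (named numeric) and `reward` (numeric vector in
#'   `[0, 1]^d`, component order = declared objective order); `failed = TRUE`
#'   with the condition message if any adapter failed.
#' @export
evaluate_objectives <- function(smiles, objset) {
  specs <- if (inherits(objset, "momcts_objective_set")) objset$specs else objset
  raw <- numeric(length(specs))
  reward <- numeric(length(specs))
  names(raw) <- names(reward) <- vapply(specs, `[[`, "", "name")
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    val <- tryCatch(sp$compute(smiles), error = function(e) e)
    if (inherits(val, "condition") || !length(val) || is.na(val)) {
      return(list(raw = raw, reward = reward, failed = TRUE,
                  message = if (inherits(val, "condition")) conditionMessage(val)
                            else "objective returned no value"))
    }
    raw[i] <- as.numeric(val)[1L]
    reward[i] <- min(1, max(0, sp$transform(raw[i])))
  }
  list(raw = raw, reward = reward, failed = FALSE)
}

# ---------------------------------------------------------------------------
# External docking adapter

#' Docking adapter configuration
#'
#' Configuration for scoring binding affinity with an external AutoDock
#' Vina-compatible engine.  The receptor must already be prepared as PDBQT
#' (hydrogens and charges assigned); the search box is given as center and
#' extents in Angstroms, typically a rectangular prism covering the
#' cocrystal ligand from its centroid.  Ligand 3D conformers are built with
#' Open Babel (one lowest-energy conformer per molecule).
#'
#' @param receptor path to the receptor PDBQT.
#' @param center numeric length-3 box center (x, y, z) in Angstroms.
#' @param size numeric length-3 box extents in Angstroms.
#' @param exhaustiveness engine exhaustiveness (1 keeps per-molecule cost
#'   low enough to dock every generated compound).
#' @param vina path to the engine binary (empty string if absent).
#' @param obabel path to the Open Babel binary.
#' @return a list of class `momcts_docking_config`.
#' @export
docking_config <- function(receptor, center, size, exhaustiveness = 1L,
                           vina = Sys.which("vina"),
                           obabel = Sys.which("obabel")) {
  if (length(center) != 3L || length(size) != 3L || any(size <= 0)) {
    momcts_error("box center and positive extents must each have 3 components",
                 "momcts_domain_error")
  }
  if (!is_count(exhaustiveness)) {
    momcts_error("exhaustiveness must be a positive integer", "momcts_domain_error")
  }
  structure(list(receptor = receptor, center = as.numeric(center),
                 size = as.numeric(size),
                 exhaustiveness = as.integer(exhaustiveness),
                 vina = unname(vina), obabel = unname(obabel)),
            class = "momcts_docking_config")
}

#' Dock one molecule
#'
#' Embeds a single lowest-energy 3D conformer with Open Babel, runs the
#' docking engine and returns the top-ranked affinity in kcal/mol.
#'
#' @param smiles a single SMILES string.
#' @param config a [docking_config()].
#' @return best-mode affinity (kcal/mol).
#' @export
dock_molecule <- function(smiles, config) {
  if (!nzchar(config$obabel)) momcts_error("obabel not found", "momcts_adapter_error")
  if (!nzchar(config$vina)) momcts_error("docking engine not found", "momcts_adapter_error")
  lig <- tempfile(fileext = ".pdbqt")
  on.exit(unlink(lig), add = TRUE)
  st <- system2(config$obabel,
                c(paste0("-:", shQuote(smiles)), "-opdbqt", "-O", shQuote(lig),
                  "--gen3d", "--best", "-h"),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L || !file.exists(lig)) {
    momcts_error("3D conformer generation failed", "momcts_adapter_error")
  }
  out <- system2(config$vina,
                 c("--receptor", shQuote(config$receptor),
                   "--ligand", shQuote(lig),
                   "--center_x", config$center[1], "--center_y", config$center[2],
                   "--center_z", config$center[3],
                   "--size_x", config$size[1], "--size_y", config$size[2],
                   "--size_z", config$size[3],
                   "--exhaustiveness", config$exhaustiveness),
                 stdout = TRUE, stderr = TRUE)
  parse_vina_affinity(out)
}

#' Parse the best-mode affinity from docking engine output
#'
#' Accepts either the result table printed on stdout (`mode | affinity`
#' listing) or `REMARK VINA RESULT` lines from an output PDBQT.
#'
#' @param lines character vector of output lines.
#' @return affinity of mode 1 in kcal/mol.
#' @export
parse_vina_affinity <- function(lines) {
  rem <- grep("REMARK VINA RESULT:", lines, value = TRUE)
  if (length(rem)) {
    val <- suppressWarnings(as.numeric(strsplit(trimws(sub(".*RESULT:", "", rem[1L])),
                                                "\\s+")[[1]][1]))
    if (!is.na(val)) return(val)
  }
  tab <- grep("^\\s*1\\s+-?[0-9]", lines, value = TRUE)
  if (length(tab)) {
    val <- suppressWarnings(as.numeric(strsplit(trimws(tab[1L]), "\\s+")[[1]][2]))
    if (!is.na(val)) return(val)
  }
  momcts_error("could not parse an affinity from the docking output",
               "momcts_adapter_error")
}
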
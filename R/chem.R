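#' Chemistry backend
#'
#' SMILES sanitization, canonicalization, QED descriptor properties,
#' synthetic-accessibility scores and Morgan fingerprints are computed by
#' RDKit in a persistent python worker process.  The worker is started
#' lazily on first use, communicates over a pair of FIFOs with a JSON-lines
#' protocol, and is shut down when the package is unloaded or the R session
#' ends.  All client functions are vectorized over molecules so each call is
#' a single round trip.
#'
#' @name chem-backend
NULL

.chem <- new.env(parent = emptyenv())

chem_worker_script <- function() {
  system.file("python", "chem_worker.py", package = "momcts", mustWork = FALSE)
}

#' Is the chemistry backend available?
#'
#' @return `TRUE` when a python interpreter with RDKit can be started.
#' @export
chem_available <- function() {
  ok <- tryCatch({ chem_worker(); TRUE }, error = function(e) FALSE)
  ok
}

chem_worker <- function() {
  if (!is.null(.chem$con_out) && !is.null(.chem$alive) && .chem$alive) {
    return(invisible(NULL))
  }
  python <- Sys.getenv("MOMCTS_PYTHON", unset = Sys.which("python3"))
  if (!nzchar(python)) python <- Sys.which("python")
  if (!nzchar(python)) momcts_error("no python interpreter found", "momcts_chem_error")
  script <- chem_worker_script()
  if (!nzchar(script) || !file.exists(script)) {
    # during development the package may not be installed yet
    script <- file.path("inst", "python", "chem_worker.py")
  }
  if (!file.exists(script)) momcts_error("chem_worker.py not found", "momcts_chem_error")
  dir <- tempfile("momcts-chem-")
  dir.create(dir)
  req <- file.path(dir, "req.fifo")
  resp <- file.path(dir, "resp.fifo")
  if (system(paste("mkfifo", shQuote(req), shQuote(resp))) != 0L) {
    momcts_error("could not create FIFOs for the chemistry worker", "momcts_chem_error")
  }
  errfile <- file.path(dir, "worker.log")
  system2(python, c(shQuote(script), shQuote(req), shQuote(resp)),
          wait = FALSE, stdout = errfile, stderr = errfile)
  # the worker drops an .alive file before opening its FIFO end, so poll for
  # that with a timeout instead of blocking on the FIFO open
  alive_file <- paste0(resp, ".alive")
  deadline <- Sys.time() + 20
  while (!file.exists(alive_file) && Sys.time() < deadline) Sys.sleep(0.05)
  if (!file.exists(alive_file)) {
    momcts_error(paste0("chemistry worker did not start; log:\n",
                        paste(readLines(errfile, warn = FALSE), collapse = "\n")),
                 "momcts_chem_error")
  }
  con_out <- fifo(req, open = "w", blocking = TRUE)
  con_in <- fifo(resp, open = "r", blocking = FALSE)
  .chem$con_out <- con_out
  .chem$con_in <- con_in
  .chem$errfile <- errfile
  .chem$alive <- TRUE
  # handshake: first reply also covers the rdkit import time
  reply <- tryCatch(chem_request(list(op = "ping"), timeout = 60),
                    error = function(e) {
                      chem_shutdown()
                      momcts_error(paste0("chemistry worker failed to initialize; log:\n",
                                          paste(readLines(errfile, warn = FALSE), collapse = "\n")),
                                   "momcts_chem_error")
                    })
  invisible(NULL)
}

chem_request <- function(msg, timeout = 120) {
  writeLines(jsonlite::toJSON(msg, auto_unbox = TRUE, null = "null"), .chem$con_out)
  flush(.chem$con_out)
  deadline <- Sys.time() + timeout
  repeat {
    line <- readLines(.chem$con_in, n = 1L)
    if (length(line)) break
    if (Sys.time() > deadline) {
      .chem$alive <- FALSE
      momcts_error("chemistry worker timed out", "momcts_chem_error")
    }
    Sys.sleep(0.002)
  }
  reply <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  if (!is.null(reply$error)) {
    momcts_error(paste("chemistry worker error:", reply$error), "momcts_chem_error")
  }
  reply
}

chem_shutdown <- function() {
  if (!is.null(.chem$con_out)) {
    tryCatch({
      writeLines('{"op":"quit"}', .chem$con_out)
      flush(.chem$con_out)
    }, error = function(e) NULL)
    tryCatch(close(.chem$con_out), error = function(e) NULL)
  }
  if (!is.null(.chem$con_in)) tryCatch(close(.chem$con_in), error = function(e) NULL)
  .chem$con_out <- NULL
  .chem$con_in <- NULL
  .chem$alive <- FALSE
  invisible(NULL)
}

.onUnload <- function(libpath) {
  chem_shutdown()
}

chem_call <- function(msg, field) {
  chem_worker()
  reply <- tryCatch(chem_request(msg), error = function(e) {
    # one restart attempt in case the worker died
    chem_shutdown()
    chem_worker()
    chem_request(msg)
  })
  reply[[field]]
}

#' Check SMILES validity and canonicalize
#'
#' Validity means the string parses and survives sanitization in the
#' chemistry toolkit (valence check, aromaticity perception).  Invalidity is
#' a result, not an error.
#'
#' @param smiles character vector of SMILES strings.
#' @return for `check_validity()`: a data.frame with columns `smiles`,
#'   `valid` and `canonical` (`NA` where invalid).  For
#'   `canonical_smiles()`: a character vector with `NA` where invalid.
#' @export
check_validity <- function(smiles) {
  can <- canonical_smiles(smiles)
  data.frame(smiles = smiles, valid = !is.na(can), canonical = can,
             stringsAsFactors = FALSE)
}

#' @rdname check_validity
#' @export
canonical_smiles <- function(smiles) {
  if (!length(smiles)) return(character(0))
  out <- chem_call(list(op = "canon", smiles = as.list(as.character(smiles))),
                   "canonical")
  vapply(out, function(x) if (is.null(x)) NA_character_ else x, "")
}

#' QED descriptor properties
#'
#' The eight physicochemical descriptors entering the quantitative estimate
#' of drug-likeness: molecular weight (MW), Crippen logP (ALOGP), hydrogen
#' bond acceptors (HBA) and donors (HBD), topological polar surface area
#' (PSA), rotatable bonds (ROTB), aromatic rings (AROM) and structural
#' alerts (ALERTS).
#'
#' @param smiles character vector.
#' @return a data.frame with one row per molecule (NA rows where invalid).
#' @export
qed_properties <- function(smiles) {
  out <- chem_call(list(op = "qed_props", smiles = as.list(as.character(smiles))),
                   "properties")
  cols <- c("MW", "ALOGP", "HBA", "HBD", "PSA", "ROTB", "AROM", "ALERTS")
  df <- as.data.frame(matrix(NA_real_, length(out), length(cols)))
  names(df) <- cols
  for (i in seq_along(out)) {
    if (!is.null(out[[i]])) df[i, ] <- as.numeric(unlist(out[[i]])[cols])
  }
  df
}

#' Synthetic accessibility score
#'
#' The fragment-contribution synthetic accessibility score on the 1 (easy)
#' to 10 (hard) scale, computed by the published fragment-based method.
#'
#' @param smiles character vector.
#' @return numeric vector (`NA` where invalid).
#' @export
sa_score <- function(smiles) {
  out <- chem_call(list(op = "sa_score", smiles = as.list(as.character(smiles))),
                   "sa_score")
  vapply(out, function(x) if (is.null(x)) NA_real_ else as.numeric(x), 0)
}

#' Morgan (circular) fingerprints
#'
#' @param smiles character vector.
#' @param radius circular neighborhood radius (2 corresponds to ECFP4).
#' @param nbits folded fingerprint length.
#' @return a list of sorted integer vectors of 1-based on-bit positions
#'   (`NULL` where invalid).
#' @export
morgan_fingerprints <- function(smiles, radius = 2L, nbits = 2048L) {
  out <- chem_call(list(op = "morgan_fp", smiles = as.list(as.character(smiles)),
                        radius = radius, nbits = nbits), "bits")
  lapply(out, function(x) if (is.null(x)) NULL else sort(as.integer(unlist(x))))
}

#' Tanimoto similarity of two on-bit sets
#'
#' @param a,b integer vectors of on-bit positions.
#' @return similarity in `[0, 1]`; two empty fingerprints have similarity 1.
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Simple structural descriptors
#'
#' Heavy-atom count, smallest-set-of-smallest-rings count, molecular weight,
#' TPSA and Crippen logP; used by the deterministic mock objectives.
#'
#' @param smiles character vector.
#' @return data.frame with one row per molecule.
#' @export
basic_descriptors <- function(smiles) {
  out <- chem_call(list(op = "descriptors", smiles = as.list(as.character(smiles))),
                   "descriptors")
  cols <- c("heavy_atoms", "rings", "mw", "tpsa", "logp")
  df <- as.data.frame(matrix(NA_real_, length(out), length(cols)))
  names(df) <- cols
  for (i in seq_along(out)) {
    if (!is.null(out[[i]])) df[i, ] <- as.numeric(unlist(out[[i]])[cols])
  }
  df
}
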
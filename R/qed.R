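#' Quantitative estimate of drug-likeness (QED)
#'
#' QED maps eight physicochemical descriptors through asymmetric double
#' sigmoid desirability functions fitted to the property distributions of
#' approved oral drugs (Bickerton et al. 2012, Nat. Chem. 4:90), then
#' aggregates the desirabilities by a weighted geometric mean.  The
#' desirability model is implemented here natively; descriptor values come
#' from the chemistry backend ([qed_properties()]).
#'
#' @name qed
NULL

# Asymmetric double sigmoid parameters (a, b, c, d, e, f, dmax) per
# descriptor, from the published QED desirability model.
QED_ADS_PARAMETERS <- list(
  MW     = c(a = 2.817065973, b = 392.5754953, c = 290.7489764,
             d = 2.419764353, e = 49.22325677, f = 65.37051707,
             dmax = 104.9805561),
  ALOGP  = c(a = 3.172690585, b = 137.8624751, c = 2.534937431,
             d = 4.581497897, e = 0.822739154, f = 0.576295591,
             dmax = 131.3186604),
  HBA    = c(a = 2.948620388, b = 160.4605972, c = 3.615294657,
             d = 4.435986202, e = 0.290141953, f = 1.300669958,
             dmax = 148.7763046),
  HBD    = c(a = 1.618662227, b = 1010.051101, c = 0.985094388,
             d = 1e-09, e = 0.713820843, f = 0.920922555,
             dmax = 258.1632616),
  PSA    = c(a = 1.876861559, b = 125.2232657, c = 62.90773554,
             d = 87.83366614, e = 12.01999824, f = 28.51324732,
             dmax = 104.5686167),
  ROTB   = c(a = 0.01, b = 272.4121427, c = 2.55837997,
             d = 1.565547684, e = 1.271567166, f = 2.758063707,
             dmax = 105.4420403),
  AROM   = c(a = 3.21778897, b = 957.7374108, c = 2.274627939,
             d = 1e-09, e = 1.317690384, f = 0.375760881,
             dmax = 312.337261),
  ALERTS = c(a = 0.01, b = 1199.094025, c = -0.09002883,
             d = 1e-09, e = 0.185904477, f = 0.875193782,
             dmax = 417.725314))

# Weighted-mean descriptor weights of the published model (the "QEDw,mo"
# weighting, the default in common toolkits).
QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                 PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

#' Asymmetric double sigmoid desirability
#'
#' @param x descriptor value(s).
#' @param p named parameter vector `(a, b, c, d, e, f, dmax)`.
#' @return desirability in `(0, 1]`.
#' @keywords internal
qed_ads <- function(x, p) {
  raw <- p[["a"]] +
    p[["b"]] / (1 + exp(-(x - p[["c"]] + p[["d"]] / 2) / p[["e"]])) *
      (1 - 1 / (1 + exp(-(x - p[["c"]] - p[["d"]] / 2) / p[["f"]])))
  raw / p[["dmax"]]
}

#' QED from descriptor values
#'
#' Aggregates the eight desirabilities by the weighted geometric mean
#' `exp(sum(w_i log d_i) / sum(w_i))`.  Exposed separately from
#' [qed_score()] so the aggregation can be verified against descriptor
#' values computed elsewhere.
#'
#' @param props a data.frame or named list/vector with elements `MW`,
#'   `ALOGP`, `HBA`, `HBD`, `PSA`, `ROTB`, `AROM`, `ALERTS`.
#' @param weights named descriptor weights; default the published
#'   weighted-mean set.
#' @return numeric vector of QED values in `[0, 1]`.
#' @export
qed_from_properties <- function(props, weights = QED_WEIGHTS) {
  if (!is.data.frame(props)) props <- as.data.frame(as.list(props))
  missing_cols <- setdiff(names(QED_ADS_PARAMETERS), names(props))
  if (length(missing_cols)) {
    momcts_error(paste("missing QED descriptors:", paste(missing_cols, collapse = ", ")),
                 "momcts_domain_error")
  }
  w <- weights[names(QED_ADS_PARAMETERS)]
  out <- numeric(nrow(props))
  for (i in seq_len(nrow(props))) {
    if (anyNA(props[i, names(QED_ADS_PARAMETERS)])) { out[i] <- NA_real_; next }
    d <- vapply(names(QED_ADS_PARAMETERS), function(nm) {
      qed_ads(as.numeric(props[[nm]][i]), QED_ADS_PARAMETERS[[nm]])
    }, 0)
    out[i] <- exp(sum(w * log(pmax(d, 1e-300))) / sum(w))
  }
  out
}

#' QED of molecules
#'
#' @param smiles character vector of SMILES strings.
#' @return numeric vector of QED values (`NA` where invalid).
#' @export
qed_score <- function(smiles) {
  qed_from_properties(qed_properties(smiles))
}
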
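# Scaling laws for the change in critical solution temperature on
# mutation. Three ansaetze relate delta Tc to the number of substitutions
# N of one residue type, the protein length L, and a class-specific
# constant S:
#   count:    delta Tc = S * N          (length-independent)
#   fraction: delta Tc = S * N / L      (strong length buffering)
#   sqrt:     delta Tc = S * N / sqrt(L) (intermediate buffering)
# Fits are through the origin: zero mutations leave Tc unchanged by
# construction, so no intercept is estimated and R^2 is defined against
# the raw sum of squares of the response.

ANSATZE <- c("count", "fraction", "sqrt")

#' Ansatz covariate x for a bound mutation spec
#'
#' @param n number of substitutions (>= 0).
#' @param L protein length (>= 1).
#' @param ansatz one of `"count"` (x = N), `"fraction"` (x = N/L) or
#'   `"sqrt"` (x = N/sqrt(L)).
#' @return numeric covariate, vectorised over `n`/`L`.
#' @export
ansatz_x <- function(n, L, ansatz = c("count", "fraction", "sqrt")) {
  ansatz <- match.arg(ansatz)
  stopifnot(all(n >= 0), all(L >= 1))
  switch(ansatz,
         count = n,
         fraction = n / L,
         sqrt = n / sqrt(L))
}

#' Scaling-law object
#'
#' @param pair mutation-pair label, e.g. `"Y->F"` or `"R->X"`.
#' @param ansatz ansatz name.
#' @param S scaling constant (Kelvin per unit covariate).
#' @param S_err standard error of `S` (NA when not estimable).
#' @param r_squared through-origin coefficient of determination.
#' @param source `"fitted"` or `"published"`.
#' @return object of class `scaling_law`.
#' @export
scaling_law <- function(pair, ansatz, S, S_err = NA_real_,
                        r_squared = NA_real_, source = "fitted") {
  ansatz <- match.arg(ansatz, ANSATZE)
  structure(list(pair = pair, ansatz = ansatz, S = S, S_err = S_err,
                 r_squared = r_squared, source = source),
            class = "scaling_law")
}

#' @export
print.scaling_law <- function(x, ...) {
  cat(sprintf("<scaling_law> %s [%s]: S = %.4g +/- %.2g (R^2 = %.3g, %s)\n",
              x$pair, x$ansatz, x$S, x$S_err, x$r_squared, x$source))
  invisible(x)
}

#' Reverse a scaling law (antisymmetry)
#'
#' By definition `S(X1->X2) = -S(X2->X1)` under the same ansatz.
#' @param law a [scaling_law()].
#' @return the law for the reversed pair.
#' @export
reverse_law <- function(law) {
  parts <- strsplit(law$pair, "->", fixed = TRUE)[[1]]
  scaling_law(paste0(parts[2], "->", parts[1]), law$ansatz, -law$S,
              law$S_err, law$r_squared, law$source)
}

#' Build a variant-observation table
#'
#' @param variant_id identifiers.
#' @param pair mutation-pair labels (e.g. `"R->K"`).
#' @param N substitution counts (>= 1).
#' @param L protein lengths (>= N).
#' @param delta_tc observed Tc changes (Kelvin).
#' @param delta_tc_err optional standard errors.
#' @param multi_type logical; flagged observations are refused by the fits.
#' @return data.frame of class `variant_observations`.
#' @export
variant_observations <- function(variant_id, pair, N, L, delta_tc,
                                 delta_tc_err = NA_real_,
                                 multi_type = FALSE) {
  stopifnot(all(N >= 1), all(L >= N))
  out <- data.frame(variant_id = variant_id, pair = pair,
                    N = as.integer(N), L = as.integer(L),
                    delta_tc = delta_tc, delta_tc_err = delta_tc_err,
                    multi_type = multi_type, stringsAsFactors = FALSE)
  class(out) <- c("variant_observations", "data.frame")
  out
}

#' Fit a scaling constant for one mutation family
#'
#' Through-origin least squares of `delta_tc` on the ansatz covariate.
#' `S_err` is the slope's standard error; `r_squared = 1 - SS_res / sum(y^2)`
#' (the through-origin convention).
#'
#' @param data a [variant_observations()] table, all rows one mutation pair
#'   and none flagged multi-type.
#' @param ansatz ansatz name.
#' @return a [scaling_law()].
#' @export
fit_scaling_constant <- function(data,
                                 ansatz = c("count", "fraction", "sqrt")) {
  ansatz <- match.arg(ansatz)
  if (length(unique(data$pair)) != 1L) {
    stop("observations mix mutation pairs: ",
         paste(unique(data$pair), collapse = ", "), call. = FALSE)
  }
  if (any(data$multi_type)) {
    stop("multi-type observations cannot enter a single-pair scaling fit",
         call. = FALSE)
  }
  x <- ansatz_x(data$N, data$L, ansatz)
  y <- data$delta_tc
  fit <- stats::lm(y ~ 0 + x)
  S <- unname(stats::coef(fit)[1])
  if (nrow(data) >= 2L) {
    # a perfect (noise-free) fit triggers a harmless precision warning
    S_err <- suppressWarnings(
      summary(fit)$coefficients["x", "Std. Error"])
  } else {
    S_err <- NA_real_
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum(y^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  scaling_law(unique(data$pair), ansatz, S, S_err, r2, source = "fitted")
}

#' Fit all three ansaetze and select the best by R-squared
#'
#' When all observations share one length L the three covariates are
#' proportional and the ansaetze cannot be distinguished; the result then
#' carries `indistinguishable = TRUE` and no winner.
#'
#' @param data a [variant_observations()] table (one mutation pair).
#' @return list with `laws` (named list of [scaling_law()] per ansatz),
#'   `best` (winning ansatz name or NA), `indistinguishable` (logical).
#' @export
select_ansatz <- function(data) {
  laws <- lapply(stats::setNames(ANSATZE, ANSATZE),
                 function(a) fit_scaling_constant(data, a))
  if (length(unique(data$L)) < 2L) {
    return(list(laws = laws, best = NA_character_,
                indistinguishable = TRUE))
  }
  r2 <- vapply(laws, function(l) l$r_squared, numeric(1))
  list(laws = laws, best = names(which.max(r2)), indistinguishable = FALSE)
}

#' Predict the critical-temperature change for a mutation
#'
#' `value = S * x`, `error = |x| * S_err`, with `x` the law's ansatz
#' covariate for (`n`, `L`). A spec whose pair is the reverse of the law's
#' is handled by the antisymmetry `S(X1->X2) = -S(X2->X1)`.
#'
#' @param spec a [mutation_spec()] (or list with `source`, `target`, `n`).
#' @param L protein length.
#' @param law a [scaling_law()].
#' @return list with `value` and `error` (Kelvin).
#' @export
predict_delta_tc <- function(spec, L, law) {
  if (is.na(law$S)) {
    stop("law for ", law$pair, " has no published constant; cannot predict",
         call. = FALSE)
  }
  lab <- pair_label(spec)
  use <- if (identical(lab, law$pair)) {
    law
  } else if (identical(lab, reverse_law(law)$pair)) {
    reverse_law(law)
  } else {
    stop("mutation ", lab, " does not match law ", law$pair, call. = FALSE)
  }
  x <- ansatz_x(spec$n, L, use$ansatz)
  list(value = use$S * x,
       error = if (is.na(use$S_err)) NA_real_ else abs(x) * use$S_err)
}

#' Cumulative prediction for several single-type mutations
#'
#' The laws are additive: successive mutations of different classes
#' contribute the sum of their individual predictions, with errors added
#' in quadrature.
#'
#' @param specs list of [mutation_spec()] objects (each single-type).
#' @param L protein length.
#' @param laws list of [scaling_law()] objects to match against.
#' @return list with `value` and `error` (Kelvin).
#' @export
cumulative_prediction <- function(specs, L, laws = published_laws()) {
  if (length(specs) == 0L) return(list(value = 0, error = 0))
  preds <- lapply(specs, function(sp) {
    if (isTRUE(sp$multi_type)) {
      stop("multi-type spec cannot be matched to a single law",
           call. = FALSE)
    }
    law <- find_law(sp, laws)
    predict_delta_tc(sp, L, law)
  })
  list(value = sum(vapply(preds, `[[`, numeric(1), "value")),
       error = sqrt(sum(vapply(preds, `[[`, numeric(1), "error")^2)))
}

find_law <- function(spec, laws) {
  lab <- pair_label(spec)
  for (law in laws) {
    if (identical(lab, law$pair) ||
        identical(lab, reverse_law(law)$pair)) {
      return(law)
    }
  }
  stop("no scaling law matches mutation ", lab, call. = FALSE)
}

#' Published scaling constants for the nine mutation classes
#'
#' The constants shipped here are the fitted values reported for the PLD
#' family dataset (Kelvin per unit covariate, with standard errors and the
#' reported R^2 where available):
#' count ansatz for Y->F (-0.40), F/Y->W (4.3), S->T (-0.09),
#' G->T (-0.08), A->S (0.16); fraction ansatz for R->K (-1300),
#' R->X (-640), N->Q (50); sqrt ansatz for F/Y->X (-56). They are data,
#' never silently refit. G->S is reported qualitatively only (a very minor
#' decrease) and ships without a constant; predictions refuse it.
#'
#' @return named list of [scaling_law()] objects keyed by pair label.
#' @export
published_laws <- function() {
  mk <- function(pair, ansatz, S, S_err, r2) {
    scaling_law(pair, ansatz, S, S_err, r2, source = "published")
  }
  list(
    "Y->F"   = mk("Y->F",   "count",    -0.40, 0.04, 0.88),
    "F/Y->W" = mk("F/Y->W", "count",     4.3,  0.1,  0.99),
    "F/Y->X" = mk("F/Y->X", "sqrt",    -56,    5,    NA_real_),
    "R->K"   = mk("R->K",   "fraction", -1300, 100,  0.94),
    "R->X"   = mk("R->X",   "fraction", -640,  50,   0.96),
    "N->Q"   = mk("N->Q",   "fraction",  50,   5,    0.84),
    "S->T"   = mk("S->T",   "count",    -0.09, 0.03, 0.70),
    "G->T"   = mk("G->T",   "count",    -0.08, 0.02, 0.70),
    "A->S"   = mk("A->S",   "count",     0.16, 0.05, 0.77),
    "G->S"   = mk("G->S",   "count",     NA_real_, NA_real_, NA_real_)
  )
}

# Significant-figure rounding with halves away from zero (the convention
# used for printed uncertainties, e.g. 0.25 -> 0.3).
signif_half_up <- function(x, digits = 1) {
  ifelse(x == 0, 0, {
    m <- 10^(floor(log10(abs(x))) - digits + 1)
    sign(x) * floor(abs(x) / m + 0.5) * m
  })
}

#' Single-point-mutation prediction grid
#'
#' Predicted `delta Tc +/- err` (Kelvin) for one substitution (N = 1) of
#' each mutation class at each length. Raw values are reported alongside a
#' rounded view (value to 2 significant figures, error to 1), matching the
#' conventions of the published summary grid.
#'
#' @param laws named list of [scaling_law()] objects (pairs without a
#'   constant are skipped).
#' @param lengths integer vector of protein lengths L.
#' @return data.frame with columns pair, ansatz, L, value, error,
#'   value_rounded, error_rounded.
#' @export
build_table1 <- function(laws = published_laws(),
                         lengths = c(100L, 200L, 300L)) {
  rows <- list()
  for (law in laws) {
    if (is.na(law$S)) next
    for (L in lengths) {
      x <- ansatz_x(1L, L, law$ansatz)
      v <- law$S * x
      e <- abs(x) * law$S_err
      rows[[length(rows) + 1L]] <- data.frame(
        pair = law$pair, ansatz = law$ansatz, L = L,
        value = v, error = e,
        value_rounded = signif(v, 2), error_rounded = signif_half_up(e, 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
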
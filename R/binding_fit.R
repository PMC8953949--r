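# Saturation-binding analysis: one-site model A = Amax/(1 + Kd/L), Hill
# generalization A = Amax * L^h / (Kd^h + L^h), Scatchard transform, and
# the percent-inhibition summary used for competition assays.

#' Binding curve container
#'
#' @param L Ligand concentrations (nM), strictly positive.
#' @param A Absorbance readings (OD units).
#' @param replicate Optional replicate labels.
#' @return A `binding_curve` data frame with columns `L`, `A` (and
#'   `replicate` when given).
#' @export
binding_curve <- function(L, A, replicate = NULL) {
  L <- as.numeric(L); A <- as.numeric(A)
  stopifnot(length(L) == length(A))
  if (any(!is.finite(L)) || any(L <= 0))
    stop("domain-error: concentrations must be positive", call. = FALSE)
  out <- data.frame(L = L, A = A)
  if (!is.null(replicate)) out$replicate <- replicate
  class(out) <- c("binding_curve", "data.frame")
  out
}

#' Read a binding curve from TSV
#'
#' Expects either a `conc_nM` column, or `conc_ug_ml` plus `mw_kda` (in
#' which case concentrations are converted with [ugml_to_nm()]), and an
#' `od` column.
#'
#' @param path TSV file path.
#' @return A [binding_curve()].
#' @export
read_binding_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if ("conc_nM" %in% names(d)) L <- d$conc_nM
  else if (all(c("conc_ug_ml", "mw_kda") %in% names(d)))
    L <- ugml_to_nm(d$conc_ug_ml, d$mw_kda)
  else stop("need conc_nM, or conc_ug_ml + mw_kda columns", call. = FALSE)
  if (!"od" %in% names(d)) stop("need an od column", call. = FALSE)
  binding_curve(L, d$od, replicate = d$replicate)
}

#' Convert a mass concentration to molar
#'
#' `nM = 1000 * (ug/mL) / (kDa)`; plate coatings are usually stated in
#' ug/mL while the binding model works in nM.
#'
#' @param ug_ml Concentration in micrograms per milliliter.
#' @param mw_kda Molecular weight in kilodaltons.
#' @return Concentration in nM.
#' @export
ugml_to_nm <- function(ug_ml, mw_kda) {
  stopifnot(all(mw_kda > 0))
  1000 * ug_ml / mw_kda
}

#' One-site saturation binding model
#'
#' `A = Amax * L^h / (Kd^h + L^h)`; with `h = 1` this is exactly
#' `A = Amax / (1 + Kd/L)`. At `L = Kd` the response is `Amax/2` for any
#' Hill slope.
#'
#' @param L Ligand concentration(s), nM, > 0.
#' @param Amax Saturation absorbance, > 0.
#' @param Kd Dissociation constant, nM, > 0.
#' @param h Hill slope, > 0 (default 1).
#' @return Model absorbance value(s).
#' @export
model_one_site <- function(L, Amax, Kd, h = 1) {
  if (any(L <= 0) || Amax <= 0 || Kd <= 0 || h <= 0)
    stop("domain-error: L, Amax, Kd, h must all be positive", call. = FALSE)
  Amax * L^h / (Kd^h + L^h)
}

#' Fit a saturation-binding curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) on `(Amax, Kd)` or
#' `(Amax, Kd, h)`. Initialization: `Amax0 = max(A)`, `Kd0 =` the
#' concentration whose reading is closest to `Amax0/2`, `h0 = 1`; all
#' parameters bounded below by a small positive value. Standard errors
#' come from the Jacobian at the optimum. Non-convergence is flagged in
#' the result, not thrown.
#'
#' @param curve A [binding_curve()] with at least 4 distinct
#'   concentrations.
#' @param hill Fit the Hill slope (`TRUE`) or fix `h = 1`.
#' @return A `binding_fit`: `Amax`, `Kd`, `h`, `se` (named vector),
#'   `rss`, `converged`, `n`, and the underlying `nls` object in `$fit`.
#' @export
fit_binding <- function(curve, hill = FALSE) {
  stopifnot(inherits(curve, "binding_curve"))
  if (length(unique(curve$L)) < 4)
    stop("domain-error: need >= 4 distinct concentrations", call. = FALSE)
  Amax0 <- max(curve$A)
  if (Amax0 <= 0) Amax0 <- 1e-3
  Kd0 <- curve$L[which.min(abs(curve$A - Amax0 / 2))]
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                     maxiter = 500)
  lo <- 1e-12
  fit <- tryCatch({
    if (hill)
      minpack.lm::nlsLM(A ~ Amax * L^h / (Kd^h + L^h), data = curve,
                        start = list(Amax = Amax0, Kd = Kd0, h = 1),
                        lower = c(lo, lo, lo), control = ctrl)
    else
      minpack.lm::nlsLM(A ~ Amax * L / (Kd + L), data = curve,
                        start = list(Amax = Amax0, Kd = Kd0),
                        lower = c(lo, lo), control = ctrl)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(Amax = NA_real_, Kd = NA_real_, h = NA_real_,
                          se = c(Amax = NA_real_, Kd = NA_real_),
                          rss = NA_real_, converged = FALSE,
                          n = nrow(curve), hill = hill, fit = NULL),
                     class = "binding_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(cf)),
                                              names(cf)))
  structure(list(Amax = unname(cf["Amax"]), Kd = unname(cf["Kd"]),
                 h = if (hill) unname(cf["h"]) else 1,
                 se = se, rss = sum(residuals(fit)^2),
                 converged = isTRUE(fit$convInfo$isConv),
                 n = nrow(curve), hill = hill, fit = fit),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "binding_fit: Kd = %.4g nM, Amax = %.4g OD, h = %.3g (%s, n = %d)\n",
    x$Kd, x$Amax, x$h,
    if (x$converged) "converged" else "NOT converged", x$n))
  invisible(x)
}

#' Scatchard transform
#'
#' Returns the points `(A, A/L)` and their least-squares line. For
#' noiseless one-site data the slope is `-1/Kd` and the x-intercept is
#' `Amax`.
#'
#' @param curve A [binding_curve()].
#' @return List with `points` (data frame `bound`, `bound_over_free`),
#'   `slope`, `intercept`, `x_intercept`, `kd_est = -1/slope`.
#' @export
scatchard <- function(curve) {
  stopifnot(inherits(curve, "binding_curve"))
  pts <- data.frame(bound = curve$A, bound_over_free = curve$A / curve$L)
  ln <- lm(bound_over_free ~ bound, data = pts)
  slope <- unname(coef(ln)["bound"])
  intercept <- unname(coef(ln)["(Intercept)"])
  list(points = pts, slope = slope, intercept = intercept,
       x_intercept = -intercept / slope,
       kd_est = -1 / slope)
}

#' Percent inhibition of binding by a competitor
#'
#' `100 * (1 - OD_with / OD_alone)`, capped at 100%.
#'
#' @param od_with_competitor OD with the competitor present.
#' @param od_alone OD of the uncompeted binding, > 0.
#' @return Percent inhibition (can be negative for enhancement).
#' @export
percent_inhibition <- function(od_with_competitor, od_alone) {
  if (any(od_alone <= 0))
    stop("domain-error: od_alone must be positive", call. = FALSE)
  pmin(100, 100 * (1 - od_with_competitor / od_alone))
}
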
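# Indirect competitive ELISA: inhibition ratio, four-parameter logistic
# (4PL) curve fitting, and IC50 comparison across samples.

#' Competitive-ELISA inhibition ratio
#'
#' `(1 - (B1 - B0) / (B2 - B0)) * 100`, where `B0` is the blank-well
#' absorbance, `B1` the sample well and `B2` the positive (no competitor)
#' well. The ratio is affine-invariant: adding a constant to all three
#' absorbances, or scaling all three by a positive factor, leaves it
#' unchanged. Values outside `[0, 100]` can occur in noisy wells; they are
#' flagged with a warning but never clipped, since clipping would bias a
#' later curve fit.
#'
#' @param b0,b1,b2 Absorbances (vectors are recycled to a common length).
#' @return Inhibition ratio(s) in percent.
#' @examples
#' inhibition_ratio(0.1, 0.6, 1.1)  # 50
#' @export
inhibition_ratio <- function(b0, b1, b2) {
  if (any(b0 < 0 | b1 < 0 | b2 < 0))
    stop("absorbances must be non-negative")
  if (any(b2 <= b0))
    stop("invalid plate: positive-well absorbance must exceed the blank")
  ir <- (1 - (b1 - b0) / (b2 - b0)) * 100
  n_out <- sum(ir < 0 | ir > 100)
  if (n_out > 0L)
    warning(n_out, " inhibition ratio(s) outside [0, 100] (kept unclipped)")
  ir
}

#' Four-parameter logistic dose-response curve
#'
#' `bottom + (top - bottom) / (1 + (ic50 / conc)^hill)`. At
#' `conc = ic50` the curve passes exactly through `(bottom + top) / 2`.
#'
#' @param conc Concentration(s), same units as `ic50`.
#' @param bottom,top Lower/upper asymptotes (percent inhibition).
#' @param ic50 Midpoint concentration.
#' @param hill Hill slope.
#' @return Predicted inhibition ratio(s).
#' @export
four_pl <- function(conc, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (ic50 / conc)^hill)
}

#' Fit a 4PL inhibition curve and estimate the IC50
#'
#' Least-squares fit of the four-parameter logistic to
#' (concentration, inhibition %) points via Levenberg-Marquardt.
#' Initialisation: `bottom = min(IR)`, `top = max(IR)`, `ic50 =` geometric
#' mean of the concentrations, `hill = 1`, with positivity bounds on `ic50`
#' and `hill`. Replicate wells at a concentration are averaged before
#' fitting unless `average_replicates = FALSE`. Zero/negative
#' concentrations are dropped from the fit with a warning (the logistic is
#' undefined there). A lower IC50 means a stronger competitor, i.e. higher
#' antibody-binding capacity.
#'
#' @param concentration Concentrations (e.g. ug/mL); at least 4 distinct
#'   positive values are required.
#' @param inhibition Inhibition ratios in percent (see
#'   [inhibition_ratio()]).
#' @param average_replicates Average replicate wells per concentration?
#' @return An `elisa_fit` object with `coefficients` (bottom, top, ic50,
#'   hill), `ic50`, the fitted `points`, `residual_norm` and a convergence
#'   flag; supports `print`, `coef`, `predict`, `residuals`, `plot` and
#'   `summary`.
#' @export
fit_4pl <- function(concentration, inhibition, average_replicates = TRUE) {
  if (length(concentration) != length(inhibition))
    stop("concentration and inhibition must have equal length")
  ok <- concentration > 0
  if (any(!ok)) {
    warning(sum(!ok), " non-positive concentration(s) dropped from the fit")
    concentration <- concentration[ok]
    inhibition <- inhibition[ok]
  }
  if (average_replicates) {
    agg <- stats::aggregate(inhibition,
                            by = list(concentration = concentration), mean)
    concentration <- agg$concentration
    inhibition <- agg$x
  }
  dat <- data.frame(concentration = concentration, inhibition = inhibition)
  dat <- dat[order(dat$concentration), , drop = FALSE]
  if (length(unique(dat$concentration)) < 4L)
    stop("need at least 4 distinct positive concentrations to fit a 4PL")
  if (diff(range(dat$inhibition)) < 1e-6)
    stop("degenerate flat inhibition data; no dose response to fit")
  start <- list(bottom = min(dat$inhibition), top = max(dat$inhibition),
                ic50 = exp(mean(log(dat$concentration))), hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      inhibition ~ bottom + (top - bottom) / (1 + (ic50 / concentration)^hill),
      data = dat, start = start,
      lower = c(bottom = -Inf, top = -Inf, ic50 = 1e-12, hill = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("4PL fit failed: ", conditionMessage(e)))
  conv <- isTRUE(fit$convInfo$isConv)
  if (!conv)
    stop("4PL fit did not converge: ", fit$convInfo$stopMessage)
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  structure(list(points = dat, coefficients = cf,
                 ic50 = unname(cf["ic50"]),
                 residual_norm = sqrt(sum(res^2)),
                 converged = conv, n = nrow(dat),
                 fit = fit), class = "elisa_fit")
}

#' IC50 of a fitted inhibition curve
#'
#' @param object An `elisa_fit`.
#' @return The IC50 in the concentration units of the fit.
#' @export
ic50 <- function(object) {
  stopifnot(inherits(object, "elisa_fit"))
  object$ic50
}

#' @export
coef.elisa_fit <- function(object, ...) object$coefficients

#' @export
print.elisa_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("4PL competitive-ELISA fit on", x$n, "points\n")
  cat(sprintf("  bottom %.3f  top %.3f  hill %.3f\n",
              cf["bottom"], cf["top"], cf["hill"]))
  cat(sprintf("  IC50 %.4g (residual norm %.3g)\n",
              x$ic50, x$residual_norm))
  invisible(x)
}

#' @export
predict.elisa_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$points$concentration
          else if (is.numeric(newdata)) newdata
          else newdata$concentration
  cf <- object$coefficients
  four_pl(conc, cf["bottom"], cf["top"], cf["ic50"], cf["hill"])
}

#' @export
residuals.elisa_fit <- function(object, ...) {
  object$points$inhibition - predict(object)
}

#' @export
summary.elisa_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients, ic50 = object$ic50,
              residual_norm = object$residual_norm, n = object$n,
              converged = object$converged)
  class(out) <- "summary.elisa_fit"
  out
}

#' @export
print.summary.elisa_fit <- function(x, ...) {
  cat("4PL fit summary\n")
  print(round(x$coefficients, 6))
  cat(sprintf("IC50 = %.6g; residual norm = %.4g; n = %d; converged = %s\n",
              x$ic50, x$residual_norm, x$n, x$converged))
  invisible(x)
}

#' @export
plot.elisa_fit <- function(x, ...) {
  pts <- x$points
  grid <- exp(seq(log(min(pts$concentration)), log(max(pts$concentration)),
                  length.out = 200))
  graphics::plot(pts$concentration, pts$inhibition, log = "x",
                 xlab = "concentration", ylab = "inhibition ratio (%)",
                 main = "Competitive ELISA 4PL fit", ...)
  graphics::lines(grid, predict(x, grid))
  graphics::abline(v = x$ic50, lty = 2)
  invisible(x)
}

#' Rank samples by fitted IC50
#'
#' Reports each sample's IC50, the fold change against a reference sample
#' and the induced binding-capacity order: ascending IC50 corresponds to
#' descending IgE-binding capacity (a lower IC50 means less competitor was
#' needed to reach half-inhibition).
#'
#' @param curves Named list of `elisa_fit` objects.
#' @param reference Name of the reference curve in `curves`.
#' @return data.frame sorted by ascending IC50: `sample`, `ic50`,
#'   `fold_vs_reference`, `binding_rank` (1 = strongest binding).
#' @export
compare_ic50 <- function(curves, reference) {
  if (is.null(names(curves)) || any(!nzchar(names(curves))))
    stop("curves must be a named list")
  if (!reference %in% names(curves))
    stop("reference '", reference, "' not among the curves")
  vals <- vapply(curves, ic50, numeric(1))
  out <- data.frame(sample = names(vals), ic50 = unname(vals),
                    fold_vs_reference = unname(vals / vals[[reference]]),
                    binding_rank = rank(unname(vals), ties.method = "min"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$ic50, out$sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}
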
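## Dose-response processing: viability normalization, relative-AUC resistance
## scoring, four-parameter log-logistic fitting and ZIP synergy surfaces.

#' Normalize raw viability readings to untreated controls
#'
#' Each reading is divided by the mean of the untreated (vehicle) control
#' readings.
#'
#' @param raw Numeric vector/matrix of raw plate readings.
#' @param untreated Readings of the untreated control wells.
#' @return Normalized viability fractions (same shape as \code{raw}).
#' @export
normalize_viability <- function(raw, untreated) {
  m <- mean(untreated)
  if (!is.finite(m) || m <= 0) stop("untreated control mean must be > 0")
  raw / m
}

#' Relative AUC resistance score of a dose-response curve
#'
#' Trapezoidal area under the normalized viability curve over
#' log10(concentration), divided by the area of a hypothetical non-responder
#' (viability identically 1) over the same log-dose range, times 100. A fully
#' resistant line scores 100 percent, a fully susceptible one 0 percent.
#' Zero-dose points are excluded from the log axis.
#'
#' @param concentrations Dose axis (any consistent unit); zero doses dropped.
#' @param viability Normalized viability fractions, same length.
#' @return Relative AUC in percent.
#' @examples
#' relative_auc(10^(0:8), rep(0.5, 9))  # 50
#' @export
relative_auc <- function(concentrations, viability) {
  stopifnot(length(concentrations) == length(viability))
  keep <- concentrations > 0
  x <- log10(concentrations[keep])
  y <- viability[keep]
  if (length(x) < 2) stop("need >= 2 nonzero concentrations")
  o <- order(x)
  x <- x[o]; y <- y[o]
  100 * pracma::trapz(x, y) / (max(x) - min(x))
}

#' Fit a four-parameter log-logistic inhibition curve
#'
#' Least-squares fit of \eqn{y = lower + (upper - lower) /
#' (1 + (EC50/x)^{slope})} (inhibition rising with dose) with bounds
#' \eqn{0 \le lower \le upper \le 1}, EC50 within the dose range extended
#' 100-fold on both sides and slope in \code{[0.1, 10]}. Initialization is a
#' deterministic multi-start grid over slopes and EC50 candidates; the best
#' converged fit by residual sum of squares is kept. A monotone-decreasing
#' response (viability handed in instead of inhibition) is detected and
#' flipped with a warning; a constant response returns a flat fallback fit
#' with \code{slope = NA} and \code{degenerate = TRUE}.
#'
#' @param concentrations Nonzero dose values (>= 4 distinct for a full fit).
#' @param responses Inhibition fractions at those doses.
#' @param lower_fixed,upper_fixed Optionally pin the asymptotes (used by the
#'   ZIP potency-shifted refits).
#' @return List with \code{lower}, \code{upper}, \code{ec50}, \code{slope},
#'   \code{rss}, \code{degenerate}, \code{flipped} and \code{predict}, a
#'   function of dose.
#' @examples
#' x <- c(1, 3, 10, 30, 100)
#' fit <- fit_loglogistic(x, 1 / (1 + (10 / x)))
#' c(fit$ec50, fit$slope)
#' @export
fit_loglogistic <- function(concentrations, responses,
                            lower_fixed = NULL, upper_fixed = NULL) {
  stopifnot(length(concentrations) == length(responses))
  keep <- concentrations > 0 & is.finite(responses)
  x <- concentrations[keep]; y <- responses[keep]
  flipped <- FALSE
  if (length(unique(x)) >= 2 && stats::sd(y) > 0 && is.null(lower_fixed) &&
      stats::cor(log(x), y) < -0.2) {
    warning("response decreases with dose; flipping viability to inhibition")
    y <- 1 - y
    flipped <- TRUE
  }
  make_result <- function(lower, upper, ec50, slope, rss,
                          degenerate = FALSE) {
    pred <- function(dose) {
      if (!is.finite(slope) || upper == lower)
        return(rep(lower, length(dose)))
      lower + (upper - lower) * ifelse(dose > 0,
        1 / (1 + (ec50 / dose)^slope), 0)
    }
    list(lower = lower, upper = upper, ec50 = ec50, slope = slope,
         rss = rss, degenerate = degenerate, flipped = flipped,
         predict = pred)
  }
  if (length(unique(round(y, 10))) == 1L || length(unique(x)) < 2) {
    v <- y[1]
    return(make_result(v, v, stats::median(x), NA_real_, 0,
                       degenerate = TRUE))
  }
  fix_lower <- !is.null(lower_fixed)
  fix_upper <- !is.null(upper_fixed)
  ## parameters: log(ec50), log(slope), then free asymptotes
  le_b <- log(c(min(x) / 100, max(x) * 100))
  ls_b <- log(c(0.1, 10))
  unpack <- function(par) {
    lower <- if (fix_lower) lower_fixed else par[3]
    upper <- if (fix_upper) upper_fixed else par[if (fix_lower) 3 else 4]
    list(lower = lower, upper = upper,
         ec50 = exp(par[1]), slope = exp(par[2]))
  }
  objective <- function(par) {
    p <- unpack(par)
    yhat <- p$lower + (p$upper - p$lower) / (1 + (p$ec50 / x)^p$slope)
    sum((yhat - y)^2)
  }
  lo <- c(le_b[1], ls_b[1])
  hi <- c(le_b[2], ls_b[2])
  if (!fix_lower) { lo <- c(lo, 0); hi <- c(hi, 1) }
  if (!fix_upper) { lo <- c(lo, 0); hi <- c(hi, 1) }
  ec50_grid <- unique(c(stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
                        sqrt(min(x) * max(x))))
  best <- NULL
  for (s0 in c(0.5, 1, 2, 4)) for (e0 in ec50_grid) {
    par0 <- c(log(e0), log(s0))
    if (!fix_lower) par0 <- c(par0, max(min(y), 0))
    if (!fix_upper) par0 <- c(par0, min(max(y), 1))
    opt <- tryCatch(
      stats::optim(par0, objective, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(factr = 1e3, maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-15) best <- opt
  }
  if (is.null(best)) {
    v <- mean(y)
    return(make_result(v, v, stats::median(x), NA_real_,
                       sum((y - v)^2), degenerate = TRUE))
  }
  p <- unpack(best$par)
  rss <- best$value
  ## Levenberg-Marquardt polish for high-precision convergence; the L-BFGS-B
  ## solution stands when the polish fails (e.g. singular gradient on
  ## noiseless data)
  polish <- tryCatch({
    start <- list(ec50 = p$ec50, slope = p$slope)
    if (!fix_lower) start$lower <- p$lower
    if (!fix_upper) start$upper <- p$upper
    lo_b <- c(lower = 0, upper = 0, ec50 = exp(le_b[1]), slope = exp(ls_b[1]))
    hi_b <- c(lower = 1, upper = 1, ec50 = exp(le_b[2]), slope = exp(ls_b[2]))
    form_terms <- c(
      lower = if (fix_lower) format(lower_fixed, digits = 17) else "lower",
      upper = if (fix_upper) format(upper_fixed, digits = 17) else "upper")
    form <- stats::as.formula(paste0(
      "y ~ ", form_terms["lower"], " + (", form_terms["upper"], " - ",
      form_terms["lower"], ") / (1 + (ec50 / x)^slope)"))
    fit <- suppressWarnings(minpack.lm::nlsLM(
      form, data = data.frame(x = x, y = y),
                             start = start,
                             lower = lo_b[names(start)],
                             upper = hi_b[names(start)],
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200, ftol = 1e-15, ptol = 1e-15)))
    cf <- stats::coef(fit)
    list(lower = if (fix_lower) lower_fixed else unname(cf["lower"]),
         upper = if (fix_upper) upper_fixed else unname(cf["upper"]),
         ec50 = unname(cf["ec50"]), slope = unname(cf["slope"]),
         rss = sum(stats::residuals(fit)^2))
  }, error = function(e) NULL)
  if (!is.null(polish) && polish$rss <= rss)
    return(make_result(polish$lower, polish$upper, polish$ec50,
                       polish$slope, polish$rss))
  make_result(p$lower, p$upper, p$ec50, p$slope, rss)
}

## ---------------------------------------------------------------------------
## ZIP synergy
## ---------------------------------------------------------------------------

## Monotherapy inhibition fits for both axes of a dose matrix.
monotherapy_fits <- function(mat) {
  inh <- pmin(pmax(1 - mat$viability, 0), 1)
  a_nz <- mat$conc_a > 0
  b_nz <- mat$conc_b > 0
  fit_a <- fit_loglogistic(mat$conc_a[a_nz], inh[1, a_nz])
  fit_b <- fit_loglogistic(mat$conc_b[b_nz], inh[b_nz, 1])
  list(inh = inh, fit_a = fit_a, fit_b = fit_b, a_nz = a_nz, b_nz = b_nz)
}

#' ZIP synergy surface of a drug-combination matrix
#'
#' Zero interaction potency (ZIP) scoring. Viability is converted to
#' inhibition (\eqn{y = 1 - viability}, clipped to \code{[0, 1]}) and each
#' monotherapy axis is fitted with a log-logistic curve. The expected surface
#' under zero interaction is the independence baseline
#' \eqn{y_a + y_b - y_a y_b} of the fitted monotherapy effects. The observed
#' surface is smoothed by potency-shifted refits: for each nonzero dose of
#' drug B, the combination responses along the drug-A axis are refitted with
#' the lower asymptote pinned at drug B's fitted monotherapy effect and the
#' upper asymptote at 1 (and symmetrically along the other axis). The delta
#' surface is the mean of the two directional (refit minus expected)
#' surfaces over cells where both doses are nonzero, and the summary score is
#' the mean of the \code{n_top} (default 9) largest delta values. Axes whose
#' refit fails fall back to the observed inhibition values and are flagged.
#'
#' @param mat A \code{dose_matrix} with normalized viability and both
#'   monotherapy axes present.
#' @param n_top Number of largest delta cells averaged into the summary
#'   (default 9, covering a 3x3 region's worth of wells).
#' @param top_mode \code{"cells"} (default) averages the \code{n_top} largest
#'   delta cells anywhere in the matrix; \code{"window"} averages the most
#'   synergistic contiguous 3x3 window.
#' @return A \code{zip_result}: list with \code{delta} (matrix over nonzero
#'   dose cells), \code{summary}, \code{expected}, \code{fit_a},
#'   \code{fit_b} and \code{fallback} (logical).
#' @examples
#' m <- simulate_dose_response(delta_true = 0, noise_sd = 0, seed = 1)
#' zip_delta(m)$summary  # ~0 under exact Bliss independence
#' @export
zip_delta <- function(mat, n_top = 9, top_mode = c("cells", "window")) {
  top_mode <- match.arg(top_mode)
  stopifnot(inherits(mat, "dose_matrix"))
  if (!any(mat$conc_a == 0) || !any(mat$conc_b == 0))
    stop("monotherapy axis missing (need zero-dose row and column)")
  mono <- monotherapy_fits(mat)
  res <- zip_core(mono$inh, mat$conc_a, mat$conc_b,
                  mono$fit_a, mono$fit_b, y_c = 0)
  summary_score <- top_delta_mean(res$delta, n_top, top_mode)
  structure(list(delta = res$delta, summary = summary_score,
                 expected = res$expected,
                 fit_a = mono$fit_a, fit_b = mono$fit_b,
                 fallback = res$fallback),
            class = "zip_result")
}

## Directional potency-shifted refits + independence baseline; y_c folds a
## third drug's effect into floors and expectation (y_c = 0 reduces to 2-D).
zip_core <- function(inh, conc_a, conc_b, fit_a, fit_b, y_c = 0) {
  a_nz <- which(conc_a > 0)
  b_nz <- which(conc_b > 0)
  ya <- fit_a$predict(conc_a[a_nz])
  yb <- fit_b$predict(conc_b[b_nz])
  expected <- outer(yb, ya, function(b, a) 1 - (1 - a) * (1 - b) * (1 - y_c))
  fallback <- FALSE
  fit1 <- matrix(NA_real_, length(b_nz), length(a_nz))
  for (j in seq_along(b_nz)) {   # along A at fixed B dose
    floor_j <- 1 - (1 - yb[j]) * (1 - y_c)
    obs <- inh[b_nz[j], a_nz]
    f <- fit_loglogistic(conc_a[a_nz], obs,
                         lower_fixed = min(floor_j, 1),
                         upper_fixed = 1)
    if (f$degenerate) { fit1[j, ] <- obs; fallback <- TRUE }
    else fit1[j, ] <- f$predict(conc_a[a_nz])
  }
  fit2 <- matrix(NA_real_, length(b_nz), length(a_nz))
  for (i in seq_along(a_nz)) {   # along B at fixed A dose
    floor_i <- 1 - (1 - ya[i]) * (1 - y_c)
    obs <- inh[b_nz, a_nz[i]]
    f <- fit_loglogistic(conc_b[b_nz], obs,
                         lower_fixed = min(floor_i, 1),
                         upper_fixed = 1)
    if (f$degenerate) { fit2[, i] <- obs; fallback <- TRUE }
    else fit2[, i] <- f$predict(conc_b[b_nz])
  }
  delta <- (fit1 + fit2) / 2 - expected
  dimnames(delta) <- list(format(conc_b[b_nz], trim = TRUE),
                          format(conc_a[a_nz], trim = TRUE))
  list(delta = delta, expected = expected, fallback = fallback)
}

top_delta_mean <- function(delta, n_top, top_mode) {
  v <- delta[is.finite(delta)]
  if (top_mode == "cells") {
    n_top <- min(n_top, length(v))
    return(mean(sort(v, decreasing = TRUE)[seq_len(n_top)]))
  }
  ## most synergistic contiguous 3x3 window
  nr <- nrow(delta); nc <- ncol(delta)
  if (nr < 3 || nc < 3) return(mean(v))
  best <- -Inf
  for (i in 1:(nr - 2)) for (j in 1:(nc - 2)) {
    m <- mean(delta[i:(i + 2), j:(j + 2)])
    if (m > best) best <- m
  }
  best
}

#' Per-layer ZIP synergy of a three-drug dose stack
#'
#' For a stack of dose matrices acquired at fixed doses of a third drug, each
#' layer is scored with the ZIP machinery of \code{\link{zip_delta}}, with
#' the third drug's monotherapy effect at the layer's dose folded into the
#' independence baseline (three-way Bliss:
#' \eqn{1 - (1-y_a)(1-y_b)(1-y_c)}) and into the refit floors. The third
#' drug's effect per layer is read from the double-vehicle well of the layer
#' (inhibition at zero dose of drugs A and B). With an inert third drug every
#' layer reduces exactly to the two-drug analysis.
#'
#' @param stack List of \code{dose_matrix} layers (>= 2) with identical
#'   concentration axes.
#' @param conc_c Third-drug dose per layer (same length as \code{stack});
#'   defaults to layer index metadata only.
#' @param n_top,top_mode Passed to the per-layer summary.
#' @return List with \code{layers} (per-layer \code{zip_result}),
#'   \code{summaries} (numeric vector), \code{y_c} (third-drug effect per
#'   layer) and \code{cube} (deviation array, layer x B-dose x A-dose).
#' @export
zip_delta_3d <- function(stack, conc_c = seq_along(stack) - 1,
                         n_top = 9, top_mode = "cells") {
  stopifnot(length(stack) >= 2)
  ca <- stack[[1]]$conc_a; cb <- stack[[1]]$conc_b
  for (m in stack)
    if (!isTRUE(all.equal(m$conc_a, ca)) || !isTRUE(all.equal(m$conc_b, cb)))
      stop("inconsistent concentration axes across layers")
  layers <- vector("list", length(stack))
  y_c <- numeric(length(stack))
  for (k in seq_along(stack)) {
    mat <- stack[[k]]
    inh <- pmin(pmax(1 - mat$viability, 0), 1)
    y_c[k] <- inh[1, 1]
    ## monotherapy axes net of the third drug's effect at this layer
    strip <- function(y) pmin(pmax((y - y_c[k]) / max(1 - y_c[k], 1e-9), 0), 1)
    a_nz <- ca > 0; b_nz <- cb > 0
    fit_a <- fit_loglogistic(ca[a_nz], strip(inh[1, a_nz]))
    fit_b <- fit_loglogistic(cb[b_nz], strip(inh[b_nz, 1]))
    res <- zip_core(inh, ca, cb, fit_a, fit_b, y_c = y_c[k])
    layers[[k]] <- structure(
      list(delta = res$delta, summary = top_delta_mean(res$delta, n_top,
                                                       top_mode),
           expected = res$expected, fit_a = fit_a, fit_b = fit_b,
           fallback = res$fallback),
      class = "zip_result")
  }
  cube <- array(NA_real_,
                dim = c(length(stack), sum(cb > 0), sum(ca > 0)),
                dimnames = list(format(conc_c, trim = TRUE), NULL, NULL))
  for (k in seq_along(stack)) cube[k, , ] <- layers[[k]]$delta
  list(layers = layers,
       summaries = vapply(layers, `[[`, 0, "summary"),
       y_c = y_c, conc_c = conc_c, cube = cube)
}

#' @export
print.zip_result <- function(x, ...) {
  cat("ZIP synergy: summary (mean of top deltas) =",
      signif(x$summary, 4), "\n")
  if (x$fallback)
    cat("  note: one or more axes used observed values (unfittable refit)\n")
  invisible(x)
}
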
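# Fluorescence-polarization binding analysis: polarization from intensity
# pairs, the four-parameter logistic and single-site receptor-depletion
# isotherms, nonlinear least-squares fitting, and model comparison
# including the probe_total/2 depletion offset.

#' Fluorescence polarization from intensity pair
#'
#' `P = (I_par - I_perp) / (I_par + I_perp)`; mP = 1000 P.
#'
#' @param i_parallel,i_perp emitted intensities parallel/perpendicular to
#'   the excitation plane (non-negative; vectors allowed).
#' @return list with `P` (dimensionless) and `mP` (millipolarization).
#' @export
polarization <- function(i_parallel, i_perp) {
  if (any(i_parallel < 0) || any(i_perp < 0))
    stop("intensities must be non-negative")
  tot <- i_parallel + i_perp
  if (any(tot <= 0)) stop("zero total intensity")
  P <- (i_parallel - i_perp) / tot
  list(P = P, mP = 1000 * P)
}

#' Four-parameter logistic binding isotherm (log-concentration sigmoid)
#'
#' Boltzmann-type sigmoid in `x = log10(concentration)`:
#' `mP(x) = A2 + (A1 - A2) / (1 + exp((x - x0) / dx))`,
#' so the value tends to A1 at the dilute end, A2 at saturation, equals
#' `(A1 + A2)/2` at `x = x0` (the log10 apparent Kd), with transition width
#' `dx` in decades. The slope-factor mapping `n_H = 1 / (dx ln 10)` is the
#' Hill-coefficient convention reported alongside dx.
#'
#' @param x log10 molar concentration (vector allowed).
#' @param params list or named vector with `A1`, `A2`, `x0`, `dx` (dx != 0).
#' @return mP values.
#' @export
eval_logistic4 <- function(x, params) {
  p <- as.list(params)
  if (p$dx == 0) stop("dx must be nonzero")
  p$A2 + (p$A1 - p$A2) / (1 + exp((x - p$x0) / p$dx))
}

#' Single-site receptor-depletion binding isotherm
#'
#' The exact 1:1 quadratic isotherm: with titrant total `T`, fixed-species
#' (labelled probe) total `L`, and dissociation constant `Kd`, the bound
#' fraction of probe is
#' `f = (T + L + Kd - sqrt((T + L + Kd)^2 - 4 T L)) / (2 L)`,
#' and `mP = A1 + (A2 - A1) f`. Unlike the free-ligand approximation, this
#' form remains valid when the probe concentration is comparable to Kd; its
#' half-saturation point sits at `T = Kd + L/2`, which is why an
#' approximation-based fit overestimates Kd by about `L/2`.
#'
#' @param titrant_total titrant (receptor) total concentration, M (vector).
#' @param params list with `A1`, `A2`, `Kd` (> 0), `probe_total` (> 0).
#' @return mP values.
#' @export
eval_depletion <- function(titrant_total, params) {
  p <- as.list(params)
  stopifnot(p$Kd > 0, p$probe_total > 0)
  if (any(titrant_total < 0)) stop("concentrations must be non-negative")
  s <- titrant_total + p$probe_total + p$Kd
  disc <- s^2 - 4 * titrant_total * p$probe_total
  if (any(disc < 0)) stop("negative discriminant in depletion isotherm")
  f <- (s - sqrt(disc)) / (2 * p$probe_total)
  p$A1 + (p$A2 - p$A1) * f
}

guess_logistic4 <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  q <- max(3, floor(n / 4))
  A1 <- mean(y[seq_len(q)])
  A2 <- mean(y[seq(n - q + 1, n)])
  half <- (A1 + A2) / 2
  sign_up <- A2 >= A1
  cross <- which(if (sign_up) y >= half else y <= half)[1]
  x0 <- if (is.na(cross) || cross == 1) stats::median(x) else
    stats::approx(y[(cross - 1):cross], x[(cross - 1):cross], xout = half,
                  ties = "ordered")$y
  if (is.na(x0)) x0 <- stats::median(x)
  list(A1 = A1, A2 = A2, x0 = x0, dx = 1 / log(10))
}

#' Fit a binding isotherm to FP titration data
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) of either the
#' four-parameter logistic ([eval_logistic4()], fitted against
#' log10 concentration) or the receptor-depletion quadratic isotherm
#' ([eval_depletion()], Kd parameterized on the log10 scale for stability).
#' All replicate points are fitted individually by default. Initial guesses
#' are automatic: plateaus from the extreme quartiles and the midpoint from
#' the half-height crossing.
#'
#' @param data an `fp_dataset` from [simulate_fp()], or a data.frame with
#'   columns `conc_M` and `mP` (optionally `replicate`).
#' @param model_kind `"logistic4"` or `"depletion"`.
#' @param probe_total fixed-species total, M; taken from the dataset
#'   attribute when absent (required for the depletion model).
#' @param initial_guess optional named list overriding the automatic start.
#' @param average_replicates fit replicate means instead of raw points?
#' @return a `binding_fit`: list with `model_kind`, `params`, `se`, `rss`,
#'   `n_points`, `converged`, `kd` (M; `10^x0` for the logistic model),
#'   `kd_se`, `hill_report` (logistic only: `dx` and `n_H = 1/(dx ln 10)`),
#'   `probe_total`, and the underlying `fit` object.
#' @export
fit_model <- function(data, model_kind = c("logistic4", "depletion"),
                      probe_total = NULL, initial_guess = NULL,
                      average_replicates = FALSE) {
  model_kind <- match.arg(model_kind)
  df <- as.data.frame(data)
  stopifnot(all(c("conc_M", "mP") %in% names(df)))
  if (is.null(probe_total)) probe_total <- attr(data, "probe_total")
  if (average_replicates) {
    df <- stats::aggregate(mP ~ conc_M, df, mean)
  }
  if (length(unique(df$conc_M)) < 6)
    stop("need at least 6 distinct concentrations")
  x <- log10(df$conc_M)
  y <- df$mP
  g <- guess_logistic4(x, y)
  if (model_kind == "logistic4") {
    start <- utils::modifyList(g, as.list(initial_guess %||% list()))
    fit <- minpack.lm::nlsLM(
      mP ~ A2 + (A1 - A2) / (1 + exp((lx - x0) / dx)),
      data = data.frame(lx = x, mP = y),
      start = start, control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    if (is.null(probe_total))
      stop("probe_total is required for the depletion model")
    start <- list(A1 = g$A1, A2 = g$A2, lKd = g$x0)
    if (!is.null(initial_guess)) {
      ig <- as.list(initial_guess)
      if (!is.null(ig$Kd)) { ig$lKd <- log10(ig$Kd); ig$Kd <- NULL }
      start <- utils::modifyList(start, ig)
    }
    fit <- minpack.lm::nlsLM(
      mP ~ A1 + (A2 - A1) *
        ((conc + L + 10^lKd) -
           sqrt((conc + L + 10^lKd)^2 - 4 * conc * L)) / (2 * L),
      data = data.frame(conc = df$conc_M, L = probe_total, mP = y),
      start = start, control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  sm <- summary(fit)
  cf <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  converged <- fit$convInfo$isConv %||% TRUE
  if (model_kind == "logistic4") {
    kd <- 10^cf[["x0"]]
    kd_se <- kd * log(10) * se[["x0"]]
    hill <- list(dx = cf[["dx"]], n_H = 1 / (cf[["dx"]] * log(10)))
    if (cf[["x0"]] < min(x) || cf[["x0"]] > max(x))
      warning("transition midpoint not bracketed by the data")
    params <- as.list(cf)
  } else {
    kd <- 10^cf[["lKd"]]
    kd_se <- kd * log(10) * se[["lKd"]]
    hill <- NULL
    if (log10(kd) < min(x) || log10(kd) > max(x))
      warning("transition midpoint not bracketed by the data")
    params <- list(A1 = cf[["A1"]], A2 = cf[["A2"]], Kd = kd)
  }
  structure(list(model_kind = model_kind, params = params,
                 se = as.list(se), rss = sum(stats::residuals(fit)^2),
                 n_points = length(y), converged = isTRUE(converged),
                 kd = kd, kd_se = kd_se, hill_report = hill,
                 probe_total = probe_total, fit = fit),
            class = "binding_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("binding_fit (%s): Kd = %.3g M (se %.2g), rss = %.3g over %d points%s\n",
              x$model_kind, x$kd, x$kd_se, x$rss, x$n_points,
              if (x$converged) "" else " [NOT CONVERGED]"))
  if (!is.null(x$hill_report))
    cat(sprintf("  dx = %.4f decades, n_H = %.3f\n",
                x$hill_report$dx, x$hill_report$n_H))
  invisible(x)
}

#' Compare a logistic and a depletion fit of the same dataset
#'
#' Tabulates the two Kd estimates, their percent difference, residual sums
#' of squares, the predicted depletion offset `probe_total / 2`, and the
#' logistic slope report (`dx`, `n_H`).
#'
#' @param fit_logistic,fit_depletion `binding_fit`s of different kinds on
#'   the same data.
#' @return a `binding_comparison` list.
#' @export
compare_fits <- function(fit_logistic, fit_depletion) {
  if (fit_logistic$model_kind == fit_depletion$model_kind)
    stop("fits must come from the two different models")
  if (fit_logistic$model_kind != "logistic4")
    return(compare_fits(fit_depletion, fit_logistic))
  kd_l <- fit_logistic$kd
  kd_d <- fit_depletion$kd
  structure(list(
    kd_logistic = kd_l, kd_depletion = kd_d,
    percent_difference = 100 * (kd_l - kd_d) / kd_d,
    offset = kd_l - kd_d,
    predicted_offset = fit_depletion$probe_total / 2,
    rss_logistic = fit_logistic$rss, rss_depletion = fit_depletion$rss,
    hill_report = fit_logistic$hill_report),
    class = "binding_comparison")
}

#' @export
print.binding_comparison <- function(x, ...) {
  cat(sprintf("Kd(logistic) %.3g M vs Kd(depletion) %.3g M (%+.1f%%)\n",
              x$kd_logistic, x$kd_depletion, x$percent_difference))
  cat(sprintf("  offset %.3g M; predicted depletion offset probe/2 = %.3g M\n",
              x$offset, x$predicted_offset))
  cat(sprintf("  n_H (logistic) = %.3f\n", x$hill_report$n_H))
  invisible(x)
}
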
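# HTRF ratio algebra and the three binding-assay fits: four-parameter
# logistic competition curves, Boltzmann melt curves, and the one-site
# (Wiseman) ITC isotherm with its thermodynamic derivations.

R_GAS <- 8.314          # J / (mol K)

#' Model functions for the binding assays
#'
#' `fourpl()` is the variable-slope four-parameter logistic in log10
#' concentration: `bottom + (top - bottom) / (1 + 10^((logIC50 - x) * hill))`.
#' `boltzmann_sigmoid()` is the melt sigmoid
#' `f_min + (f_max - f_min) / (1 + exp((tm_c - t_c) / slope_a))`.
#' `wiseman_ndh()` is the differential one-site isotherm: the heat per mole
#' of injectant at total-ligand/total-macromolecule molar ratio `xr`,
#' `delta_H * dB/dXt`, with the bound fraction `B` from the exact quadratic
#' one-site binding equation (association constant `K_A` in 1/M,
#' stoichiometry `n_sites`, cell concentration in M).
#'
#' @param x log10 molar concentration.
#' @param top,bottom,logIC50,hill 4PL parameters (`hill` nonzero).
#' @name assay_models
#' @export
fourpl <- function(x, top, bottom, logIC50, hill) {
  bottom + (top - bottom) / (1 + 10^((logIC50 - x) * hill))
}

#' @rdname assay_models
#' @param t_c temperature in degrees Celsius.
#' @param f_min,f_max,tm_c,slope_a Boltzmann parameters (`slope_a` > 0).
#' @export
boltzmann_sigmoid <- function(t_c, f_min, f_max, tm_c, slope_a) {
  f_min + (f_max - f_min) / (1 + exp((tm_c - t_c) / slope_a))
}

#' @rdname assay_models
#' @param xr molar ratio (total injectant / total macromolecule in cell).
#' @param n_sites,K_A,delta_H one-site parameters (K_A in 1/M, delta_H in
#'   kJ/mol).
#' @param cell_conc macromolecule concentration in the cell (M).
#' @export
wiseman_ndh <- function(xr, n_sites, K_A, delta_H, cell_conc) {
  Mt <- cell_conc
  Xt <- xr * Mt
  A <- n_sites * Mt + Xt + 1 / K_A
  S <- sqrt(A^2 - 4 * n_sites * Mt * Xt)
  dBdX <- (1 - (A - 2 * n_sites * Mt) / S) / 2
  delta_H * dBdX
}

#' HTRF delta-F from acceptor/donor ratios
#'
#' `delta_f()` computes the background-corrected percent change
#' `100 * (R_sample - R_nsb) / R_nsb` where `R` is the A665/A615
#' fluorescence ratio and `R_nsb` the non-specific-binding control.
#' `normalize_competition()` divides competition delta-F values by the
#' no-competitor maximum `dF0`.
#'
#' @param r_sample A665/A615 ratio(s) of the sample wells.
#' @param r_nsb positive A665/A615 ratio of the no-protein control.
#' @return Percent delta-F, same length as `r_sample`.
#' @export
delta_f <- function(r_sample, r_nsb) {
  if (!is.numeric(r_nsb) || length(r_nsb) != 1L || !is.finite(r_nsb) ||
      r_nsb <= 0)
    stop("'r_nsb' must be a positive scalar")
  100 * (r_sample - r_nsb) / r_nsb
}

#' @rdname delta_f
#' @param dF numeric vector of delta-F values.
#' @param dF0 positive scalar, delta-F in the absence of competitor.
#' @export
normalize_competition <- function(dF, dF0) {
  if (!is.numeric(dF0) || length(dF0) != 1L || !is.finite(dF0) || dF0 <= 0)
    stop("'dF0' must be a positive scalar")
  dF / dF0
}

best_nls <- function(formula, data, starts, lower = NULL, upper = NULL) {
  best <- NULL; best_rss <- Inf; last_err <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) { last_err <- fit; next }
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss) { best <- fit; best_rss <- rss }
  }
  if (is.null(best))
    stop("no start converged; last optimiser error: ",
         conditionMessage(last_err))
  best
}

r_squared <- function(y, fitted) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(0)     # flat data carry no explainable variance
  1 - sum((y - fitted)^2) / ss_tot
}

#' Fit a variable-slope four-parameter logistic competition curve
#'
#' Least-squares fit of [fourpl()] to normalised competition data, with
#' top/bottom initialised from the response extremes, logIC50 at the
#' interpolated half-maximum crossing and Hill slope of either sign, plus
#' seeded multistart jitter to escape local minima. Fits with
#' `r_squared > 0.99` are flagged significant.
#'
#' @param x_log_molar log10 molar competitor concentrations (>= 5 distinct).
#' @param y responses (e.g. delta-F / delta-F0).
#' @param multistart number of jittered restarts (default 8).
#' @param seed integer seed for the restarts.
#' @return Object of class `dose_response_fit`: `top`, `bottom`,
#'   `logIC50`, `hill`, `ic50` (molar), `r_squared`, `significant`,
#'   `fitted`, `data`.
#' @export
fit_4pl <- function(x_log_molar, y, multistart = 8L, seed = 1L) {
  stopifnot(length(x_log_molar) == length(y))
  if (length(unique(x_log_molar)) < 5L)
    stop("need at least 5 distinct doses")
  local_seed(seed)
  d <- data.frame(x = x_log_molar, y = y)
  if (stats::sd(y) == 0)   # flat response: nothing to fit, never significant
    return(structure(list(top = y[1], bottom = y[1],
                          logIC50 = stats::median(x_log_molar), hill = 1,
                          ic50 = 10^stats::median(x_log_molar),
                          r_squared = 0, significant = FALSE,
                          fitted = y, data = d),
                     class = "dose_response_fit"))
  top0 <- max(y); bot0 <- min(y)
  half <- (top0 + bot0) / 2
  ord <- order(d$x)
  xs <- d$x[ord]; ys <- d$y[ord]
  cross <- which(diff(sign(ys - half)) != 0)
  lid0 <- if (length(cross)) {
    i <- cross[1]
    xs[i] + (half - ys[i]) * (xs[i + 1] - xs[i]) / (ys[i + 1] - ys[i])
  } else stats::median(xs)
  starts <- list()
  for (h in c(1, -1))
    starts[[length(starts) + 1L]] <-
      list(top = top0, bottom = bot0, logIC50 = lid0, hill = h)
  for (k in seq_len(max(0L, multistart - 2L)))
    starts[[length(starts) + 1L]] <- list(
      top = top0 + stats::rnorm(1, 0, 0.05 * max(abs(top0), 1)),
      bottom = bot0 + stats::rnorm(1, 0, 0.05 * max(abs(top0), 1)),
      logIC50 = lid0 + stats::rnorm(1, 0, 0.5),
      hill = sample(c(-1, 1), 1) * stats::runif(1, 0.5, 2))
  fit <- best_nls(y ~ fourpl(x, top, bottom, logIC50, hill), d, starts)
  cf <- as.list(stats::coef(fit))
  if (cf$hill < 0) {        # mirror parameterization: identical curve
    tmp <- cf$top; cf$top <- cf$bottom; cf$bottom <- tmp
    cf$hill <- -cf$hill
  }
  r2 <- r_squared(d$y, stats::fitted(fit))
  structure(list(top = cf$top, bottom = cf$bottom, logIC50 = cf$logIC50,
                 hill = cf$hill, ic50 = 10^cf$logIC50,
                 r_squared = r2, significant = r2 > 0.99,
                 fitted = as.numeric(stats::fitted(fit)), data = d),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("4PL fit: IC50 = %.3g M (logIC50 = %.3f), hill = %.2f,\n",
                     "  top = %.3g, bottom = %.3g, R^2 = %.4f (%ssignificant)\n"),
              x$ic50, x$logIC50, x$hill, x$top, x$bottom, x$r_squared,
              if (x$significant) "" else "not "))
  invisible(x)
}

#' Fit a Boltzmann sigmoid to a thermal melt curve
#'
#' The curve is truncated at its global fluorescence maximum before
#' fitting (the post-peak decay reflects dye dissociation from
#' aggregates, not the unfolding transition the sigmoid models), then
#' [boltzmann_sigmoid()] is fitted by least squares. The melting
#' temperature is the sigmoid midpoint.
#'
#' @param t_c temperatures in degrees Celsius, increasing.
#' @param f fluorescence readings.
#' @param reference_tm_c optional control Tm; when given, `delta_tm_c =
#'   tm_c - reference_tm_c` reports the thermal shift.
#' @return Object of class `melt_fit`: `f_min`, `f_max`, `tm_c`,
#'   `slope_a`, `delta_tm_c`, `r_squared`, `data` (truncated window).
#' @export
fit_boltzmann <- function(t_c, f, reference_tm_c = NULL) {
  stopifnot(length(t_c) == length(f))
  if (is.unsorted(t_c, strictly = TRUE)) stop("temperatures must increase")
  peak <- which.max(f)
  if (peak < 8L)
    stop("no rising transition before the fluorescence maximum")
  d <- data.frame(t = t_c[seq_len(peak)], f = f[seq_len(peak)])
  f0 <- min(d$f); f1 <- max(d$f)
  half <- (f0 + f1) / 2
  tm0 <- d$t[which.min(abs(d$f - half))]
  starts <- lapply(c(1, 2.5, 5), function(a)
    list(f_min = f0, f_max = f1, tm_c = tm0, slope_a = a))
  fit <- best_nls(f ~ boltzmann_sigmoid(t, f_min, f_max, tm_c, slope_a),
                  d, starts,
                  lower = c(-Inf, -Inf, min(d$t), 1e-6),
                  upper = c(Inf, Inf, max(d$t), Inf))
  cf <- as.list(stats::coef(fit))
  if (cf$f_max <= cf$f_min) stop("no transition: fitted amplitude <= 0")
  structure(list(f_min = cf$f_min, f_max = cf$f_max, tm_c = cf$tm_c,
                 slope_a = cf$slope_a,
                 delta_tm_c = if (is.null(reference_tm_c)) NA_real_
                              else cf$tm_c - reference_tm_c,
                 r_squared = r_squared(d$f, stats::fitted(fit)),
                 data = d),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Boltzmann melt fit: Tm = %.2f C (slope %.2f), R^2 = %.4f\n",
              x$tm_c, x$slope_a, x$r_squared))
  if (!is.na(x$delta_tm_c))
    cat(sprintf("  delta-Tm vs control = %+.2f C\n", x$delta_tm_c))
  invisible(x)
}

#' Thermodynamic derivations from an association constant
#'
#' `delta_G = -R * T * ln(K_A)` and `T_delta_S = delta_H - delta_G`, with
#' the gas constant `R = 8.314` J/(mol K); energies are reported in
#' kJ/mol.
#'
#' @param K_A association constant (1/M), positive.
#' @param delta_H binding enthalpy (kJ/mol).
#' @param T_kelvin absolute temperature (K), positive.
#' @return list with `delta_G` and `T_delta_S` (kJ/mol).
#' @export
derive_thermo <- function(K_A, delta_H, T_kelvin) {
  stopifnot(K_A > 0, T_kelvin > 0)
  delta_G <- -R_GAS * T_kelvin * log(K_A) / 1000
  list(delta_G = delta_G, T_delta_S = delta_H - delta_G)
}

#' Fit a one-site ITC isotherm
#'
#' Least-squares fit of the differential Wiseman isotherm
#' ([wiseman_ndh()]) to integrated per-injection heats, estimating the
#' stoichiometry `n_sites`, association constant `K_A` and enthalpy
#' `delta_H`. The first injection is discarded by default (the customary
#' small priming injection). Gibbs energy and entropy follow from
#' [derive_thermo()], so `delta_G = delta_H - T_delta_S` holds exactly on
#' every returned fit. Fits with Wiseman c-value `K_A * cell_conc *
#' n_sites < 1` are flagged low-confidence.
#'
#' @param molar_ratio total injectant / total macromolecule per injection.
#' @param ndh integrated heat per mole of injectant (kJ/mol).
#' @param cell_conc macromolecule concentration in the cell (M).
#' @param multistart number of jittered restarts (default 8).
#' @param seed integer seed for the restarts.
#' @param T_kelvin experiment temperature (default 298.15 K).
#' @param drop_first discard the first injection (default TRUE).
#' @return Object of class `itc_fit`: `n_sites`, `K_A`, `K_d`, `delta_H`,
#'   `delta_G`, `T_delta_S`, `T_kelvin`, `c_value`, `low_confidence`,
#'   `r_squared`, `data`.
#' @export
fit_itc_one_site <- function(molar_ratio, ndh, cell_conc, multistart = 8L,
                             seed = 1L, T_kelvin = 298.15,
                             drop_first = TRUE) {
  stopifnot(length(molar_ratio) == length(ndh), cell_conc > 0)
  keep <- if (drop_first) -1L else seq_along(ndh)
  xr <- molar_ratio[keep]; q <- ndh[keep]
  if (length(xr) < 10L) stop("need at least 10 injections")
  if (all(abs(q) < 1e-9 * max(1, abs(cell_conc))))
    stop("all heats are zero: no binding signal to fit")
  local_seed(seed)
  d <- data.frame(xr = xr, q = q)
  dh0 <- q[which.max(abs(q))]
  n0 <- xr[which.min(abs(q - dh0 / 2))]      # half-saturation molar ratio
  if (!is.finite(n0) || n0 <= 0) n0 <- 1
  starts <- list(list(n_sites = n0, lK = log10(1 / (cell_conc)), dH = dh0),
                 list(n_sites = 1, lK = 6, dH = dh0))
  for (k in seq_len(max(0L, multistart - 2L)))
    starts[[length(starts) + 1L]] <- list(
      n_sites = stats::runif(1, 0.5, 2) * n0,
      lK = stats::runif(1, 3, 9),
      dH = dh0 * stats::runif(1, 0.5, 2))
  fit <- best_nls(q ~ wiseman_ndh(xr, n_sites, 10^lK, dH, cell_conc),
                  d, starts,
                  lower = c(1e-3, 0, -Inf), upper = c(100, 15, Inf))
  cf <- as.list(stats::coef(fit))
  K_A <- 10^cf$lK
  th <- derive_thermo(K_A, cf$dH, T_kelvin)
  cval <- K_A * cell_conc * cf$n_sites
  structure(list(n_sites = cf$n_sites, K_A = K_A, K_d = 1 / K_A,
                 delta_H = cf$dH, delta_G = th$delta_G,
                 T_delta_S = th$T_delta_S, T_kelvin = T_kelvin,
                 c_value = cval, low_confidence = cval < 1,
                 r_squared = r_squared(d$q, stats::fitted(fit)),
                 data = d),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf(paste0("one-site ITC fit: n = %.3f, K_d = %.3g M, ",
                     "dH = %.2f kJ/mol\n  dG = %.2f, TdS = %.2f kJ/mol ",
                     "(T = %.2f K, c = %.3g%s)\n"),
              x$n_sites, x$K_d, x$delta_H, x$delta_G, x$T_delta_S,
              x$T_kelvin, x$c_value,
              if (x$low_confidence) ", low confidence" else ""))
  invisible(x)
}
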
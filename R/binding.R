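#' Fluorescence polarization from raw intensities
#'
#' `FP = 1000 * (S - G*P) / (S + G*P)` (mP-like scale in \[-1000, 1000\]),
#' where S and P are the emission intensities parallel and perpendicular
#' to the excitation beam and G corrects for instrument bias.
#'
#' @param S,P Non-negative intensities (vectors recycled).
#' @param G Instrument correction factor (> 0).
#' @return Polarization values.
#' @export
fp_from_intensities <- function(S, P, G = 1) {
  if (any(S < 0) || any(P < 0)) stop("intensities must be >= 0")
  if (G <= 0) stop("G factor must be > 0")
  denom <- S + G * P
  if (any(denom == 0)) stop("S + G*P must be > 0")
  1000 * (S - G * P) / denom
}

#' Estimate the instrument G factor from a probe-only well
#'
#' Solves the polarization equation for G given the intensities of the
#' free probe and its nominal polarization `FP0` (default 0, in which
#' case G = S0/P0).
#'
#' @param S0,P0 Probe-only parallel / perpendicular intensities (> 0).
#' @param FP0 Nominal polarization of the free probe.
#' @return The G factor.
#' @export
estimate_g_factor <- function(S0, P0, FP0 = 0) {
  if (any(S0 <= 0) || any(P0 <= 0)) stop("probe intensities must be > 0")
  if (any(abs(FP0) >= 1000)) stop("FP0 must lie strictly within (-1000, 1000)")
  (S0 / P0) * (1000 - FP0) / (1000 + FP0)
}

#' Quadratic ligand-depletion binding isotherm
#'
#' Polarization of a labeled ligand (total concentration `L_T`) titrated
#' with protein at total concentration `P_T`, under the exact (ligand
#' depletion) solution of 1:1 binding:
#' `F = F_L + (F_LP - F_L) * (b - sqrt(b^2 - 4*L_T*P_T)) / (2*L_T)` with
#' `b = L_T + P_T + K_D`. Reduces to the hyperbola
#' `F_L + (F_LP - F_L) * P_T / (P_T + K_D)` when `L_T << K_D`.
#'
#' @param P_T Total protein concentration(s) (molar, >= 0).
#' @param K_D Dissociation constant (molar, > 0).
#' @param F_L Polarization of the free ligand.
#' @param F_LP Maximum polarization of the complex.
#' @param L_T Total labeled ligand concentration (molar, > 0).
#' @return Polarization value(s) F.
#' @export
isotherm_value <- function(P_T, K_D, F_L, F_LP, L_T) {
  if (any(P_T < 0)) stop("P_T must be >= 0")
  if (K_D <= 0 || L_T <= 0) stop("K_D and L_T must be > 0")
  b <- L_T + P_T + K_D
  disc <- b^2 - 4 * L_T * P_T
  if (any(disc < 0)) stop("negative discriminant: invalid inputs")
  bound_frac <- (b - sqrt(disc)) / (2 * L_T)  # fraction of ligand bound
  F_L + (F_LP - F_L) * bound_frac
}

#' Fit the ligand-depletion isotherm to a titration curve
#'
#' Unweighted least squares of `(K_D, F_L, F_LP)` with `L_T` fixed.
#' K_D is fitted on the log scale (positivity and conditioning), starting
#' from the geometric mean of the protein grid; `F_L`/`F_LP` start at the
#' min/max observed polarization. Standard errors come from the local
#' curvature at the optimum; a fit is reported `converged = FALSE` when
#' the optimiser fails or the data do not determine K_D (flat curve, or
#' log-K_D standard error exceeding 1, i.e. K_D undetermined within a
#' factor of e).
#'
#' @param P_T Protein concentrations (molar, >= 5 points).
#' @param F Measured polarizations.
#' @param L_T Total labeled ligand concentration (molar).
#' @return An object of class `isotherm_fit`: list with `K_D`, `F_L`,
#'   `F_LP`, `se` (named; `se["K_D"]` by the delta method), `residual_norm`,
#'   `converged`, `n_points`, `L_T`.
#' @export
fit_isotherm <- function(P_T, F, L_T) {
  stopifnot(length(P_T) == length(F))
  if (length(P_T) < 5) stop("need >= 5 titration points")
  failed <- function() structure(
    list(K_D = NA_real_, F_L = NA_real_, F_LP = NA_real_,
         se = c(K_D = NA_real_, F_L = NA_real_, F_LP = NA_real_),
         residual_norm = NA_real_, converged = FALSE,
         n_points = length(P_T), L_T = L_T), class = "isotherm_fit")
  if (diff(range(F)) == 0) return(failed())
  df <- data.frame(P_T = P_T, F = F)
  start <- list(lKD = log(exp(mean(log(P_T[P_T > 0])))),
                F_L = min(F), F_LP = max(F))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      F ~ isotherm_value(P_T, exp(lKD), F_L, F_LP, L_T),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, 3) |> stats::setNames(names(cf)))
  K_D <- exp(cf[["lKD"]])
  identifiable <- is.finite(se[["lKD"]]) && se[["lKD"]] < 1
  structure(list(
    K_D = K_D, F_L = cf[["F_L"]], F_LP = cf[["F_LP"]],
    se = c(K_D = K_D * se[["lKD"]], F_L = se[["F_L"]],
           F_LP = se[["F_LP"]]),
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    converged = isTRUE(fit$convInfo$isConv) && identifiable,
    n_points = length(P_T), L_T = L_T), class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat("isotherm_fit (n =", x$n_points, ", converged =", x$converged, ")\n")
  cat(sprintf("  K_D  = %.4g M (se %.2g)\n", x$K_D, x$se[["K_D"]]))
  cat(sprintf("  F_L  = %.4g (se %.2g)\n", x$F_L, x$se[["F_L"]]))
  cat(sprintf("  F_LP = %.4g (se %.2g)\n", x$F_LP, x$se[["F_LP"]]))
  invisible(x)
}

#' Read a fluorescence polarization titration CSV
#'
#' Expects a column `P_T` (molar) plus either `FP`, or raw intensities
#' `S` and `P` (converted with [fp_from_intensities()] using `G`).
#'
#' @param path CSV path.
#' @param G G factor used when converting raw intensities.
#' @return data.frame with columns `P_T` and `FP`.
#' @export
read_fp_csv <- function(path, G = 1) {
  df <- utils::read.table(path, sep = ",", header = TRUE)
  if (!"P_T" %in% names(df)) stop("CSV needs a P_T column")
  if (!"FP" %in% names(df)) {
    if (!all(c("S", "P") %in% names(df)))
      stop("CSV needs FP, or S and P columns")
    df$FP <- fp_from_intensities(df$S, df$P, G)
  }
  df[, c("P_T", "FP")]
}
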
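#' Fit the actin-activated steady-state ATPase model
#'
#' Nonlinear least squares on
#' `rate = V0 + kcat * [actin] / (K_actin + [actin])`,
#' the Michaelis-Menten hyperbola with a basal offset: `V0` is the basal
#' ATPase rate of the motor alone, `kcat` the maximal actin-activated rate
#' and `K_actin` the actin concentration at half-maximal activation.
#' Parameters are constrained non-negative (bounded Levenberg-Marquardt);
#' initial guesses are V0 = min rate, kcat = max - min, K_actin = the
#' concentration nearest the half-rise.
#'
#' @param data a data.frame with `actin` (uM) and `rate` (s^-1), e.g. from
#'   [simulate_atpase()]; needs at least 4 distinct concentrations.
#' @return a list of class `kinetics_fit`: `V0`, `kcat`, `K_actin`,
#'   standard errors (`se`), `rss`, `converged`, `boundary_warning` and
#'   the `fitted` rates.
#' @examples
#' d <- simulate_atpase(kinetics_sim_spec(noise_sd = 0))
#' fit_atpase(d)$kcat  # recovers 5.5
#' @export
fit_atpase <- function(data) {
  if (!all(c("actin", "rate") %in% names(data)))
    stopf("data needs columns actin, rate", class = "nucleopol_format_error")
  a <- as.numeric(data$actin); v <- as.numeric(data$rate)
  keep <- is.finite(a) & is.finite(v) & a >= 0
  a <- a[keep]; v <- v[keep]
  if (length(unique(a)) < 4)
    stopf("need at least 4 distinct actin concentrations",
          class = "nucleopol_insufficient_data_error")
  v0_init <- max(min(v), 0)
  kcat_init <- max(max(v) - min(v), 1e-6)
  half <- v0_init + kcat_init / 2
  K_init <- max(a[which.min(abs(v - half))], 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ V0 + kcat * a / (K + a),
                      start = list(V0 = v0_init, kcat = kcat_init,
                                   K = K_init),
                      lower = c(0, 1e-9, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(V0 = NA_real_, kcat = NA_real_,
                          K_actin = NA_real_, se = NULL, rss = NA_real_,
                          converged = FALSE,
                          diagnostics = conditionMessage(fit)),
                     class = "kinetics_fit"))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(V0 = unname(cf["V0"]), kcat = unname(cf["kcat"]),
                 K_actin = unname(cf["K"]),
                 se = setNames(unname(se), c("V0", "kcat", "K_actin")),
                 rss = sum(residuals(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 boundary_warning = any(cf <= c(0, 1e-9, 1e-9) + 1e-12),
                 fitted = unname(fitted(fit))),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("ATPase fit: did not converge\n")
    if (!is.null(x$diagnostics)) cat(" ", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("ATPase fit: V0 = %.3g s^-1, kcat = %.3g s^-1, ",
                     "K_actin = %.3g uM (rss %.3g)\n"),
              x$V0, x$kcat, x$K_actin, x$rss))
  invisible(x)
}

#' Mean residue ellipticity from a CD reading
#'
#' Converts a raw circular-dichroism signal (millidegrees of ellipticity)
#' to the per-residue normalised form
#' `theta_MRW = (MW / (n - 1) * theta) / (l * c * 10)`,
#' with `MW` the molecular weight (g/mol), `n` the number of residues
#' (n - 1 peptide bonds), `l` the path length (cm) and `c` the protein
#' concentration (mg/mL).
#'
#' @param theta observed ellipticity (millidegrees); vectorised.
#' @param mw molecular weight (g/mol).
#' @param n_residues number of amino acids (>= 2).
#' @param path_length cuvette path length (cm).
#' @param conc concentration (mg/mL).
#' @return mean residue ellipticity (deg cm^2 dmol^-1).
#' @examples
#' mean_residue_ellipticity(10, mw = 1000, n_residues = 11,
#'                          path_length = 1, conc = 1)  # 100
#' @export
mean_residue_ellipticity <- function(theta, mw, n_residues, path_length,
                                     conc) {
  if (n_residues < 2)
    stopf("n_residues must be at least 2", class = "nucleopol_parameter_error")
  if (path_length <= 0 || conc <= 0 || mw <= 0)
    stopf("mw, path_length and conc must be positive",
          class = "nucleopol_parameter_error")
  (mw / (n_residues - 1) * theta) / (path_length * conc * 10)
}
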
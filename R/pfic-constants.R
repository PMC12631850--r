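#' Fixed constants of the neural-mass and hemodynamic models
#'
#' The excitatory/inhibitory neural-mass equations and the hemodynamic
#' forward model take a set of fixed kinetic and transfer-function constants.
#' Defaults follow the dynamic mean-field model literature this model family
#' derives from (reduced Wong-Wang two-population model with feedback
#' inhibition control; Balloon-Windkessel hemodynamics in the
#' Friston/Obata parameterization). Every value can be overridden.
#'
#' @param ... name = value overrides of any listed constant.
#' @return named list of constants:
#' \describe{
#'   \item{a_E, b_E, d_E}{excitatory transfer function: 310 nC^-1, 125 Hz,
#'     0.16 s.}
#'   \item{a_I, b_I, d_I}{inhibitory transfer function: 615 nC^-1, 177 Hz,
#'     0.087 s.}
#'   \item{tau_E, tau_I}{synaptic gating time constants: 0.1 s (NMDA),
#'     0.01 s (GABA).}
#'   \item{gamma}{excitatory gating kinetic rate, 0.641 (dimensionless).}
#'   \item{J_NMDA}{synaptic coupling constant, 0.15 nA.}
#'   \item{I_0}{baseline input current, 0.382 nA.}
#'   \item{w_E, w_I}{input-current scaling for the E and I populations,
#'     1.0 and 0.7.}
#'   \item{W_II}{inhibitory-to-inhibitory weight, 1.0.}
#'   \item{kappa, gamma_h, tau_h, alpha, rho}{hemodynamics: signal decay
#'     0.65 s^-1, flow-dependent elimination 0.41 s^-1, transit time 0.98 s,
#'     Grubb exponent 0.32, resting oxygen extraction 0.34.}
#'   \item{V0, k1, k2, k3}{BOLD readout: resting venous volume fraction 0.02
#'     and weights 7*rho, 2, 2*rho - 0.2.}
#' }
#' @export
pfic_constants <- function(...) {
  const <- list(
    # Wong-Wang / dynamic mean-field transfer and kinetics
    a_E = 310, b_E = 125, d_E = 0.16,
    a_I = 615, b_I = 177, d_I = 0.087,
    tau_E = 0.1, tau_I = 0.01, gamma = 0.641,
    J_NMDA = 0.15, I_0 = 0.382, w_E = 1.0, w_I = 0.7, W_II = 1.0,
    # Balloon-Windkessel hemodynamics (Friston/Obata)
    kappa = 0.65, gamma_h = 0.41, tau_h = 0.98, alpha = 0.32, rho = 0.34,
    V0 = 0.02, k1 = 7 * 0.34, k2 = 2, k3 = 2 * 0.34 - 0.2)
  override <- list(...)
  unknown <- setdiff(names(override), names(const))
  if (length(unknown))
    stop("unknown constant(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pos <- c("a_E", "b_E", "d_E", "a_I", "b_I", "d_I", "tau_E", "tau_I",
           "gamma", "J_NMDA", "I_0", "kappa", "gamma_h", "tau_h", "alpha",
           "rho", "V0")
  const <- utils::modifyList(const, override)
  bad <- pos[vapply(const[pos], function(v) !is.numeric(v) || v <= 0, TRUE)]
  if (length(bad))
    stop("constants must be strictly positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  const
}
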
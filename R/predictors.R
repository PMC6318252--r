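## Comparator protection-factor predictors: the phenomenological
## approximation from hydrogen-bond and burial counts, and COREX-style
## Boltzmann aggregation over a supplied ensemble of partially unfolded
## microstates.

#' Phenomenological approximation presets
#'
#' The published coefficient pairs for
#' \eqn{\ln PF_i = \beta_H N_i^H + \beta_C N_i^C}: counting all heavy atoms
#' gives \eqn{\beta_C = 0.35, \beta_H = 2.0}; counting backbone atoms only
#' gives \eqn{\beta_C = 1.0, \beta_H = 5.0}.
#'
#' @param mode `"all-atoms"` or `"backbone-only"`.
#' @return List with `beta_H`, `beta_C`, `mode`.
#' @export
phenom_params <- function(mode = c("all-atoms", "backbone-only")) {
  mode <- match.arg(mode)
  if (mode == "all-atoms") list(beta_H = 2.0, beta_C = 0.35, mode = mode)
  else list(beta_H = 5.0, beta_C = 1.0, mode = mode)
}

#' Phenomenological protection-factor approximation
#'
#' Computes \eqn{\ln PF_i = \beta_H N_i^H + \beta_C N_i^C} from the number
#' of amide hydrogen bonds and the burial count (heavy atoms within 6.5
#' angstrom of the amide nitrogen), with no intercept. The model is stated
#' in natural log; the default return value is converted to log10 to match
#' the package-wide logPF convention. `assume_log10 = TRUE` skips the
#' conversion, reproducing a literal base-10 reading of the formula.
#'
#' @param n_hbond Hydrogen-bond count(s) \eqn{N_i^H}, >= 0.
#' @param n_burial Burial count(s) \eqn{N_i^C}, >= 0.
#' @param params Coefficients from [phenom_params()].
#' @param assume_log10 Treat the formula's output as already base-10.
#' @return logPF (log10) vector.
#' @export
phenomenological_logpf <- function(n_hbond, n_burial,
                                   params = phenom_params(),
                                   assume_log10 = FALSE) {
  if (any(n_hbond < 0) || any(n_burial < 0))
    stop("hydrogen-bond and burial counts must be non-negative")
  ln_pf <- params$beta_H * n_hbond + params$beta_C * n_burial
  if (assume_log10) ln_pf else ln_pf / log(10)
}

#' Boltzmann probabilities of microstates
#'
#' Normalised Boltzmann weights \eqn{\Pr(s) = e^{-\Delta G_s/RT} / \sum_s
#' e^{-\Delta G_s/RT}}, computed with log-sum-exp stabilisation so that
#' large free energies cannot overflow. Probabilities are invariant under
#' adding a constant to all free energies.
#'
#' @param dG Microstate free energies in kcal/mol.
#' @param temperature Temperature in kelvin.
#' @return Probability vector summing to 1.
#' @export
boltzmann_probabilities <- function(dG, temperature = 293.15) {
  if (!length(dG)) stop("empty ensemble")
  if (any(!is.finite(dG))) stop("microstate free energies must be finite")
  lw <- -dG / (R_KCAL * temperature)
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}

#' COREX-style protection factor from a microstate ensemble
#'
#' Aggregates an externally supplied ensemble of partially unfolded
#' microstates into a per-residue protection factor: the ratio of the total
#' probability of states in which the residue is folded and not solvent
#' exposed to the total probability of states in which it is unfolded and
#' exposed, each reduced by `pr_i`, the ensemble probability that the
#' residue is solvent accessible in its native form or through partial
#' unfolding of other residues. Generation of the ensemble itself (surface
#' -area-based free energies, conformational entropy) is out of scope;
#' `pr_i` must be supplied with the ensemble and defaults to 0 with a
#' warning.
#'
#' @param dG Microstate free energies in kcal/mol (>= 2 states).
#' @param folded,exposed Logical vectors over states for one residue.
#' @param temperature Temperature in kelvin.
#' @param pr_i Solvent-accessibility probability correction (default 0,
#'   with a warning when not explicitly supplied).
#' @return Protection factor; `Inf` (with a warning) when the denominator
#'   is not positive, i.e. the residue is never unfolded-and-exposed.
#' @export
corex_pf <- function(dG, folded, exposed, temperature = 293.15,
                     pr_i = NULL) {
  if (length(dG) < 2) stop("need at least 2 microstates")
  if (length(folded) != length(dG) || length(exposed) != length(dG))
    stop("folded/exposed flags must be defined for every microstate")
  if (is.null(pr_i)) {
    warning("pr_i not supplied; defaulting to 0")
    pr_i <- 0
  }
  pr <- boltzmann_probabilities(dG, temperature)
  num <- sum(pr[folded & !exposed]) - pr_i
  den <- sum(pr[!folded & exposed]) - pr_i
  if (!is.finite(num) || !is.finite(den))
    stop("non-finite microstate probabilities")
  if (den <= 0) {
    warning("denominator <= 0: residue is never unfolded-and-exposed; ",
            "returning infinite protection")
    return(Inf)
  }
  num / den
}

#' COREX protection factors for every residue of an ensemble
#'
#' @param ensemble A microstate ensemble from [as_microstate_ensemble()].
#' @param temperature Temperature in kelvin.
#' @return Named numeric vector of protection factors, one per residue.
#' @export
corex_pf_table <- function(ensemble, temperature = 293.15) {
  res <- colnames(ensemble$folded)
  vapply(res, function(r) {
    suppressWarnings(
      corex_pf(ensemble$dG, ensemble$folded[, r], ensemble$exposed[, r],
               temperature = temperature, pr_i = ensemble$pr_i[[r]]))
  }, numeric(1))
}
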
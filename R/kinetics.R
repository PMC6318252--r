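## Intrinsic amide exchange rates (Bai reference parameterization) and the
## two-state opening/closing algebra linking k_ex, K_open, the protection
## factor and Delta G_ex.

#' Intrinsic-rate reference parameters
#'
#' Loads the per-residue acid/base inductive log-factors and the
#' poly-DL-alanine reference constants of the standard Bai-style
#' parameterization for amide hydrogen-to-deuterium exchange in D2O.
#' For the amide hydrogen of residue i, the acid- and base-catalysed rates
#' pick up the `_L` factor of residue i's own side chain and the `_R`
#' factor of the preceding residue; the water term follows the base
#' factors. Rows `NT`/`CT` carry the extra factors of the charged N- and
#' C-terminal groups.
#'
#' Reference constants (per minute, 293.15 K): `log10 kA = 1.62` (1/M),
#' `log10 kB = 10.18` (1/M), `log10 kW = -1.5`; D2O ion product
#' `pKD = 15.05`; Arrhenius activation energies 14, 17 and 19 kcal/mol for
#' the acid, base and water channels.
#'
#' @param path Optional path to an alternative factor CSV with columns
#'   `residue`, `acid_L`, `acid_R`, `base_L`, `base_R`.
#' @return A list with elements `factors` (data frame) and the reference
#'   constants `log_ka`, `log_kb`, `log_kw`, `pKD`, `Ea_acid`, `Ea_base`,
#'   `Ea_water`, `T_ref`.
#' @export
bai_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "bai_parameters.csv", package = "poppet")
  factors <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue", "acid_L", "acid_R", "base_L", "base_R")
  miss <- setdiff(need, names(factors))
  if (length(miss))
    stop("Bai factor table missing column(s): ", paste(miss, collapse = ", "))
  list(factors = factors,
       log_ka = 1.62, log_kb = 10.18, log_kw = -1.5,
       pKD = 15.05,
       Ea_acid = 14, Ea_base = 17, Ea_water = 19,
       T_ref = 293.15)
}

bai_factor <- function(params, residue, column) {
  i <- match(residue, params$factors$residue)
  if (is.na(i)) stop("no intrinsic-rate factors tabulated for residue '",
                     residue, "'")
  params$factors[[column]][i]
}

#' Intrinsic exchange rate of one amide hydrogen
#'
#' Computes the sequence-dependent intrinsic (unstructured-chain) exchange
#' rate \eqn{k_{int} = k_{acid} + k_{base} + k_{water}} for the amide
#' hydrogen of the residue at `position`, with neighbour-dependent
#' inductive factors and Arrhenius temperature correction. The first
#' residue has no recordable amide hydrogen (very fast back exchange) and
#' prolines have none at all; both are errors.
#'
#' @param sequence Protein sequence, 1-letter codes.
#' @param position Residue position, `2 <= position <= nchar(sequence)`.
#' @param pD pD of the exchange buffer (directly, no glass-electrode
#'   correction applied).
#' @param temperature Temperature in kelvin.
#' @param params Parameter list from [bai_params()].
#' @param termini Apply the charged N-/C-terminal group factors (default
#'   `TRUE`).
#' @return Intrinsic rate in 1/s.
#' @seealso [intrinsic_rates()] for a whole sequence at once.
#' @export
intrinsic_rate <- function(sequence, position, pD = 7.0,
                           temperature = 293.15, params = bai_params(),
                           termini = TRUE) {
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(seq_chars)
  if (position < 1 || position > n) stop("position out of range")
  if (position == 1)
    stop("excluded residue: the amide hydrogen of the first residue ",
         "cannot be recorded (very fast back exchange)")
  res <- seq_chars[position]
  if (res == "P")
    stop("no amide hydrogen: proline at position ", position)
  prev <- seq_chars[position - 1]

  fa <- bai_factor(params, res, "acid_L") + bai_factor(params, prev, "acid_R")
  fb <- bai_factor(params, res, "base_L") + bai_factor(params, prev, "base_R")
  if (termini && position == 2) {
    fa <- fa + bai_factor(params, "NT", "acid_R")
    fb <- fb + bai_factor(params, "NT", "base_R")
  }
  if (termini && position == n) {
    fa <- fa + bai_factor(params, "CT", "acid_L")
    fb <- fb + bai_factor(params, "CT", "base_L")
  }
  k_acid <- 10^(params$log_ka + fa - pD)
  k_base <- 10^(params$log_kb + fb + pD - params$pKD)
  k_water <- 10^(params$log_kw + fb)
  arr <- function(Ea) exp(-(Ea / R_KCAL) * (1 / temperature - 1 / params$T_ref))
  k_min <- k_acid * arr(params$Ea_acid) + k_base * arr(params$Ea_base) +
    k_water * arr(params$Ea_water)
  k_min / 60
}

#' Intrinsic exchange rates for a whole sequence
#'
#' Vectorised wrapper around [intrinsic_rate()]: returns one rate per
#' residue, with `NA` for position 1 and for prolines.
#'
#' @inheritParams intrinsic_rate
#' @return Numeric vector of length `nchar(sequence)` in 1/s.
#' @export
intrinsic_rates <- function(sequence, pD = 7.0, temperature = 293.15,
                            params = bai_params(), termini = TRUE) {
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  vapply(seq_along(seq_chars), function(i) {
    if (i == 1 || seq_chars[i] == "P") return(NA_real_)
    intrinsic_rate(sequence, i, pD = pD, temperature = temperature,
                   params = params, termini = termini)
  }, numeric(1))
}

#' Observed exchange rate from opening/closing kinetics
#'
#' Two-state model: the amide must open (rate `k_open`) before chemical
#' exchange (intrinsic rate `k_int`) competes with reclosing (`k_close`):
#' \deqn{k_{ex} = \frac{k_{open} k_{int}}{k_{close} + k_{open} + k_{int}}}
#' In the EX2 limit (`k_close` much larger than both other rates) this
#' reduces to \eqn{K_{open} k_{int}}; in the EX1 limit (`k_int` much larger
#' than `k_close`) it approaches `k_open`.
#'
#' @param k_open,k_close,k_int Non-negative rates in 1/s.
#' @return Exchange rate in 1/s.
#' @export
exchange_rate <- function(k_open, k_close, k_int) {
  if (any(c(k_open, k_close, k_int) < 0)) stop("rates must be non-negative")
  denom <- k_close + k_open + k_int
  if (any(denom == 0)) stop("undefined rate: k_open, k_close and k_int are all zero")
  k_open * k_int / denom
}

#' Protection factor and free energy from rates
#'
#' `pf_from_rates()` gives \eqn{PF = k_{int}/k_{ex} \approx 1/K_{open}};
#' a zero exchange rate returns the infinite-protection sentinel `Inf`
#' rather than an error. `logpf()` is the base-10 logarithm used throughout
#' the public interface. `dg_from_pf()` converts to the opening free energy
#' \eqn{\Delta G_{ex} = R T \ln PF} in kcal/mol (natural log internally).
#'
#' @param k_int,k_ex Rates in 1/s; `k_int >= 0`, `k_ex >= 0`.
#' @return `pf_from_rates`: dimensionless protection factor.
#' @export
pf_from_rates <- function(k_int, k_ex) {
  if (any(k_int < 0) || any(k_ex < 0)) stop("rates must be non-negative")
  ifelse(k_ex == 0, Inf, k_int / k_ex)
}

#' @rdname pf_from_rates
#' @param PF Protection factor(s), > 0 (Inf allowed as the
#'   infinite-protection sentinel).
#' @export
logpf <- function(PF) {
  if (any(PF <= 0)) stop("PF must be positive")
  log10(PF)
}

#' @rdname pf_from_rates
#' @param temperature Temperature in kelvin.
#' @export
dg_from_pf <- function(PF, temperature = 293.15) {
  if (any(PF <= 0)) stop("PF must be positive")
  R_KCAL * temperature * log(PF)
}

#' @rdname pf_from_rates
#' @param dG_ex Opening free energy in kcal/mol.
#' @export
pf_from_dg <- function(dG_ex, temperature = 293.15) {
  exp(dG_ex / (R_KCAL * temperature))
}
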
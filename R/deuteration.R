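## Forward simulation of deuterium uptake from protection factors and
## intrinsic rates: single-exponential EX2-style kinetics per residue,
## summed over peptide residues 2..n (the first residue's deuterium is
## lost to back exchange before measurement; prolines have no amide H).

#' Deuterium uptake of one amide hydrogen
#'
#' \deqn{D_i(t) = 1 - \exp\{-(k_{int,i}/PF_i)\, t\}}
#' The infinite-protection sentinel `PF = Inf` gives 0 at every finite
#' time.
#'
#' @param k_int Intrinsic rate in 1/s, >= 0.
#' @param PF Protection factor, > 0 (may be `Inf`).
#' @param time Labelling time(s) in seconds, >= 0.
#' @return Expected deuterium content in [0, 1], vectorised over `time`.
#' @export
residue_uptake <- function(k_int, PF, time) {
  if (any(PF <= 0)) stop("PF must be positive")
  if (any(k_int < 0)) stop("k_int must be non-negative")
  if (any(time < 0)) stop("time must be non-negative")
  rate <- ifelse(is.infinite(PF), 0, k_int / PF)
  1 - exp(-rate * time)
}

#' Geometric labelling-time grid
#'
#' Default grid: 16 points from 30 s to 16 days (1,382,400 s), geometrically
#' spaced so consecutive ratios are equal.
#'
#' @param n_points Number of points (>= 2).
#' @param t_min,t_max First and last time in seconds, `t_min < t_max`.
#' @return Ascending numeric vector of length `n_points` with `t_min` and
#'   `t_max` as endpoints.
#' @export
make_time_grid <- function(n_points = 16, t_min = 30, t_max = 16 * 86400) {
  if (n_points < 2) stop("need at least 2 time points")
  if (!(t_min > 0 && t_min < t_max)) stop("require 0 < t_min < t_max")
  exp(seq(log(t_min), log(t_max), length.out = n_points))
}

#' Theoretical deuterium uptake of a peptide
#'
#' Sums [residue_uptake()] over the peptide's residues from the second
#' onwards (the first amide's deuterium back-exchanges too fast to record);
#' prolines contribute zero. Protection factors and intrinsic rates are
#' looked up per residue; a missing value for an exchanging residue is an
#' error, never silently imputed.
#'
#' @param peptide One-row data frame or list with `peptide` (id), `chain`,
#'   `start`, `end`, `sequence` (1-letter codes, length `end - start + 1`).
#' @param pf_table Data frame with columns `chain`, `resno` and either `PF`
#'   or `logPF` (log10).
#' @param kint_table Data frame with columns `chain`, `resno`, `k_int`
#'   (1/s), or a named numeric vector indexed by residue number.
#' @param times Labelling times in seconds (see [make_time_grid()]).
#' @param back_exchange Optional scalar in (0, 1] multiplying the total
#'   uptake; a crude account of deuterium loss during sample handling.
#' @return Object of class `deuteration_profile`: list with `peptide`,
#'   `times`, `D` (expected deuterons per time), `per_residue` (residue x
#'   time matrix) and `n_exchanging`.
#' @export
peptide_uptake <- function(peptide, pf_table, kint_table, times,
                           back_exchange = 1) {
  stopifnot(back_exchange > 0, back_exchange <= 1)
  pep <- as.list(peptide)
  resnos <- seq.int(pep$start, pep$end)
  aa <- strsplit(toupper(pep$sequence), "")[[1]]
  if (length(aa) != length(resnos))
    stop("peptide sequence length inconsistent with residue span")
  ## residues 2..n of the peptide; prolines carry no amide hydrogen
  idx <- which(seq_along(resnos) >= 2 & aa != "P")
  lookup <- function(tab, resno, what) {
    if (is.numeric(tab) && !is.null(names(tab))) {
      v <- tab[as.character(resno)]
      if (is.na(v)) stop("missing ", what, " for residue ",
                         pep$chain, ":", resno)
      return(unname(v))
    }
    i <- which(tab$chain == pep$chain & tab$resno == resno)
    if (!length(i)) stop("missing ", what, " for residue ",
                         pep$chain, ":", resno)
    if (what == "PF") {
      if (!is.null(tab$PF) && !is.na(tab$PF[i[1]])) return(tab$PF[i[1]])
      if (!is.null(tab$logPF) && !is.na(tab$logPF[i[1]]))
        return(10^tab$logPF[i[1]])
      stop("missing PF for residue ", pep$chain, ":", resno)
    }
    tab$k_int[i[1]]
  }
  per_res <- matrix(0, nrow = length(resnos), ncol = length(times),
                    dimnames = list(resnos, NULL))
  for (j in idx) {
    pf <- lookup(pf_table, resnos[j], "PF")
    ki <- lookup(kint_table, resnos[j], "k_int")
    per_res[j, ] <- residue_uptake(ki, pf, times)
  }
  D <- back_exchange * colSums(per_res)
  structure(list(peptide = pep$peptide %||% NA, times = times, D = D,
                 per_residue = per_res, n_exchanging = length(idx)),
            class = "deuteration_profile")
}

#' @export
print.deuteration_profile <- function(x, ...) {
  cat("<deuteration_profile> peptide ", x$peptide, ": ",
      x$n_exchanging, " exchanging residues, ", length(x$times),
      " time points, D range [", signif(min(x$D), 4), ", ",
      signif(max(x$D), 4), "]\n", sep = "")
  invisible(x)
}

#' Difference between two deuteration profiles
#'
#' Signed per-time differences `a - b` between two profiles of the same
#' peptide on the same time grid, with min/max summary.
#'
#' @param a,b `deuteration_profile` objects from [peptide_uptake()].
#' @return List with `times`, `difference`, `min`, `max`.
#' @export
profile_difference <- function(a, b) {
  if (length(a$times) != length(b$times) ||
      any(abs(a$times - b$times) > 1e-9 * pmax(a$times, 1)))
    stop("alignment error: profiles are on different time grids")
  if (!identical(a$peptide, b$peptide))
    stop("alignment error: profiles belong to different peptides")
  d <- a$D - b$D
  list(times = a$times, difference = d, min = min(d), max = max(d))
}
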
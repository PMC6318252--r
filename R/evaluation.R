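## Accuracy metrics on the logPF scale and on the deuteration (Da) scale,
## plus the synthetic-data generator matching the model's assumed
## structure (linear predictor + Gaussian residual).

#' Compare predicted and measured logPFs
#'
#' Joins the two tables on (chain, residue) and reports signed differences
#' (predicted minus measured), their mean and maximum absolute values, the
#' signed mean, and the Pearson correlation on the logPF scale.
#'
#' @param measured,predicted Data frames with columns `chain`, `resno`,
#'   `logPF` (log10); `measured` may carry a `set` column for subsetting.
#' @param subset Optional value of `measured$set` to restrict to (e.g.
#'   `"test"`).
#' @param scale `"logPF"` (default) or `"PF"`; correlation and differences
#'   are computed on the chosen scale.
#' @return Object of class `pf_accuracy`: list with `n`, `signed`
#'   (named vector of predicted - measured), `mean_abs`, `max_abs`,
#'   `mean_signed`, `pearson`, `subset`.
#' @export
compare_logpf <- function(measured, predicted, subset = NULL,
                          scale = c("logPF", "PF")) {
  scale <- match.arg(scale)
  if (!is.null(subset)) {
    if (is.null(measured$set)) stop("measured table has no 'set' column")
    measured <- measured[measured$set == subset, , drop = FALSE]
  }
  key_m <- paste(measured$chain, measured$resno)
  key_p <- paste(predicted$chain, predicted$resno)
  shared <- intersect(key_m, key_p)
  if (length(shared) < 2)
    stop("insufficient overlap: fewer than 2 shared residues")
  m <- measured$logPF[match(shared, key_m)]
  p <- predicted$logPF[match(shared, key_p)]
  if (scale == "PF") { m <- 10^m; p <- 10^p }
  signed <- stats::setNames(p - m, shared)
  structure(list(n = length(shared), signed = signed,
                 mean_abs = mean(abs(signed)), max_abs = max(abs(signed)),
                 mean_signed = mean(signed),
                 pearson = stats::cor(m, p),
                 subset = subset %||% "all", scale = scale),
            class = "pf_accuracy")
}

#' @export
print.pf_accuracy <- function(x, ...) {
  cat("<pf_accuracy> subset = ", x$subset, " (n = ", x$n, ", ",
      x$scale, " scale)\n", sep = "")
  cat(sprintf("  mean |diff| = %.4g   max |diff| = %.4g   mean signed = %.4g\n",
              x$mean_abs, x$max_abs, x$mean_signed))
  cat(sprintf("  Pearson rho = %.4f\n", x$pearson))
  invisible(x)
}

#' Deuteration-scale prediction error
#'
#' Propagates two protection-factor tables (typically measured and
#' predicted) through [peptide_uptake()] for each peptide and differences
#' the resulting profiles. The reported difference is
#' `D(measured) - D(predicted)` at each time point.
#'
#' @param measured_pf,predicted_pf PF tables (see [peptide_uptake()]).
#' @param peptides Peptide definition data frame (see [read_table()], kind
#'   `"peptide"`).
#' @param kint_table Per-residue intrinsic rates (data frame `chain`,
#'   `resno`, `k_int`, or named vector).
#' @param times Labelling times in seconds.
#' @param back_exchange Scalar back-exchange factor, passed through.
#' @return Long-format data frame: `peptide`, `time_s`, `D_measured`,
#'   `D_predicted`, `difference`.
#' @export
deuteration_error <- function(measured_pf, predicted_pf, peptides,
                              kint_table, times = make_time_grid(),
                              back_exchange = 1) {
  validate_table(peptides, "peptide")
  rows <- lapply(seq_len(nrow(peptides)), function(i) {
    pep <- peptides[i, , drop = FALSE]
    a <- peptide_uptake(pep, measured_pf, kint_table, times, back_exchange)
    b <- peptide_uptake(pep, predicted_pf, kint_table, times, back_exchange)
    d <- profile_difference(a, b)
    data.frame(peptide = pep$peptide, time_s = times, D_measured = a$D,
               D_predicted = b$D, difference = d$difference,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Covariate distribution for the synthetic-data generator
#'
#' Defines how [simulate_pf_dataset()] draws feature vectors. Defaults
#' emulate a globular alpha/beta protein whose amide hydrogens mostly
#' hydrogen-bond to main-chain oxygens, with burial counts Poisson around
#' 59.1 (the mean burial of the staphylococcal-nuclease training
#' hydrogens).
#'
#' @param motion_probs,ss_probs,hbond_probs Named probability vectors over
#'   the closed category sets.
#' @param burial_mean Mean of the Poisson burial distribution.
#' @return List of class `covariate_spec`.
#' @export
covariate_spec <- function(
    motion_probs = c("L" = 0.4, "UD" = 0.2, "EX1" = 0.2, "UD+EX1" = 0.2),
    ss_probs = c("no" = 0.3, "helix" = 0.45, "beta-sheet" = 0.25),
    hbond_probs = c("no" = 0.1, "Hbond-with-H2O" = 0.05,
                    "Hbond-with-mainchain-O" = 0.75,
                    "Hbond-with-sidechain-O" = 0.1),
    burial_mean = 59.1) {
  chk <- function(p, valid, what) {
    if (!all(names(p) %in% valid) || any(p < 0) || sum(p) <= 0)
      stop("invalid ", what, " probabilities")
    p / sum(p)
  }
  spec <- list(motion_probs = chk(motion_probs, MOTION_CATEGORIES, "motion"),
               ss_probs = chk(ss_probs, SS_CATEGORIES, "ss"),
               hbond_probs = chk(hbond_probs, HBOND_CATEGORIES, "hbond"),
               burial_mean = burial_mean)
  degenerate <- function(p) sum(p > 0) < 2
  if (degenerate(spec$motion_probs) && degenerate(spec$ss_probs) &&
      degenerate(spec$hbond_probs))
    warning("degenerate covariate spec: every factor has a single ",
            "category; downstream fits will be rank deficient")
  structure(spec, class = "covariate_spec")
}

#' Simulate a protection-factor dataset from the model
#'
#' Draws feature vectors from a [covariate_spec()] and generates
#' `logPF = linear predictor + N(0, sigma^2)` noise under a coefficient
#' set, i.e. data with exactly the structure the log-linear model assumes.
#' Deterministic for a fixed seed.
#'
#' @param coeffs A `poppet_coefs` object (preset or fitted).
#' @param n Number of residues to simulate (>= 10).
#' @param spec A [covariate_spec()].
#' @param sigma Residual standard deviation of logPF.
#' @param seed Integer seed.
#' @return Data frame with columns `chain`, `resno`, `motion`, `ss`,
#'   `burial`, `hbond`, `lp` (noise-free linear predictor) and `logPF`.
#' @export
simulate_pf_dataset <- function(coeffs, n = 200, spec = covariate_spec(),
                                sigma = 0.5, seed = 1) {
  if (n < 10) stop("n must be >= 10")
  if (sigma < 0) stop("sigma must be >= 0")
  set.seed(seed)
  draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  feats <- data.frame(
    chain = "A", resno = seq_len(n),
    motion = draw(spec$motion_probs),
    ss = draw(spec$ss_probs),
    burial = stats::rpois(n, spec$burial_mean),
    hbond = draw(spec$hbond_probs),
    stringsAsFactors = FALSE)
  feats$lp <- predict(coeffs, feats)
  feats$logPF <- feats$lp + stats::rnorm(n, 0, sigma)
  feats
}

#' Split residues into training and test sets
#'
#' Random caller-seeded split utility; adds a `set` column with values
#' `"train"` / `"test"`.
#'
#' @param df Data frame of residues.
#' @param n_train Number of training rows.
#' @param seed Integer seed.
#' @return `df` with a `set` column.
#' @export
train_test_split <- function(df, n_train, seed = 1) {
  if (n_train < 1 || n_train >= nrow(df))
    stop("n_train must be between 1 and nrow(df) - 1")
  set.seed(seed)
  idx <- sample(nrow(df), n_train)
  df$set <- ifelse(seq_len(nrow(df)) %in% idx, "train", "test")
  df
}
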
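## The POPPeT log-linear protection-factor model: logPF regressed on the
## HX-enabling motion category, secondary-structure category, burial and
## hydrogen-bond category with indicator coding, fitted by OLS with
## backward elimination of non-significant terms.

## Candidate design terms and the categorical factor each belongs to.
## Reference levels (motion "L", ss "no", hbond "no") carry no indicator.
POPPET_TERMS <- data.frame(
  term = c("UD", "EX1", "UD+EX1", "helix", "beta-sheet", "burial",
           "Hbond-with-H2O", "Hbond-with-mainchain-O",
           "Hbond-with-sidechain-O"),
  group = c("motion", "motion", "motion", "ss", "ss", "burial",
            "hbond", "hbond", "hbond"),
  stringsAsFactors = FALSE)

## Indicator design matrix for a feature table. `terms` selects columns.
poppet_design <- function(features, terms = POPPET_TERMS$term) {
  n <- nrow(features)
  need_motion <- any(terms %in% c("UD", "EX1", "UD+EX1"))
  if (need_motion) {
    if (is.null(features$motion) || any(is.na(features$motion)))
      stop("missing covariate: motion category is unset for ",
           if (is.null(features$motion)) "all rows"
           else paste0(sum(is.na(features$motion)), " row(s)"))
    bad <- setdiff(unique(features$motion), MOTION_CATEGORIES)
    if (length(bad)) stop("invalid motion category value(s): ",
                          paste(bad, collapse = ", "))
  }
  if ("burial" %in% terms && (is.null(features$burial) ||
                              any(is.na(features$burial))))
    stop("missing covariate: burial is unset")
  cols <- lapply(terms, function(tm) {
    switch(tm,
      "UD" = as.numeric(features$motion == "UD"),
      "EX1" = as.numeric(features$motion == "EX1"),
      "UD+EX1" = as.numeric(features$motion == "UD+EX1"),
      "helix" = as.numeric((features$ss %||% rep("no", n)) == "helix"),
      "beta-sheet" = as.numeric((features$ss %||% rep("no", n)) == "beta-sheet"),
      "burial" = as.numeric(features$burial),
      "Hbond-with-H2O" =
        as.numeric((features$hbond %||% rep("no", n)) == "Hbond-with-H2O"),
      "Hbond-with-mainchain-O" =
        as.numeric((features$hbond %||% rep("no", n)) == "Hbond-with-mainchain-O"),
      "Hbond-with-sidechain-O" =
        as.numeric((features$hbond %||% rep("no", n)) == "Hbond-with-sidechain-O"),
      stop("unknown design term: ", tm))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

new_poppet_coefs <- function(table, sigma2 = NA_real_, adj_r2 = NA_real_,
                             n_train = NA_integer_, dropped = character(0)) {
  structure(list(table = table, sigma2 = sigma2, adj_r2 = adj_r2,
                 n_train = n_train, dropped = dropped),
            class = "poppet_coefs")
}

#' Published coefficient presets for the protection-factor model
#'
#' `"poppet-2018"` is the coefficient set fitted to the 30-hydrogen
#' staphylococcal nuclease training set: motion, secondary-structure and
#' burial terms retained, hydrogen-bond terms eliminated as
#' non-significant. Standard errors and p-values are the published ones;
#' the residual variance was not published and is `NA`.
#'
#' @param preset Preset name; currently `"poppet-2018"`.
#' @return A `poppet_coefs` object usable with [predict.poppet_coefs()] and
#'   [simulate_pf_dataset()].
#' @export
poppet_coefficients <- function(preset = "poppet-2018") {
  if (!identical(preset, "poppet-2018"))
    stop("unknown coefficient preset: ", preset)
  tab <- data.frame(
    term = c("(Intercept)", POPPET_TERMS$term),
    estimate = c(2.19940, 1.63431, 2.12078, 2.15429, 0.59534, 0.35710,
                 0.04371, NA, NA, NA),
    se = c(0.59566, 0.22449, 0.19786, 0.18957, 0.19881, 0.18679,
           0.01164, NA, NA, NA),
    p = c(0.00120, 2.08e-7, 2.03e-10, 6.50e-11, 0.00647, 0.06844,
          0.00103, NA, NA, NA),
    retained = c(rep(TRUE, 7), rep(FALSE, 3)),
    stringsAsFactors = FALSE)
  new_poppet_coefs(tab, n_train = 30L)
}

#' @export
print.poppet_coefs <- function(x, ...) {
  cat("<poppet_coefs> protection-factor model coefficients\n")
  tab <- x$table
  tab$estimate <- round(tab$estimate, 5)
  tab$se <- round(tab$se, 5)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  if (!is.na(x$sigma2))
    cat("residual sigma^2 =", signif(x$sigma2, 4),
        " adjusted R^2 =", signif(x$adj_r2, 4), "\n")
  if (!is.na(x$n_train)) cat("n_train =", x$n_train, "\n")
  if (length(x$dropped))
    cat("columns dropped before fitting:", paste(x$dropped, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
coef.poppet_coefs <- function(object, ...) {
  tab <- object$table[object$table$retained, , drop = FALSE]
  stats::setNames(tab$estimate, tab$term)
}

#' Predict logPF from a coefficient set
#'
#' Evaluates the log-linear predictor on a feature table: the intercept
#' plus the retained coefficients times the indicator/burial covariates
#' (reference levels: motion `"L"`, secondary structure `"no"`, H-bond
#' `"no"`). Eliminated terms contribute 0.
#'
#' @param object A `poppet_coefs` object ([poppet_coefficients()] or the
#'   `$coefs` element of a fitted [poppet()] model).
#' @param newdata Feature data frame with columns `motion`, `ss`, `burial`,
#'   `hbond` as produced by [build_features()] or [simulate_pf_dataset()].
#' @param ... Unused.
#' @return Numeric vector of predicted logPF (log10).
#' @export
predict.poppet_coefs <- function(object, newdata, ...) {
  tab <- object$table[object$table$retained, , drop = FALSE]
  terms <- setdiff(tab$term, "(Intercept)")
  lp <- rep(0, nrow(newdata))
  if ("(Intercept)" %in% tab$term)
    lp <- lp + tab$estimate[tab$term == "(Intercept)"]
  if (length(terms)) {
    X <- poppet_design(newdata, terms)
    beta <- tab$estimate[match(terms, tab$term)]
    lp <- lp + drop(X %*% beta)
  }
  lp
}

#' Fit the log-linear protection-factor model
#'
#' Regresses measured logPF (log10) on the HX-enabling motion category,
#' secondary-structure category, burial and hydrogen-bond category by
#' ordinary least squares on the full indicator design, then performs
#' backward elimination: the least significant term (or whole categorical
#' factor, the default) is removed and the model refitted until every
#' retained term has p < `alpha`. Factor-wise elimination keeps a
#' categorical factor as long as any of its levels is significant, which is
#' how a marginally non-significant level (such as a beta-sheet indicator
#' at p = 0.068) can remain in the final model.
#'
#' @param formula Model formula; the response is the measured logPF column
#'   of `data`, the right-hand side selects candidate features among
#'   `motion`, `ss`, `burial`, `hbond`. Default uses all four.
#' @param data Feature data frame (see [build_features()] /
#'   [simulate_pf_dataset()]) with the response column.
#' @param alpha Retention threshold for two-sided t-test p-values.
#' @param elimination `"factor"` removes whole categorical factors (the
#'   factor's p-value is the smallest among its levels); `"term"` removes
#'   single indicator columns.
#' @return An object of class `poppet` with components `coefs` (a
#'   `poppet_coefs`: all candidate terms with estimate/SE/p, retained
#'   flags, residual variance, adjusted R-squared), `fit` (the final
#'   `stats::lm` object), `full_fit`, `fitted`, `residuals`, `data`,
#'   `alpha`, `elimination`, `call`.
#' @examples
#' set.seed(1)
#' dat <- simulate_pf_dataset(poppet_coefficients(), n = 120, sigma = 0.3,
#'                            seed = 1)
#' m <- poppet(logPF ~ motion + ss + burial + hbond, dat)
#' summary(m)
#' predict(m, dat[1:3, ])
#' @export
poppet <- function(formula = logPF ~ motion + ss + burial + hbond, data,
                   alpha = 0.05, elimination = c("factor", "term")) {
  elimination <- match.arg(elimination)
  cl <- match.call()
  resp_name <- all.vars(formula[[2]])
  if (!resp_name %in% names(data)) {
    if (resp_name == "logPF" && "logPF_measured" %in% names(data))
      resp_name <- "logPF_measured"
    else stop("response column '", resp_name, "' not found in data")
  }
  y <- data[[resp_name]]
  if (any(is.na(y))) stop("response contains missing values")
  groups_wanted <- intersect(all.vars(formula[[3]]),
                             unique(POPPET_TERMS$group))
  if (!length(groups_wanted)) stop("no candidate features in formula")
  cand <- POPPET_TERMS[POPPET_TERMS$group %in% groups_wanted, , drop = FALSE]
  n <- length(y)
  if (n <= nrow(cand) + 1)
    stop("insufficient training data: n = ", n, " with ",
         nrow(cand), " candidate terms")
  if ("motion" %in% groups_wanted &&
      length(unique(data$motion)) < 2)
    stop("at least two motion categories must be present to fit the ",
         "motion factor")

  X <- poppet_design(data, cand$term)
  ## rank check before fitting: constant columns cannot be estimated
  const <- apply(X, 2, function(col) length(unique(col)) < 2)
  dropped <- colnames(X)[const]
  if (length(dropped))
    message("dropped unidentifiable design column(s) before fitting: ",
            paste(dropped, collapse = ", "))
  X <- X[, !const, drop = FALSE]

  fit_ols <- function(cols) {
    df <- data.frame(y = y, X[, cols, drop = FALSE], check.names = FALSE)
    stats::lm(y ~ ., data = df)
  }
  coef_row <- function(mat, term) {
    i <- which(rownames(mat) == term | rownames(mat) == make.names(term) |
               rownames(mat) == paste0("`", term, "`"))
    if (length(i)) mat[i[1], ] else NULL
  }
  pvals <- function(fit, cols) {
    sm <- suppressWarnings(summary(fit))$coefficients
    p <- stats::setNames(rep(1, length(cols)), cols)
    for (cc in cols) {
      row <- coef_row(sm, cc)
      if (is.null(row)) next
      ## perfect fits give NaN p-values: a non-zero estimate with zero
      ## residual variance is infinitely significant, a zero one is not
      p[cc] <- if (is.nan(row[4])) (if (abs(row[1]) > 1e-12) 0 else 1)
               else row[4]
    }
    p
  }

  active <- colnames(X)
  full_fit <- fit_ols(active)
  full_sm <- suppressWarnings(summary(full_fit))$coefficients
  repeat {
    if (!length(active)) { fit <- stats::lm(y ~ 1); break }
    fit <- fit_ols(active)
    ## columns aliased within lm (perfect collinearity): drop and restart
    aliased <- active[is.na(stats::coef(fit)[-1])]
    if (length(aliased)) {
      message("dropped aliased design column(s): ",
              paste(aliased, collapse = ", "))
      dropped <- c(dropped, aliased)
      active <- setdiff(active, aliased)
      next
    }
    p <- pvals(fit, active)
    if (elimination == "factor") {
      grp <- cand$group[match(active, cand$term)]
      gp <- tapply(p, grp, min)
      worst <- names(gp)[which.max(gp)]
      if (max(gp) >= alpha) active <- active[grp != worst] else break
    } else {
      worst <- names(p)[which.max(p)]
      if (max(p) >= alpha) active <- setdiff(active, worst) else break
    }
  }

  sm <- suppressWarnings(summary(fit))
  cfs <- sm$coefficients
  tab <- data.frame(term = c("(Intercept)", cand$term),
                    estimate = NA_real_, se = NA_real_, p = NA_real_,
                    retained = FALSE, stringsAsFactors = FALSE)
  fill <- function(tab, term, src_row) {
    i <- match(term, tab$term)
    tab$estimate[i] <- src_row[1]; tab$se[i] <- src_row[2]
    tab$p[i] <- src_row[4]
    tab
  }
  tab <- fill(tab, "(Intercept)", cfs["(Intercept)", ])
  tab$retained[1] <- TRUE
  for (tm in cand$term) {
    row <- coef_row(cfs, tm)
    if (tm %in% active && !is.null(row)) {
      tab <- fill(tab, tm, row)
      tab$retained[match(tm, tab$term)] <- TRUE
    } else {
      ## report the full-design estimate for eliminated terms
      row <- coef_row(full_sm, tm)
      if (!is.null(row)) tab <- fill(tab, tm, row)
    }
  }
  coefs <- new_poppet_coefs(tab, sigma2 = sm$sigma^2,
                            adj_r2 = sm$adj.r.squared,
                            n_train = as.integer(n), dropped = dropped)
  structure(list(coefs = coefs, fit = fit, full_fit = full_fit,
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::residuals(fit)),
                 data = data, response = resp_name, alpha = alpha,
                 elimination = elimination, call = cl),
            class = "poppet")
}

#' @export
print.poppet <- function(x, ...) {
  cat("POPPeT log-linear protection-factor model\n")
  cat("Call: "); print(x$call)
  kept <- x$coefs$table[x$coefs$table$retained, , drop = FALSE]
  cat("Retained terms (p <", x$alpha, ",", x$elimination,
      "elimination):\n")
  print(stats::setNames(round(kept$estimate, 5), kept$term))
  invisible(x)
}

#' @export
summary.poppet <- function(object, ...) {
  structure(list(coefs = object$coefs, alpha = object$alpha,
                 elimination = object$elimination,
                 n = object$coefs$n_train), class = "summary.poppet")
}

#' @export
print.summary.poppet <- function(x, ...) {
  cat("POPPeT log-linear protection-factor model (",
      x$elimination, "-wise backward elimination, alpha = ", x$alpha,
      ", n = ", x$n, ")\n", sep = "")
  print(x$coefs)
  invisible(x)
}

#' @export
coef.poppet <- function(object, ...) coef(object$coefs)

#' @export
residuals.poppet <- function(object, ...) object$residuals

#' @export
fitted.poppet <- function(object, ...) object$fitted

#' @rdname predict.poppet_coefs
#' @export
predict.poppet <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict(object$coefs, newdata)
}

#' Simulate logPF observations from a fitted model
#'
#' Draws new responses from the fitted linear predictor plus Gaussian
#' residual noise at the estimated residual standard deviation.
#'
#' @param object A fitted [poppet()] model.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated logPF.
#' @export
simulate.poppet <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(object$coefs$sigma2)
  lp <- object$fitted
  out <- as.data.frame(replicate(nsim, lp + stats::rnorm(length(lp), 0, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Diagnostic plot for a fitted protection-factor model
#'
#' Measured versus fitted logPF with the identity line.
#'
#' @param x A fitted [poppet()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.poppet <- function(x, ...) {
  y <- x$data[[x$response]]
  graphics::plot(x$fitted, y, xlab = "fitted logPF", ylab = "measured logPF",
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
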
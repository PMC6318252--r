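base_features <- function(motion = "L", ss = "no", burial = 0,
                          hbond = "no") {
  data.frame(motion = motion, ss = ss, burial = burial, hbond = hbond,
             stringsAsFactors = FALSE)
}

test_that("the published coefficient set reproduces the worked examples", {
  cf <- poppet_coefficients("poppet-2018")
  ## reference-level prediction is the intercept
  expect_equal(predict(cf, base_features()), 2.19940)
  ## burial of 30 contributes 30 x 0.04371
  expect_equal(predict(cf, base_features(burial = 30)) -
                 predict(cf, base_features()), 30 * 0.04371)
  expect_equal(30 * 0.04371, 1.3113, tolerance = 1e-12)
  ## motion L -> UD adds 1.63431; helix adds 0.59534
  expect_equal(predict(cf, base_features(motion = "UD")) -
                 predict(cf, base_features()), 1.63431)
  expect_equal(predict(cf, base_features(ss = "helix")) -
                 predict(cf, base_features()), 0.59534)
  ## eliminated hydrogen-bond terms contribute exactly 0
  expect_equal(predict(cf, base_features(hbond = "Hbond-with-mainchain-O")),
               predict(cf, base_features()))
  expect_error(poppet_coefficients("poppet-2099"), "unknown")
})

test_that("prediction is affine in the covariates", {
  cf <- poppet_coefficients()
  b <- coef(cf)
  f1 <- base_features(motion = "EX1", ss = "beta-sheet", burial = 40)
  f2 <- base_features(motion = "UD+EX1", ss = "helix", burial = 25)
  diff <- predict(cf, f1) - predict(cf, f2)
  expect_equal(diff, (b["EX1"] - b["UD+EX1"]) + (b["beta-sheet"] - b["helix"]) +
                 b["burial"] * (40 - 25), ignore_attr = TRUE)
})

test_that("an unset motion category is a missing-covariate error", {
  cf <- poppet_coefficients()
  expect_error(predict(cf, base_features(motion = NA)), "missing covariate")
  expect_error(predict(cf, data.frame(ss = "no", burial = 1, hbond = "no")),
               "missing covariate")
})

test_that("noise-free simulated data are recovered exactly by the fit", {
  cf <- poppet_coefficients()
  d <- simulate_pf_dataset(cf, n = 120, sigma = 0, seed = 9)
  m <- poppet(logPF ~ motion + ss + burial, d)
  expect_lt(max(abs(residuals(m))), 1e-8)
  b <- coef(m)
  expect_equal(b[["(Intercept)"]], 2.19940, tolerance = 1e-6)
  expect_equal(b[["UD"]], 1.63431, tolerance = 1e-6)
  expect_equal(b[["burial"]], 0.04371, tolerance = 1e-8)
  retained <- m$coefs$table
  expect_true(all(retained$retained[retained$term %in%
                                      c("UD", "EX1", "UD+EX1", "burial")]))
})

test_that("the fitted model recovers coefficients within their confidence intervals", {
  cf <- poppet_coefficients()
  truth <- coef(cf)
  hits <- 0L
  n_rep <- 40
  for (s in seq_len(n_rep)) {
    d <- simulate_pf_dataset(cf, n = 200, sigma = 0.5, seed = 1000 + s)
    m <- poppet(logPF ~ motion + ss + burial, d, alpha = 1)  # keep all terms
    tab <- m$coefs$table
    tab <- tab[tab$term %in% names(truth), ]
    ok <- abs(tab$estimate - truth[tab$term]) <= 1.96 * tab$se
    hits <- hits + all(ok)
  }
  ## every true coefficient inside its 95% CI in most replicates
  expect_gte(hits / n_rep, 0.7)
})

test_that("eliminated terms are reported with their full-design estimates", {
  cf <- poppet_coefficients()
  d <- simulate_pf_dataset(cf, n = 300, sigma = 0.4, seed = 21)
  m <- poppet(logPF ~ motion + ss + burial + hbond, d)
  tab <- m$coefs$table
  hb <- tab[grepl("^Hbond", tab$term), ]
  ## the generator gives H-bond categories no effect, so they are dropped
  expect_false(any(hb$retained))
  expect_true(all(is.finite(hb$estimate)))   # but still reported
  expect_true(all(is.finite(hb$p)))
  ## sigma and adjusted R^2 are reported
  expect_gt(m$coefs$sigma2, 0)
  expect_lt(abs(sqrt(m$coefs$sigma2) - 0.4), 0.1)
  expect_true(m$coefs$adj_r2 > 0 && m$coefs$adj_r2 <= 1)
})

test_that("factor-wise elimination keeps a factor when any level is significant", {
  ## construct data where beta-sheet is weak but helix is strong, as in a
  ## model whose sheet indicator sits just above the threshold
  cf0 <- poppet_coefficients()
  tab <- cf0$table
  tab$estimate[tab$term == "beta-sheet"] <- 0.05  # weak level
  cf <- poppet:::new_poppet_coefs(tab)
  set.seed(31)
  d <- simulate_pf_dataset(cf, n = 150, sigma = 0.4, seed = 31)
  m_factor <- poppet(logPF ~ motion + ss + burial, d, elimination = "factor")
  tabf <- m_factor$coefs$table
  ## helix significant -> whole ss factor (incl. beta-sheet) retained
  if (tabf$p[tabf$term == "helix"] < 0.05)
    expect_true(tabf$retained[tabf$term == "beta-sheet"])
  m_term <- poppet(logPF ~ motion + ss + burial, d, elimination = "term")
  tabt <- m_term$coefs$table
  ## term-wise mode judges beta-sheet on its own p-value
  if (tabt$retained[tabt$term == "beta-sheet"])
    expect_lt(tabt$p[tabt$term == "beta-sheet"], 0.05)
})

test_that("rank-deficient designs report dropped columns before fitting", {
  cf <- poppet_coefficients()
  d <- simulate_pf_dataset(cf, n = 100, sigma = 0.3, seed = 5,
                           spec = covariate_spec(
                             ss_probs = c("no" = 1, "helix" = 0,
                                          "beta-sheet" = 0)))
  expect_message(m <- poppet(logPF ~ motion + ss + burial, d),
                 "helix.*beta-sheet|dropped")
  expect_true(all(c("helix", "beta-sheet") %in% m$coefs$dropped))
  expect_false(any(m$coefs$table$retained[m$coefs$table$term %in%
                                            c("helix", "beta-sheet")]))
})

test_that("model preconditions are enforced", {
  cf <- poppet_coefficients()
  d <- simulate_pf_dataset(cf, n = 50, sigma = 0.3, seed = 3)
  expect_error(poppet(logPF ~ motion + ss + burial, d[1:6, ]),
               "insufficient")
  d1 <- d; d1$motion <- "L"
  expect_error(poppet(logPF ~ motion + ss + burial, d1),
               "two motion categories")
})

test_that("phenomenological approximation evaluates the printed coefficients", {
  ## zero counts give zero in any base
  expect_equal(phenomenological_logpf(0, 0), 0)
  ## all-atoms preset: ln PF = 2.0*1 + 0.35*10 = 5.5 -> log10 = 5.5/ln 10
  expect_equal(phenomenological_logpf(1, 10), 5.5 / log(10))
  expect_equal(phenomenological_logpf(1, 10), 2.389, tolerance = 1e-3)
  ## backbone preset: ln PF = 5.0*1 + 1.0*10 = 15
  expect_equal(phenomenological_logpf(1, 10, phenom_params("backbone-only")),
               15 / log(10))
  ## literal base-10 reading skips the conversion
  expect_equal(phenomenological_logpf(1, 10, assume_log10 = TRUE), 5.5)
  ## linear and monotone in both counts
  expect_equal(phenomenological_logpf(2, 20), 2 * phenomenological_logpf(1, 10))
  expect_gt(phenomenological_logpf(2, 10), phenomenological_logpf(1, 10))
  expect_error(phenomenological_logpf(-1, 5), "non-negative")
})

test_that("Boltzmann probabilities are normalised, ordered and shift-invariant", {
  RT <- gas_constant_kcal() * 293.15
  p <- boltzmann_probabilities(c(0, RT * log(2), RT * log(4)))
  expect_equal(p, c(4, 2, 1) / 7)
  expect_equal(boltzmann_probabilities(c(1, 1)), c(0.5, 0.5))
  set.seed(8)
  for (i in 1:20) {
    dG <- rnorm(sample(2:200, 1), sd = 5)
    p <- boltzmann_probabilities(dG)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(boltzmann_probabilities(dG + 123.4), p, tolerance = 1e-12)
  }
  ## large free energies neither overflow nor underflow to NaN
  expect_equal(sum(boltzmann_probabilities(c(0, 5000, -5000))), 1)
})

test_that("COREX aggregation computes the folded/exposed probability ratio", {
  RT <- gas_constant_kcal() * 293.15
  dG <- c(0, RT * log(2), RT * log(4))    # Pr = 4/7, 2/7, 1/7
  folded <- c(TRUE, TRUE, FALSE)
  exposed <- c(FALSE, FALSE, TRUE)
  pf <- corex_pf(dG, folded, exposed, pr_i = 0)
  expect_equal(pf, (4 / 7 + 2 / 7) / (1 / 7))
  ## pr_i shifts numerator and denominator
  pf2 <- corex_pf(dG, folded, exposed, pr_i = 0.05)
  expect_equal(pf2, (6 / 7 - 0.05) / (1 / 7 - 0.05))
  ## residue folded in every state -> infinite protection with a warning
  expect_warning(pf3 <- corex_pf(dG, c(TRUE, TRUE, TRUE),
                                 c(FALSE, FALSE, FALSE), pr_i = 0),
                 "infinite")
  expect_identical(pf3, Inf)
  ## missing pr_i defaults to 0 with a warning
  expect_warning(corex_pf(dG, folded, exposed), "pr_i")
  expect_error(corex_pf(dG[1], TRUE, FALSE, pr_i = 0), "at least 2")
})

test_that("microstate tables parse into ensembles usable by corex_pf_table", {
  df <- data.frame(state = 1:3, dG_s = c(0, 1, 2),
                   folded_10 = c(1, 1, 0), folded_11 = c(1, 0, 0),
                   exposed_10 = c(0, 0, 1), exposed_11 = c(0, 1, 1),
                   stringsAsFactors = FALSE)
  ens <- as_microstate_ensemble(df)
  expect_equal(colnames(ens$folded), c("10", "11"))
  pfs <- corex_pf_table(ens)
  p <- boltzmann_probabilities(c(0, 1, 2))
  expect_equal(unname(pfs["10"]), (p[1] + p[2]) / p[3])
  expect_equal(unname(pfs["11"]), p[1] / (p[2] + p[3]))
})
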
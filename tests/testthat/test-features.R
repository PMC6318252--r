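test_that("burial counts heavy atoms within the cutoff, boundary inclusive", {
  pc <- make_synthetic_structure("point-cloud", seed = 3,
                                 distances = c(5, 6, 7))
  expect_equal(compute_burial(pc, "A", 1), 2)   # 5 and 6 in; 7 out
  pc65 <- make_synthetic_structure("point-cloud", seed = 3,
                                   distances = c(5, 6.5, 7))
  expect_equal(compute_burial(pc65, "A", 1), 2) # exactly 6.5 counts
})

test_that("burial ignores hydrogens, waters and HETATM unless asked", {
  pc <- make_synthetic_structure("point-cloud", seed = 5,
                                 distances = c(2, 3, 4),
                                 elements = c("H", "H", "H"))
  expect_equal(compute_burial(pc, "A", 1), 0)
  pc2 <- make_synthetic_structure("point-cloud", seed = 5,
                                  distances = c(3, 4))
  pc2$atoms$het[3] <- TRUE
  expect_equal(compute_burial(pc2, "A", 1), 1)
  expect_equal(compute_burial(pc2, "A", 1, include_het = TRUE), 2)
})

test_that("burial equals the brute-force oracle on random point clouds", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    pc <- make_synthetic_structure("point-cloud", seed = rep,
                                   distances = runif(n, 1, 12))
    expect_equal(compute_burial(pc, "A", 1),
                 brute_force_burial(pc, "A", 1))
  }
  helix <- make_synthetic_structure("ideal-helix", 15)
  for (r in 3:12)
    expect_equal(compute_burial(helix, "A", r),
                 brute_force_burial(helix, "A", r))
})

test_that("burial is monotone in radius and rigid-body invariant", {
  s <- make_synthetic_structure("ideal-helix", 15)
  for (r in 4:10) {
    expect_lte(compute_burial(s, "A", r, radius = 6.5),
               compute_burial(s, "A", r, radius = 8.0))
  }
  moved <- rotate_structure(s)
  for (r in 3:12)
    expect_equal(compute_burial(moved, "A", r), compute_burial(s, "A", r))
})

test_that("residues without a backbone N are a feature-unavailable error", {
  s <- make_synthetic_structure("ideal-helix", 5)
  s$atoms <- s$atoms[!(s$atoms$resno == 3 & s$atoms$elety == "N"), ]
  expect_error(compute_burial(s, "A", 3), "no backbone N")
  expect_error(hbond_category(s, "A", 3), "no backbone N")
})

test_that("secondary-structure categories map helix/strand spans", {
  helix <- make_synthetic_structure("ideal-helix", 8)
  expect_equal(ss_category(helix, "A", 4), "helix")
  strand <- make_synthetic_structure("ideal-strand", 8)
  expect_equal(ss_category(strand, "A", 4), "beta-sheet")
  expect_equal(ss_category(helix, "A", 99), "no")
  ## 3/10- and pi-helical spans also count as helix; bridges as beta-sheet
  s <- helix
  s$ss_spans <- data.frame(chain = "A", start = 1L, end = 4L,
                           kind = "pi-helix", stringsAsFactors = FALSE)
  expect_equal(ss_category(s, "A", 2), "helix")
  s$ss_spans$kind <- "bridge"
  expect_equal(ss_category(s, "A", 2), "beta-sheet")
  ## no spans at all -> "no"
  s$ss_spans <- s$ss_spans[0, ]
  expect_equal(ss_category(s, "A", 2), "no")
})

## Build an exact donor/acceptor geometry: N at origin, CA and previous C
## placed so the reconstructed H points along +x; acceptor O along +x.
make_hbond_fixture <- function(o_dist = 2.9, o_angle_deg = 0,
                               o_resid = "GLY", o_elety = "O",
                               extra = NULL) {
  ang <- 109.5 * pi / 180 / 2
  atoms <- data.frame(
    chain = "A",
    resno = c(1L, 2L, 2L, 3L),
    resid = c("ALA", "ALA", "ALA", o_resid),
    elety = c("C", "N", "CA", o_elety),
    elesy = c("C", "N", "C", "O"),
    x = c(-cos(ang), 0, -cos(ang),
          o_dist * cos(o_angle_deg * pi / 180)),
    y = c(sin(ang), 0, -sin(ang),
          o_dist * sin(o_angle_deg * pi / 180)),
    z = 0, het = FALSE, o = 1, stringsAsFactors = FALSE)
  if (!is.null(extra)) atoms <- rbind(atoms, extra)
  protein_structure(atoms)
}

test_that("hydrogen bonds are detected by distance and angle criteria", {
  ## near-linear N-H...O at 2.9 angstrom -> main-chain H-bond
  s <- make_hbond_fixture(o_dist = 2.9, o_angle_deg = 0)
  hb <- hbond_category(s, "A", 2)
  expect_equal(hb$category, "Hbond-with-mainchain-O")
  expect_equal(hb$n_hbond, 1L)
  ## too far -> no bond
  s_far <- make_hbond_fixture(o_dist = 3.8)
  expect_equal(hbond_category(s_far, "A", 2)$category, "no")
  ## bad D-H...A angle (acceptor behind the hydrogen) -> no bond
  s_bent <- make_hbond_fixture(o_dist = 2.9, o_angle_deg = 150)
  hb_bent <- hbond_category(s_bent, "A", 2)
  expect_equal(hb_bent$category, "no")
  expect_equal(hb_bent$n_hbond, 0L)
})

test_that("acceptor-type precedence is main-chain > side-chain > water", {
  water <- data.frame(chain = "A", resno = 50L, resid = "HOH",
                      elety = "O", elesy = "O", x = 2.8, y = 0.3, z = 0,
                      het = TRUE, o = 1, stringsAsFactors = FALSE)
  both <- make_hbond_fixture(o_dist = 2.9, extra = water)
  hb <- hbond_category(both, "A", 2)
  expect_equal(hb$category, "Hbond-with-mainchain-O")
  expect_equal(hb$n_hbond, 2L)   # both acceptors qualify
  ## side-chain O alone
  sc <- make_hbond_fixture(o_dist = 2.9, o_elety = "OG", o_resid = "SER")
  expect_equal(hbond_category(sc, "A", 2)$category, "Hbond-with-sidechain-O")
  ## water alone
  w_only <- make_hbond_fixture(o_dist = 10, extra = water)
  expect_equal(hbond_category(w_only, "A", 2)$category, "Hbond-with-H2O")
})

test_that("hbond category is 'no' exactly when the count is zero", {
  cases <- list(make_hbond_fixture(2.9), make_hbond_fixture(3.8),
                make_hbond_fixture(2.9, o_angle_deg = 150))
  for (s in cases) {
    hb <- hbond_category(s, "A", 2)
    expect_identical(hb$category == "no", hb$n_hbond == 0L)
  }
})

test_that("interior helix amides hydrogen-bond to the i-4 main-chain oxygen", {
  s <- make_synthetic_structure("ideal-helix", 12)
  for (r in 6:10) {
    hb <- hbond_category(s, "A", r)
    expect_equal(hb$category, "Hbond-with-mainchain-O")
    expect_gte(hb$n_hbond, 1L)
  }
})

test_that("motion classification separates flat, curved and linear series", {
  conc <- seq(0, 3, by = 0.5)
  expect_equal(classify_motion(conc, rep(5, length(conc))), "L")
  ## strong linear dependence, zero curvature -> global unfolding
  expect_equal(classify_motion(conc, 5 + 2.0 * conc), "UD+EX1")
  ## pronounced quadratic kink -> partial unfolding
  set.seed(2)
  curved <- 5 + 2.0 * conc - 0.9 * conc^2 + rnorm(length(conc), 0, 0.01)
  expect_equal(classify_motion(conc, curved), "UD")
  ## errors
  expect_error(classify_motion(c(0, 1), c(1, 2)), "insufficient")
  expect_error(classify_motion(c(0, 1, 1), c(1, 2, 3)), "increasing")
})

test_that("motion classification is scale-consistent", {
  conc <- seq(0, 3, by = 0.5)
  dg <- 4 + 1.5 * conc
  for (c_mult in c(2, 5, 10)) {
    expect_equal(classify_motion(conc, c_mult * dg,
                                 slope_threshold = c_mult * 0.5),
                 classify_motion(conc, dg, slope_threshold = 0.5))
  }
})

test_that("build_features assembles covariates with overrides and exclusions", {
  s <- make_synthetic_structure("ideal-helix", 10)
  ann <- data.frame(chain = "A", resno = c(2, 5, 6, 7),
                    aa = c("A", "P", "A", "A"),
                    motion = c("L", "UD", "EX1", "UD+EX1"),
                    burial = c(NA, NA, 30, NA),
                    stringsAsFactors = FALSE)
  f <- build_features(s, ann)
  expect_equal(nrow(f), 4)
  expect_equal(f$burial[f$resno == 6], 30)          # override wins
  expect_false(f$exchanging[f$resno == 5])          # proline
  expect_true(all(f$exchanging[f$resno != 5]))
  expect_equal(f$ss[f$resno == 7], "helix")         # from the fixture span
  expect_equal(f$motion, ann$motion)
  ## first residue of a chain is non-exchanging
  ann1 <- data.frame(chain = "A", resno = 1, aa = "A", stringsAsFactors = FALSE)
  expect_false(build_features(s, ann1)$exchanging)
})

test_that("numbering mismatches are keyed errors", {
  s <- make_synthetic_structure("ideal-helix", 5)
  ann <- data.frame(chain = "A", resno = c(3, 99), stringsAsFactors = FALSE)
  expect_error(build_features(s, ann), "A:99")
})
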
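## Structural covariates for each backbone amide hydrogen: burial (heavy
## atoms within a cutoff of the amide nitrogen), secondary-structure
## category, geometric hydrogen-bond category, and classification of the
## HX-enabling motion from a denaturant dependence of Delta G_ex.

find_atom <- function(structure, chain, resno, elety, insert = NA) {
  a <- structure$atoms
  sel <- a$chain == chain & a$resno == resno & a$elety == elety
  if (!is.na(insert)) sel <- sel & !is.na(a$insert) & a$insert == insert
  else sel <- sel & is.na(a$insert)
  idx <- which(sel)
  if (!length(idx)) return(NULL)
  a[idx[1], , drop = FALSE]
}

atom_xyz <- function(row) c(row$x, row$y, row$z)

is_water <- function(resid) toupper(resid) %in% WATER_RESIDUES

#' Burial of an amide nitrogen
#'
#' Counts the non-hydrogen atoms within `radius` angstrom of the backbone
#' amide nitrogen of the given residue, excluding the nitrogen itself. This
#' is the packing-density covariate of both the log-linear protection-factor
#' model and the phenomenological approximation (default cutoff 6.5
#' angstrom, boundary inclusive).
#'
#' @param structure A [protein_structure()].
#' @param chain,resno,insert Residue key (author numbering).
#' @param radius Cutoff distance in angstrom (> 0); atoms at exactly the
#'   cutoff are counted.
#' @param scope `"all-atoms"` counts every heavy atom; `"backbone-only"`
#'   restricts to N, CA, C, O backbone atoms.
#' @param include_het If `FALSE` (default) waters and HETATM records are
#'   excluded: burial measures protein packing.
#' @return Non-negative integer count.
#' @export
compute_burial <- function(structure, chain, resno, insert = NA,
                           radius = 6.5,
                           scope = c("all-atoms", "backbone-only"),
                           include_het = FALSE) {
  scope <- match.arg(scope)
  if (radius <= 0) stop("radius must be > 0")
  namide <- find_atom(structure, chain, resno, "N", insert)
  if (is.null(namide))
    stop("feature unavailable: residue ", chain, ":", resno,
         " has no backbone N atom")
  a <- structure$atoms
  keep <- toupper(a$elesy) != "H" & toupper(a$elesy) != "D"
  if (!include_het) keep <- keep & !a$het & !is_water(a$resid)
  if (scope == "backbone-only") keep <- keep & a$elety %in% c("N", "CA", "C", "O")
  ## exclude the probe nitrogen itself
  self <- a$chain == chain & a$resno == resno & a$elety == "N" &
    (if (is.na(insert)) is.na(a$insert) else !is.na(a$insert) & a$insert == insert)
  keep <- keep & !self
  p <- atom_xyz(namide)
  d2 <- (a$x - p[1])^2 + (a$y - p[2])^2 + (a$z - p[3])^2
  sum(keep & d2 <= radius^2)
}

#' Secondary-structure category of a residue
#'
#' Maps the parsed secondary-structure spans to the three-level category
#' used by the protection-factor model: residues inside an alpha-, 3/10- or
#' pi-helical span are `"helix"`, residues inside a strand or bridge span
#' are `"beta-sheet"`, and everything else is `"no"`.
#'
#' @inheritParams compute_burial
#' @return One of `"no"`, `"helix"`, `"beta-sheet"`.
#' @export
ss_category <- function(structure, chain, resno) {
  ss <- structure$ss_spans
  if (is.null(ss) || !nrow(ss)) return("no")
  hit <- ss[ss$chain == chain & ss$start <= resno & ss$end >= resno, , drop = FALSE]
  if (!nrow(hit)) return("no")
  kinds <- hit$kind
  if (any(kinds %in% c("alpha-helix", "3/10-helix", "pi-helix"))) return("helix")
  if (any(kinds %in% c("strand", "bridge"))) return("beta-sheet")
  "no"
}

#' Hydrogen-bond detection criteria
#'
#' Relaxed geometric criteria for amide N-H...O hydrogen bonds: the
#' donor-acceptor (N...O) distance must not exceed `max_da_dist` and the
#' D-H...A angle at the hydrogen must be at least `min_dha_angle`.
#'
#' @param max_da_dist Maximum N...O distance in angstrom.
#' @param min_dha_angle Minimum N-H...O angle in degrees.
#' @return A list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_dist = 3.5, min_dha_angle = 120) {
  stopifnot(max_da_dist > 0, min_dha_angle >= 0, min_dha_angle <= 180)
  structure(list(max_da_dist = max_da_dist, min_dha_angle = min_dha_angle),
            class = "hbond_criteria")
}

## Amide hydrogen position: taken from the file when present (H/HN/D atom
## on the residue), otherwise built from backbone geometry in the plane of
## C(prev), N, CA at 1.01 angstrom along the external bisector.
amide_h_position <- function(structure, chain, resno, insert = NA) {
  for (nm in c("H", "HN", "D", "DN")) {
    h <- find_atom(structure, chain, resno, nm, insert)
    if (!is.null(h)) return(atom_xyz(h))
  }
  n <- find_atom(structure, chain, resno, "N", insert)
  ca <- find_atom(structure, chain, resno, "CA", insert)
  if (is.null(n) || is.null(ca)) return(NULL)
  a <- structure$atoms
  prev <- a[a$chain == chain & a$elety == "C" & a$resno < resno & !a$het, ,
            drop = FALSE]
  if (!nrow(prev)) return(NULL)
  prev <- prev[which.max(prev$resno), , drop = FALSE]
  np <- atom_xyz(n)
  np + 1.01 * vunit(vunit(np - atom_xyz(prev)) + vunit(np - atom_xyz(ca)))
}

#' Hydrogen-bond category of an amide hydrogen
#'
#' Applies a geometric criterion (see [hbond_criteria()]) with the backbone
#' amide N-H as donor and oxygen atoms as acceptor candidates. Acceptors
#' covalently adjacent to the donor (the carbonyl O of the preceding
#' residue and the residue's own backbone O) are excluded. The category is
#' decided by the acceptor type with precedence main-chain O > side-chain
#' O > water; the returned count `n_hbond` is the total number of
#' qualifying acceptors.
#'
#' When the structure contains no amide hydrogen, its position is
#' reconstructed from backbone geometry; if that is impossible (first
#' residue of a chain with no preceding carbonyl) only the distance
#' criterion is applied.
#'
#' @inheritParams compute_burial
#' @param criteria An [hbond_criteria()] object.
#' @return List with `category` (one of the four H-bond categories) and
#'   `n_hbond` (non-negative integer).
#' @export
hbond_category <- function(structure, chain, resno, insert = NA,
                           criteria = hbond_criteria()) {
  n <- find_atom(structure, chain, resno, "N", insert)
  if (is.null(n))
    stop("feature unavailable: residue ", chain, ":", resno,
         " has no backbone N atom")
  np <- atom_xyz(n)
  hp <- amide_h_position(structure, chain, resno, insert)
  a <- structure$atoms
  ## acceptor candidates: any oxygen, excluding covalent neighbours of N
  ox <- toupper(a$elesy) == "O"
  own_bb_o <- a$chain == chain & a$resno == resno & a$elety %in% c("O", "OXT")
  prev_res <- a$chain == chain & a$resno == resno - 1 & a$elety == "O"
  cand <- which(ox & !own_bb_o & !prev_res)
  if (!length(cand)) return(list(category = "no", n_hbond = 0L))
  acc <- a[cand, , drop = FALSE]
  d <- sqrt((acc$x - np[1])^2 + (acc$y - np[2])^2 + (acc$z - np[3])^2)
  ok <- d <= criteria$max_da_dist & d > 1e-6
  if (!is.null(hp)) {
    v1 <- np - hp
    v2 <- cbind(acc$x - hp[1], acc$y - hp[2], acc$z - hp[3])
    cosang <- drop(v2 %*% v1) /
      (vnorm(v1) * pmax(sqrt(rowSums(v2^2)), 1e-12))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    ok <- ok & ang >= criteria$min_dha_angle
  }
  acc <- acc[ok, , drop = FALSE]
  if (!nrow(acc)) return(list(category = "no", n_hbond = 0L))
  water <- is_water(acc$resid)
  mainchain <- !water & acc$elety %in% c("O", "OXT") & !acc$het
  sidechain <- !water & !mainchain & !acc$het
  category <- if (any(mainchain)) "Hbond-with-mainchain-O"
  else if (any(sidechain)) "Hbond-with-sidechain-O"
  else if (any(water)) "Hbond-with-H2O"
  else "no"
  n_h <- sum(mainchain | sidechain | water)
  if (n_h == 0L) category <- "no"
  list(category = category, n_hbond = as.integer(n_h))
}

#' Classify the HX-enabling motion from a denaturant series
#'
#' Classifies how an amide hydrogen becomes exchange competent from the
#' dependence of its exchange free energy on denaturant concentration.
#' A flat dependence (fitted slope magnitude below `slope_threshold`)
#' indicates exchange through local fluctuations (`"L"`). A non-linear
#' dependence (significant quadratic lack-of-fit at level `alpha`)
#' indicates partial (sub-global) unfolding (`"UD"`). A strong linear
#' dependence indicates global unfolding (`"UD+EX1"`). The `"EX1"` category
#' is an experimental label from elevated-pH experiments and is never
#' produced by this classifier.
#'
#' @param concentration Denaturant concentrations in M, strictly increasing,
#'   at least 3 points.
#' @param dG_ex Exchange free energies in kcal/mol, same length.
#' @param slope_threshold Slope magnitude (kcal/mol/M) below which the
#'   series counts as flat. Default 0.5.
#' @param alpha Significance level for the quadratic lack-of-fit test.
#' @return One of `"L"`, `"UD"`, `"UD+EX1"`.
#' @export
classify_motion <- function(concentration, dG_ex, slope_threshold = 0.5,
                            alpha = 0.05) {
  if (length(concentration) < 3 || length(dG_ex) != length(concentration))
    stop("insufficient data: need >= 3 matched (concentration, dG_ex) points")
  if (any(diff(concentration) <= 0))
    stop("concentrations must be strictly increasing")
  lin <- stats::lm(dG_ex ~ concentration)
  slope <- unname(stats::coef(lin)[2])
  if (abs(slope) < slope_threshold) return("L")
  quad <- stats::lm(dG_ex ~ concentration + I(concentration^2))
  cf <- suppressWarnings(summary(quad))$coefficients
  p_quad <- if (nrow(cf) >= 3 && !is.na(cf[3, 4])) cf[3, 4] else 1
  ## guard against numerically perfect linear fits, where round-off can
  ## make a ~1e-16 curvature term spuriously "significant": the curvature
  ## must also contribute a non-negligible amount over the observed range
  c2 <- unname(stats::coef(quad)[3])
  span2 <- diff(range(concentration))^2
  meaningful <- is.finite(c2) &&
    abs(c2) * span2 > 1e-6 * max(1, diff(range(dG_ex)))
  if (p_quad < alpha && meaningful) "UD" else "UD+EX1"
}

#' Assemble the model covariates for annotated residues
#'
#' Builds one feature row per annotated residue: burial, secondary-structure
#' category, hydrogen-bond category and count, and the HX-enabling motion
#' category. Columns already present in the annotation table (precomputed
#' `burial`, `hbond`, `motion`) override structure-derived values. Prolines
#' and the first residue of each chain are flagged as non-exchanging (no
#' recordable amide hydrogen).
#'
#' @param structure A [protein_structure()]; may be `NULL` if every needed
#'   feature is precomputed in `annotations`.
#' @param annotations Annotation data frame (see [read_table()], kind
#'   `"annotation"`): columns `chain`, `resno`, optionally `aa`,
#'   `logPF_measured`, `motion`, `burial`, `hbond`, `set`.
#' @param radius,scope,include_het Passed to [compute_burial()].
#' @param criteria Passed to [hbond_category()].
#' @return Data frame with one row per annotation row: `chain`, `resno`,
#'   `aa`, `burial`, `ss`, `hbond`, `n_hbond`, `motion`, `exchanging`,
#'   plus `logPF_measured` and `set` when present in the annotations.
#' @export
build_features <- function(structure, annotations, radius = 6.5,
                           scope = "all-atoms", include_het = FALSE,
                           criteria = hbond_criteria()) {
  validate_table(annotations, "annotation")
  ann <- annotations
  n <- nrow(ann)
  has_struct <- !is.null(structure)
  if (has_struct) {
    sa <- structure$atoms[!structure$atoms$het, , drop = FALSE]
    skey <- paste(sa$chain, sa$resno)
    first_res <- tapply(sa$resno, sa$chain, min)
  } else {
    need <- character(0)
    if (is.null(ann$burial)) need <- c(need, "burial")
    if (length(need))
      stop("no structure supplied and annotation table lacks precomputed ",
           paste(need, collapse = ", "))
  }
  unmatched <- character(0)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    chain <- ann$chain[i]; resno <- ann$resno[i]
    aa <- if (!is.null(ann$aa)) ann$aa[i] else NA_character_
    in_struct <- has_struct && any(skey == paste(chain, resno))
    need_struct <- is.null(ann$burial) || is.na(ann$burial[i]) ||
      is.null(ann$hbond) || is.na(ann$hbond[i])
    if (!in_struct && has_struct && need_struct) {
      unmatched <- c(unmatched, paste0(chain, ":", resno))
      next
    }
    burial <- if (!is.null(ann$burial) && !is.na(ann$burial[i])) ann$burial[i]
    else compute_burial(structure, chain, resno, radius = radius,
                        scope = scope, include_het = include_het)
    ss <- if (!is.null(ann$ss) && !is.na(ann$ss[i])) ann$ss[i]
    else if (in_struct) ss_category(structure, chain, resno) else "no"
    if (!is.null(ann$hbond) && !is.na(ann$hbond[i])) {
      hb <- ann$hbond[i]
      n_hb <- if (!is.null(ann$n_hbond) && !is.na(ann$n_hbond[i]))
        ann$n_hbond[i] else if (hb == "no") 0L else 1L
    } else {
      hc <- hbond_category(structure, chain, resno, criteria = criteria)
      hb <- hc$category; n_hb <- hc$n_hbond
    }
    motion <- if (!is.null(ann$motion)) ann$motion[i] else NA_character_
    is_pro <- !is.na(aa) && toupper(aa) %in% c("P", "PRO")
    if (has_struct && in_struct && !is_pro) {
      resid3 <- sa$resid[match(paste(chain, resno), skey)]
      is_pro <- toupper(resid3) == "PRO"
    }
    is_first <- if (has_struct && in_struct)
      resno == first_res[[chain]] else FALSE
    out[[i]] <- data.frame(
      chain = chain, resno = resno, aa = aa, burial = as.numeric(burial),
      ss = ss, hbond = hb, n_hbond = as.integer(n_hb), motion = motion,
      exchanging = !(is_pro || is_first), stringsAsFactors = FALSE)
  }
  if (length(unmatched))
    stop("residue numbering mismatch: annotation rows not found in the ",
         "structure: ", paste(unmatched, collapse = ", "))
  res <- do.call(rbind, out)
  if (!is.null(ann$logPF_measured)) res$logPF_measured <- ann$logPF_measured
  if (!is.null(ann$set)) res$set <- ann$set
  rownames(res) <- NULL
  res
}
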
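#' @keywords internal
"_PACKAGE"

## Gas constant in kcal/(mol K); used for Delta G_ex = R T ln PF and for
## Boltzmann weights over microstate free energies.
R_KCAL <- 1.9872e-3

## Closed category sets shared by the annotation tables, the feature
## extractor and the model design matrix.
MOTION_CATEGORIES <- c("L", "UD", "EX1", "UD+EX1")
SS_CATEGORIES <- c("no", "helix", "beta-sheet")
HBOND_CATEGORIES <- c("no", "Hbond-with-H2O", "Hbond-with-mainchain-O",
                      "Hbond-with-sidechain-O")

## Secondary-structure span kinds as parsed from coordinate files.
SS_SPAN_KINDS <- c("alpha-helix", "3/10-helix", "pi-helix", "strand", "bridge")

## Residue names treated as water when classifying hydrogen-bond acceptors
## and when excluding solvent from burial counts.
WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")

#' Gas constant used throughout the package
#'
#' Returns the molar gas constant in kcal/(mol K), the value used in the
#' free-energy relation \eqn{\Delta G_{ex} = R T \ln PF} and in Boltzmann
#' weighting of microstates.
#'
#' @return A numeric scalar, 1.9872e-3 kcal/(mol K).
#' @export
gas_constant_kcal <- function() R_KCAL

`%||%` <- function(a, b) if (is.null(a)) b else a

## vector norm / unit helpers used by the geometry code
vnorm <- function(v) sqrt(sum(v^2))
vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}
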
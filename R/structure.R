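## Protein structure container and PDB input.
##
## A `protein_structure` is a plain list with two data frames:
##   atoms:    chain, resno, insert, resid, elety, elesy, x, y, z, het, o
##   ss_spans: chain, start, end, kind   (kind in SS_SPAN_KINDS)
## Author residue numbering from the coordinate file is the coordinate
## system everywhere; only the first MODEL of multi-model files is kept.

new_protein_structure <- function(atoms, ss_spans) {
  structure(list(atoms = atoms, ss_spans = ss_spans),
            class = "protein_structure")
}

#' Build a protein structure from an atom table
#'
#' Low-level constructor used by the synthetic-structure generators and by
#' tests that need exact atom placement. Validates the invariants expected
#' of structures read from PDB files: finite coordinates, non-empty element
#' symbols and unique atom identities within a residue.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid` (3-letter
#'   residue name), `elety` (atom name), `elesy` (element symbol), `x`, `y`,
#'   `z` (angstrom) and optionally `insert`, `het` (logical), `o`
#'   (occupancy).
#' @param ss_spans Data frame with columns `chain`, `start`, `end`, `kind`
#'   (one of `r paste(SS_SPAN_KINDS, collapse = ", ")`), or `NULL` for none.
#' @return A `protein_structure` object.
#' @export
protein_structure <- function(atoms, ss_spans = NULL) {
  stopifnot(is.data.frame(atoms))
  req <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atom table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("all atom coordinates must be finite")
  if (any(!nzchar(atoms$elesy) | is.na(atoms$elesy)))
    stop("element symbol must be non-empty for every atom")
  if (is.null(atoms$insert)) atoms$insert <- NA_character_
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(ss_spans)) {
    ss_spans <- data.frame(chain = character(), start = integer(),
                           end = integer(), kind = character(),
                           stringsAsFactors = FALSE)
  } else {
    bad <- setdiff(ss_spans$kind, SS_SPAN_KINDS)
    if (length(bad))
      stop("unknown secondary-structure kind(s): ", paste(bad, collapse = ", "),
           "; valid kinds are: ", paste(SS_SPAN_KINDS, collapse = ", "))
  }
  new_protein_structure(atoms, ss_spans)
}

#' @export
print.protein_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resno", "insert")]))
  cat("<protein_structure> ", nrow(x$atoms), " atoms, ", nres,
      " residues, ", length(unique(x$atoms$chain)), " chain(s), ",
      nrow(x$ss_spans), " secondary-structure span(s)\n", sep = "")
  invisible(x)
}

## PDB helix class codes (column 39-40 of HELIX records) to span kinds.
## Right- and left-handed alpha map to alpha; unknown codes default to alpha.
helix_class_to_kind <- function(code) {
  code <- suppressWarnings(as.integer(code))
  kind <- rep("alpha-helix", length(code))
  kind[!is.na(code) & code == 5L] <- "3/10-helix"
  kind[!is.na(code) & code == 3L] <- "pi-helix"
  kind
}

## Infer an element symbol from a PDB atom name when columns 77-78 are
## absent. Leading digits (e.g. "1HB") indicate hydrogens in old files;
## otherwise the first alphabetic character of the name is the element for
## standard residues (" CA " is a C-alpha carbon, not calcium).
infer_element <- function(elety) {
  vapply(elety, function(a) {
    a <- gsub("[' \"]", "", a)
    if (!nzchar(a)) return("X")
    if (grepl("^[0-9]", a)) return("H")
    first <- toupper(substr(a, 1, 1))
    if (first %in% c("H", "C", "N", "O", "S", "P")) first else first
  }, character(1), USE.NAMES = FALSE)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM coordinate records and HELIX/SHEET secondary-structure
#' records. Only the first MODEL of a multi-model file is used. When
#' alternate locations are present, the highest-occupancy conformer is kept
#' (ties broken alphabetically by altloc, so 'A' wins). Element symbols are
#' taken from columns 77-78 and inferred from the atom name when absent.
#'
#' @param path Path to a PDB-format file containing at least one ATOM record.
#' @return A [protein_structure()] object. If the file has no HELIX/SHEET
#'   records, `ss_spans` is empty and a warning is issued.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("could not parse PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || !any(at$type == "ATOM"))
    stop("no ATOM records found in '", path, "'")

  elesy <- at$elesy
  missing_el <- is.na(elesy) | !nzchar(trimws(elesy))
  if (any(missing_el)) elesy[missing_el] <- infer_element(at$elety[missing_el])
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), NA_character_, at$insert),
    resid = at$resid,
    elety = at$elety,
    elesy = trimws(elesy),
    x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM",
    o = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE)

  ## alternate locations: keep the highest-occupancy copy of each atom
  if (any(nzchar(atoms$alt))) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
    ord <- order(key, -atoms$o, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                     atoms$elety, sep = "|")), , drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  }
  atoms$alt <- NULL
  rownames(atoms) <- NULL

  spans <- list()
  hx <- pdb$helix
  if (!is.null(hx) && length(hx$start)) {
    spans[[length(spans) + 1L]] <- data.frame(
      chain = hx$chain, start = as.integer(hx$start),
      end = as.integer(hx$end), kind = helix_class_to_kind(hx$type),
      stringsAsFactors = FALSE)
  }
  sh <- pdb$sheet
  if (!is.null(sh) && length(sh$start)) {
    spans[[length(spans) + 1L]] <- data.frame(
      chain = sh$chain, start = as.integer(sh$start),
      end = as.integer(sh$end), kind = "strand",
      stringsAsFactors = FALSE)
  }
  if (!length(spans)) {
    warning("no HELIX/SHEET records in '", path,
            "'; secondary-structure categories will all be \"no\"")
    ss <- NULL
  } else {
    ss <- do.call(rbind, spans)
    rownames(ss) <- NULL
  }
  protein_structure(atoms, ss)
}

## ---- synthetic structures -------------------------------------------------

## Place a new atom D given bonded chain A-B-C, bond length |CD|, angle
## B-C-D (degrees) and dihedral A-B-C-D (degrees). Standard internal- to
## Cartesian-coordinate step used to build idealised backbones.
place_atom <- function(a, b, c, length, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- vunit(c - b)
  ab <- b - a
  n <- vunit(pracma_cross(ab, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(dih),
          length * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## Ideal backbone geometry (lengths in angstrom, angles in degrees).
.BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.8, omega = 180)

build_backbone <- function(n_residues, phi, psi) {
  ## seed atoms for residue 1
  n1 <- c(0, 0, 0)
  ca1 <- c(.BB$n_ca, 0, 0)
  ang <- .BB$ang_n_ca_c * pi / 180
  c1 <- ca1 + .BB$ca_c * c(-cos(ang), sin(ang), 0)
  coords <- list(list(N = n1, CA = ca1, C = c1))
  for (i in seq_len(n_residues - 1)) {
    prev <- coords[[i]]
    ni <- place_atom(prev$N, prev$CA, prev$C, .BB$c_n, .BB$ang_ca_c_n, psi)
    cai <- place_atom(prev$CA, prev$C, ni, .BB$n_ca, .BB$ang_c_n_ca, .BB$omega)
    ci <- place_atom(prev$C, ni, cai, .BB$ca_c, .BB$ang_n_ca_c, phi)
    coords[[i + 1]] <- list(N = ni, CA = cai, C = ci)
  }
  ## carbonyl oxygens from the N-CA-C-O dihedral (psi + 180)
  for (i in seq_len(n_residues)) {
    r <- coords[[i]]
    coords[[i]]$O <- place_atom(r$N, r$CA, r$C, .BB$c_o, .BB$ang_ca_c_o,
                                psi + 180)
  }
  coords
}

backbone_to_atoms <- function(coords, chain = "A", resid = "ALA") {
  rows <- lapply(seq_along(coords), function(i) {
    r <- coords[[i]]
    data.frame(chain = chain, resno = i, insert = NA_character_,
               resid = resid, elety = c("N", "CA", "C", "O"),
               elesy = c("N", "C", "C", "O"),
               x = c(r$N[1], r$CA[1], r$C[1], r$O[1]),
               y = c(r$N[2], r$CA[2], r$C[2], r$O[2]),
               z = c(r$N[3], r$CA[3], r$C[3], r$O[3]),
               het = FALSE, o = 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate deterministic synthetic protein structures
#'
#' Fixture generator producing idealised structures for testing feature
#' extraction without external coordinate files.
#'
#' \describe{
#'   \item{`ideal-helix`}{A poly-alanine backbone built with canonical
#'     alpha-helical dihedrals (phi = -57, psi = -47 degrees), giving a rise
#'     of about 1.5 angstrom and about 100 degrees of twist per residue so
#'     that the i -> i+4 carbonyl-to-amide hydrogen-bond geometry holds. A
#'     matching helix span covering all residues is attached.}
#'   \item{`ideal-strand`}{An extended poly-alanine backbone
#'     (phi = -135, psi = 135) with a strand span attached.}
#'   \item{`point-cloud`}{A probe amide nitrogen at the origin (residue 1)
#'     plus one carbon atom per entry of `distances`, each placed at exactly
#'     that distance from the probe in a seed-deterministic random
#'     direction. `elements` overrides the element symbols, which lets tests
#'     place hydrogens or oxygen acceptors at known distances.}
#' }
#'
#' @param kind One of `"ideal-helix"`, `"ideal-strand"`, `"point-cloud"`.
#' @param n_residues Number of residues (helix/strand kinds); at least 1.
#' @param seed Integer seed; identical seeds give byte-identical structures.
#' @param distances Numeric vector of probe distances (point-cloud only).
#' @param elements Element symbols for the point-cloud atoms (recycled).
#' @return A [protein_structure()].
#' @export
make_synthetic_structure <- function(kind = c("ideal-helix", "ideal-strand",
                                              "point-cloud"),
                                     n_residues = 10, seed = 1,
                                     distances = NULL, elements = "C") {
  kind <- match.arg(kind)
  if (kind != "point-cloud" && n_residues < 1)
    stop("n_residues must be >= 1")
  if (kind == "ideal-helix" || kind == "ideal-strand") {
    ang <- if (kind == "ideal-helix") c(-57, -47) else c(-135, 135)
    coords <- build_backbone(n_residues, phi = ang[1], psi = ang[2])
    atoms <- backbone_to_atoms(coords)
    span_kind <- if (kind == "ideal-helix") "alpha-helix" else "strand"
    ss <- data.frame(chain = "A", start = 1L, end = as.integer(n_residues),
                     kind = span_kind, stringsAsFactors = FALSE)
    return(protein_structure(atoms, ss))
  }
  ## point-cloud
  if (is.null(distances)) stop("point-cloud requires a 'distances' vector")
  if (any(distances <= 0)) stop("point-cloud distances must be positive")
  set.seed(seed)
  elements <- rep_len(elements, length(distances))
  dirs <- matrix(stats::rnorm(3 * length(distances)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  xyz <- dirs * distances
  atoms <- data.frame(
    chain = "A",
    resno = c(1L, seq_along(distances) + 1L),
    insert = NA_character_,
    resid = c("ALA", rep("UNK", length(distances))),
    elety = c("N", ifelse(elements == "H", "H", elements)),
    elesy = c("N", elements),
    x = c(0, xyz[, 1]), y = c(0, xyz[, 2]), z = c(0, xyz[, 3]),
    het = FALSE, o = 1, stringsAsFactors = FALSE)
  protein_structure(atoms, NULL)
}
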
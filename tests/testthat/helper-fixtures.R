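## Shared fixtures: tiny PDB texts written at test time and convenience
## builders for exact-geometry structures.

## A 3-residue alanine stretch with one HELIX record; second MODEL present
## to check that only MODEL 1 is read. Coordinates are an idealised helix
## fragment (values only need to be plausible and finite).
write_fixture_pdb <- function(path, elements = TRUE, altloc = FALSE) {
  atom <- function(serial, name, resno, x, y, z, el, alt = " ", occ = 1) {
    sprintf("ATOM  %5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, alt, "ALA", "A", resno, x, y, z, occ, 0,
            if (elements) el else "")
  }
  lines <- c(
    "HELIX    1   1 ALA A    1  ALA A    3  1                                   3",
    "MODEL        1",
    atom(1, " N  ", 1, 0.0, 0.0, 0.0, "N"),
    atom(2, " CA ", 1, 1.458, 0.0, 0.0, "C"),
    atom(3, " C  ", 1, 2.0, 1.4, 0.0, "C"),
    atom(4, " O  ", 1, 1.4, 2.5, 0.0, "O"),
    if (altloc) c(atom(5, " N  ", 2, 2.2, 1.5, 1.2, "N", "A", 0.4),
                  atom(6, " N  ", 2, 2.3, 1.6, 1.3, "N", "B", 0.6))
    else atom(5, " N  ", 2, 2.2, 1.5, 1.2, "N"),
    atom(7, " CA ", 2, 3.3, 2.2, 1.8, "C"),
    atom(8, " C  ", 2, 4.2, 1.4, 2.7, "C"),
    atom(9, " O  ", 2, 4.0, 0.2, 2.9, "O"),
    atom(10, " N  ", 3, 5.2, 2.0, 3.3, "N"),
    atom(11, " CA ", 3, 6.2, 1.3, 4.1, "C"),
    "ENDMDL",
    "MODEL        2",
    atom(1, " N  ", 1, 9.0, 9.0, 9.0, "N"),
    "ENDMDL",
    "END")
  writeLines(lines, path)
  path
}

## Brute-force burial oracle: O(n^2) loop over every atom, independent of
## the implementation's vectorised distance computation.
brute_force_burial <- function(structure, chain, resno, radius = 6.5,
                               include_het = FALSE,
                               scope = "all-atoms") {
  a <- structure$atoms
  probe <- a[a$chain == chain & a$resno == resno & a$elety == "N", ]
  stopifnot(nrow(probe) == 1)
  count <- 0L
  for (i in seq_len(nrow(a))) {
    row <- a[i, ]
    if (toupper(row$elesy) %in% c("H", "D")) next
    if (!include_het && (row$het || toupper(row$resid) %in%
                         c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL"))) next
    if (scope == "backbone-only" && !row$elety %in% c("N", "CA", "C", "O")) next
    if (row$chain == chain && row$resno == resno && row$elety == "N") next
    d <- sqrt((row$x - probe$x)^2 + (row$y - probe$y)^2 + (row$z - probe$z)^2)
    if (d <= radius) count <- count + 1L
  }
  count
}

## Rigid-body transform of a structure (rotation about z + translation).
rotate_structure <- function(structure, angle = 0.7, shift = c(5, -3, 2)) {
  a <- structure$atoms
  xy <- cbind(a$x, a$y) %*% matrix(c(cos(angle), sin(angle),
                                     -sin(angle), cos(angle)), 2)
  a$x <- xy[, 1] + shift[1]
  a$y <- xy[, 2] + shift[2]
  a$z <- a$z + shift[3]
  s <- structure
  s$atoms <- a
  s
}
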
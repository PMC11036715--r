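#' @importFrom stats rnorm runif setNames
#' @importFrom utils head modifyList write.table read.delim
NULL

# Frozen element table for the 64-slot atom-type vocabulary.  Masses are
# standard atomic weights, radii are van der Waals / covalent radii in
# Angstrom.  `valence` is the default (maximum implicit) valence used for
# implicit-hydrogen filling and valence validation; NA means "no implicit
# hydrogens, any coordination accepted" (metals and other elements without
# a fixed organic valence model).
.element_table <- local({
  txt <- "
symbol mass   vdw  cov  valence
B      10.812 1.80 0.84 3
C      12.011 1.70 0.76 4
N      14.007 1.60 0.71 3
O      15.999 1.55 0.66 2
F      18.998 1.50 0.57 1
Si     28.086 2.10 1.11 4
P      30.974 1.95 1.07 5
S      32.067 1.80 1.05 6
Cl     35.453 1.80 1.02 1
Br     79.904 1.90 1.20 1
I      126.904 2.10 1.39 1
Se     78.960 1.90 1.20 2
Te     127.600 2.10 1.38 2
As     74.922 2.05 1.19 3
Ge     72.610 2.10 1.20 4
Sn     118.711 2.25 1.39 4
Sb     121.760 2.20 1.39 3
Bi     208.980 2.30 1.48 3
Pb     207.200 2.30 1.46 4
Al     26.982 2.10 1.21 3
Ga     69.723 2.10 1.22 3
In     114.818 2.20 1.42 3
Tl     204.383 2.20 1.45 NA
Li     6.941  2.20 1.28 1
Na     22.990 2.40 1.66 1
K      39.098 2.80 2.03 1
Rb     85.468 2.90 2.20 1
Cs     132.905 3.00 2.44 1
Be     9.012  1.90 0.96 2
Mg     24.305 2.20 1.41 2
Ca     40.078 2.40 1.76 2
Sr     87.620 2.55 1.95 2
Ba     137.328 2.70 2.15 2
Sc     44.956 2.30 1.70 NA
Ti     47.867 2.15 1.60 NA
V      50.944 2.05 1.52 NA
Cr     51.996 2.05 1.39 NA
Mn     54.938 2.05 1.39 NA
Fe     55.845 2.05 1.32 NA
Co     58.933 2.00 1.26 NA
Ni     58.693 2.00 1.24 NA
Cu     63.546 2.00 1.32 NA
Zn     65.390 2.10 1.22 NA
Y      88.906 2.40 1.90 NA
Zr     91.224 2.30 1.75 NA
Nb     92.906 2.15 1.64 NA
Mo     95.940 2.10 1.54 NA
Tc     98.000 2.05 1.47 NA
Ru     101.070 2.05 1.46 NA
Rh     102.906 2.00 1.42 NA
Pd     106.420 2.05 1.39 NA
Ag     107.868 2.10 1.45 NA
Cd     112.412 2.20 1.44 NA
Hf     178.490 2.25 1.75 NA
Ta     180.948 2.20 1.70 NA
W      183.840 2.10 1.62 NA
Re     186.207 2.05 1.51 NA
Os     190.230 2.00 1.44 NA
Ir     192.217 2.00 1.41 NA
Pt     195.078 2.05 1.36 NA
Au     196.967 2.10 1.36 NA
Hg     200.590 2.05 1.32 NA
La     138.906 2.50 2.07 NA
Ce     140.116 2.48 2.04 NA
"
  tab <- read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 64L, !anyDuplicated(tab$symbol))
  rownames(tab) <- tab$symbol
  tab
})

# min-max scaling constants over the vocabulary, frozen with the table
.scale01 <- function(x, lo, hi) (x - lo) / (hi - lo)

.element_scaled <- local({
  t <- .element_table
  data.frame(
    row.names = t$symbol,
    mass = .scale01(t$mass, min(t$mass), max(t$mass)),
    vdw  = .scale01(t$vdw,  min(t$vdw),  max(t$vdw)),
    cov  = .scale01(t$cov,  min(t$cov),  max(t$cov))
  )
})

.hybridizations <- c("s", "sp", "sp2", "sp3", "sp3d", "sp3d2", "other")
.chirality_types <- c("unspecified", "tet_cw", "tet_ccw", "other")
.bond_orders <- c("single", "double", "triple", "aromatic")

#' Atom and bond feature schema
#'
#' Describes the fixed one-hot/scalar block layout used to featurize atoms
#' and bonds.  Atom vectors concatenate, in order: atom type (64 slots, no
#' catch-all), number of heavy neighbors (0--4, more than four), formal
#' charge (-3..3, extreme), hybridization (s, sp, sp2, sp3, sp3d, sp3d2,
#' other), explicit valence (1--6), in-ring flag, aromaticity flag, scaled
#' atomic mass, scaled van der Waals radius, scaled covalent radius,
#' chirality type (unspecified, tetrahedral CW, tetrahedral CCW, other) and
#' hydrogen count (0--4, more than four).  Bond vectors concatenate the
#' bond-type one-hot (single, double, triple, aromatic), a conjugation flag
#' and an in-ring flag.
#'
#' @return A list with elements `atom_blocks` (data frame of block name,
#'   size and kind) and `bond_blocks`; total lengths are available as
#'   `atom_len` (106) and `bond_len` (6).
#' @examples
#' feature_schema()$atom_len
#' @export
feature_schema <- function() {
  atom_blocks <- data.frame(
    name = c("atom_type", "n_heavy_neighbors", "formal_charge",
             "hybridization", "explicit_valence", "is_in_ring",
             "aromaticity", "mass_scaled", "vdw_radius_scaled",
             "covalent_radius_scaled", "chirality_type", "n_hydrogen"),
    size = c(64L, 6L, 8L, 7L, 6L, 1L, 1L, 1L, 1L, 1L, 4L, 6L),
    kind = c("one_hot", "one_hot", "one_hot", "one_hot", "one_hot",
             "scalar", "scalar", "scalar", "scalar", "scalar",
             "one_hot", "one_hot"),
    stringsAsFactors = FALSE
  )
  bond_blocks <- data.frame(
    name = c("bond_type", "conjugated", "in_ring"),
    size = c(4L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  list(atom_blocks = atom_blocks, bond_blocks = bond_blocks,
       atom_len = sum(atom_blocks$size), bond_len = sum(bond_blocks$size))
}

#' Element vocabulary
#'
#' The fixed ordered 64-element vocabulary backing the atom-type one-hot
#' block, together with the frozen mass/radius constants used for the
#' scaled scalar features.
#'
#' @return Data frame with columns `symbol`, `mass`, `vdw`, `cov`,
#'   `valence` (default valence; NA where no implicit-hydrogen model
#'   applies).
#' @export
element_vocabulary <- function() .element_table

.one_hot <- function(idx, size) {
  v <- numeric(size)
  v[idx] <- 1
  v
}

#' Featurize a single atom
#'
#' Builds the 106-long atom feature vector from an atom descriptor.
#' Out-of-range categorical values fall into each block's catch-all slot
#' ("more than four" neighbors/hydrogens, "extreme" charge, "other"
#' hybridization or chirality); explicit valence, whose block has no
#' catch-all slot, is clamped into 1..6.
#'
#' @param symbol element symbol; must be in [element_vocabulary()]
#' @param n_heavy number of heavy-atom neighbors
#' @param charge formal charge (integer)
#' @param hybridization one of `"s"`, `"sp"`, `"sp2"`, `"sp3"`, `"sp3d"`,
#'   `"sp3d2"`, `"other"`
#' @param valence explicit valence (total bond order including hydrogens)
#' @param in_ring,aromatic logical flags
#' @param chirality one of `"unspecified"`, `"tet_cw"`, `"tet_ccw"`,
#'   `"other"`
#' @param n_h number of (implicit) hydrogens
#' @return numeric vector of length `feature_schema()$atom_len`
#' @examples
#' length(featurize_atom("C", 2, 0, "sp2", 4, TRUE, TRUE, "unspecified", 1))
#' @export
featurize_atom <- function(symbol, n_heavy, charge, hybridization, valence,
                           in_ring, aromatic, chirality = "unspecified",
                           n_h = 0L) {
  ti <- match(symbol, .element_table$symbol)
  if (is.na(ti)) {
    stop("element '", symbol,
         "' is not in the 64-slot atom-type vocabulary (no catch-all slot)",
         call. = FALSE)
  }
  hy <- match(hybridization, .hybridizations)
  if (is.na(hy)) hy <- match("other", .hybridizations)
  ch <- match(chirality, .chirality_types)
  if (is.na(ch)) ch <- match("other", .chirality_types)
  heavy_slot <- if (n_heavy > 4L) 6L else n_heavy + 1L
  charge_slot <- if (charge < -3L || charge > 3L) 8L else charge + 4L
  val_slot <- min(max(round(valence), 1L), 6L)
  h_slot <- if (n_h > 4L) 6L else n_h + 1L
  sc <- .element_scaled[symbol, ]
  c(.one_hot(ti, 64L),
    .one_hot(heavy_slot, 6L),
    .one_hot(charge_slot, 8L),
    .one_hot(hy, 7L),
    .one_hot(val_slot, 6L),
    as.numeric(in_ring),
    as.numeric(aromatic),
    sc$mass, sc$vdw, sc$cov,
    .one_hot(ch, 4L),
    .one_hot(h_slot, 6L))
}

#' Featurize a single bond
#'
#' @param order one of `"single"`, `"double"`, `"triple"`, `"aromatic"`
#' @param conjugated,in_ring logical flags
#' @return numeric vector of length 6
#' @examples
#' featurize_bond("double", conjugated = TRUE, in_ring = FALSE)
#' @export
featurize_bond <- function(order, conjugated = FALSE, in_ring = FALSE) {
  oi <- match(order, .bond_orders)
  if (is.na(oi)) stop("unrecognized bond order '", order, "'", call. = FALSE)
  c(.one_hot(oi, 4L), as.numeric(conjugated), as.numeric(in_ring))
}
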
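# Seeded generator of toy peptide-receptor complexes and controlled
# model ensembles. Structures are built from idealized internal
# coordinates (standard bond lengths/angles, fully extended backbone),
# arranged as beta-strand-like chains whose backbones hydrogen-bond
# across the interface -- enough geometry for every metric in the
# package to be exercised without downloading any real structure.
# Physical realism (rotamer libraries, energies) is out of scope.

FIXTURE_ALPHABET <- c(
  "ALA", "ARG", "ASN", "ASP", "GLN", "GLU", "GLY", "HIS", "ILE", "LEU",
  "LYS", "MET", "PHE", "SER", "THR", "TRP", "TYR", "VAL"
)

# Backbone internal coordinates (Engh-Huber-style ideal values).
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
  ang_ca_c_o = 120.8
)

# Side-chain Z-matrix per residue type. Each row places `atom` from
# reference atoms (a, b, c) with bond |c-atom|, angle b-c-atom and
# dihedral a-b-c-atom; dihedral = chi index k means "chi_k + offset".
zrow <- function(atom, a, b, c, bond, angle, chi = NA, offset = 0) {
  list(atom = atom, a = a, b = b, c = c, bond = bond, angle = angle,
       chi = chi, offset = offset)
}

SIDECHAIN_ZMAT <- list(
  ALA = list(),
  SER = list(zrow("OG", "N", "CA", "CB", 1.417, 110.8, 1)),
  THR = list(
    zrow("OG1", "N", "CA", "CB", 1.433, 109.5, 1),
    zrow("CG2", "N", "CA", "CB", 1.521, 110.5, 1, -120)
  ),
  VAL = list(
    zrow("CG1", "N", "CA", "CB", 1.527, 110.5, 1),
    zrow("CG2", "N", "CA", "CB", 1.527, 110.5, 1, 122)
  ),
  LEU = list(
    zrow("CG", "N", "CA", "CB", 1.530, 116.3, 1),
    zrow("CD1", "CA", "CB", "CG", 1.524, 110.7, 2),
    zrow("CD2", "CA", "CB", "CG", 1.524, 110.7, 2, 122)
  ),
  ILE = list(
    zrow("CG1", "N", "CA", "CB", 1.530, 110.4, 1),
    zrow("CG2", "N", "CA", "CB", 1.521, 110.5, 1, -122),
    zrow("CD1", "CA", "CB", "CG1", 1.513, 113.8, 2)
  ),
  ASP = list(
    zrow("CG", "N", "CA", "CB", 1.516, 112.6, 1),
    zrow("OD1", "CA", "CB", "CG", 1.249, 118.4, 2),
    zrow("OD2", "CA", "CB", "CG", 1.249, 118.4, 2, 180)
  ),
  ASN = list(
    zrow("CG", "N", "CA", "CB", 1.516, 112.6, 1),
    zrow("OD1", "CA", "CB", "CG", 1.231, 120.8, 2),
    zrow("ND2", "CA", "CB", "CG", 1.328, 116.4, 2, 180)
  ),
  GLU = list(
    zrow("CG", "N", "CA", "CB", 1.520, 114.1, 1),
    zrow("CD", "CA", "CB", "CG", 1.516, 112.6, 2),
    zrow("OE1", "CB", "CG", "CD", 1.249, 118.4, 3),
    zrow("OE2", "CB", "CG", "CD", 1.249, 118.4, 3, 180)
  ),
  GLN = list(
    zrow("CG", "N", "CA", "CB", 1.520, 114.1, 1),
    zrow("CD", "CA", "CB", "CG", 1.516, 112.6, 2),
    zrow("OE1", "CB", "CG", "CD", 1.231, 120.8, 3),
    zrow("NE2", "CB", "CG", "CD", 1.328, 116.4, 3, 180)
  ),
  LYS = list(
    zrow("CG", "N", "CA", "CB", 1.520, 114.1, 1),
    zrow("CD", "CA", "CB", "CG", 1.520, 111.3, 2),
    zrow("CE", "CB", "CG", "CD", 1.520, 111.3, 3),
    zrow("NZ", "CG", "CD", "CE", 1.489, 111.9, 4)
  ),
  ARG = list(
    zrow("CG", "N", "CA", "CB", 1.520, 114.1, 1),
    zrow("CD", "CA", "CB", "CG", 1.520, 111.3, 2),
    zrow("NE", "CB", "CG", "CD", 1.461, 112.0, 3),
    zrow("CZ", "CG", "CD", "NE", 1.329, 124.2, 4),
    zrow("NH1", "CD", "NE", "CZ", 1.326, 120.0, NA, 0),
    zrow("NH2", "CD", "NE", "CZ", 1.326, 120.0, NA, 180)
  ),
  PHE = list(
    zrow("CG", "N", "CA", "CB", 1.502, 113.8, 1),
    zrow("CD1", "CA", "CB", "CG", 1.390, 120.0, 2),
    zrow("CD2", "CA", "CB", "CG", 1.390, 120.0, 2, 180),
    zrow("CE1", "CB", "CG", "CD1", 1.390, 120.0, NA, 180),
    zrow("CE2", "CB", "CG", "CD2", 1.390, 120.0, NA, 180),
    zrow("CZ", "CG", "CD1", "CE1", 1.390, 120.0, NA, 0)
  ),
  TYR = list(
    zrow("CG", "N", "CA", "CB", 1.502, 113.8, 1),
    zrow("CD1", "CA", "CB", "CG", 1.390, 120.0, 2),
    zrow("CD2", "CA", "CB", "CG", 1.390, 120.0, 2, 180),
    zrow("CE1", "CB", "CG", "CD1", 1.390, 120.0, NA, 180),
    zrow("CE2", "CB", "CG", "CD2", 1.390, 120.0, NA, 180),
    zrow("CZ", "CG", "CD1", "CE1", 1.390, 120.0, NA, 0),
    zrow("OH", "CD1", "CE1", "CZ", 1.376, 120.0, NA, 180)
  ),
  HIS = list(
    zrow("CG", "N", "CA", "CB", 1.497, 113.7, 1),
    zrow("ND1", "CA", "CB", "CG", 1.380, 122.7, 2),
    zrow("CD2", "CA", "CB", "CG", 1.354, 131.0, 2, 180),
    zrow("CE1", "CB", "CG", "ND1", 1.326, 109.3, NA, 180),
    zrow("NE2", "CB", "CG", "CD2", 1.373, 107.2, NA, 180)
  ),
  TRP = list(
    zrow("CG", "N", "CA", "CB", 1.498, 113.6, 1),
    zrow("CD1", "CA", "CB", "CG", 1.365, 126.9, 2),
    zrow("CD2", "CA", "CB", "CG", 1.433, 126.7, 2, 180),
    zrow("NE1", "CB", "CG", "CD1", 1.374, 110.2, NA, 180),
    zrow("CE2", "CB", "CG", "CD2", 1.409, 107.2, NA, 180),
    zrow("CE3", "CB", "CG", "CD2", 1.398, 133.9, NA, 0),
    zrow("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, NA, 180),
    zrow("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, NA, 180),
    zrow("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, NA, 0)
  ),
  MET = list(
    zrow("CG", "N", "CA", "CB", 1.520, 114.1, 1),
    zrow("SD", "CA", "CB", "CG", 1.803, 112.7, 2),
    zrow("CE", "CB", "CG", "SD", 1.791, 100.8, 3)
  )
)

# Default (idealized-rotamer) chi angles, degrees.
DEFAULT_CHI <- function(resname) {
  chi <- c(180, 180, 180, 180)
  if (resname %in% c("PHE", "TYR", "HIS", "TRP")) chi[2] <- 90
  if (resname %in% c("ASP", "ASN")) chi[2] <- 0
  if (resname %in% c("GLU", "GLN")) chi[3] <- 0
  chi
}

# Rotatable chi bonds and the side-chain atoms distal to each, used by
# the side-chain perturbation (rotation about the bond axis).
CHI_TABLE <- list(
  SER = list(list(axis = c("CA", "CB"), moved = "OG")),
  THR = list(list(axis = c("CA", "CB"), moved = c("OG1", "CG2"))),
  VAL = list(list(axis = c("CA", "CB"), moved = c("CG1", "CG2"))),
  LEU = list(
    list(axis = c("CA", "CB"), moved = c("CG", "CD1", "CD2")),
    list(axis = c("CB", "CG"), moved = c("CD1", "CD2"))
  ),
  ILE = list(
    list(axis = c("CA", "CB"), moved = c("CG1", "CG2", "CD1")),
    list(axis = c("CB", "CG1"), moved = "CD1")
  ),
  ASP = list(
    list(axis = c("CA", "CB"), moved = c("CG", "OD1", "OD2")),
    list(axis = c("CB", "CG"), moved = c("OD1", "OD2"))
  ),
  ASN = list(
    list(axis = c("CA", "CB"), moved = c("CG", "OD1", "ND2")),
    list(axis = c("CB", "CG"), moved = c("OD1", "ND2"))
  ),
  GLU = list(
    list(axis = c("CA", "CB"), moved = c("CG", "CD", "OE1", "OE2")),
    list(axis = c("CB", "CG"), moved = c("CD", "OE1", "OE2")),
    list(axis = c("CG", "CD"), moved = c("OE1", "OE2"))
  ),
  GLN = list(
    list(axis = c("CA", "CB"), moved = c("CG", "CD", "OE1", "NE2")),
    list(axis = c("CB", "CG"), moved = c("CD", "OE1", "NE2")),
    list(axis = c("CG", "CD"), moved = c("OE1", "NE2"))
  ),
  LYS = list(
    list(axis = c("CA", "CB"), moved = c("CG", "CD", "CE", "NZ")),
    list(axis = c("CB", "CG"), moved = c("CD", "CE", "NZ")),
    list(axis = c("CG", "CD"), moved = c("CE", "NZ")),
    list(axis = c("CD", "CE"), moved = "NZ")
  ),
  ARG = list(
    list(axis = c("CA", "CB"), moved = c("CG", "CD", "NE", "CZ", "NH1", "NH2")),
    list(axis = c("CB", "CG"), moved = c("CD", "NE", "CZ", "NH1", "NH2")),
    list(axis = c("CG", "CD"), moved = c("NE", "CZ", "NH1", "NH2")),
    list(axis = c("CD", "NE"), moved = c("CZ", "NH1", "NH2"))
  ),
  PHE = list(
    list(axis = c("CA", "CB"), moved = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    list(axis = c("CB", "CG"), moved = c("CD1", "CD2", "CE1", "CE2", "CZ"))
  ),
  TYR = list(
    list(axis = c("CA", "CB"),
         moved = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH")),
    list(axis = c("CB", "CG"), moved = c("CD1", "CD2", "CE1", "CE2", "CZ", "OH"))
  ),
  HIS = list(
    list(axis = c("CA", "CB"), moved = c("CG", "ND1", "CD2", "CE1", "NE2")),
    list(axis = c("CB", "CG"), moved = c("ND1", "CD2", "CE1", "NE2"))
  ),
  TRP = list(
    list(axis = c("CA", "CB"),
         moved = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
    list(axis = c("CB", "CG"),
         moved = c("CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
  ),
  MET = list(
    list(axis = c("CA", "CB"), moved = c("CG", "SD", "CE")),
    list(axis = c("CB", "CG"), moved = c("SD", "CE")),
    list(axis = c("CG", "SD"), moved = "CE")
  )
)

element_of <- function(atom) substr(gsub("^[0-9]+", "", atom), 1, 1)

place_sidechain <- function(resname, coords, chi) {
  for (zr in SIDECHAIN_ZMAT[[resname]] %||% list()) {
    dih <- if (is.na(zr$chi)) zr$offset else chi[zr$chi] + zr$offset
    coords[[zr$atom]] <- place_atom(coords[[zr$a]], coords[[zr$b]],
                                    coords[[zr$c]], zr$bond, zr$angle, dih)
  }
  coords
}

# Deterministic idealized-rotamer choice: strands are built in the xy
# plane and stacked along y, so chi1 is picked (30-degree grid) to
# minimise the side chain's in-plane (y) reach beyond CA -- side chains
# point out of the strand plane and stay clear of the partner strand
# whatever the sequence.
pick_chi1 <- function(resname, coords) {
  zmat <- SIDECHAIN_ZMAT[[resname]] %||% list()
  if (length(zmat) == 0 || is.na(zmat[[1]]$chi)) return(180)
  cand <- seq(-150, 180, 30)
  chi0 <- DEFAULT_CHI(resname)
  score <- vapply(cand, function(ch) {
    chi0[1] <- ch
    full <- place_sidechain(resname, coords, chi0)
    sc <- full[setdiff(names(full), c("N", "CA", "C", "O", "CB"))]
    max(vapply(sc, function(p) abs(p[2] - coords$CA[2]), numeric(1)))
  }, numeric(1))
  cand[which.min(score)]
}

# Build one chain as a fully extended strand (phi = psi = omega = 180)
# with idealized side chains; returns an atom tibble.
build_strand <- function(sequence, chain_id, start_resnum = 1,
                         chi_list = NULL) {
  g <- BB_GEOM
  out_res <- integer(0)
  out_name <- character(0)
  out_atom <- character(0)
  out_xyz <- list()
  prev <- NULL  # list(n, ca, c)
  for (i in seq_along(sequence)) {
    resname <- sequence[i]
    if (is.null(prev)) {
      n <- c(0, 0, 0)
      ca <- c(g$n_ca, 0, 0)
      th <- (180 - g$ang_n_ca_c) * pi / 180
      cc <- ca + g$ca_c * c(cos(th), sin(th), 0)
    } else {
      n <- place_atom(prev$n, prev$ca, prev$c, g$c_n, g$ang_ca_c_n, 180)
      ca <- place_atom(prev$ca, prev$c, n, g$n_ca, g$ang_c_n_ca, 180)
      cc <- place_atom(prev$c, n, ca, g$ca_c, g$ang_n_ca_c, 180)
    }
    # carbonyl O: dihedral N-CA-C-O = psi + 180 = 0 for the extended chain
    o <- place_atom(n, ca, cc, g$c_o, g$ang_ca_c_o, 0)
    coords <- list(N = n, CA = ca, C = cc, O = o)
    if (resname != "GLY") {
      coords$CB <- place_atom(cc, n, ca, 1.530, 110.4, -122.5)
      if (!is.null(chi_list)) {
        chi <- chi_list[[i]]
      } else {
        chi <- DEFAULT_CHI(resname)
        chi[1] <- pick_chi1(resname, coords)
      }
      coords <- place_sidechain(resname, coords, chi)
    }
    out_res <- c(out_res, rep(start_resnum + i - 1, length(coords)))
    out_name <- c(out_name, rep(resname, length(coords)))
    out_atom <- c(out_atom, names(coords))
    out_xyz <- c(out_xyz, unname(coords))
    prev <- list(n = n, ca = ca, c = cc)
  }
  xyz <- do.call(rbind, out_xyz)
  tibble(
    chain = chain_id, resnum = out_res, icode = "", resname = out_name,
    atom = out_atom, element = element_of(out_atom),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

shift_atoms <- function(atoms, dx = 0, dy = 0, dz = 0) {
  atoms$x <- atoms$x + dx
  atoms$y <- atoms$y + dy
  atoms$z <- atoms$z + dz
  atoms
}

rotate_atoms <- function(atoms, rotmat, about = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, about) %*% t(rotmat), 2, about, "+")
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  atoms
}

center_atoms <- function(atoms) {
  shift_atoms(atoms, -mean(atoms$x), -mean(atoms$y), -mean(atoms$z))
}

# Rotate a built strand about z so its CA-CA axis runs along +x, then
# centre it; strands are then stacked side by side along y.
align_strand <- function(atoms) {
  ca <- atoms[atoms$atom == "CA", ]
  axis <- c(ca$x[nrow(ca)] - ca$x[1], ca$y[nrow(ca)] - ca$y[1])
  ang <- -atan2(axis[2], axis[1]) * 180 / pi
  center_atoms(rotate_atoms(atoms, rotation_about_axis(c(0, 0, 1), ang)))
}

# Inter-strand placement constants, fixed once from the extended-strand
# geometry so that adjacent strands form cross-chain backbone hydrogen
# bonds (beta-ladder-like) and well over five 4-A residue contacts.
STRAND_SEP <- 5.0   # A between strand axes
STRAND_REG <- 0.0   # A register shift along the strand axis

#' Generate a toy peptide-receptor complex
#'
#' Builds idealized extended chains with full side chains: a peptide
#' strand laid into a receptor "groove" (two flanking receptor strands)
#' or onto a single receptor strand (`"flat"`). The construction
#' guarantees at least five cross-partition residue contacts at 4 A and
#' at least one cross-partition hydrogen bond, and errors if a spec
#' cannot satisfy that. Output is deterministic given the seed; the
#' spec and seed are recorded in PDB REMARKs by [write_structure()].
#'
#' @param n_receptor,n_peptide Residue counts (peptide >= 3). For the
#'   groove geometry the receptor is split into two strands.
#' @param receptor_seq,peptide_seq Optional explicit three-letter
#'   sequences; defaults are sampled from a 18-residue alphabet
#'   (no Pro/Cys) using `seed`.
#' @param geometry `"groove"` or `"flat"`.
#' @param seed Integer RNG seed.
#' @return A `pepqa_complex` (receptor chain `A`, peptide chain `B`).
#' @export
make_toy_complex <- function(n_receptor = 24, n_peptide = 6,
                             receptor_seq = NULL, peptide_seq = NULL,
                             geometry = c("groove", "flat"), seed = 1) {
  geometry <- match.arg(geometry)
  if (n_peptide < 3) abort("peptide must have at least 3 residues")
  if (n_receptor < 4) abort("receptor must have at least 4 residues")
  withr::with_seed(seed, {
    if (is.null(receptor_seq)) {
      receptor_seq <- sample(FIXTURE_ALPHABET, n_receptor, replace = TRUE)
    }
    if (is.null(peptide_seq)) {
      peptide_seq <- sample(FIXTURE_ALPHABET, n_peptide, replace = TRUE)
    }
  })
  if (length(receptor_seq) != n_receptor || length(peptide_seq) != n_peptide) {
    abort("sequence lengths must match the residue counts")
  }
  bad <- setdiff(c(receptor_seq, peptide_seq), FIXTURE_ALPHABET)
  if (length(bad) > 0) {
    abort(paste0("unsupported residue type(s) in fixture: ",
                 paste(unique(bad), collapse = ", ")))
  }

  pep <- align_strand(build_strand(peptide_seq, "B"))
  flip <- rotation_about_axis(c(0, 0, 1), 180)  # antiparallel neighbour
  if (geometry == "groove") {
    n1 <- ceiling(n_receptor / 2)
    s1 <- align_strand(build_strand(receptor_seq[1:n1], "A"))
    s1 <- shift_atoms(rotate_atoms(s1, flip), STRAND_REG, -STRAND_SEP, 0)
    s2 <- align_strand(build_strand(receptor_seq[(n1 + 1):n_receptor], "A",
                                    start_resnum = n1 + 1))
    s2 <- shift_atoms(rotate_atoms(s2, flip), STRAND_REG, STRAND_SEP, 0)
    rec <- dplyr::bind_rows(s1, s2)
  } else {
    rec <- align_strand(build_strand(receptor_seq, "A"))
    rec <- shift_atoms(rotate_atoms(rec, flip), STRAND_REG, -STRAND_SEP, 0)
  }
  x <- complex_structure(dplyr::bind_rows(rec, pep), "A", "B")
  attr(x, "remarks") <- sprintf(
    "pepqa toy complex: seed=%d geometry=%s n_receptor=%d n_peptide=%d",
    seed, geometry, n_receptor, n_peptide
  )
  if (nrow(contacts(x)) < 5) {
    abort("fixture spec cannot satisfy the >=5 cross-partition contact guarantee")
  }
  if (nrow(detect_interface_hbonds(x)) < 1) {
    abort("fixture spec cannot satisfy the >=1 cross-partition hydrogen-bond guarantee")
  }
  x
}

#' Generate perturbed model ensembles from a reference
#'
#' Rigid perturbations apply a rotation/translation to the peptide only
#' (receptor untouched); side-chain perturbations rotate side-chain chi
#' bonds by Gaussian noise (backbone untouched); `"mixed"` does both.
#' Models keep the reference numbering, so correspondence is trivial.
#'
#' @param reference A `pepqa_complex`.
#' @param kind `"rigid"`, `"sidechain"` or `"mixed"`.
#' @param translation Either a length-3 displacement vector (applied
#'   as-is to every model) or a single magnitude in Angstrom (a random
#'   direction is drawn per model).
#' @param rotation Either `list(axis =, angle =)` (degrees, applied
#'   about the peptide centroid) or a single angle magnitude with a
#'   random axis per model.
#' @param chi_noise_deg Standard deviation of the chi-angle noise,
#'   degrees.
#' @param n_models Number of models.
#' @param seed Integer RNG seed; the ensemble is deterministic given it.
#' @return List of `pepqa_complex` models, named `model_001`, ...
#' @export
perturb <- function(reference, kind = c("rigid", "sidechain", "mixed"),
                    translation = NULL, rotation = NULL, chi_noise_deg = 0,
                    n_models = 1, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(reference, "pepqa_complex"))
  withr::with_seed(seed, {
    models <- lapply(seq_len(n_models), function(m) {
      x <- reference
      if (kind %in% c("sidechain", "mixed")) {
        x <- perturb_sidechains(x, chi_noise_deg)
      }
      if (kind %in% c("rigid", "mixed")) {
        x <- perturb_rigid(x, translation, rotation)
      }
      attr(x, "remarks") <- sprintf(
        "pepqa perturbed model %d: kind=%s seed=%d", m, kind, seed)
      x
    })
  })
  names(models) <- sprintf("model_%03d", seq_len(n_models))
  models
}

random_unit_vector <- function() {
  v <- rnorm(3)
  while (vnorm(v) < 1e-8) v <- rnorm(3)
  unit(v)
}

perturb_rigid <- function(x, translation, rotation) {
  a <- x$atoms
  sel <- a$side == "peptide"
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  if (!is.null(rotation)) {
    if (is.list(rotation)) {
      rot <- rotation_about_axis(rotation$axis, rotation$angle)
    } else {
      rot <- rotation_about_axis(random_unit_vector(), rotation)
    }
    ctr <- colMeans(xyz)
    xyz <- sweep(sweep(xyz, 2, ctr) %*% t(rot), 2, ctr, "+")
  }
  if (!is.null(translation)) {
    t_vec <- if (length(translation) == 3) translation
             else translation * random_unit_vector()
    xyz <- sweep(xyz, 2, t_vec, "+")
  }
  a$x[sel] <- xyz[, 1]
  a$y[sel] <- xyz[, 2]
  a$z[sel] <- xyz[, 3]
  x$atoms <- a
  x
}

perturb_sidechains <- function(x, chi_noise_deg) {
  if (chi_noise_deg == 0) return(x)
  a <- x$atoms
  a$key <- res_key(a$chain, a$resnum, a$icode)
  for (key in unique(a$key)) {
    sel <- which(a$key == key)
    resname <- a$resname[sel[1]]
    chis <- CHI_TABLE[[resname]]
    if (is.null(chis)) next
    for (chi in chis) {
      i_b <- sel[a$atom[sel] == chi$axis[1]]
      i_c <- sel[a$atom[sel] == chi$axis[2]]
      moved <- sel[a$atom[sel] %in% chi$moved]
      if (length(i_b) != 1 || length(i_c) != 1 || length(moved) == 0) next
      axis <- c(a$x[i_c] - a$x[i_b], a$y[i_c] - a$y[i_b], a$z[i_c] - a$z[i_b])
      rot <- rotation_about_axis(axis, rnorm(1, 0, chi_noise_deg))
      pivot <- c(a$x[i_c], a$y[i_c], a$z[i_c])
      xyz <- as.matrix(a[moved, c("x", "y", "z")])
      xyz <- sweep(sweep(xyz, 2, pivot) %*% t(rot), 2, pivot, "+")
      a$x[moved] <- xyz[, 1]
      a$y[moved] <- xyz[, 2]
      a$z[moved] <- xyz[, 3]
    }
  }
  x$atoms <- a[, setdiff(names(a), "key")]
  x
}

#' Generate a synthetic ddG ensemble with planted hotspots
#'
#' Per model, planted hotspot residues draw ddG from
#' Normal(`hot_mean`, `noise_sd`) and all other universe residues from
#' Normal(`cold_mean`, `noise_sd`) -- a controlled substrate for the
#' hit-rate and recovery analyses.
#'
#' @param universe Tibble of residues (`chain`, `resnum`, `icode`,
#'   optionally `resname`), e.g. from [residue_table()] or
#'   [interface_residues()].
#' @param planted_keys Character vector of residue keys (as from
#'   [res_key()] / the `key` column) that are true hotspots.
#' @param n_models Number of models (default 200).
#' @param hot_mean,cold_mean,noise_sd ddG distribution parameters in
#'   approximately kcal/mol (defaults 2.0, 0.0, 0.5).
#' @param seed Integer RNG seed.
#' @return Tibble of ddG records (`model_id`, `chain`, `resnum`,
#'   `icode`, `wt`, `mut`, `ddg`).
#' @export
make_ddg_ensemble <- function(universe, planted_keys, n_models = 200,
                              hot_mean = 2.0, cold_mean = 0.0,
                              noise_sd = 0.5, seed = 1) {
  if (hot_mean <= cold_mean) abort("hot_mean must exceed cold_mean")
  universe <- as_tibble(universe)
  universe$key <- res_key(universe$chain, universe$resnum, universe$icode)
  if (!all(planted_keys %in% universe$key)) {
    abort("planted_keys must be a subset of the universe")
  }
  if (!"resname" %in% names(universe)) universe$resname <- "UNK"
  mu <- ifelse(universe$key %in% planted_keys, hot_mean, cold_mean)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_models), function(m) {
      tibble(
        model_id = sprintf("model_%03d", m),
        chain = universe$chain, resnum = universe$resnum,
        icode = universe$icode, wt = universe$resname, mut = "ALA",
        ddg = rnorm(nrow(universe), mu, noise_sd)
      )
    })
  })
}

#' Residue key string
#'
#' The `chain:resnum:icode` identifier used throughout result tables.
#'
#' @param chain,resnum,icode Vectors of chain id, residue number,
#'   insertion code (empty string when absent).
#' @return Character vector of keys.
#' @export
residue_key <- function(chain, resnum, icode = "") {
  res_key(chain, resnum, icode)
}
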
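# The three CAPRI RMSD measures. All superpositions use paired heavy
# backbone atoms {N, CA, C, O}; the interface is always defined on the
# reference structure (the native defines "the" interface), and S-RMSD
# is evaluated in the I-RMSD superposition frame unless refit_sidechain
# is requested for sensitivity analysis.

# Chemically symmetry-equivalent side-chain atom name swaps, resolved
# per residue to the minimum summed squared deviation.
SYMMETRY_SWAPS <- list(
  PHE = list(c("CD1", "CD2"), c("CE1", "CE2")),
  TYR = list(c("CD1", "CD2"), c("CE1", "CE2")),
  ASP = list(c("OD1", "OD2")),
  GLU = list(c("OE1", "OE2")),
  ARG = list(c("NH1", "NH2")),
  LEU = list(c("CD1", "CD2")),
  VAL = list(c("CG1", "CG2"))
)

paired_coords <- function(reference, model, map, keys = NULL,
                          region = NULL, heavy_only = TRUE) {
  ap <- map$atom_pairs
  if (heavy_only) ap <- dplyr::filter(ap, !.data$is_hydrogen)
  if (!is.null(region)) ap <- dplyr::filter(ap, .data$region %in% !!region)
  if (!is.null(keys)) ap <- dplyr::filter(ap, .data$ref_key %in% !!keys)
  list(
    pairs = ap,
    ref = coords_matrix(reference, ap$ref_idx),
    mod = coords_matrix(model, ap$mod_idx)
  )
}

#' Ligand (peptide) RMSD
#'
#' Superposes the model onto the reference on paired receptor backbone
#' atoms, then reports the RMSD over paired peptide backbone atoms under
#' that transform -- the peptide is never refit.
#'
#' @param reference,model `pepqa_complex` objects.
#' @param map A `pepqa_correspondence` from [build_correspondence()].
#' @return L-RMSD in Angstrom.
#' @export
ligand_rmsd <- function(reference, model, map) {
  rec <- paired_coords(reference, model, map, region = "backbone")
  rec_sel <- rec$pairs$side == "receptor"
  pep_sel <- rec$pairs$side == "peptide"
  if (sum(rec_sel) < 3) {
    abort(paste0("need >= 3 paired receptor backbone atoms for the fit; have ",
                 sum(rec_sel)))
  }
  if (sum(pep_sel) < 1) {
    abort("no paired peptide backbone atoms to evaluate")
  }
  fit <- kabsch(rec$mod[rec_sel, , drop = FALSE],
                rec$ref[rec_sel, , drop = FALSE])
  moved <- apply_transform(rec$mod[pep_sel, , drop = FALSE], fit)
  rmsd_between(moved, rec$ref[pep_sel, , drop = FALSE])
}

#' Interface backbone and side-chain RMSD (I-RMSD, S-RMSD)
#'
#' The interface is the set of reference residues whose CB (CA for Gly)
#' lies within `interface_cutoff` of the other side. Backbone mode
#' (I-RMSD) fits and evaluates on paired backbone atoms of those
#' residues. Side-chain mode (S-RMSD) reuses that backbone fit and
#' evaluates the RMSD over paired side-chain heavy atoms of the same
#' residues, resolving chemically symmetric atom names (Phe/Tyr ring,
#' Asp/Glu carboxylates, Arg NH, Leu/Val methyls) per residue to the
#' minimum contribution.
#'
#' @inheritParams ligand_rmsd
#' @param atomset `"backbone"` for I-RMSD, `"sidechain"` for S-RMSD.
#' @param interface_cutoff Interface definition cutoff in Angstrom
#'   (default 8.0).
#' @param refit_sidechain If `TRUE`, S-RMSD refits the superposition on
#'   the side-chain atoms themselves instead of reusing the backbone
#'   frame (sensitivity knob; default `FALSE`).
#' @return RMSD in Angstrom; `NA` with a warning in side-chain mode when
#'   no side-chain atom pairs exist at the interface (e.g. all-Gly).
#' @export
interface_rmsd <- function(reference, model, map,
                           atomset = c("backbone", "sidechain"),
                           interface_cutoff = 8.0,
                           refit_sidechain = FALSE) {
  atomset <- match.arg(atomset)
  iface <- interface_residues(reference, cutoff = interface_cutoff)
  if (nrow(iface) == 0) abort("reference has no interface residues")
  bb <- paired_coords(reference, model, map, keys = iface$key,
                      region = "backbone")
  if (nrow(bb$pairs) < 3) {
    abort("fewer than 3 paired interface backbone atoms; cannot superpose")
  }
  fit <- kabsch(bb$mod, bb$ref)
  if (atomset == "backbone") {
    return(fit$rmsd)
  }
  sc <- paired_coords(reference, model, map, keys = iface$key,
                      region = "sidechain")
  if (nrow(sc$pairs) == 0) {
    warn("no paired interface side-chain atoms; S-RMSD is NA")
    return(NA_real_)
  }
  if (refit_sidechain) {
    if (nrow(sc$pairs) < 3) {
      warn("fewer than 3 side-chain atom pairs; cannot refit, S-RMSD is NA")
      return(NA_real_)
    }
    refit <- kabsch(sc$mod, sc$ref)
    mod_fit <- apply_transform(sc$mod, refit)
  } else {
    mod_fit <- apply_transform(sc$mod, fit)
  }
  ss <- sidechain_squared_dev(sc$pairs, sc$ref, mod_fit, reference)
  sqrt(ss$total / ss$n)
}

# Sum of squared deviations over side-chain pairs with per-residue
# symmetry-swap resolution. Swapping atom names on the model side is
# equivalent to permuting model rows within the swap pair.
sidechain_squared_dev <- function(pairs, ref, mod, reference) {
  total <- 0
  n <- 0
  resname_of <- setNames(residue_table(reference)$resname,
                         residue_table(reference)$key)
  for (key in unique(pairs$ref_key)) {
    sel <- which(pairs$ref_key == key)
    atoms <- pairs$atom[sel]
    r <- ref[sel, , drop = FALSE]
    m <- mod[sel, , drop = FALSE]
    base <- rowSums((r - m)^2)
    best <- sum(base)
    swaps <- SYMMETRY_SWAPS[[resname_of[[key]] %||% ""]]
    if (!is.null(swaps)) {
      # swap groups of one residue act jointly (ring flips move CD and
      # CE together); evaluate identity vs full swap
      perm <- seq_along(atoms)
      swappable <- TRUE
      for (sw in swaps) {
        i <- match(sw[1], atoms)
        j <- match(sw[2], atoms)
        if (!is.na(i) && !is.na(j)) {
          perm[c(i, j)] <- perm[c(j, i)]
        } else if (xor(is.na(i), is.na(j))) {
          swappable <- FALSE
        }
      }
      if (swappable && any(perm != seq_along(atoms))) {
        swapped <- sum(rowSums((r - m[perm, , drop = FALSE])^2))
        best <- min(best, swapped)
      }
    }
    total <- total + best
    n <- n + length(sel)
  }
  list(total = total, n = n)
}
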
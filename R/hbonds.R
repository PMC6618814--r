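# Geometric cross-interface hydrogen-bond detection in the style of
# HBplus: donor-acceptor distance < 3.9 A, donor-hydrogen-acceptor
# angle > 90 deg with hydrogen-acceptor < 2.5 A where a hydrogen is
# present or placeable by ideal geometry, and donor-acceptor-antecedent
# angle > 90 deg. Charged-donor to carboxylate-oxygen pairs within
# 4.0 A are flagged and counted as short-range salt bridges.

# Donor table: antecedent defines the heavy neighbour(s) used to place
# ideal hydrogens. kind: "bisector" = sp2/backbone N with two heavy
# neighbours and one H; "sp2pair" = planar N with two H at +-120 deg
# from the antecedent bond (plane fixed by `ref`); "rotatable" =
# hydroxyl/ammonium whose H position is dihedral-dependent, judged on
# heavy-atom criteria only.
SIDECHAIN_DONORS <- list(
  SER = list(list(atom = "OG",  kind = "rotatable")),
  THR = list(list(atom = "OG1", kind = "rotatable")),
  TYR = list(list(atom = "OH",  kind = "rotatable")),
  LYS = list(list(atom = "NZ",  kind = "rotatable")),
  ARG = list(
    list(atom = "NE",  kind = "bisector", nbrs = c("CD", "CZ")),
    list(atom = "NH1", kind = "sp2pair", ant = "CZ", ref = "NE"),
    list(atom = "NH2", kind = "sp2pair", ant = "CZ", ref = "NE")
  ),
  ASN = list(list(atom = "ND2", kind = "sp2pair", ant = "CG", ref = "OD1")),
  GLN = list(list(atom = "NE2", kind = "sp2pair", ant = "CD", ref = "OE1")),
  TRP = list(list(atom = "NE1", kind = "bisector", nbrs = c("CD1", "CE2"))),
  HIS = list(
    list(atom = "ND1", kind = "bisector", nbrs = c("CG", "CE1")),
    list(atom = "NE2", kind = "bisector", nbrs = c("CD2", "CE1"))
  ),
  CYS = list(list(atom = "SG", kind = "rotatable"))
)

# Acceptor table: antecedent used for the donor-acceptor-antecedent
# angle criterion.
SIDECHAIN_ACCEPTORS <- list(
  SER = list(list(atom = "OG",  ant = "CB")),
  THR = list(list(atom = "OG1", ant = "CB")),
  TYR = list(list(atom = "OH",  ant = "CZ")),
  ASP = list(list(atom = "OD1", ant = "CG"), list(atom = "OD2", ant = "CG")),
  GLU = list(list(atom = "OE1", ant = "CD"), list(atom = "OE2", ant = "CD")),
  ASN = list(list(atom = "OD1", ant = "CG")),
  GLN = list(list(atom = "OE1", ant = "CD")),
  HIS = list(
    list(atom = "ND1", ant = "CG"),
    list(atom = "NE2", ant = "CD2")
  ),
  MET = list(list(atom = "SD", ant = "CG"))
)

CHARGED_DONOR_ATOMS <- list(
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2")
)
CARBOXYLATE_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)

#' Hydrogen-bond donors and acceptors of a residue type
#'
#' Fixed chemistry table: every residue donates through backbone N
#' (except proline) and accepts through backbone O; side-chain donors
#' and acceptors follow standard amino-acid chemistry (hydroxyls of
#' Ser/Thr/Tyr are both).
#'
#' @param resname Three-letter residue name (e.g. `"SER"`).
#' @return List with tibbles `donors` (`atom`, `kind`) and `acceptors`
#'   (`atom`, `antecedent`); empty with a warning for unknown types.
#' @export
donors_acceptors <- function(resname) {
  resname <- toupper(resname)
  known <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")
  if (!resname %in% known) {
    warn(paste0("unknown residue type ", resname, "; no donors/acceptors"))
    return(list(
      donors = tibble(atom = character(0), kind = character(0)),
      acceptors = tibble(atom = character(0), antecedent = character(0))
    ))
  }
  don <- tibble(atom = character(0), kind = character(0))
  if (resname != "PRO") don <- tibble(atom = "N", kind = "bisector")
  for (d in SIDECHAIN_DONORS[[resname]] %||% list()) {
    don <- dplyr::bind_rows(don, tibble(atom = d$atom, kind = d$kind))
  }
  acc <- tibble(atom = "O", antecedent = "C")
  for (a in SIDECHAIN_ACCEPTORS[[resname]] %||% list()) {
    acc <- dplyr::bind_rows(acc, tibble(atom = a$atom, antecedent = a$ant))
  }
  list(donors = don, acceptors = acc)
}

# Ideal hydrogen position(s) for a donor atom, or NULL when the donor
# is rotatable / geometry incomplete. Explicit hydrogens within 1.3 A
# of the donor take precedence.
donor_hydrogens <- function(donor_row, res_atoms, prev_c, structure_h) {
  d <- c(donor_row$x, donor_row$y, donor_row$z)
  if (nrow(structure_h) > 0) {
    hx <- as.matrix(structure_h[, c("x", "y", "z")])
    dist <- sqrt(rowSums(sweep(hx, 2, d)^2))
    if (any(dist < 1.3)) return(hx[dist < 1.3, , drop = FALSE])
  }
  get_xyz <- function(name, tbl = res_atoms) {
    row <- tbl[tbl$atom == name, , drop = FALSE]
    if (nrow(row) == 0) return(NULL)
    c(row$x[1], row$y[1], row$z[1])
  }
  spec <- NULL
  if (donor_row$atom == "N") {
    ca <- get_xyz("CA")
    if (is.null(ca) || is.null(prev_c)) return(NULL)  # chain start: heavy-only
    return(matrix(d + 1.01 * unit(unit(d - ca) + unit(d - prev_c)), 1, 3))
  }
  for (s in SIDECHAIN_DONORS[[donor_row$resname]] %||% list()) {
    if (s$atom == donor_row$atom) spec <- s
  }
  if (is.null(spec) || spec$kind == "rotatable") return(NULL)
  if (spec$kind == "bisector") {
    b1 <- get_xyz(spec$nbrs[1])
    b2 <- get_xyz(spec$nbrs[2])
    if (is.null(b1) || is.null(b2)) return(NULL)
    return(matrix(d + 1.01 * unit(unit(d - b1) + unit(d - b2)), 1, 3))
  }
  # sp2pair: two hydrogens in the plane of (donor, antecedent, ref)
  ant <- get_xyz(spec$ant)
  ref <- get_xyz(spec$ref)
  if (is.null(ant) || is.null(ref)) return(NULL)
  u <- unit(d - ant)
  w0 <- (ref - ant) - sum((ref - ant) * u) * u
  if (vnorm(w0) < 1e-9) return(NULL)
  w <- unit(w0)
  rbind(
    d + 1.01 * (0.5 * u + sqrt(0.75) * w),
    d + 1.01 * (0.5 * u - sqrt(0.75) * w)
  )
}

#' Detect cross-interface hydrogen bonds
#'
#' Enumerates donor/acceptor atoms on both sides of the
#' receptor/peptide partition and applies HBplus-style geometric
#' criteria (see module header). Hydrogens are used when present;
#' otherwise they are placed by ideal geometry for unambiguous donors,
#' while rotatable hydroxyls and ammonium groups are judged on
#' heavy-atom criteria alone.
#'
#' @param structure A `pepqa_complex`.
#' @param d_da_max Donor-acceptor distance cutoff, Angstrom (default 3.9).
#' @param d_ha_max Hydrogen-acceptor distance cutoff, Angstrom (default 2.5).
#' @param min_angle Minimum D-H-A and D-A-antecedent angle, degrees
#'   (default 90).
#' @param salt_bridge_max Distance within which a charged donor and a
#'   carboxylate oxygen count as a salt bridge, Angstrom (default 4.0).
#' @return Tibble of bonds: donor/acceptor residue keys and atom names,
#'   `d_da`, `is_salt_bridge`.
#' @export
detect_interface_hbonds <- function(structure, d_da_max = 3.9, d_ha_max = 2.5,
                                    min_angle = 90, salt_bridge_max = 4.0) {
  stopifnot(inherits(structure, "pepqa_complex"))
  a <- structure$atoms
  a$key <- res_key(a$chain, a$resnum, a$icode)
  heavy <- dplyr::filter(a, !.data$is_hydrogen)
  hydro <- dplyr::filter(a, .data$is_hydrogen)

  site_rows <- function(role) {
    lookup <- purrr::map_dfr(unique(heavy$resname), function(rn) {
      tab <- suppressWarnings(donors_acceptors(rn))
      tbl <- if (role == "donor") tab$donors else tab$acceptors
      if (nrow(tbl) == 0) return(NULL)
      tibble(resname = rn, atom = tbl$atom)
    })
    dplyr::semi_join(heavy, lookup, by = c("resname", "atom"))
  }
  donors <- site_rows("donor")
  acceptors <- site_rows("acceptor")
  empty <- tibble(
    don_key = character(0), don_atom = character(0),
    acc_key = character(0), acc_atom = character(0),
    d_da = numeric(0), is_salt_bridge = logical(0)
  )
  if (nrow(donors) == 0 || nrow(acceptors) == 0) return(empty)

  # previous-residue carbonyl C for backbone amide H placement
  prev_c_of <- function(row) {
    cand <- heavy[heavy$chain == row$chain & heavy$atom == "C" &
                    heavy$resnum == row$resnum - 1 & heavy$icode == "", ,
                  drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    c(cand$x[1], cand$y[1], cand$z[1])
  }
  acc_ant_of <- function(row) {
    tab <- suppressWarnings(donors_acceptors(row$resname))$acceptors
    ant_name <- tab$antecedent[match(row$atom, tab$atom)]
    cand <- heavy[heavy$key == row$key & heavy$atom == ant_name, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    c(cand$x[1], cand$y[1], cand$z[1])
  }

  bonds <- list()
  for (i in seq_len(nrow(donors))) {
    drow <- donors[i, ]
    dpos <- c(drow$x, drow$y, drow$z)
    opp <- acceptors[acceptors$side != drow$side, , drop = FALSE]
    if (nrow(opp) == 0) next
    dist <- sqrt(rowSums(sweep(as.matrix(opp[, c("x", "y", "z")]), 2, dpos)^2))
    cand_idx <- which(dist < max(d_da_max, salt_bridge_max))
    if (length(cand_idx) == 0) next
    res_atoms <- heavy[heavy$key == drow$key, , drop = FALSE]
    res_h <- hydro[hydro$key == drow$key, , drop = FALSE]
    hpos <- donor_hydrogens(drow, res_atoms, prev_c_of(drow), res_h)
    charged <- drow$atom %in% (CHARGED_DONOR_ATOMS[[drow$resname]] %||% "")
    for (j in cand_idx) {
      arow <- opp[j, ]
      apos <- c(arow$x, arow$y, arow$z)
      carboxy <- arow$atom %in% (CARBOXYLATE_ACCEPTORS[[arow$resname]] %||% "")
      salt <- charged && carboxy && dist[j] < salt_bridge_max
      ant <- acc_ant_of(arow)
      ant_ok <- is.null(ant) || angle_deg(dpos, apos, ant) > min_angle
      if (salt && ant_ok) {
        bonds[[length(bonds) + 1]] <- tibble(
          don_key = drow$key, don_atom = drow$atom,
          acc_key = arow$key, acc_atom = arow$atom,
          d_da = dist[j], is_salt_bridge = TRUE
        )
        next
      }
      if (dist[j] >= d_da_max || !ant_ok) next
      h_ok <- TRUE
      if (!is.null(hpos)) {
        h_ok <- FALSE
        for (k in seq_len(nrow(hpos))) {
          h <- hpos[k, ]
          if (vnorm(h - apos) < d_ha_max &&
              angle_deg(dpos, h, apos) > min_angle) {
            h_ok <- TRUE
            break
          }
        }
      }
      if (!h_ok) next
      bonds[[length(bonds) + 1]] <- tibble(
        don_key = drow$key, don_atom = drow$atom,
        acc_key = arow$key, acc_atom = arow$atom,
        d_da = dist[j], is_salt_bridge = FALSE
      )
    }
  }
  if (length(bonds) == 0) return(empty)
  dplyr::bind_rows(bonds) |>
    dplyr::distinct(.data$don_key, .data$don_atom, .data$acc_key,
                    .data$acc_atom, .keep_all = TRUE)
}

#' Fraction of native hydrogen bonds recovered (fnat_hb)
#'
#' Native bonds are mapped residue-wise through the correspondence and
#' matched in the model's bond set, by donor/acceptor atom identity by
#' default, or by residue pair for threaded models.
#'
#' @param reference_hb,model_hb Bond tibbles from
#'   [detect_interface_hbonds()] on reference and model.
#' @param map A `pepqa_correspondence`.
#' @param match One of `"atom"` (default) or `"residue"`.
#' @return Fraction in \[0, 1\], or `NA` when the reference has no
#'   cross-interface hydrogen bonds.
#' @export
fnat_hb <- function(reference_hb, model_hb, map, match = c("atom", "residue")) {
  match <- match.arg(match)
  stopifnot(inherits(map, "pepqa_correspondence"))
  if (nrow(reference_hb) == 0) return(NA_real_)
  key_map <- setNames(map$residue_pairs$mod_key, map$residue_pairs$ref_key)
  dk <- unname(key_map[reference_hb$don_key])
  ak <- unname(key_map[reference_hb$acc_key])
  if (match == "atom") {
    ref_ids <- paste(dk, reference_hb$don_atom, ak, reference_hb$acc_atom)
    mod_ids <- paste(model_hb$don_key, model_hb$don_atom,
                     model_hb$acc_key, model_hb$acc_atom)
  } else {
    ref_ids <- paste(dk, ak)
    mod_ids <- paste(model_hb$don_key, model_hb$acc_key)
  }
  mean(!is.na(dk) & !is.na(ak) & ref_ids %in% mod_ids)
}
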
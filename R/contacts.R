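# Table-1(A) interface detectors. All cutoffs are strict "<" as
# printed; contacts and clashes use heavy atoms only (CAPRI practice;
# toggle with include_hydrogens at your own risk).

cross_distance_table <- function(structure, include_hydrogens = FALSE) {
  a <- structure$atoms
  if (!include_hydrogens) a <- dplyr::filter(a, !.data$is_hydrogen)
  rec <- dplyr::filter(a, .data$side == "receptor")
  pep <- dplyr::filter(a, .data$side == "peptide")
  d <- cross_dist(as.matrix(rec[, c("x", "y", "z")]),
                  as.matrix(pep[, c("x", "y", "z")]))
  list(rec = rec, pep = pep, d = d)
}

# Euclidean distance matrix between two coordinate sets (rows of a vs
# b). Computed from explicit coordinate differences: the usual
# norm-expansion shortcut loses exactness through cancellation, which
# matters because the Table-1(A) cutoffs are strict inequalities.
cross_dist <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Interface residues (CB-CB 8 A rule)
#'
#' A residue is at the interface if its representative atom (CB, or CA
#' for glycine) lies strictly within `cutoff` of the representative atom
#' of any residue on the other side of the receptor/peptide partition.
#' Non-glycine residues lacking CB fall back to CA with a warning;
#' residues with neither are excluded with a warning.
#'
#' @param structure A `pepqa_complex`.
#' @param cutoff Distance cutoff in Angstrom (default 8.0, strict `<`).
#' @return A tibble of interface residues: `chain`, `resnum`, `icode`,
#'   `resname`, `side`, `key`.
#' @export
interface_residues <- function(structure, cutoff = 8.0) {
  stopifnot(inherits(structure, "pepqa_complex"), cutoff > 0)
  res <- residue_table(structure)
  a <- dplyr::filter(structure$atoms, !.data$is_hydrogen)
  a$key <- res_key(a$chain, a$resnum, a$icode)
  rep_at <- a |>
    dplyr::group_by(.data$key) |>
    dplyr::group_map(function(g, k) {
      resname <- g$resname[1]
      pick <- if (resname == "GLY") "CA" else "CB"
      row <- g[g$atom == pick, , drop = FALSE]
      if (nrow(row) == 0 && pick == "CB") {
        warn(paste0("residue ", k$key, " (", resname, ") lacks CB; using CA"))
        row <- g[g$atom == "CA", , drop = FALSE]
      }
      if (nrow(row) == 0) {
        warn(paste0("residue ", k$key, " has neither CB nor CA; excluded"))
        return(NULL)
      }
      tibble(key = k$key, side = g$side[1],
             x = row$x[1], y = row$y[1], z = row$z[1])
    }, .keep = TRUE) |>
    dplyr::bind_rows()
  rec <- dplyr::filter(rep_at, .data$side == "receptor")
  pep <- dplyr::filter(rep_at, .data$side == "peptide")
  keep <- character(0)
  if (nrow(rec) > 0 && nrow(pep) > 0) {
    d <- cross_dist(as.matrix(rec[, c("x", "y", "z")]),
                    as.matrix(pep[, c("x", "y", "z")]))
    hit <- d < cutoff
    keep <- c(rec$key[rowSums(hit) > 0], pep$key[colSums(hit) > 0])
  }
  out <- dplyr::filter(res, .data$key %in% keep)
  attr(out, "cutoff") <- cutoff
  out
}

#' Cross-interface residue contacts (4 A rule)
#'
#' A receptor residue and a peptide residue are in contact if any pair
#' of their heavy atoms lies strictly within `cutoff` (residue-based
#' counting: one contact per residue pair).
#'
#' @inheritParams interface_residues
#' @param cutoff Distance cutoff in Angstrom (default 4.0, strict `<`).
#' @param include_hydrogens Include hydrogen atoms in the scan
#'   (default `FALSE`, the CAPRI convention).
#' @return A tibble with one row per contacting residue pair:
#'   `rec_key`, `pep_key`, `min_dist`.
#' @export
contacts <- function(structure, cutoff = 4.0, include_hydrogens = FALSE) {
  stopifnot(inherits(structure, "pepqa_complex"), cutoff > 0)
  ct <- cross_distance_table(structure, include_hydrogens)
  if (nrow(ct$rec) == 0 || nrow(ct$pep) == 0) {
    return(tibble(rec_key = character(0), pep_key = character(0),
                  min_dist = numeric(0)))
  }
  idx <- which(ct$d < cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble(rec_key = character(0), pep_key = character(0),
                  min_dist = numeric(0)))
  }
  tibble(
    rec_key = res_key(ct$rec$chain[idx[, 1]], ct$rec$resnum[idx[, 1]],
                      ct$rec$icode[idx[, 1]]),
    pep_key = res_key(ct$pep$chain[idx[, 2]], ct$pep$resnum[idx[, 2]],
                      ct$pep$icode[idx[, 2]]),
    dist = ct$d[idx]
  ) |>
    dplyr::group_by(.data$rec_key, .data$pep_key) |>
    dplyr::summarise(min_dist = min(.data$dist), .groups = "drop")
}

#' Cross-interface atomic clashes (3 A rule)
#'
#' Counts every cross-partition heavy-atom pair strictly within
#' `cutoff` (atom-based: each qualifying pair counts once). Reported
#' for information; no model is disqualified on clashes.
#'
#' @inheritParams contacts
#' @param cutoff Distance cutoff in Angstrom (default 3.0, strict `<`).
#' @return Integer clash count.
#' @export
count_clashes <- function(structure, cutoff = 3.0, include_hydrogens = FALSE) {
  stopifnot(inherits(structure, "pepqa_complex"), cutoff > 0)
  ct <- cross_distance_table(structure, include_hydrogens)
  if (nrow(ct$rec) == 0 || nrow(ct$pep) == 0) return(0L)
  sum(ct$d < cutoff)
}

#' Fraction of native contacts recovered by a model (fnat)
#'
#' Native (reference) residue contacts are mapped through the
#' reference-to-model correspondence and looked up in the model's
#' contact set; the denominator is always the native set.
#'
#' @param reference_contacts,model_contacts Contact tibbles from
#'   [contacts()], computed on the reference and the model.
#' @param map A `pepqa_correspondence` from [build_correspondence()].
#' @return Fraction in \[0, 1\].
#' @export
fnat <- function(reference_contacts, model_contacts, map) {
  stopifnot(inherits(map, "pepqa_correspondence"))
  if (nrow(reference_contacts) == 0) {
    abort("reference structure has no cross-interface contacts; cannot compute fnat")
  }
  key_map <- setNames(map$residue_pairs$mod_key, map$residue_pairs$ref_key)
  mapped_rec <- unname(key_map[reference_contacts$rec_key])
  mapped_pep <- unname(key_map[reference_contacts$pep_key])
  model_keys <- paste(model_contacts$rec_key, model_contacts$pep_key)
  recovered <- !is.na(mapped_rec) & !is.na(mapped_pep) &
    paste(mapped_rec, mapped_pep) %in% model_keys
  mean(recovered)
}
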
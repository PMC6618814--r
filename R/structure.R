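# Structures are a light S3 record: an atom tibble plus the
# receptor/peptide chain partition. One row per atom; residues are
# identified by (chain, resnum, icode) -- no sequence alignment is ever
# attempted, so models must keep the reference numbering (the CAPRI
# convention).

#' Construct a peptide-protein complex from an atom table
#'
#' @param atoms A data frame with one row per atom and columns `chain`,
#'   `resnum`, `icode`, `resname`, `atom`, `element`, `x`, `y`, `z`,
#'   and optionally `occ` (default 1) and `bfactor` (default 0).
#' @param receptor_chains,peptide_chains Character vectors of chain ids
#'   making up the receptor and the peptide. Must be disjoint, non-empty,
#'   and jointly cover every chain in `atoms`.
#' @return An object of class `pepqa_complex`.
#' @export
complex_structure <- function(atoms, receptor_chains, peptide_chains) {
  atoms <- as_tibble(atoms)
  need <- c("chain", "resnum", "icode", "resname", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"bfactor" %in% names(atoms)) atoms$bfactor <- 0
  if (!"is_hydrogen" %in% names(atoms)) {
    atoms$is_hydrogen <- atoms$element == "H"
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  if (any(!nzchar(atoms$atom))) abort("atom names must be non-empty")
  receptor_chains <- as.character(receptor_chains)
  peptide_chains <- as.character(peptide_chains)
  if (length(intersect(receptor_chains, peptide_chains)) > 0) {
    abort("receptor and peptide chains must be disjoint")
  }
  if (length(receptor_chains) == 0 || length(peptide_chains) == 0) {
    abort("both receptor and peptide chain sets must be non-empty")
  }
  for (side in list(receptor_chains, peptide_chains)) {
    absent <- setdiff(side, unique(atoms$chain))
    if (length(absent) > 0) {
      abort(paste0("designated chain(s) not present in structure: ",
                   paste(absent, collapse = ", ")))
    }
  }
  stray <- setdiff(unique(atoms$chain), c(receptor_chains, peptide_chains))
  if (length(stray) > 0) {
    abort(paste0("chain(s) not assigned to receptor or peptide: ",
                 paste(stray, collapse = ", ")))
  }
  atoms$side <- ifelse(atoms$chain %in% receptor_chains, "receptor", "peptide")
  structure(
    list(
      atoms = atoms,
      receptor_chains = receptor_chains,
      peptide_chains = peptide_chains
    ),
    class = "pepqa_complex"
  )
}

#' @export
print.pepqa_complex <- function(x, ...) {
  res <- residue_table(x)
  cat("<pepqa_complex> ",
      nrow(x$atoms), " atoms, ", nrow(res), " residues\n",
      "  receptor chains: ", paste(x$receptor_chains, collapse = ", "),
      " (", sum(res$side == "receptor"), " residues)\n",
      "  peptide chains:  ", paste(x$peptide_chains, collapse = ", "),
      " (", sum(res$side == "peptide"), " residues)\n", sep = "")
  invisible(x)
}

#' Residue-level view of a complex
#'
#' @param x A `pepqa_complex`.
#' @return A tibble with one row per residue: `chain`, `resnum`,
#'   `icode`, `resname`, `side`, `key`.
#' @export
residue_table <- function(x) {
  stopifnot(inherits(x, "pepqa_complex"))
  dplyr::distinct(
    x$atoms, .data$chain, .data$resnum, .data$icode, .data$resname, .data$side
  ) |>
    dplyr::mutate(key = res_key(.data$chain, .data$resnum, .data$icode))
}

#' Read a peptide-protein complex from a PDB file
#'
#' Parses ATOM records with `bio3d`, resolves alternate locations to the
#' highest-occupancy conformer (ties broken by file order), drops
#' HETATM records and waters (selenomethionine, MSE, is rescued and
#' renamed to MET with a warning), and keeps hydrogens flagged so that
#' metrics can exclude them.
#'
#' @param path Path to a PDB file.
#' @inheritParams complex_structure
#' @return A `pepqa_complex`.
#' @export
read_structure <- function(path, receptor_chains, peptide_chains) {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- as_tibble(pdb$atom)
  is_mse <- at$type == "HETATM" & at$resid == "MSE"
  if (any(is_mse)) {
    warn("selenomethionine (MSE) mapped to MET")
    at$resid[is_mse] <- "MET"
    at$elety[is_mse] <- ifelse(at$elety[is_mse] == "SE", "SD", at$elety[is_mse])
    at$type[is_mse] <- "ATOM"
  }
  at <- dplyr::filter(at, .data$type == "ATOM", .data$resid != "HOH")
  if (nrow(at) == 0) abort(paste0("no ATOM records in ", path))
  at$icode <- ifelse(is.na(at$insert), "", at$insert)
  at$o <- ifelse(is.na(at$o), 1, at$o)
  at$file_order <- seq_len(nrow(at))
  # altloc: keep the highest-occupancy record per atom, ties by file order
  at <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$icode, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$file_order, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$file_order)
  elem <- ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                 substr(gsub("^[0-9]", "", at$elety), 1, 1), at$elesy)
  atoms <- tibble(
    chain = at$chain, resnum = at$resno, icode = at$icode,
    resname = at$resid, atom = at$elety, element = elem,
    x = at$x, y = at$y, z = at$z,
    occ = at$o, bfactor = ifelse(is.na(at$b), 0, at$b),
    is_hydrogen = elem == "H"
  )
  x <- complex_structure(atoms, receptor_chains, peptide_chains)
  for (side in list(receptor_chains, peptide_chains)) {
    for (ch in side) {
      if (sum(!atoms$is_hydrogen & atoms$chain == ch) == 0) {
        abort(paste0("designated chain ", ch, " has no protein atoms"))
      }
    }
  }
  x
}

#' Write a complex to a PDB file
#'
#' Emits standard fixed-width ATOM records through `bio3d::write.pdb`,
#' preceded by any REMARK lines attached to the structure (the fixture
#' generator records its spec and seed there).
#'
#' @param x A `pepqa_complex`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "pepqa_complex"))
  a <- x$atoms
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(
    file = tmp,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    resno = a$resnum, resid = a$resname, chain = a$chain,
    insert = ifelse(nzchar(a$icode), a$icode, ""),
    elety = a$atom, o = a$occ, b = a$bfactor, elesy = a$element
  )
  lines <- readLines(tmp)
  remarks <- attr(x, "remarks")
  if (!is.null(remarks)) {
    lines <- c(sprintf("REMARK 250 %s", remarks), lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Select atoms of a residue by structural region
#'
#' Backbone is the CAPRI peptide-assessment set \{N, CA, C, O\}; side
#' chain is every other heavy atom (CB included, so Gly has an empty
#' side chain). Hydrogens are never returned.
#'
#' @param residue A data frame of atom rows (one residue of a
#'   `pepqa_complex` atom table).
#' @param selector One of `"backbone"`, `"sidechain"`, `"all-heavy"`.
#' @return The selected atom rows.
#' @export
select_atoms <- function(residue, selector = c("backbone", "sidechain", "all-heavy")) {
  selector <- match.arg(selector)
  heavy <- dplyr::filter(as_tibble(residue), !.data$is_hydrogen)
  switch(selector,
    "backbone" = dplyr::filter(heavy, .data$atom %in% BACKBONE_ATOMS),
    "sidechain" = dplyr::filter(heavy, !.data$atom %in% BACKBONE_ATOMS),
    "all-heavy" = heavy
  )
}

#' Pair residues and atoms of a reference and a model
#'
#' Residues are paired by (mapped chain, residue number, insertion
#' code); atoms within a paired residue by identical PDB atom name.
#' Residues whose names disagree across the pair are kept with backbone
#' atom pairs only (threaded models keep their L-/I-RMSD while S-RMSD
#' honestly excludes them), with a warning. Unpaired residues and atoms
#' are recorded, not fatal.
#'
#' @param reference,model `pepqa_complex` objects.
#' @param chain_map Named character vector mapping reference chain ids
#'   to model chain ids; default pairs chains by identical id.
#' @return An object of class `pepqa_correspondence`: list with tibbles
#'   `residue_pairs`, `atom_pairs` (reference/model row indices, atom
#'   name, region), `unpaired_residues`, `unpaired_atoms`.
#' @export
build_correspondence <- function(reference, model, chain_map = NULL) {
  stopifnot(inherits(reference, "pepqa_complex"), inherits(model, "pepqa_complex"))
  ref_chains <- c(reference$receptor_chains, reference$peptide_chains)
  if (is.null(chain_map)) chain_map <- setNames(ref_chains, ref_chains)
  uncovered <- setdiff(ref_chains, names(chain_map))
  if (length(uncovered) > 0) {
    abort(paste0("chain_map does not cover reference chain(s): ",
                 paste(uncovered, collapse = ", ")))
  }
  ref_res <- residue_table(reference)
  mod_res <- residue_table(model)
  ref_res$mapped_chain <- unname(chain_map[ref_res$chain])
  ref_res$mod_key <- res_key(ref_res$mapped_chain, ref_res$resnum, ref_res$icode)

  pairs <- dplyr::inner_join(
    dplyr::select(ref_res, ref_key = "key", "mod_key", "chain", "resnum",
                  "icode", "side", ref_resname = "resname"),
    dplyr::select(mod_res, mod_key = "key", mod_resname = "resname"),
    by = "mod_key"
  )
  mismatch <- pairs$ref_resname != pairs$mod_resname
  if (any(mismatch)) {
    warn(paste0(sum(mismatch), " paired residue(s) differ in residue name; ",
                "keeping backbone atom pairs only for those"))
  }
  pairs$name_mismatch <- mismatch

  unpaired_res <- dplyr::bind_rows(
    tibble(side_of = "reference",
           key = setdiff(ref_res$key, pairs$ref_key)),
    tibble(side_of = "model",
           key = setdiff(mod_res$key, pairs$mod_key))
  )

  ref_atoms <- reference$atoms |>
    dplyr::mutate(ref_idx = dplyr::row_number(),
                  ref_key = res_key(.data$chain, .data$resnum, .data$icode))
  mod_atoms <- model$atoms |>
    dplyr::mutate(mod_idx = dplyr::row_number(),
                  mod_key = res_key(.data$chain, .data$resnum, .data$icode))

  atom_pairs <- pairs |>
    dplyr::select("ref_key", "mod_key", "side", "name_mismatch") |>
    dplyr::inner_join(
      dplyr::select(ref_atoms, "ref_key", atom = "atom", "ref_idx",
                    is_hydrogen = "is_hydrogen"),
      by = "ref_key", relationship = "one-to-many"
    ) |>
    dplyr::inner_join(
      dplyr::select(mod_atoms, "mod_key", atom = "atom", "mod_idx"),
      by = c("mod_key", "atom")
    ) |>
    dplyr::mutate(region = ifelse(.data$atom %in% BACKBONE_ATOMS,
                                  "backbone", "sidechain")) |>
    dplyr::filter(!(.data$name_mismatch & .data$region == "sidechain")) |>
    dplyr::select("ref_key", "mod_key", "atom", "region", "side",
                  "ref_idx", "mod_idx", "is_hydrogen")

  unpaired_atoms <- dplyr::anti_join(
    dplyr::filter(ref_atoms, .data$ref_key %in% pairs$ref_key, !.data$is_hydrogen),
    atom_pairs,
    by = "ref_idx"
  ) |>
    dplyr::select(key = "ref_key", "atom")

  structure(
    list(
      residue_pairs = as_tibble(pairs),
      atom_pairs = as_tibble(atom_pairs),
      unpaired_residues = unpaired_res,
      unpaired_atoms = as_tibble(unpaired_atoms),
      chain_map = chain_map
    ),
    class = "pepqa_correspondence"
  )
}

#' @export
print.pepqa_correspondence <- function(x, ...) {
  cat("<pepqa_correspondence> ", nrow(x$residue_pairs), " residue pairs, ",
      nrow(x$atom_pairs), " atom pairs; ",
      nrow(x$unpaired_residues), " unpaired residues, ",
      nrow(x$unpaired_atoms), " unpaired heavy atoms\n", sep = "")
  invisible(x)
}

coords_matrix <- function(x, idx = NULL) {
  a <- x$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

# Apply a rigid transform to (part of) a complex, returning a new one.
transform_structure <- function(x, transform, chains = NULL) {
  a <- x$atoms
  sel <- if (is.null(chains)) rep(TRUE, nrow(a)) else a$chain %in% chains
  xyz <- apply_transform(as.matrix(a[sel, c("x", "y", "z")]), transform)
  a$x[sel] <- xyz[, 1]
  a$y[sel] <- xyz[, 2]
  a$z[sel] <- xyz[, 3]
  out <- x
  out$atoms <- a
  out
}
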
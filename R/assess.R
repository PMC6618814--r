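# The per-model metric bundle and batch assessment driver.

#' Compute the full metric bundle for one model
#'
#' fnat, fnat_hb, L-RMSD, I-RMSD, S-RMSD, clash count and the native
#' contact / hydrogen-bond counts of one model against the reference.
#'
#' @param reference,model `pepqa_complex` objects.
#' @param chain_map Optional named chain map (reference -> model ids).
#' @param interface_cutoff,contact_cutoff,clash_cutoff Table-1(A)
#'   cutoffs in Angstrom (defaults 8.0, 4.0, 3.0).
#' @return One-row tibble with columns `fnat`, `fnat_hb`, `l_rmsd`,
#'   `i_rmsd`, `s_rmsd`, `clashes`, `n_native_contacts`,
#'   `n_native_hbonds`.
#' @export
compute_metrics <- function(reference, model, chain_map = NULL,
                            interface_cutoff = 8.0, contact_cutoff = 4.0,
                            clash_cutoff = 3.0) {
  map <- build_correspondence(reference, model, chain_map)
  ref_con <- contacts(reference, cutoff = contact_cutoff)
  mod_con <- contacts(model, cutoff = contact_cutoff)
  ref_hb <- detect_interface_hbonds(reference)
  mod_hb <- detect_interface_hbonds(model)
  tibble(
    fnat = fnat(ref_con, mod_con, map),
    fnat_hb = fnat_hb(ref_hb, mod_hb, map),
    l_rmsd = ligand_rmsd(reference, model, map),
    i_rmsd = interface_rmsd(reference, model, map, "backbone",
                            interface_cutoff = interface_cutoff),
    s_rmsd = interface_rmsd(reference, model, map, "sidechain",
                            interface_cutoff = interface_cutoff),
    clashes = as.integer(count_clashes(model, cutoff = clash_cutoff)),
    n_native_contacts = nrow(ref_con),
    n_native_hbonds = nrow(ref_hb)
  )
}

#' Assess a batch of models against a reference
#'
#' Computes the metric bundle and both classifications for every model,
#' in input order. A model that fails to parse or assess is marked
#' `FAILED` in the `status` column and does not abort the batch.
#'
#' @param reference A `pepqa_complex`, or a path to a reference PDB.
#' @param models A named list of `pepqa_complex` objects (as from
#'   [perturb()]) or a character vector of model PDB paths.
#' @param receptor_chains,peptide_chains Chain designations, required
#'   when `reference`/`models` are paths.
#' @param scheme A `pepqa_scheme` for the refined classification.
#' @param ... Passed on to [compute_metrics()].
#' @return A tibble with one row per model: `model_id`, `status`, the
#'   metric bundle, `class`, `rule`, `class_refined`, `rule_refined`.
#' @export
assess_models <- function(reference, models, receptor_chains = NULL,
                          peptide_chains = NULL, scheme = refined_scheme(),
                          ...) {
  if (is.character(reference)) {
    reference <- read_structure(reference, receptor_chains, peptide_chains)
  }
  if (is.character(models)) {
    paths <- models
    ids <- ifelse(nzchar(names(paths) %||% ""), names(paths),
                  sub("\\.pdb$", "", basename(paths)))
  } else {
    paths <- NULL
    ids <- names(models) %||% sprintf("model_%03d", seq_along(models))
  }
  rows <- purrr::map(seq_along(ids), function(i) {
    res <- tryCatch({
      model <- if (is.null(paths)) models[[i]] else
        read_structure(paths[i], receptor_chains, peptide_chains)
      m <- compute_metrics(reference, model, ...)
      cls <- classify_refined(m, scheme)
      dplyr::bind_cols(tibble(model_id = ids[i], status = "OK"), cls)
    }, error = function(e) {
      warn(paste0("model ", ids[i], " failed: ", conditionMessage(e)))
      tibble(model_id = ids[i], status = "FAILED")
    })
    res
  })
  dplyr::bind_rows(rows)
}

#' Write a result table as TSV
#'
#' Tab-separated, header line, `NA` for undefined values; numeric
#' columns rounded to 3 decimals (ddG columns to 2).
#'
#' @param x A data frame.
#' @param path Output path.
#' @param comment Optional comment line(s) written as `# ...` above the
#'   header.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, comment = NULL) {
  x <- dplyr::mutate(
    as_tibble(x),
    dplyr::across(dplyr::where(is.numeric),
                  ~ round(., if (dplyr::cur_column() == "ddg") 2 else 3))
  )
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}
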
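# Aggregation of computational alanine-scanning tables: per-model
# hotspot flagging at the ddG cutoff, ensemble hit-rate maps, recovery
# histograms against a reference hotspot list, and B-factor annotation
# of structures for surface colouring. The predictors themselves
# (Robetta / FoldX / mCSM and kin) are never run here; their exported
# tables are the input.

#' Read a per-residue ddG table
#'
#' Expects a TSV with header columns `model_id`, `chain`, `resnum`,
#' `icode`, `wt`, `mut`, `ddg`; `col_map` renames predictor-specific
#' layouts onto these names.
#'
#' @param path Path to a tab-separated file.
#' @param col_map Optional named character vector, `c(ours = theirs)`.
#' @return Tibble of ddG records.
#' @export
read_ddg <- function(path, col_map = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!is.null(col_map)) tbl <- dplyr::rename(tbl, dplyr::all_of(col_map))
  need <- c("model_id", "chain", "resnum", "icode", "wt", "mut", "ddg")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("ddG table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl$icode <- ifelse(is.na(tbl$icode), "", as.character(tbl$icode))
  as_tibble(tbl[need])
}

#' Read a reference hotspot list
#'
#' TSV with header columns `chain`, `resnum`, `icode`, `side`
#' (`receptor` or `peptide`) and free-text `note`.
#'
#' @param path Path to a tab-separated file.
#' @return Tibble with a `key` column added.
#' @export
read_hotspot_reference <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- c("chain", "resnum", "icode", "side")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("hotspot reference lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl$icode <- ifelse(is.na(tbl$icode), "", as.character(tbl$icode))
  if (!"note" %in% names(tbl)) tbl$note <- ""
  tbl$key <- res_key(tbl$chain, tbl$resnum, tbl$icode)
  if (anyDuplicated(tbl$key) > 0) abort("duplicate residues in hotspot reference")
  as_tibble(tbl)
}

#' Flag predicted hotspots at a ddG cutoff
#'
#' A residue is a hotspot for a model iff its predicted ddG is at or
#' above `cutoff` (inclusive: the cutoff of 0.95 is itself chosen to
#' absorb minor noise around 1 kcal/mol). Records with missing ddG are
#' skipped with a warning; duplicate (model, residue, mutation) keys are
#' an error.
#'
#' @param ddg_table Tibble of ddG records as from [read_ddg()] or
#'   [make_ddg_ensemble()].
#' @param cutoff Hotspot threshold in predictor units, approximately
#'   kcal/mol (default 0.95).
#' @return The table with `key` and logical `hotspot` columns appended.
#' @export
flag_hotspots <- function(ddg_table, cutoff = 0.95) {
  ddg_table <- as_tibble(ddg_table)
  id <- paste(ddg_table$model_id, ddg_table$chain, ddg_table$resnum,
              ddg_table$icode, ddg_table$mut)
  if (anyDuplicated(id) > 0) {
    abort("duplicate (model_id, chain, resnum, icode, mutation) records")
  }
  if (anyNA(ddg_table$ddg)) {
    warn(paste0(sum(is.na(ddg_table$ddg)), " record(s) with missing ddG skipped"))
    ddg_table <- dplyr::filter(ddg_table, !is.na(.data$ddg))
  }
  ddg_table |>
    dplyr::mutate(
      key = res_key(.data$chain, .data$resnum, .data$icode),
      hotspot = .data$ddg >= cutoff
    )
}

#' Per-residue hotspot hit rates over a model ensemble
#'
#' Counts, for every residue, in how many models it was flagged as a
#' hotspot. Residues present in the universe but never flagged get a
#' count of 0.
#'
#' @param flagged Output of [flag_hotspots()] covering all models.
#' @param universe Optional tibble with `chain`, `resnum`, `icode`
#'   defining the residues to report (default: all residues appearing in
#'   `flagged`).
#' @return Tibble with one row per residue: `chain`, `resnum`, `icode`,
#'   `key`, `hit_count`, `n_models`, `hit_rate`.
#' @export
hit_rates <- function(flagged, universe = NULL) {
  stopifnot(all(c("model_id", "key", "hotspot") %in% names(flagged)))
  n_models <- dplyr::n_distinct(flagged$model_id)
  if (n_models < 1) abort("need at least one model")
  if (is.null(universe)) {
    universe <- dplyr::distinct(flagged, .data$chain, .data$resnum, .data$icode)
  }
  universe <- universe |>
    dplyr::mutate(key = res_key(.data$chain, .data$resnum, .data$icode)) |>
    dplyr::distinct(.data$chain, .data$resnum, .data$icode, .data$key)
  counts <- flagged |>
    dplyr::filter(.data$hotspot) |>
    dplyr::distinct(.data$model_id, .data$key) |>
    dplyr::count(.data$key, name = "hit_count")
  universe |>
    dplyr::left_join(counts, by = "key") |>
    dplyr::mutate(
      hit_count = dplyr::coalesce(.data$hit_count, 0L),
      n_models = n_models,
      hit_rate = .data$hit_count / n_models
    )
}

#' Histogram of reference-hotspot recovery across models
#'
#' For each model, counts how many reference hotspots on the chosen side
#' it flags, and tabulates models by that count (the familiar
#' hotspot-recovery histogram, with the crystal-structure table as an
#' optional baseline "star").
#'
#' @inheritParams hit_rates
#' @param reference Hotspot reference tibble from
#'   [read_hotspot_reference()] (columns `key`, `side`).
#' @param side `"receptor"` or `"peptide"`.
#' @param baseline Optional flagged table (as from [flag_hotspots()])
#'   for a single baseline structure, e.g. the crystal itself.
#' @return Tibble `n_recovered` (0 .. number of reference hotspots),
#'   `n_models`; attributes `n_reference` and `baseline_recovered`.
#' @export
recovery_histogram <- function(flagged, reference,
                               side = c("receptor", "peptide"),
                               baseline = NULL) {
  side <- match.arg(side)
  ref_keys <- reference$key[reference$side == side]
  if (length(ref_keys) == 0) {
    abort(paste0("hotspot reference has no ", side, " entries"))
  }
  per_model <- flagged |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(
      n_recovered = sum(unique(.data$key[.data$hotspot]) %in% ref_keys),
      .groups = "drop"
    )
  hist <- tibble(n_recovered = 0:length(ref_keys)) |>
    dplyr::left_join(dplyr::count(per_model, .data$n_recovered,
                                  name = "n_models"),
                     by = "n_recovered") |>
    dplyr::mutate(n_models = dplyr::coalesce(.data$n_models, 0L))
  attr(hist, "n_reference") <- length(ref_keys)
  if (!is.null(baseline)) {
    attr(hist, "baseline_recovered") <-
      sum(unique(baseline$key[baseline$hotspot]) %in% ref_keys)
  }
  hist
}

#' Write per-residue hit values into B-factors
#'
#' Every atom of a residue receives the residue's hit count (or rate);
#' residues absent from the map get 0. Writing the structure out and
#' colouring by B-factor reproduces the blue-to-red hit-rate surface
#' rendering.
#'
#' @param structure A `pepqa_complex`.
#' @param rates Hit-rate tibble from [hit_rates()].
#' @param mode `"count"` or `"rate"`.
#' @return The structure with updated B-factors.
#' @export
annotate_structure <- function(structure, rates, mode = c("count", "rate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(structure, "pepqa_complex"))
  val <- setNames(
    if (mode == "count") as.numeric(rates$hit_count) else rates$hit_rate,
    rates$key
  )
  a <- structure$atoms
  akey <- res_key(a$chain, a$resnum, a$icode)
  a$bfactor <- unname(ifelse(akey %in% names(val), val[akey], 0))
  structure$atoms <- a
  structure
}
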
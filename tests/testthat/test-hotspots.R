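iface_universe <- function(ref = REF) {
  interface_residues(ref)[, c("chain", "resnum", "icode", "resname")]
}

test_that("hotspot flagging is inclusive at the ddG cutoff", {
  tbl <- tibble::tibble(
    model_id = "m1", chain = "A", resnum = 1:4, icode = "",
    wt = "LYS", mut = "ALA", ddg = c(3.17, 0.13, 0.95, 0.9499)
  )
  fl <- flag_hotspots(tbl)
  expect_equal(fl$hotspot, c(TRUE, FALSE, TRUE, FALSE))
  # predicted hotspot values well above and below the cutoff
  expect_true(fl$hotspot[fl$ddg == 3.17])
  expect_false(fl$hotspot[fl$ddg == 0.13])
})

test_that("duplicate records error and missing ddG is skipped with a warning", {
  tbl <- tibble::tibble(
    model_id = "m1", chain = "A", resnum = c(1, 1), icode = "",
    wt = "LYS", mut = "ALA", ddg = c(1, 2)
  )
  expect_error(flag_hotspots(tbl), "duplicate")
  tbl2 <- tibble::tibble(
    model_id = "m1", chain = "A", resnum = 1:3, icode = "",
    wt = "LYS", mut = "ALA", ddg = c(1, NA, 2)
  )
  expect_warning(fl <- flag_hotspots(tbl2), "missing ddG")
  expect_equal(nrow(fl), 2L)
})

test_that("hit rates count per residue with zero-filled universe", {
  uni <- iface_universe()
  planted <- residue_key(uni$chain, uni$resnum, uni$icode)[1:3]
  ens <- make_ddg_ensemble(uni, planted, n_models = 10, noise_sd = 0,
                           seed = 5)
  rates <- hit_rates(flag_hotspots(ens))
  expect_equal(nrow(rates), nrow(uni))
  expect_true(all(rates$n_models == 10))
  expect_equal(rates$hit_count[rates$key %in% planted], rep(10L, 3))
  expect_equal(rates$hit_count[!rates$key %in% planted],
               rep(0L, nrow(uni) - 3))
  expect_equal(rates$hit_rate, rates$hit_count / rates$n_models)
})

test_that("hit counts are conserved and monotone in the cutoff", {
  uni <- iface_universe()
  planted <- residue_key(uni$chain, uni$resnum, uni$icode)[c(2, 5)]
  ens <- make_ddg_ensemble(uni, planted, n_models = 50, noise_sd = 0.8,
                           seed = 9)
  for (cut in c(0.5, 0.95, 1.45)) {
    fl <- flag_hotspots(ens, cutoff = cut)
    rates <- hit_rates(fl)
    expect_equal(sum(rates$hit_count), sum(fl$hotspot))
  }
  counts <- vapply(c(0.5, 0.95, 1.45, 2.0), function(cut) {
    sum(hit_rates(flag_hotspots(ens, cutoff = cut))$hit_count)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("empirical hit rates track the planted normal tail probability", {
  uni <- iface_universe()
  keys <- residue_key(uni$chain, uni$resnum, uni$icode)
  planted <- keys[1:4]
  n_models <- 200
  sd <- 0.5
  ens <- make_ddg_ensemble(uni, planted, n_models = n_models, hot_mean = 2,
                           cold_mean = 0, noise_sd = sd, seed = 13)
  rates <- hit_rates(flag_hotspots(ens, cutoff = 0.95))
  p_hot <- pnorm(0.95, mean = 2, sd = sd, lower.tail = FALSE)
  p_cold <- pnorm(0.95, mean = 0, sd = sd, lower.tail = FALSE)
  for (k in seq_len(nrow(rates))) {
    p <- if (rates$key[k] %in% planted) p_hot else p_cold
    se <- sqrt(p * (1 - p) / n_models)
    expect_lt(abs(rates$hit_rate[k] - p), 3 * se + 1e-9)
  }
})

test_that("recovery histogram matches per-model enumeration and flags baselines", {
  uni <- iface_universe()
  ref_hot <- uni |>
    dplyr::mutate(key = residue_key(chain, resnum, icode),
                  side = ifelse(chain == "A", "receptor", "peptide"),
                  note = "")
  ref_rec <- ref_hot[ref_hot$side == "receptor", ][1:4, ]
  ens <- make_ddg_ensemble(uni, ref_rec$key[1:3], n_models = 40,
                           noise_sd = 0.7, seed = 3)
  fl <- flag_hotspots(ens)
  hist <- recovery_histogram(fl, ref_rec, side = "receptor")
  expect_equal(sum(hist$n_models), 40L)
  expect_equal(hist$n_recovered, 0:4)
  # brute-force per-model intersection
  oracle <- table(factor(vapply(split(fl, fl$model_id), function(g) {
    length(intersect(g$key[g$hotspot], ref_rec$key))
  }, numeric(1)), levels = 0:4))
  expect_equal(hist$n_models, as.integer(oracle))
  # crystal baseline star
  base <- flag_hotspots(make_ddg_ensemble(uni, ref_rec$key, n_models = 1,
                                          noise_sd = 0, seed = 1))
  hist2 <- recovery_histogram(fl, ref_rec, side = "receptor",
                              baseline = base)
  expect_equal(attr(hist2, "baseline_recovered"), 4L)
  expect_error(recovery_histogram(fl, ref_rec[0, ], side = "receptor"),
               "no receptor entries")
})

test_that("zero-noise planted ensembles recover every planted hotspot in every model", {
  uni <- iface_universe()
  keys <- residue_key(uni$chain, uni$resnum, uni$icode)
  planted <- keys[c(1, 4, 7)]
  ens <- make_ddg_ensemble(uni, planted, n_models = 25,
                           hot_mean = 0.95 + 1, cold_mean = 0,
                           noise_sd = 0, seed = 2)
  fl <- flag_hotspots(ens, cutoff = 0.95)
  per_model <- vapply(split(fl, fl$model_id), function(g) {
    setequal(g$key[g$hotspot], planted)
  }, logical(1))
  expect_true(all(per_model))
})

test_that("annotation writes per-residue values into B-factors and round-trips", {
  uni <- iface_universe()
  planted <- residue_key(uni$chain, uni$resnum, uni$icode)[1:2]
  ens <- make_ddg_ensemble(uni, planted, n_models = 7, noise_sd = 0, seed = 4)
  rates <- hit_rates(flag_hotspots(ens))
  ann <- annotate_structure(REF, rates, mode = "count")
  akey <- residue_key(ann$atoms$chain, ann$atoms$resnum, ann$atoms$icode)
  expect_true(all(ann$atoms$bfactor[akey %in% planted] == 7))
  expect_true(all(ann$atoms$bfactor[!akey %in% rates$key] == 0))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ann, f)
  back <- read_structure(f, "A", "B")
  expect_equal(back$atoms$bfactor, ann$atoms$bfactor, tolerance = 0.01)
  # all-zero rates give all-zero B-factors
  zero <- rates
  zero$hit_count <- 0L
  ann0 <- annotate_structure(REF, zero, mode = "count")
  expect_true(all(ann0$atoms$bfactor == 0))
})

test_that("ddg TSV and hotspot reference readers validate their layouts", {
  uni <- iface_universe()
  ens <- make_ddg_ensemble(uni, residue_key(uni$chain, uni$resnum,
                                            uni$icode)[1],
                           n_models = 2, seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ens, f)
  back <- read_ddg(f)
  expect_equal(nrow(back), nrow(ens))
  expect_equal(back$ddg, ens$ddg, tolerance = 1e-9)
  # column mapping for predictor-specific layouts
  alt <- dplyr::rename(ens, dG_change = ddg)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(alt, f2)
  expect_error(read_ddg(f2), "ddg")
  expect_equal(nrow(read_ddg(f2, col_map = c(ddg = "dG_change"))), nrow(ens))
  hot <- tibble::tibble(chain = "A", resnum = 1:2, icode = "",
                        side = "receptor", note = "x")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(hot, f3)
  expect_equal(nrow(read_hotspot_reference(f3)), 2L)
})
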
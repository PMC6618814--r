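test_that("toy complexes are deterministic given the seed", {
  a <- make_toy_complex(seed = 8)
  b <- make_toy_complex(seed = 8)
  expect_identical(a$atoms, b$atoms)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(a, f1)
  write_structure(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  c1 <- make_toy_complex(seed = 9)
  expect_false(identical(a$atoms$resname, c1$atoms$resname))
})

test_that("construction guarantees contacts and hydrogen bonds at the interface", {
  for (s in c(1, 3, 12)) {
    x <- make_toy_complex(seed = s)
    expect_gte(nrow(contacts(x)), 5)
    expect_gte(nrow(detect_interface_hbonds(x)), 1)
    expect_gt(nrow(interface_residues(x)), 0)
  }
})

test_that("generated bond lengths match the ideal internal-coordinate tables", {
  x <- make_toy_complex(seed = 6)
  a <- x$atoms
  a$key <- residue_key(a$chain, a$resnum, a$icode)
  dist_of <- function(g, n1, n2) {
    p <- g[g$atom == n1, c("x", "y", "z")]
    q <- g[g$atom == n2, c("x", "y", "z")]
    sqrt(sum((as.numeric(p) - as.numeric(q))^2))
  }
  for (key in unique(a$key)) {
    g <- a[a$key == key, ]
    expect_equal(dist_of(g, "N", "CA"), 1.458, tolerance = 0.05)
    expect_equal(dist_of(g, "CA", "C"), 1.525, tolerance = 0.05)
    expect_equal(dist_of(g, "C", "O"), 1.231, tolerance = 0.05)
    if ("CB" %in% g$atom) {
      expect_equal(dist_of(g, "CA", "CB"), 1.530, tolerance = 0.05)
    }
    # every side-chain atom placed by the Z-matrix sits at its ideal
    # bond length from its parent
    for (zr in pepqa:::SIDECHAIN_ZMAT[[g$resname[1]]] %||% list()) {
      if (all(c(zr$c, zr$atom) %in% g$atom)) {
        expect_equal(dist_of(g, zr$c, zr$atom), zr$bond, tolerance = 0.05)
      }
    }
  }
  # peptide bonds between consecutive residues within a strand
  for (ch in c("A", "B")) {
    g <- a[a$chain == ch, ]
    for (r in setdiff(unique(g$resnum), max(g$resnum))) {
      c_at <- g[g$resnum == r & g$atom == "C", ]
      n_at <- g[g$resnum == r + 1 & g$atom == "N", ]
      if (nrow(c_at) == 1 && nrow(n_at) == 1) {
        d <- sqrt((c_at$x - n_at$x)^2 + (c_at$y - n_at$y)^2 +
                    (c_at$z - n_at$z)^2)
        # the groove receptor has one deliberate chain break
        if (d < 5) expect_equal(d, 1.329, tolerance = 0.05)
      }
    }
  }
})

test_that("rigid perturbations hit the requested displacement exactly", {
  model <- perturb(REF, "rigid", translation = c(1.5, -2, 0))[[1]]
  map <- build_correspondence(REF, model)
  expect_equal(ligand_rmsd(REF, model, map), 2.5, tolerance = 1e-9)
  # receptor untouched
  rec_sel <- REF$atoms$chain == "A"
  expect_identical(model$atoms[rec_sel, c("x", "y", "z")],
                   REF$atoms[rec_sel, c("x", "y", "z")])
  # magnitude form draws a random direction but keeps |t|
  ms <- perturb(REF, "rigid", translation = 3.0, n_models = 4, seed = 21)
  for (m in ms) {
    expect_equal(ligand_rmsd(REF, m, build_correspondence(REF, m)), 3.0,
                 tolerance = 1e-9)
  }
  # rotation-only matches the independent per-atom displacement RMSD
  mr <- perturb(REF, "rigid",
                rotation = list(axis = c(0, 1, 0), angle = 25))[[1]]
  pep_sel <- REF$atoms$chain == "B" & REF$atoms$atom %in%
    c("N", "CA", "C", "O")
  direct <- sqrt(mean(rowSums(
    (as.matrix(mr$atoms[pep_sel, c("x", "y", "z")]) -
       as.matrix(REF$atoms[pep_sel, c("x", "y", "z")]))^2
  )))
  expect_equal(ligand_rmsd(REF, mr, build_correspondence(REF, mr)), direct,
               tolerance = 1e-9)
})

test_that("side-chain perturbation leaves the backbone untouched and is seeded", {
  m0 <- perturb(REF, "sidechain", chi_noise_deg = 0)[[1]]
  expect_identical(m0$atoms, REF$atoms)
  m1 <- perturb(REF, "sidechain", chi_noise_deg = 30, seed = 11)[[1]]
  m2 <- perturb(REF, "sidechain", chi_noise_deg = 30, seed = 11)[[1]]
  expect_identical(m1$atoms, m2$atoms)
  bb <- REF$atoms$atom %in% c("N", "CA", "C", "O")
  expect_identical(m1$atoms[bb, c("x", "y", "z")],
                   REF$atoms[bb, c("x", "y", "z")])
  expect_false(identical(m1$atoms[!bb, c("x", "y", "z")],
                         REF$atoms[!bb, c("x", "y", "z")]))
  # chi rotations preserve bond lengths: same-residue pair distances to
  # the rotation-axis atoms are unchanged for a spot-checked lysine
  res <- residue_table(REF)
  lys <- res[res$resname == "LYS", ][1, ]
  sel <- REF$atoms$chain == lys$chain & REF$atoms$resnum == lys$resnum
  d0 <- dist(as.matrix(REF$atoms[sel, c("x", "y", "z")]))
  d1 <- dist(as.matrix(m1$atoms[sel, c("x", "y", "z")]))
  expect_equal(sort(round(as.numeric(d0)[1:10], 6)),
               sort(round(as.numeric(d1)[1:10], 6)),
               tolerance = 0.2)
})

test_that("a rigid-magnitude ladder degrades the CAPRI class monotonically", {
  mags <- c(0.2, 3.0, 9.0)
  cls <- vapply(mags, function(mag) {
    m <- perturb(REF, "rigid", translation = c(mag, 0, 0))[[1]]
    as.character(classify_capri(compute_metrics(REF, m))$class)
  }, character(1))
  ranks <- match(cls, c("Incorrect", "Acceptable", "Medium", "High"))
  expect_true(all(diff(ranks) <= 0))
  expect_equal(cls[1], "High")
  expect_equal(cls[3], "Incorrect")
})

test_that("ddg ensembles are seeded and separate hot from cold at zero noise", {
  uni <- residue_table(REF)[, c("chain", "resnum", "icode", "resname")]
  keys <- residue_key(uni$chain, uni$resnum, uni$icode)
  e1 <- make_ddg_ensemble(uni, keys[1:2], n_models = 5, seed = 3)
  e2 <- make_ddg_ensemble(uni, keys[1:2], n_models = 5, seed = 3)
  expect_identical(e1, e2)
  e0 <- make_ddg_ensemble(uni, keys[1:2], n_models = 3, hot_mean = 2,
                          cold_mean = 0, noise_sd = 0, seed = 1)
  expect_setequal(unique(e0$ddg), c(0, 2))
  expect_error(make_ddg_ensemble(uni, keys[1], hot_mean = 0, cold_mean = 1),
               "hot_mean")
  expect_error(make_ddg_ensemble(uni, "Z:99:", n_models = 2), "subset")
})

test_that("batch assessment marks corrupt models FAILED without killing the batch", {
  good <- perturb(REF, "rigid", translation = 0.4, n_models = 2, seed = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(good[[1]], f)
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("garbage, not a pdb", bad)
  res <- suppressWarnings(
    assess_models(REF, c(ok = f, broken = bad),
                  receptor_chains = "A", peptide_chains = "B")
  )
  expect_equal(res$status, c("OK", "FAILED"))
  expect_equal(as.character(res$class[1]), "High")
  expect_true(is.na(res$fnat[2]))
})
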
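test_that("kabsch recovers exact rigid motions and forbids reflections", {
  withr::with_seed(3, {
    x <- matrix(rnorm(30, sd = 3), 10, 3)
  })
  fit0 <- kabsch(x, x)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  rot <- pepqa:::rotation_about_axis(c(0, 0, 1), 90)
  y <- sweep(x %*% t(rot), 2, c(1, 2, 3), "+")
  fit <- kabsch(x, y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_transform(x, fit), y, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # mirrored target: best proper rotation, never a reflection
  ym <- x
  ym[, 1] <- -ym[, 1]
  fitm <- kabsch(x, ym)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-9)
  expect_gt(fitm$rmsd, 0)
})

test_that("kabsch rmsd matches the quaternion closed form on noisy clouds", {
  withr::with_seed(21, {
    for (i in 1:5) {
      x <- matrix(rnorm(30, sd = 3), 10, 3)
      tr <- random_transform()
      y <- sweep(x %*% t(tr$rotation), 2, tr$translation, "+") +
        matrix(rnorm(30, sd = 0.3), 10, 3)
      expect_equal(kabsch(x, y)$rmsd, horn_rmsd(x, y), tolerance = 1e-6)
    }
  })
})

test_that("kabsch rmsd is minimal over random rigid transforms", {
  withr::with_seed(5, {
    x <- matrix(rnorm(24, sd = 2), 8, 3)
    y <- x + matrix(rnorm(24, sd = 0.5), 8, 3)
    opt <- kabsch(x, y)$rmsd
    for (i in 1:20) {
      tr <- random_transform()
      alt <- sqrt(sum((sweep(x %*% t(tr$rotation), 2, tr$translation, "+") -
                         y)^2) / nrow(x))
      expect_gte(alt, opt - 1e-9)
    }
  })
})

test_that("kabsch validates input and warns on degenerate sets", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  expect_error(kabsch(matrix(0, 4, 3), matrix(0, 3, 3)), "equal size")
  line <- cbind(1:5, 0, 0)
  expect_warning(kabsch(line, line), "collinear")
})

test_that("ligand RMSD equals the applied displacement for pure peptide translation", {
  map <- build_correspondence(REF, REF)
  expect_equal(ligand_rmsd(REF, REF, map), 0)
  for (t_vec in list(c(2.5, 0, 0), c(1, -2, 2))) {
    model <- perturb(REF, "rigid", translation = t_vec)[[1]]
    expect_equal(ligand_rmsd(REF, model, map), sqrt(sum(t_vec^2)),
                 tolerance = 1e-9)
  }
})

test_that("ligand RMSD matches an explicit two-step fit-then-sum oracle", {
  model <- perturb(REF, "rigid", translation = c(1, 0.5, -0.3),
                   rotation = list(axis = c(0, 0, 1), angle = 20))[[1]]
  map <- build_correspondence(REF, model)
  got <- ligand_rmsd(REF, model, map)
  # oracle: superpose receptor backbones explicitly, then direct sum
  ap <- map$atom_pairs[map$atom_pairs$region == "backbone", ]
  rec <- ap[ap$side == "receptor", ]
  pep <- ap[ap$side == "peptide", ]
  cm <- function(x, idx) as.matrix(x$atoms[idx, c("x", "y", "z")])
  fit <- kabsch(cm(model, rec$mod_idx), cm(REF, rec$ref_idx))
  moved <- apply_transform(cm(model, pep$mod_idx), fit)
  oracle <- sqrt(mean(rowSums((moved - cm(REF, pep$ref_idx))^2)))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_gt(got, 0)
})

test_that("I-RMSD is zero and S-RMSD positive under chi-only perturbation", {
  model <- perturb(REF, "sidechain", chi_noise_deg = 25, seed = 9)[[1]]
  map <- build_correspondence(REF, model)
  expect_equal(interface_rmsd(REF, model, map, "backbone"), 0,
               tolerance = 1e-9)
  s <- interface_rmsd(REF, model, map, "sidechain")
  expect_gt(s, 0)
  # direct per-atom deviation oracle in the identity frame (backbone
  # untouched, so the interface-backbone fit is the identity)
  iface <- interface_residues(REF)
  ap <- map$atom_pairs[map$atom_pairs$region == "sidechain" &
                         map$atom_pairs$ref_key %in% iface$key, ]
  r <- as.matrix(REF$atoms[ap$ref_idx, c("x", "y", "z")])
  m <- as.matrix(model$atoms[ap$mod_idx, c("x", "y", "z")])
  dev <- pepqa:::sidechain_squared_dev(ap, r, m, REF)
  expect_equal(s, sqrt(dev$total / dev$n), tolerance = 1e-9)
})

test_that("symmetry-equivalent side-chain naming does not inflate S-RMSD", {
  # flipping a symmetric group (Glu carboxylate swap via chi3 + 180)
  # changes atom names but not the physical structure
  res <- residue_table(REF)
  glu <- res[res$resname == "GLU" & res$side == "peptide", ]
  expect_gt(nrow(glu), 0)  # seed-1 fixture has peptide glutamates
  model <- REF
  a <- model$atoms
  sel <- which(a$chain == glu$chain[1] & a$resnum == glu$resnum[1] &
                 a$atom %in% c("OE1", "OE2"))
  a[sel, c("x", "y", "z")] <- a[rev(sel), c("x", "y", "z")]
  model$atoms <- a
  map <- build_correspondence(REF, model)
  expect_equal(interface_rmsd(REF, model, map, "sidechain"), 0,
               tolerance = 1e-9)
  expect_equal(interface_rmsd(REF, model, map, "backbone"), 0,
               tolerance = 1e-9)
})

test_that("aromatic ring flip by 180 degrees gives S-RMSD 0 via symmetry swap", {
  ref <- make_toy_complex(peptide_seq = c("ALA", "PHE", "SER", "LYS", "GLY",
                                          "ASP"),
                          seed = 4)
  model <- ref
  a <- model$atoms
  sel_res <- a$chain == "B" & a$resnum == 2
  cb <- which(sel_res & a$atom == "CB")
  cg <- which(sel_res & a$atom == "CG")
  axis <- c(a$x[cg] - a$x[cb], a$y[cg] - a$y[cb], a$z[cg] - a$z[cb])
  rot <- pepqa:::rotation_about_axis(axis, 180)
  ring <- which(sel_res & a$atom %in% c("CD1", "CD2", "CE1", "CE2", "CZ"))
  pivot <- c(a$x[cg], a$y[cg], a$z[cg])
  xyz <- sweep(sweep(as.matrix(a[ring, c("x", "y", "z")]), 2, pivot) %*%
                 t(rot), 2, pivot, "+")
  a[ring, c("x", "y", "z")] <- xyz
  model$atoms <- a
  map <- build_correspondence(ref, model)
  expect_equal(interface_rmsd(ref, model, map, "sidechain"), 0,
               tolerance = 1e-6)
})

test_that("all RMSDs are invariant under a global rigid transform of the model", {
  model <- perturb(REF, "mixed", translation = c(0.8, 0.4, 0),
                   chi_noise_deg = 15, seed = 13)[[1]]
  map <- build_correspondence(REF, model)
  base <- c(
    l = ligand_rmsd(REF, model, map),
    i = interface_rmsd(REF, model, map, "backbone"),
    s = interface_rmsd(REF, model, map, "sidechain")
  )
  withr::with_seed(17, {
    for (k in 1:3) {
      moved <- move_complex(model, random_transform())
      map2 <- build_correspondence(REF, moved)
      expect_equal(ligand_rmsd(REF, moved, map2), base[["l"]],
                   tolerance = 1e-6)
      expect_equal(interface_rmsd(REF, moved, map2, "backbone"),
                   base[["i"]], tolerance = 1e-6)
      expect_equal(interface_rmsd(REF, moved, map2, "sidechain"),
                   base[["s"]], tolerance = 1e-6)
    }
  })
})

test_that("an interface with no paired side-chain atoms yields NA S-RMSD with a warning", {
  # model stripped to backbone: every side-chain atom is unpaired
  model <- REF
  model$atoms <- model$atoms[model$atoms$atom %in% c("N", "CA", "C", "O"), ]
  map <- build_correspondence(REF, model)
  expect_warning(s <- interface_rmsd(REF, model, map, "sidechain"),
                 "no paired interface side-chain atoms")
  expect_true(is.na(s))
  expect_equal(interface_rmsd(REF, model, map, "backbone"), 0,
               tolerance = 1e-9)
})
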
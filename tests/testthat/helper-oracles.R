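# Shared fixtures and independent oracles. Oracles deliberately use a
# different algorithmic route than the implementation they check.

toy_ref <- function(seed = 1, ...) make_toy_complex(seed = seed, ...)

# cached default reference so the suite builds it once
REF <- toy_ref()

atom_row <- function(chain, resnum, resname, atom, x, y, z, icode = "",
                     occ = 1, bfactor = 0) {
  tibble::tibble(
    chain = chain, resnum = resnum, icode = icode, resname = resname,
    atom = atom, element = substr(gsub("^[0-9]+", "", atom), 1, 1),
    x = x, y = y, z = z, occ = occ, bfactor = bfactor
  )
}

# Brute-force residue-contact scan: explicit loops over residue pairs
# and their atom pairs.
contacts_oracle <- function(structure, cutoff = 4.0) {
  a <- structure$atoms[!structure$atoms$is_hydrogen, ]
  a$key <- residue_key(a$chain, a$resnum, a$icode)
  rec_keys <- unique(a$key[a$side == "receptor"])
  pep_keys <- unique(a$key[a$side == "peptide"])
  out <- character(0)
  for (rk in rec_keys) {
    ra <- a[a$key == rk, c("x", "y", "z")]
    for (pk in pep_keys) {
      pa <- a[a$key == pk, c("x", "y", "z")]
      hit <- FALSE
      for (i in seq_len(nrow(ra))) {
        for (j in seq_len(nrow(pa))) {
          d <- sqrt(sum((as.numeric(ra[i, ]) - as.numeric(pa[j, ]))^2))
          if (d < cutoff) hit <- TRUE
        }
      }
      if (hit) out <- c(out, paste(rk, pk))
    }
  }
  sort(out)
}

clashes_oracle <- function(structure, cutoff = 3.0) {
  a <- structure$atoms[!structure$atoms$is_hydrogen, ]
  rec <- a[a$side == "receptor", c("x", "y", "z")]
  pep <- a[a$side == "peptide", c("x", "y", "z")]
  n <- 0L
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(pep))) {
      if (sqrt(sum((as.numeric(rec[i, ]) - as.numeric(pep[j, ]))^2)) < cutoff) {
        n <- n + 1L
      }
    }
  }
  n
}

# Horn's closed-form quaternion solution for the optimal superposition
# RMSD (largest eigenvalue of the 4x4 key matrix) -- an algorithm
# independent of the SVD route used by kabsch().
horn_rmsd <- function(mobile, target) {
  p <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  q <- sweep(as.matrix(target), 2, colMeans(target))
  s <- crossprod(p, q)
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  sq <- (sum(p^2) + sum(q^2) - 2 * lam) / nrow(p)
  sqrt(max(sq, 0))
}

# Independent H-bond oracle: loops over every donor x acceptor pair and
# re-applies the geometric criteria with its own small vector helpers.
hbond_oracle <- function(structure, d_da_max = 3.9, d_ha_max = 2.5,
                         min_angle = 90, salt_bridge_max = 4.0) {
  ang <- function(a, b, c) {
    u <- a - b
    v <- c - b
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  a <- structure$atoms
  a$key <- residue_key(a$chain, a$resnum, a$icode)
  heavy <- a[!a$is_hydrogen, ]
  xyz_of <- function(key, atom) {
    r <- heavy[heavy$key == key & heavy$atom == atom, ]
    if (nrow(r) == 0) return(NULL)
    c(r$x[1], r$y[1], r$z[1])
  }
  charged <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                  HIS = c("ND1", "NE2"))
  carboxy <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  found <- character(0)
  res <- unique(heavy[, c("key", "resname", "side")])
  for (i in seq_len(nrow(res))) {
    tab_d <- suppressWarnings(donors_acceptors(res$resname[i]))$donors
    for (da in tab_d$atom) {
      dpos <- xyz_of(res$key[i], da)
      if (is.null(dpos)) next
      hmat <- pepqa:::donor_hydrogens(
        heavy[heavy$key == res$key[i] & heavy$atom == da, ],
        heavy[heavy$key == res$key[i], ],
        {
          rrow <- heavy[heavy$key == res$key[i], ][1, ]
          pc <- heavy[heavy$chain == rrow$chain &
                        heavy$resnum == rrow$resnum - 1 &
                        heavy$atom == "C" & heavy$icode == "", ]
          if (nrow(pc) == 0) NULL else c(pc$x[1], pc$y[1], pc$z[1])
        },
        a[a$is_hydrogen & a$key == res$key[i], ]
      )
      for (j in seq_len(nrow(res))) {
        if (res$side[j] == res$side[i]) next
        tab_a <- suppressWarnings(donors_acceptors(res$resname[j]))$acceptors
        for (k in seq_len(nrow(tab_a))) {
          apos <- xyz_of(res$key[j], tab_a$atom[k])
          if (is.null(apos)) next
          dda <- sqrt(sum((dpos - apos)^2))
          antpos <- xyz_of(res$key[j], tab_a$antecedent[k])
          ant_ok <- is.null(antpos) || ang(dpos, apos, antpos) > min_angle
          is_salt <- da %in% (charged[[res$resname[i]]] %||% "") &&
            tab_a$atom[k] %in% (carboxy[[res$resname[j]]] %||% "") &&
            dda < salt_bridge_max
          ok <- FALSE
          if (is_salt && ant_ok) {
            ok <- TRUE
          } else if (dda < d_da_max && ant_ok) {
            if (is.null(hmat)) {
              ok <- TRUE
            } else {
              for (hi in seq_len(nrow(hmat))) {
                h <- hmat[hi, ]
                if (sqrt(sum((h - apos)^2)) < d_ha_max &&
                    ang(dpos, h, apos) > min_angle) ok <- TRUE
              }
            }
          }
          if (ok) {
            found <- c(found, paste(res$key[i], da, res$key[j], tab_a$atom[k]))
          }
        }
      }
    }
  }
  sort(unique(found))
}

hb_ids <- function(hb) {
  sort(paste(hb$don_key, hb$don_atom, hb$acc_key, hb$acc_atom))
}

contact_ids <- function(con) sort(paste(con$rec_key, con$pep_key))

# Spearman rho from the explicit rank formula (Pearson on ranks).
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

random_transform <- function() {
  ax <- rnorm(3)
  list(
    rotation = pepqa:::rotation_about_axis(ax / sqrt(sum(ax^2)),
                                           runif(1, 10, 170)),
    translation = rnorm(3, sd = 5)
  )
}

# Apply a global rigid transform to a whole complex.
move_complex <- function(x, tr) {
  pepqa:::transform_structure(x, tr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
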
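# CAPRI peptide quality classification and the S-RMSD-augmented
# refined scheme. Clause boundaries follow the printed criteria: fnat
# intervals are lower-inclusive with the better class winning at shared
# boundaries (0.8 is High-eligible, 0.5 Medium-eligible, 0.2
# Acceptable-eligible); RMSD thresholds are inclusive (<=).

CLASS_LEVELS <- c("Incorrect", "Acceptable", "Medium", "High")

capri_clauses <- function(fnat, l, i, loosen = 0) {
  list(
    High = list(
      high = fnat >= 0.8 & (l <= 1.0 + loosen | i <= 0.5 + loosen)
    ),
    Medium = list(
      medium_1 = fnat >= 0.5 & fnat < 0.8 &
        (l <= 2.0 + loosen | i <= 1.0 + loosen),
      medium_2 = fnat >= 0.8 & l > 1.0 + loosen & i > 0.5 + loosen
    ),
    Acceptable = list(
      acceptable_1 = fnat >= 0.2 & fnat < 0.5 &
        (l <= 4.0 + loosen | i <= 2.0 + loosen),
      acceptable_2 = fnat >= 0.5 & l > 2.0 + loosen & i > 1.0 + loosen
    )
  )
}

eval_clauses <- function(fnat, l, i, loosen = 0, class_gate = NULL) {
  n <- length(fnat)
  label <- rep("Incorrect", n)
  rule <- rep("incorrect_rest", n)
  cl <- capri_clauses(fnat, l, i, loosen)
  for (class in c("High", "Medium", "Acceptable")) {
    gate <- if (is.null(class_gate)) rep(TRUE, n) else class_gate[[class]]
    for (rule_name in names(cl[[class]])) {
      hit <- label == "Incorrect" & cl[[class]][[rule_name]] & gate
      label[hit] <- class
      rule[hit] <- rule_name
    }
  }
  list(label = label, rule = rule)
}

#' CAPRI quality classification
#'
#' Assigns each model one of High / Medium / Acceptable / Incorrect from
#' its fnat, L-RMSD and I-RMSD, evaluating clauses best-class-first and
#' recording which clause fired.
#'
#' @param metrics A data frame with numeric columns `fnat`, `l_rmsd`,
#'   `i_rmsd` (one row per model). A [compute_metrics()] /
#'   [assess_models()] result works directly.
#' @return `metrics` with columns `class` (ordered factor, Incorrect <
#'   Acceptable < Medium < High) and `rule` (the clause that fired)
#'   appended.
#' @examples
#' classify_capri(data.frame(fnat = 0.83, l_rmsd = 0.39, i_rmsd = 0.35))
#' @export
classify_capri <- function(metrics) {
  metrics <- as_tibble(metrics)
  need <- c("fnat", "l_rmsd", "i_rmsd")
  if (!all(need %in% names(metrics))) {
    abort("`metrics` needs columns fnat, l_rmsd, i_rmsd")
  }
  if (anyNA(metrics[need])) {
    abort("fnat, l_rmsd and i_rmsd must be defined (non-NA) for classification")
  }
  res <- eval_clauses(metrics$fnat, metrics$l_rmsd, metrics$i_rmsd)
  metrics$class <- factor(res$label, levels = CLASS_LEVELS, ordered = TRUE)
  metrics$rule <- res$rule
  metrics
}

#' Parameters of the refined (S-RMSD-capped) scheme
#'
#' The refined scheme loosens the L-/I-RMSD thresholds of every class by
#' a fixed amount while awarding a class only when S-RMSD stays under a
#' per-class cap. The defaults here are this package's placeholders, not
#' published values: the scheme is proposed parametrically and its
#' calibration is left open pending larger assessment sets.
#'
#' @param backbone_loosening Angstrom added to every L- and I-RMSD
#'   threshold (default 0.5).
#' @param s_rmsd_caps Named numeric vector of per-class maximum S-RMSD
#'   in Angstrom, names `High`, `Medium`, `Acceptable` (defaults 0.5,
#'   1.0, 2.0).
#' @return An object of class `pepqa_scheme`.
#' @export
refined_scheme <- function(backbone_loosening = 0.5,
                           s_rmsd_caps = c(High = 0.5, Medium = 1.0,
                                           Acceptable = 2.0)) {
  if (backbone_loosening < 0) abort("backbone_loosening must be >= 0")
  if (!all(c("High", "Medium", "Acceptable") %in% names(s_rmsd_caps))) {
    abort("s_rmsd_caps needs entries High, Medium, Acceptable")
  }
  if (any(s_rmsd_caps <= 0)) abort("s_rmsd_caps must be > 0")
  structure(
    list(backbone_loosening = backbone_loosening,
         s_rmsd_caps = s_rmsd_caps[c("High", "Medium", "Acceptable")]),
    class = "pepqa_scheme"
  )
}

#' Refined classification with loosened backbone and capped S-RMSD
#'
#' Re-evaluates the CAPRI clauses with each class's L-/I-RMSD thresholds
#' increased by the scheme's loosening, awarding a class only if S-RMSD
#' is at or under that class's cap, and never demoting a model below its
#' plain CAPRI class. Rows with `s_rmsd` `NA` keep their CAPRI class.
#'
#' @inheritParams classify_capri
#' @param metrics As in [classify_capri()], plus a numeric `s_rmsd`
#'   column (`NA` allowed).
#' @param scheme A `pepqa_scheme` from [refined_scheme()].
#' @return `metrics` with `class`, `rule` (CAPRI) and `class_refined`,
#'   `rule_refined` appended.
#' @export
classify_refined <- function(metrics, scheme = refined_scheme()) {
  stopifnot(inherits(scheme, "pepqa_scheme"))
  metrics <- classify_capri(metrics)
  s <- if ("s_rmsd" %in% names(metrics)) metrics$s_rmsd else
    rep(NA_real_, nrow(metrics))
  gate <- lapply(
    setNames(nm = c("High", "Medium", "Acceptable")),
    function(cl) !is.na(s) & s <= scheme$s_rmsd_caps[[cl]]
  )
  ref <- eval_clauses(metrics$fnat, metrics$l_rmsd, metrics$i_rmsd,
                      loosen = scheme$backbone_loosening, class_gate = gate)
  ref_class <- factor(ref$label, levels = CLASS_LEVELS, ordered = TRUE)
  keep_capri <- is.na(s) | ref_class < metrics$class
  metrics$class_refined <- dplyr::if_else(keep_capri, metrics$class, ref_class)
  metrics$rule_refined <- ifelse(keep_capri, paste0("capri:", metrics$rule),
                                 ref$rule)
  metrics
}

#' Pairwise Spearman correlations between quality metrics
#'
#' Rank correlations (with p-values) between fnat, fnat_hb and the three
#' RMSD measures over a set of models, with pairwise deletion of
#' undefined values. Pairs with fewer than 3 complete observations give
#' `NA`.
#'
#' @param metrics A data frame of per-model metrics (at least 3 rows);
#'   columns among `vars` that exist are used.
#' @param vars Metric columns to correlate.
#' @return An object of class `pepqa_cor` with matrices `rho`, `p`, `n`.
#'   Use [tidy()] for a long tibble or [autoplot()] for a tile plot.
#' @export
metric_correlations <- function(metrics,
                                vars = c("fnat", "fnat_hb", "l_rmsd",
                                         "i_rmsd", "s_rmsd")) {
  metrics <- as_tibble(metrics)
  vars <- intersect(vars, names(metrics))
  if (length(vars) < 2) abort("need at least two metric columns")
  if (nrow(metrics) < 3) abort("need at least 3 models")
  k <- length(vars)
  rho <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1
  diag(p) <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      x <- metrics[[vars[i]]]
      y <- metrics[[vars[j]]]
      ok <- is.finite(x) & is.finite(y)
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) >= 3) {
        ct <- suppressWarnings(
          cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
        )
        rho[i, j] <- rho[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  diag(n) <- nrow(metrics)
  structure(list(rho = rho, p = p, n = n), class = "pepqa_cor")
}

#' @export
print.pepqa_cor <- function(x, digits = 3, ...) {
  cat("Spearman rank correlations between quality metrics\n")
  print(round(x$rho, digits))
  invisible(x)
}

#' @rdname metric_correlations
#' @param x A `pepqa_cor` object.
#' @param ... Unused.
#' @export
tidy.pepqa_cor <- function(x, ...) {
  vars <- rownames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble(
    metric_x = vars[idx[, 1]],
    metric_y = vars[idx[, 2]],
    rho = x$rho[idx],
    p_value = x$p[idx],
    n = as.integer(x$n[idx])
  )
}

#' @rdname metric_correlations
#' @export
glance.pepqa_cor <- function(x, ...) {
  td <- tidy(x)
  tibble(
    n_metrics = nrow(x$rho),
    n_pairs = nrow(td),
    n_models = max(td$n, na.rm = TRUE),
    min_rho = min(td$rho, na.rm = TRUE),
    max_rho = max(td$rho, na.rm = TRUE)
  )
}
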
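#' Best-classifier proteins separating two MoA groups
#'
#' For every protein, scores how well a single-threshold rule on that
#' protein's signal separates the two groups, by leave-one-out accuracy:
#' for each held-out MoA the threshold and orientation are refitted on the
#' remaining MoAs (maximizing training accuracy, deterministic tie-break on
#' the smaller threshold, `+1` orientation first) and the held-out MoA is
#' classified. Both orientations are part of the rule search; a LOO
#' accuracy below chance (possible for uninformative proteins) is reported
#' as 0.5, so accuracies lie in `[0.5, 1]`.
#' Optionally protein *pairs* are scored with the best axis-aligned
#' two-threshold conjunction (resubstitution accuracy; quadratic cost).
#'
#' A protein whose pooled values are constant carries no information and
#' gets accuracy 0.5 by convention.
#'
#' @param groupA,groupB numeric signal matrices (rows = MoAs, columns =
#'   proteins, same columns), each with >= 2 rows.
#' @param top_n how many candidates to keep (default 200).
#' @param include_pairs also score protein pairs (default `FALSE`).
#' @param n_thresholds_pairs per-axis threshold grid size for pairs.
#' @return data.frame ranked by decreasing accuracy (ties by protein id):
#'   `proteins` (id, or `"p1+p2"`), `accuracy`, `threshold`, `orientation`
#'   (`+1` predicts group A above threshold), `kind` (`single`/`pair`).
#' @export
best_classifiers <- function(groupA, groupB, top_n = 200L,
                             include_pairs = FALSE,
                             n_thresholds_pairs = 8L) {
  groupA <- as_cloud(groupA, "groupA"); groupB <- as_cloud(groupB, "groupB")
  if (nrow(groupA) < 2L || nrow(groupB) < 2L) {
    stop_("both groups need at least 2 MoAs")
  }
  if (!identical(colnames(groupA), colnames(groupB))) {
    stop_("groups must share the same protein columns")
  }
  prots <- colnames(groupA) %||% paste0("V", seq_len(ncol(groupA)))
  y <- c(rep(1L, nrow(groupA)), rep(0L, nrow(groupB)))
  res <- lapply(seq_along(prots), function(j) {
    v <- c(groupA[, j], groupB[, j])
    st <- stump_loo(v, y)
    data.frame(proteins = prots[j], accuracy = st$accuracy,
               threshold = st$threshold, orientation = st$orientation,
               kind = "single", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (include_pairs) {
    pair_res <- list()
    for (j in seq_len(length(prots) - 1L)) {
      for (k in seq(j + 1L, length(prots))) {
        v1 <- c(groupA[, j], groupB[, j])
        v2 <- c(groupA[, k], groupB[, k])
        pr <- pair_rule(v1, v2, y, n_thresholds_pairs)
        pair_res[[length(pair_res) + 1L]] <- data.frame(
          proteins = paste0(prots[j], "+", prots[k]),
          accuracy = pr$accuracy, threshold = NA_real_,
          orientation = NA_real_, kind = "pair",
          stringsAsFactors = FALSE)
      }
    }
    res <- rbind(res, do.call(rbind, pair_res))
  }
  res <- res[order(-res$accuracy, res$proteins), , drop = FALSE]
  rownames(res) <- NULL
  head(res, top_n)
}

# Fit the optimal single-threshold stump on one training fold.
# Orientation o = +1 predicts class 1 (group A) when v > t; o = -1 when
# v < t. Candidate thresholds are the midpoints of consecutive sorted
# unique training values plus outer sentinels; ties resolve to the first
# rule in threshold-major order (ascending threshold, +1 before -1).
stump_fit <- function(vt, yt) {
  u <- sort(unique(vt))
  thr <- if (length(u) == 1L) c(u - 1, u + 1) else {
    c(u[1L] - 1, (u[-1L] + u[-length(u)]) / 2, u[length(u)] + 1)
  }
  nT <- length(thr)
  pred_hi <- outer(vt, thr, ">")
  corr_hi <- pred_hi == (yt == 1L)
  corr_lo <- (!pred_hi) == (yt == 1L)           # v < t; ties at t cannot
                                                # occur at midpoints
  order_tm <- as.vector(rbind(seq_len(nT), nT + seq_len(nT)))
  tot <- c(colSums(corr_hi), colSums(corr_lo))[order_tm]
  best <- order_tm[which.max(tot)]
  o <- if (best <= nT) 1 else -1
  list(orientation = o, threshold = thr[(best - 1L) %% nT + 1L])
}

# Leave-one-out accuracy of the optimal stump: for each held-out MoA the
# rule (grid and all) is refitted on the remaining MoAs and the held-out
# MoA classified by it. Orientation is part of the rule search; a LOO
# accuracy below chance means the protein carries no generalizable signal
# and is reported as 0.5, keeping accuracies in [0.5, 1].
stump_loo <- function(v, y) {
  if (length(unique(v)) == 1L) {
    return(list(accuracy = 0.5, threshold = v[1L], orientation = 1))
  }
  n <- length(v)
  hits <- 0L
  for (i in seq_len(n)) {
    r <- stump_fit(v[-i], y[-i])
    pred <- r$orientation * v[i] > r$orientation * r$threshold
    if (pred == (y[i] == 1L)) hits <- hits + 1L
  }
  acc <- hits / n
  full <- stump_fit(v, y)
  list(accuracy = max(acc, 0.5), threshold = full$threshold,
       orientation = full$orientation)
}

# Best axis-aligned two-threshold conjunction on a coarse quantile grid;
# resubstitution accuracy, flipped to [0.5, 1].
pair_rule <- function(v1, v2, y, n_thresholds) {
  grid <- function(v) {
    u <- sort(unique(v))
    if (length(u) == 1L) return(u)
    q <- stats::quantile(v, probs = seq(0, 1, length.out = n_thresholds))
    sort(unique(c(u[1L] - 1, q)))
  }
  t1s <- grid(v1); t2s <- grid(v2)
  best <- 0.5
  for (o1 in c(1, -1)) for (o2 in c(1, -1)) {
    for (t1 in t1s) for (t2 in t2s) {
      pred <- (o1 * v1 > o1 * t1) & (o2 * v2 > o2 * t2)
      acc <- mean(pred == (y == 1L))
      acc <- max(acc, 1 - acc)
      if (acc > best) best <- acc
    }
  }
  list(accuracy = best)
}

#' Mann-Whitney U test between two signal distributions
#'
#' Two-sided test, exact when both samples have at most 8 values and the
#' pooled sample is tie-free, otherwise the normal approximation with tie
#' correction (no continuity correction, so identical samples give p = 1).
#'
#' @param a,b numeric vectors (each non-empty).
#' @return list with `U` (the Mann-Whitney statistic for `a`) and `p`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop_("empty group")
  if (length(unique(c(a, b))) == 1L) {
    # a single pooled value: the tie-corrected variance is 0 and the
    # distributions are trivially identical
    return(list(U = length(a) * length(b) / 2, p = 1))
  }
  exact <- length(a) <= 8L && length(b) <= 8L &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Multiplicity adjustment of p-values
#'
#' @param ps numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (Benjamini-Hochberg, default), `"bonferroni"` or
#'   `"none"`.
#' @return adjusted p-values, same order as the input.
#' @export
adjust_pvalues <- function(ps, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  if (any(!is.finite(ps)) || any(ps < 0 | ps > 1)) {
    stop_("p-values must lie in [0, 1]")
  }
  stats::p.adjust(ps, method = method)
}

#' Differential test of candidate proteins between two MoA groups
#'
#' For each candidate protein: group means, Mann-Whitney p-value and its
#' multiplicity adjustment. Feed the result to [differential_filter()] to
#' apply the significance and opposite-sign rules.
#'
#' @param groupA,groupB numeric signal matrices sharing columns.
#' @param candidates character vector of proteins to test (default: all
#'   columns; typically the [best_classifiers()] single-protein hits).
#' @param adjust method passed to [adjust_pvalues()].
#' @return data.frame: `protein`, `mean_A`, `mean_B`, `strength`
#'   (`|mean_A * mean_B|`), `U`, `p_raw`, `p_adjusted`.
#' @export
differential_test <- function(groupA, groupB, candidates = NULL,
                              adjust = "BH") {
  groupA <- as_cloud(groupA, "groupA"); groupB <- as_cloud(groupB, "groupB")
  candidates <- candidates %||% colnames(groupA)
  missing_p <- setdiff(candidates, colnames(groupA))
  if (length(missing_p)) {
    stop_("candidate(s) not in signal matrix: ",
          paste(head(missing_p, 5L), collapse = ", "))
  }
  rows <- lapply(candidates, function(p) {
    mw <- mann_whitney(groupA[, p], groupB[, p])
    data.frame(protein = p,
               mean_A = mean(groupA[, p]), mean_B = mean(groupB[, p]),
               U = mw$U, p_raw = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_pvalues(out$p_raw, adjust)
  out$strength <- abs(out$mean_A * out$mean_B)
  out[, c("protein", "mean_A", "mean_B", "strength", "U",
          "p_raw", "p_adjusted")]
}

#' Differential biomarker filter: significance plus opposite-sign means
#'
#' Keeps candidates whose adjusted p-value is below `alpha` *and* whose
#' group means have strictly opposite signs (a zero mean fails), and
#' partitions them into proteins active in group A / inactive in group B
#' (`"A_active"`) and the reverse (`"A_inactive"`).
#'
#' @param records data.frame with columns `protein`, `mean_A`, `mean_B`,
#'   `p_adjusted` (e.g. from [differential_test()]).
#' @param alpha significance level on adjusted p-values (default 0.01).
#' @return the kept subset with an added `direction` column.
#' @export
differential_filter <- function(records, alpha = 0.01) {
  need <- c("protein", "mean_A", "mean_B", "p_adjusted")
  if (!all(need %in% names(records))) {
    stop_("records need columns: ", paste(need, collapse = ", "))
  }
  keep <- records$p_adjusted < alpha &
    sign(records$mean_A) != 0 &
    sign(records$mean_A) == -sign(records$mean_B)
  out <- records[keep, , drop = FALSE]
  out$direction <- ifelse(out$mean_A > 0, "A_active", "A_inactive")
  rownames(out) <- NULL
  out
}

#' Table-style biomarker report
#'
#' Sorts records by signal strength (default `|mean_A * mean_B|`,
#' recomputed if absent) and annotates each protein with the phenotypes for
#' which it was a best-classifier protein.
#'
#' @param records filtered records from [differential_filter()].
#' @param bcp_sets named list of character vectors: per phenotype, the
#'   best-classifier proteins (e.g. `list(HF = ..., MD = ...)`).
#' @return data.frame sorted by decreasing `strength` with a `bcp` column
#'   (`"-"` when the protein classifies no phenotype).
#' @export
biomarker_report <- function(records, bcp_sets = list()) {
  out <- records
  if (is.null(out$strength)) out$strength <- abs(out$mean_A * out$mean_B)
  if (nrow(out)) {
    out$bcp <- vapply(out$protein, function(p) {
      hit <- names(bcp_sets)[vapply(bcp_sets, function(s) p %in% s, TRUE)]
      if (length(hit)) paste(hit, collapse = "&") else "-"
    }, "")
    out <- out[order(-out$strength, out$protein), , drop = FALSE]
  } else {
    out$bcp <- character(0)
  }
  rownames(out) <- NULL
  out
}

#' Published biomarker reference table
#'
#' The 30 candidate biomarker proteins reported for sacubitril/valsartan
#' prototype-patient models: proteins with opposite mean signal between the
#' MoAs that respond well for heart failure while inducing low vs high
#' macular-degeneration effector signal. Columns: UniProt accession, gene
#' symbol, protein name, the two group means (`mean_LMD`, `mean_HMD`), the
#' published signal-strength column (`strength_printed`, carried verbatim
#' and not recomputable from the printed means), the adjusted p-value, the
#' best-classifier membership (`bcp`: `MD`, `HF&MD` or `-`) and whether the
#' protein was also recovered by the published network-proximity analysis
#' (`in_proximity_set`).
#'
#' @return data.frame of 30 rows.
#' @export
reference_biomarkers <- function() {
  path <- system.file("extdata", "sacubitril_valsartan_biomarkers.tsv",
                      package = "netmoa", mustWork = TRUE)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  df$in_proximity_set <- as.logical(df$in_proximity_set)
  df
}
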
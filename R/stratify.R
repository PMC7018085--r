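#' TSignal: average signal arriving at a phenotype's effectors
#'
#' The intensity measure used to rank mechanisms: the state-weighted mean
#' signal over the phenotype's effector proteins,
#' `P = mean(state_e * signal_e)`. `P = 1` means every effector exactly
#' reproduces its phenotype state (the phenotype is fully induced);
#' `P = -1` means every effector is exactly reverted.
#'
#' @param moa an `moa` object (or anything with a `$signals` vector).
#' @param effectors an [effector_set()].
#' @return a value in `[-1, 1]`.
#' @export
tsignal <- function(moa, effectors) {
  tsignal_signals(moa$signals, effectors)
}

tsignal_signals <- function(signals, effectors) {
  stopifnot(inherits(effectors, "effector_set"))
  if (length(effectors$states) == 0L) stop_("empty effector set")
  absent <- setdiff(names(effectors$states), names(signals))
  if (length(absent)) {
    stop_("effector(s) missing from signals: ",
          paste(head(absent, 5L), collapse = ", "))
  }
  mean(effectors$states * signals[names(effectors$states)])
}

#' Quartile stratification of a MoA ensemble by response intensity
#'
#' MoAs are ranked by response intensity for the phenotype and the extreme
#' quartiles are labelled. Intensity is the TSignal projection `P`
#' oriented by role: for an indication the drug should *revert* the
#' effector states, so intensity is `-P` and the strongest responders are
#' the "Low"-disease group (low disease-effector signal); for an adverse
#' event intensity is `+P` and the strongest responders are the
#' "High"-adverse-event group. The top `floor(K/4)` MoAs get that label,
#' the bottom `floor(K/4)` the opposite label, the rest are `"Mid"`. Ties
#' are broken by MoA seed (ascending); a warning is emitted when ties cross
#' a quartile boundary.
#'
#' @param object a `netmoa` fit or `moa_ensemble`.
#' @param effectors an [effector_set()] (its `role` sets the orientation).
#' @param quartile fraction in each extreme group (default 0.25).
#' @return object of class `moa_groups`: list with `phenotype`, `role`,
#'   `labels` (named character over MoA ids), `intensity`, `tsignal`
#'   (named numeric, the unoriented projection `P`), `moa_ids`.
#' @export
stratify_ensemble <- function(object, effectors, quartile = 0.25) {
  moas <- if (inherits(object, "netmoa")) object$ensemble$moas
          else if (inherits(object, "moa_ensemble")) object$moas
          else stop_("expected a netmoa fit or moa_ensemble")
  stopifnot(inherits(effectors, "effector_set"))
  K <- length(moas)
  if (K < 4L) stop_("need an ensemble of at least 4 MoAs")
  ids <- vapply(moas, function(m) paste0("moa_", m$seed), "")
  seeds <- vapply(moas, function(m) m$seed, 0L)
  P <- vapply(moas, tsignal, 0, effectors = effectors)
  names(P) <- ids
  orient <- if (effectors$role == "indication") -1 else 1
  intensity <- orient * P
  g <- floor(K * quartile)
  ord <- order(-intensity, seeds)
  if (any(duplicated(intensity)) &&
      (intensity[ord[g]] == intensity[ord[g + 1L]] ||
       intensity[ord[K - g + 1L]] == intensity[ord[K - g]])) {
    warning("tied intensities at a quartile boundary; groups filled in ",
            "seed order", call. = FALSE)
  }
  top_label <- if (effectors$role == "indication") "Low" else "High"
  bottom_label <- if (top_label == "Low") "High" else "Low"
  labels <- rep("Mid", K)
  names(labels) <- ids
  labels[ids[ord[seq_len(g)]]] <- top_label
  labels[ids[ord[seq(K - g + 1L, K)]]] <- bottom_label
  structure(list(phenotype = effectors$name, role = effectors$role,
                 labels = labels, intensity = stats::setNames(intensity, ids),
                 tsignal = P, moa_ids = ids),
            class = "moa_groups")
}

#' @export
print.moa_groups <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("Low", "Mid", "High")))
  cat(sprintf("Stratification of %d MoAs by '%s' (%s):\n",
              length(x$labels), x$phenotype, x$role))
  cat(sprintf("  Low %d / Mid %d / High %d; TSignal range %.3f..%.3f\n",
              tab["Low"], tab["Mid"], tab["High"],
              min(x$tsignal), max(x$tsignal)))
  invisible(x)
}

#' MoA ids carrying a given label
#'
#' @param groups a [stratify_ensemble()] result.
#' @param label `"Low"`, `"Mid"` or `"High"`.
#' @return character vector of MoA ids.
#' @export
group_members <- function(groups, label) {
  stopifnot(inherits(groups, "moa_groups"))
  label <- match.arg(label, c("Low", "Mid", "High"))
  names(groups$labels)[groups$labels == label]
}

#' Intersect two stratification groups of the same ensemble
#'
#' E.g. the MoAs that respond strongly for the indication *and* strongly
#' induce the adverse event. The two stratifications must come from the
#' same ensemble; the intersection may be empty.
#'
#' @param groupsA,groupsB [stratify_ensemble()] results over one ensemble.
#' @param labelA,labelB which label to take from each.
#' @return character vector of MoA ids in both groups.
#' @export
intersect_groups <- function(groupsA, groupsB, labelA, labelB) {
  stopifnot(inherits(groupsA, "moa_groups"), inherits(groupsB, "moa_groups"))
  if (!identical(sort(groupsA$moa_ids), sort(groupsB$moa_ids))) {
    stop_("stratifications come from different ensembles")
  }
  intersect(group_members(groupsA, labelA), group_members(groupsB, labelB))
}

#' Per-MoA stratification table
#'
#' @param ... named [stratify_ensemble()] results over one ensemble.
#' @return data.frame with one row per MoA: id, then `<name>_tsignal`,
#'   `<name>_intensity`, `<name>_label` per stratification.
#' @export
stratification_table <- function(...) {
  gs <- list(...)
  stopifnot(length(gs) >= 1L, all(vapply(gs, inherits, TRUE, "moa_groups")))
  if (is.null(names(gs)) || any(names(gs) == "")) {
    names(gs) <- vapply(gs, function(g) g$phenotype, "")
  }
  ids <- gs[[1L]]$moa_ids
  out <- data.frame(moa = ids, stringsAsFactors = FALSE)
  for (nm in names(gs)) {
    g <- gs[[nm]]
    out[[paste0(nm, "_tsignal")]] <- unname(g$tsignal[ids])
    out[[paste0(nm, "_intensity")]] <- unname(g$intensity[ids])
    out[[paste0(nm, "_label")]] <- unname(g$labels[ids])
  }
  out
}
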
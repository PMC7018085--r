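#' Network-proximity scores by random walk with restart
#'
#' A generic proximity scorer (an RWR stand-in for service-based guilt-by-
#' association tools, not a re-implementation of any of them): a random
#' walk on the *unweighted, undirected* skeleton of the network restarts
#' with probability `restart_prob` at one of the seed proteins (uniformly).
#' Scores are the stationary visiting probabilities and sum to 1. Dangling
#' (degree-zero) nodes hand their mass back to the restart distribution, so
#' an isolated seed keeps restart mass only (with a warning).
#'
#' @param network a [signed_network()].
#' @param seeds character vector of seed proteins (non-empty, in network).
#' @param restart_prob restart probability (default 0.15).
#' @param tol convergence tolerance on the L1 change (default 1e-12).
#' @param max_iterations iteration cap (default 10000).
#' @return object of class `proximity_result`: list with `scores` (named,
#'   sums to 1), `seeds`, `restart_prob`.
#' @export
propagate_seeds <- function(network, seeds, restart_prob = 0.15,
                            tol = 1e-12, max_iterations = 10000L) {
  stopifnot(inherits(network, "signed_network"))
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop_("seeds must be non-empty")
  absent <- setdiff(seeds, network$nodes)
  if (length(absent)) {
    stop_("seed(s) not in network: ", paste(head(absent, 5L), collapse = ", "))
  }
  if (restart_prob <= 0 || restart_prob > 1) {
    stop_("restart_prob must be in (0, 1]")
  }
  nodes <- network$nodes
  n <- length(nodes)
  # undirected unweighted skeleton as an adjacency list
  i <- match(network$edges$source, nodes)
  j <- match(network$edges$target, nodes)
  deg <- tabulate(c(i, j), nbins = n)
  isolated <- intersect(seeds, nodes[deg == 0L])
  if (length(isolated)) {
    warning("seed(s) with no edges keep restart mass only: ",
            paste(isolated, collapse = ", "), call. = FALSE)
  }
  e <- numeric(n)
  e[match(seeds, nodes)] <- 1 / length(seeds)
  s <- e
  r <- restart_prob
  from <- c(i, j)
  to <- c(j, i)
  for (it in seq_len(max_iterations)) {
    out_mass <- ifelse(deg > 0L, s / deg, 0)
    walked <- numeric(n)
    acc <- tapply(out_mass[from], to, sum)
    walked[as.integer(names(acc))] <- acc
    dangling <- sum(s[deg == 0L])
    s_new <- (1 - r) * (walked + dangling * e) + r * e
    if (sum(abs(s_new - s)) < tol) {
      s <- s_new
      break
    }
    s <- s_new
  }
  names(s) <- nodes
  structure(list(scores = s, seeds = seeds, restart_prob = r),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("RWR proximity: %d nodes, %d seeds, restart %.2f\n",
              length(x$scores), length(x$seeds), x$restart_prob))
  top <- head(sort(x$scores, decreasing = TRUE), 5L)
  cat("  top:", paste(sprintf("%s=%.4f", names(top), top), collapse = ", "),
      "\n")
  invisible(x)
}

#' Top-scoring fraction of proximity-ranked proteins
#'
#' The `ceiling(fraction * n_nodes)` highest-scoring proteins; score ties
#' are broken by protein id (ascending). Seeds are always retained even
#' when the cut would drop them (a message reports how many were rescued).
#'
#' @param result a [propagate_seeds()] result.
#' @param fraction fraction of nodes to keep, in (0, 1] (default 0.02).
#' @return character vector of protein ids.
#' @export
top_fraction <- function(result, fraction = 0.02) {
  stopifnot(inherits(result, "proximity_result"))
  if (fraction <= 0 || fraction > 1) stop_("fraction must be in (0, 1]")
  n_keep <- ceiling(fraction * length(result$scores))
  ord <- order(-result$scores, names(result$scores))
  kept <- names(result$scores)[ord[seq_len(n_keep)]]
  rescued <- setdiff(result$seeds, kept)
  if (length(rescued)) {
    message("retaining ", length(rescued),
            " seed(s) below the score cut: ",
            paste(rescued, collapse = ", "))
    kept <- union(kept, rescued)
  }
  kept
}

#' Overlap of biomarkers with merged top-proximity sets
#'
#' Unions the given top sets (e.g. top-drug, top-indication,
#' top-adverse-event), intersects with the biomarker list, and reports the
#' hypergeometric enrichment p-value of the overlap against the network
#' background.
#'
#' @param biomarkers character vector of proteins.
#' @param top_sets list of character vectors (top-fraction sets).
#' @param background character vector, normally all network nodes.
#' @return list: `union_set`, `overlap`, `count`, `p` (upper-tail
#'   hypergeometric, P(X >= count)).
#' @export
overlap_report <- function(biomarkers, top_sets, background) {
  stopifnot(is.list(top_sets))
  background <- unique(background)
  biomarkers <- unique(intersect(biomarkers, background))
  u <- unique(intersect(unlist(top_sets), background))
  ov <- intersect(biomarkers, u)
  # P(X >= |overlap|) drawing |biomarkers| from background with |union|
  # marked
  p <- stats::phyper(length(ov) - 1L, length(u),
                     length(background) - length(u),
                     length(biomarkers), lower.tail = FALSE)
  list(union_set = sort(u), overlap = sort(ov), count = length(ov), p = p)
}
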
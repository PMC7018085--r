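#' Propagation control parameters
#'
#' The network is cyclic in general, so the perceptron-like evaluation is run
#' as a damped synchronous fixed-point iteration
#' `x <- (1 - damping) * tanh(W x) + damping * x`, with stimulus nodes
#' clamped at their +/-1 values. On an acyclic graph this reduces to layered
#' feed-forward evaluation.
#'
#' @param max_iterations maximum sweeps (default 200).
#' @param convergence_tol stop when the largest per-node change falls below
#'   this (default 1e-6).
#' @param damping damping factor in `[0, 1)` (default 0.5).
#' @return list of class `propagation_params`.
#' @export
propagation_params <- function(max_iterations = 200L,
                               convergence_tol = 1e-6,
                               damping = 0.5) {
  stopifnot(max_iterations >= 1L, convergence_tol > 0,
            damping >= 0, damping < 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 damping = damping),
            class = "propagation_params")
}

#' Propagate a clamped stimulus through the weighted network
#'
#' Each node receives the sum of `weight * signal` over its incoming edges
#' and responds with the hyperbolic tangent of that sum; the result is the
#' node's output signal towards its outgoing edges. Stimulus nodes are
#' clamped at their +/-1 states throughout. Nodes unreachable from the
#' stimulus keep signal 0 ("neutral").
#'
#' @param network a [signed_network()] whose weights are set.
#' @param stim a [stimulus()].
#' @param params a [propagation_params()].
#' @return named numeric vector of signals in `[-1, 1]` over all nodes, with
#'   attributes `converged` (logical) and `iterations` (integer).
#' @examples
#' net <- signed_network(data.frame(source = c("S", "A"),
#'                                  target = c("A", "B"),
#'                                  sign = 1, weight = 1))
#' sig <- propagate(net, stimulus(c(S = 1), net))
#' all.equal(unname(sig["A"]), tanh(1))
#' @export
propagate <- function(network, stim, params = propagation_params()) {
  stopifnot(inherits(network, "signed_network"), inherits(stim, "stimulus"))
  if (any(!is.finite(network$edges$weight))) {
    stop_("non-finite edge weight; set weights before propagating")
  }
  nodes <- network$nodes
  x <- numeric(length(nodes))
  names(x) <- nodes
  clamp <- match(names(stim), nodes)
  x[clamp] <- as.numeric(stim)
  src <- match(network$edges$source, nodes)
  dst <- match(network$edges$target, nodes)
  w <- network$edges$weight
  free <- setdiff(seq_along(nodes), clamp)
  d <- params$damping
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(params$max_iterations)) {
    inp <- numeric(length(nodes))
    contrib <- w * x[src]
    # rowsum-style accumulation of incoming contributions
    acc <- tapply(contrib, dst, sum)
    inp[as.integer(names(acc))] <- acc
    x_new <- x
    x_new[free] <- (1 - d) * tanh(inp[free]) + d * x[free]
    delta <- max(abs(x_new - x))
    x <- x_new
    if (delta < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  attr(x, "converged") <- converged
  attr(x, "iterations") <- iter
  x
}

#' Fraction of restrictions a signal vector satisfies
#'
#' A restriction `(p, s)` is satisfied when the propagated signal at `p` has
#' the required sign `s` and magnitude at least `min_magnitude` (a signal
#' closer to 0 than that is considered neutral, satisfying nothing).
#'
#' @param signals named numeric signal vector (as returned by [propagate()]).
#' @param restrictions a [restriction_set()].
#' @param min_magnitude minimal |signal| to count as active/inactive
#'   (default 0.05).
#' @return fraction in `[0, 1]` of satisfied restrictions.
#' @export
restriction_accuracy <- function(signals, restrictions,
                                 min_magnitude = 0.05) {
  stopifnot(inherits(restrictions, "restriction_set"))
  if (nrow(restrictions) == 0L) stop_("restrictions must be non-empty")
  absent <- setdiff(restrictions$protein, names(signals))
  if (length(absent)) {
    stop_("restriction on unknown protein: ",
          paste(head(absent, 5L), collapse = ", "))
  }
  s <- signals[restrictions$protein]
  ok <- (sign(s) == restrictions$state) & (abs(s) >= min_magnitude)
  sum(ok) / length(ok)
}
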
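#' Simulated-annealing schedule
#'
#' Controls the stochastic weight fit. One uniformly chosen edge weight is
#' perturbed per step by a Gaussian of sd `move_scale` (clipped to the
#' edge's allowed interval); moves are accepted by the Metropolis rule on
#' the objective (satisfied-restriction count, with a continuous tie-break
#' on restriction-aligned signal). Temperature is multiplied by
#' `cooling_factor` after every `steps_per_temperature` steps.
#'
#' @param initial_temperature starting temperature, in objective units
#'   (one restriction = 1); default 1.
#' @param cooling_factor geometric cooling in (0, 1); default 0.9.
#' @param steps_per_temperature moves per temperature; default 100.
#' @param n_temperatures number of temperature stages; default 60.
#' @param move_scale sd of the Gaussian weight perturbation; default 0.25.
#' @return list of class `anneal_schedule`.
#' @export
anneal_schedule <- function(initial_temperature = 1,
                            cooling_factor = 0.9,
                            steps_per_temperature = 100L,
                            n_temperatures = 60L,
                            move_scale = 0.25) {
  stopifnot(initial_temperature > 0, cooling_factor > 0, cooling_factor < 1,
            steps_per_temperature >= 0L, n_temperatures >= 1L,
            move_scale > 0)
  structure(list(initial_temperature = initial_temperature,
                 cooling_factor = cooling_factor,
                 steps_per_temperature = as.integer(steps_per_temperature),
                 n_temperatures = as.integer(n_temperatures),
                 move_scale = move_scale),
            class = "anneal_schedule")
}

weight_bounds <- function(network, free_sign = FALSE) {
  sg <- network$edges$sign
  if (free_sign) {
    list(lo = rep(-1, length(sg)), hi = rep(1, length(sg)))
  } else {
    list(lo = ifelse(sg > 0, 0, -1), hi = ifelse(sg > 0, 1, 0))
  }
}

#' Fit edge weights for one mechanism of action
#'
#' Runs one simulated-annealing search for edge weights under which the
#' propagated stimulus satisfies as many restrictions as possible. Weights
#' are initialized uniformly on each edge's allowed interval (the sign's
#' half-interval unless `free_sign`), and the best-so-far solution is
#' returned, deterministic given `seed`.
#'
#' @param network a [signed_network()].
#' @param stim a [stimulus()].
#' @param restrictions a [restriction_set()].
#' @param schedule an [anneal_schedule()].
#' @param params a [propagation_params()].
#' @param seed integer RNG seed for this run.
#' @param min_magnitude minimal |signal| counting as active/inactive.
#' @param free_sign allow fitted weights to contradict the curated edge
#'   sign (full interval `[-1, 1]`); default `FALSE`.
#' @return an object of class `moa`: list with `signals` (named vector over
#'   all nodes), `weights` (numeric, one per edge), `accuracy`, `seed`,
#'   `trace` (best objective per temperature) and `converged`.
#' @export
anneal_weights <- function(network, stim, restrictions,
                           schedule = anneal_schedule(),
                           params = propagation_params(),
                           seed = 1L, min_magnitude = 0.05,
                           free_sign = FALSE) {
  stopifnot(inherits(network, "signed_network"), inherits(stim, "stimulus"),
            inherits(restrictions, "restriction_set"),
            inherits(schedule, "anneal_schedule"),
            inherits(params, "propagation_params"))
  if (nrow(restrictions) == 0L) stop_("restrictions must be non-empty")
  nodes <- network$nodes
  ei <- edge_index(network)
  b <- weight_bounds(network, free_sign)
  clamp_idx <- match(names(stim), nodes) - 1L
  restr_idx <- match(restrictions$protein, nodes)
  if (anyNA(restr_idx)) stop_("restriction on protein absent from network")
  fit <- cpp_anneal(
    n = length(nodes), src = ei$src, dst = ei$dst,
    lo = b$lo, hi = b$hi,
    clamp_idx = clamp_idx, clamp_val = as.numeric(stim),
    restr_idx = restr_idx - 1L, restr_state = restrictions$state,
    min_mag = min_magnitude,
    t0 = schedule$initial_temperature, cooling = schedule$cooling_factor,
    steps_per_t = schedule$steps_per_temperature,
    n_temps = schedule$n_temperatures, move_scale = schedule$move_scale,
    max_iter = params$max_iterations, tol = params$convergence_tol,
    damping = params$damping, seed = as.integer(seed) %% 2147483647L
  )
  signals <- fit$signals
  names(signals) <- nodes
  structure(list(signals = signals, weights = fit$weights,
                 accuracy = fit$accuracy, seed = as.integer(seed),
                 trace = fit$trace, converged = fit$converged),
            class = "moa")
}

#' @export
print.moa <- function(x, ...) {
  cat(sprintf("MoA (seed %d): accuracy %.3f over %d proteins\n",
              x$seed, x$accuracy, length(x$signals)))
  invisible(x)
}

#' Sample an ensemble of mechanisms of action
#'
#' Runs `n_runs` independent annealing fits with seeds
#' `base_seed, base_seed + 1, ..., base_seed + n_runs - 1`. Runs share no
#' state, so the result is identical regardless of execution order.
#'
#' @inheritParams anneal_weights
#' @param n_runs number of independent fits (>= 1).
#' @param base_seed seed of the first run.
#' @return list of [anneal_weights()] `moa` objects, in seed order.
#' @export
sample_ensemble <- function(network, stim, restrictions, n_runs,
                            schedule = anneal_schedule(),
                            params = propagation_params(),
                            base_seed = 1L, min_magnitude = 0.05,
                            free_sign = FALSE) {
  stopifnot(n_runs >= 1L)
  lapply(seq_len(n_runs) - 1L, function(k) {
    anneal_weights(network, stim, restrictions, schedule, params,
                   seed = base_seed + k, min_magnitude = min_magnitude,
                   free_sign = free_sign)
  })
}

#' Select the top-K mechanisms by accuracy
#'
#' Keeps MoAs with accuracy at least `min_accuracy`, sorts by accuracy
#' (decreasing, ties by seed increasing) and truncates to the `K` best —
#' the published selection rule is the 200 MoAs satisfying the largest
#' number of restrictions, and at least 80% of them.
#'
#' @param moas list of `moa` objects.
#' @param K ensemble size to keep (>= 4 so quartile groups are non-empty).
#' @param min_accuracy minimal accuracy to be eligible (default 0.8).
#' @param allow_fewer keep a smaller ensemble instead of erroring when
#'   fewer than `K` MoAs qualify.
#' @return list with class `moa_ensemble`: `moas` (the kept list), and
#'   selection metadata `K`, `min_accuracy`, `n_sampled`.
#' @export
select_top <- function(moas, K = 200L, min_accuracy = 0.8,
                       allow_fewer = FALSE) {
  stopifnot(K >= 4L)
  acc <- vapply(moas, function(m) m$accuracy, 0)
  seeds <- vapply(moas, function(m) m$seed, 0L)
  keep <- which(acc >= min_accuracy)
  if (length(keep) == 0L) {
    stop_("no MoA reached accuracy ", min_accuracy,
          "; lengthen the annealing schedule or relax the threshold")
  }
  if (length(keep) < K && !allow_fewer) {
    stop_("only ", length(keep), " MoAs reached accuracy ", min_accuracy,
          " (need K = ", K, "); increase n_runs or set allow_fewer = TRUE")
  }
  ord <- keep[order(-acc[keep], seeds[keep])]
  ord <- head(ord, K)
  structure(list(moas = moas[ord], K = as.integer(K),
                 min_accuracy = min_accuracy,
                 n_sampled = length(moas)),
            class = "moa_ensemble")
}
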
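#' Fit an ensemble model of drug mechanisms of action
#'
#' The main fitting function. The drug stimulus (target proteins clamped at
#' +1/-1) is propagated through the signed network with tanh node
#' responses; edge weights are fitted by simulated annealing so the
#' propagated signals reproduce the required active/inactive restriction
#' states; `n_runs` independent fits are sampled and the `K` most accurate
#' (at least `min_accuracy`) form the ensemble. Each retained solution is
#' one candidate mechanism of action — under the prototype-patient reading,
#' one hypothetical patient whose cells all follow that mechanism.
#'
#' @inheritParams anneal_weights
#' @param n_runs number of independent annealing runs (default 250).
#' @param K ensemble size kept after selection (default 200).
#' @param min_accuracy minimal restriction accuracy to keep a run
#'   (default 0.8).
#' @param base_seed seed of the first run; run `k` uses `base_seed + k - 1`.
#' @param allow_fewer see [select_top()].
#' @return An object of class `netmoa`: a list with `ensemble`
#'   (a `moa_ensemble`), `network`, `stimulus`, `restrictions`,
#'   `min_magnitude`, `schedule`, `params`, `base_seed`, `n_runs` and
#'   `call`. Methods are provided for `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `simulate` and `plot`.
#' @examples
#' inst <- plant_instance(generate_network(60, seed = 1), seed = 1,
#'                        n_eff_ind = 5, n_eff_adv = 5)
#' fit <- netmoa(inst$network, inst$stimulus, inst$restrictions,
#'               n_runs = 8, K = 4, allow_fewer = TRUE,
#'               schedule = anneal_schedule(n_temperatures = 20,
#'                                          steps_per_temperature = 40))
#' summary(fit)
#' @export
netmoa <- function(network, stim, restrictions,
                   n_runs = 250L, K = 200L, min_accuracy = 0.8,
                   schedule = anneal_schedule(),
                   params = propagation_params(),
                   base_seed = 1L, min_magnitude = 0.05,
                   free_sign = FALSE, allow_fewer = FALSE) {
  moas <- sample_ensemble(network, stim, restrictions, n_runs,
                          schedule, params, base_seed,
                          min_magnitude, free_sign)
  ens <- select_top(moas, K = K, min_accuracy = min_accuracy,
                    allow_fewer = allow_fewer)
  structure(list(ensemble = ens, network = network, stimulus = stim,
                 restrictions = restrictions,
                 min_magnitude = min_magnitude, schedule = schedule,
                 params = params, base_seed = as.integer(base_seed),
                 n_runs = as.integer(n_runs), call = match.call()),
            class = "netmoa")
}

#' Signal matrix of a fitted ensemble
#'
#' @param object a `netmoa` fit or a `moa_ensemble`.
#' @return numeric matrix, rows = MoAs (named `moa_<seed>`), columns =
#'   proteins in network node order.
#' @export
signal_matrix <- function(object) {
  moas <- if (inherits(object, "netmoa")) object$ensemble$moas
          else if (inherits(object, "moa_ensemble")) object$moas
          else stop_("expected a netmoa fit or moa_ensemble")
  m <- do.call(rbind, lapply(moas, function(x) x$signals))
  rownames(m) <- vapply(moas, function(x) paste0("moa_", x$seed), "")
  m
}

#' Per-MoA accuracies of a fitted ensemble
#' @inheritParams signal_matrix
#' @return named numeric vector of restriction accuracies.
#' @export
accuracies <- function(object) {
  moas <- if (inherits(object, "netmoa")) object$ensemble$moas
          else object$moas
  a <- vapply(moas, function(x) x$accuracy, 0)
  names(a) <- vapply(moas, function(x) paste0("moa_", x$seed), "")
  a
}

#' @export
print.netmoa <- function(x, ...) {
  ens <- x$ensemble
  cat("Mechanism-of-action ensemble fit\n")
  cat(sprintf("  network: %d proteins, %d edges\n",
              n_nodes(x$network), n_edges(x$network)))
  cat(sprintf("  stimulus: %s\n",
              paste(sprintf("%s(%+d)", names(x$stimulus),
                            as.integer(x$stimulus)), collapse = ", ")))
  cat(sprintf("  restrictions: %d; kept %d/%d runs with accuracy >= %.2f\n",
              nrow(x$restrictions), length(ens$moas), ens$n_sampled,
              ens$min_accuracy))
  acc <- accuracies(x)
  cat(sprintf("  accuracy: min %.3f, median %.3f, max %.3f\n",
              min(acc), stats::median(acc), max(acc)))
  invisible(x)
}

#' Summarize a fitted MoA ensemble
#'
#' @param object a `netmoa` fit.
#' @param effectors optional list of [effector_set()]s; TSignal summaries
#'   are added for each.
#' @param ... unused.
#' @return object of class `summary.netmoa`.
#' @export
summary.netmoa <- function(object, effectors = NULL, ...) {
  acc <- accuracies(object)
  ts <- NULL
  if (!is.null(effectors)) {
    if (inherits(effectors, "effector_set")) effectors <- list(effectors)
    ts <- lapply(effectors, function(e) {
      v <- vapply(object$ensemble$moas, tsignal, 0, effectors = e)
      c(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v))
    })
    names(ts) <- vapply(effectors, function(e) e$name, "")
  }
  structure(list(n_kept = length(acc), n_sampled = object$ensemble$n_sampled,
                 K = object$ensemble$K,
                 min_accuracy = object$ensemble$min_accuracy,
                 accuracy = summary(acc), tsignal = ts),
            class = "summary.netmoa")
}

#' @export
print.summary.netmoa <- function(x, ...) {
  cat(sprintf("MoA ensemble: kept %d of %d runs (K = %d, accuracy >= %.2f)\n",
              x$n_kept, x$n_sampled, x$K, x$min_accuracy))
  cat("Restriction accuracy:\n")
  print(x$accuracy)
  if (!is.null(x$tsignal)) {
    for (nm in names(x$tsignal)) {
      v <- x$tsignal[[nm]]
      cat(sprintf("TSignal[%s]: mean %.3f (sd %.3f, range %.3f..%.3f)\n",
                  nm, v["mean"], v["sd"], v["min"], v["max"]))
    }
  }
  invisible(x)
}

#' Fitted edge weights
#'
#' @param object a `netmoa` fit.
#' @param ... unused.
#' @return numeric matrix, rows = MoAs, columns = edges
#'   (named `source->target`).
#' @export
coef.netmoa <- function(object, ...) {
  w <- do.call(rbind, lapply(object$ensemble$moas, function(m) m$weights))
  rownames(w) <- vapply(object$ensemble$moas,
                        function(m) paste0("moa_", m$seed), "")
  colnames(w) <- paste0(object$network$edges$source, "->",
                        object$network$edges$target)
  w
}

#' Propagated signals under the fitted weights
#'
#' With no new stimulus this returns the fitted signal matrix. With
#' `newstimulus`, each MoA's fitted weights are re-propagated under the new
#' clamped inputs — the in-silico analogue of giving the same prototype
#' patients a different drug.
#'
#' @param object a `netmoa` fit.
#' @param newstimulus optional [stimulus()] on the same network.
#' @param type `"signals"` (matrix) or `"tsignal"` (per-MoA average signal
#'   arriving at `effectors`).
#' @param effectors an [effector_set()], required for `type = "tsignal"`.
#' @param ... unused.
#' @return matrix of signals, or named vector of TSignal values.
#' @export
predict.netmoa <- function(object, newstimulus = NULL,
                           type = c("signals", "tsignal"),
                           effectors = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newstimulus)) {
    sm <- signal_matrix(object)
  } else {
    stopifnot(inherits(newstimulus, "stimulus"))
    sm <- do.call(rbind, lapply(object$ensemble$moas, function(m) {
      propagate(set_weights(object$network, m$weights), newstimulus,
                object$params)
    }))
    rownames(sm) <- rownames(signal_matrix(object))
  }
  if (type == "signals") return(sm)
  if (is.null(effectors)) stop_("type = 'tsignal' needs `effectors`")
  apply(sm, 1L, function(s) tsignal_signals(s, effectors))
}

#' Restriction residuals of the fitted ensemble
#'
#' Residual of MoA `m` at restricted protein `p` is
#' `state_p - signal_mp`: 0 when the protein reaches its required +/-1
#' state exactly, sign-opposed values up to magnitude 2 when it ends on the
#' wrong side.
#'
#' @param object a `netmoa` fit.
#' @param ... unused.
#' @return numeric matrix, rows = MoAs, columns = restricted proteins.
#' @export
residuals.netmoa <- function(object, ...) {
  sm <- signal_matrix(object)[, object$restrictions$protein, drop = FALSE]
  sweep(-sm, 2L, object$restrictions$state, "+")
}

#' Sample additional mechanisms from a fitted model
#'
#' Draws `nsim` further independent annealing runs under the stored data,
#' schedule and parameters, continuing the fit's seed sequence (run `k` of
#' the simulation uses seed `base_seed + n_runs + k - 1` unless `seed` is
#' given).
#'
#' @param object a `netmoa` fit.
#' @param nsim number of additional runs.
#' @param seed optional integer overriding the continued seed sequence.
#' @param ... unused.
#' @return list of `moa` objects.
#' @export
simulate.netmoa <- function(object, nsim = 1, seed = NULL, ...) {
  start <- if (is.null(seed)) object$base_seed + object$n_runs
           else as.integer(seed)
  sample_ensemble(object$network, object$stimulus, object$restrictions,
                  n_runs = nsim, schedule = object$schedule,
                  params = object$params, base_seed = start,
                  min_magnitude = object$min_magnitude)
}

#' Plot a fitted MoA ensemble
#'
#' Classical-MDS map of the ensemble's signal vectors (one point per MoA),
#' optionally coloured by stratification labels.
#'
#' @param x a `netmoa` fit.
#' @param groups optional [stratify_ensemble()] result used to colour
#'   points.
#' @param ... passed to [graphics::plot()].
#' @return the 2-D coordinates, invisibly.
#' @export
plot.netmoa <- function(x, groups = NULL, ...) {
  sm <- signal_matrix(x)
  xy <- mds_embed(sm, dims = 2L)
  col <- "grey30"
  pch <- 19L
  if (!is.null(groups)) {
    lab <- groups$labels[rownames(xy)]
    pal <- c(Low = "#2166AC", Mid = "grey60", High = "#B2182B")
    col <- pal[lab]
    pch <- c(Low = 19L, Mid = 1L, High = 17L)[lab]
  }
  graphics::plot(xy[, 1L], xy[, 2L], col = col, pch = pch,
                 xlab = "MDS 1", ylab = "MDS 2", ...)
  if (!is.null(groups)) {
    graphics::legend("topright", legend = names(table(groups$labels)),
                     col = c("#B2182B", "#2166AC", "grey60")[
                       match(names(table(groups$labels)),
                             c("High", "Low", "Mid"))],
                     pch = c(17L, 19L, 1L)[
                       match(names(table(groups$labels)),
                             c("High", "Low", "Mid"))],
                     bty = "n")
  }
  invisible(xy)
}
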
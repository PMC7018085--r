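#' Generate a synthetic signed directed network
#'
#' Scale-free-ish topology: an undirected preferential-attachment graph
#' (Barabasi-Albert via [igraph::sample_pa()]), each edge then given a
#' uniformly random orientation and an inhibitory sign with probability
#' `p_inhibition`. Deterministic given `seed`.
#'
#' @param n_nodes number of proteins (>= 5); node names are `P001`, ...
#' @param attach_m edges attached per new node (default 2).
#' @param p_inhibition probability an edge is inhibitory (-1); default 0.3.
#' @param seed integer seed.
#' @return a [signed_network()].
#' @export
generate_network <- function(n_nodes, attach_m = 2L, p_inhibition = 0.3,
                             seed = 1L) {
  if (n_nodes < 5L) stop_("n_nodes must be >= 5")
  if (attach_m < 1L || attach_m >= n_nodes) {
    stop_("attach_m must be in [1, n_nodes)")
  }
  if (p_inhibition < 0 || p_inhibition > 1) {
    stop_("p_inhibition must be a probability")
  }
  with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = attach_m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    flip <- stats::runif(nrow(el)) < 0.5
    src <- ifelse(flip, el[, 2L], el[, 1L])
    dst <- ifelse(flip, el[, 1L], el[, 2L])
    sg <- ifelse(stats::runif(nrow(el)) < p_inhibition, -1, 1)
    fmt <- paste0("P%0", nchar(as.character(n_nodes)), "d")
    nm <- sprintf(fmt, seq_len(n_nodes))
    signed_network(
      data.frame(source = nm[src], target = nm[dst], sign = sg,
                 weight = 0, stringsAsFactors = FALSE),
      nodes = nm
    )
  })
}

#' Plant a solvable model instance with known ground truth
#'
#' Draws "true" edge weights respecting edge signs, propagates the stimulus
#' to get true signals, and picks effector proteins among reachable nodes
#' whose true signal magnitude clears `magnitude_floor` (so planted states
#' are not numerical noise). The *indication* effectors get the untreated
#' disease state, i.e. the opposite of the drug's propagated signal: the
#' planted drug response reverts the indication phenotype, as a working
#' treatment should. The *adverse-event* effectors get the sign of the true
#' signal itself: the planted response induces that phenotype, emulating a
#' mechanism-borne side effect. The restriction set (the training data)
#' holds the drug *response* states — sign of the true signal — at the
#' indication effectors plus `n_extra_restrictions` further reachable
#' nodes, each extra state flipped with probability `restriction_noise`.
#' With zero noise, the planted weights satisfy every restriction exactly.
#'
#' @param network a [signed_network()]; weights are ignored.
#' @param n_targets number of stimulus proteins (default 2, both clamped at
#'   -1, mirroring a dual-inhibitor drug).
#' @param n_eff_ind,n_eff_adv effector counts for the indication and the
#'   adverse-event phenotype (defaults 15 and 15). The two sets may
#'   overlap: they are distinct phenotype definitions over one network.
#' @param n_extra_restrictions additional (non-effector-derived)
#'   restrictions, tagged `expression` (default 15).
#' @param restriction_noise probability of flipping each extra
#'   restriction's state (default 0).
#' @param magnitude_floor minimal |true signal| for a node to be eligible
#'   as effector/restriction (default 0.05).
#' @param seed integer seed.
#' @param params a [propagation_params()].
#' @return list of class `planted_instance`: `network` (with true weights
#'   set), `stimulus`, `indication`, `adverse_event`, `restrictions`,
#'   `true_weights`, `true_signals`, `seed`.
#' @export
plant_instance <- function(network, n_targets = 2L,
                           n_eff_ind = 15L, n_eff_adv = 15L,
                           n_extra_restrictions = 15L,
                           restriction_noise = 0,
                           magnitude_floor = 0.05, seed = 1L,
                           params = propagation_params()) {
  stopifnot(inherits(network, "signed_network"))
  if (restriction_noise < 0 || restriction_noise > 1) {
    stop_("restriction_noise must be a probability")
  }
  with_seed(seed, {
    nodes <- network$nodes
    # favour high out-degree targets so the stimulus reaches the network
    outdeg <- table(factor(network$edges$source, levels = nodes))
    targets <- names(sort(outdeg, decreasing = TRUE))[seq_len(n_targets)]
    stim <- stimulus(stats::setNames(rep(-1, n_targets), targets), network)

    b <- weight_bounds(network)
    tw <- b$lo + (b$hi - b$lo) * stats::runif(n_edges(network))
    net <- set_weights(network, tw)
    true_signals <- propagate(net, stim, params)

    eligible <- setdiff(nodes[abs(true_signals) >= magnitude_floor],
                        names(stim))
    need <- n_eff_ind + n_eff_adv + n_extra_restrictions
    if (length(eligible) < max(n_eff_ind, n_eff_adv)) {
      stop_("only ", length(eligible), " reachable nodes clear the ",
            "magnitude floor; requested ", need,
            " effector/restriction slots")
    }
    pick <- function(n) sample(eligible, n)
    ind_p <- pick(n_eff_ind)
    adv_p <- pick(n_eff_adv)
    # indication: disease state opposed to the drug response (reverted by
    # the planted mechanism); adverse event: induced by it
    indication <- effector_set(
      "indication", "indication",
      stats::setNames(-sign(true_signals[ind_p]), ind_p), network)
    adverse <- effector_set(
      "adverse_event", "adverse_event",
      stats::setNames(sign(true_signals[adv_p]), adv_p), network)

    restr <- restriction_set(
      stats::setNames(sign(true_signals[ind_p]), ind_p),
      source = "effector", network = network)
    extra_pool <- setdiff(eligible, ind_p)
    n_extra <- min(n_extra_restrictions, length(extra_pool))
    if (n_extra > 0L) {
      ex_p <- sample(extra_pool, n_extra)
      st <- sign(true_signals[ex_p])
      flip <- stats::runif(n_extra) < restriction_noise
      st[flip] <- -st[flip]
      restr <- merge_restrictions(
        restr,
        restriction_set(stats::setNames(st, ex_p), source = "expression",
                        network = network))
    }
    structure(list(network = net, stimulus = stim, indication = indication,
                   adverse_event = adverse, restrictions = restr,
                   true_weights = tw, true_signals = true_signals,
                   seed = as.integer(seed)),
              class = "planted_instance")
  })
}

#' @export
print.planted_instance <- function(x, ...) {
  cat("Planted synthetic instance (seed", x$seed, ")\n")
  print(x$network)
  cat(sprintf("  stimulus: %s; effectors: %d indication / %d adverse; %d restrictions\n",
              paste(names(x$stimulus), collapse = ", "),
              length(x$indication$states), length(x$adverse_event$states),
              nrow(x$restrictions)))
  invisible(x)
}

#' Write a planted instance to a directory
#'
#' Emits the instance in the package's file formats: `network.tsv`,
#' `stimulus.tsv`, `effectors_indication.tsv`, `effectors_adverse.tsv`,
#' `restrictions.tsv` plus `truth.json` (true weights and signals).
#'
#' @param instance a [plant_instance()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_instance <- function(instance, dir) {
  stopifnot(inherits(instance, "planted_instance"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(instance$network, file.path(dir, "network.tsv"))
  write_states(instance$stimulus, file.path(dir, "stimulus.tsv"))
  write_states(instance$indication, file.path(dir, "effectors_indication.tsv"))
  write_states(instance$adverse_event, file.path(dir, "effectors_adverse.tsv"))
  write_states(instance$restrictions, file.path(dir, "restrictions.tsv"))
  truth <- list(seed = instance$seed,
                true_weights = unname(instance$true_weights),
                true_signals = as.list(instance$true_signals))
  writeLines(to_json(truth), file.path(dir, "truth.json"))
  invisible(dir)
}

# minimal JSON writer (numbers, strings, lists); enough for the truth file
to_json <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    if (is.null(names(x))) {
      return(paste0("[", paste(vapply(x, to_json, ""), collapse = ","), "]"))
    }
    kv <- vapply(seq_along(x), function(i) {
      paste0("\"", names(x)[i], "\":", to_json(x[[i]]))
    }, "")
    return(paste0("{", paste(kv, collapse = ","), "}"))
  }
  if (is.character(x)) {
    return(if (length(x) == 1L) paste0("\"", x, "\"")
           else to_json(as.list(x)))
  }
  if (length(x) == 1L) {
    return(format(x, digits = 15L, scientific = FALSE, trim = TRUE))
  }
  to_json(as.list(x))
}
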
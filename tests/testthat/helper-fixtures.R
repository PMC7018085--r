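# Small builders shared across test files.

# a 3-node chain S -> A -> B with unit activating weights
chain_net <- function() {
  signed_network(data.frame(source = c("S", "A"), target = c("A", "B"),
                            sign = 1, weight = 1))
}

# random signed network as a plain edge data.frame (for round-trip tests)
random_edges <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nm <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- expand.grid(source = nm, target = nm,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pick <- pairs[sample(nrow(pairs), n_edges), ]
  pick$sign <- sample(c(-1, 1), n_edges, replace = TRUE)
  pick$weight <- round(runif(n_edges, -1, 1) * ifelse(pick$sign > 0, 1, 1), 6)
  pick$weight <- ifelse(pick$sign > 0, abs(pick$weight), -abs(pick$weight))
  rownames(pick) <- NULL
  pick
}

# a tiny planted instance quick enough for per-test annealing
small_instance <- function(seed = 3, n_nodes = 80) {
  plant_instance(generate_network(n_nodes, seed = seed), seed = seed,
                 n_eff_ind = 6, n_eff_adv = 6, n_extra_restrictions = 6)
}

# synthetic "moa" objects with prescribed signals (no annealing), for
# stratification/geometry tests
fake_moa <- function(signals, accuracy = 1, seed = 1L) {
  structure(list(signals = signals, weights = numeric(0),
                 accuracy = accuracy, seed = as.integer(seed),
                 trace = numeric(0), converged = TRUE),
            class = "moa")
}

fake_ensemble <- function(signal_matrix, accuracies = NULL) {
  accuracies <- accuracies %||% rep(1, nrow(signal_matrix))
  moas <- lapply(seq_len(nrow(signal_matrix)), function(i) {
    fake_moa(signal_matrix[i, ], accuracy = accuracies[i], seed = i)
  })
  structure(list(moas = moas, K = nrow(signal_matrix), min_accuracy = 0,
                 n_sampled = nrow(signal_matrix)),
            class = "moa_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force modified Hausdorff distance (independent double-loop oracle)
mhd_oracle <- function(A, B) {
  dmin <- function(P, Q) {
    vapply(seq_len(nrow(P)), function(i) {
      min(vapply(seq_len(nrow(Q)), function(j) {
        sqrt(sum((P[i, ] - Q[j, ])^2))
      }, 0))
    }, 0)
  }
  max(mean(dmin(A, B)), mean(dmin(B, A)))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  ustat <- function(x, y) {
    sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), 0))
  }
  u_obs <- ustat(a, b)
  mu <- length(a) * length(b) / 2
  us <- apply(idx, 2L, function(k) ustat(pooled[k], pooled[-k]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
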
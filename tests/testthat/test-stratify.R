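test_that("tsignal is the state-weighted mean effector signal", {
  net <- signed_network(random_edges(6, 10, seed = 1))
  eff <- effector_set("ph", "indication",
                      c(N01 = 1, N02 = 1, N03 = -1), net)
  sig <- stats::setNames(numeric(6), net$nodes)
  sig[c("N01", "N02", "N03")] <- c(1, 1, -1)
  expect_equal(tsignal(fake_moa(sig), eff), 1)      # states matched exactly
  sig[c("N01", "N02", "N03")] <- c(-1, -1, 1)
  expect_equal(tsignal(fake_moa(sig), eff), -1)     # states fully reverted
  sig[c("N01", "N02", "N03")] <- c(0.5, -0.5, 0.5)
  expect_equal(tsignal(fake_moa(sig), eff), -1 / 6) # hand computation
  expect_error(tsignal(fake_moa(sig[1:2]), eff), "missing")
})

make_strat_ensemble <- function(K, seed = 1) {
  set.seed(seed)
  sm <- matrix(runif(K * 5, -1, 1), nrow = K,
               dimnames = list(NULL, sprintf("N%02d", 1:5)))
  fake_ensemble(sm)
}

test_that("quartile groups have size floor(K/4) with role-aware labels", {
  net <- signed_network(random_edges(5, 10, seed = 2))
  eff_ind <- effector_set("HF", "indication", c(N01 = 1, N02 = -1), net)
  eff_adv <- effector_set("MD", "adverse_event", c(N02 = 1, N03 = -1), net)
  for (K in c(8, 200, 203)) {
    ens <- make_strat_ensemble(K, seed = K)
    g <- stratify_ensemble(ens, eff_ind)
    expect_equal(sum(g$labels == "Low"), floor(K / 4))
    expect_equal(sum(g$labels == "High"), floor(K / 4))
    # indication: the Low group holds the strongest reverters (-P largest)
    expect_gte(min(g$intensity[g$labels == "Low"]),
               max(g$intensity[g$labels == "Mid"]))
    expect_gte(min(g$intensity[g$labels == "Mid"]),
               max(g$intensity[g$labels == "High"]))
    ga <- stratify_ensemble(ens, eff_adv)
    # adverse event: the High group holds the strongest inducers (+P)
    expect_gte(min(ga$intensity[ga$labels == "High"]),
               max(ga$intensity[ga$labels == "Mid"]))
  }
})

test_that("orientation is the only difference between the two roles", {
  net <- signed_network(random_edges(5, 10, seed = 3))
  states <- c(N01 = 1, N03 = -1)
  ens <- make_strat_ensemble(40, seed = 9)
  g_ind <- stratify_ensemble(ens, effector_set("x", "indication", states, net))
  g_adv <- stratify_ensemble(ens,
                             effector_set("x", "adverse_event", states, net))
  expect_equal(g_ind$tsignal, g_adv$tsignal)
  expect_equal(g_ind$intensity, -g_adv$intensity)
})

test_that("stratification is invariant to MoA input order", {
  net <- signed_network(random_edges(5, 10, seed = 4))
  eff <- effector_set("x", "indication", c(N01 = 1, N02 = -1), net)
  ens <- make_strat_ensemble(24, seed = 5)
  rev_ens <- structure(list(moas = rev(ens$moas), K = ens$K,
                            min_accuracy = 0, n_sampled = ens$n_sampled),
                       class = "moa_ensemble")
  g1 <- stratify_ensemble(ens, eff)
  g2 <- stratify_ensemble(rev_ens, eff)
  expect_equal(g1$labels[sort(names(g1$labels))],
               g2$labels[sort(names(g2$labels))])
})

test_that("ties fill groups in seed order with a warning", {
  net <- signed_network(random_edges(5, 10, seed = 6))
  eff <- effector_set("x", "indication", c(N01 = 1), net)
  sm <- matrix(0.5, nrow = 8, ncol = 5,
               dimnames = list(NULL, sprintf("N%02d", 1:5)))
  ens <- fake_ensemble(sm)
  expect_warning(g <- stratify_ensemble(ens, eff), "tied")
  expect_equal(sum(g$labels == "Low"), 2L)
  expect_equal(unname(g$labels[c("moa_1", "moa_2")]), c("Low", "Low"))
})

test_that("group intersections match a brute-force membership loop", {
  net <- signed_network(random_edges(5, 10, seed = 7))
  eff_a <- effector_set("A", "indication", c(N01 = 1, N04 = -1), net)
  eff_b <- effector_set("B", "adverse_event", c(N02 = 1, N05 = -1), net)
  for (seed in 1:5) {
    ens <- make_strat_ensemble(40, seed = seed)
    ga <- stratify_ensemble(ens, eff_a)
    gb <- stratify_ensemble(ens, eff_b)
    for (la in c("Low", "High")) for (lb in c("Low", "High")) {
      got <- intersect_groups(ga, gb, la, lb)
      brute <- character(0)
      for (id in ga$moa_ids) {
        if (ga$labels[id] == la && gb$labels[id] == lb) {
          brute <- c(brute, id)
        }
      }
      expect_setequal(got, brute)
    }
  }
  # identical groupings intersected with themselves give the group back
  ga <- stratify_ensemble(make_strat_ensemble(20), eff_a)
  expect_setequal(intersect_groups(ga, ga, "Low", "Low"),
                  group_members(ga, "Low"))
  # disjoint labels give an empty set without error
  expect_length(intersect_groups(ga, ga, "Low", "High"), 0L)
  # mismatched ensembles error
  gb_other <- stratify_ensemble(make_strat_ensemble(24), eff_b)
  expect_error(intersect_groups(ga, gb_other, "Low", "Low"),
               "different ensembles")
})

test_that("an annealed ensemble reverts the planted indication", {
  inst <- small_instance(seed = 21, n_nodes = 120)
  sch <- anneal_schedule(n_temperatures = 25, steps_per_temperature = 50)
  fit <- netmoa(inst$network, inst$stimulus, inst$restrictions,
                n_runs = 16, K = 8, min_accuracy = 0.5,
                schedule = sch, base_seed = 1, allow_fewer = TRUE)
  g <- stratify_ensemble(fit, inst$indication)
  # the strongest responders drive the indication effectors away from
  # their disease states
  expect_lt(mean(g$tsignal[group_members(g, "Low")]), 0)
  # and across the whole ensemble the mean response is a reversion
  expect_lt(mean(g$tsignal), 0)
})
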
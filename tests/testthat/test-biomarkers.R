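test_that("a perfectly separating protein scores accuracy 1", {
  A <- cbind(p1 = c(0.5, 0.7, 0.9), p2 = c(0.1, -0.1, 0.2))
  B <- cbind(p1 = c(-0.5, -0.7, -0.9), p2 = c(0.15, -0.05, 0.1))
  bc <- best_classifiers(A, B)
  expect_equal(bc$proteins[1], "p1")
  expect_equal(bc$accuracy[1], 1)
})

test_that("identical distributions score near chance", {
  set.seed(1)
  v <- rnorm(10)
  A <- cbind(p = v)
  B <- cbind(p = v)
  bc <- best_classifiers(A, B)
  expect_lte(abs(bc$accuracy[1] - 0.5), 0.15)
  # constant pooled values get 0.5 by convention
  bc0 <- best_classifiers(cbind(p = rep(1, 3)), cbind(p = rep(1, 3)))
  expect_equal(bc0$accuracy, 0.5)
})

test_that("classifier ranking matches an exhaustive LOO oracle", {
  # independent oracle: for each held-out point, enumerate every midpoint
  # threshold and orientation on the remaining points (first best rule in
  # threshold-major order) and classify the held-out point with it
  loo_oracle <- function(vA, vB) {
    v <- c(vA, vB); y <- c(rep(1, length(vA)), rep(0, length(vB)))
    hits <- 0
    for (i in seq_along(v)) {
      vt <- v[-i]; yt <- y[-i]
      u <- sort(unique(vt))
      thr <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
      best_acc <- -1; best_rule <- NULL
      for (t in thr) for (o in c(1, -1)) {
        acc <- mean((o * vt > o * t) == (yt == 1))
        if (acc > best_acc + 1e-12) {
          best_acc <- acc; best_rule <- c(o, t)
        }
      }
      pred <- best_rule[1] * v[i] > best_rule[1] * best_rule[2]
      if (pred == (y[i] == 1)) hits <- hits + 1
    }
    max(hits / length(v), 0.5)
  }
  set.seed(7)
  A <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, paste0("p", 1:4)))
  B <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, paste0("p", 1:4)))
  B[, 1] <- B[, 1] + 2
  B[, 2] <- B[, 2] + 0.5
  bc <- best_classifiers(A, B)
  oracle <- vapply(paste0("p", 1:4),
                   function(p) loo_oracle(A[, p], B[, p]), 0)
  oracle <- sort(oracle, decreasing = TRUE)
  expect_equal(bc$accuracy, unname(oracle[bc$proteins]))
  expect_equal(bc$proteins, names(oracle))
})

test_that("orientation flips keep accuracy at or above chance", {
  set.seed(2)
  for (s in 1:5) {
    A <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("p", 1:4)))
    B <- matrix(rnorm(20, mean = 1.2), 5, 4,
                dimnames = list(NULL, paste0("p", 1:4)))
    bc <- best_classifiers(A, B)
    expect_true(all(bc$accuracy >= 0.5 & bc$accuracy <= 1))
    # swapping group labels leaves accuracies unchanged
    bc_sw <- best_classifiers(B, A)
    expect_equal(bc$accuracy, bc_sw$accuracy)
    # and within-group row order does not matter
    bc_perm <- best_classifiers(A[sample(5), ], B[sample(5), ])
    expect_equal(bc$accuracy, bc_perm$accuracy)
  }
})

test_that("protein pairs can outclassify single stumps (XOR layout)", {
  A <- cbind(p1 = c(1, 1, -1, -1) + 0.01 * (1:4),
             p2 = c(1, 1, -1, -1) + 0.02 * (1:4))
  B <- cbind(p1 = c(1, -1, 1, -1), p2 = c(-1, 1, 1, -1))
  bc <- best_classifiers(A, B, include_pairs = TRUE, top_n = 20)
  expect_true(any(bc$kind == "pair"))
  best_pair <- max(bc$accuracy[bc$kind == "pair"])
  best_single <- max(bc$accuracy[bc$kind == "single"])
  expect_gte(best_pair, best_single)
})

test_that("Mann-Whitney matches the exact enumeration oracle", {
  # identical multisets -> p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1, tolerance = 1e-9)
  # complete separation at n = m = 5: two-sided exact p = 2/252
  expect_equal(mann_whitney(1:5, 6:10)$p, 2 / choose(10, 5),
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:5) {
    a <- round(rnorm(6), 2)
    b <- round(rnorm(5, 0.8), 2)
    if (anyDuplicated(c(a, b))) next
    expect_equal(mann_whitney(a, b)$p, mw_exact_oracle(a, b),
                 tolerance = 1e-9)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("BH adjustment reproduces the hand-applied step-up", {
  expect_equal(adjust_pvalues(0.37), 0.37)
  expect_equal(adjust_pvalues(rep(0.02, 4)), rep(0.02, 4))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_pvalues(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  expect_error(adjust_pvalues(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("the differential filter applies alpha and opposite signs", {
  recs <- data.frame(
    protein = paste0("p", 1:5),
    mean_A = c(0.5, -0.4, 0.3, 0, 0.6),
    mean_B = c(-0.5, 0.4, 0.3, -0.2, -0.1),
    p_adjusted = c(0.001, 0.005, 0.001, 0.001, 0.5))
  out <- differential_filter(recs, alpha = 0.01)
  # p3 same sign, p4 zero mean, p5 not significant
  expect_equal(out$protein, c("p1", "p2"))
  expect_equal(out$direction, c("A_active", "A_inactive"))
  # brute-force agreement on random record tables
  set.seed(4)
  for (i in 1:5) {
    r <- data.frame(protein = paste0("q", 1:20),
                    mean_A = round(runif(20, -1, 1), 2),
                    mean_B = round(runif(20, -1, 1), 2),
                    p_adjusted = round(runif(20), 3))
    got <- differential_filter(r, alpha = 0.05)
    brute <- r[r$p_adjusted < 0.05 &
                 ((r$mean_A > 0 & r$mean_B < 0) |
                    (r$mean_A < 0 & r$mean_B > 0)), ]
    expect_equal(got$protein, brute$protein)
    expect_equal(sum(got$direction == "A_active") +
                   sum(got$direction == "A_inactive"), nrow(got))
  }
})

test_that("reports sort by strength and annotate classifier membership", {
  recs <- data.frame(protein = c("a", "b", "c"),
                     mean_A = c(0.2, -0.9, 0.5),
                     mean_B = c(-0.9, 0.3, -0.5),
                     p_adjusted = c(1e-3, 1e-3, 1e-3))
  rep1 <- biomarker_report(differential_filter(recs),
                           bcp_sets = list(HF = c("a", "c"), MD = "c"))
  expect_equal(rep1$protein, c("b", "c", "a"))  # 0.27, 0.25, 0.18
  expect_equal(rep1$bcp, c("-", "HF&MD", "HF"))
  empty <- biomarker_report(differential_filter(recs, alpha = 1e-9))
  expect_equal(nrow(empty), 0L)
})

test_that("the packaged biomarker table reproduces its published counts", {
  tab <- reference_biomarkers()
  expect_equal(nrow(tab), 30L)
  recs <- data.frame(protein = tab$symbol, mean_A = tab$mean_LMD,
                     mean_B = tab$mean_HMD, p_adjusted = tab$p_adjusted)
  kept <- differential_filter(recs, alpha = 0.01)
  expect_equal(nrow(kept), 30L)                      # all rows survive
  expect_equal(sum(kept$direction == "A_active"), 16L)
  expect_equal(sum(kept$direction == "A_inactive"), 14L)
})

test_that("over-representation matches the hypergeometric oracle", {
  bg <- paste0("g", 1:100)
  genes <- paste0("g", 1:10)
  sets <- list(self = genes, other = paste0("g", 51:60),
               none = paste0("g", 90:100))
  out <- overrepresentation(genes, sets, bg)
  self <- out[out$set == "self", ]
  expect_lt(self$p, 0.05)
  expect_gt(self$lod, 1)
  none <- out[out$set == "none", ]
  expect_lte(none$odds_ratio, 1)
  # 2x2 table (5, 5, 5, 85): one-sided Fisher equals the hypergeometric
  # tail sum
  genes2 <- paste0("g", 1:10)
  set2 <- paste0("g", c(1:5, 11:15))
  p_pkg <- overrepresentation(genes2, list(s = set2), bg)$p
  p_oracle <- sum(dhyper(5:10, 10, 90, 10))
  expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
  expect_error(overrepresentation(c("zz"), sets, bg), "outside")
  expect_error(overrepresentation(genes, sets, character(0)), "empty")
})

test_that("GMT files round-trip through the reader", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc A\tg1\tg2\tg3", "setB\t-\tg4"), f)
  sets <- read_gmt(f)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  writeLines("bad\tonly-two-fields", f)
  expect_error(read_gmt(f), "fewer than 3")
})
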
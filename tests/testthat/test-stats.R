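make_arr <- function(mats) {
  p <- nrow(mats[[1]])
  arr <- array(NA_real_, c(length(mats), p, p))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  arr
}

sym_mat <- function(v, p) {
  m <- matrix(NA_real_, p, p)
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

test_that("identical matrices give a degenerate Kruskal-Wallis test", {
  p <- 6
  m <- sym_mat(rep(0.3, p * (p - 1) / 2), p)
  arr <- make_arr(rep(list(m), 9))
  man <- data.frame(subject = paste0("S", 1:9),
                    grp = rep(c("a", "b", "c"), each = 3))
  res <- global_mean_connectivity(arr, man, "grp")
  expect_equal(res$tests$H, 0)
  expect_equal(res$tests$p, 1)
  expect_true(all(res$curves$mean == 0.3))
})

test_that("Kruskal-Wallis agrees with the exhaustive permutation oracle", {
  set.seed(5)
  x <- c(rnorm(4), rnorm(4) + 1, rnorm(4) + 2)
  g <- rep(1:3, each = 4)
  p <- 4
  mats <- lapply(x, function(v) sym_mat(rep(v, p * (p - 1) / 2), p))
  man <- data.frame(subject = paste0("S", 1:12), grp = g)
  kw_p <- global_mean_connectivity(make_arr(mats), man, "grp")$tests$p
  obs <- kw_H(x, g)
  cnt <- 0; tot <- 0
  for (a in utils::combn(12, 4, simplify = FALSE)) {
    rest <- setdiff(1:12, a)
    for (b in utils::combn(rest, 4, simplify = FALSE)) {
      gg <- integer(12); gg[a] <- 1; gg[b] <- 2; gg[setdiff(rest, b)] <- 3
      cnt <- cnt + (kw_H(x, gg) >= obs - 1e-12)
      tot <- tot + 1
    }
  }
  expect_equal(kw_p, cnt / tot, tolerance = 0.02 / (cnt / tot))
})

test_that("Kruskal-Wallis holds its nominal type-I error rate", {
  set.seed(99)
  rej <- mean(replicate(1000, {
    g <- factor(rep(1:3, each = 8))
    kruskal.test(rnorm(24), g)$p.value <= 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("identical groups give an empty difference network", {
  sim <- simulate_cohort_matrices(6, 6, 12, n_effect = 0, noise_sd = 0.05,
                                  seed = 4)
  comp <- edgewise_comparison(sim$A, sim$A)
  expect_equal(comp$K, 0)
  expect_equal(comp$n_edges, 66)
})

test_that("BH step-up matches a hand-computed oracle", {
  # worked example (0.01, 0.02, 0.04, 0.8) at alpha 0.05, m = 4:
  # p_(1) = 0.01 <= 1/4 * 0.05, p_(2) = 0.02 <= 2/4 * 0.05, but
  # p_(3) = 0.04 > 3/4 * 0.05 = 0.0375, so the step-up rejects exactly two
  pv <- c(0.01, 0.02, 0.04, 0.8)
  m <- length(pv)
  o <- order(pv)
  k <- max(which(sort(pv) <= seq_len(m) / m * 0.05))
  rejected <- o[seq_len(k)]
  expect_setequal(rejected, 1:2)
  expect_equal(p.adjust(pv, "BH") <= 0.05, c(TRUE, TRUE, FALSE, FALSE))
  # property: own step-up equals p.adjust on random vectors
  set.seed(8)
  for (rep in 1:20) {
    pv <- runif(50)^2
    srt <- sort(pv)
    ks <- which(srt <= seq_len(50) / 50 * 0.05)
    byhand <- logical(50)
    if (length(ks)) byhand[order(pv)[seq_len(max(ks))]] <- TRUE
    expect_equal(p.adjust(pv, "BH") <= 0.05, byhand)
  }
})

test_that("effect size equals the pair-enumeration oracle", {
  expect_equal(effect_size(4:6, 1:3), 1)
  expect_equal(effect_size(1:3, 4:6), -1)
  set.seed(2)
  expect_lt(abs(effect_size(rnorm(300), rnorm(300))), 0.15)
  # brute force over all 9 pairs of A=(1,2,3), B=(2,3,4): ties count half
  A <- c(1, 2, 3); B <- c(2, 3, 4)
  wins_a <- sum(outer(A, B, ">")) + 0.5 * sum(outer(A, B, "=="))
  wins_b <- sum(outer(A, B, "<")) + 0.5 * sum(outer(A, B, "=="))
  expect_equal(effect_size(A, B), (wins_a - wins_b) / 9)
  expect_equal(effect_size(A, B), -5 / 9)
})

test_that("implanted edge effects are recovered with FDR control", {
  sens <- numeric(10); fdp <- numeric(10)
  for (s in seq_len(10)) {
    sim <- simulate_cohort_matrices(15, 15, 30, n_effect = 40, effect = 0.3,
                                    noise_sd = 0.1, seed = 100 + s)
    comp <- edgewise_comparison(sim$A, sim$B)
    sig <- which(comp$significant & upper.tri(comp$significant), arr.ind = TRUE)
    truth_key <- paste(sim$effect_edges[, 1], sim$effect_edges[, 2])
    sig_key <- paste(pmin(sig[, 1], sig[, 2]), pmax(sig[, 1], sig[, 2]))
    sens[s] <- mean(truth_key %in% sig_key)
    fdp[s] <- if (length(sig_key)) mean(!(sig_key %in% truth_key)) else 0
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fdp), 0.05)
})

test_that("K is invariant under monotone transforms and directions are disjoint", {
  sim <- simulate_cohort_matrices(8, 8, 12, n_effect = 10, effect = 0.25,
                                  noise_sd = 0.08, seed = 5)
  comp <- edgewise_comparison(sim$A, sim$B)
  mono <- function(a) exp(2 * a + 1)
  comp2 <- edgewise_comparison(mono(sim$A), mono(sim$B))
  expect_equal(comp2$K, comp$K)
  expect_equal(comp2$significant, comp$significant)
  rev_comp <- edgewise_comparison(sim$B, sim$A)
  both <- comp$significant & rev_comp$significant
  expect_false(any(both[upper.tri(both)], na.rm = TRUE))
})

test_that("region summaries cover the trivial geometries", {
  bun <- make_toy_bundle(32, 256, 12, seed = 6)
  p <- 12
  base <- matrix(NA, p, p)
  base[upper.tri(base)] <- FALSE
  base[lower.tri(base)] <- t(base)[lower.tri(base)]
  comp <- structure(list(significant = base, K = 0, n_edges = 66,
                         alpha = 0.05, direction = "A>B", band = NA,
                         mode = NA, n = c(A = 5, B = 5)),
                    class = "group_comparison")
  rs <- region_summaries(comp, bun)
  expect_true(all(rs$node_involvement$fraction == 0))
  expect_length(rs$edge_lengths, 0)
  all_sig <- comp
  all_sig$significant[upper.tri(base) | lower.tri(base)] <- TRUE
  rs2 <- region_summaries(all_sig, bun)
  expect_true(all(rs2$node_involvement$fraction == 1))
  # every region pair with at least one possible edge reaches 1.0
  expect_true(all(rs2$region_pairs$fraction %in% c(0, 1)))
  expect_true(any(rs2$region_pairs$fraction == 1))
  expect_length(rs2$edge_lengths, 66)
  # significance confined to one hemisphere -> no interhemispheric edges
  left <- which(bun$regions$hemisphere == "left")
  if (length(left) >= 2) {
    one_h <- comp
    one_h$significant[left[1], left[2]] <- TRUE
    one_h$significant[left[2], left[1]] <- TRUE
    expect_equal(region_summaries(one_h, bun)$interhemispheric_fraction, 0)
  }
})

test_that("the spindle-removal contrast is zero when variants coincide", {
  sim <- simulate_cohort_matrices(6, 6, 10, n_effect = 5, seed = 9)
  comp <- list(b1 = edgewise_comparison(sim$A, sim$B))
  out <- spindle_removal_contrast(comp, comp)
  expect_equal(out$dK, 0)
  other <- list(b1 = edgewise_comparison(sim$A[1:5, , , drop = FALSE],
                                         sim$B[1:5, , , drop = FALSE]))
  expect_error(spindle_removal_contrast(comp, other), "differ")
})

test_that("trajectory analysis flags implanted band effects with direction", {
  set.seed(12)
  p <- 8
  man <- data.frame(subject = paste0("S", 1:22),
                    trajectory = c(rep("Typical-Typical", 8),
                                   rep("Typical-Mild", 8),
                                   rep("Mild-Severe", 5),
                                   "Severe-Typical"))
  ne <- p * (p - 1) / 2
  mk_band <- function(offsets) {
    arr <- array(NA_real_, c(22, p, p))
    for (i in 1:22)
      arr[i, , ] <- sym_mat(0.3 + offsets[i] + rnorm(ne, sd = 0.04), p)
    arr
  }
  off_low <- ifelse(man$trajectory == "Typical-Mild", 0.25, 0)
  conn <- list(low = mk_band(off_low), high = mk_band(rep(0, 22)))
  expect_message(res <- trajectory_analysis(conn, man), "dropping")
  expect_true("Severe-Typical" %in% res$dropped)
  hits <- res$tests[res$tests$significant, ]
  expect_true(all(hits$band == "low"))
  # the Typical-Mild group carries the implanted surplus, whichever side
  # of the comparison it landed on
  expect_true(any((hits$group_a == "Typical-Mild" & hits$direction == "A>B") |
                    (hits$group_b == "Typical-Mild" & hits$direction == "B>A")))
  # identically sampled trajectory groups stay quiet
  null_hits <- res$tests[res$tests$band == "high" & res$tests$significant, ]
  expect_equal(nrow(null_hits), 0)
})
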
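test_that("BM ancestral states match closed forms and the GLS oracle", {
  # two-tip tree, equal branches: root is the midpoint
  t2 <- read_timetree("(A:1,B:1);")
  expect_equal(unname(asr_bm(t2, c(A = 0, B = 2))[3]), 1)
  # unequal branches: inverse-variance weighting
  t2b <- read_timetree("(A:1,B:3);")
  expect_equal(unname(asr_bm(t2b, c(A = 0, B = 2))[3]),
               (0 / 1 + 2 / 3) / (1 / 1 + 1 / 3))
  # constant traits reconstruct constant states
  t3 <- toy_tree3()
  expect_true(all(asr_bm(t3, c(A = 4, B = 4, C = 4)) == 4))
  # GLS oracle on random trees
  set.seed(17)
  for (i in 1:20) {
    tr <- rtree_pos(sample(4:25, 1))
    x <- setNames(rnorm(length(tr$tip.label)), tr$tip.label)
    expect_equal(unname(asr_bm(tr, x)), asr_bm_oracle(tr, x),
                 tolerance = 1e-8)
  }
})

test_that("acquisition collapsing averages traits and preserves contracts", {
  tr <- simulate_tree(30, seed = 71)
  rt <- paint_regimes(tr, 4, seed = 72, talpid_shift = FALSE)
  x <- simulate_traits(tr, trait_sim_config("BM", 1, seed = 73))
  ct <- collapse_acquisitions(tr, rt$acquisitions, x)
  expect_identical(sum(ct$tree$tip.label %in% names(rt$acquisitions)),
                   length(rt$acquisitions))
  for (acq in names(rt$acquisitions))
    expect_equal(ct$traits[[acq]], mean(x[rt$acquisitions[[acq]]]))
  # singleton acquisition: pure relabel of tip and trait
  single <- list(s1 = tr$tip.label[1])
  ct1 <- collapse_acquisitions(tr, single, x)
  expect_identical(ape::Ntip(ct1$tree), 30L)
  expect_equal(ct1$traits[["s1"]], x[[tr$tip.label[1]]])
  # two-member clade with traits 0.2 / 0.4 -> 0.3
  sib <- tr$tip.label[tr$edge[tr$edge[, 1] ==
                                ape::getMRCA(tr, tr$tip.label[1:2]), 2]]
  if (all(sib %in% tr$tip.label) && length(sib) == 2) {
    xx <- x; xx[sib] <- c(0.2, 0.4)
    ct2 <- collapse_acquisitions(tr, list(pair = sib), xx)
    expect_equal(ct2$traits[["pair"]], 0.3)
  }
  # overlapping memberships refused
  expect_error(collapse_acquisitions(tr, list(a = tr$tip.label[1:3],
                                              b = tr$tip.label[3:5]), x),
               class = "osteoconv_invalid_map")
})

test_that("C1 equals exhaustive enumeration and is affine invariant", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(4:6, 1)
    tr <- rtree_pos(n)
    x <- setNames(rnorm(n), tr$tip.label)
    focal <- sample(tr$tip.label, sample(2:min(4, n), 1))
    r <- c1_statistic(tr, focal_tips = focal, traits = x)
    expect_equal(r$c1, c1_oracle(tr, x, focal), tolerance = 1e-10)
    expect_true(all(r$per_pair$Dtip <= r$per_pair$Dmax + 1e-12))
    expect_gte(r$c1, 0); expect_lte(r$c1, 1)
    # shift and positive scaling leave C1 unchanged
    r2 <- c1_statistic(tr, focal_tips = focal, traits = 3.7 + 2.5 * x)
    expect_equal(r2$c1, r$c1, tolerance = 1e-10)
  }
})

test_that("C1 is high for convergent tips and ~0 for pure divergence", {
  # two focal tips converging to identical values from distant ancestors
  tr <- read_timetree("((A:1,B:1):3,(C:1,D:1):3);")
  x <- c(A = 5, B = 4.8, C = -5, D = -4.9)
  r <- c1_statistic(tr, focal_tips = c(A = "A", C = "C"), traits = x)
  expect_lt(r$c1, 0.1) # A and C only ever diverged
  # force convergence: focal tips end at the same value
  x2 <- c(A = 5, B = 0.2, C = 5, D = -6)
  r2 <- c1_statistic(tr, focal_tips = c("A", "C"), traits = x2)
  expect_equal(r2$per_pair$Dtip, 0)
  expect_equal(r2$c1, 1)
  # identical traits everywhere: C1 undefined
  expect_error(c1_statistic(tr, focal_tips = c("A", "C"),
                            traits = c(A = 1, B = 1, C = 1, D = 1)),
               class = "osteoconv_undefined_c1")
})

test_that("excluding a focal tip only removes its pairs", {
  tr <- simulate_tree(40, seed = 81)
  rt <- paint_regimes(tr, 5, seed = 82, talpid_shift = FALSE)
  x <- simulate_traits(tr, trait_sim_config("BM", 1, seed = 83))
  ct <- collapse_acquisitions(tr, rt$acquisitions, x)
  all5 <- c1_statistic(ct)
  drop1 <- setdiff(ct$acquisitions, ct$acquisitions[1])
  sub <- c1_statistic(ct, focal_tips = drop1)
  kept <- !(all5$per_pair$tip_i == ct$acquisitions[1] |
              all5$per_pair$tip_j == ct$acquisitions[1])
  expect_equal(sum(sub$per_pair$Dtip), sum(all5$per_pair$Dtip[kept]))
  expect_equal(sum(sub$per_pair$Dmax), sum(all5$per_pair$Dmax[kept]))
  expect_equal(sub$c1, 1 - sum(all5$per_pair$Dtip[kept]) /
                 sum(all5$per_pair$Dmax[kept]))
})

test_that("the simulation p-value is deterministic and detects OU convergence", {
  tr <- simulate_tree(60, seed = 91)
  rt <- paint_regimes(tr, 8, seed = 92)
  x <- simulate_traits(rt, trait_sim_config(
    "OU", sigma2 = 0.05, alpha = 0.2,
    theta = c(background = 0, subterranean = 2, talpid_like = 3),
    seed = 93))
  ct <- collapse_acquisitions(tr, rt$acquisitions, x)
  r1 <- c1_significance(ct, n_sim = 300, seed = 5)
  r2 <- c1_significance(ct, n_sim = 300, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_lt(r1$p_value, 0.05) # strongly convergent regime structure
  expect_identical(r1$n_dropped, 0L)
  expect_error(c1_significance(ct, n_sim = 50), "n_sim")
})

test_that("strongly convergent OU data are detected with high power", {
  # shared extreme optimum, large alpha: the focal tips converge hard
  tr <- simulate_tree(50, seed = 101)
  rt <- paint_regimes(tr, 6, seed = 102, talpid_shift = FALSE)
  hits <- 0L
  n_rep <- 20L
  for (i in seq_len(n_rep)) {
    x <- simulate_traits(rt, trait_sim_config(
      "OU", sigma2 = 0.05, alpha = 0.5,
      theta = c(background = 0, subterranean = 3), seed = 2000 + i))
    ct <- collapse_acquisitions(tr, rt$acquisitions, x)
    r <- c1_significance(ct, n_sim = 500, seed = 3000 + i)
    hits <- hits + (r$p_value <= 0.05)
  }
  expect_gte(hits / n_rep, 0.8)
})
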
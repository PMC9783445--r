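test_that("phenogram coordinates pin tips at observed values and times", {
  t2 <- read_timetree("(A:1,B:1);")
  ph <- phenogram_layout(t2, c(A = 0, B = 2))
  expect_equal(ph$nodes$state[3], 1) # root point (0, 1)
  expect_equal(ph$nodes$time[3], 0)
  # tip coordinates are exactly the observations
  tr <- simulate_tree(30, seed = 111, fossil_tips = 3)
  x <- simulate_traits(tr, trait_sim_config("BM", 1, seed = 112))
  ph2 <- phenogram_layout(tr, x)
  tipd <- ph2$nodes[ph2$nodes$is_tip, ]
  expect_equal(tipd$state, unname(x[tipd$label]))
  # fossil tips plot at their true pre-present times
  fossil <- names(tip_ages(tr))[tip_ages(tr) > 1e-9]
  expect_true(all(tipd$time[tipd$label %in% fossil] < root_age(tr) - 1e-9))
  # constant traits: a horizontal phenogram
  ph3 <- phenogram_layout(tr, setNames(rep(2, 30), tr$tip.label))
  expect_true(all(ph3$nodes$state == 2))
})

test_that("branch maps interpolate linearly within node states", {
  t2 <- read_timetree("(A:1,B:1);")
  st <- asr_bm(t2, c(A = 1, B = 3))
  bm <- branch_state_map(t2, c(A = 1, B = 3), resolution = 3)
  edge_a <- bm[bm$child == 1, ]
  expect_equal(edge_a$state, c(st[[3]], (st[[3]] + 1) / 2, 1))
  # extrema bounded by the endpoint states on every edge
  tr <- simulate_tree(20, seed = 115)
  x <- simulate_traits(tr, trait_sim_config("BM", 1, seed = 116))
  bm2 <- branch_state_map(tr, x, resolution = 7)
  st2 <- asr_bm(tr, x)
  for (e in unique(bm2$edge)) {
    seg <- bm2[bm2$edge == e, ]
    lo <- min(st2[seg$parent[1]], st2[seg$child[1]])
    hi <- max(st2[seg$parent[1]], st2[seg$child[1]])
    expect_true(all(seg$state >= lo - 1e-12 & seg$state <= hi + 1e-12))
  }
  expect_error(branch_state_map(t2, c(A = 1, B = 3), resolution = 1),
               "resolution")
})

test_that("group summaries conserve the included-species total", {
  set.seed(118)
  v <- setNames(rnorm(20), paste0("s", 1:20))
  g <- setNames(rep(c("fossorial_talpid", "other_subterranean",
                      "non_subterranean", "non_subterranean"), 5), names(v))
  gs <- group_summary(v, g)
  expect_identical(sum(gs$n), 20L)
  expect_setequal(gs$group, unique(g))
  expect_equal(gs$mean[gs$group == "fossorial_talpid"],
               mean(v[g == "fossorial_talpid"]))
})

test_that("the pipeline is deterministic and honours variants and exclusions", {
  cfg <- list(
    seed = 5, n_sim = 200,
    synth = list(n_tips = 60, n_shifts = 6, fossil_tips = 0,
                 traits = c("bvtv", "compactness")))
  b1 <- run_pipeline(cfg)
  b2 <- run_pipeline(cfg)
  expect_identical(b1, b2)
  expect_named(b1$variants, "base")
  v <- b1$variants$base
  expect_identical(nrow(v$ancova), 2L)
  expect_true(all(c("bvtv", "compactness") %in% v$ancova$trait))
  # talpid acquisition excluded in the second C1 run: one fewer tip
  expect_identical(v$c1$bvtv$excluding$n_acquisitions,
                   v$c1$bvtv$n_acquisitions - 1L)
  expect_identical(v$c1$bvtv$excluding$excluded, "acq_talpid")
  # summary counts conserve species
  expect_identical(sum(v$summary$n), 60L)

  # file bundle round-trip is byte-identical
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_pipeline(cfg, out_dir = d1)
  run_pipeline(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_setequal(list.files(d1),
                  c("ancova_base.csv", "c1_base.json", "phenogram.csv",
                    "summary.csv", "run.log"))
})

test_that("tree variants each get their own ANCOVA and C1 section", {
  # find a safe attachment clade on the (reproducible) synthetic tree: a
  # non-root internal node whose stem leaves room above the fossil's age
  tr <- simulate_tree(50, seed = 9, fossil_tips = 0)
  ages <- osteoconv:::node_ages(tr)
  parent_of <- function(nd) tr$edge[tr$edge[, 2] == nd, 1]
  cand <- which(vapply(seq_along(ages), function(nd) {
    nd > 51 && ages[nd] > 30 && ages[nd] < 100 &&
      length(parent_of(nd)) == 1 && ages[parent_of(nd)] - ages[nd] > 5
  }, logical(1)))[1]
  crown <- unname(ages[cand]); gap <- unname(ages[parent_of(cand)]) - crown
  # one tip from each child subtree, so their MRCA is exactly `cand`
  kids <- tr$edge[tr$edge[, 1] == cand, 2]
  tip_in <- function(nd) if (nd <= 50) tr$tip.label[nd]
                         else ape::extract.clade(tr, nd)$tip.label[1]
  span <- c(tip_in(kids[1]), tip_in(kids[2]))
  mk <- function(age, rule)
    list(list(name = "fossil_x", age = age, tips = span, rule = rule,
              lifestyle = "subterranean", fossorial_talpid = FALSE,
              bvtv = 0.8, csa = 5))
  cfg <- list(
    seed = 9, n_sim = 200,
    synth = list(n_tips = 50, n_shifts = 5, fossil_tips = 0,
                 traits = "bvtv"),
    variants = list(
      Tree1A = mk(crown / 2, list(fraction = 0.05)),
      Tree1B = mk(crown / 2, list(fraction = 0.95)),
      Tree2 = mk(crown + gap / 2 - 1, list(push_node = 1))))
  b <- run_pipeline(cfg)
  expect_named(b$variants, c("Tree1A", "Tree1B", "Tree2"))
  for (v in b$variants) {
    expect_identical(nrow(v$ancova), 1L)
    expect_true(is.finite(v$c1$bvtv$all$c1))
    # the fossil entered the analysis with an imputed mass
    expect_true("fossil_x" %in% v$phenogram$nodes$label)
  }
})
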
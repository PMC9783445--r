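# Cross-checks of the lambda-PGLS machinery against independent references:
# ordinary least squares on a star phylogeny and nlme::gls with corPagel plus
# tip-height variance weights on structured trees.

make_reg_data <- function(tree, beta = c(1.5, 0.4), sigma2_e = 0.2,
                          seed = 7) {
  x <- simulate_traits(tree, trait_sim_config("BM", 0.5, seed = seed))
  e <- simulate_traits(tree, trait_sim_config("BM", sigma2_e,
                                              seed = seed + 1))
  data.frame(species = tree$tip.label,
             x = unname(x[tree$tip.label]),
             y = beta[1] + beta[2] * x[tree$tip.label] +
               e[tree$tip.label])
}

test_that("PGLS reduces to OLS on a star phylogeny", {
  star <- ape::stree(20, "star")
  star$edge.length <- rep(1, 20)
  set.seed(3)
  d <- data.frame(species = star$tip.label, x = rnorm(20))
  d$y <- 1 + 2 * d$x + rnorm(20, 0, 0.5)
  fit <- pgls_fit(y ~ x, d, star, lambda = 0)
  ols <- lm(y ~ x, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ols)))),
               tolerance = 1e-8)
})

test_that("PGLS matches nlme::gls with corPagel and tip-height weights", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(60, seed = 5, fossil_tips = 5)
  d <- make_reg_data(tr)
  d$w_ <- diag(ape::vcv(tr))[d$species]
  for (lam in c(0, 0.4, 0.8)) {
    for (meth in c("REML", "ML")) {
      fit <- pgls_fit(y ~ x, d, tr, lambda = lam, method = meth)
      g <- nlme::gls(y ~ x, data = d,
                     correlation = ape::corPagel(lam, tr, form = ~species,
                                                 fixed = TRUE),
                     weights = nlme::varFixed(~w_), method = meth)
      expect_equal(unname(coef(fit)), unname(coef(g)), tolerance = 1e-8)
      expect_equal(fit$logLik, as.numeric(logLik(g)), tolerance = 1e-8)
      expect_equal(unname(fit$se), unname(sqrt(diag(g$varBeta))),
                   tolerance = 1e-6)
    }
  }
})

test_that("profile likelihood at the optimum dominates a lambda grid", {
  tr <- simulate_tree(50, seed = 9)
  d <- make_reg_data(tr, seed = 11)
  fit <- pgls_fit(y ~ x, d, tr)
  prof <- function(l) osteoconv:::pgls_core(fit$model$y, fit$model$X,
                                            fit$model$Corr, fit$model$s,
                                            l, "REML")$logLik
  for (l in c(0, 0.25, 0.5, 0.75, 1))
    expect_gte(fit$logLik + 1e-8, prof(l))
})

test_that("lambda recovery separates Brownian from independent traits", {
  tr <- simulate_tree(100, seed = 21)
  lam_bm <- lam_iid <- numeric(10)
  for (i in 1:10) {
    y <- simulate_traits(tr, trait_sim_config("BM", 1, seed = 400 + i))
    d <- data.frame(species = names(y), y = unname(y))
    lam_bm[i] <- pgls_fit(y ~ 1, d, tr)$lambda
    set.seed(500 + i)
    d$y <- rnorm(100)
    lam_iid[i] <- pgls_fit(y ~ 1, d, tr)$lambda
  }
  expect_gte(mean(lam_bm), 0.9)
  expect_lte(mean(lam_iid), 0.1)
})

test_that("pseudo-R2 behaves as a likelihood-ratio R2", {
  tr <- simulate_tree(40, seed = 31)
  d <- make_reg_data(tr, seed = 33)
  fit <- pgls_fit(y ~ x, d, tr)
  null <- pgls_fit(y ~ 1, d, tr)
  r2 <- nagelkerke_pseudo_r2(fit, null)
  expect_gte(r2, 0); expect_lte(r2, 1)
  # full = null -> 0
  expect_equal(nagelkerke_pseudo_r2(null, null), 0, tolerance = 1e-6)
  # near-noiseless linear relation -> R2 near 1
  d2 <- d; d2$y <- 2 + 3 * d2$x + rnorm(40, 0, 1e-4)
  expect_gt(nagelkerke_pseudo_r2(pgls_fit(y ~ x, d2, tr)), 0.999)
  # ceiling variant stays in [0, 1] and is >= the plain one
  r2c <- nagelkerke_pseudo_r2(fit, ceiling = TRUE)
  expect_gte(r2c, r2 - 1e-8)
  expect_lte(r2c, 1)
})

test_that("phyloANCOVA recovers simulated group and covariate effects", {
  tr <- simulate_tree(100, seed = 41)
  rt <- paint_regimes(tr, 6, seed = 42, talpid_shift = FALSE)
  grp <- setNames(ifelse(rt$tip_regime == "background", "non_subterranean",
                         "subterranean"), names(rt$tip_regime))
  # strong group offset on a Brownian background
  y <- simulate_traits(tr, trait_sim_config("BM", 0.01, seed = 43))
  depth_sd <- sqrt(0.01 * root_age(tr))
  y[grp[names(y)] == "subterranean"] <-
    y[grp[names(y)] == "subterranean"] + 5 * depth_sd
  lm10 <- simulate_traits(tr, trait_sim_config("BM", 0.002, root_state = 2,
                                               seed = 44))
  d <- data.frame(species = names(y), y = unname(y),
                  lifestyle = unname(grp[names(y)]),
                  body_mass = unname(10^lm10[names(y)]))
  fit <- phylo_ancova(d, tr, "y", "lifestyle", "log10(body_mass)")
  expect_lt(fit$group_test$p, 0.001)
  expect_gt(fit$pseudo_r2, 0.2)

  # covariate recovery: trait = 0.3 log10(mass) + BM noise
  d2 <- d
  d2$y <- 0.3 * log10(d2$body_mass) +
    simulate_traits(tr, trait_sim_config("BM", 1e-4, seed = 45))[d2$species]
  fit2 <- phylo_ancova(d2, tr, "y", "lifestyle", "log10(body_mass)")
  b <- coef(fit2)[["log10(body_mass)"]]
  se <- fit2$se[["log10(body_mass)"]]
  expect_lt(abs(b - 0.3), 2 * se)

  # group size guard
  d3 <- d; d3$lifestyle <- c("a", "a", rep("b", 98))
  expect_error(phylo_ancova(d3, tr, "y", "lifestyle"), ">= 3 members")
})

test_that("body-mass imputation recovers the allometry and flags sources", {
  tr <- simulate_tree(40, seed = 51, fossil_tips = 2)
  lcsa <- simulate_traits(tr, trait_sim_config("BM", 0.02, root_state = 1,
                                               seed = 52))
  d <- data.frame(species = names(lcsa), csa = unname(10^lcsa))
  # exact power law: mass = 10^0.2 * csa^1.5
  d$body_mass <- 10^(0.2 + 1.5 * log10(d$csa))
  fossil <- tip_ages(tr)[d$species] > 1e-9
  d$body_mass[fossil] <- NA # fossils have no database mass
  out <- predict_body_mass(d, tr)
  fit <- attr(out, "fit")
  expect_equal(unname(coef(fit)), c(0.2, 1.5), tolerance = 1e-6)
  expect_gt(attr(out, "pseudo_r2"), 0.999)
  expect_true(all(out$mass_source[fossil] == "predicted"))
  expect_equal(out$body_mass_pred, 10^(0.2 + 1.5 * log10(out$csa)),
               tolerance = 1e-6)

  # noisy allometry: slope within 2 SE
  set.seed(53)
  d2 <- d
  d2$body_mass <- 10^(0.2 + 1.5 * log10(d2$csa) + rnorm(40, 0, 0.1))
  out2 <- predict_body_mass(d2, tr)
  f2 <- attr(out2, "fit")
  expect_lt(abs(coef(f2)[[2]] - 1.5), 2 * f2$se[[2]])

  # species without cross-sectional area keep their database mass
  d3 <- d2; d3$csa[1] <- NA
  out3 <- predict_body_mass(d3, tr)
  expect_identical(out3$mass_source[1], "database")
  expect_equal(out3$body_mass_pred[1], d3$body_mass[1])
})

test_that("size correction yields mass-unit-invariant residuals", {
  tr <- simulate_tree(50, seed = 61)
  lm10 <- simulate_traits(tr, trait_sim_config("BM", 0.01, root_state = 2,
                                               seed = 62))
  y <- simulate_traits(tr, trait_sim_config("BM", 0.5, seed = 63))
  d <- data.frame(species = names(y), y = unname(y),
                  body_mass_pred = unname(10^lm10[names(y)]))
  r <- size_correct(d, tr, "y")
  # trait independent of mass: residuals track the centred trait closely
  expect_gt(cor(r, y[names(r)]), 0.95)
  # exact dependence -> residuals ~ 0
  d2 <- d; d2$y <- 0.7 * log10(d2$body_mass_pred)
  expect_lt(max(abs(size_correct(d2, tr, "y"))), 1e-8)
  # g -> kg rescaling only shifts the intercept
  d3 <- d; d3$body_mass_pred <- d3$body_mass_pred / 1000
  expect_equal(r, size_correct(d3, tr, "y"), tolerance = 1e-6,
               ignore_attr = TRUE)
})
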
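#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits a linear model whose error covariance follows phylogenetic shared
#' ancestry: `Sigma = sigma2 * S^{1/2} C(lambda) S^{1/2}`, where `C(lambda)`
#' is the lambda-scaled phylogenetic correlation matrix (off-diagonals
#' multiplied by lambda) and `S` the variance weights. With the default
#' `weights = "tip_heights"`, `S` is the diagonal of the Brownian covariance
#' matrix (root-to-tip heights), which accounts for species variance
#' heterogeneity on non-ultrametric timetrees; `Sigma` then equals the
#' lambda-transformed Brownian covariance exactly. Lambda is estimated by
#' maximizing the profile restricted likelihood (REML, the default) or the
#' profile likelihood (ML) over `[0, 1]` with bounded one-dimensional
#' optimization. Coefficient tests are t-tests on the GLS standard errors
#' with `n - p` degrees of freedom.
#'
#' Rows of `data` are matched to tree tips by the `species` column (or row
#' names when absent); the tree is pruned to the modeled species and a
#' mismatch report is raised as an error if any modeled species is missing
#' from the tree. Rows with missing values in the model variables are dropped.
#'
#' @param formula model formula, e.g. `bvtv ~ lifestyle + log10(mass)`.
#' @param data data.frame with one row per species.
#' @param tree a `phylo` timetree containing (at least) the modeled species.
#' @param lambda `"ML"` to estimate (by the criterion in `method`), or a fixed
#'   numeric value in `[0, 1]`.
#' @param method `"REML"` (default) or `"ML"` likelihood for estimation and
#'   the reported `logLik`.
#' @param weights `"tip_heights"` (default) or `"none"` (unit variances).
#' @param species_col name of the species column in `data`.
#' @return An object of class `pgls` with components `coefficients`, `se`,
#'   `tstat`, `pvals`, `lambda`, `logLik`, `sigma2`, `vcov`, `residuals`,
#'   `fitted`, `n`, `p`, `df.residual` and the aligned model internals used by
#'   [nagelkerke_pseudo_r2()].
#' @seealso [phylo_ancova()], [size_correct()], [nagelkerke_pseudo_r2()]
#' @examples
#' tr <- simulate_tree(40, seed = 1)
#' d <- data.frame(species = tr$tip.label,
#'                 y = simulate_traits(tr, sigma2 = 1, seed = 2))
#' fit <- pgls_fit(y ~ 1, d, tr)
#' summary(fit)
#' @export
pgls_fit <- function(formula, data, tree, lambda = "ML",
                     method = c("REML", "ML"),
                     weights = c("tip_heights", "none"),
                     species_col = "species") {
  method <- match.arg(method)
  weights <- match.arg(weights)
  cl <- match.call()

  species <- if (species_col %in% names(data)) as.character(data[[species_col]])
             else rownames(data)
  if (is.null(species) || anyDuplicated(species))
    stop("need unique species identifiers (column `", species_col,
         "` or row names)", call. = FALSE)
  mf_all <- model.frame(formula, data, na.action = NULL)
  keep <- complete.cases(mf_all)
  species <- species[keep]
  missing_in_tree <- setdiff(species, tree$tip.label)
  if (length(missing_in_tree))
    stop("species absent from the tree: ",
         paste(head(missing_in_tree, 5), collapse = ", "),
         if (length(missing_in_tree) > 5) ", ...", call. = FALSE)
  extra <- setdiff(tree$tip.label, species)
  tr <- if (length(extra)) ape::drop.tip(tree, extra) else tree
  ord <- match(tr$tip.label, species)
  mf <- mf_all[keep, , drop = FALSE][ord, , drop = FALSE]
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  n <- length(y); p <- ncol(X)
  if (n <= p + 1L)
    stop("too few species (n = ", n, ") for ", p, " coefficients",
         call. = FALSE)
  if (qr(X)$rank < p)
    stop("rank-deficient design matrix", call. = FALSE)

  V <- ape::vcv(tr)
  h <- diag(V)
  Corr <- V / sqrt(outer(h, h))
  s <- if (weights == "tip_heights") sqrt(h) else rep(1, n)

  core <- function(lam, meth) pgls_core(y, X, Corr, s, lam, meth)
  if (identical(lambda, "ML") || identical(lambda, "optimize")) {
    obj <- function(l) core(l, method)$logLik
    opt <- optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(opt$maximum, 0, 1)
    vals <- c(opt$objective, obj(0), obj(1))
    lam_hat <- cand[which.max(vals)]
    lambda_estimated <- TRUE
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop("`lambda` must be \"ML\" or a value in [0, 1]", call. = FALSE)
    lam_hat <- lambda
    lambda_estimated <- FALSE
  }
  fit <- core(lam_hat, method)
  se <- sqrt(diag(fit$vcov))
  tstat <- fit$beta / se
  pvals <- 2 * pt(-abs(tstat), df = n - p)
  res <- setNames(as.vector(y - X %*% fit$beta), tr$tip.label)
  structure(list(
    coefficients = setNames(fit$beta, colnames(X)),
    se = setNames(se, colnames(X)),
    tstat = setNames(tstat, colnames(X)),
    pvals = setNames(pvals, colnames(X)),
    lambda = lam_hat, lambda_estimated = lambda_estimated,
    logLik = fit$logLik, sigma2 = fit$sigma2, vcov = fit$vcov,
    residuals = res, fitted = setNames(as.vector(X %*% fit$beta),
                                       tr$tip.label),
    n = n, p = p, df.residual = n - p,
    method = method, weights = weights,
    formula = formula, call = cl, terms = attr(mf, "terms"),
    assign = attr(X, "assign"), xlevels = stats::.getXlevels(
      attr(mf, "terms"), mf),
    model = list(y = setNames(as.vector(y), tr$tip.label), X = X,
                 Corr = Corr, s = s, tree = tr)),
    class = "pgls")
}

# GLS estimation for a fixed lambda; returns beta, sigma2 (REML-type),
# coefficient covariance, and the log-likelihood of `meth`.
pgls_core <- function(y, X, Corr, s, lam, meth) {
  n <- length(y); p <- ncol(X)
  C <- Corr * lam
  diag(C) <- 1
  W <- C * outer(s, s)
  ch <- tryCatch(chol(W), error = function(e)
    stop("weight matrix not positive definite at lambda = ", lam,
         ": ", conditionMessage(e), call. = FALSE))
  ty <- backsolve(ch, y, transpose = TRUE)
  tX <- backsolve(ch, X, transpose = TRUE)
  XtWX <- crossprod(tX)
  beta <- solve(XtWX, crossprod(tX, ty))
  r <- ty - tX %*% beta
  rss <- sum(r^2)
  logdetW <- 2 * sum(log(diag(ch)))
  sigma2_reml <- rss / (n - p)
  if (meth == "REML") {
    ld_xtwx <- determinant(XtWX, logarithm = TRUE)$modulus
    ll <- -0.5 * ((n - p) * log(2 * pi * sigma2_reml) + (n - p) +
                    logdetW + as.numeric(ld_xtwx))
  } else {
    sigma2_ml <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + n + logdetW)
  }
  list(beta = as.vector(beta), sigma2 = sigma2_reml,
       vcov = sigma2_reml * solve(XtWX), logLik = ll)
}

#' @export
print.pgls <- function(x, ...) {
  cat("Phylogenetic GLS (Pagel's lambda)\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("lambda = %.4f%s, logLik (%s) = %.3f, n = %d\n",
              x$lambda, if (x$lambda_estimated) " (optimized)" else " (fixed)",
              x$method, x$logLik, x$n))
  cat("Coefficients:\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$tstat, `Pr(>|t|)` = object$pvals)
  structure(list(call = object$call, coefficients = tab,
                 lambda = object$lambda, logLik = object$logLik,
                 sigma2 = object$sigma2, n = object$n,
                 df.residual = object$df.residual, method = object$method,
                 group_test = object$group_test),
            class = "summary.pgls")
}

#' @export
print.summary.pgls <- function(x, ...) {
  cat("Phylogenetic GLS (Pagel's lambda)\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nlambda = %.4f, sigma2 = %.5g, logLik (%s) = %.3f, n = %d\n",
              x$lambda, x$sigma2, x$method, x$logLik, x$n))
  if (!is.null(x$group_test))
    cat(sprintf("Group effect: F(%d, %d) = %.3f, p = %.3g\n",
                x$group_test$df1, x$group_test$df2, x$group_test$F,
                x$group_test$p))
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
residuals.pgls <- function(object, type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "response") return(r)
  m <- object$model
  C <- m$Corr * object$lambda
  diag(C) <- 1
  W <- C * outer(m$s, m$s)
  setNames(as.vector(backsolve(chol(W), r, transpose = TRUE)) /
             sqrt(object$sigma2), names(r))
}

#' @export
fitted.pgls <- function(object, ...) object$fitted

#' @export
vcov.pgls <- function(object, ...) object$vcov

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$logLik, df = object$p + 1L + object$lambda_estimated,
            nobs = object$n, class = "logLik")
}

#' @export
nobs.pgls <- function(object, ...) object$n

#' Predictions from a pgls fit
#'
#' Fixed-effect predictions `X beta` for new data; the phylogenetic
#' correlation of prediction targets with the training species is not used
#' (no BLUP correction), which matches how imputation from an allometric
#' PGLS is normally done.
#'
#' @param object a [pgls_fit()] object.
#' @param newdata data.frame of predictor values; when `NULL` the fitted
#'   values are returned.
#' @param ... unused.
#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- stats::delete.response(object$terms)
  mf <- model.frame(tt, newdata, na.action = stats::na.pass,
                    xlev = object$xlevels)
  X <- model.matrix(tt, mf)
  as.vector(X %*% object$coefficients)
}

#' @export
plot.pgls <- function(x, ...) {
  graphics::plot(x$fitted, x$residuals, xlab = "Fitted values",
                 ylab = "Residuals", main = "pgls: residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Nagelkerke pseudo-R-squared
#'
#' Likelihood-ratio pseudo-R2 of a pgls fit against the nested intercept-only
#' model on the same species and tree:
#' `R2 = 1 - exp(-(2/n) * (logLik_full - logLik_null))`. Both models are
#' evaluated at their ML (not REML) likelihood — REML likelihoods of models
#' with different fixed effects are not comparable — re-optimizing lambda for
#' each model. By default the ceiling correction
#' `R2 / (1 - exp((2/n) * logLik_null))` is *not* applied (the response is
#' continuous, so the ceiling is essentially 1); set `ceiling = TRUE` for the
#' ceiling-corrected variant.
#'
#' @param fit a [pgls_fit()] object.
#' @param null_fit optional nested null fit; default intercept-only on the
#'   same data.
#' @param ceiling apply the Nagelkerke ceiling correction?
#' @return The pseudo-R2 (in `[0, 1]` except for optimizer pathologies, which
#'   raise a warning).
#' @export
nagelkerke_pseudo_r2 <- function(fit, null_fit = NULL, ceiling = FALSE) {
  stopifnot(inherits(fit, "pgls"))
  m <- fit$model
  ml_ll <- function(X, lambda_fixed = NULL) {
    obj <- function(l) pgls_core(m$y, X, m$Corr, m$s, l, "ML")$logLik
    if (!is.null(lambda_fixed)) return(obj(lambda_fixed))
    opt <- optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-6)
    max(opt$objective, obj(0), obj(1))
  }
  ll_full <- ml_ll(m$X, if (fit$lambda_estimated) NULL else fit$lambda)
  if (is.null(null_fit)) {
    X0 <- matrix(1, nrow = fit$n, ncol = 1)
    ll_null <- ml_ll(X0, if (fit$lambda_estimated) NULL else fit$lambda)
  } else {
    stopifnot(inherits(null_fit, "pgls"))
    if (null_fit$n != fit$n)
      stop("null fit uses different data", call. = FALSE)
    ll_null <- ml_ll(null_fit$model$X,
                     if (fit$lambda_estimated) NULL else fit$lambda)
  }
  if (ll_full < ll_null - 1e-8)
    warning("full-model likelihood below the null's (optimizer artifact)")
  r2 <- 1 - exp(-(2 / fit$n) * (ll_full - ll_null))
  if (ceiling) r2 <- r2 / (1 - exp((2 / fit$n) * ll_null))
  r2
}

#' Phylogenetic ANCOVA
#'
#' PGLS of a trait on a lifestyle factor plus a continuous covariate
#' (typically log10 body mass): `trait ~ group + covariate`. The group effect
#' is reported as a Wald F test on the group coefficients (equivalent to the
#' squared t test for a two-level factor). Groups with fewer than 3 members
#' are refused.
#'
#' @param data data.frame with one row per species.
#' @param tree a `phylo` timetree.
#' @param trait name of the response column.
#' @param group name of the factor column (>= 2 levels, >= 3 members each).
#' @param covariate optional name of a numeric covariate column, or a
#'   one-sided formula expression as character (e.g. `"log10(body_mass)"`).
#' @param ... passed to [pgls_fit()].
#' @return A `pgls` object (subclass `pgls_ancova`) with an extra
#'   `group_test` component (`F`, `df1`, `df2`, `p`) and `pseudo_r2`.
#' @export
phylo_ancova <- function(data, tree, trait, group, covariate = NULL, ...) {
  if (!group %in% names(data)) stop("no column `", group, "`", call. = FALSE)
  data[[group]] <- factor(data[[group]])
  tab <- table(data[[group]][!is.na(data[[trait]])])
  if (length(tab) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 3L))
    stop("every group needs >= 3 members; smallest has ", min(tab),
         call. = FALSE)
  rhs <- c(group, covariate)
  f <- stats::as.formula(paste(trait, "~", paste(rhs, collapse = " + ")))
  fit <- pgls_fit(f, data, tree, ...)
  gi <- which(fit$assign == 1L) # group is the first term
  b <- fit$coefficients[gi]
  Vg <- fit$vcov[gi, gi, drop = FALSE]
  q <- length(gi)
  Fstat <- as.vector(t(b) %*% solve(Vg, b)) / q
  fit$group_test <- list(F = Fstat, df1 = q, df2 = fit$df.residual,
                         p = pf(Fstat, q, fit$df.residual, lower.tail = FALSE))
  fit$pseudo_r2 <- nagelkerke_pseudo_r2(fit)
  class(fit) <- c("pgls_ancova", "pgls")
  fit
}

#' @export
print.pgls_ancova <- function(x, ...) {
  NextMethod()
  cat(sprintf("Group effect: F(%d, %d) = %.3f, p = %.3g; pseudo-R2 = %.3f\n",
              x$group_test$df1, x$group_test$df2, x$group_test$F,
              x$group_test$p, x$pseudo_r2))
  invisible(x)
}

#' Impute body mass from humeral cross-sectional area
#'
#' PGLS allometric regression of log10 body mass on log10 mean total
#' cross-sectional area over the extant species with both quantities known
#' (at least 10), then prediction for every species with a cross-sectional
#' area — including fossils. Species lacking a cross-sectional area keep their
#' database mass. The log10-log10 scale is the standard power-law allometry.
#'
#' @param data data.frame with species, mass and cross-sectional-area columns.
#' @param tree a `phylo` timetree.
#' @param mass_col column with database body mass (g); may contain `NA`.
#' @param csa_col column with mean total cross-sectional area (mm^2).
#' @param species_col species column.
#' @param ... passed to [pgls_fit()].
#' @return `data` with two new columns: `body_mass_pred` (g) and `mass_source`
#'   (`"predicted"`, `"database"` or `NA`); the fit and its pseudo-R2 are in
#'   attributes `"fit"` and `"pseudo_r2"`.
#' @export
predict_body_mass <- function(data, tree, mass_col = "body_mass",
                              csa_col = "csa", species_col = "species",
                              ...) {
  mass <- data[[mass_col]]; csa <- data[[csa_col]]
  ages <- tip_ages(tree)
  sp <- as.character(data[[species_col]])
  extant <- !is.na(ages[sp]) & ages[sp] <= 1e-6 * max(1, root_age(tree))
  known <- which(!is.na(mass) & !is.na(csa) & csa > 0 & extant)
  if (length(known) < 10L)
    stop("need >= 10 extant species with both mass and cross-sectional area",
         call. = FALSE)
  df <- data.frame(species = sp[known], log_mass = log10(mass[known]),
                   log_csa = log10(csa[known]))
  fit <- pgls_fit(log_mass ~ log_csa, df, tree, ...)
  pred <- rep(NA_real_, nrow(data))
  src <- rep(NA_character_, nrow(data))
  has_csa <- !is.na(csa) & csa > 0
  pred[has_csa] <- 10^predict(fit, data.frame(log_csa = log10(csa[has_csa])))
  src[has_csa] <- "predicted"
  use_db <- !has_csa & !is.na(mass)
  pred[use_db] <- mass[use_db]
  src[use_db] <- "database"
  data$body_mass_pred <- pred
  data$mass_source <- src
  attr(data, "fit") <- fit
  attr(data, "pseudo_r2") <- nagelkerke_pseudo_r2(fit)
  data
}

#' Size-correct a trait by phylogenetic regression on body mass
#'
#' Residuals of `trait ~ log10(body mass)` fitted by [pgls_fit()]; these
#' size-corrected values feed the convergence test, the group summaries and
#' the phenograms.
#'
#' @param data data.frame with species, trait and mass columns.
#' @param tree a `phylo` timetree.
#' @param trait trait column name.
#' @param mass_col body-mass column name (g).
#' @param species_col species column.
#' @param ... passed to [pgls_fit()].
#' @return Named numeric vector of residuals (species with complete data);
#'   the underlying fit is in attribute `"fit"`.
#' @export
size_correct <- function(data, tree, trait, mass_col = "body_mass_pred",
                         species_col = "species", ...) {
  df <- data.frame(species = as.character(data[[species_col]]),
                   trait = data[[trait]],
                   log_mass = log10(data[[mass_col]]))
  fit <- pgls_fit(trait ~ log_mass, df, tree, ...)
  out <- residuals(fit)
  attr(out, "fit") <- fit
  out
}
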
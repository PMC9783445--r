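#' Phenogram (traitgram) coordinates
#'
#' Deterministic layout for a phenogram: each node is placed at
#' (time from root, trait state), with tip states the observed values and
#' internal states the Brownian ML reconstruction; edges connect parent to
#' child coordinates. Fossil tips plot at their true pre-present time.
#'
#' @param tree a `phylo` timetree.
#' @param traits named trait vector covering all tips.
#' @return An object of class `phenogram_layout`: list with `nodes`
#'   (data.frame: node, label, time, state, is_tip) and `edges` (data.frame:
#'   parent, child).
#' @export
phenogram_layout <- function(tree, traits) {
  st <- asr_bm(tree, traits)
  h <- node_heights(tree)
  ntip <- length(tree$tip.label)
  nodes <- data.frame(
    node = seq_along(st),
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
    time = h, state = unname(st),
    is_tip = seq_along(st) <= ntip)
  structure(list(nodes = nodes,
                 edges = data.frame(parent = tree$edge[, 1],
                                    child = tree$edge[, 2])),
            class = "phenogram_layout")
}

#' @export
print.phenogram_layout <- function(x, ...) {
  cat(sprintf("phenogram_layout: %d nodes (%d tips), time span %.3g\n",
              nrow(x$nodes), sum(x$nodes$is_tip), max(x$nodes$time)))
  invisible(x)
}

#' @param x a `phenogram_layout`.
#' @param col edge colour.
#' @param ... passed to `plot`.
#' @rdname phenogram_layout
#' @export
plot.phenogram_layout <- function(x, col = "grey30", ...) {
  nd <- x$nodes
  graphics::plot(nd$time, nd$state, type = "n", xlab = "Time from root (Ma)",
                 ylab = "Trait", ...)
  graphics::segments(nd$time[x$edges$parent], nd$state[x$edges$parent],
                     nd$time[x$edges$child], nd$state[x$edges$child],
                     col = col)
  graphics::points(nd$time[nd$is_tip], nd$state[nd$is_tip], pch = 16,
                   cex = 0.6)
  invisible(x)
}

#' Branch-wise continuous-character map
#'
#' Linear interpolation of the Brownian ML states along every branch at a
#' stated resolution, as used for continuous-character tree maps.
#'
#' @param tree a `phylo` timetree.
#' @param traits named trait vector covering all tips.
#' @param resolution number of interpolation points per edge (>= 2, endpoints
#'   included).
#' @return data.frame with columns edge, parent, child, time, state.
#' @export
branch_state_map <- function(tree, traits, resolution = 10L) {
  if (resolution < 2L)
    stop("`resolution` must be >= 2", call. = FALSE)
  st <- asr_bm(tree, traits)
  h <- node_heights(tree)
  out <- lapply(seq_len(nrow(tree$edge)), function(e) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    f <- seq(0, 1, length.out = resolution)
    data.frame(edge = e, parent = p, child = ch,
               time = h[p] + f * (h[ch] - h[p]),
               state = st[p] + f * (st[ch] - st[p]))
  })
  do.call(rbind, out)
}

#' Group summary of a size-corrected trait
#'
#' Per-group count, mean, median and quartiles — the numbers needed to draw a
#' violin/box summary of size-corrected values across lifestyle groups.
#'
#' @param values named numeric vector (e.g. size-corrected residuals).
#' @param groups factor or character vector aligned with `values` (or named,
#'   in which case it is matched by name).
#' @return data.frame: group, n, mean, median, q25, q75.
#' @export
group_summary <- function(values, groups) {
  if (!is.null(names(groups)) && !is.null(names(values)))
    groups <- groups[names(values)]
  stopifnot(length(groups) == length(values))
  g <- factor(groups)
  out <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- values[g == lv & !is.na(values)]
    data.frame(group = lv, n = length(v), mean = mean(v), median = median(v),
               q25 = unname(quantile(v, 0.25)),
               q75 = unname(quantile(v, 0.75)))
  }))
  if (sum(out$n) != sum(!is.na(values)))
    stop("group counts do not conserve the included-species total",
         call. = FALSE)
  out
}

#' Run the full comparative pipeline
#'
#' Drives the end-to-end analysis for one or more tree variants: optional
#' fossil grafting, body-mass imputation, size correction, phylogenetic
#' ANCOVA per trait, acquisition collapsing and the C1 convergence test (with
#' and without excluded acquisitions), group summaries and a phenogram
#' layout. The run is a pure function of (config, seed): identical configs
#' give byte-identical output bundles.
#'
#' The configuration is a named list (or the path of a YAML file with the
#' same structure) with fields:
#' \describe{
#'   \item{seed}{integer; drives every stochastic step.}
#'   \item{synth}{settings for a fully synthetic dataset:
#'     `n_tips`, `n_shifts`, `fossil_tips`, `root_age`, `sigma2`, `alpha`,
#'     `theta` (named: background, subterranean, talpid_like), traits listed
#'     under `traits` each get an independent replicate. Mutually exclusive
#'     with `tree`/`trait_table`.}
#'   \item{tree, trait_table}{paths of a Newick file and a trait CSV
#'     (columns: species, lifestyle, fossorial_talpid, the trait columns,
#'     csa, body_mass), or the corresponding R objects.}
#'   \item{clade_map}{named list of acquisition member tips (derived from the
#'     regime painting in synth mode).}
#'   \item{variants}{named list of graft lists; each graft is a list with
#'     `name`, `age`, `tips`, `rule` (see [graft_fossil()]) and optional
#'     per-trait values. Default: a single variant `"base"` with no grafts.}
#'   \item{traits}{character vector of trait columns to analyse.}
#'   \item{group_col}{lifestyle factor column (default `"lifestyle"`).}
#'   \item{exclude}{acquisition names excluded in the second C1 run (default:
#'     acquisitions named `"acq_talpid"`).}
#'   \item{n_sim}{C1 simulation count (default 1000).}
#' }
#'
#' @param config named list or YAML file path.
#' @param out_dir optional output directory; when given, writes
#'   `ancova_<variant>.csv`, `c1_<variant>.json`, `phenogram.csv`,
#'   `summary.csv` and `run.log`.
#' @return The report bundle (a named list), invisibly when `out_dir` is
#'   given.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  n_sim <- if (is.null(config$n_sim)) 1000L else as.integer(config$n_sim)
  group_col <- if (is.null(config$group_col)) "lifestyle" else config$group_col

  if (!is.null(config$synth)) {
    syn <- synth_dataset(config$synth, seed)
    tree <- syn$tree; tab <- syn$table; clade_map <- syn$clade_map
    trait_cols <- syn$trait_cols
  } else {
    tree <- if (is.character(config$tree)) read_timetree(config$tree)
            else config$tree
    tab <- if (is.character(config$trait_table)) read.csv(config$trait_table)
           else config$trait_table
    clade_map <- config$clade_map
    trait_cols <- config$traits
    validate_timetree(tree)
  }
  if (!is.null(config$traits)) trait_cols <- config$traits
  if (is.null(clade_map))
    stop("no acquisition `clade_map` available", call. = FALSE)
  exclude <- if (is.null(config$exclude))
    intersect("acq_talpid", names(clade_map)) else config$exclude
  variants <- if (is.null(config$variants)) list(base = list())
              else config$variants

  bundle <- list(config = list(seed = seed, n_sim = n_sim,
                               traits = trait_cols,
                               variants = names(variants),
                               exclude = exclude),
                 variants = list())
  log_lines <- c("osteoconv pipeline run",
                 sprintf("package version: %s",
                         as.character(utils::packageVersion("osteoconv"))),
                 sprintf("seed: %d", seed),
                 sprintf("n_sim: %d", n_sim),
                 sprintf("variants: %s", paste(names(variants),
                                               collapse = ", ")))

  for (vi in seq_along(variants)) {
    vname <- names(variants)[vi]
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop(sprintf("[%s/%s] %s", vname, what, conditionMessage(e)),
             call. = FALSE))
    }
    tree_v <- tree
    tab_v <- tab
    for (g in variants[[vi]]) {
      tree_v <- stage("graft", graft_fossil(tree_v, g$name, g$age, g$tips,
                                            g$rule))
      row <- tab_v[0, ][1, ]
      row$species <- g$name
      for (nm in setdiff(names(g), c("name", "age", "tips", "rule")))
        row[[nm]] <- g[[nm]]
      tab_v <- rbind(tab_v, row)
    }
    tab_v <- stage("body_mass", predict_body_mass(tab_v, tree_v))
    ancova_rows <- list()
    c1_res <- list()
    residuals_by_trait <- list()
    for (tr_col in trait_cols) {
      resid <- stage("size_correct",
                     size_correct(tab_v, tree_v, tr_col))
      residuals_by_trait[[tr_col]] <- resid
      an <- stage("ancova", phylo_ancova(
        tab_v, tree_v, trait = tr_col, group = group_col,
        covariate = "log10(body_mass_pred)"))
      ancova_rows[[tr_col]] <- data.frame(
        trait = tr_col, n = an$n, lambda = an$lambda,
        F = an$group_test$F, df1 = an$group_test$df1,
        df2 = an$group_test$df2, p_group = an$group_test$p,
        pseudo_r2 = an$pseudo_r2, logLik = an$logLik)
      cm <- lapply(clade_map, function(m) intersect(m, names(resid)))
      cm <- cm[lengths(cm) > 0]
      ct <- stage("collapse",
                  collapse_acquisitions(tree_keep(tree_v, names(resid)),
                                        cm, resid))
      c1_all <- stage("c1", c1_significance(ct, n_sim = n_sim,
                                            seed = seed + 1000L * vi))
      keep_acq <- setdiff(ct$acquisitions, exclude)
      c1_excl <- if (length(keep_acq) >= 2 && length(exclude))
        stage("c1_exclude",
              c1_significance(ct, focal_tips = keep_acq, n_sim = n_sim,
                              seed = seed + 1000L * vi + 500L))
      c1_res[[tr_col]] <- list(
        n_acquisitions = length(ct$acquisitions),
        all = list(c1 = c1_all$c1, p = c1_all$p_value,
                   n_sim = c1_all$n_sim, sigma2 = c1_all$sigma2),
        excluding = if (!is.null(c1_excl)) list(
          excluded = exclude, n_acquisitions = length(keep_acq),
          c1 = c1_excl$c1, p = c1_excl$p_value, n_sim = c1_excl$n_sim,
          sigma2 = c1_excl$sigma2))
    }
    resid1 <- residuals_by_trait[[1]]
    groups3 <- three_group_labels(tab_v, group_col)
    bundle$variants[[vname]] <- list(
      ancova = do.call(rbind, ancova_rows),
      c1 = c1_res,
      summary = group_summary(resid1, groups3),
      phenogram = phenogram_layout(tree_keep(tree_v, names(resid1)), resid1))
    log_lines <- c(log_lines,
                   sprintf("variant %s: n = %d species, %d acquisitions",
                           vname, sum(!is.na(tab_v[[trait_cols[1]]])),
                           c1_res[[1]]$n_acquisitions))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (vname in names(bundle$variants)) {
      v <- bundle$variants[[vname]]
      write.csv(v$ancova, file.path(out_dir, paste0("ancova_", vname, ".csv")),
                row.names = FALSE)
      jsonlite::write_json(v$c1, file.path(out_dir,
                                           paste0("c1_", vname, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    v1 <- bundle$variants[[1]]
    write.csv(v1$phenogram$nodes, file.path(out_dir, "phenogram.csv"),
              row.names = FALSE)
    write.csv(v1$summary, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
    return(invisible(bundle))
  }
  bundle
}

# prune a tree to the given tips
tree_keep <- function(tree, tips) {
  extra <- setdiff(tree$tip.label, tips)
  if (length(extra)) ape::drop.tip(tree, extra) else tree
}

# fossorial talpids / other subterranean / non-subterranean labels
three_group_labels <- function(tab, group_col) {
  g <- as.character(tab[[group_col]])
  out <- ifelse(g == "subterranean", "other_subterranean",
                "non_subterranean")
  if ("fossorial_talpid" %in% names(tab))
    out[which(tab$fossorial_talpid %in% c(TRUE, "TRUE", 1))] <-
      "fossorial_talpid"
  setNames(out, as.character(tab$species))
}

# Build the synthetic study conditions: a mammal-like timetree with the
# stated number of independent subterranean acquisitions (one talpid-like),
# OU-evolving traits with a shifted optimum per regime, an independent
# Brownian log-mass, and a cross-sectional area tied to mass by a power law.
synth_dataset <- function(syn, seed) {
  n_tips <- if (is.null(syn$n_tips)) 155L else as.integer(syn$n_tips)
  n_shifts <- if (is.null(syn$n_shifts)) 11L else as.integer(syn$n_shifts)
  fossil_tips <- if (is.null(syn$fossil_tips)) 2L
                 else as.integer(syn$fossil_tips)
  root_age <- if (is.null(syn$root_age)) 160 else syn$root_age
  trait_cols <- if (is.null(syn$traits)) "bvtv" else syn$traits
  sigma2 <- if (is.null(syn$sigma2)) 0.003 else syn$sigma2
  alpha <- if (is.null(syn$alpha)) 0.15 else syn$alpha
  theta <- if (is.null(syn$theta))
    c(background = 0.35, subterranean = 0.65, talpid_like = 0.95)
  else unlist(syn$theta)

  tree <- simulate_tree(n_tips, seed = seed, fossil_tips = fossil_tips,
                        root_age = root_age)
  rt <- paint_regimes(tree, n_shifts, seed = seed + 1L, talpid_shift = TRUE)
  tab <- data.frame(species = tree$tip.label)
  tab$lifestyle <- ifelse(rt$tip_regime[tab$species] == "background",
                          "non_subterranean", "subterranean")
  tab$fossorial_talpid <- rt$tip_regime[tab$species] == "talpid_like"
  for (k in seq_along(trait_cols)) {
    ts <- syn$trait_settings[[trait_cols[k]]]
    s2 <- if (is.null(ts$sigma2)) sigma2 else ts$sigma2
    al <- if (is.null(ts$alpha)) alpha else ts$alpha
    th <- if (is.null(ts$theta)) theta else unlist(ts$theta)
    tab[[trait_cols[k]]] <- simulate_traits(rt, trait_sim_config(
      model = "OU", sigma2 = s2, alpha = al, theta = th,
      root_state = th[["background"]], seed = seed + 10L + k))[tab$species]
  }
  # log10 body mass: independent Brownian trait around a 100 g mammal
  log_mass <- simulate_traits(tree, trait_sim_config(
    model = "BM", sigma2 = 0.005, root_state = 2, seed = seed + 90L))
  tab$body_mass <- 10^log_mass[tab$species]
  # cross-sectional area follows mass allometrically (slope 2/3 on log-log),
  # with modest lognormal scatter
  set.seed(seed + 91L)
  tab$csa <- 10^(-0.5 + (2 / 3) * log_mass[tab$species] +
                   rnorm(nrow(tab), 0, 0.05))
  list(tree = tree, table = tab, clade_map = rt$acquisitions,
       trait_cols = trait_cols, regimes = rt)
}
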
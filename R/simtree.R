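#' Simulate a mammal-like timetree
#'
#' Pure-birth (Yule) topology with `n_tips` tips, rescaled so the root age is
#' `root_age` Ma. Optionally, `fossil_tips` randomly chosen tips are truncated
#' above the present (their terminal branch shortened by a uniform fraction),
#' yielding a non-ultrametric timetree as used throughout the comparative
#' analyses.
#'
#' @param n_tips number of tips (>= 4).
#' @param seed RNG seed; identical seeds give identical Newick strings.
#' @param fossil_tips how many tips to truncate above the present.
#' @param root_age root age in Ma. The default (160 Ma) is of the order of the
#'   therian root.
#' @param birth speciation rate passed to the Yule simulator (topology shape
#'   only; depths are rescaled).
#' @return An `ape` `phylo` timetree with branch lengths in Ma.
#' @export
simulate_tree <- function(n_tips, seed = NULL, fossil_tips = 0L,
                          root_age = 160, birth = 0.1) {
  if (n_tips < 4L)
    stop("`n_tips` must be >= 4", call. = FALSE)
  if (fossil_tips < 0L || fossil_tips > n_tips)
    stop("`fossil_tips` must be in [0, n_tips]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = 0)
  tr$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (root_age / depth)
  if (fossil_tips > 0L) {
    tips <- sample.int(n_tips, fossil_tips)
    for (tp in tips) {
      e <- which(tr$edge[, 2] == tp)
      tr$edge.length[e] <- tr$edge.length[e] * (1 - runif(1, 0.1, 0.9))
    }
  }
  tr
}

#' Paint adaptive regimes on a timetree
#'
#' Places `n_shifts` mutually non-nested regime shifts (each the stem of a
#' monophyletic "subterranean" tip set) on the edges of a tree, mimicking
#' independent acquisitions of a subterranean lifestyle. One shift — the one
#' subtending the most tips — may be flagged `talpid_like`, standing for a
#' clade whose optimum exceeds the shared subterranean optimum. Placement is
#' by rejection sampling over edges with a retry cap.
#'
#' @param tree a `phylo` timetree.
#' @param n_shifts number of independent shifts (<= number of internal edges).
#' @param seed RNG seed.
#' @param talpid_shift flag the largest shift clade as `talpid_like`?
#' @param shift_edges optional explicit placement: vector of child-node ids
#'   (an entry equal to the root node paints the whole tree), bypassing the
#'   sampler.
#' @param max_tries rejection-sampling retry cap.
#' @return An object of class `regime_tree`: list with `tree`, `tip_regime`
#'   (named factor with levels background/subterranean/talpid_like),
#'   `edge_regime`, `shift_nodes` (child node of each shift edge) and
#'   `acquisitions` (named list of member tips per shift).
#' @export
paint_regimes <- function(tree, n_shifts, seed = NULL, talpid_shift = TRUE,
                          shift_edges = NULL, max_tries = 1000L) {
  ntip <- length(tree$tip.label)
  n_internal_edges <- nrow(tree$edge) - ntip
  root <- ntip + 1L
  if (is.null(shift_edges)) {
    if (n_shifts > n_internal_edges)
      stop("`n_shifts` exceeds the number of internal edges", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
  } else {
    n_shifts <- length(shift_edges)
  }
  # tip descendants per node, once
  tiplists <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tiplists[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    tiplists[[p]] <- c(tiplists[[p]], tiplists[[ch]])
  }
  if (is.null(shift_edges)) {
    candidates <- tree$edge[, 2]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      nodes <- sample(candidates, n_shifts)
      sets <- tiplists[nodes]
      if (sum(lengths(sets)) == length(unique(unlist(sets)))) { ok <- TRUE; break }
    }
    if (!ok)
      stop(structure(class = c("osteoconv_placement_failure", "error",
                               "condition"),
                     list(message = paste0("could not place ", n_shifts,
                          " non-nested shifts in ", max_tries, " tries"),
                          call = NULL)))
    shift_nodes <- nodes
  } else {
    shift_nodes <- as.integer(shift_edges)
    sets <- tiplists[shift_nodes]
    if (n_shifts > 0 &&
        sum(lengths(sets)) != length(unique(unlist(sets))))
      stop("explicit `shift_edges` are nested", call. = FALSE)
  }
  lv <- c("background", "subterranean", "talpid_like")
  tip_regime <- factor(rep("background", ntip), levels = lv)
  names(tip_regime) <- tree$tip.label
  edge_regime <- factor(rep("background", nrow(tree$edge)), levels = lv)
  acquisitions <- list()
  if (n_shifts > 0) {
    sizes <- lengths(tiplists[shift_nodes])
    talpid_idx <- if (talpid_shift) which.max(sizes) else 0L
    for (s in seq_len(n_shifts)) {
      reg <- if (s == talpid_idx) "talpid_like" else "subterranean"
      nd <- shift_nodes[s]
      members <- tiplists[[nd]]
      tip_regime[members] <- reg
      # painted edges: the shift edge plus all edges within the clade
      sub_nodes <- nd
      if (nd > ntip) {
        # all nodes inside the clade
        stack <- nd; inside <- integer(0)
        while (length(stack)) {
          cur <- stack[1]; stack <- stack[-1]
          inside <- c(inside, cur)
          kids <- tree$edge[tree$edge[, 1] == cur, 2]
          stack <- c(stack, kids)
        }
        sub_nodes <- inside
      }
      painted <- tree$edge[, 2] %in% sub_nodes
      edge_regime[painted] <- reg
      acquisitions[[sprintf("acq_%02d", s)]] <- tree$tip.label[members]
    }
    names(acquisitions) <- ifelse(seq_len(n_shifts) == talpid_idx,
                                  "acq_talpid", names(acquisitions))
  }
  structure(list(tree = tree, tip_regime = tip_regime,
                 edge_regime = edge_regime, shift_nodes = shift_nodes,
                 acquisitions = acquisitions),
            class = "regime_tree")
}

#' @export
print.regime_tree <- function(x, ...) {
  cat(sprintf("regime_tree: %d tips, %d independent shifts (%s talpid-like)\n",
              length(x$tree$tip.label), length(x$shift_nodes),
              if (any(x$tip_regime == "talpid_like")) "one" else "no"))
  print(table(x$tip_regime))
  invisible(x)
}

#' Trait-evolution simulation settings
#'
#' Validated container for [simulate_traits()]: Brownian motion (`BM`) or a
#' multi-optimum Ornstein-Uhlenbeck process (`OU`) whose optimum differs by
#' painted regime. Under BM, `alpha` and `theta` are ignored.
#'
#' @param model `"BM"` or `"OU"`.
#' @param sigma2 diffusion rate (trait^2 / Ma), > 0.
#' @param alpha OU pull strength (1/Ma), >= 0; 0 reduces to BM.
#' @param theta named vector of optima by regime (background, subterranean,
#'   talpid_like), OU only.
#' @param root_state trait value at the root.
#' @param seed RNG seed.
#' @return An object of class `trait_sim_config`.
#' @export
trait_sim_config <- function(model = c("BM", "OU"), sigma2, alpha = 0,
                             theta = NULL, root_state = 0, seed = NULL) {
  model <- match.arg(model)
  if (!is.numeric(sigma2) || sigma2 <= 0)
    stop("`sigma2` must be > 0", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (model == "OU" && alpha > 0 && is.null(theta))
    stop("OU with alpha > 0 needs `theta`", call. = FALSE)
  structure(list(model = model, sigma2 = sigma2, alpha = alpha, theta = theta,
                 root_state = root_state, seed = seed),
            class = "trait_sim_config")
}

#' Simulate trait evolution along a timetree
#'
#' Recursive simulation along branches. BM: the child state is the parent
#' state plus a Normal(0, sigma2 * t) increment. OU: the exact transition is
#' used — mean `theta + (parent - theta) * exp(-alpha * t)` and variance
#' `sigma2 * (1 - exp(-2 * alpha * t)) / (2 * alpha)` — so there is no
#' discretization error. With a `regime_tree`, each branch uses the optimum of
#' its painted regime.
#'
#' @param x a `phylo` tree or a [paint_regimes()] `regime_tree`.
#' @param config a [trait_sim_config()]; alternatively pass `sigma2` etc.
#'   directly via `...`.
#' @param n_sim number of independent replicate datasets.
#' @param ... used to build a `trait_sim_config` when `config` is missing.
#' @return Named numeric vector of tip states (`n_sim = 1`) or a matrix with
#'   one column per replicate.
#' @export
simulate_traits <- function(x, config = NULL, n_sim = 1L, ...) {
  if (is.null(config)) config <- trait_sim_config(...)
  stopifnot(inherits(config, "trait_sim_config"))
  if (inherits(x, "regime_tree")) {
    tree <- x$tree
    edge_regime <- as.character(x$edge_regime)
  } else {
    tree <- x
    edge_regime <- rep("background", nrow(tree$edge))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  # carry the regime painting through the reorder by matching edges
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  po_regime <- edge_regime[match(paste(po$edge[, 1], po$edge[, 2]), key)]
  states <- matrix(NA_real_, nrow = ntot, ncol = n_sim)
  states[ntip + 1L, ] <- config$root_state
  th <- config$theta
  use_ou <- config$model == "OU" && config$alpha > 0
  for (e in rev(seq_len(nrow(po$edge)))) { # reverse postorder = preorder
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    t_e <- po$edge.length[e]
    parent_state <- states[p, ]
    if (use_ou) {
      reg <- po_regime[e]
      theta_e <- th[[reg]]
      if (is.null(theta_e) || is.na(theta_e))
        stop("no optimum for regime ", reg, call. = FALSE)
      w <- exp(-config$alpha * t_e)
      m <- theta_e + (parent_state - theta_e) * w
      v <- config$sigma2 * (1 - exp(-2 * config$alpha * t_e)) /
        (2 * config$alpha)
    } else {
      m <- parent_state
      v <- config$sigma2 * t_e
    }
    states[ch, ] <- m + rnorm(n_sim, 0, sqrt(v))
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  if (n_sim == 1L) out[, 1] else out
}
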
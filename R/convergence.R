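#' Maximum-likelihood ancestral states under Brownian motion
#'
#' ML (equivalently GLS) reconstruction of internal-node states for a
#' continuous trait evolving by Brownian motion, computed by Gaussian message
#' passing on the tree in linear time. The root state equals the BM ML root
#' estimate; tip states are the observations.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param traits named numeric vector covering all tips.
#' @return Named numeric vector of states for all nodes (tip labels, then
#'   internal node numbers in `ape` order; the root is `ntip + 1`).
#' @export
asr_bm <- function(tree, traits) {
  ntip <- length(tree$tip.label)
  if (!all(tree$tip.label %in% names(traits)))
    stop("`traits` must cover every tip", call. = FALSE)
  x <- as.numeric(traits[tree$tip.label])
  if (anyNA(x)) stop("missing trait values", call. = FALSE)
  if (any(tree$edge.length <= 0)) {
    pend <- tree$edge[, 2] <= ntip
    bad <- tree$edge.length <= 0
    if (any(bad & !pend))
      stop("zero-length internal edges", call. = FALSE)
    warning("zero-length pendant edges perturbed by 1e-8")
    tree$edge.length[bad] <- 1e-8
  }
  po <- ape::reorder.phylo(tree, "postorder")
  st <- cpp_asr_bm(po$edge, po$edge.length, ntip, tree$Nnode, x)
  names(st) <- c(tree$tip.label,
                 as.character((ntip + 1L):(ntip + tree$Nnode)))
  st
}

#' Collapse independent acquisitions to single tips
#'
#' For the convergence test, each independent acquisition of the derived
#' lifestyle is represented by one tip: the members of each acquisition clade
#' are replaced by a single tip hanging from the clade's stem, with tip height
#' equal to the mean member tip height and trait value equal to the arithmetic
#' mean of the members' (size-corrected) values. Background tips are kept
#' unchanged. Acquisition memberships must not overlap and each must form a
#' clade (singletons trivially do).
#'
#' @param tree a `phylo` timetree.
#' @param clade_map named list: acquisition name -> character vector of member
#'   tips.
#' @param traits named numeric vector of (size-corrected) trait values for all
#'   tips of `tree` that survive the collapse (members and background).
#' @param allow_paraphyletic accept member sets that are not monophyletic,
#'   using the first member as the representative stem? Default `FALSE`.
#' @return An object of class `collapsed_tree`: list with `tree` (one tip per
#'   acquisition plus background tips), `traits`, `acquisitions` (names) and
#'   `members`.
#' @export
collapse_acquisitions <- function(tree, clade_map, traits,
                                  allow_paraphyletic = FALSE) {
  stopifnot(is.list(clade_map), !is.null(names(clade_map)))
  members_all <- unlist(clade_map, use.names = FALSE)
  if (anyDuplicated(members_all))
    stop(structure(class = c("osteoconv_invalid_map", "error", "condition"),
                   list(message = "overlapping acquisition memberships",
                        call = NULL)))
  if (!all(members_all %in% tree$tip.label))
    stop("acquisition members absent from the tree", call. = FALSE)
  h <- node_heights(tree)
  ntip <- length(tree$tip.label)
  tip_h <- setNames(h[seq_len(ntip)], tree$tip.label)
  out <- tree
  new_traits <- traits
  for (acq in names(clade_map)) {
    mem <- clade_map[[acq]]
    if (length(mem) > 1L) {
      mrca <- ape::getMRCA(out, mem)
      clade_tips <- ape::extract.clade(out, mrca)$tip.label
      if (!setequal(clade_tips, mem)) {
        if (!allow_paraphyletic)
          stop(structure(class = c("osteoconv_invalid_map", "error",
                                   "condition"),
                         list(message = paste0("acquisition `", acq,
                              "` is not monophyletic"), call = NULL)))
      }
      keep <- mem[1]
      out <- ape::drop.tip(out, setdiff(mem, keep))
    } else keep <- mem
    # set the representative's height to the mean member height, then relabel
    i <- match(keep, out$tip.label)
    e <- which(out$edge[, 2] == i)
    hh <- ape::node.depth.edgelength(out)
    parent_h <- hh[out$edge[e, 1]]
    target_h <- mean(tip_h[clade_map[[acq]]])
    if (target_h <= parent_h)
      stop("mean member height falls below the stem of `", acq, "`",
           call. = FALSE)
    out$edge.length[e] <- target_h - parent_h
    out$tip.label[i] <- acq
    new_traits <- new_traits[setdiff(names(new_traits), clade_map[[acq]])]
    new_traits[acq] <- mean(traits[clade_map[[acq]]])
  }
  missing <- setdiff(out$tip.label, names(new_traits))
  if (length(missing))
    stop("no trait value for: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  structure(list(tree = out, traits = new_traits[out$tip.label],
                 acquisitions = names(clade_map), members = clade_map),
            class = "collapsed_tree")
}

#' @export
print.collapsed_tree <- function(x, ...) {
  cat(sprintf("collapsed_tree: %d tips, %d acquisitions (%s)\n",
              length(x$tree$tip.label), length(x$acquisitions),
              paste(head(x$acquisitions, 6), collapse = ", ")))
  invisible(x)
}

# Per-pair path encoding for the C1 kernels: for each focal pair, the node
# paths from each tip back to (and including) their MRCA, flattened.
c1_paths <- function(tree, focal_idx) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  chain <- function(i) {
    out <- i
    while (i != root) { i <- parent[i]; out <- c(out, i) }
    out
  }
  chains <- lapply(focal_idx, chain)
  pairs <- utils::combn(seq_along(focal_idx), 2)
  nodes <- integer(0); starts <- 1L
  labs <- matrix("", ncol(pairs), 2)
  for (q in seq_len(ncol(pairs))) {
    ci <- chains[[pairs[1, q]]]; cj <- chains[[pairs[2, q]]]
    common <- intersect(ci, cj)
    mrca <- common[1] # chains are tipward->rootward; first shared node
    pi <- ci[seq_len(match(mrca, ci))]
    pj <- cj[seq_len(match(mrca, cj))]
    nodes <- c(nodes, pi, pj)
    starts <- c(starts, starts[length(starts)] + length(pi),
                starts[length(starts)] + length(pi) + length(pj))
    labs[q, ] <- tree$tip.label[focal_idx[pairs[, q]]]
  }
  list(nodes = nodes, starts = starts, npair = ncol(pairs), labs = labs)
}

#' Univariate C1 convergence statistic
#'
#' For each pair of focal tips, `Dtip` is the absolute difference of their
#' (size-corrected) trait values and `Dmax` the maximum absolute difference
#' between any two ancestral states on the paths from each tip back to their
#' MRCA (tip and MRCA states included, so `Dmax >= Dtip`); ancestral states
#' are ML reconstructions under Brownian motion on the whole tree. The
#' statistic aggregates over pairs as `C1 = 1 - sum(Dtip) / sum(Dmax)`: 1 is
#' complete convergence, 0 means the focal tips are as distinct now as their
#' lineages ever were. Including tip states among the `Dmax` candidates fixes
#' the C1 = 0 baseline for lineages that only ever diverged.
#'
#' @param x a [collapse_acquisitions()] `collapsed_tree`, or a `phylo` tree
#'   (then supply `traits`).
#' @param focal_tips tips measured for convergence; default: the acquisitions
#'   of a collapsed tree.
#' @param traits named trait vector (ignored for a collapsed tree).
#' @return An object of class `c1_test` with `c1`, `per_pair` (data.frame:
#'   tip_i, tip_j, Dtip, Dmax) and the reconstructed `states`.
#' @export
c1_statistic <- function(x, focal_tips = NULL, traits = NULL) {
  if (inherits(x, "collapsed_tree")) {
    tree <- x$tree; traits <- x$traits
    if (is.null(focal_tips)) focal_tips <- x$acquisitions
  } else tree <- x
  if (is.null(focal_tips) || length(focal_tips) < 2L)
    stop("need at least 2 focal tips", call. = FALSE)
  if (!all(focal_tips %in% tree$tip.label))
    stop("focal tips absent from the tree", call. = FALSE)
  st <- asr_bm(tree, traits)
  enc <- c1_paths(tree, match(focal_tips, tree$tip.label))
  dd <- cpp_c1_pairs(unname(st), enc$nodes, enc$starts, enc$npair)
  per_pair <- data.frame(tip_i = enc$labs[, 1], tip_j = enc$labs[, 2],
                         Dtip = dd[, 1], Dmax = dd[, 2])
  if (sum(per_pair$Dmax) <= 0)
    stop(structure(class = c("osteoconv_undefined_c1", "error", "condition"),
                   list(message = "all ancestral states identical: C1 undefined",
                        call = NULL)))
  structure(list(c1 = 1 - sum(per_pair$Dtip) / sum(per_pair$Dmax),
                 per_pair = per_pair, focal_tips = focal_tips,
                 states = st, tree = tree, traits = traits),
            class = "c1_test")
}

#' Simulation-based significance of C1
#'
#' Estimates the Brownian rate from the observed traits on the (collapsed)
#' tree by REML (mean squared phylogenetically independent contrast), then
#' simulates `n_sim` Brownian datasets from the ML root state, recomputes C1
#' on each, and reports `p = (count of simulated C1 >= observed + 1) /
#' (n_valid + 1)`. Replicates with undefined C1 are dropped and counted; a
#' warning is raised when more than 10% are dropped.
#'
#' @inheritParams c1_statistic
#' @param n_sim number of Brownian null datasets (>= 100).
#' @param seed RNG seed; same seed gives the same p.
#' @return A `c1_test` with additional `p_value`, `n_sim`, `n_dropped`,
#'   `sigma2`, `seed` and `sim_c1` components.
#' @export
c1_significance <- function(x, focal_tips = NULL, n_sim = 1000L, seed = NULL,
                            traits = NULL) {
  if (n_sim < 100L) stop("`n_sim` must be >= 100", call. = FALSE)
  obs <- c1_statistic(x, focal_tips, traits)
  tree <- obs$tree
  ntip <- length(tree$tip.label)
  pics <- ape::pic(obs$traits[tree$tip.label], tree)
  sigma2 <- mean(pics^2) # REML estimate of the Brownian rate
  root_state <- unname(obs$states[ntip + 1L])
  if (!is.null(seed)) set.seed(seed)
  sims <- simulate_traits(tree, trait_sim_config(
    model = "BM", sigma2 = sigma2, root_state = root_state), n_sim = n_sim)
  po <- ape::reorder.phylo(tree, "postorder")
  enc <- c1_paths(tree, match(obs$focal_tips, tree$tip.label))
  sim_c1 <- cpp_c1_batch(po$edge, po$edge.length, ntip, tree$Nnode,
                         sims[tree$tip.label, , drop = FALSE],
                         enc$nodes, enc$starts, enc$npair)
  n_dropped <- sum(is.na(sim_c1))
  if (n_dropped > 0.1 * n_sim)
    warning(n_dropped, " of ", n_sim, " null replicates had undefined C1")
  valid <- sim_c1[!is.na(sim_c1)]
  obs$p_value <- (sum(valid >= obs$c1) + 1) / (length(valid) + 1)
  obs$n_sim <- n_sim
  obs$n_dropped <- n_dropped
  obs$sigma2 <- sigma2
  obs$seed <- seed
  obs$sim_c1 <- sim_c1
  obs
}

#' @export
print.c1_test <- function(x, ...) {
  cat(sprintf("C1 convergence test: %d focal tips, %d pairs\n",
              length(x$focal_tips), nrow(x$per_pair)))
  cat(sprintf("  C1 = %.4f (sum Dtip = %.4g, sum Dmax = %.4g)\n", x$c1,
              sum(x$per_pair$Dtip), sum(x$per_pair$Dmax)))
  if (!is.null(x$p_value))
    cat(sprintf("  p = %.4g (%d BM simulations, %d dropped, sigma2 = %.4g)\n",
                x$p_value, x$n_sim, x$n_dropped, x$sigma2))
  invisible(x)
}
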
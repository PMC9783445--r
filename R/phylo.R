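#' Read and write timetrees
#'
#' Thin wrappers around `ape`'s Newick parser that enforce the contracts the
#' comparative analyses rely on: branch lengths present and positive, binary
#' topology (polytomies are rejected — a lambda covariance matrix on an
#' unresolved tree would be silently ambiguous), unique tip labels.
#' Non-ultrametric trees (fossil tips ending above the present) are allowed.
#'
#' @param x a Newick string or the path of a Newick file.
#' @return `read_timetree`: an `ape` `phylo` object with branch lengths in Ma.
#' @export
read_timetree <- function(x) {
  tr <- if (length(x) == 1L && grepl("[();]", x))
    ape::read.tree(text = x)
  else ape::read.tree(x)
  if (is.null(tr)) stop("could not parse Newick input", call. = FALSE)
  validate_timetree(tr)
  tr
}

#' @rdname read_timetree
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return `write_timetree`: the Newick string (invisibly when writing to a
#'   file).
#' @export
write_timetree <- function(tree, file = NULL) {
  s <- ape::write.tree(tree, digits = 12)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

validate_timetree <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length) || any(tree$edge.length <= 0))
    stop("all branch lengths must be positive", call. = FALSE)
  if (!ape::is.binary.phylo(tree))
    stop("polytomies are not supported; resolve the tree first",
         call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels", call. = FALSE)
  invisible(tree)
}

#' Node heights, root age and tip ages
#'
#' Heights are root-to-node path lengths; ages are Ma before present, with the
#' present defined by the highest tip. Fossil tips therefore have positive
#' ages.
#'
#' @param tree a `phylo` timetree.
#' @return `node_heights`: numeric vector over all nodes (tips first, in `ape`
#'   numbering). `tip_ages`: named vector of tip ages (0 for extant tips).
#'   `root_age`: scalar.
#' @export
node_heights <- function(tree) ape::node.depth.edgelength(tree)

#' @rdname node_heights
#' @export
root_age <- function(tree) {
  h <- node_heights(tree)
  max(h[seq_along(tree$tip.label)])
}

#' @rdname node_heights
#' @export
tip_ages <- function(tree) {
  h <- node_heights(tree)
  ntip <- length(tree$tip.label)
  setNames(max(h[seq_len(ntip)]) - h[seq_len(ntip)], tree$tip.label)
}

# age (Ma before present) of every node
node_ages <- function(tree) {
  h <- node_heights(tree)
  max(h[seq_along(tree$tip.label)]) - h
}

#' Recalibrate a divergence
#'
#' Moves the most recent common ancestor of two tips to a new age, adjusting
#' only the branches adjacent to that node; all other node ages are unchanged.
#' Used e.g. to replace a source-tree divergence with an external calibration
#' before grafting a fossil whose age conflicts with the original divergence.
#'
#' @param tree a `phylo` timetree.
#' @param tip_a,tip_b tip labels spanning the divergence.
#' @param new_age new age of their MRCA, in Ma before present. Must be older
#'   than both child nodes of the MRCA and younger than its parent.
#' @return The recalibrated tree.
#' @export
recalibrate_divergence <- function(tree, tip_a, tip_b, new_age) {
  validate_timetree(tree)
  m <- ape::getMRCA(tree, c(tip_a, tip_b))
  ages <- node_ages(tree)
  child_edges <- which(tree$edge[, 1] == m)
  child_ages <- ages[tree$edge[child_edges, 2]]
  parent_edge <- which(tree$edge[, 2] == m)
  calib_conflict <- function(msg)
    stop(structure(class = c("osteoconv_calibration_conflict", "error",
                             "condition"),
                   list(message = msg, call = NULL)))
  if (new_age <= max(child_ages))
    calib_conflict(sprintf(
      "new age %.3f Ma is not older than the node's children (%.3f Ma)",
      new_age, max(child_ages)))
  if (length(parent_edge)) {
    parent_age <- ages[tree$edge[parent_edge, 1]]
    if (new_age >= parent_age)
      calib_conflict(sprintf(
        "new age %.3f Ma is not younger than the parent node (%.3f Ma)",
        new_age, parent_age))
    tree$edge.length[parent_edge] <- parent_age - new_age
  }
  tree$edge.length[child_edges] <- new_age - child_ages
  tree
}

#' Graft a fossil tip onto a timetree
#'
#' Attaches a fossil of known age to the stem branch of a host clade (given by
#' one tip or by two spanning tips). Two placement rules are supported,
#' matching the common ways of handling topological uncertainty:
#'
#' * `rule = list(fraction = f)`: the divergence with the fossil is placed at
#'   a fraction `f` of the stem-branch length, measured from the older
#'   (rootward) end of that branch.
#' * `rule = list(push_node = delta)`: the divergence is placed at
#'   `fossil_age + delta` Ma — older than the host crown where needed to
#'   accommodate the fossil (so the fossil's terminal branch is exactly
#'   `delta` Ma).
#' * `rule = list(midpoint = TRUE)`: the divergence is placed halfway between
#'   the older end of the stem branch and the fossil's age.
#' * `rule = list(age = a)`: explicit divergence age.
#'
#' The fossil's terminal branch length is `divergence age - fossil_age` and
#' must be positive.
#'
#' @param tree a `phylo` timetree.
#' @param name fossil tip label.
#' @param age fossil tip age, Ma before present.
#' @param tips one tip label (graft on its terminal branch) or two labels
#'   (graft on the stem branch of their MRCA clade).
#' @param rule `list(fraction = f)` with `f` in (0, 1), or
#'   `list(push_node = delta)` with `delta > 0`.
#' @return The tree with the fossil tip added.
#' @export
graft_fossil <- function(tree, name, age, tips,
                         rule = list(fraction = 0.05)) {
  validate_timetree(tree)
  if (name %in% tree$tip.label)
    stop("tip `", name, "` already present", call. = FALSE)
  m <- if (length(tips) == 1L) match(tips, tree$tip.label)
       else ape::getMRCA(tree, tips)
  if (is.na(m) || is.null(m)) stop("attachment tips not found", call. = FALSE)
  ages <- node_ages(tree)
  stem_edge <- which(tree$edge[, 2] == m)
  if (!length(stem_edge))
    stop("cannot graft on the root stem; supply an ingroup clade",
         call. = FALSE)
  age_m <- ages[m]
  age_parent <- ages[tree$edge[stem_edge, 1]]
  calib_conflict <- function(msg)
    stop(structure(class = c("osteoconv_calibration_conflict", "error",
                             "condition"),
                   list(message = msg, call = NULL)))
  if (!is.null(rule$fraction)) {
    f <- rule$fraction
    if (f <= 0 || f >= 1)
      stop("`fraction` must be in (0, 1)", call. = FALSE)
    div_age <- age_parent - f * (age_parent - age_m)
  } else if (!is.null(rule$push_node)) {
    if (rule$push_node <= 0)
      stop("`push_node` must be > 0", call. = FALSE)
    div_age <- age + rule$push_node
    if (div_age <= age_m)
      calib_conflict(sprintf(
        "pushed divergence (%.3f Ma) is not older than the host node (%.3f Ma)",
        div_age, age_m))
  } else if (isTRUE(rule$midpoint)) {
    div_age <- (age_parent + age) / 2
  } else if (!is.null(rule$age)) {
    div_age <- rule$age
  } else stop("`rule` must contain `fraction`, `push_node`, `midpoint` or `age`",
              call. = FALSE)
  if (div_age >= age_parent)
    calib_conflict(sprintf(
      "divergence age %.3f Ma reaches the parent node (%.3f Ma)",
      div_age, age_parent))
  if (div_age <= age)
    calib_conflict(sprintf(
      "fossil age %.3f Ma is older than its divergence (%.3f Ma)",
      age, div_age))
  tip_tree <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                             tip.label = name,
                             edge.length = div_age - age, Nnode = 1L),
                        class = "phylo")
  out <- ape::bind.tree(tree, tip_tree, where = m, position = div_age - age_m)
  validate_timetree(out)
  out
}

#' Lambda-scaled phylogenetic covariance matrix
#'
#' The Brownian covariance of two tips is the shared root-to-MRCA path length;
#' the variance of a tip is its root-to-tip height. Pagel's lambda multiplies
#' the off-diagonal entries only, so on a non-ultrametric tree the diagonal
#' keeps the unequal tip heights — the source of the variance-heterogeneity
#' weights used by [pgls_fit()].
#'
#' @param tree a `phylo` timetree with uniquely named tips.
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @return The species covariance matrix (tips in `tree$tip.label` order).
#' @export
phylo_vcv <- function(tree, lambda = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("`lambda` must be a single value in [0, 1]", call. = FALSE)
  V <- ape::vcv(tree)
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

#' Report tree/table taxon mismatches
#'
#' Exact, case-sensitive matching between tree tip labels and a species
#' column; returns the shared species and messages listing what is missing on
#' either side.
#'
#' @param tree a `phylo` object.
#' @param species character vector of species names.
#' @return List with `shared`, `only_tree`, `only_data`.
#' @export
match_taxa <- function(tree, species) {
  shared <- intersect(tree$tip.label, species)
  list(shared = shared,
       only_tree = setdiff(tree$tip.label, species),
       only_data = setdiff(species, tree$tip.label))
}
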
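# Shared fixture builders and independent oracles. Everything is generated in
# code; no binary fixtures.

# balanced three-tip tree used across the phylo tests
toy_tree3 <- function() read_timetree("((A:1,B:1):1,C:2);")

# rasterized sphere of diameter d voxels, centred in a cube
sphere_volume <- function(d, pad = 8L, voxel_size = 0.01) {
  n <- as.integer(ceiling(d) + 2L * pad)
  cc <- (n - 1) / 2
  ax <- (seq_len(n) - 1 - cc)^2
  arr <- outer(outer(ax, ax, `+`), ax, `+`) <= (d / 2)^2
  voxel_volume(array(arr, dim = c(n, n, n)), voxel_size, binary = TRUE)
}

# Independent BM ancestral-state oracle: GLS reconstruction from the joint
# covariance (shared path lengths via ape::mrca), no message passing.
asr_bm_oracle <- function(tree, x) {
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  h <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  S <- matrix(h[M], ntot, ntot) # shared path length for every node pair
  x <- x[tree$tip.label]
  Vtt <- S[1:ntip, 1:ntip]
  anc_idx <- (ntip + 1L):ntot
  one <- rep(1, ntip)
  Vi <- solve(Vtt)
  mu <- as.numeric((one %*% Vi %*% x) / (one %*% Vi %*% one))
  st <- rep(NA_real_, ntot)
  st[1:ntip] <- x
  for (a in anc_idx) {
    va <- S[a, 1:ntip]
    st[a] <- mu + as.numeric(va %*% Vi %*% (x - mu))
  }
  st
}

# Exhaustive C1 oracle: oracle ancestral states + ape::nodepath enumeration.
c1_oracle <- function(tree, traits, focal_tips) {
  st <- asr_bm_oracle(tree, traits)
  idx <- match(focal_tips, tree$tip.label)
  pairs <- utils::combn(idx, 2)
  sdt <- 0; sdm <- 0
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    m <- ape::getMRCA(tree, c(i, j))
    pi <- ape::nodepath(tree, i, m)
    pj <- ape::nodepath(tree, j, m)
    sdt <- sdt + abs(st[i] - st[j])
    sdm <- sdm + max(abs(outer(st[pi], st[pj], `-`)))
  }
  1 - sdt / sdm
}

# random tree with strictly positive branch lengths
rtree_pos <- function(n, min_len = 0.1) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + min_len
  tr
}
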
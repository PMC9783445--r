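#' Voxel volumes
#'
#' A `voxel_volume` wraps a 3-D numeric or logical array together with its
#' isotropic voxel size (mm). Binary volumes (`binary = TRUE`) hold bone as
#' `TRUE`/1; grayscale volumes must be binarized (see [binarize()]) before any
#' microanatomical quantity is computed.
#'
#' @param grid 3-D array (numeric or logical).
#' @param voxel_size isotropic voxel edge length in mm (> 0).
#' @param binary logical; is the volume already thresholded? Defaults to
#'   `TRUE` when `grid` is logical or contains only values 0/1.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(grid, voxel_size, binary = NULL) {
  if (length(dim(grid)) != 3L)
    stop("`grid` must be a 3-D array", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (mm)", call. = FALSE)
  if (is.null(binary)) {
    u <- unique(as.vector(grid))
    binary <- is.logical(grid) || all(u %in% c(0, 1))
  }
  structure(list(grid = grid, voxel_size = voxel_size, binary = isTRUE(binary)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("voxel_volume: %d x %d x %d voxels, %.4g mm/voxel, %s\n",
              d[1], d[2], d[3], x$voxel_size,
              if (x$binary) sprintf("binary (BV/TV = %.3f)", mean(x$grid > 0))
              else "grayscale"))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$grid)

#' Volume of interest specification
#'
#' Describes a cubic or spherical sub-volume in which epiphyseal parameters
#' (BV/TV, mean Tb.Th) are measured. Coordinates are 0-based voxel indices and
#' cube bounds are half-open, so a cube of extent `e` mm covers
#' `round(e / voxel_size)` voxels per axis. Specimens whose VOI intersects the
#' epiphyseal line are flagged for exclusion upstream of any quantification
#' (`epiphyseal_line = TRUE` makes the measurement functions signal a
#' condition of class `"osteoconv_voi_excluded"`).
#'
#' @param center numeric length-3, VOI centre in 0-based voxel coordinates.
#' @param extent edge length (cube) or diameter (sphere), in mm.
#' @param shape `"cube"` or `"sphere"`.
#' @param epiphyseal_line logical exclusion flag supplied by the operator.
#' @return An object of class `voi_spec`.
#' @export
voi_spec <- function(center, extent, shape = c("cube", "sphere"),
                     epiphyseal_line = FALSE) {
  shape <- match.arg(shape)
  if (length(center) != 3L || !is.numeric(center))
    stop("`center` must be numeric length 3", call. = FALSE)
  if (!is.numeric(extent) || length(extent) != 1L || extent <= 0)
    stop("`extent` must be a single positive number (mm)", call. = FALSE)
  structure(list(center = as.numeric(center), extent = extent, shape = shape,
                 epiphyseal_line = isTRUE(epiphyseal_line)),
            class = "voi_spec")
}

# 0-based voxel index ranges (per axis) and a logical mask for a VOI.
# Errors when the VOI is not fully inside the volume.
voi_mask <- function(volume, voi) {
  d <- dim(volume$grid)
  half_vox <- voi$extent / volume$voxel_size / 2
  lo <- ceiling(voi$center - half_vox + 1e-9)
  hi <- floor(voi$center + half_vox - 1e-9)
  if (any(lo < 0) || any(hi > d - 1L))
    stop("VOI extends outside the volume", call. = FALSE)
  idx <- lapply(1:3, function(a) (lo[a]:hi[a]) + 1L) # to 1-based
  if (voi$shape == "cube") {
    mask <- array(TRUE, dim = hi - lo + 1L)
  } else {
    r <- voi$extent / volume$voxel_size / 2
    gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
    dx2 <- (gx - voi$center[1])^2
    dy2 <- (gy - voi$center[2])^2
    dz2 <- (gz - voi$center[3])^2
    mask <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
  }
  list(idx = idx, mask = mask)
}

voi_excluded_error <- function() {
  stop(structure(class = c("osteoconv_voi_excluded", "error", "condition"),
                 list(message = paste0(
                   "VOI intersects the epiphyseal line; specimen is excluded ",
                   "from quantitative analysis"), call = NULL)))
}

check_binary <- function(volume) {
  if (!inherits(volume, "voxel_volume"))
    stop("expected a `voxel_volume`", call. = FALSE)
  if (!volume$binary)
    stop("volume must be binarized first (see `binarize()`)", call. = FALSE)
}

#' Otsu threshold of a grayscale sample
#'
#' Maximizes the between-class variance of the two-class split of the
#' intensity histogram (256 bins over the observed range).
#'
#' @param values numeric vector of voxel intensities.
#' @param n_bins number of histogram bins.
#' @return The threshold value; voxels `>=` threshold are classed as bone.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("empty intensity sample", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(h); m <- cumsum(h * mids)
  n <- w[n_bins]; mtot <- m[n_bins]
  w0 <- w[-n_bins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[-n_bins] / w0
  mu1 <- (mtot - m[-n_bins]) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  k <- which.max(bcv)
  # threshold between the two classes: upper edge of bin k
  breaks[k + 1L]
}

#' Binarize a grayscale voxel volume
#'
#' Voxels with intensity greater than or equal to the threshold are classed as
#' bone. With `threshold = "otsu"` the threshold maximizing the between-class
#' variance of the intensity histogram is computed on the volume itself (pass
#' the extracted VOI sub-stack to threshold per-VOI).
#'
#' @param volume a grayscale `voxel_volume`.
#' @param threshold numeric threshold, or `"otsu"` (default).
#' @return A binary `voxel_volume` with attribute `"threshold"`.
#' @export
binarize <- function(volume, threshold = "otsu") {
  if (!inherits(volume, "voxel_volume"))
    stop("expected a `voxel_volume`", call. = FALSE)
  if (volume$binary)
    stop("volume is already binary", call. = FALSE)
  vals <- as.vector(volume$grid)
  if (identical(threshold, "otsu")) {
    threshold <- otsu_threshold(vals)
  } else if (!is.numeric(threshold) || length(threshold) != 1L) {
    stop("`threshold` must be a single number or \"otsu\"", call. = FALSE)
  } else if (threshold < min(vals) || threshold > max(vals)) {
    stop("numeric threshold outside the grayscale range", call. = FALSE)
  }
  out <- voxel_volume(array(volume$grid >= threshold, dim = dim(volume$grid)),
                      volume$voxel_size, binary = TRUE)
  attr(out, "threshold") <- threshold
  out
}

#' Extract a VOI sub-stack
#'
#' @param volume a `voxel_volume`.
#' @param voi a [voi_spec()]. For spherical VOIs voxels outside the sphere are
#'   set to `NA` in the returned grid.
#' @return A `voxel_volume` covering the VOI bounding box.
#' @export
voi_extract <- function(volume, voi) {
  vm <- voi_mask(volume, voi)
  sub <- volume$grid[vm$idx[[1]], vm$idx[[2]], vm$idx[[3]], drop = FALSE]
  if (voi$shape == "sphere") sub[!vm$mask] <- NA
  voxel_volume(sub, volume$voxel_size, binary = volume$binary)
}

#' Capitulum VOI centre from operator landmarks
#'
#' Reproduces the landmark protocol for placing the distal-epiphysis VOI:
#' the proximodistal (z) position is the midpoint of the capitulum's
#' proximodistal extremes; the in-plane position is the centre of the
#' rectangle bounded anteriorly and laterally by the capitulum edges, medially
#' by the point of maximal concavity of the anterior articular surface (the
#' capitulum/trochlea junction), and posteriorly by the maximal posterior
#' extension at the mediolateral middle.
#'
#' @param landmarks a list with numeric fields `lateral`, `medial` (x bounds),
#'   `anterior`, `posterior` (y bounds), `proximal`, `distal` (z extremes),
#'   all in voxel coordinates.
#' @return Numeric length-3 `(x, y, z)` VOI centre.
#' @export
capitulum_voi_center <- function(landmarks) {
  need <- c("lateral", "medial", "anterior", "posterior", "proximal", "distal")
  miss <- setdiff(need, names(landmarks))
  if (length(miss))
    stop("missing landmarks: ", paste(miss, collapse = ", "), call. = FALSE)
  lm <- lapply(landmarks[need], as.numeric)
  if (lm$lateral == lm$medial || lm$anterior == lm$posterior)
    stop("degenerate bounding rectangle (zero width)", call. = FALSE)
  z <- (lm$proximal + lm$distal) / 2
  x <- (lm$lateral + lm$medial) / 2
  y <- (lm$anterior + lm$posterior) / 2
  c(x = unname(x), y = unname(y), z = unname(z))
}

#' Bone volume fraction (BV/TV)
#'
#' Ratio of bone voxels to total voxels inside the VOI of a binary volume.
#'
#' @param volume a binary `voxel_volume`.
#' @param voi a [voi_spec()], or `NULL` to use the whole volume.
#' @return BV/TV in `[0, 1]`.
#' @export
bone_volume_fraction <- function(volume, voi = NULL) {
  check_binary(volume)
  if (is.null(voi)) return(mean(volume$grid > 0))
  if (voi$epiphyseal_line) voi_excluded_error()
  vm <- voi_mask(volume, voi)
  sub <- volume$grid[vm$idx[[1]], vm$idx[[2]], vm$idx[[3]], drop = FALSE]
  mean(sub[vm$mask] > 0)
}

#' Local thickness map
#'
#' Model-independent local thickness: the value at each bone voxel is the
#' diameter (mm) of the largest sphere fully contained in bone that contains
#' the voxel, computed from the exact Euclidean distance transform followed by
#' sphere painting from (ridge-filtered) candidate centres. Structures
#' touching the volume faces are not eroded by the border: distances are
#' measured to actual background voxels only.
#'
#' @param volume a binary `voxel_volume`.
#' @return A `voxel_volume` (grayscale) holding the thickness map in mm;
#'   background voxels are 0.
#' @export
local_thickness_map <- function(volume) {
  check_binary(volume)
  g <- volume$grid > 0
  edt <- cpp_edt_sq(as.vector(g), dim(g))
  th <- cpp_local_thickness(edt, dim(g))
  if (any(is.infinite(edt)))
    warning("volume has no background voxels; thickness is undefined (Inf)")
  arr <- array(th * volume$voxel_size, dim = dim(g))
  arr[is.infinite(array(edt, dim = dim(g)))] <- Inf
  voxel_volume(arr, volume$voxel_size, binary = FALSE)
}

#' Mean trabecular thickness (mean Tb.Th)
#'
#' Mean of the local thickness map over bone voxels inside the VOI, in mm.
#'
#' @inheritParams bone_volume_fraction
#' @param thickness_map optional precomputed [local_thickness_map()] of
#'   `volume` (computed on the full volume so spheres may extend beyond the
#'   VOI, as in the standard protocol).
#' @return Mean Tb.Th in mm.
#' @export
mean_trabecular_thickness <- function(volume, voi = NULL,
                                      thickness_map = NULL) {
  check_binary(volume)
  if (!is.null(voi) && voi$epiphyseal_line) voi_excluded_error()
  if (is.null(thickness_map)) thickness_map <- local_thickness_map(volume)
  if (is.null(voi)) {
    sel <- volume$grid > 0
    vals <- thickness_map$grid[sel]
  } else {
    vm <- voi_mask(volume, voi)
    sub_b <- volume$grid[vm$idx[[1]], vm$idx[[2]], vm$idx[[3]], drop = FALSE]
    sub_t <- thickness_map$grid[vm$idx[[1]], vm$idx[[2]], vm$idx[[3]],
                                drop = FALSE]
    sel <- (sub_b > 0) & vm$mask
    vals <- sub_t[sel]
  }
  if (length(vals) == 0L)
    stop(structure(class = c("osteoconv_no_bone", "error", "condition"),
                   list(message = "no bone voxels: thickness undefined",
                        call = NULL)))
  mean(vals)
}

#' Diaphyseal compactness profile
#'
#' Per transverse (z) slice of a binary diaphysis volume: total cross-sectional
#' area is the area enclosed by the periosteal (outer) contour, obtained by
#' morphological closing (to bridge nutrient foramina) followed by hole
#' filling; compactness is bone area divided by that total area. Slices with no
#' bone are flagged and excluded from the means.
#'
#' @param volume a binary `voxel_volume` oriented with the shaft axis along z.
#' @param slices integer vector of 1-based slice indices spanning the
#'   diaphysis; default all slices.
#' @param closing_radius radius (voxels) of the disk used for morphological
#'   closing before hole filling.
#' @return A list of class `diaphysis_profile` with elements `per_slice`
#'   (data.frame: slice, bone_area, total_area, compactness, empty),
#'   `mean_global_compactness` and `mean_total_area` (mm^2).
#' @export
diaphysis_profile <- function(volume, slices = NULL, closing_radius = 3L) {
  check_binary(volume)
  d <- dim(volume$grid)
  if (is.null(slices)) slices <- seq_len(d[3])
  if (any(slices < 1L | slices > d[3]))
    stop("`slices` outside the volume", call. = FALSE)
  brush <- if (closing_radius > 0)
    EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, shape = "disc")
  vx2 <- volume$voxel_size^2
  res <- lapply(slices, function(k) {
    sl <- volume$grid[, , k] > 0
    nb <- sum(sl)
    if (nb == 0L)
      return(data.frame(slice = k, bone_area = 0, total_area = NA_real_,
                        compactness = NA_real_, empty = TRUE))
    img <- EBImage::Image(sl * 1)
    if (closing_radius > 0) img <- EBImage::closing(img, brush)
    filled <- EBImage::fillHull(img)
    tot <- sum(EBImage::imageData(filled) > 0)
    data.frame(slice = k, bone_area = nb * vx2, total_area = tot * vx2,
               compactness = nb / tot, empty = FALSE)
  })
  per_slice <- do.call(rbind, res)
  ok <- !per_slice$empty
  if (!all(ok))
    warning(sum(!ok), " slice(s) with no bone excluded from the means")
  structure(list(per_slice = per_slice,
                 mean_global_compactness = mean(per_slice$compactness[ok]),
                 mean_total_area = mean(per_slice$total_area[ok])),
            class = "diaphysis_profile")
}

#' @export
print.diaphysis_profile <- function(x, ...) {
  cat(sprintf(paste0("diaphysis_profile: %d slices (%d empty), mean global ",
                     "compactness %.4f, mean total area %.4g mm^2\n"),
              nrow(x$per_slice), sum(x$per_slice$empty),
              x$mean_global_compactness, x$mean_total_area))
  invisible(x)
}

#' Summarize humeral microanatomy of one specimen
#'
#' Convenience wrapper producing one record with the four quantities used in
#' the comparative analyses: head BV/TV and mean Tb.Th inside the epiphyseal
#' VOI, and mean global compactness and mean total cross-sectional area over
#' the diaphyseal slices.
#'
#' @param head_volume binary `voxel_volume` of the (proximal) epiphysis.
#' @param head_voi [voi_spec()] for the head VOI.
#' @param diaphysis_volume binary `voxel_volume` of the diaphysis.
#' @param slices slice range passed to [diaphysis_profile()].
#' @return A one-row data.frame: bvtv, mean_tbth, mean_global_compactness,
#'   mean_cross_sectional_area.
#' @export
microanatomy_record <- function(head_volume, head_voi, diaphysis_volume,
                                slices = NULL) {
  prof <- diaphysis_profile(diaphysis_volume, slices)
  data.frame(
    bvtv = bone_volume_fraction(head_volume, head_voi),
    mean_tbth = mean_trabecular_thickness(head_volume, head_voi),
    mean_global_compactness = prof$mean_global_compactness,
    mean_cross_sectional_area = prof$mean_total_area)
}
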
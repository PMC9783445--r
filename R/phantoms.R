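#' Trabecular phantom specification
#'
#' Describes a synthetic voxel phantom of known ground truth, used to validate
#' the microanatomy measurements: `solid`/`empty` uniform volumes,
#' `rod_lattice` (axis-aligned cylinders of a stated diameter on a regular
#' grid, along all three axes), `plate_stack` (parallel slabs of a stated
#' thickness separated by gaps), and `grf` (smoothed Gaussian noise
#' thresholded to a target bone fraction, mimicking trabecular texture).
#'
#' @param kind one of `"solid"`, `"empty"`, `"rod_lattice"`, `"plate_stack"`,
#'   `"grf"`.
#' @param dims voxel counts per axis (scalar or length 3); at least 32 per
#'   axis so discretized measurements are meaningful.
#' @param voxel_size isotropic voxel size in mm.
#' @param element_thickness rod diameter / plate thickness / texture scale, in
#'   mm; must discretize to >= 3 voxels where it applies.
#' @param target_bvtv target bone fraction in (0, 1), `grf` only.
#' @param seed RNG seed (`grf` only); identical specs give identical volumes.
#' @param spacing centre-to-centre element spacing in mm; defaults to
#'   3 x `element_thickness` for rods and 2 x for plate periods (plate + gap).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("solid", "empty", "rod_lattice",
                                  "plate_stack", "grf"),
                         dims = 64L, voxel_size = 0.01,
                         element_thickness = NULL, target_bvtv = NULL,
                         seed = 1L, spacing = NULL) {
  kind <- match.arg(kind)
  dims <- rep(as.integer(dims), length.out = 3L)
  if (any(dims < 32L))
    stop("`dims` must be >= 32 voxels per axis", call. = FALSE)
  if (kind %in% c("rod_lattice", "plate_stack", "grf")) {
    if (is.null(element_thickness))
      stop("`element_thickness` required for kind = ", kind, call. = FALSE)
    tv <- element_thickness / voxel_size
    if (kind != "grf" && tv < 3)
      stop("`element_thickness` must be >= 3 voxels", call. = FALSE)
  }
  if (kind == "grf") {
    if (is.null(target_bvtv) || target_bvtv <= 0 || target_bvtv >= 1)
      stop("`target_bvtv` must be in (0, 1) for grf phantoms", call. = FALSE)
  }
  structure(list(kind = kind, dims = dims, voxel_size = voxel_size,
                 element_thickness = element_thickness,
                 target_bvtv = target_bvtv, seed = as.integer(seed),
                 spacing = spacing),
            class = "phantom_spec")
}

#' Generate a voxel phantom
#'
#' Realizes a [phantom_spec()] as a binary `voxel_volume`. `grf` phantoms are
#' built from white noise smoothed by a Gaussian kernel of standard deviation
#' `element_thickness / 2` and thresholded at the intensity quantile that
#' makes the achieved bone fraction match `target_bvtv` (within one voxel in
#' the count, i.e. well inside 0.01); the calibrated threshold is returned in
#' attribute `"threshold"` and the grayscale field in attribute `"grayscale"`
#' so the binarization round-trip can be checked.
#'
#' @param spec a [phantom_spec()].
#' @return A binary `voxel_volume`; attribute `"achieved_bvtv"` holds the
#'   measured bone fraction.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  vx <- spec$voxel_size
  grid <- switch(spec$kind,
    solid = array(TRUE, dim = d),
    empty = array(FALSE, dim = d),
    plate_stack = {
      t_vox <- round(spec$element_thickness / vx)
      gap <- if (is.null(spec$spacing)) t_vox
             else round(spec$spacing / vx) - t_vox
      period <- t_vox + gap
      # first gap at the face so every plate has background on both sides
      z_in_plate <- ((seq_len(d[3]) - 1L) %% period) >= gap
      array(rep(z_in_plate, each = d[1] * d[2]), dim = d)
    },
    rod_lattice = {
      t_vox <- spec$element_thickness / vx
      r <- t_vox / 2
      sp <- if (is.null(spec$spacing)) 3 * t_vox
            else spec$spacing / vx
      centers <- function(n) {
        k <- seq(ceiling(r), n - 1 - ceiling(r), by = sp)
        if (!length(k)) (n - 1) / 2 else k
      }
      g <- array(FALSE, dim = d)
      ax <- lapply(d, function(n) seq_len(n) - 1)
      mindist2 <- function(x, cs) {
        m <- rep(Inf, length(x))
        for (cc in cs) m <- pmin(m, (x - cc)^2)
        m
      }
      dx2 <- mindist2(ax[[1]], centers(d[1]))
      dy2 <- mindist2(ax[[2]], centers(d[2]))
      dz2 <- mindist2(ax[[3]], centers(d[3]))
      # rods along z: (x, y) near a grid point; likewise along x and y
      in_z <- outer(dx2, dy2, `+`) <= r^2
      in_x <- outer(dy2, dz2, `+`) <= r^2
      in_y <- outer(dx2, dz2, `+`) <= r^2
      for (k in seq_len(d[3])) {
        g[, , k] <- in_z |
          matrix(in_x[, k], nrow = d[1], ncol = d[2], byrow = TRUE) |
          matrix(in_y[, k], nrow = d[1], ncol = d[2])
      }
      g
    },
    grf = {
      set.seed(spec$seed)
      noise <- array(rnorm(prod(d)), dim = d)
      sigma <- (spec$element_thickness / vx) / 2
      sm <- gaussian_smooth3(noise, sigma)
      thr <- quantile(sm, probs = 1 - spec$target_bvtv, names = FALSE,
                      type = 1)
      out <- sm >= thr
      attr(out, "threshold") <- thr
      attr(out, "grayscale") <- sm
      out
    })
  thr <- attr(grid, "threshold")
  gray <- attr(grid, "grayscale")
  vol <- voxel_volume(array(as.vector(grid), dim = d), vx, binary = TRUE)
  attr(vol, "achieved_bvtv") <- mean(vol$grid)
  if (!is.null(thr)) attr(vol, "threshold") <- thr
  if (!is.null(gray))
    attr(vol, "grayscale") <- voxel_volume(array(gray, dim = d), vx,
                                           binary = FALSE)
  vol
}

# Separable periodic Gaussian smoothing via FFT; sigma in voxels.
gaussian_smooth3 <- function(a, sigma) {
  d <- dim(a)
  kf <- lapply(d, function(n) {
    x <- pmin(0:(n - 1), n - (0:(n - 1)))
    k <- exp(-x^2 / (2 * sigma^2))
    Re(stats::fft(k / sum(k)))
  })
  K <- outer(outer(kf[[1]], kf[[2]]), kf[[3]])
  Re(stats::fft(stats::fft(a) * K, inverse = TRUE)) / prod(d)
}

#' Hollow tube phantom
#'
#' Cylindrical annulus along z, the reference object for diaphyseal
#' compactness: the expected compactness is
#' `(r_out^2 - r_in^2) / r_out^2` and the expected total cross-sectional area
#' `pi * r_out^2 * voxel_size^2` per slice. Used in tests and examples; not
#' part of [phantom_spec()] because its ground truth is analytic rather than
#' calibrated.
#'
#' @param dims voxel counts (scalar or length 3).
#' @param r_out,r_in outer/inner radius in voxels.
#' @param voxel_size voxel size in mm.
#' @return A binary `voxel_volume`.
#' @export
tube_phantom <- function(dims = 64L, r_out = 20, r_in = 10, voxel_size = 0.01) {
  d <- rep(as.integer(dims), length.out = 3L)
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
  dx2 <- (seq_len(d[1]) - 1 - cx)^2
  dy2 <- (seq_len(d[2]) - 1 - cy)^2
  rad2 <- outer(dx2, dy2, `+`)
  sl <- rad2 <= r_out^2 & rad2 > r_in^2
  voxel_volume(array(rep(sl, d[3]), dim = d), voxel_size, binary = TRUE)
}
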
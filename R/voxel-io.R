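#' Read and write voxel volumes
#'
#' TIFF stacks are read/written with one page per z-slice; because TIFF
#' carries no voxel size, it is stored in a JSON sidecar (`<file>.json` with
#' field `voxel_size_mm`). NRRD files (a single header + raw little-endian
#' data) carry the voxel size in their header; only the subset of NRRD
#' needed for scalar isotropic volumes is supported (types uint8/float/double,
#' encodings raw and text, no compression).
#'
#' @param path file path (`.tif`/`.tiff` or `.nrrd`).
#' @param voxel_size voxel size in mm; for TIFF, overrides the sidecar.
#' @return A `voxel_volume`.
#' @export
read_voxel_volume <- function(path, voxel_size = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    d <- c(dim(pages[[1]])[1:2], length(pages))
    arr <- array(unlist(pages), dim = d)
    if (is.null(voxel_size)) {
      sidecar <- paste0(path, ".json")
      if (!file.exists(sidecar))
        stop("no voxel size: supply `voxel_size` or a JSON sidecar",
             call. = FALSE)
      voxel_size <- jsonlite::read_json(sidecar)$voxel_size_mm
    }
    voxel_volume(arr, voxel_size)
  } else if (ext == "nrrd") {
    read_nrrd(path)
  } else stop("unsupported extension: ", ext, call. = FALSE)
}

#' @rdname read_voxel_volume
#' @param volume a `voxel_volume`.
#' @export
write_voxel_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    g <- volume$grid
    if (is.logical(g)) g <- g * 1
    rng <- range(g)
    if (rng[1] < 0 || rng[2] > 1) g <- (g - rng[1]) / (rng[2] - rng[1])
    pages <- lapply(seq_len(dim(g)[3]), function(k) g[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    jsonlite::write_json(list(voxel_size_mm = volume$voxel_size),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else if (ext == "nrrd") {
    write_nrrd(volume, path)
  } else stop("unsupported extension: ", ext, call. = FALSE)
  invisible(path)
}

read_nrrd <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header ends at the first blank line
  nl <- which(bytes == as.raw(10L))
  blank <- NA_integer_
  prev <- 0L
  for (pos in nl) {
    if (pos == prev + 1L) { blank <- pos; break }
    prev <- pos
  }
  if (is.na(blank)) stop("malformed NRRD: no blank line", call. = FALSE)
  hdr <- strsplit(rawToChar(bytes[seq_len(blank - 1L)]), "\n")[[1]]
  if (!grepl("^NRRD", hdr[1])) stop("not an NRRD file", call. = FALSE)
  fields <- list()
  for (line in hdr[-1]) {
    if (line == "" || grepl("^#", line)) next
    kv <- strsplit(line, ":[ =]?", perl = TRUE)[[1]]
    fields[[tolower(trimws(kv[1]))]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3-D NRRD supported", call. = FALSE)
  type <- fields$type
  enc <- fields$encoding
  n <- prod(sizes)
  payload <- bytes[(blank + 1L):length(bytes)]
  vals <- if (enc == "raw") {
    switch(type,
      uint8 = as.numeric(readBin(payload, "integer", n, size = 1L,
                                 signed = FALSE)),
      float = readBin(payload, "numeric", n, size = 4L, endian = "little"),
      double = readBin(payload, "numeric", n, size = 8L, endian = "little"),
      stop("unsupported NRRD type: ", type, call. = FALSE))
  } else if (enc %in% c("text", "txt", "ascii")) {
    as.numeric(strsplit(trimws(rawToChar(payload)), "\\s+")[[1]])[seq_len(n)]
  } else stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  vs <- if (!is.null(fields$spacings))
    as.numeric(strsplit(fields$spacings, "\\s+")[[1]])[1]
  else 1
  voxel_volume(array(vals, dim = sizes), vs)
}

write_nrrd <- function(volume, path, encoding = "raw") {
  g <- volume$grid
  binary <- volume$binary
  type <- if (binary) "uint8" else "double"
  header <- c("NRRD0004",
              "# osteoconv voxel volume",
              paste0("type: ", type),
              "dimension: 3",
              paste0("sizes: ", paste(dim(g), collapse = " ")),
              paste0("spacings: ", paste(rep(volume$voxel_size, 3),
                                         collapse = " ")),
              paste0("encoding: ", encoding),
              "endian: little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n\n")), con)
  if (encoding == "raw") {
    if (binary) writeBin(as.integer(g != 0), con, size = 1L)
    else writeBin(as.numeric(g), con, size = 8L, endian = "little")
  } else {
    writeBin(charToRaw(paste0(paste(as.numeric(g), collapse = " "), "\n")),
             con)
  }
  invisible(path)
}

#' Write synthetic fixtures to disk
#'
#' Convenience exporter for the synthetic-data generators: the tree as
#' Newick, the tip table (species, regime, trait) as CSV, and any phantoms as
#' NRRD volumes. Everything is reproducible from the seed alone; the files
#' exist so external tools can consume the same inputs.
#'
#' @param rtree a [paint_regimes()] `regime_tree`.
#' @param traits named trait vector for the tips.
#' @param out_dir output directory (created if needed).
#' @param phantoms optional named list of [phantom_spec()]s.
#' @return Invisibly, the vector of files written.
#' @export
write_synth_fixtures <- function(rtree, traits, out_dir, phantoms = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(out_dir, "tree.nwk")
  write_timetree(rtree$tree, f)
  files <- c(files, f)
  tab <- data.frame(species = rtree$tree$tip.label,
                    regime = as.character(rtree$tip_regime[
                      rtree$tree$tip.label]),
                    trait = unname(traits[rtree$tree$tip.label]))
  f <- file.path(out_dir, "tips.csv")
  write.csv(tab, f, row.names = FALSE)
  files <- c(files, f)
  for (nm in names(phantoms)) {
    f <- file.path(out_dir, paste0(nm, ".nrrd"))
    write_voxel_volume(generate_phantom(phantoms[[nm]]), f)
    files <- c(files, f)
  }
  invisible(files)
}
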
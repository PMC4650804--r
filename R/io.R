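# Volume I/O (multi-page TIFF, NRRD raw), run configuration and the
# end-to-end pipeline driver.

#' Read a tomogram volume
#'
#' Multi-page TIFF stacks (one trans-axial slice per page; grey 8/16-bit or
#' float, values read as stored, integers are not rescaled) and NRRD (raw
#' encoding) are supported. NRRD voxel spacing is taken from the header;
#' an explicit `voxel_size_um` overrides it with a warning. TIFF carries no
#' spacing metadata, so `voxel_size_um` is required there.
#'
#' @param path file path (`.tif`/`.tiff` or `.nrrd`).
#' @param voxel_size_um voxel size flag; see above.
#' @param axial_axis axis running along the vessel (default 3).
#' @return A [tomogram()].
#' @export
read_volume <- function(path, voxel_size_um = NULL, axial_axis = 3L) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    dims <- lapply(pages, dim)
    ref <- dims[[1]]
    bad <- which(!vapply(dims, function(d) identical(d, ref), logical(1)))
    if (length(bad))
      stop("inconsistent TIFF page shapes: page ", bad[1], " is ",
           paste(dims[[bad[1]]], collapse = "x"), ", expected ",
           paste(ref, collapse = "x"))
    if (is.null(voxel_size_um))
      stop("TIFF carries no voxel-size metadata; supply voxel_size_um")
    vol <- array(unlist(pages), c(ref[1], ref[2], length(pages)))
    tomogram(vol + 0, voxel_size_um, axial_axis)
  } else if (ext == "nrrd") {
    nr <- read_nrrd(path)
    vs <- nr$spacing
    if (!is.null(voxel_size_um)) {
      if (!is.null(vs) && abs(vs - voxel_size_um) > 1e-9)
        warning("overriding NRRD spacing ", vs, " with flag value ",
                voxel_size_um)
      vs <- voxel_size_um
    }
    if (is.null(vs)) stop("no spacing in NRRD header; supply voxel_size_um")
    tomogram(nr$data, vs, axial_axis)
  } else {
    stop("unknown volume format: .", ext, " (expected .tif/.tiff or .nrrd)")
  }
}

#' Write a tomogram volume
#'
#' `.tif` writes a multi-page TIFF: integer dtypes store exact integer
#' values (8 or 16 bit); float volumes must go to `.nrrd` (raw 32/64-bit),
#' which also records the voxel spacing.
#'
#' @param vol a [tomogram()] or 3D array.
#' @param path output path, `.tif`/`.tiff` or `.nrrd`.
#' @param dtype `"uint8"`, `"uint16"`, `"float"` or `"double"`.
#' @param voxel_size_um voxel size when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, dtype = c("uint16", "uint8", "float",
                                              "double"),
                         voxel_size_um = NULL) {
  vol <- as_tomogram(vol, voxel_size_um)
  dtype <- match.arg(dtype)
  ext <- tolower(tools::file_ext(path))
  v <- vol$values
  if (ext %in% c("tif", "tiff")) {
    if (dtype %in% c("float", "double"))
      stop("float TIFF is not supported; write float volumes to .nrrd")
    bits <- if (dtype == "uint8") 8L else 16L
    mx <- 2^bits - 1
    if (any(v < 0 | v > mx | v != round(v)))
      stop("values outside ", dtype, " range (or non-integer); rescale first")
    pages <- lapply(seq_len(dim(v)[3]),
                    function(z) v[, , z] / mx)
    tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  } else if (ext == "nrrd") {
    write_nrrd(v, path, vol$voxel_size_um, dtype)
  } else {
    stop("unknown volume format: .", ext)
  }
  invisible(path)
}

read_nrrd <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  # header ends at the first blank line
  nl <- which(raw_all == as.raw(10L))
  hdr_end <- NA
  prev <- 0L
  for (i in nl) {
    if (i == prev + 1L) { hdr_end <- i; break }
    prev <- i
  }
  if (is.na(hdr_end)) stop("malformed NRRD: no blank line after header")
  hdr <- strsplit(rawToChar(raw_all[seq_len(hdr_end - 1L)]), "\n")[[1]]
  field <- function(key) {
    ln <- grep(paste0("^", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^", key, ":\\s*"), "", ln[1]))
  }
  type <- field("type") %||% stop("NRRD missing type")
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  enc <- field("encoding")
  if (!identical(enc, "raw")) stop("only raw NRRD encoding is supported")
  spc <- field("spacings")
  spacing <- if (!is.null(spc)) as.numeric(strsplit(spc, "\\s+")[[1]])[1] else NULL
  what <- switch(type,
                 "float" = "numeric", "double" = "numeric",
                 "uint8" = "integer", "uchar" = "integer",
                 "uint16" = "integer", "unsigned short" = "integer",
                 stop("unsupported NRRD type: ", type))
  size <- switch(type, "float" = 4L, "double" = 8L,
                 "uint8" = 1L, "uchar" = 1L, 2L)
  n <- prod(sizes)
  data_raw <- raw_all[(hdr_end + 1L):length(raw_all)]
  vals <- readBin(data_raw, what, n = n, size = size,
                  signed = size > 2L, endian = "little")
  list(data = array(vals, sizes), spacing = spacing, type = type)
}

write_nrrd <- function(arr, path, spacing, dtype = "float") {
  type <- switch(dtype, float = "float", double = "double",
                 uint8 = "uint8", uint16 = "uint16")
  size <- switch(dtype, float = 4L, double = 8L, uint8 = 1L, uint16 = 2L)
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(dim(arr), collapse = " ")),
           paste0("spacings: ", paste(rep(spacing, 3), collapse = " ")),
           "encoding: raw",
           "endian: little",
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (dtype %in% c("uint8", "uint16"))
    writeBin(as.integer(arr), con, size = size, endian = "little")
  else
    writeBin(as.numeric(arr), con, size = size, endian = "little")
  invisible(path)
}

#' Full run configuration
#'
#' Bundles every stage parameter: the [segment_config()], pore-segmentation
#' settings, voxel size, axial axis and RNG seed. Serialises to YAML and
#' round-trips identically via [write_run_config()] / [read_run_config()].
#'
#' @param voxel_size_um voxel size in micrometres.
#' @param axial_axis vessel axis of input arrays.
#' @param seed RNG seed for any stochastic stage.
#' @param segment a [segment_config()].
#' @param pore_k_sd,pore_min_size_vox [segment_pores()] parameters.
#' @return A `run_config` list.
#' @export
run_config <- function(voxel_size_um = 0.75, axial_axis = 3L, seed = 1L,
                       segment = segment_config(),
                       pore_k_sd = 3, pore_min_size_vox = 9L) {
  if (voxel_size_um <= 0) stop("voxel_size_um must be > 0")
  if (pore_k_sd <= 0) stop("pore_k_sd must be > 0")
  structure(list(voxel_size_um = voxel_size_um,
                 axial_axis = as.integer(axial_axis),
                 seed = as.integer(seed),
                 segment = segment,
                 pore_k_sd = pore_k_sd,
                 pore_min_size_vox = as.integer(pore_min_size_vox)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  lst$segment <- unclass(lst$segment)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  seg <- do.call(segment_config, lst$segment %||% list())
  do.call(run_config, c(lst[setdiff(names(lst), "segment")],
                        list(segment = seg)))
}

#' Write pipeline outputs with a checksum manifest
#'
#' Writes the label volume (8-bit multi-page TIFF), boundary contours
#' (CSV), morphometry table (CSV), the per-slice diagnostics log (CSV) and
#' the run configuration (YAML), then a manifest listing each file with its
#' MD5 checksum. If any write fails, already-written files are removed and
#' no manifest is produced.
#'
#' @param seg a `layer_segmentation`.
#' @param table a [morphometry_table()] tibble.
#' @param outdir output directory (created if needed).
#' @param config optional `run_config` to record.
#' @return Tibble manifest (`file`, `md5`), invisibly.
#' @export
write_outputs <- function(seg, table, outdir, config = NULL) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  if (file.access(outdir, 2L) != 0L)
    stop("output directory is not writable: ", outdir)
  written <- character(0)
  emit <- function(fname, writer) {
    p <- file.path(outdir, fname)
    writer(p)
    written <<- c(written, p)
    p
  }
  tryCatch({
    emit("labels.tif", function(p)
      write_volume(tomogram(seg$labels + 0, seg$voxel_size_um), p, "uint8"))
    emit("contours.csv", function(p)
      utils::write.csv(seg$contours, p, row.names = FALSE))
    emit("morphometry.csv", function(p)
      utils::write.csv(table, p, row.names = FALSE))
    emit("run_log.csv", function(p)
      utils::write.csv(seg$diagnostics, p, row.names = FALSE))
    if (!is.null(config))
      emit("config.yaml", function(p) write_run_config(config, p))
  }, error = function(e) {
    unlink(written)
    stop("output write failed (rolled back): ", conditionMessage(e))
  })
  manifest <- tibble::tibble(file = basename(written),
                             md5 = unname(tools::md5sum(written)))
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Run the complete pipeline on a volume file
#'
#' Reads the volume, segments the wall layers, segments pores, quantifies
#' morphometry and writes all outputs with a manifest. Stage timings and
#' per-slice diagnostics go to the run log.
#'
#' @param config a [run_config()].
#' @param in_path input volume (TIFF stack or NRRD).
#' @param outdir output directory.
#' @return Invisibly, a list with `segmentation`, `pores`, `table`,
#'   `manifest` and `status` (0 on success, 1 if any slice hard-failed).
#' @export
run_pipeline <- function(config, in_path, outdir) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  vol <- read_volume(in_path, voxel_size_um = config$voxel_size_um,
                     axial_axis = config$axial_axis)
  seg <- segment_volume(vol, config$segment)
  pores <- segment_pores(vol, seg, k_sd = config$pore_k_sd,
                         min_size_vox = config$pore_min_size_vox)
  tab <- morphometry_table(seg, pores)
  manifest <- write_outputs(seg, tab, outdir, config)
  status <- as.integer(any(startsWith(seg$diagnostics$status, "flagged")))
  message(sprintf("pipeline finished in %.1f s (status %d)",
                  proc.time()[["elapsed"]] - t0, status))
  invisible(list(segmentation = seg, pores = pores, table = tab,
                 manifest = manifest, status = status))
}
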
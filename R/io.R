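# File formats: TIFF stacks and NIfTI volumes for images, legacy VTK
# structured points for strain maps and vector fields (renderable in
# ParaView), CSV for series, YAML/JSON for configuration and metadata.

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop_("package '%s' is required for this file format", pkg)
}

#' Write / read a 3D volume
#'
#' Format follows the extension: `.nii` / `.nii.gz` (NIfTI, carries the voxel
#' size) or `.tif` / `.tiff` (multi-page float TIFF, one page per z slice;
#' intensities are written as-is, so keep them in `[0, 1]`).
#'
#' @param vol numeric 3D array.
#' @param path output file.
#' @param voxel_size voxel edge in micrometres (stored in NIfTI headers).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = 1) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("nii")) {
    need_pkg("RNifti")
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- rep(voxel_size, 3)
    RNifti::writeNifti(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    need_pkg("tiff")
    pages <- lapply(seq_len(dim(vol)[3]), function(z) vol[, , z])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  } else stop_("unsupported volume format: '%s'", ext)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("nii")) {
    need_pkg("RNifti")
    img <- RNifti::readNifti(path)
    out <- array(as.numeric(img), dim = dim(img))
    attr(out, "voxel_size") <- RNifti::pixdim(img)[1]
    out
  } else if (ext %in% c("tif", "tiff")) {
    need_pkg("tiff")
    pages <- tiff::readTIFF(path, all = TRUE)
    out <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) out[, , z] <- pages[[z]]
    out
  } else stop_("unsupported volume format: '%s'", ext)
}

#' Write / read a phase series as one volume per file plus a JSON sidecar
#'
#' The sidecar (`series.json`) is authoritative for voxel size and phase
#' times.
#'
#' @param series a [volume_series()].
#' @param dir output directory (created if needed).
#' @param format "nii" or "tif".
#' @return the directory, invisibly.
#' @export
write_series <- function(series, dir, format = c("nii", "tif")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("phase_%03d.%s", seq_along(series$volumes) - 1, format)
  for (i in seq_along(series$volumes))
    write_volume(series$volumes[[i]], file.path(dir, files[i]), series$voxel_size)
  meta <- list(voxel_size_um = series$voxel_size, times_s = series$times,
               files = files)
  jsonlite::write_json(meta, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_series
#' @export
read_series <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "series.json"), simplifyVector = TRUE)
  vols <- lapply(file.path(dir, meta$files), function(f) {
    v <- read_volume(f)
    attr(v, "voxel_size") <- NULL   # the sidecar is authoritative
    v
  })
  volume_series(vols, voxel_size = meta$voxel_size_um, times = meta$times_s)
}

#' Export a volume, field or mask as legacy VTK structured points
#'
#' Writes ASCII legacy VTK that standard renderers open. Scalars are written
#' at full precision so a write/read cycle is bit-exact. Masked voxels (if a
#' mask is supplied) are encoded as NaN with the mask stored as a second
#' array.
#'
#' @param x numeric 3D array (scalars) or nx x ny x nz x 3 array (vectors),
#'   or a [displacement_field()].
#' @param path output `.vtk` file.
#' @param spacing physical voxel spacing (micrometres); must be positive.
#' @param name array name in the file.
#' @param mask optional logical array: FALSE voxels are written as NaN.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(x, path, spacing = NULL, name = "values", mask = NULL) {
  if (inherits(x, "displacement_field")) {
    if (is.null(spacing)) spacing <- x$voxel_size
    if (is.null(mask) && !is.null(x$oob)) mask <- !x$oob
    x <- x$u
  }
  assert_that(!is.null(spacing) && spacing > 0, "spacing must be set and positive")
  d <- dim(x)
  vector_data <- length(d) == 4 && d[4] == 3
  dims <- d[1:3]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "lungmech export", "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
               sprintf("ORIGIN 0 0 0"),
               sprintf("SPACING %.17g %.17g %.17g", spacing, spacing, spacing),
               sprintf("POINT_DATA %d", prod(dims))), con)
  fmt <- function(v) sprintf("%.17g", v)
  if (vector_data) {
    writeLines(sprintf("VECTORS %s double", name), con)
    m <- cbind(as.numeric(x[, , , 1]), as.numeric(x[, , , 2]), as.numeric(x[, , , 3]))
    if (!is.null(mask)) m[!as.logical(mask), ] <- NaN
    writeLines(paste(fmt(m[, 1]), fmt(m[, 2]), fmt(m[, 3])), con)
  } else {
    writeLines(c(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default"), con)
    v <- as.numeric(x)
    if (!is.null(mask)) v[!as.logical(mask)] <- NaN
    writeLines(fmt(v), con)
  }
  if (!is.null(mask)) {
    writeLines(c("SCALARS mask int 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%d", as.integer(as.logical(mask))), con)
  }
  invisible(path)
}

#' Read a legacy VTK structured-points file written by [write_vtk()]
#'
#' @param path `.vtk` file.
#' @return list with `data` (3D or 4D array), `spacing`, and optionally
#'   `mask`.
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(grep("^DIMENSIONS", lines, value = TRUE), " ")[[1]][2:4])
  spacing <- as.numeric(strsplit(grep("^SPACING", lines, value = TRUE), " ")[[1]][2])
  n <- prod(dims)
  out <- list(spacing = spacing)
  i <- grep("^VECTORS|^SCALARS", lines)
  for (hdr_i in i) {
    hdr <- strsplit(lines[hdr_i], " ")[[1]]
    if (hdr[1] == "VECTORS") {
      vals <- scan(text = lines[(hdr_i + 1):(hdr_i + n)], quiet = TRUE)
      out$data <- array(cbind(matrix(vals, ncol = 3, byrow = TRUE)), dim = c(dims, 3))
    } else {
      start <- hdr_i + 2  # skip LOOKUP_TABLE
      vals <- scan(text = lines[start:(start + n - 1)], quiet = TRUE)
      if (hdr[2] == "mask") out$mask <- array(vals != 0, dim = dims)
      else out$data <- array(vals, dim = dims)
    }
  }
  out
}

#' Write / read a displacement field archive (VTK vectors + JSON metadata)
#'
#' @param field a [displacement_field()].
#' @param path base path; `.vtk` and `.json` files are written next to it.
#' @return base path, invisibly.
#' @export
write_field <- function(field, path) {
  base <- sub("\\.(vtk|json)$", "", path)
  write_vtk(field, paste0(base, ".vtk"), name = "displacement")
  jsonlite::write_json(
    list(kind = field$kind, from_step = field$from_step,
         to_step = field$to_step, voxel_size = field$voxel_size),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  base <- sub("\\.(vtk|json)$", "", path)
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  v <- read_vtk(paste0(base, ".vtk"))
  u <- v$data
  u[is.nan(u)] <- 0
  displacement_field(u, meta$kind, meta$from_step, meta$to_step,
                     meta$voxel_size, oob = if (!is.null(v$mask)) !v$mask else NULL)
}

#' Write / read ROI series tables as CSV
#'
#' @param rs list of `roi_series` objects (or one).
#' @param path CSV file.
#' @return `path` / data.frame.
#' @export
write_series_csv <- function(rs, path) {
  if (inherits(rs, "roi_series")) rs <- list(rs)
  tabs <- lapply(rs, function(r) cbind(roi = r$id, r$series))
  write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) read.csv(path)

#' Load / save a pipeline or phantom configuration (YAML)
#'
#' @param x named list of configuration values.
#' @param path YAML file.
#' @return list / `path`.
#' @export
write_config <- function(x, path) {
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
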
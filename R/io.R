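## Native on-disk format: a raw little-endian binary payload (<stem>.raw)
## plus a human-readable YAML sidecar header (<stem>.hdr).  Payload order is
## always the R array order: first index fastest.

strip_ext <- function(path) sub("\\.(hdr|raw)$", "", path)

#' Projection stack payload size
#'
#' Byte count of the raw binary payload of a projection stack (or volume)
#' with the given dimensions and element type.  [payload_megabytes()]
#' converts to MB defined as 2^20 bytes, the convention under which a
#' 512 x 768 x 361 float32 stack is 542 MB and a 512 x 512 x 768 float32
#' volume is 768 MB.
#'
#' @param det_rows,det_cols,n_angles stack dimensions.
#' @param dtype `"float32"` or `"float64"`.
#' @return number of bytes.
#' @export
stack_payload_bytes <- function(det_rows, det_cols, n_angles, dtype = "float32") {
  as.numeric(det_rows) * det_cols * n_angles * dtype_size(dtype)
}

#' @rdname stack_payload_bytes
#' @param nx,ny,nz volume dimensions.
#' @export
volume_payload_bytes <- function(nx, ny, nz, dtype = "float32") {
  as.numeric(nx) * ny * nz * dtype_size(dtype)
}

#' @rdname stack_payload_bytes
#' @param bytes byte count.
#' @export
payload_megabytes <- function(bytes) bytes / 2^20

#' Write / read a projection stack (raw + YAML header)
#'
#' `write_projection_stack()` writes `<stem>.raw` (little-endian binary)
#' and `<stem>.hdr` (YAML: dimensions, dtype, byte order, stage, and the
#' full geometry with angles in degrees).  `read_projection_stack()`
#' inverts it, validating the payload size against the header and
#' restoring the geometry; round-trips are bitwise for both dtypes.
#'
#' @param stack a [projection_stack()].
#' @param stem path stem (extensions are added) or a path ending in
#'   `.hdr`/`.raw`.
#' @return `write_projection_stack()` the stem, invisibly;
#'   `read_projection_stack()` a [projection_stack()].
#' @export
write_projection_stack <- function(stack, stem) {
  stem <- strip_ext(stem)
  dtype <- precision_dtype(stack$precision)
  hdr <- c(list(format = "fdk-projection-stack-v1",
                dtype = dtype, byte_order = "little",
                det_rows = stack$geom$det_rows,
                det_cols = stack$geom$det_cols,
                n_angles = stack$geom$n_angles,
                stage = stack$stage),
           list(geometry = geometry_to_list(stack$geom)))
  yaml::write_yaml(hdr, paste0(stem, ".hdr"), precision = 17)
  con <- file(paste0(stem, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(stack$data), con, size = dtype_size(dtype),
           endian = "little")
  invisible(stem)
}

#' @rdname write_projection_stack
#' @export
read_projection_stack <- function(stem) {
  stem <- strip_ext(stem)
  hdr_path <- paste0(stem, ".hdr"); raw_path <- paste0(stem, ".raw")
  if (!file.exists(hdr_path)) stopf("header not found: %s", hdr_path)
  hdr <- yaml::read_yaml(hdr_path)
  for (f in c("dtype", "det_rows", "det_cols", "n_angles", "geometry"))
    if (is.null(hdr[[f]])) stopf("header %s is missing field '%s'", hdr_path, f)
  size <- dtype_size(hdr$dtype)
  n <- as.numeric(hdr$det_rows) * hdr$det_cols * hdr$n_angles
  expected <- n * size
  actual <- file.info(raw_path)$size
  if (is.na(actual)) stopf("payload not found: %s", raw_path)
  if (actual != expected)
    stopf("payload size mismatch in %s: expected %.0f bytes, found %.0f",
          raw_path, expected, actual)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  endian <- hdr$byte_order %||% "little"
  data <- readBin(con, "numeric", n = n, size = size, endian = endian)
  dim(data) <- c(hdr$det_rows, hdr$det_cols, hdr$n_angles)
  geom <- as_cone_geometry(hdr$geometry)
  projection_stack(data, geom, stage = hdr$stage %||% "raw",
                   precision = if (size == 4L) "single" else "double")
}

#' Write a volume to disk
#'
#' Formats: `"raw"` (little-endian payload + YAML header, bitwise
#' round-trip), `"mha"` (MetaImage with embedded payload,
#' `ElementDataFile = LOCAL`, recording voxel spacing and origin), or
#' `"tiff"` (one 32-bit float slice per z; values min/max-normalized to
#' [0, 1] — a visualization format, not lossless).
#'
#' @param volume an [fdk_volume()].
#' @param path output path (for `"raw"`, a stem; extensions added).
#' @param format `"raw"`, `"mha"` or `"tiff"`.
#' @return the path/stem, invisibly.
#' @export
write_volume <- function(volume, path, format = c("raw", "mha", "tiff")) {
  format <- match.arg(format)
  if (anyNA(volume$values) || any(!is.finite(volume$values)))
    stopf("volume contains NaN/Inf values; refusing to write")
  g <- volume$grid
  dtype <- precision_dtype(volume$precision)
  if (format == "raw") {
    stem <- strip_ext(path)
    hdr <- list(format = "fdk-volume-v1", dtype = dtype, byte_order = "little",
                nx = g$nx, ny = g$ny, nz = g$nz,
                dx = g$dx, dy = g$dy, dz = g$dz,
                origin = as.numeric(g$origin))
    yaml::write_yaml(hdr, paste0(stem, ".hdr"), precision = 17)
    con <- file(paste0(stem, ".raw"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(volume$values), con, size = dtype_size(dtype),
             endian = "little")
    return(invisible(stem))
  }
  if (format == "mha") {
    lines <- c("ObjectType = Image",
               "NDims = 3",
               "BinaryData = True",
               "BinaryDataByteOrderMSB = False",
               sprintf("DimSize = %d %d %d", g$nx, g$ny, g$nz),
               sprintf("ElementSpacing = %.17g %.17g %.17g", g$dx, g$dy, g$dz),
               sprintf("Offset = %.17g %.17g %.17g",
                       g$origin[1], g$origin[2], g$origin[3]),
               sprintf("ElementType = %s",
                       if (dtype == "float32") "MET_FLOAT" else "MET_DOUBLE"),
               "ElementDataFile = LOCAL")
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(lines, collapse = "\n"), "\n"), con, eos = NULL)
    writeBin(as.numeric(volume$values), con, size = dtype_size(dtype),
             endian = "little")
    return(invisible(path))
  }
  # tiff stack, one slice per z, normalized into [0, 1]
  v <- volume$values
  rng <- range(v)
  vn <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  slices <- lapply(seq_len(g$nz), function(k) t(vn[, , k])[g$ny:1, , drop = FALSE])
  tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' Supports the `"raw"` (stem.hdr + stem.raw) and `"mha"` formats.
#'
#' @param path stem or `.mha` path.
#' @return an [fdk_volume()].
#' @export
read_volume <- function(path) {
  if (grepl("\\.mha$", path)) return(read_mha(path))
  stem <- strip_ext(path)
  hdr_path <- paste0(stem, ".hdr")
  if (!file.exists(hdr_path)) stopf("header not found: %s", hdr_path)
  hdr <- yaml::read_yaml(hdr_path)
  size <- dtype_size(hdr$dtype)
  n <- as.numeric(hdr$nx) * hdr$ny * hdr$nz
  raw_path <- paste0(stem, ".raw")
  actual <- file.info(raw_path)$size
  if (is.na(actual)) stopf("payload not found: %s", raw_path)
  if (actual != n * size)
    stopf("payload size mismatch in %s: expected %.0f bytes, found %.0f",
          raw_path, n * size, actual)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n, size = size,
                  endian = hdr$byte_order %||% "little")
  dim(vals) <- c(hdr$nx, hdr$ny, hdr$nz)
  grid <- volume_grid(hdr$nx, hdr$ny, hdr$nz, hdr$dx, hdr$dy, hdr$dz,
                      origin = as.numeric(hdr$origin))
  fdk_volume(vals, grid, precision = if (size == 4L) "single" else "double")
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  # read header byte-wise so no payload bytes are consumed by buffering
  read_line <- function() {
    out <- raw()
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L) stopf("unexpected end of MHA header in %s", path)
      if (b == as.raw(10L)) break
      out <- c(out, b)
    }
    rawToChar(out)
  }
  repeat {
    line <- read_line()
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr$ElementDataFile, "LOCAL"))
    stopf("only ElementDataFile = LOCAL MHA files are supported")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  off <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  size <- switch(hdr$ElementType, MET_FLOAT = 4L, MET_DOUBLE = 8L,
                 stopf("unsupported ElementType '%s'", hdr$ElementType))
  msb <- identical(tolower(hdr$BinaryDataByteOrderMSB %||% "false"), "true")
  vals <- readBin(con, "numeric", n = prod(dims), size = size,
                  endian = if (msb) "big" else "little")
  if (length(vals) < prod(dims))
    stopf("truncated MHA payload in %s: expected %d values, found %d",
          path, prod(dims), length(vals))
  dim(vals) <- dims
  grid <- volume_grid(dims[1], dims[2], dims[3], sp[1], sp[2], sp[3],
                      origin = off)
  fdk_volume(vals, grid, precision = if (size == 4L) "single" else "double")
}

## grayscale QC PNG of a matrix, min/max normalized
write_qc_png <- function(mat, path) {
  rng <- range(mat)
  m <- if (diff(rng) > 0) (mat - rng[1]) / diff(rng) else mat * 0
  png::writePNG(m, path)
  invisible(path)
}
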
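## Minimal baseline TIFF support: uncompressed, little-endian,
## single-sample multi-page files. Two flavours are written: 8-bit
## unsigned pages for label volumes and 32-bit IEEE float pages for
## intensity stacks. No R TIFF reader is available in the target
## environment, so the subset needed by the pipeline is implemented
## here; anything fancier (compression, tiles, palettes) is out of
## scope and rejected on read.

TAG <- c(width = 256L, length = 257L, bps = 258L, compression = 259L,
         photometric = 262L, strip_offsets = 273L, spp = 277L,
         rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

## slices: 3D array [x, y, slice]; matrix rows are written as image rows.
write_tiff <- function(arr, path, type = c("uint8", "float32")) {
  type <- match.arg(type)
  d <- dim(arr)
  nr <- d[1]; nc <- d[2]; np <- d[3]
  bps <- if (type == "uint8") 8L else 32L
  fmt <- if (type == "uint8") 1L else 3L
  bytes_per <- bps / 8L
  strip_len <- nr * nc * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  data_start <- 8L
  ifd_start <- as.integer(data_start + np * strip_len)
  writeBin(ifd_start, con, size = 4, endian = "little")
  for (k in seq_len(np)) {
    page <- t(arr[, , k])  # row-major within a page
    if (type == "uint8") {
      writeBin(as.raw(as.integer(page)), con)
    } else {
      writeBin(as.numeric(page), con, size = 4, endian = "little")
    }
  }
  n_entries <- 10L
  entry <- function(tag, typ, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(typ), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  for (k in seq_len(np)) {
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(TAG[["width"]], 3L, 1L, nc)
    entry(TAG[["length"]], 3L, 1L, nr)
    entry(TAG[["bps"]], 3L, 1L, bps)
    entry(TAG[["compression"]], 3L, 1L, 1L)
    entry(TAG[["photometric"]], 3L, 1L, 1L)
    entry(TAG[["strip_offsets"]], 4L, 1L, data_start + (k - 1L) * strip_len)
    entry(TAG[["spp"]], 3L, 1L, 1L)
    entry(TAG[["rows_per_strip"]], 3L, 1L, nr)
    entry(TAG[["strip_bytes"]], 4L, 1L, strip_len)
    entry(TAG[["sample_format"]], 3L, 1L, fmt)
    next_ifd <- if (k < np) ifd_start + k * (2L + n_entries * 12L + 4L) else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (!identical(rawToChar(raw[1:2]), "II"))
    stop("only little-endian TIFF supported", call. = FALSE)
  u16 <- function(off) as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * 256^(0:3))
  ifd <- u32(4L)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd + 2L + (i - 1L) * 12L
      tag <- u16(e)
      typ <- u16(e + 2L)
      val <- if (typ == 3L) u16(e + 8L) else u32(e + 8L)
      tags[[as.character(tag)]] <- val
    }
    g <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) default else v
    }
    if (g(TAG[["compression"]], 1L) != 1L)
      stop("compressed TIFF not supported", call. = FALSE)
    nc <- g(TAG[["width"]]); nr <- g(TAG[["length"]])
    bps <- g(TAG[["bps"]], 8L); fmt <- g(TAG[["sample_format"]], 1L)
    off <- g(TAG[["strip_offsets"]])
    nbytes <- nr * nc * bps / 8L
    if (bps == 8L && fmt == 1L) {
      vals <- as.integer(raw[off + seq_len(nbytes)])
    } else if (bps == 32L && fmt == 3L) {
      vals <- readBin(raw[off + seq_len(nbytes)], "numeric", n = nr * nc,
                      size = 4, endian = "little")
    } else stop("unsupported TIFF sample layout", call. = FALSE)
    pages[[length(pages) + 1L]] <- t(matrix(vals, nc, nr))  # undo row-major
    ifd <- u32(ifd + 2L + n * 12L)
  }
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr
}

#' Write a case bundle to disk
#'
#' Writes pre/post label volumes (8-bit multi-page TIFF), pre/post
#' pseudo-ultrasound stacks (32-bit float multi-page TIFF), the breach
#' record (CSV) and a JSON sidecar carrying spacings, seed, label
#' alphabet and provenance.
#'
#' @param bundle a `case_bundle` from [generate_case()]
#' @param dir output directory (created if needed)
#' @param name base name for the files
#' @return invisibly, the sidecar path
#' @export
write_case_bundle <- function(bundle, dir, name = "case") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(suffix) file.path(dir, paste0(name, suffix))
  write_tiff(unclass(bundle$pre_labels), p("_pre_labels.tif"), "uint8")
  write_tiff(unclass(bundle$post_labels), p("_post_labels.tif"), "uint8")
  write_tiff(unclass(bundle$pre_stack), p("_pre_us.tif"), "float32")
  write_tiff(unclass(bundle$post_stack), p("_post_us.tif"), "float32")
  write.csv(bundle$breaches, p("_breaches.csv"), row.names = FALSE)
  spec <- attr(bundle$pre_labels, "spec")
  sidecar <- list(
    format = "turpeval case bundle v1",
    units = list(length = "mm", area = "mm^2"),
    pixel_spacing_mm = attr(bundle$pre_labels, "pixel_spacing_mm"),
    slice_spacing_mm = attr(bundle$pre_labels, "slice_spacing_mm"),
    n_slices = dim(bundle$pre_labels)[3],
    labels = as.list(LBL),
    seed = bundle$seed,
    spec = unclass(spec),
    skill = attr(bundle$post_labels, "meta")$skill,
    noise = attr(bundle$pre_stack, "meta"),
    software = paste0("turpeval ", pkg_version()),
    files = list(pre_labels = basename(p("_pre_labels.tif")),
                 post_labels = basename(p("_post_labels.tif")),
                 pre_us = basename(p("_pre_us.tif")),
                 post_us = basename(p("_post_us.tif")),
                 breaches = basename(p("_breaches.csv"))))
  jsonlite::write_json(sidecar, p(".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(p(".json"))
}

#' Read a case bundle from disk
#'
#' @param sidecar path to the JSON sidecar written by
#'   [write_case_bundle()]
#' @return a `case_bundle`
#' @export
read_case_bundle <- function(sidecar) {
  if (!file.exists(sidecar))
    stop(sprintf("case sidecar not found: %s", sidecar), call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  spec <- do.call(phantom_spec, meta$spec[names(meta$spec) != ""])
  lab <- function(f) {
    arr <- read_tiff(file.path(dir, f))
    storage.mode(arr) <- "integer"
    new_label_volume(arr, spec)
  }
  stk <- function(f) {
    structure(read_tiff(file.path(dir, f)),
              pixel_spacing_mm = meta$pixel_spacing_mm,
              slice_spacing_mm = meta$slice_spacing_mm,
              meta = meta$noise, class = "slice_stack")
  }
  structure(list(pre_labels = lab(meta$files$pre_labels),
                 post_labels = lab(meta$files$post_labels),
                 pre_stack = stk(meta$files$pre_us),
                 post_stack = stk(meta$files$post_us),
                 breaches = {
                   br <- read.csv(file.path(dir, meta$files$breaches))
                   br$slice <- as.integer(br$slice)
                   for (cc in c("angle_rad", "depth_mm", "depth_fraction"))
                     br[[cc]] <- as.numeric(br[[cc]])
                   br
                 },
                 seed = meta$seed),
            class = "case_bundle")
}

#' Export a label overlay as PNG
#'
#' Writes an RGB rendering of one label slice for visual inspection
#' (blue: peripheral zone, red: central zone, pink: urethra/cavity,
#' black: background), one pixel per image pixel.
#'
#' @param labels integer label matrix
#' @param path output PNG path
#' @return invisibly, the path
#' @export
export_label_png <- function(labels, path) {
  cols <- c("#000000", "#2040c0", "#c03030", "#f080c0")  # bg, peri, cent, cav
  m <- matrix(cols[unclass(labels) + 1L], nrow(labels), ncol(labels))
  png(path, width = ncol(labels), height = nrow(labels))
  op <- par(mar = c(0, 0, 0, 0))
  plot.new()
  rasterImage(as.raster(m), 0, 0, 1, 1, interpolate = FALSE)
  par(op)
  dev.off()
  invisible(path)
}

#' Write case metrics to CSV and JSON
#'
#' CSV: one row per slice (pre and post columns side by side).
#' JSON: the three aggregates plus bookkeeping and provenance.
#'
#' @param cm a `case_metrics` from [evaluate_case()]
#' @param csv_file,json_file output paths (NULL to skip either)
#' @param provenance optional named list stored in the JSON
#' @return invisibly, `cm`
#' @export
write_case_metrics <- function(cm, csv_file = NULL, json_file = NULL,
                               provenance = list()) {
  if (!is.null(csv_file)) {
    pre <- cm$pre; post <- cm$post
    names(pre)[-1] <- paste0("pre_", names(pre)[-1])
    names(post)[-1] <- paste0("post_", names(post)[-1])
    write.csv(cbind(pre, post[-1]), csv_file, row.names = FALSE)
  }
  if (!is.null(json_file)) {
    jsonlite::write_json(
      c(list(R_pres = cm$R_pres, R_smoo = cm$R_smoo, R_circ = cm$R_circ,
             n = cm$n,
             excluded = cm$excluded,
             units = list(length = "mm", area = "mm^2"),
             software = paste0("turpeval ", pkg_version())),
        provenance),
      json_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(cm)
}
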
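# File I/O. The deployment environment provides no R TIFF/PNG bindings, so the
# package carries a minimal codec pair sufficient for its own interchange
# formats: uncompressed little-endian 16-bit grayscale multi-page TIFF for
# slice stacks, and 8-bit grayscale PNG (filter 0) for masks. Both are
# readable by any standard imaging library (cross-checked against Python's
# tifffile/imageio in the test suite).

.u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
.u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.tiff_entry <- function(tag, type, count, value) {
  val <- if (type == 3L) c(.u16le(value), as.raw(c(0, 0))) else .u32le(value)
  c(.u16le(tag), .u16le(type), .u32le(count), val)
}

#' Write a slice stack as an uncompressed 16-bit multi-page TIFF
#'
#' Intensities in `[0, 1]` are scaled to the 16-bit range; pages are stored in
#' slice order (bottom to top), one strip per page.
#'
#' @param stack a `slice_stack`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "slice_stack"))
  n <- length(stack$slices)
  H <- nrow(stack$slices[[1]]); W <- ncol(stack$slices[[1]])
  bytes_per <- H * W * 2L
  ifd_len <- 2L + 9L * 12L + 4L
  data_off <- 8L + (seq_len(n) - 1L) * (bytes_per + ifd_len)
  ifd_off <- data_off + bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49)), .u16le(42L), .u32le(ifd_off[1])), con)
  for (i in seq_len(n)) {
    v <- as.integer(round(clip01(stack$slices[[i]]) * 65535))
    v <- as.integer(t(matrix(v, H, W)))  # TIFF rows are contiguous
    r <- raw(2L * length(v))
    r[seq(1L, length(r), 2L)] <- as.raw(v %% 256L)
    r[seq(2L, length(r), 2L)] <- as.raw(v %/% 256L)
    writeBin(r, con)
    entries <- c(
      .tiff_entry(256L, 3L, 1L, W),          # ImageWidth
      .tiff_entry(257L, 3L, 1L, H),          # ImageLength
      .tiff_entry(258L, 3L, 1L, 16L),        # BitsPerSample
      .tiff_entry(259L, 3L, 1L, 1L),         # Compression: none
      .tiff_entry(262L, 3L, 1L, 1L),         # Photometric: BlackIsZero
      .tiff_entry(273L, 4L, 1L, data_off[i]),# StripOffsets
      .tiff_entry(277L, 3L, 1L, 1L),         # SamplesPerPixel
      .tiff_entry(278L, 3L, 1L, H),          # RowsPerStrip
      .tiff_entry(279L, 4L, 1L, bytes_per)   # StripByteCounts
    )
    nxt <- if (i < n) ifd_off[i + 1] else 0L
    writeBin(c(.u16le(9L), entries, .u32le(nxt)), con)
  }
  invisible(path)
}

.rd_u16 <- function(buf, pos) as.integer(buf[pos]) + 256L * as.integer(buf[pos + 1])
.rd_u32 <- function(buf, pos) {
  as.numeric(buf[pos]) + 256 * as.numeric(buf[pos + 1]) +
    65536 * as.numeric(buf[pos + 2]) + 16777216 * as.numeric(buf[pos + 3])
}

#' Read a multi-page grayscale TIFF as a slice stack
#'
#' Supports the subset written by [write_stack()] (uncompressed, single
#' sample, 8- or 16-bit, little-endian, any number of strips).
#'
#' @param path TIFF file.
#' @param embryo_id id for the returned stack (default: file name).
#' @param expected_slices if given, error when the page count differs.
#' @param slice_pitch_um vertical pitch metadata.
#' @return a `slice_stack` with intensities in `[0, 1]`.
#' @export
read_stack <- function(path, embryo_id = NULL, expected_slices = NULL,
                       slice_pitch_um = 10) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (!(buf[1] == 0x49 && buf[2] == 0x49 && .rd_u16(buf, 3L) == 42L))
    stopf("%s is not a little-endian TIFF", path)
  off <- .rd_u32(buf, 5L)
  slices <- list()
  while (off != 0) {
    ne <- .rd_u16(buf, off + 1)
    tags <- list()
    for (e in seq_len(ne)) {
      p <- off + 2L + (e - 1L) * 12L + 1L
      tag <- .rd_u16(buf, p)
      type <- .rd_u16(buf, p + 2L)
      count <- .rd_u32(buf, p + 4L)
      vals <- if (type == 3L && count <= 2) {
        vapply(seq_len(count), function(j) .rd_u16(buf, p + 8L + (j - 1) * 2L),
               integer(1))
      } else if (type %in% c(3L, 4L)) {
        sz <- if (type == 3L) 2L else 4L
        vp <- if (count * sz <= 4) p + 8L else .rd_u32(buf, p + 8L) + 1L
        vapply(seq_len(count), function(j) {
          q <- vp + (j - 1L) * sz
          if (type == 3L) as.numeric(.rd_u16(buf, q)) else .rd_u32(buf, q)
        }, numeric(1))
      } else NULL
      if (!is.null(vals)) tags[[as.character(tag)]] <- vals
    }
    W <- tags[["256"]]; H <- tags[["257"]]
    bits <- (tags[["258"]] %||% 8)[1]
    comp <- tags[["259"]] %||% 1
    if (comp != 1) stopf("unsupported TIFF compression %d in %s", comp, path)
    if (!bits %in% c(8, 16)) stopf("unsupported bit depth %d in %s", bits, path)
    offs <- tags[["273"]]
    cnts <- tags[["279"]]
    bytes <- raw(sum(cnts))
    at <- 0L
    for (s in seq_along(offs)) {
      bytes[at + seq_len(cnts[s])] <- buf[offs[s] + seq_len(cnts[s])]
      at <- at + cnts[s]
    }
    v <- if (bits == 16) {
      lo <- as.integer(bytes[seq(1L, length(bytes), 2L)])
      hi <- as.integer(bytes[seq(2L, length(bytes), 2L)])
      (lo + 256L * hi) / 65535
    } else as.integer(bytes) / 255
    slices[[length(slices) + 1L]] <- t(matrix(v, W, H))
    off <- .rd_u32(buf, off + 2L + ne * 12L + 1L)
  }
  if (!is.null(expected_slices) && length(slices) != expected_slices)
    stopf("%s has %d pages, expected %d", path, length(slices),
          expected_slices)
  slice_stack(embryo_id %||% sub("\\.[^.]*$", "", basename(path)), slices,
              slice_pitch_um = slice_pitch_um)
}

# ---- PNG (8-bit grayscale, filter 0) ----------------------------------------

.io_env <- new.env(parent = emptyenv())

.crc_table <- function() {
  if (is.null(.io_env$crc)) {
    tab <- integer(256)
    for (i in 0:255) {
      c <- i
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L)
          bitwXor(-306674912L, bitwShiftR(c, 1L))  # 0xEDB88320
        else bitwShiftR(c, 1L)
      }
      tab[i + 1] <- c
    }
    .io_env$crc <- tab
  }
  .io_env$crc
}

.crc32 <- function(bytes) {
  tab <- .crc_table()
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (x in b)
    crc <- bitwXor(tab[bitwAnd(bitwXor(crc, x), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  bitwXor(crc, -1L)
}

.u32be <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c((x %/% 16777216) %% 256, (x %/% 65536) %% 256,
           (x %/% 256) %% 256, x %% 256))
}

.int_u32be <- function(x) {  # signed 32-bit int -> big-endian bytes
  if (x < 0) x <- x + 4294967296
  .u32be(x)
}

.png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(.u32be(length(data)), body, .int_u32be(.crc32(body)))
}

#' Write a binary mask (or 8-bit grayscale image) as PNG
#'
#' @param img matrix with values in `[0, 1]`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_mask_png <- function(img, path) {
  H <- nrow(img); W <- ncol(img)
  ihdr <- c(.u32be(W), .u32be(H), as.raw(c(8L, 0L, 0L, 0L, 0L)))
  px <- matrix(as.integer(round(clip01(img) * 255)), H, W)
  rows <- lapply(seq_len(H), function(i) as.raw(c(0L, px[i, ])))
  idat <- memCompress(unlist(rows), type = "gzip")  # zlib stream
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           .png_chunk("IHDR", ihdr), .png_chunk("IDAT", idat),
           .png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG written by [write_mask_png()]
#'
#' @param path PNG file.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_mask_png <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (!all(buf[1:8] == as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))))
    stopf("%s is not a PNG", path)
  pos <- 9L
  W <- H <- NULL
  idat <- raw(0)
  while (pos < length(buf)) {
    len <- .rd_u32be(buf, pos)
    type <- rawToChar(buf[pos + 4L + 0:3])
    data <- if (len > 0) buf[pos + 8L + seq_len(len) - 1L] else raw(0)
    if (type == "IHDR") {
      W <- .rd_u32be(buf, pos + 8L)
      H <- .rd_u32be(buf, pos + 12L)
      if (as.integer(data[9]) != 8 || as.integer(data[10]) != 0)
        stopf("%s: only 8-bit grayscale PNG is supported", path)
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  rawpx <- memDecompress(idat, type = "gzip")
  stride <- W + 1L
  m <- matrix(0, H, W)
  for (i in seq_len(H)) {
    row <- rawpx[(i - 1L) * stride + 1L + seq_len(W)]
    ft <- as.integer(rawpx[(i - 1L) * stride + 1L])
    if (ft != 0L) stopf("%s: PNG filter type %d not supported", path, ft)
    m[i, ] <- as.integer(row) / 255
  }
  m
}

.rd_u32be <- function(buf, pos) {
  16777216 * as.numeric(buf[pos]) + 65536 * as.numeric(buf[pos + 1]) +
    256 * as.numeric(buf[pos + 2]) + as.numeric(buf[pos + 3])
}

# ---- CEE tables and manifests ------------------------------------------------

#' Write a CEE table to CSV
#'
#' @param tab data.frame containing (at least) the nine canonical factor
#'   columns.
#' @param path output CSV.
#' @export
write_cee <- function(tab, path) {
  miss <- setdiff(cee_factor_names(), names(tab))
  if (length(miss))
    stopf("CEE table is missing column(s): %s", paste(miss, collapse = ", "))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a CEE table from CSV with schema and range validation
#'
#' Requires the nine canonical factor columns (extra columns are kept but
#' ignored downstream). Values outside the published `[min, max]` ranges are
#' flagged in the `out_of_range` attribute, with a warning.
#'
#' @param path CSV file.
#' @param specs regression specs carrying the published ranges.
#' @return data.frame of CEE records.
#' @export
read_cee <- function(path, specs = default_cee_specs()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(vapply(specs, `[[`, character(1), "name"), names(tab))
  if (length(miss))
    stopf("schema error: CEE CSV %s is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  oor <- list()
  for (sp in specs) {
    m <- sp$marginal
    lo <- if (!is.null(m$min)) m$min else min(m$support)
    hi <- if (!is.null(m$max)) m$max else max(m$support)
    bad <- which(tab[[sp$name]] < lo | tab[[sp$name]] > hi)
    if (length(bad)) oor[[sp$name]] <- bad
  }
  if (length(oor))
    warning(sprintf("out-of-range CEE values in: %s",
                    paste(names(oor), collapse = ", ")), call. = FALSE)
  attr(tab, "out_of_range") <- oor
  tab
}

#' Export a synthetic cohort to disk
#'
#' Writes one multi-page TIFF per embryo (slices bottom to top), ground-truth
#' masks as PNG, the CEE table as CSV, and a manifest CSV (embryo_id, tiff,
#' outcome).
#'
#' @param cohort list of `synthetic_embryo` from [generate_cohort()].
#' @param dir output directory (created).
#' @param write_masks also write per-slice mask PNGs.
#' @return the manifest data.frame, invisibly.
#' @export
export_cohort <- function(cohort, dir, write_masks = TRUE) {
  dir.create(file.path(dir, "stacks"), recursive = TRUE, showWarnings = FALSE)
  if (write_masks)
    dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(e) {
    tiff <- file.path("stacks", paste0(e$embryo_id, ".tiff"))
    write_stack(e$stack, file.path(dir, tiff))
    if (write_masks) {
      for (i in seq_along(e$masks))
        write_mask_png(e$masks[[i]],
                       file.path(dir, "masks",
                                 sprintf("%s_slice%02d.png", e$embryo_id, i)))
    }
    data.frame(embryo_id = e$embryo_id, tiff = tiff, outcome = e$outcome)
  })
  manifest <- do.call(rbind, rows)
  cee <- do.call(rbind, lapply(cohort, `[[`, "cee"))
  cee <- cbind(embryo_id = manifest$embryo_id, cee)
  write_cee(cee, file.path(dir, "cee.csv"))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort manifest and validate the join against a CEE table
#'
#' @param dir cohort directory with `manifest.csv` and `cee.csv`.
#' @return list with `manifest` and `cee` data.frames (rows aligned).
#' @export
read_cohort_manifest <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  cee <- read_cee(file.path(dir, "cee.csv"))
  if (is.null(cee$embryo_id)) stopf("cee.csv has no embryo_id column")
  orphans <- setdiff(manifest$embryo_id, cee$embryo_id)
  if (length(orphans))
    stopf("manifest embryo_id(s) missing from the CEE table: %s",
          paste(orphans, collapse = ", "))
  cee <- cee[match(manifest$embryo_id, cee$embryo_id), , drop = FALSE]
  list(manifest = manifest, cee = cee)
}
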
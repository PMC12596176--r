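## ---- minimal DICOM support -------------------------------------------
## A deliberately small reader/writer for uncompressed single-frame CT
## series in Explicit VR Little Endian.  No R DICOM package is available
## in this stack, so the subset needed for HU-calibrated phantom series is
## implemented here: geometry tags, rescale tags and 16-bit pixel data.
## Full DICOM conformance (sequences, compressed transfer syntaxes,
## multi-frame objects) is out of scope.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_ROOT <- "1.2.826.0.1.3680043.10.1442."

new_uid <- function() {
  paste0(UID_ROOT, paste0(sample(0:9, 12, replace = TRUE), collapse = ""),
         ".", round(as.numeric(Sys.time()) * 100) %% 1e8)
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

pad_even <- function(s, pad = as.raw(32)) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, pad)
  r
}

## one data element, explicit VR
dicom_element <- function(group, element, vr, value) {
  if (vr %in% c("OB", "OW")) {
    body <- value
    c(u16(group), u16(element), charToRaw(vr), as.raw(c(0, 0)),
      u32(length(body)), body)
  } else {
    body <- if (vr == "US") u16(value) else if (vr == "UL") u32(value) else
      pad_even(as.character(value), as.raw(if (vr == "UI") 0 else 32))
    c(u16(group), u16(element), charToRaw(vr), u16(length(body)), body)
  }
}

ds_fmt <- function(x) paste(trimws(formatC(x, format = "fg", digits = 10)), collapse = "\\")

write_dicom_slice <- function(path, pixmat, meta, uids, k, z, spacing, origin) {
  stored <- round(pixmat + 1024)
  stored[stored < 0] <- 0; stored[stored > 65535] <- 65535
  stored <- as.integer(stored)
  stored[stored > 32767L] <- stored[stored > 32767L] - 65536L
  pix <- writeBin(stored, raw(), size = 2, endian = "little")

  sop_uid <- paste0(uids$series, ".", k)
  meta_elems <- c(
    dicom_element(2L, 1L, "OB", as.raw(c(0, 1))),
    dicom_element(2L, 2L, "UI", SOP_CT),
    dicom_element(2L, 3L, "UI", sop_uid),
    dicom_element(2L, 16L, "UI", TS_EXPLICIT_LE))
  header <- c(rep(as.raw(0), 128), charToRaw("DICM"),
              dicom_element(2L, 0L, "UL", length(meta_elems)), meta_elems)

  els <- c(
    dicom_element(0x0008, 0x0016, "UI", SOP_CT),
    dicom_element(0x0008, 0x0018, "UI", sop_uid),
    dicom_element(0x0008, 0x0060, "CS", "CT"),
    dicom_element(0x0008, 0x1090, "LO", meta$scanner_label %||% ""),
    dicom_element(0x0018, 0x0050, "DS", ds_fmt(spacing[3])),
    dicom_element(0x0018, 0x0060, "DS", meta$kvp %||% ""),
    dicom_element(0x0018, 0x1210, "SH", meta$recon_label %||% ""),
    dicom_element(0x0018, 0x9345, "DS",
                  if (is.null(meta$ctdi_vol) || is.na(meta$ctdi_vol)) ""
                  else ds_fmt(meta$ctdi_vol)),
    dicom_element(0x0020, 0x000D, "UI", uids$study),
    dicom_element(0x0020, 0x000E, "UI", uids$series),
    dicom_element(0x0020, 0x0013, "IS", as.character(k)),
    dicom_element(0x0020, 0x0032, "DS",
                  ds_fmt(c(origin[1], origin[2], z))),
    dicom_element(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
    dicom_element(0x0028, 0x0002, "US", 1L),
    dicom_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dicom_element(0x0028, 0x0010, "US", ncol(pixmat)),   # rows = y
    dicom_element(0x0028, 0x0011, "US", nrow(pixmat)),   # cols = x
    dicom_element(0x0028, 0x0030, "DS", ds_fmt(c(spacing[2], spacing[1]))),
    dicom_element(0x0028, 0x0100, "US", 16L),
    dicom_element(0x0028, 0x0101, "US", 16L),
    dicom_element(0x0028, 0x0102, "US", 15L),
    dicom_element(0x0028, 0x0103, "US", 0L),
    dicom_element(0x0028, 0x1052, "DS", "-1024"),
    dicom_element(0x0028, 0x1053, "DS", "1"),
    dicom_element(0x7FE0, 0x0010, "OW", pix))
  writeBin(c(header, els), path)
}

#' Write a volume as a DICOM series
#'
#' One uncompressed Explicit-VR-Little-Endian CT file per slice, with the
#' conventional Rescale Slope 1 / Intercept -1024 HU calibration, geometry
#' tags and (when supplied) protocol metadata.
#'
#' @param vol a [voxel_volume()].
#' @param directory output directory (created if needed).
#' @param meta optional [protocol_meta()] stored in scanner/recon/dose tags.
#' @return The directory, invisibly.
#' @export
write_dicom_series <- function(vol, directory, meta = NULL) {
  vol <- as_voxel_volume(vol)
  meta <- meta %||% list()
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$voxels)
  uids <- list(study = new_uid(), series = new_uid())
  for (k in seq_len(d[3])) {
    z <- vol$origin[3] + (k - 1) * vol$spacing[3]
    write_dicom_slice(file.path(directory, sprintf("slice_%04d.dcm", k)),
                      vol$voxels[, , k], meta, uids, k, z, vol$spacing,
                      vol$origin)
  }
  invisible(directory)
}

## --- reading -----------------------------------------------------------

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stopf("'%s' is not a DICOM part-10 file", basename(path))
  pos <- 133L
  rd_u16 <- function(at) sum(as.integer(raw[at + 0:1]) * c(1L, 256L))
  rd_u32 <- function(at) sum(as.numeric(raw[at + 0:3]) * c(1, 256, 65536, 16777216))
  tags <- list()
  n <- length(raw)
  ts <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7 <= n) {
    group <- rd_u16(pos); element <- rd_u16(pos + 2L)
    vr <- rawToChar(raw[pos + 4:5])
    if (vr %in% long_vrs) {
      len <- rd_u32(pos + 8L); data_at <- pos + 12L
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- rd_u16(pos + 6L); data_at <- pos + 8L
    } else stopf("'%s': implicit VR or unsupported encoding", basename(path))
    if (len == 4294967295) stopf("'%s': undefined-length element unsupported",
                                 basename(path))
    key <- sprintf("%04X,%04X", group, element)
    if (key == "7FE0,0010") {
      tags[[key]] <- raw[data_at:(data_at + len - 1)]
    } else if (group != 2 || element %in% c(16L)) {
      body <- if (len > 0) raw[data_at:(data_at + len - 1)] else raw(0)
      val <- rawToChar(body[body != as.raw(0)])
      if (vr == "US" && len >= 2) val <- rd_u16(data_at)
      tags[[key]] <- val
    }
    if (group == 2 && element == 16L)
      ts <- trimws(tags[[key]])
    pos <- data_at + len
    if (pos > 132 && group == 2 && !is.null(ts) && ts != TS_EXPLICIT_LE)
      stopf("'%s': unsupported transfer syntax %s", basename(path), ts)
  }
  tags
}

tag_str <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) return(NULL)
  trimws(as.character(v))
}
tag_num <- function(tags, key) {
  v <- tag_str(tags, key)
  if (is.null(v) || v == "") return(NULL)
  as.numeric(trimws(strsplit(v, "\\\\")[[1]]))
}

#' Read a DICOM series as a calibrated HU volume
#'
#' Reads every `*.dcm` file in a directory, sorts slices by their position
#' along the slice normal (independently of file names), converts stored
#' pixel values to HU via the mandatory rescale slope/intercept, and
#' derives the slice interval from inter-slice position differences rather
#' than the thickness tag (overlapping reconstructions make the two
#' differ).
#'
#' @param directory directory holding exactly one series of
#'   consistent-geometry slices.
#' @return A list with `volume` (a [voxel_volume()]) and `meta`
#'   (a [protocol_meta()] populated from tags where present).
#' @export
read_dicom_series <- function(directory) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stopf("no DICOM files in '%s'", directory)
  slices <- lapply(files, read_dicom_file)

  need <- function(tg, key, what) {
    v <- tag_num(tg, key)
    if (is.null(v)) stopf("HU calibration mandatory: missing %s", what)
    v
  }
  ref <- slices[[1]]
  rows <- as.integer(tag_num(ref, "0028,0010"))
  cols <- as.integer(tag_num(ref, "0028,0011"))
  pxsp <- tag_num(ref, "0028,0030")
  for (key in c("0028,0010", "0028,0011", "0028,0030", "0020,0037")) {
    vals <- vapply(slices, function(t) paste(tag_str(t, key), collapse = "/"), "")
    if (length(unique(vals)) != 1L)
      stopf("inconsistent series: attribute (%s) varies across slices", key)
  }
  zpos <- vapply(slices, function(t) need(t, "0020,0032", "ImagePositionPatient")[3], 0)
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]
  nz <- length(slices)
  dz <- if (nz > 1) diff(zpos) else tag_num(ref, "0018,0050") %||% 1
  if (nz > 2 && (max(dz) - min(dz)) > 1e-3)
    stopf("inconsistent series: slice spacing varies (ImagePositionPatient)")
  dz <- mean(dz)

  arr <- array(0, c(cols, rows, nz))
  for (k in seq_len(nz)) {
    tg <- slices[[k]]
    slope <- need(tg, "0028,1053", "RescaleSlope")
    inter <- need(tg, "0028,1052", "RescaleIntercept")
    pix <- readBin(tg[["7FE0,0010"]], "integer", n = rows * cols, size = 2,
                   endian = "little", signed = FALSE)
    arr[, , k] <- matrix(pix, nrow = cols) * slope + inter
  }
  ipp <- tag_num(slices[[1]], "0020,0032")
  vol <- voxel_volume(arr, spacing = c(pxsp[2], pxsp[1], dz),
                      origin = c(ipp[1], ipp[2], zpos[1]))
  meta <- protocol_meta(
    scanner_label = tag_str(ref, "0008,1090") %||% "",
    recon_label = tag_str(ref, "0018,1210") %||% "",
    ctdi_vol = tag_num(ref, "0018,9345") %||% NA_real_,
    kvp = tag_str(ref, "0018,0060") %||% "")
  list(volume = vol, meta = meta)
}
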
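# Minimal DICOM series reader: uncompressed single-frame CT images in the
# explicit-VR little-endian transfer syntax. No installed R package reads
# DICOM, so the small subset of the format needed for CT series (geometry,
# rescale, 16-bit pixel data) is parsed here directly.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM") {
    stopf("%s: not a DICOM part-10 file (missing DICM magic)", basename(path))
  }
  pos <- 133L
  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(raw[at:(at + 3L)], "integer", size = 4,
                              endian = "little")
  elements <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stopf("%s: element (%s) has no valid explicit VR; implicit-VR transfer syntaxes are unsupported",
            basename(path), dcm_tag(group, element))
    }
    if (vr %in% LONG_VRS) {
      len <- u32(pos + 8L)
      body_at <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      body_at <- pos + 8L
    }
    if (len < 0 || (vr == "SQ" && len == -1)) {
      stopf("%s: undefined-length element (%s) unsupported", basename(path),
            dcm_tag(group, element))
    }
    body <- if (len > 0) raw[body_at:(body_at + len - 1L)] else raw(0)
    elements[[dcm_tag(group, element)]] <- list(vr = vr, body = body)
    pos <- body_at + len
    if (group == 0x7FE0 && element == 0x0010) break
  }
  elements
}

dcm_string <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$body))
}

dcm_numeric <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(dcm_string(el), "\\\\")[[1]])
}

dcm_uint16 <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$body, "integer", n = length(el$body) / 2, size = 2,
          endian = "little", signed = FALSE)
}

dcm_required <- function(elements, tag, name, path) {
  el <- elements[[tag]]
  if (is.null(el)) {
    stopf("%s: required DICOM attribute %s (%s) is missing", basename(path),
          name, tag)
  }
  el
}

read_dicom_slice <- function(path) {
  el <- read_dicom_file(path)
  ts <- dcm_string(el[["0002,0010"]])
  if (!is.null(ts) && !ts %in% c("1.2.840.10008.1.2.1")) {
    stopf("%s: unsupported transfer syntax %s (only explicit VR little endian)",
          basename(path), ts)
  }
  modality <- dcm_string(dcm_required(el, "0008,0060", "Modality", path))
  if (!identical(modality, "CT")) {
    stopf("%s: Modality is '%s', expected 'CT'", basename(path), modality)
  }
  rows <- dcm_uint16(dcm_required(el, "0028,0010", "Rows", path))
  cols <- dcm_uint16(dcm_required(el, "0028,0011", "Columns", path))
  bits <- dcm_uint16(dcm_required(el, "0028,0100", "BitsAllocated", path))
  if (bits != 16) stopf("%s: BitsAllocated %d unsupported (need 16)",
                        basename(path), bits)
  pixrep <- dcm_uint16(el[["0028,0103"]]) %||% 0L
  ps <- dcm_numeric(dcm_required(el, "0028,0030", "PixelSpacing", path))
  ipp <- dcm_numeric(dcm_required(el, "0020,0032", "ImagePositionPatient", path))
  iop <- dcm_numeric(dcm_required(el, "0020,0037", "ImageOrientationPatient", path))
  slope <- (dcm_numeric(el[["0028,1053"]]) %||% 1)[1]
  intercept <- (dcm_numeric(el[["0028,1052"]]) %||% 0)[1]
  pd <- dcm_required(el, "7FE0,0010", "PixelData", path)
  stored <- readBin(pd$body, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = pixrep == 1L)
  if (pixrep == 0L) stored[stored < 0] <- stored[stored < 0] + 65536
  # Pixel data are row-major: first index (fastest) is the column. Our voxel
  # axis 1 is the column direction (iop[1:3]), axis 2 the row direction.
  plane <- matrix(stored, nrow = cols, ncol = rows)
  list(hu = slope * plane + intercept,
       ipp = ipp, row_dir = iop[1:3], col_dir = iop[4:6],
       spacing = c(ps[2], ps[1]),  # (column spacing, row spacing)
       path = path)
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2L) stopf("DICOM series needs at least 2 slices in %s", dir)
  slices <- lapply(files, read_dicom_slice)
  ref <- slices[[1]]
  for (s in slices[-1]) {
    if (max(abs(s$row_dir - ref$row_dir), abs(s$col_dir - ref$col_dir)) > 1e-4) {
      stopf("inconsistent ImageOrientationPatient across series (%s vs %s)",
            basename(ref$path), basename(s$path))
    }
    if (max(abs(s$spacing - ref$spacing)) > 1e-6) {
      stopf("inconsistent PixelSpacing across series (%s vs %s)",
            basename(ref$path), basename(s$path))
    }
    if (!all(dim(s$hu) == dim(ref$hu))) {
      stopf("inconsistent Rows/Columns across series (%s vs %s)",
            basename(ref$path), basename(s$path))
    }
  }
  normal <- cross3(ref$row_dir, ref$col_dir)
  z <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  dz <- diff(z)
  if (any(dz <= 1e-9)) stopf("duplicate slice positions in series")
  step <- stats::median(dz)
  bad <- which(abs(dz - step) > 0.01 * step)
  if (length(bad)) {
    stopf("missing or unevenly spaced slice between positions %.3f and %.3f mm (expected step %.3f mm)",
          z[bad[1]], z[bad[1] + 1L], step)
  }
  vals <- array(0, dim = c(dim(ref$hu), length(slices)))
  for (k in seq_along(slices)) vals[, , k] <- slices[[k]]$hu
  ct_volume(vals,
            spacing = c(ref$spacing, step),
            origin = slices[[1]]$ipp,
            orientation = cbind(ref$row_dir, ref$col_dir, normal))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
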
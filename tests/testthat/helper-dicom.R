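# Writes minimal explicit-VR little-endian CT DICOM files so the series
# reader can be exercised without storing binary fixtures.

dcm_pad_even <- function(raw) {
  if (length(raw) %% 2 == 1L) c(raw, as.raw(0x20)) else raw
}

dcm_element <- function(group, element, vr, body) {
  long <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  if (is.character(body)) body <- charToRaw(body)
  body <- dcm_pad_even(body)
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(element), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  len <- if (long) {
    c(as.raw(c(0, 0)),
      writeBin(length(body), raw(), size = 4, endian = "little"))
  } else {
    writeBin(length(body), raw(), size = 2, endian = "little")
  }
  c(head, len, body)
}

dcm_us <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

# hu: matrix indexed [column, row] (axis 1 = column direction).
write_test_dicom <- function(path, hu, ipp, pixel_spacing = c(0.8, 0.7),
                             slope = 1, intercept = -1024,
                             modality = "CT",
                             iop = c(1, 0, 0, 0, 1, 0),
                             transfer_syntax = "1.2.840.10008.1.2.1") {
  stored <- as.integer(round((as.vector(hu) - intercept) / slope))
  # pixel order is row-major: rows of the image, each across columns; our
  # matrix is [col, row] so as.vector() already gives column-fastest order
  pix <- writeBin(stored, raw(), size = 2, endian = "little")
  body <- c(
    dcm_element(0x0002, 0x0010, "UI", transfer_syntax),
    dcm_element(0x0008, 0x0060, "CS", modality),
    dcm_element(0x0020, 0x0032, "DS", paste(ipp, collapse = "\\")),
    dcm_element(0x0020, 0x0037, "DS", paste(iop, collapse = "\\")),
    dcm_element(0x0028, 0x0010, "US", dcm_us(ncol(hu))),   # Rows
    dcm_element(0x0028, 0x0011, "US", dcm_us(nrow(hu))),   # Columns
    dcm_element(0x0028, 0x0030, "DS",
                paste(c(pixel_spacing[2], pixel_spacing[1]), collapse = "\\")),
    dcm_element(0x0028, 0x0100, "US", dcm_us(16)),
    dcm_element(0x0028, 0x0103, "US", dcm_us(1)),
    dcm_element(0x0028, 0x1052, "DS", format(intercept)),
    dcm_element(0x0028, 0x1053, "DS", format(slope)),
    dcm_element(0x7FE0, 0x0010, "OW", pix))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}

# Writes a whole axis-aligned series from a 3D HU array; returns the dir.
write_test_series <- function(dir, values, spacing = c(0.8, 0.7, 1.5),
                              origin = c(10, 20, 30), shuffle = FALSE, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(values)[3]
  ks <- if (shuffle) sample(seq_len(nz)) else seq_len(nz)
  for (i in seq_along(ks)) {
    k <- ks[i]
    write_test_dicom(
      file.path(dir, sprintf("slice_%03d.dcm", i)),
      hu = values[, , k],
      ipp = c(origin[1], origin[2], origin[3] + (k - 1) * spacing[3]),
      pixel_spacing = spacing[1:2], ...)
  }
  dir
}
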
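# Build a minimal single-frame grayscale DICOM file (explicit VR little
# endian) byte by byte, so DICOM reading can be tested without shipping
# binary fixtures. Includes a couple of patient-metadata elements on
# purpose: loading must discard them.
write_test_dicom <- function(pixels, path, bit_depth = 8L,
                             implicit = FALSE,
                             patient_name = "Doe^Jane") {
  stopifnot(is.matrix(pixels))
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                              endian = "little")
  pad_even <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2L == 1L) r <- c(r, as.raw(0L))
    r
  }
  explicit_el <- function(group, element, vr, value) {
    if (vr %in% c("OB", "OW")) {
      c(u16(group), u16(element), charToRaw(vr), as.raw(c(0L, 0L)),
        u32(length(value)), value)
    } else {
      c(u16(group), u16(element), charToRaw(vr), u16(length(value)), value)
    }
  }
  implicit_el <- function(group, element, value) {
    c(u16(group), u16(element), u32(length(value)), value)
  }
  us_val <- function(x) u16(x)

  syntax <- if (implicit) "1.2.840.10008.1.2" else "1.2.840.10008.1.2.1"
  meta <- c(
    explicit_el(0x0002, 0x0010, "UI", pad_even(syntax)),
    explicit_el(0x0002, 0x0013, "SH", pad_even("cervroi-test"))
  )

  el <- if (implicit) {
    function(group, element, vr, value) implicit_el(group, element, value)
  } else {
    explicit_el
  }
  n <- length(pixels)
  pix_raw <- if (bit_depth <= 8L) {
    as.raw(as.integer(t(pixels)))
  } else {
    v <- as.integer(t(pixels))
    as.raw(as.vector(rbind(v %% 256L, v %/% 256L)))
  }
  body <- c(
    el(0x0010, 0x0010, "PN", pad_even(patient_name)),
    el(0x0010, 0x0020, "LO", pad_even("TEST-0001")),
    el(0x0028, 0x0002, "US", us_val(1L)),
    el(0x0028, 0x0004, "CS", pad_even("MONOCHROME2")),
    el(0x0028, 0x0010, "US", us_val(nrow(pixels))),
    el(0x0028, 0x0011, "US", us_val(ncol(pixels))),
    el(0x0028, 0x0100, "US", us_val(if (bit_depth <= 8L) 8L else 16L)),
    el(0x0028, 0x0101, "US", us_val(bit_depth)),
    el(0x0028, 0x0102, "US", us_val(bit_depth - 1L)),
    el(0x0028, 0x0103, "US", us_val(0L)),
    if (implicit) implicit_el(0x7FE0, 0x0010, pix_raw)
    else explicit_el(0x7FE0, 0x0010, "OW", pix_raw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
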
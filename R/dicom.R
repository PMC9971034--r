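# Minimal single-frame CT DICOM support: explicit VR little endian, the
# handful of tags the pipeline needs (geometry, ordering, 16-bit pixels).
# Multi-frame/enhanced DICOM and other transfer syntaxes are out of scope.

dicom_uid_root <- "1.2.826.0.1.3680043.10.999"

raw_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                   endian = "little")
raw_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                   endian = "little")

pad_even <- function(r, pad = as.raw(0L)) {
  if (length(r) %% 2 == 1) c(r, pad) else r
}

# one explicit-VR element
dcm_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    v <- charToRaw(value)
    v <- pad_even(v, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  } else {
    v <- value  # already raw
  }
  head <- c(raw_uint16(group), raw_uint16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), raw_uint32(length(v)), v)
  } else {
    c(head, raw_uint16(length(v)), v)
  }
}

ds_str <- function(x) paste(format(x, trim = TRUE, scientific = FALSE,
                                   digits = 10), collapse = "\\")

#' Write one CT slice as a DICOM file
#'
#' @param img Integer matrix (rows x cols) of stored values in 0..65535.
#' @param path Output file path.
#' @param pixel_spacing `(row, col)` spacing in mm.
#' @param slice_thickness,spacing_between Slice geometry in mm.
#' @param position `(x, y, z)` image position in mm.
#' @param instance Instance (acquisition) number.
#' @param series_uid Series instance UID shared by the stack.
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(img, path, pixel_spacing, slice_thickness,
                              spacing_between, position, instance,
                              series_uid) {
  img <- round(img)
  if (min(img) < 0 || max(img) > 65535)
    stop("stored values must be within 0..65535")
  sop_uid <- paste0(series_uid, ".", instance)
  pix <- writeBin(as.integer(t(img)), raw(), size = 2, endian = "little")
  body <- c(
    dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "CT"),
    dcm_element(0x0018, 0x0050, "DS", ds_str(slice_thickness)),
    dcm_element(0x0018, 0x0088, "DS", ds_str(spacing_between)),
    dcm_element(0x0020, 0x000D, "UI", paste0(series_uid, ".0")),
    dcm_element(0x0020, 0x000E, "UI", series_uid),
    dcm_element(0x0020, 0x0013, "IS", as.character(instance)),
    dcm_element(0x0020, 0x0032, "DS", ds_str(position)),
    dcm_element(0x0020, 0x0037, "DS", ds_str(c(1, 0, 0, 0, 1, 0))),
    dcm_element(0x0028, 0x0002, "US", raw_uint16(1)),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", raw_uint16(nrow(img))),
    dcm_element(0x0028, 0x0011, "US", raw_uint16(ncol(img))),
    dcm_element(0x0028, 0x0030, "DS", ds_str(pixel_spacing)),
    dcm_element(0x0028, 0x0100, "US", raw_uint16(16)),
    dcm_element(0x0028, 0x0101, "US", raw_uint16(16)),
    dcm_element(0x0028, 0x0102, "US", raw_uint16(15)),
    dcm_element(0x0028, 0x0103, "US", raw_uint16(0)),
    dcm_element(0x7FE0, 0x0010, "OW", pix)
  )
  meta <- c(
    dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", raw_uint32(length(meta))), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

read_u16 <- function(r, off) {
  readBin(r[off:(off + 1)], "integer", size = 2, endian = "little",
          signed = FALSE)
}
read_u32 <- function(r, off) {
  readBin(r[off:(off + 3)], "integer", size = 4, endian = "little")
}

#' Read one single-frame DICOM file
#'
#' Parses explicit-VR little-endian elements into the metadata the
#' pipeline uses plus the 16-bit pixel matrix.
#'
#' @param path DICOM file.
#' @return List with `img`, `pixel_spacing`, `slice_thickness`,
#'   `spacing_between`, `position`, `instance`, `series_uid`.
#' @export
read_dicom_slice <- function(path) {
  r <- readBin(path, raw(), n = file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  off <- 133L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  out <- list(slice_thickness = NA_real_, spacing_between = NA_real_,
              instance = NA_integer_)
  rows <- cols <- NULL
  while (off + 7 <= length(r)) {
    group <- read_u16(r, off); elem <- read_u16(r, off + 2)
    vr <- rawToChar(r[(off + 4):(off + 5)])
    if (vr %in% long_vrs) {
      len <- read_u32(r, off + 8)
      val_off <- off + 12L
    } else {
      len <- read_u16(r, off + 6)
      val_off <- off + 8L
    }
    val <- if (len > 0) r[val_off:(val_off + len - 1)] else raw(0)
    str_val <- function() sub(" +$", "", rawToChar(val[val != as.raw(0L)]))
    num_vals <- function() as.numeric(strsplit(str_val(), "\\\\")[[1]])
    if (group == 0x7FE0 && elem == 0x0010) {
      if (is.null(rows) || is.null(cols)) stop("pixel data before dimensions")
      px <- readBin(val, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = FALSE)
      out$img <- matrix(px, nrow = rows, ncol = cols, byrow = TRUE)
      break
    } else if (group == 0x0028 && elem == 0x0010) {
      rows <- readBin(val, "integer", size = 2, endian = "little",
                      signed = FALSE)
    } else if (group == 0x0028 && elem == 0x0011) {
      cols <- readBin(val, "integer", size = 2, endian = "little",
                      signed = FALSE)
    } else if (group == 0x0028 && elem == 0x0030) {
      out$pixel_spacing <- num_vals()
    } else if (group == 0x0018 && elem == 0x0050) {
      out$slice_thickness <- num_vals()[1]
    } else if (group == 0x0018 && elem == 0x0088) {
      out$spacing_between <- num_vals()[1]
    } else if (group == 0x0020 && elem == 0x0032) {
      out$position <- num_vals()
    } else if (group == 0x0020 && elem == 0x0013) {
      out$instance <- as.integer(str_val())
    } else if (group == 0x0020 && elem == 0x000E) {
      out$series_uid <- str_val()
    }
    off <- val_off + len
  }
  if (is.null(out$img)) stop("no pixel data found in ", path)
  out
}
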
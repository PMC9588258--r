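# Minimal DICOM codec covering the RT Plan / RT Image element subset this
# toolkit touches. Datasets are lists of elements; an element is
#   list(group, element, vr, value = raw)            for leaves, or
#   list(group, element, vr = "SQ", items = list(dataset, ...), undefined)
# for sequences. Values of unmodified elements are kept as raw bytes so that
# write-back preserves them byte-for-byte.

DCM_TRANSFER_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_TRANSFER_IMPLICIT_LE <- "1.2.840.10008.1.2"
DCM_SOP_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
DCM_SOP_RTIMAGE <- "1.2.840.10008.5.1.4.1.1.481.1"

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length
.dcm_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# tag dictionary for the subset: used for implicit-VR reads and for writing
.dcm_dict <- local({
  d <- rbind(
    c(0x0002, 0x0000, "UL"), c(0x0002, 0x0001, "OB"), c(0x0002, 0x0002, "UI"),
    c(0x0002, 0x0003, "UI"), c(0x0002, 0x0010, "UI"), c(0x0002, 0x0012, "UI"),
    c(0x0008, 0x0016, "UI"), c(0x0008, 0x0018, "UI"), c(0x0008, 0x0020, "DA"),
    c(0x0008, 0x0023, "DA"), c(0x0008, 0x0060, "CS"), c(0x0008, 0x1010, "SH"),
    c(0x0028, 0x0010, "US"), c(0x0028, 0x0011, "US"), c(0x0028, 0x0030, "DS"),
    c(0x0028, 0x0100, "US"), c(0x0028, 0x0101, "US"), c(0x0028, 0x0102, "US"),
    c(0x0028, 0x0103, "US"), c(0x0028, 0x1052, "DS"), c(0x0028, 0x1053, "DS"),
    c(0x3002, 0x0002, "SH"), c(0x3002, 0x0011, "DS"), c(0x3002, 0x000D, "DS"),
    c(0x3002, 0x0026, "DS"),
    c(0x300A, 0x0002, "SH"), c(0x300A, 0x0070, "SQ"), c(0x300A, 0x0078, "IS"),
    c(0x300A, 0x0086, "DS"), c(0x300A, 0x00B0, "SQ"), c(0x300A, 0x00B8, "CS"),
    c(0x300A, 0x00BC, "IS"), c(0x300A, 0x00C0, "IS"), c(0x300A, 0x00C2, "LO"),
    c(0x300A, 0x00C4, "CS"), c(0x300A, 0x00C6, "CS"), c(0x300A, 0x010E, "DS"),
    c(0x300A, 0x0110, "IS"), c(0x300A, 0x0111, "SQ"), c(0x300A, 0x0112, "IS"),
    c(0x300A, 0x011A, "SQ"), c(0x300A, 0x011C, "DS"), c(0x300A, 0x011E, "DS"),
    c(0x300A, 0x011F, "CS"), c(0x300A, 0x0134, "DS"),
    c(0x300C, 0x0004, "SQ"), c(0x300C, 0x0006, "IS"),
    c(0x7FE0, 0x0010, "OW")
  )
  data.frame(group = as.integer(d[, 1]),
             element = as.integer(d[, 2]), vr = d[, 3],
             stringsAsFactors = FALSE)
})

.dcm_lookup_vr <- function(group, element) {
  hit <- .dcm_dict$vr[.dcm_dict$group == group & .dcm_dict$element == element]
  if (length(hit)) hit[[1]] else "UN"
}

.uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.uint32 <- function(x) {
  # writeBin(size = 4) is signed; lengths here never exceed 2^31 - 1 except
  # the undefined-length marker, emitted explicitly as 0xFFFFFFFF
  if (x == 0xFFFFFFFF) return(as.raw(c(0xFF, 0xFF, 0xFF, 0xFF)))
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

.read_u16 <- function(raw, pos) {
  sum(as.integer(raw[pos:(pos + 1)]) * c(1, 256))
}
.read_u32 <- function(raw, pos) {
  b <- as.numeric(raw[pos:(pos + 3)])
  b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
}

dcm_element <- function(group, element, vr, value) {
  list(group = as.integer(group), element = as.integer(element),
       vr = vr, value = value)
}

dcm_sequence <- function(group, element, items, undefined = TRUE) {
  list(group = as.integer(group), element = as.integer(element),
       vr = "SQ", items = items, undefined = isTRUE(undefined))
}

# ---- value encoding -------------------------------------------------------

# decimal string: DICOM caps DS at 16 bytes per value
.ds_format1 <- function(x) {
  for (d in c(12, 10, 8, 6)) {
    s <- formatC(x, format = "g", digits = d, width = 1)
    s <- sub("e([+-])0(\\d\\d)$", "e\\1\\2", s)
    if (nchar(s) <= 16) return(s)
  }
  s
}

dcm_string_value <- function(x, pad = " ") {
  s <- paste(x, collapse = "\\")
  b <- charToRaw(s)
  if (length(b) %% 2 == 1) b <- c(b, charToRaw(pad))
  b
}

dcm_ds_value <- function(x) dcm_string_value(vapply(x, .ds_format1, ""))
dcm_is_value <- function(x) dcm_string_value(format(as.integer(x), trim = TRUE, scientific = FALSE))
dcm_ui_value <- function(x) {
  b <- charToRaw(paste(x, collapse = "\\"))
  if (length(b) %% 2 == 1) b <- c(b, as.raw(0))
  b
}
dcm_us_value <- function(x) .uint16(x)

dcm_decode_string <- function(el) {
  s <- rawToChar(el$value)
  s <- gsub("\\x00", "", s, useBytes = TRUE)
  s <- sub("[ ]+$", "", s)
  strsplit(s, "\\", fixed = TRUE)[[1]]
}
dcm_decode_numeric <- function(el) as.numeric(dcm_decode_string(el))
# first value of a string element, NA when empty
dcm_decode_string1 <- function(el) {
  s <- dcm_decode_string(el)
  if (length(s)) s[[1]] else NA_character_
}
dcm_decode_us <- function(el) {
  n <- length(el$value) / 2
  vapply(seq_len(n), function(i) .read_u16(el$value, 2L * i - 1L), 0)
}

# ---- reading --------------------------------------------------------------

.dcm_parse_elements <- function(raw, pos, end, explicit) {
  out <- list()
  while (pos < end) {
    parsed <- .dcm_parse_one(raw, pos, explicit)
    out[[length(out) + 1]] <- parsed$element
    pos <- parsed$pos
  }
  list(elements = out, pos = pos)
}

.dcm_parse_items <- function(raw, pos, end, explicit) {
  items <- list()
  repeat {
    if (!is.na(end) && pos >= end) break
    group <- .read_u16(raw, pos); element <- .read_u16(raw, pos + 2)
    len <- .read_u32(raw, pos + 4); pos <- pos + 8
    if (group == 0xFFFE && element == 0xE0DD) break            # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000)) stop("malformed sequence item tag")
    if (len == 0xFFFFFFFF) {
      parsed <- .dcm_parse_item_undef(raw, pos, explicit)
      items[[length(items) + 1]] <- parsed$elements
      pos <- parsed$pos
    } else {
      parsed <- .dcm_parse_elements(raw, pos, pos + len, explicit)
      items[[length(items) + 1]] <- parsed$elements
      pos <- pos + len
    }
  }
  list(items = items, pos = pos)
}

.dcm_parse_item_undef <- function(raw, pos, explicit) {
  out <- list()
  repeat {
    group <- .read_u16(raw, pos); element <- .read_u16(raw, pos + 2)
    if (group == 0xFFFE && element == 0xE00D) {                # item delimiter
      pos <- pos + 8
      break
    }
    parsed <- .dcm_parse_one(raw, pos, explicit)
    out[[length(out) + 1]] <- parsed$element
    pos <- parsed$pos
  }
  list(elements = out, pos = pos)
}

.dcm_parse_one <- function(raw, pos, explicit) {
  group <- .read_u16(raw, pos); element <- .read_u16(raw, pos + 2); pos <- pos + 4
  if (explicit) {
    vr <- rawToChar(raw[pos:(pos + 1)]); pos <- pos + 2
    if (vr %in% .dcm_long_vrs) {
      len <- .read_u32(raw, pos + 2); pos <- pos + 6
    } else {
      len <- .read_u16(raw, pos); pos <- pos + 2
    }
  } else {
    vr <- .dcm_lookup_vr(group, element)
    len <- .read_u32(raw, pos); pos <- pos + 4
  }
  undefined <- (len == 0xFFFFFFFF)
  if (vr == "SQ" || (undefined && vr == "UN")) {
    parsed <- .dcm_parse_items(raw, pos, if (undefined) NA else pos + len, explicit)
    list(element = dcm_sequence(group, element, parsed$items, undefined), pos = parsed$pos)
  } else {
    if (undefined) stop("undefined-length non-sequence element not supported")
    val <- if (len > 0) raw[pos:(pos + len - 1)] else raw(0)
    list(element = dcm_element(group, element, vr, val), pos = pos + len)
  }
}

#' Read a DICOM file
#'
#' Parses the preamble, file meta group, and main dataset of a DICOM part-10
#' file. Explicit and implicit VR little endian transfer syntaxes are
#' supported; elements outside the toolkit's dictionary are retained as opaque
#' byte strings so that write-back preserves them.
#'
#' @param path file path.
#' @return list with components `meta` and `data` (element lists) and
#'   `transfer_syntax`.
#' @keywords internal
dcm_read <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133
  # file meta group is always explicit VR; (0002,0000) gives its byte length
  first <- .dcm_parse_one(raw, pos, explicit = TRUE)
  if (first$element$group != 2L || first$element$element != 0L)
    stop("missing file meta group length")
  meta_len <- .read_u32(first$element$value, 1)
  meta_end <- first$pos + meta_len
  meta <- .dcm_parse_elements(raw, first$pos, meta_end, explicit = TRUE)$elements
  meta <- c(list(first$element), meta)
  ts_el <- dcm_find(meta, 0x0002, 0x0010)
  ts <- if (is.null(ts_el)) DCM_TRANSFER_EXPLICIT_LE else dcm_decode_string(ts_el)[[1]]
  explicit <- ts != DCM_TRANSFER_IMPLICIT_LE
  if (!ts %in% c(DCM_TRANSFER_EXPLICIT_LE, DCM_TRANSFER_IMPLICIT_LE))
    stop("unsupported transfer syntax: ", ts)
  data <- .dcm_parse_elements(raw, meta_end, length(raw) + 1, explicit)$elements
  list(meta = meta, data = data, transfer_syntax = ts)
}

dcm_find <- function(elements, group, element) {
  for (el in elements)
    if (el$group == group && el$element == element) return(el)
  NULL
}

dcm_find_all <- function(elements, group, element) {
  Filter(function(el) el$group == group && el$element == element, elements)
}

# replace (or append, keeping tag order) a leaf element's value
dcm_set <- function(elements, group, element, vr, value) {
  for (i in seq_along(elements)) {
    if (elements[[i]]$group == group && elements[[i]]$element == element) {
      elements[[i]] <- dcm_element(group, element, vr, value)
      return(elements)
    }
  }
  keys <- vapply(elements, function(e) e$group * 2^16 + e$element, 0)
  at <- sum(keys < group * 2^16 + element)
  append(elements, list(dcm_element(group, element, vr, value)), after = at)
}

# ---- writing --------------------------------------------------------------

.dcm_write_element <- function(el) {
  head <- c(.uint16(el$group), .uint16(el$element))
  if (el$vr == "SQ") {
    body <- do.call(c, c(list(raw(0)), lapply(el$items, .dcm_write_item, undefined = isTRUE(el$undefined))))
    if (isTRUE(el$undefined)) {
      c(head, charToRaw("SQ"), as.raw(c(0, 0)), .uint32(0xFFFFFFFF), body,
        .uint16(0xFFFE), .uint16(0xE0DD), .uint32(0))
    } else {
      c(head, charToRaw("SQ"), as.raw(c(0, 0)), .uint32(length(body)), body)
    }
  } else if (el$vr %in% .dcm_long_vrs) {
    c(head, charToRaw(el$vr), as.raw(c(0, 0)), .uint32(length(el$value)), el$value)
  } else {
    c(head, charToRaw(el$vr), .uint16(length(el$value)), el$value)
  }
}

.dcm_write_item <- function(item, undefined = TRUE) {
  body <- do.call(c, c(list(raw(0)), lapply(item, .dcm_write_element)))
  if (undefined) {
    c(.uint16(0xFFFE), .uint16(0xE000), .uint32(0xFFFFFFFF), body,
      .uint16(0xFFFE), .uint16(0xE00D), .uint32(0))
  } else {
    c(.uint16(0xFFFE), .uint16(0xE000), .uint32(length(body)), body)
  }
}

dcm_write_elements <- function(elements) {
  do.call(c, c(list(raw(0)), lapply(elements, .dcm_write_element)))
}

#' Generate a DICOM UID
#'
#' UIDs under the 2.25 (UUID-derived) root, drawn from R's random number
#' stream so that fixture generation is fully reproducible under a fixed seed.
#' @keywords internal
dcm_new_uid <- function() {
  digits <- sample.int(10L, 32L, replace = TRUE) - 1L
  digits[1] <- sample.int(9L, 1L)  # no leading zero
  paste0("2.25.", paste(digits, collapse = ""))
}

#' Write a DICOM part-10 file
#'
#' Serializes a dataset with a standard preamble and file meta group in
#' explicit VR little endian.
#' @keywords internal
dcm_write <- function(data_elements, path, sop_class, sop_instance) {
  meta_body <- dcm_write_elements(list(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", dcm_ui_value(sop_class)),
    dcm_element(0x0002, 0x0003, "UI", dcm_ui_value(sop_instance)),
    dcm_element(0x0002, 0x0010, "UI", dcm_ui_value(DCM_TRANSFER_EXPLICIT_LE)),
    dcm_element(0x0002, 0x0012, "UI", dcm_ui_value("2.25.1000"))
  ))
  meta <- c(dcm_write_elements(list(
    dcm_element(0x0002, 0x0000, "UL", .uint32(length(meta_body)))
  )), meta_body)
  out <- c(raw(128), charToRaw("DICM"), meta, dcm_write_elements(data_elements))
  writeBin(out, path)
  invisible(path)
}
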
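# Minimal DICOM codec: explicit/implicit VR little endian, the tag subset
# needed for CT image slices, RTSTRUCT and RTDOSE objects. Datasets are
# represented as named lists keyed by DICOM keyword; sequence (SQ) elements
# hold a list of item datasets. This is deliberately not a conformant DICOM
# implementation (see package non-goals); it reads what it writes, plus
# standard explicit/implicit little-endian files restricted to these tags.

dcm_dictionary <- function() {
  d <- rbind(
    c("FileMetaInformationVersion",          "0002", "0001", "OB"),
    c("MediaStorageSOPClassUID",             "0002", "0002", "UI"),
    c("MediaStorageSOPInstanceUID",          "0002", "0003", "UI"),
    c("TransferSyntaxUID",                   "0002", "0010", "UI"),
    c("ImplementationClassUID",              "0002", "0012", "UI"),
    c("SOPClassUID",                         "0008", "0016", "UI"),
    c("SOPInstanceUID",                      "0008", "0018", "UI"),
    c("StudyDate",                           "0008", "0020", "DA"),
    c("StudyTime",                           "0008", "0030", "TM"),
    c("Modality",                            "0008", "0060", "CS"),
    c("PatientName",                         "0010", "0010", "PN"),
    c("PatientID",                           "0010", "0020", "LO"),
    c("SliceThickness",                      "0018", "0050", "DS"),
    c("StudyInstanceUID",                    "0020", "000d", "UI"),
    c("SeriesInstanceUID",                   "0020", "000e", "UI"),
    c("SeriesNumber",                        "0020", "0011", "IS"),
    c("InstanceNumber",                      "0020", "0013", "IS"),
    c("ImagePositionPatient",                "0020", "0032", "DS"),
    c("ImageOrientationPatient",             "0020", "0037", "DS"),
    c("FrameOfReferenceUID",                 "0020", "0052", "UI"),
    c("SamplesPerPixel",                     "0028", "0002", "US"),
    c("PhotometricInterpretation",           "0028", "0004", "CS"),
    c("NumberOfFrames",                      "0028", "0008", "IS"),
    c("Rows",                                "0028", "0010", "US"),
    c("Columns",                             "0028", "0011", "US"),
    c("PixelSpacing",                        "0028", "0030", "DS"),
    c("BitsAllocated",                       "0028", "0100", "US"),
    c("BitsStored",                          "0028", "0101", "US"),
    c("HighBit",                             "0028", "0102", "US"),
    c("PixelRepresentation",                 "0028", "0103", "US"),
    c("RescaleIntercept",                    "0028", "1052", "DS"),
    c("RescaleSlope",                        "0028", "1053", "DS"),
    c("DoseUnits",                           "3004", "0002", "CS"),
    c("DoseType",                            "3004", "0004", "CS"),
    c("DoseSummationType",                   "3004", "000a", "CS"),
    c("GridFrameOffsetVector",               "3004", "000c", "DS"),
    c("DoseGridScaling",                     "3004", "000e", "DS"),
    c("StructureSetLabel",                   "3006", "0002", "SH"),
    c("ReferencedFrameOfReferenceSequence",  "3006", "0010", "SQ"),
    c("StructureSetROISequence",             "3006", "0020", "SQ"),
    c("ROINumber",                           "3006", "0022", "IS"),
    c("ReferencedFrameOfReferenceUID",       "3006", "0024", "UI"),
    c("ROIName",                             "3006", "0026", "LO"),
    c("ROIGenerationAlgorithm",              "3006", "0036", "CS"),
    c("ROIContourSequence",                  "3006", "0039", "SQ"),
    c("ContourSequence",                     "3006", "0040", "SQ"),
    c("ContourGeometricType",                "3006", "0042", "CS"),
    c("NumberOfContourPoints",               "3006", "0046", "IS"),
    c("ContourData",                         "3006", "0050", "DS"),
    c("ReferencedROINumber",                 "3006", "0084", "IS"),
    c("PixelData",                           "7fe0", "0010", "OW")
  )
  data.frame(keyword = d[, 1], group = d[, 2], elem = d[, 3], vr = d[, 4],
             stringsAsFactors = FALSE)
}

.dcm_dict <- dcm_dictionary()

dcm_lookup_keyword <- function(keyword) {
  i <- match(keyword, .dcm_dict$keyword)
  if (is.na(i)) stop("tag keyword not in dictionary: ", keyword)
  .dcm_dict[i, ]
}

dcm_lookup_tag <- function(group, elem) {
  i <- which(.dcm_dict$group == group & .dcm_dict$elem == elem)
  if (length(i) == 0) return(NULL)
  .dcm_dict[i[1], ]
}

.dcm_string_vrs <- c("UI", "CS", "SH", "LO", "ST", "PN", "DA", "TM", "AE")
.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_uid <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    paste0("2.25.", format(counter, scientific = FALSE), ".",
           paste0(sample.int(9, 12, replace = TRUE), collapse = ""))
  }
})

# ---- encoding -------------------------------------------------------------

dcm_uint16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                       endian = "little")
dcm_uint32_raw <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                       endian = "little")

dcm_encode_value <- function(vr, value) {
  if (is.raw(value)) {
    out <- value
  } else if (vr %in% c("DS")) {
    out <- charToRaw(paste(vapply(as.numeric(value), function(v)
      sprintf("%.10g", v), ""), collapse = "\\"))
  } else if (vr %in% c("IS")) {
    out <- charToRaw(paste(format(as.integer(value)), collapse = "\\"))
  } else if (vr %in% .dcm_string_vrs) {
    out <- charToRaw(paste(as.character(value), collapse = "\\"))
  } else if (vr == "US") {
    out <- dcm_uint16_raw(value)
  } else if (vr == "UL") {
    out <- dcm_uint32_raw(value)
  } else if (vr == "FD") {
    out <- writeBin(as.numeric(value), raw(), size = 8, endian = "little")
  } else if (vr == "FL") {
    out <- writeBin(as.numeric(value), raw(), size = 4, endian = "little")
  } else {
    stop("cannot encode VR ", vr)
  }
  if (length(out) %% 2 == 1) {
    pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
    out <- c(out, pad)
  }
  out
}

dcm_encode_element <- function(group, elem, vr, payload) {
  tag <- c(dcm_uint16_raw(strtoi(group, 16L)), dcm_uint16_raw(strtoi(elem, 16L)))
  if (vr %in% .dcm_long_vrs) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)), dcm_uint32_raw(length(payload)),
      payload)
  } else {
    c(tag, charToRaw(vr), dcm_uint16_raw(length(payload)), payload)
  }
}

dcm_encode_dataset <- function(ds) {
  keys <- names(ds)
  info <- do.call(rbind, lapply(keys, dcm_lookup_keyword))
  ord <- order(info$group, info$elem)
  parts <- lapply(ord, function(i) {
    vr <- info$vr[i]
    value <- ds[[keys[i]]]
    if (vr == "SQ") {
      items <- lapply(value, function(item) {
        body <- dcm_encode_dataset(item)
        c(dcm_uint16_raw(0xFFFE), dcm_uint16_raw(0xE000),
          dcm_uint32_raw(length(body)), body)
      })
      payload <- do.call(c, c(items, list(raw(0))))
    } else {
      payload <- dcm_encode_value(vr, value)
    }
    dcm_encode_element(info$group[i], info$elem[i], vr, payload)
  })
  do.call(c, c(parts, list(raw(0))))
}

#' @noRd
dcm_write <- function(ds, path) {
  if (is.null(ds$SOPClassUID)) stop("dataset must carry SOPClassUID")
  if (is.null(ds$SOPInstanceUID)) ds$SOPInstanceUID <- dcm_uid()
  meta <- list(
    FileMetaInformationVersion = as.raw(c(0, 1)),
    MediaStorageSOPClassUID = ds$SOPClassUID,
    MediaStorageSOPInstanceUID = ds$SOPInstanceUID,
    TransferSyntaxUID = "1.2.840.10008.1.2.1",
    ImplementationClassUID = "2.25.190844300706"
  )
  meta_body <- dcm_encode_dataset(meta)
  # group length element (0002,0000)
  group_len <- c(dcm_uint16_raw(2L), dcm_uint16_raw(0L), charToRaw("UL"),
                 dcm_uint16_raw(4L), dcm_uint32_raw(length(meta_body)))
  body <- dcm_encode_dataset(ds)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), group_len, meta_body, body), con)
  invisible(path)
}

# ---- decoding -------------------------------------------------------------

dcm_read_uint <- function(buf, pos, size) {
  v <- readBin(buf[pos:(pos + size - 1)], "integer", n = 1, size = size,
               signed = size >= 4, endian = "little")
  if (size >= 4 && v < 0) v <- NA_integer_  # 0xFFFFFFFF = undefined length
  if (size < 4 && v < 0) v <- v + 2^(8 * size)
  v
}

dcm_parse_value <- function(vr, payload) {
  if (vr %in% c("DS", "IS")) {
    s <- trimws(rawToChar(payload))
    if (nchar(s) == 0) return(numeric(0))
    as.numeric(strsplit(s, "\\\\")[[1]])
  } else if (vr %in% .dcm_string_vrs || vr == "UN") {
    s <- rawToChar(payload[payload != as.raw(0)])
    s <- sub("[ ]+$", "", s)
    if (grepl("\\\\", s)) strsplit(s, "\\\\")[[1]] else s
  } else if (vr == "US") {
    readBin(payload, "integer", n = length(payload) / 2, size = 2,
            signed = FALSE, endian = "little")
  } else if (vr == "SS") {
    readBin(payload, "integer", n = length(payload) / 2, size = 2,
            signed = TRUE, endian = "little")
  } else if (vr == "UL") {
    readBin(payload, "integer", n = length(payload) / 4, size = 4,
            endian = "little")
  } else if (vr == "FD") {
    readBin(payload, "double", n = length(payload) / 8, size = 8,
            endian = "little")
  } else if (vr == "FL") {
    readBin(payload, "double", n = length(payload) / 4, size = 4,
            endian = "little")
  } else {
    payload  # OB/OW and friends stay raw
  }
}

# Parse elements of one dataset between pos and end (1-based, inclusive
# start, exclusive end). Returns list(data=..., pos=...). `stop_tag` allows
# item parsing to end at an item delimiter.
dcm_parse_dataset <- function(buf, pos, end, implicit = FALSE) {
  out <- list()
  while (pos < end) {
    group <- sprintf("%04x", dcm_read_uint(buf, pos, 2))
    elem <- sprintf("%04x", dcm_read_uint(buf, pos + 2, 2))
    pos <- pos + 4
    if (group == "fffe") {  # item delimitation inside undefined-length item
      pos <- pos + 4
      if (elem == "e00d" || elem == "e0dd") break
      next
    }
    entry <- dcm_lookup_tag(group, elem)
    if (implicit) {
      len <- dcm_read_uint(buf, pos, 4)
      pos <- pos + 4
      vr <- if (!is.null(entry)) entry$vr else "UN"
      if (is.na(len)) vr <- "SQ"  # undefined length implies a sequence here
    } else {
      vr <- rawToChar(buf[pos:(pos + 1)])
      pos <- pos + 2
      if (vr %in% .dcm_long_vrs) {
        len <- dcm_read_uint(buf, pos + 2, 4)
        pos <- pos + 6
      } else {
        len <- dcm_read_uint(buf, pos, 2)
        pos <- pos + 2
      }
    }
    if (vr == "SQ" || (is.na(len) && vr %in% c("UN", "OB"))) {
      sq_end <- if (is.na(len)) end else pos + len
      items <- list()
      while (pos < sq_end) {
        ig <- dcm_read_uint(buf, pos, 2)
        ie <- dcm_read_uint(buf, pos + 2, 2)
        ilen <- dcm_read_uint(buf, pos + 4, 4)
        pos <- pos + 8
        if (ig == 0xFFFE && ie == 0xE0DD) break     # sequence delimiter
        if (ig != 0xFFFE || ie != 0xE000)
          stop("malformed sequence item at byte ", pos - 8)
        item_end <- if (is.na(ilen)) sq_end else pos + ilen
        parsed <- dcm_parse_dataset(buf, pos, item_end, implicit)
        items[[length(items) + 1]] <- parsed$data
        pos <- parsed$pos
      }
      if (!is.null(entry)) out[[entry$keyword]] <- items
    } else {
      if (is.na(len)) stop("undefined length on non-sequence element ",
                           group, ",", elem)
      payload <- if (len > 0) buf[pos:(pos + len - 1)] else raw(0)
      pos <- pos + len
      if (!is.null(entry)) out[[entry$keyword]] <- dcm_parse_value(entry$vr,
                                                                  payload)
    }
  }
  list(data = out, pos = pos)
}

#' @noRd
dcm_read <- function(path) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133
  # file meta group is always explicit little endian
  ts <- "1.2.840.10008.1.2.1"
  repeat {
    if (pos >= length(buf)) break
    group <- dcm_read_uint(buf, pos, 2)
    if (group != 2L) break
    elem <- sprintf("%04x", dcm_read_uint(buf, pos + 2, 2))
    vr <- rawToChar(buf[(pos + 4):(pos + 5)])
    if (vr %in% .dcm_long_vrs) {
      len <- dcm_read_uint(buf, pos + 8, 4)
      vstart <- pos + 12
    } else {
      len <- dcm_read_uint(buf, pos + 6, 2)
      vstart <- pos + 8
    }
    if (elem == "0010")
      ts <- dcm_parse_value("UI", buf[vstart:(vstart + len - 1)])
    pos <- vstart + len
  }
  implicit <- identical(ts, "1.2.840.10008.1.2")
  if (!implicit && !identical(ts, "1.2.840.10008.1.2.1"))
    stop("unsupported transfer syntax: ", ts)
  dcm_parse_dataset(buf, pos, length(buf) + 1, implicit)$data
}
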
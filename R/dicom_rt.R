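# DICOM radiotherapy object I/O built on the minimal codec in dicom.R:
# CT image series (one file per axial slice), RTSTRUCT planar contours,
# RTDOSE gridded dose.

.uid_ct <- "1.2.840.10008.5.1.4.1.1.2"
.uid_rtstruct <- "1.2.840.10008.5.1.4.1.1.481.3"
.uid_rtdose <- "1.2.840.10008.5.1.4.1.1.481.2"

#' Write an image volume as a DICOM CT series
#'
#' One file per axial slice, explicit VR little endian. Intensities are
#' stored as unsigned 16-bit with rescale intercept -1024 and slope 1, so
#' integer HU round-trip exactly.
#'
#' @param volume an [image_volume] in HU.
#' @param directory output directory (created if needed).
#' @param patient_id identifier written to the files.
#' @param frame_uid frame-of-reference UID; generated when `NULL`.
#' @return The frame-of-reference UID, invisibly.
#' @export
write_ct_series <- function(volume, directory, patient_id = "PHANTOM",
                            frame_uid = NULL) {
  stopifnot_volume(volume)
  d <- dim(volume$voxels)
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  if (is.null(frame_uid)) frame_uid <- dcm_uid()
  series_uid <- dcm_uid()
  study_uid <- dcm_uid()
  for (k in seq_len(d[3])) {
    hu <- round(volume$voxels[, , k])
    px <- pmin(pmax(hu + 1024, 0), 65535)
    ds <- list(
      SOPClassUID = .uid_ct,
      SOPInstanceUID = dcm_uid(),
      Modality = "CT",
      PatientName = patient_id,
      PatientID = patient_id,
      StudyInstanceUID = study_uid,
      SeriesInstanceUID = series_uid,
      FrameOfReferenceUID = frame_uid,
      InstanceNumber = k,
      ImagePositionPatient = c(volume$origin[1], volume$origin[2],
                               volume$origin[3] + (k - 1) * volume$spacing[3]),
      ImageOrientationPatient = c(1, 0, 0, 0, 1, 0),
      SliceThickness = volume$spacing[3],
      SamplesPerPixel = 1L,
      PhotometricInterpretation = "MONOCHROME2",
      Rows = d[2],
      Columns = d[1],
      PixelSpacing = c(volume$spacing[2], volume$spacing[1]),
      BitsAllocated = 16L,
      BitsStored = 16L,
      HighBit = 15L,
      PixelRepresentation = 0L,
      RescaleIntercept = -1024,
      RescaleSlope = 1,
      PixelData = writeBin(as.integer(px), raw(), size = 2, endian = "little")
    )
    dcm_write(ds, file.path(directory, sprintf("ct_%04d.dcm", k)))
  }
  invisible(frame_uid)
}

#' Load a DICOM CT series from a directory
#'
#' Slices are sorted by their z position regardless of file order; rescale
#' slope and intercept are applied so voxels are in HU. The series must be a
#' single coherent axial series: mixed series UIDs, non-uniform z gaps and
#' non-axial orientations are rejected with descriptive errors.
#'
#' @param directory directory containing one CT series (`.dcm` files).
#' @param z_tol tolerance (mm) on slice-gap uniformity.
#' @return An [image_volume] in HU, with the frame-of-reference UID in
#'   attribute `frame_uid`.
#' @export
load_ct_series <- function(directory, z_tol = 0.01) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) stop("no DICOM files in ", directory)
  slices <- lapply(files, dcm_read)
  modal <- vapply(slices, function(s) s$Modality %||% "", "")
  slices <- slices[modal == "CT"]
  if (length(slices) < 2) stop("fewer than 2 slices in CT series")
  series <- vapply(slices, function(s) s$SeriesInstanceUID %||% "", "")
  if (length(unique(series)) > 1)
    stop("mixed series: directory contains ", length(unique(series)),
         " different SeriesInstanceUIDs")
  for (s in slices) {
    iop <- s$ImageOrientationPatient
    if (is.null(iop) || max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
      stop("non-axial orientation is not supported")
  }
  zs <- vapply(slices, function(s) s$ImagePositionPatient[3], 0)
  ord <- order(zs)
  slices <- slices[ord]
  zs <- zs[ord]
  gaps <- diff(zs)
  if (any(abs(gaps - gaps[1]) > z_tol))
    stop(sprintf(paste0("missing slices or non-uniform z spacing: gaps range ",
                        "%.4f to %.4f mm"), min(gaps), max(gaps)))
  first <- slices[[1]]
  nx <- first$Columns
  ny <- first$Rows
  ps <- first$PixelSpacing  # (row spacing = dy, column spacing = dx)
  for (s in slices) {
    if (s$Columns != nx || s$Rows != ny || max(abs(s$PixelSpacing - ps)) > 1e-9)
      stop("inconsistent in-plane geometry across slices")
  }
  vox <- array(0, dim = c(nx, ny, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    signed <- isTRUE(s$PixelRepresentation == 1)
    px <- readBin(s$PixelData, "integer", n = nx * ny, size = 2,
                  signed = signed, endian = "little")
    slope <- s$RescaleSlope %||% 1
    icpt <- s$RescaleIntercept %||% 0
    vox[, , k] <- array(px * slope + icpt, dim = c(nx, ny))
  }
  vol <- image_volume(vox, spacing = c(ps[2], ps[1], gaps[1]),
                      origin = c(first$ImagePositionPatient[1:2], zs[1]))
  attr(vol, "frame_uid") <- first$FrameOfReferenceUID %||% NA_character_
  vol
}

#' Write and read a structure set as DICOM RTSTRUCT
#'
#' Contour points are stored in patient mm as CLOSED_PLANAR contours;
#' write-then-read round trips preserve vertices to well under 1e-3 mm.
#' Open polylines present in a file are kept but flagged with a warning
#' rather than silently closed.
#'
#' @param ss a [structure_set].
#' @param path output/input `.dcm` file.
#' @param frame_uid frame-of-reference UID; defaults to the set's frame.
#' @param name for reading: select the ROI with this name (default: first).
#' @return `read_structure_set` returns a [structure_set].
#' @export
write_structure_set <- function(ss, path, frame_uid = NULL) {
  if (!is_structure_set(ss)) stop("expected a 'structure_set'")
  if (is.null(frame_uid))
    frame_uid <- if (!is.null(ss$frame)) ss$frame else dcm_uid()
  contour_items <- lapply(ss$contours, function(ct) {
    pts3 <- cbind(ct$points, ct$z)
    list(ContourGeometricType = "CLOSED_PLANAR",
         NumberOfContourPoints = nrow(ct$points),
         ContourData = as.numeric(t(pts3)))
  })
  ds <- list(
    SOPClassUID = .uid_rtstruct,
    SOPInstanceUID = dcm_uid(),
    Modality = "RTSTRUCT",
    StructureSetLabel = substr(ss$name, 1, 16),
    ReferencedFrameOfReferenceSequence = list(
      list(FrameOfReferenceUID = frame_uid)
    ),
    StructureSetROISequence = list(
      list(ROINumber = 1L,
           ReferencedFrameOfReferenceUID = frame_uid,
           ROIName = ss$name,
           ROIGenerationAlgorithm = "AUTOMATIC")
    ),
    ROIContourSequence = list(
      list(ReferencedROINumber = 1L, ContourSequence = contour_items)
    )
  )
  dcm_write(ds, path)
  invisible(path)
}

#' @rdname write_structure_set
#' @export
read_structure_set <- function(path, name = NULL) {
  ds <- dcm_read(path)
  rois <- ds$StructureSetROISequence
  if (is.null(rois) || length(rois) == 0) stop("no contours: RTSTRUCT has no ROIs")
  idx <- 1L
  if (!is.null(name)) {
    nm <- vapply(rois, function(r) r$ROIName %||% "", "")
    idx <- match(name, nm)
    if (is.na(idx)) stop("no ROI named '", name, "'")
  }
  roi <- rois[[idx]]
  roi_number <- roi$ROINumber %||% idx
  contour_seqs <- ds$ROIContourSequence
  ctseq <- NULL
  for (cs in contour_seqs) {
    if (isTRUE((cs$ReferencedROINumber %||% -1) == roi_number))
      ctseq <- cs$ContourSequence
  }
  if (is.null(ctseq) || length(ctseq) == 0)
    stop("no contours: ROI '", roi$ROIName %||% idx, "' is empty")
  open_seen <- FALSE
  contours <- lapply(ctseq, function(item) {
    pts3 <- matrix(item$ContourData, ncol = 3, byrow = TRUE)
    if (!identical(item$ContourGeometricType, "CLOSED_PLANAR"))
      open_seen <<- TRUE
    if (max(pts3[, 3]) - min(pts3[, 3]) > 1e-3)
      stop("non-planar contour in RTSTRUCT")
    list(z = mean(pts3[, 3]), points = pts3[, 1:2, drop = FALSE])
  })
  if (open_seen)
    warning("structure set contains non-CLOSED_PLANAR contours; kept as-is")
  frame <- roi$ReferencedFrameOfReferenceUID %||% NULL
  out <- structure_set(roi$ROIName %||% "ROI", contours, frame = frame)
  if (open_seen) attr(out, "open_polylines") <- TRUE
  out
}

#' Write and read a dose grid as DICOM RTDOSE
#'
#' Dose is stored as a scaled 32-bit multi-frame grid in Gy with a
#' GridFrameOffsetVector of uniform slice offsets.
#'
#' @param volume an [image_volume] whose voxels are dose in Gy.
#' @param path output/input `.dcm` file.
#' @param frame_uid frame-of-reference UID; generated when `NULL`.
#' @return `read_rtdose` returns an [image_volume] in Gy.
#' @export
write_rtdose <- function(volume, path, frame_uid = NULL) {
  stopifnot_volume(volume)
  if (any(volume$voxels < 0 | !is.finite(volume$voxels)))
    stop("dose values must be finite and non-negative")
  d <- dim(volume$voxels)
  dmax <- max(volume$voxels)
  scaling <- if (dmax > 0) dmax / 2e9 else 1e-9
  px <- as.integer(round(volume$voxels / scaling))
  ds <- list(
    SOPClassUID = .uid_rtdose,
    SOPInstanceUID = dcm_uid(),
    Modality = "RTDOSE",
    FrameOfReferenceUID = frame_uid %||% dcm_uid(),
    ImagePositionPatient = volume$origin,
    ImageOrientationPatient = c(1, 0, 0, 0, 1, 0),
    SamplesPerPixel = 1L,
    PhotometricInterpretation = "MONOCHROME2",
    NumberOfFrames = d[3],
    Rows = d[2],
    Columns = d[1],
    PixelSpacing = c(volume$spacing[2], volume$spacing[1]),
    BitsAllocated = 32L,
    BitsStored = 32L,
    HighBit = 31L,
    PixelRepresentation = 0L,
    DoseUnits = "GY",
    DoseType = "PHYSICAL",
    DoseSummationType = "FRACTION",
    GridFrameOffsetVector = (seq_len(d[3]) - 1) * volume$spacing[3],
    DoseGridScaling = scaling,
    PixelData = writeBin(px, raw(), size = 4, endian = "little")
  )
  dcm_write(ds, path)
  invisible(path)
}

#' @rdname write_rtdose
#' @export
read_rtdose <- function(path) {
  ds <- dcm_read(path)
  if (!identical(ds$Modality, "RTDOSE")) stop("not an RTDOSE file: ", path)
  nx <- ds$Columns; ny <- ds$Rows; nz <- ds$NumberOfFrames
  offs <- ds$GridFrameOffsetVector
  if (length(offs) != nz) stop("GridFrameOffsetVector length mismatch")
  gaps <- diff(offs)
  if (nz > 1 && any(abs(gaps - gaps[1]) > 1e-6))
    stop("non-uniform dose grid offsets are not supported")
  dz <- if (nz > 1) gaps[1] else ds$SliceThickness %||% 1
  px <- readBin(ds$PixelData, "integer", n = nx * ny * nz, size = 4,
                endian = "little")
  if (any(px < 0)) stop("dose pixel values overflow the signed 32-bit reader")
  vox <- array(px * ds$DoseGridScaling, dim = c(nx, ny, nz))
  ps <- ds$PixelSpacing
  vol <- image_volume(vox, spacing = c(ps[2], ps[1], dz),
                      origin = ds$ImagePositionPatient + c(0, 0, offs[1]))
  attr(vol, "frame_uid") <- ds$FrameOfReferenceUID %||% NA_character_
  vol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
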
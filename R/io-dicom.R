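#' @include io-nifti.R
NULL

## Minimal DICOM series writer/reader: explicit VR little endian, secondary
## capture, one single-frame file per slice. Written because no DICOM
## package is available to the package; covers the export contract (series
## readable by standard viewers, geometry and rescale round-trip).

.UID_ROOT <- "2.25."
.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.SOP_SECONDARY <- "1.2.840.10008.5.1.4.1.1.7"

## Hex (FNV-1a) -> decimal string, for 2.25.x content-derived UIDs.
.hexToDec <- function(hex) {
  digits <- strtoi(strsplit(tolower(hex), "")[[1]], 16L)
  acc <- c(0L)  # little-endian base-10 digit vector
  for (d in digits) {
    carry <- d
    for (i in seq_along(acc)) {
      v <- acc[i] * 16L + carry
      acc[i] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      acc <- c(acc, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  paste(rev(acc), collapse = "")
}

.contentUID <- function(...) {
  bytes <- serialize(list(...), NULL)
  paste0(.UID_ROOT, .hexToDec(cpp_fnv1a(bytes)))
}

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                             endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                             endian = "little")

.evenPad <- function(raw, padByte = as.raw(0)) {
  if (length(raw) %% 2 == 1) c(raw, padByte) else raw
}

## One explicit-VR element. value: raw vector already encoded.
.dcmElement <- function(group, elem, vr, value) {
  value <- .evenPad(value, if (vr == "UI") as.raw(0) else as.raw(0x20))
  header <- c(.u16(group), .u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(header, as.raw(c(0, 0)), .u32(length(value)), value)
  else
    c(header, .u16(length(value)), value)
}

.dcmStr <- function(group, elem, vr, s) .dcmElement(group, elem, vr,
                                                    charToRaw(s))
.dcmDS <- function(group, elem, vals)
  .dcmStr(group, elem, "DS", paste(formatC(vals, format = "g", digits = 10),
                                   collapse = "\\"))
.dcmUS <- function(group, elem, v) .dcmElement(group, elem, "US", .u16(v))

.writeDicomSlice <- function(file, pix16, nx, ny, ipp, rowDir, colDir,
                             spacing, slope, intercept, seriesUID, studyUID,
                             sopUID, instance, meta) {
  fmiBody <- c(
    .dcmElement(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .dcmStr(0x0002, 0x0002, "UI", .SOP_SECONDARY),
    .dcmStr(0x0002, 0x0003, "UI", sopUID),
    .dcmStr(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE),
    .dcmStr(0x0002, 0x0012, "UI", paste0(.UID_ROOT, "723561770.1")))
  fmi <- c(.dcmElement(0x0002, 0x0000, "UL", .u32(length(fmiBody))), fmiBody)
  pixInt <- as.integer(pix16)
  pixInt[pixInt > 32767L] <- pixInt[pixInt > 32767L] - 65536L  # two's complement
  pixRaw <- writeBin(pixInt, raw(), size = 2, endian = "little")
  ds <- c(
    .dcmStr(0x0008, 0x0016, "UI", .SOP_SECONDARY),
    .dcmStr(0x0008, 0x0018, "UI", sopUID),
    .dcmStr(0x0008, 0x0020, "DA", "20200101"),
    .dcmStr(0x0008, 0x0030, "TM", "000000"),
    .dcmStr(0x0008, 0x0060, "CS", meta@modality),
    .dcmStr(0x0008, 0x103E, "LO", meta@seriesDescription),
    .dcmStr(0x0010, 0x0010, "PN", meta@patientName),
    .dcmStr(0x0010, 0x0020, "LO", meta@patientID),
    .dcmDS(0x0018, 0x0050, spacing[3]),
    .dcmDS(0x0018, 0x0088, spacing[3]),
    .dcmStr(0x0020, 0x000D, "UI", studyUID),
    .dcmStr(0x0020, 0x000E, "UI", seriesUID),
    .dcmStr(0x0020, 0x0013, "IS", as.character(instance)),
    .dcmDS(0x0020, 0x0032, ipp),
    .dcmDS(0x0020, 0x0037, c(rowDir, colDir)),
    .dcmUS(0x0028, 0x0002, 1),
    .dcmStr(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcmUS(0x0028, 0x0010, ny),        # Rows
    .dcmUS(0x0028, 0x0011, nx),        # Columns
    .dcmDS(0x0028, 0x0030, c(spacing[2], spacing[1])),  # row\col spacing
    .dcmUS(0x0028, 0x0100, 16),
    .dcmUS(0x0028, 0x0101, 16),
    .dcmUS(0x0028, 0x0102, 15),
    .dcmUS(0x0028, 0x0103, 0),
    .dcmDS(0x0028, 0x1052, intercept),
    .dcmDS(0x0028, 0x1053, slope),
    .dcmElement(0x7FE0, 0x0010, "OW", pixRaw))
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(fmi, ds), con)
  invisible(file)
}

.writeDicomSeries <- function(volume, dir, meta = NULL) {
  d <- dim(volume@voxels)
  if (is.null(meta))
    meta <- SeriesMetadata(spacing = volume@spacing,
                           direction = volume@direction)
  rng <- range(volume@voxels)
  if (identical(meta@rescaleSlope, 1) && identical(meta@rescaleIntercept, 0)) {
    ## choose slope/intercept so the intensity range maps onto [0, 32767]
    intercept <- rng[1]
    slope <- if (rng[2] > rng[1]) (rng[2] - rng[1]) / 32767 else 1
  } else {
    intercept <- meta@rescaleIntercept
    slope <- meta@rescaleSlope
  }
  stored <- round((volume@voxels - intercept) / slope)
  if (min(stored) < 0 || max(stored) > 65535)
    stop("writeVolume: intensities exceed the 16-bit range after rescale")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seriesUID <- .contentUID("series", volume@voxels, volume@spacing,
                           volume@origin, volume@direction)
  studyUID <- .contentUID("study", meta@patientID)
  rowDir <- volume@direction[, 1]
  colDir <- volume@direction[, 2]
  normal <- volume@direction[, 3]
  for (k in seq_len(d[3])) {
    ipp <- volume@origin + (k - 1) * volume@spacing[3] * normal
    sopUID <- .contentUID("sop", seriesUID, k)
    .writeDicomSlice(file.path(dir, sprintf("slice_%04d.dcm", k)),
                     stored[, , k], d[1], d[2], ipp, rowDir, colDir,
                     volume@spacing, slope, intercept, seriesUID, studyUID,
                     sopUID, k, meta)
  }
  invisible(dir)
}

## ---- reading ---------------------------------------------------------------

.parseDicomFile <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  pos <- 133L
  longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  readU16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  readU32 <- function(at) readU16(at) + 65536 * readU16(at + 2L)
  while (pos + 8L <= length(raw) + 1L) {
    group <- readU16(pos); elem <- readU16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% longVRs) {
      len <- readU32(pos + 8L)
      valAt <- pos + 12L
    } else {
      len <- readU16(pos + 6L)
      valAt <- pos + 8L
    }
    key <- sprintf("%04x%04x", group, elem)
    val <- if (len > 0L) raw[valAt:(valAt + len - 1L)] else raw(0)
    tags[[key]] <- list(vr = vr, value = val)
    pos <- valAt + len
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  tags
}

.tagStr <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  v <- t$value[t$value != as.raw(0)]  # strip UI null padding
  trimws(rawToChar(v))
}

.tagNum <- function(tags, key) {
  s <- .tagStr(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.tagU16 <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  readBin(t$value, "integer", size = 2, endian = "little", signed = FALSE)
}

.readDicomSeries <- function(dir, modality = "DERIVED") {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("readVolume: no files in DICOM directory ", dir)
  parsed <- lapply(files, .parseDicomFile)
  uids <- vapply(parsed, function(t) .tagStr(t, "0020000e") %||% "", "")
  if (length(unique(uids)) > 1L)
    stop("readVolume: directory contains multiple series: ",
         paste(unique(uids), collapse = ", "))
  first <- parsed[[1]]
  iop <- .tagNum(first, "00200037")
  if (is.null(iop))
    stop("readVolume: DICOM series lacks ImageOrientationPatient; refusing to guess orientation")
  rowDir <- iop[1:3]; colDir <- iop[4:6]
  normal <- c(rowDir[2] * colDir[3] - rowDir[3] * colDir[2],
              rowDir[3] * colDir[1] - rowDir[1] * colDir[3],
              rowDir[1] * colDir[2] - rowDir[2] * colDir[1])
  ipps <- t(vapply(parsed, function(t) {
    v <- .tagNum(t, "00200032")
    if (is.null(v)) stop("readVolume: DICOM slice lacks ImagePositionPatient")
    v
  }, numeric(3)))
  ord <- order(ipps %*% normal)
  parsed <- parsed[ord]
  ipps <- ipps[ord, , drop = FALSE]
  nx <- .tagU16(first, "00280011")  # Columns
  ny <- .tagU16(first, "00280010")  # Rows
  ps <- .tagNum(first, "00280030")  # row\col spacing
  spacingXY <- c(ps[2], ps[1])
  nz <- length(parsed)
  dz <- if (nz > 1) mean(diff(as.numeric(ipps %*% normal)))
        else (.tagNum(first, "00180050") %||% 1)
  arr <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    t <- parsed[[k]]
    slope <- (.tagNum(t, "00281053") %||% 1)
    intercept <- (.tagNum(t, "00281052") %||% 0)
    pix <- readBin(t[["7fe00010"]]$value, "integer", n = nx * ny, size = 2,
                   endian = "little", signed = FALSE)
    arr[, , k] <- pix * slope + intercept
  }
  direction <- cbind(rowDir, colDir, normal)
  dimnames(direction) <- NULL
  vol <- ImageVolume(arr, spacing = c(spacingXY, dz), origin = ipps[1, ],
                     direction = direction, modality = modality)
  firstT <- parsed[[1]]
  meta <- SeriesMetadata(
    patientID = .tagStr(firstT, "00100020") %||% "ANON",
    patientName = .tagStr(firstT, "00100010") %||% "ANON",
    modality = .tagStr(firstT, "00080060") %||% "OT",
    seriesDescription = .tagStr(firstT, "0008103e") %||% "",
    spacing = c(spacingXY, dz), direction = direction,
    rescaleSlope = (.tagNum(firstT, "00281053") %||% 1),
    rescaleIntercept = (.tagNum(firstT, "00281052") %||% 0))
  list(volume = vol, metadata = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
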
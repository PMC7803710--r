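#' @include io-dicom.R
NULL

## Corner encoding: voxel (i,j,k) 0-based; corners live at half-integer voxel
## coordinates, stored doubled (integers) and packed into one double.
.packCorner <- function(x2, y2, z2) (x2 + 500) + 2000 * ((y2 + 500) +
                                                         2000 * (z2 + 500))
.unpackCorner <- function(key) {
  x2 <- key %% 2000 - 500
  r <- key %/% 2000
  y2 <- r %% 2000 - 500
  z2 <- r %/% 2000 - 500
  cbind(x2, y2, z2)
}

## Boundary faces of a mask along one signed axis direction.
.facesAlong <- function(arr, axis, sign) {
  d <- dim(arr)
  shifted <- array(FALSE, dim = d)
  if (axis == 1) {
    if (sign > 0) shifted[1:(d[1] - 1), , ] <- arr[2:d[1], , ]
    else          shifted[2:d[1], , ]       <- arr[1:(d[1] - 1), , ]
  } else if (axis == 2) {
    if (sign > 0) shifted[, 1:(d[2] - 1), ] <- arr[, 2:d[2], ]
    else          shifted[, 2:d[2], ]       <- arr[, 1:(d[2] - 1), ]
  } else {
    if (sign > 0) shifted[, , 1:(d[3] - 1)] <- arr[, , 2:d[3]]
    else          shifted[, , 2:d[3]]       <- arr[, , 1:(d[3] - 1)]
  }
  which(arr & !shifted, arr.ind = TRUE) - 1L  # 0-based voxel indices
}

.faceQuads <- function(idx, axis, sign) {
  ## returns 4 corner-key columns, CCW from outside
  i2 <- 2L * idx
  x <- i2[, 1]; y <- i2[, 2]; z <- i2[, 3]
  if (axis == 1) {
    f <- x + sign
    if (sign > 0)
      list(.packCorner(f, y - 1, z - 1), .packCorner(f, y + 1, z - 1),
           .packCorner(f, y + 1, z + 1), .packCorner(f, y - 1, z + 1))
    else
      list(.packCorner(f, y - 1, z - 1), .packCorner(f, y - 1, z + 1),
           .packCorner(f, y + 1, z + 1), .packCorner(f, y + 1, z - 1))
  } else if (axis == 2) {
    f <- y + sign
    if (sign > 0)
      list(.packCorner(x - 1, f, z - 1), .packCorner(x - 1, f, z + 1),
           .packCorner(x + 1, f, z + 1), .packCorner(x + 1, f, z - 1))
    else
      list(.packCorner(x - 1, f, z - 1), .packCorner(x + 1, f, z - 1),
           .packCorner(x + 1, f, z + 1), .packCorner(x - 1, f, z + 1))
  } else {
    f <- z + sign
    if (sign > 0)
      list(.packCorner(x - 1, y - 1, f), .packCorner(x + 1, y - 1, f),
           .packCorner(x + 1, y + 1, f), .packCorner(x - 1, y + 1, f))
    else
      list(.packCorner(x - 1, y - 1, f), .packCorner(x - 1, y + 1, f),
           .packCorner(x + 1, y + 1, f), .packCorner(x + 1, y - 1, f))
  }
}

## Extract the boundary surface of a mask as a welded triangle mesh in
## physical coordinates.
.maskSurface <- function(mask) {
  arr <- mask@voxels
  quadKeys <- vector("list", 6)
  n <- 0
  for (axis in 1:3) for (sign in c(1L, -1L)) {
    idx <- .facesAlong(arr, axis, sign)
    n <- n + 1
    quadKeys[[n]] <- if (nrow(idx)) .faceQuads(idx, axis, sign) else NULL
  }
  quadKeys <- quadKeys[!vapply(quadKeys, is.null, TRUE)]
  if (!length(quadKeys)) stop("exportMesh: mask is empty")
  c1 <- unlist(lapply(quadKeys, `[[`, 1))
  c2 <- unlist(lapply(quadKeys, `[[`, 2))
  c3 <- unlist(lapply(quadKeys, `[[`, 3))
  c4 <- unlist(lapply(quadKeys, `[[`, 4))
  allKeys <- c(c1, c2, c3, c4)
  verts <- sort(unique(allKeys))
  lookup <- match(allKeys, verts)
  nq <- length(c1)
  v1 <- lookup[seq_len(nq)]
  v2 <- lookup[nq + seq_len(nq)]
  v3 <- lookup[2 * nq + seq_len(nq)]
  v4 <- lookup[3 * nq + seq_len(nq)]
  tris <- rbind(cbind(v1, v2, v3), cbind(v1, v3, v4))
  halfIdx <- .unpackCorner(verts) / 2  # half-integer voxel coordinates
  coords <- .indexToWorld(.gridOf(mask), halfIdx)
  list(vertices = coords, triangles = tris)
}

.smoothMesh <- function(mesh, iters, lambda = 0.5) {
  if (iters <= 0) return(mesh)
  tris <- mesh$triangles
  edges <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  edges <- unique(edges)
  deg <- tabulate(edges[, 1], nbins = nrow(mesh$vertices))
  v <- mesh$vertices
  for (it in seq_len(iters)) {
    nbSum <- rowsum(v[edges[, 2], , drop = FALSE], edges[, 1])
    mean <- nbSum / deg
    v <- v + lambda * (mean - v)
  }
  mesh$vertices <- v
  mesh
}

.writeSTL <- function(mesh, path) {
  v <- mesh$vertices
  tris <- mesh$triangles
  a <- v[tris[, 1], , drop = FALSE]
  b <- v[tris[, 2], , drop = FALSE]
  cc <- v[tris[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("CranioSeg binary STL", width = -80))
  writeBin(header[1:80], con)
  writeBin(as.integer(nrow(tris)), con, size = 4, endian = "little")
  ## interleave: per triangle 12 floats + uint16
  dat <- t(cbind(nrm, a, b, cc))  # 12 x n
  for (t in seq_len(nrow(tris))) {
    writeBin(as.numeric(dat[, t]), con, size = 4, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  }
  invisible(path)
}

## Internal STL reader (test oracle for topology/extent checks).
.readSTL <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  nTri <- readBin(raw[81:84], "integer", size = 4, endian = "little")
  body <- raw[-(1:84)]
  tris <- matrix(0, nTri, 9)
  rec <- 50L  # 12 floats + 2 bytes
  for (t in seq_len(nTri)) {
    off <- (t - 1L) * rec
    vals <- readBin(body[off + 1:48], "numeric", n = 12, size = 4,
                    endian = "little")
    tris[t, ] <- vals[4:12]
  }
  tris
}

#' Export the surface of a binary mask as a binary STL mesh
#'
#' Extracts the watertight boundary surface of the mask in physical
#' coordinates (voxel-boundary faces, triangulated with outward-facing
#' windings and welded vertices) and optionally applies Laplacian smoothing.
#' Smoothing defaults to off: heavier smoothing improves aesthetics at the
#' cost of geometric accuracy, so it is an explicit choice.
#'
#' @param mask A nonempty [BinaryMask-class].
#' @param path Output `.stl` path.
#' @param smoothingIters Laplacian smoothing iterations (default 0).
#' @return The triangle count, invisibly.
#' @export
exportMesh <- function(mask, path, smoothingIters = 0) {
  stopifnot(is(mask, "BinaryMask"))
  if (!any(mask@voxels)) stop("exportMesh: mask is empty")
  mesh <- .maskSurface(mask)
  mesh <- .smoothMesh(mesh, smoothingIters)
  .writeSTL(mesh, path)
  invisible(nrow(mesh$triangles))
}
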
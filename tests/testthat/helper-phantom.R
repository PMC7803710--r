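## Shared fixtures: phantoms and pipeline results are expensive, so they are
## generated once per session and cached across test files.

.fixtureCache <- new.env(parent = emptyenv())

cachedPhantom <- function(name, seed = 1, modalities = c("zte", "bb")) {
  key <- paste("ph", name, seed, paste(sort(modalities), collapse = "+"))
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generatePhantom(defaultSpecs(seed = seed)[[name]],
                                            modalities = modalities)
  .fixtureCache[[key]]
}

## Pipeline results on the cached phantoms (config defaults).
cachedResult <- function(name, mode = c("bb-only", "zte-driven"),
                         highres = "bb", seed = 1) {
  mode <- match.arg(mode)
  key <- paste("res", name, mode, highres, seed)
  if (is.null(.fixtureCache[[key]])) {
    mods <- unique(c("zte", highres))
    ph <- cachedPhantom(name, seed, modalities = mods)
    .fixtureCache[[key]] <- if (mode == "bb-only")
      bbOnlyPipeline(ph@volumes[[highres]])
    else zteDrivenPipeline(ph@volumes$zte, ph@volumes[[highres]])
  }
  .fixtureCache[[key]]
}

## Small axis-aligned test volume.
makeVol <- function(arr, spacing = c(1, 1, 1), origin = NULL,
                    modality = "DERIVED") {
  if (is.null(origin)) origin <- -(dim(arr) - 1) / 2 * spacing
  ImageVolume(arr, spacing = spacing, origin = origin, modality = modality)
}

makeMask <- function(arr, spacing = c(1, 1, 1), origin = NULL) {
  if (is.null(origin)) origin <- -(dim(arr) - 1) / 2 * spacing
  BinaryMask(arr, spacing = spacing, origin = origin)
}

## Brute-force binary morphology oracle (physical-space ball), small arrays.
bruteMorph <- function(arr, spacing, radiusMm, op) {
  d <- dim(arr)
  offs <- CranioSeg:::.ballOffsets(radiusMm, spacing)
  out <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    vals <- logical(nrow(offs))
    for (m in seq_len(nrow(offs))) {
      ii <- i + offs[m, 1]; jj <- j + offs[m, 2]; kk <- k + offs[m, 3]
      vals[m] <- ii >= 1 && jj >= 1 && kk >= 1 && ii <= d[1] &&
        jj <= d[2] && kk <= d[3] && arr[ii, jj, kk]
    }
    out[i, j, k] <- if (op == "dilate") any(vals) else all(vals)
  }
  out
}

## Brute-force connected components by flood fill (26-connectivity).
bruteComponents <- function(arr) {
  d <- dim(arr)
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(arr)) {
    if (lab[s] > 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ijk <- arrayInd(q, d)
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        ii <- ijk[1] + di; jj <- ijk[2] + dj; kk <- ijk[3] + dk
        if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] ||
            kk > d[3]) next
        p <- ii + d[1] * ((jj - 1) + d[2] * (kk - 1))
        if (arr[p] && lab[p] == 0L) { lab[p] <- nxt; queue <- c(queue, p) }
      }
    }
  }
  lab
}

## Max parameter discrepancy of two transforms over the head bounding box.
transformDiscrepancyMm <- function(a, b,
                                   box = as.matrix(expand.grid(
                                     c(-26, 26), c(-32, 32), c(-28, 28)))) {
  max(sqrt(rowSums((transformPoints(a, box) - transformPoints(b, box))^2)))
}

## Rotation-angle difference (degrees) between two rigid transforms.
rotationAngleDeg <- function(a, b) {
  Ra <- CranioSeg:::.rotationMatrix(a@rotation)
  Rb <- CranioSeg:::.rotationMatrix(b@rotation)
  R <- Ra %*% t(Rb)
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

## Welded Euler characteristic of a binary STL file.
stlEuler <- function(path) {
  tris <- CranioSeg:::.readSTL(path)
  nt <- nrow(tris)
  vkey <- apply(rbind(tris[, 1:3], tris[, 4:6], tris[, 7:9]), 1, paste,
                collapse = ",")
  verts <- unique(vkey)
  vi <- match(vkey, verts)
  tri <- cbind(vi[1:nt], vi[nt + 1:nt], vi[2 * nt + 1:nt])
  edges <- unique(t(apply(rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)]), 1,
                          sort)))
  length(verts) - nrow(edges) + nt
}
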
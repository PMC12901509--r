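# Shared fixtures: small phantoms, open fields and independent oracles.
# Everything is generated in code; no stored data.

# Rectangular water slab as a body mask. The grid extends `pad` mm beyond
# the slab on every axis.
slabBody <- function(halfX = 50, halfY = 40, halfZ = 50,
                     spacing = c(2.5, 2.5, 2.5), pad = 5) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  lo <- c(-halfX, -halfY, -halfZ) - pad
  hi <- c(halfX, halfY, halfZ) + pad
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  geom <- structureMask("body", "body", array(TRUE, dims), lo, spacing)
  pts <- gridCoordinates(geom)
  inside <- abs(pts[, 1]) <= halfX & abs(pts[, 2]) <= halfY &
    abs(pts[, 3]) <= halfZ
  structureMask("body", "body", array(inside, dims), lo, spacing)
}

# Control point with a centred rectangular w x h aperture.
openFieldCP <- function(width = 40, height = 40, mu = 1, gantry = 0,
                        leafWidth = 5, nPairs = 24) {
  bankOffset <- -nPairs * leafWidth / 2
  left <- rep(0, nPairs)
  right <- rep(0, nPairs)
  rowLo <- bankOffset + (seq_len(nPairs) - 1) * leafWidth
  open <- rowLo >= -height / 2 & (rowLo + leafWidth) <= height / 2
  left[open] <- -width / 2
  right[open] <- width / 2
  controlPoint(gantry = gantry, mu = mu, leafLeft = left, leafRight = right,
               leafWidth = leafWidth, bankOffset = bankOffset)
}

# Sharp-edged beam model: no penumbra, no transmission.
sharpBeam <- function(...) beamModel(penumbraSigma = 0, leafTransmission = 0,
                                     ...)

# Small case spec with few fractions for fast end-to-end audit tests.
tinyCase <- function() {
  caseSpec(
    name = "tiny-synthetic",
    body = shapeSphere(c(0, 0, 0), 55),
    ctvs = list(CTV = shapeSphere(c(12, 5, 0), 10)),
    phases = data.frame(label = "primary", ctv = "CTV", coverage = "D50",
                        prescription = 20, fractionDose = 5, ref = "",
                        stringsAsFactors = FALSE),
    oars = list(
      list(name = "serial_oar", role = "oar_serial",
           shape = shapeCapsule(c(-7.5, 5, -25), c(-7.5, 5, 20), 4)),
      list(name = "parallel_oar", role = "oar_parallel",
           shape = shapeEllipsoid(c(-30, 0, 0), c(8, 8, 10))),
      list(name = "distant_oar", role = "oar_parallel", distant = TRUE,
           shape = shapeSphere(c(5, -38, -25), 4))),
    ptvMargin = 5, distantMin = 25)
}

tinyAuditCase <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateCase(tinyCase(), spacing = 5, nControlPoints = 12,
                             seed = 7)
    cache
  }
})

# Built-in brainlike case at the desk-scale audit resolution, generated
# once and shared across test files.
brainCase5mm <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateCase("brainlike", spacing = 5, nControlPoints = 24,
                             seed = 1)
    cache
  }
})

# --- Independent oracles -----------------------------------------------

# Nearest-rank dose-volume endpoint by an explicit cumulative-volume walk
# (independent of the package's implementation).
bruteForceEndpoint <- function(doses, voxelVolume, kind, parameter) {
  if (kind == "D_mean") return(sum(doses) / length(doses))
  V <- if (kind == "D_percent") parameter / 100 * length(doses) * voxelVolume
       else parameter
  ds <- sort(doses, decreasing = TRUE)
  cum <- 0
  for (i in seq_along(ds)) {
    cum <- cum + voxelVolume
    if (cum >= V - 1e-9 * voxelVolume) return(ds[i])
  }
  ds[length(ds)]
}

# Worst case by a plain scan: signed difference of maximal |diff|,
# first occurrence wins.
bruteForceWorst <- function(diffs) {
  best <- 1L
  for (i in seq_along(diffs)) if (abs(diffs[i]) > abs(diffs[best])) best <- i
  list(value = diffs[best], index = best)
}

# Explicit rotation matrices about the coordinate axes (angle in degrees),
# used as the geometry oracle.
oracleRotX <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
oracleRotY <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
oracleRotZ <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Separable 3-D Gaussian convolution with edge replication, used by the
# static-dose-cloud (convolution-limit) check.
gaussianBlur3D <- function(vals, sigma, spacing) {
  out <- vals
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    m <- ceiling(4 * sigma[ax] / spacing[ax])
    k <- dnorm(seq(-m, m) * spacing[ax], sd = sigma[ax])
    k <- k / sum(k)
    n <- dim(out)[ax]
    acc <- array(0, dim(out))
    for (j in seq_along(k)) {
      shift <- j - m - 1L
      idx <- pmin(pmax(seq_len(n) + shift, 1L), n)
      acc <- acc + k[j] * switch(ax,
        out[idx, , , drop = FALSE],
        out[, idx, , drop = FALSE],
        out[, , idx, drop = FALSE])
    }
    out <- acc
  }
  out
}
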
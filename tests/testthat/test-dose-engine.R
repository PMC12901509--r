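test_that("fluence map of closed apertures and open rectangles", {
  bm <- sharpBeam()
  # all pairs closed, zero transmission: zero fluence everywhere
  cp0 <- controlPoint(0, mu = 3, leafLeft = rep(0, 10),
                      leafRight = rep(0, 10))
  fm0 <- fluenceMap(cp0, bm)
  expect_true(all(fm0$F == 0))
  # 40 x 40 rectangle, no blur, mu = 2: fluence 2 inside, 0 outside
  cp <- openFieldCP(width = 40, height = 40, mu = 2)
  fm <- fluenceMap(cp, bm, resolution = 0.5)
  expect_setequal(unique(as.vector(fm$F)), c(0, 2))
  aGrid <- fm$a0 + (seq_len(nrow(fm$F)) - 1) * fm$da
  bGrid <- fm$b0 + (seq_len(ncol(fm$F)) - 1) * fm$db
  inside <- outer(abs(aGrid) < 19, abs(bGrid) < 19, "&")
  expect_true(all(fm$F[inside] == 2))
  outside <- outer(abs(aGrid) > 21, abs(bGrid) > 21, "|")
  expect_true(all(fm$F[outside] == 0))
})

test_that("MLC delta grows the open area by 2*delta*height per open pair", {
  bm <- sharpBeam()
  # every pair of the bank is open (the delta also opens parked pairs, so
  # the 2*delta*h growth per open pair needs a fully open bank)
  cp <- openFieldCP(width = 20, height = 20, mu = 1, leafWidth = 5,
                    nPairs = 4)
  # pixel-count oracle at fine resolution
  area <- function(delta) {
    fm <- fluenceMap(cp, bm, mlcDelta = delta, resolution = 0.1)
    sum(fm$F > 0.5) * fm$da * fm$db
  }
  h <- 20  # 4 open pairs x 5 mm leaves
  for (delta in c(0.5, 1, 2)) {
    growth <- area(delta) - area(0)
    expect_equal(growth, 2 * delta * h, tolerance = 0.02)
  }
})

test_that("integral fluence is monotone in the MLC delta", {
  cp <- openFieldCP(width = 30, height = 20, mu = 1)
  deltas <- c(-2, -1, -0.5, 0, 0.5, 1, 2)
  for (bm in list(sharpBeam(), beamModel())) {
    fl <- vapply(deltas, function(d)
      integralFluence(fluenceMap(cp, bm, mlcDelta = d)), 0)
    expect_true(all(diff(fl) >= 0))
  }
  # strictly increasing with zero transmission while a pair is open
  fl0 <- vapply(c(0, 0.5, 1), function(d)
    integralFluence(fluenceMap(cp, sharpBeam(), mlcDelta = d)), 0)
  expect_true(all(diff(fl0) > 0))
})

test_that("over-closing clamps at the gap midpoint", {
  tips <- perturbLeafTips(-1, 1, -2)
  expect_equal(tips$left, 0)
  expect_equal(tips$right, 0)
  tips <- perturbLeafTips(c(-10, 3), c(10, 4), -1)
  expect_equal(tips$left, c(-9, 3.5))
  expect_equal(tips$right, c(9, 3.5))
})

test_that("zero-MU phases give zero dose and the engine is deterministic", {
  body <- slabBody(30, 30, 30, spacing = 5)
  bm <- beamModel()
  cp <- openFieldCP(width = 30, height = 30, mu = 0)
  ph <- planPhase(list(cp), 1)
  d <- computeDose(ph, body, bm, c(0, 0, 0))
  expect_true(all(d@values == 0))
  cp1 <- openFieldCP(width = 30, height = 30, mu = 2)
  ph1 <- planPhase(list(cp1), 1)
  d1 <- computeDose(ph1, body, bm, c(0, 0, 0))
  d2 <- computeDose(ph1, body, bm, c(0, 0, 0))
  expect_identical(d1@values, d2@values)
  expect_gt(max(d1@values), 0)
  # voxels outside the body receive exactly zero
  expect_true(all(d1@values[!body@members] == 0))
})

test_that("on-axis depth dose follows the exponential times inverse square", {
  body <- slabBody(50, 50, 50, spacing = 2.5)
  bm <- sharpBeam(muWater = 0.005, output = 0.01)
  ph <- planPhase(list(openFieldCP(width = 60, height = 60, mu = 100)), 1)
  d <- computeDose(ph, body, bm, c(0, 0, 0))
  # on-axis voxels at (0, y, 0); slab surface at y = +50
  atY <- function(y) {
    idx <- round((c(0, y, 0) - body@origin) / body@spacing) + 1
    d@values[idx[1], idx[2], idx[3]]
  }
  y1 <- 40; y2 <- 0  # depths 10 and 50 mm
  expected <- exp(-bm@muWater * ((50 - y1) - (50 - y2))) *
    ((bm@sad - y2) / (bm@sad - y1))^2
  expect_equal(atY(y1) / atY(y2), expected, tolerance = 0.01)
})

test_that("dose is linear in MU and superposes over control points", {
  body <- slabBody(30, 30, 30, spacing = 5)
  bm <- beamModel()
  cpA <- openFieldCP(width = 30, height = 30, mu = 1.3, gantry = 0)
  cpB <- openFieldCP(width = 20, height = 40, mu = 0.7, gantry = 120)
  cpA2 <- openFieldCP(width = 30, height = 30, mu = 2.6, gantry = 0)
  cpB2 <- openFieldCP(width = 20, height = 40, mu = 1.4, gantry = 120)
  iso <- c(0, 0, 0)
  d1 <- computeDose(planPhase(list(cpA, cpB), 1), body, bm, iso)
  d2 <- computeDose(planPhase(list(cpA2, cpB2), 1), body, bm, iso)
  nz <- d1@values > 0
  expect_lt(max(abs(d2@values[nz] / d1@values[nz] - 2)), 1e-9)
  dA <- computeDose(planPhase(list(cpA), 1), body, bm, iso)
  dB <- computeDose(planPhase(list(cpB), 1), body, bm, iso)
  expect_equal(d1@values, dA@values + dB@values, tolerance = 1e-12)
})

test_that("laterally infinite slab dose is translation-equivariant", {
  # body fills the whole grid; shift the patient by 2 voxels in LR
  sp <- 2.5
  body <- slabBody(60, 40, 40, spacing = sp, pad = 0)
  body@members[] <- TRUE
  bm <- beamModel()
  ph <- planPhase(list(openFieldCP(width = 40, height = 40, mu = 10)), 1)
  iso <- c(0, 0, 0)
  nom <- computeDose(ph, body, bm, iso)
  shift <- 2L
  tr <- rigidTransform(tx = shift * sp)
  mov <- computeDose(ph, body, bm, iso, transform = tr)
  dims <- dim(nom@values)
  i <- seq(3, dims[1] - 2 - shift)
  expected <- nom@values[i + shift, 3:(dims[2] - 2), 3:(dims[3] - 2)]
  got <- mov@values[i, 3:(dims[2] - 2), 3:(dims[3] - 2)]
  keep <- expected > 0.01 * max(expected)
  relErr <- abs(got[keep] - expected[keep]) / expected[keep]
  expect_lt(max(relErr), 0.01)
})

test_that("sumDoses weights voxel-wise and enforces congruence", {
  g1 <- doseGrid(array(1, c(4, 4, 4)), spacing = c(5, 5, 5))
  g2 <- doseGrid(array(2, c(4, 4, 4)), spacing = c(5, 5, 5))
  expect_identical(sumDoses(list(g1), 1)@values, g1@values)
  expect_true(all(sumDoses(list(g1, g2), c(0, 0))@values == 0))
  expect_true(all(sumDoses(list(g1, g2), c(1, 0.5))@values == 2))
  g3 <- doseGrid(array(1, c(4, 4, 4)), origin = c(1, 0, 0),
                 spacing = c(5, 5, 5))
  expect_error(sumDoses(list(g1, g3)), "congruent")
  expect_error(sumDoses(list(g1, g2), c(1, -1)), "weights")
})

test_that("dose grid file round-trips through the array format", {
  g <- doseGrid(array(runif(60), c(3, 4, 5)), origin = c(-1, 0, 2),
                spacing = c(2.5, 2.5, 3))
  path <- tempfile(fileext = ".dose")
  writeDoseGrid(g, path)
  g2 <- readDoseGrid(path)
  expect_identical(g2@values, g@values)
  expect_identical(g2@origin, g@origin)
  m <- structureMask("x", "oar_serial", array(runif(60) > 0.5, c(3, 4, 5)),
                     c(0, 0, 0), c(2, 2, 2))
  path2 <- tempfile(fileext = ".mask")
  writeStructureMask(m, path2)
  m2 <- readStructureMask(path2)
  expect_identical(m2@members, m@members)
  expect_identical(m2@role, m@role)
})
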
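test_that("margin expansion on exact-SDF shapes matches direct rasterization", {
  # deep-seated spherical CTV, 5 mm margin: the PTV must be exactly the
  # rasterized 15 mm sphere (trim zone far away)
  spec <- caseSpec(
    name = "sphere-test", body = shapeSphere(c(0, 0, 0), 60),
    ctvs = list(CTV = shapeSphere(c(0, 0, 0), 10)),
    phases = data.frame(label = "p", ctv = "CTV", coverage = "D50",
                        prescription = 60, fractionDose = 2, ref = "",
                        stringsAsFactors = FALSE),
    oars = list(), ptvMargin = 5)
  ph <- generatePhantom(spec, spacing = 1.5)
  ptv <- phantomStructure(ph, "PTV")
  pts <- gridCoordinates(ptv)
  oracle <- sdfShape(shapeSphere(c(0, 0, 0), 15), pts) <= 0
  expect_identical(as.vector(ptv@members), as.vector(oracle))
  # volume against the analytic sphere, within half a voxel shell
  vol <- sum(ptv@members) * prod(ptv@spacing)
  analytic <- 4 / 3 * pi * 15^3
  expect_lt(abs(vol - analytic), 4 * pi * 15^2 * 1.5 / 2)
})

test_that("PRV expansion of a tube equals the widened tube", {
  spec <- caseSpec(
    name = "tube-test", body = shapeSphere(c(0, 0, 0), 60),
    ctvs = list(CTV = shapeSphere(c(25, 0, 0), 8)),
    phases = data.frame(label = "p", ctv = "CTV", coverage = "D50",
                        prescription = 60, fractionDose = 2, ref = "",
                        stringsAsFactors = FALSE),
    oars = list(list(name = "cord", role = "oar_serial", prv = TRUE,
                     shape = shapeCapsule(c(-20, 0, -30), c(-20, 0, 30), 3))),
    ptvMargin = 3, prvMargin = 3)
  ph <- generatePhantom(spec, spacing = 1.5)
  prv <- phantomStructure(ph, "cord_prv")
  pts <- gridCoordinates(prv)
  widened <- sdfShape(shapeCapsule(c(-20, 0, -30), c(-20, 0, 30), 6),
                      pts) <= 0
  body <- as.vector(phantomBody(ph)@members)
  expect_identical(as.vector(prv@members), as.vector(widened) & body)
})

test_that("zero PTV margin reproduces the CTV away from the trim zone", {
  spec <- caseSpec(
    name = "m0", body = shapeSphere(c(0, 0, 0), 60),
    ctvs = list(CTV = shapeSphere(c(0, 0, 0), 12)),
    phases = data.frame(label = "p", ctv = "CTV", coverage = "D50",
                        prescription = 60, fractionDose = 2, ref = "",
                        stringsAsFactors = FALSE),
    oars = list(), ptvMargin = 0)
  ph <- generatePhantom(spec, spacing = 2.5)
  expect_identical(phantomStructure(ph, "PTV")@members,
                   phantomStructure(ph, "CTV")@members)
})

test_that("a CTV touching the body surface is rejected", {
  spec <- caseSpec(
    name = "bad", body = shapeSphere(c(0, 0, 0), 40),
    ctvs = list(CTV = shapeSphere(c(35, 0, 0), 10)),
    phases = data.frame(label = "p", ctv = "CTV", coverage = "D50",
                        prescription = 60, fractionDose = 2, ref = "",
                        stringsAsFactors = FALSE),
    oars = list(), ptvMargin = 5)
  expect_error(generatePhantom(spec, spacing = 2.5), "body surface")
})

test_that("fraction counts derive from the prescription statements", {
  expect_equal(builtinCase("brainlike")$phases$nFractions, 30)
  expect_equal(builtinCase("hn-unilateral")$phases$nFractions, c(25, 10))
  expect_equal(builtinCase("hn-bilateral")$phases$nFractions, c(25, 8, 2))
  # non-integer fraction counts are rejected
  expect_error(caseSpec(
    name = "frac", body = shapeSphere(c(0, 0, 0), 60),
    ctvs = list(CTV = shapeSphere(c(0, 0, 0), 10)),
    phases = data.frame(label = "p", ctv = "CTV", coverage = "D50",
                        prescription = 61, fractionDose = 2, ref = "",
                        stringsAsFactors = FALSE),
    oars = list(), ptvMargin = 5), "fraction count")
})

test_that("built-in geometries satisfy the layout invariants", {
  for (nm in c("brainlike", "hn-unilateral", "hn-bilateral")) {
    spec <- builtinCase(nm)
    ph <- generatePhantom(spec, spacing = 5)
    firstPtv <- sub("^CTV", "PTV", spec$phases$ctv[1])
    ptvPts <- gridCoordinates(ph@body)[
      as.vector(phantomStructure(ph, firstPtv)@members), , drop = FALSE]
    for (o in spec$oars) {
      d <- min(sdfShape(o$shape, ptvPts))
      if (identical(o$role, "oar_serial")) {
        # serial OAR abuts the PTV: closest PTV voxel centre within a voxel
        expect_lt(d, max(ph@body@spacing))
        expect_gt(d, 0)  # but no overlap
      }
      if (isTRUE(o$distant)) {
        expect_gt(d, spec$distantMin - max(ph@body@spacing) * sqrt(3))
      }
    }
    # every structure non-empty at audit resolution
    for (s in ph@structures) expect_gt(sum(s@members), 0)
  }
})

test_that("phantom and plan generation are reproducible", {
  spec <- builtinCase("brainlike")
  p1 <- generatePhantom(spec, spacing = 5)
  p2 <- generatePhantom(spec, spacing = 5)
  expect_identical(p1@body@members, p2@body@members)
  a <- generateArcPlan(p1, spec, nControlPoints = 8, seed = 3)
  b <- generateArcPlan(p2, spec, nControlPoints = 8, seed = 3)
  expect_identical(
    lapply(a@phases[[1]]@controlPoints, function(cp) cp@leafLeft),
    lapply(b@phases[[1]]@controlPoints, function(cp) cp@leafLeft))
  expect_identical(a@isocenter, b@isocenter)
})

test_that("single-control-point aperture approximates the projected disc", {
  spec <- caseSpec(
    name = "disc", body = shapeSphere(c(0, 0, 0), 60),
    ctvs = list(CTV = shapeSphere(c(0, 0, 0), 15)),
    phases = data.frame(label = "p", ctv = "CTV", coverage = "D50",
                        prescription = 60, fractionDose = 2, ref = "",
                        stringsAsFactors = FALSE),
    oars = list(), ptvMargin = 0)
  ph <- generatePhantom(spec, spacing = 1.5)
  plan <- generateArcPlan(ph, spec, nControlPoints = 1, seed = 1,
                          apertureMargin = 0, leafWidth = 2.5)
  cp <- plan@phases[[1]]@controlPoints[[1]]
  openArea <- sum((cp@leafRight - cp@leafLeft)) * cp@leafWidth
  expect_equal(openArea, pi * 15^2, tolerance = 0.05)
  # rows fully lateral of the target stay closed
  rowCentres <- cp@bankOffset + (seq_along(cp@leafLeft) - 0.5) * cp@leafWidth
  closed <- cp@leafRight == cp@leafLeft
  expect_true(all(closed[abs(rowCentres) > 17]))
})

test_that("normalization enforces the prescription statements", {
  cs <- tinyAuditCase()
  ptv <- phantomStructure(cs$phantom, "PTV")
  expect_equal(evaluateEndpoint(cs$nominal, ptv, endpoint("D_percent", 50)),
               20, tolerance = 1e-6)
  # renormalizing an already-normalized plan gives scale factors of 1
  renorm <- normalizePlan(cs$plan, cs$phantom, cs$spec)
  expect_equal(renorm$scale, 1, tolerance = 1e-6)
  # doubling the beam output then normalizing yields the same final dose
  bm <- cs$plan@beamModel
  bm2 <- beamModel(sad = bm@sad, penumbraSigma = bm@penumbraSigma,
                   muWater = bm@muWater,
                   leafTransmission = bm@leafTransmission,
                   output = bm@output * 2)
  plan2 <- rtPlan(lapply(cs$plan@phases, identity), cs$plan@isocenter, bm2)
  norm2 <- normalizePlan(plan2, cs$phantom, cs$spec)
  rel <- abs(norm2$nominal@values - cs$nominal@values) /
    pmax(cs$nominal@values, 1e-9)
  expect_lt(max(rel[cs$nominal@values > 0.01]), 1e-6)
})

test_that("multi-phase normalization honours summed-plan boost coverage", {
  cs <- generateCase("hn-unilateral", spacing = 6, nControlPoints = 12,
                     seed = 2)
  boost <- phantomStructure(cs$phantom, "PTV_boost")
  elect <- phantomStructure(cs$phantom, "PTV_elective")
  # elective phase alone reaches 50 Gy to 95% of its PTV
  expect_equal(
    evaluateEndpoint(cs$phaseDoses[[1]], elect, endpoint("D_percent", 95)),
    50, tolerance = 1e-6)
  # summed plan reaches 70 Gy to 95% of the boost PTV
  expect_equal(
    evaluateEndpoint(cs$nominal, boost, endpoint("D_percent", 95)),
    70, tolerance = 1e-6)
  # the summed nominal equals the sum of the scaled phase doses
  expect_equal(cs$nominal@values,
               sumDoses(cs$phaseDoses)@values, tolerance = 1e-12)
})
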
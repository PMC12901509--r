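# Synthetic cases: phantoms, structure sets and conformal arc plans.
#
# Structures are analytic shapes rasterized by voxel-centre inclusion.
# Margin expansions (CTV -> PTV, OAR -> PRV) are isotropic Euclidean
# expansions realized on the analytic signed-distance function of the
# parent shape, i.e. the continuous morphological dilation rasterized on
# the lattice. The ellipsoid signed distance uses the normalized-radius
# approximation (exact for spheres); sphere and capsule distances are
# exact and are the ones used by expansion oracles.

#' Analytic shapes
#'
#' Shape constructors used in case specifications. All dimensions in mm.
#' `shapeCylinder` is a finite right cylinder with axis along SI.
#' @param center,radius,radii,p1,p2,halfLength,lo,hi geometry parameters.
#' @return A shape list understood by [sdfShape()].
#' @export
shapeSphere <- function(center, radius)
  list(type = "sphere", center = as.numeric(center), radius = radius)

#' @rdname shapeSphere
#' @export
shapeEllipsoid <- function(center, radii)
  list(type = "ellipsoid", center = as.numeric(center),
       radii = as.numeric(radii))

#' @rdname shapeSphere
#' @export
shapeCapsule <- function(p1, p2, radius)
  list(type = "capsule", p1 = as.numeric(p1), p2 = as.numeric(p2),
       radius = radius)

#' @rdname shapeSphere
#' @export
shapeCylinder <- function(center, radius, halfLength)
  list(type = "cylinder", center = as.numeric(center), radius = radius,
       halfLength = halfLength)

#' @rdname shapeSphere
#' @export
shapeBox <- function(lo, hi)
  list(type = "box", lo = as.numeric(lo), hi = as.numeric(hi))

#' Signed distance from points to a shape surface
#'
#' Negative inside, positive outside. Exact for spheres, capsules, boxes
#' and cylinders; the ellipsoid value uses the normalized-radius
#' approximation `(|x/r| - 1) * min(r)`, adequate for membership tests and
#' body trimming but not for expansion oracles.
#'
#' @param shape a shape from [shapeSphere()] and friends.
#' @param pts n x 3 matrix of points, mm.
#' @return Numeric vector of signed distances, mm.
#' @export
sdfShape <- function(shape, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1)
  switch(shape$type,
    sphere = {
      d <- sweep(pts, 2, shape$center)
      sqrt(rowSums(d^2)) - shape$radius
    },
    ellipsoid = {
      d <- sweep(pts, 2, shape$center)
      nrm <- sqrt(rowSums(sweep(d, 2, shape$radii, "/")^2))
      (nrm - 1) * min(shape$radii)
    },
    capsule = {
      ab <- shape$p2 - shape$p1
      d <- sweep(pts, 2, shape$p1)
      t <- pmin(1, pmax(0, (d %*% ab) / sum(ab^2)))
      proj <- d - outer(as.numeric(t), ab)
      sqrt(rowSums(proj^2)) - shape$radius
    },
    cylinder = {
      d <- sweep(pts, 2, shape$center)
      dr <- sqrt(d[, 1]^2 + d[, 2]^2) - shape$radius
      dz <- abs(d[, 3]) - shape$halfLength
      out <- sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2)
      out + pmin(pmax(dr, dz), 0)
    },
    box = {
      q1 <- sweep(pts, 2, shape$lo, "-") * -1
      q2 <- sweep(pts, 2, shape$hi, "-")
      q <- pmax(q1, q2)
      inside <- pmin(apply(q, 1, max), 0)
      sqrt(rowSums(pmax(q, 0)^2)) + inside
    },
    stop(sprintf("unknown shape type '%s'", shape$type)))
}

.shapeBBox <- function(shape) {
  switch(shape$type,
    sphere = rbind(shape$center - shape$radius, shape$center + shape$radius),
    ellipsoid = rbind(shape$center - shape$radii, shape$center + shape$radii),
    capsule = rbind(pmin(shape$p1, shape$p2) - shape$radius,
                    pmax(shape$p1, shape$p2) + shape$radius),
    cylinder = rbind(shape$center - c(shape$radius, shape$radius,
                                      shape$halfLength),
                     shape$center + c(shape$radius, shape$radius,
                                      shape$halfLength)),
    box = rbind(shape$lo, shape$hi))
}

#' Voxel-centre coordinates of a lattice
#' @param x a `DoseGrid` or `StructureMask`.
#' @return n x 3 matrix of voxel centres (column-major order of the array).
#' @export
gridCoordinates <- function(x) {
  d <- dim(.gridSlot(x))
  xc <- x@origin[1] + (seq_len(d[1]) - 1) * x@spacing[1]
  yc <- x@origin[2] + (seq_len(d[2]) - 1) * x@spacing[2]
  zc <- x@origin[3] + (seq_len(d[3]) - 1) * x@spacing[3]
  cbind(rep(xc, times = d[2] * d[3]),
        rep(rep(yc, each = d[1]), times = d[3]),
        rep(zc, each = d[1] * d[2]))
}

# ---------------------------------------------------------------------------
# Case specifications
# ---------------------------------------------------------------------------

#' Define a synthetic case
#'
#' A case specification holds the body shape, one CTV shape per plan
#' phase, margins, the OAR layout (at least one serial OAR abutting the
#' target, one parallel OAR lateral to it and one distant OAR), and the
#' prescription statements the plan is normalized to.
#'
#' @param name case name.
#' @param body body shape.
#' @param ctvs named list of CTV shapes; each name must start with `CTV`
#'   and yields a PTV named by replacing that prefix.
#' @param phases data.frame with columns `label`, `ctv` (name in `ctvs`),
#'   `coverage` (`"D50"` or `"D95"`), `prescription` (Gy, on the summed
#'   dose), `fractionDose` (Gy) and `ref` (label of the phase whose
#'   prescription the fraction count is measured from; `""` for none).
#' @param oars list of `list(name, role, shape, prv = FALSE,
#'   distant = FALSE)` entries.
#' @param ptvMargin CTV-to-PTV margin, mm.
#' @param trimMargin PTV trim distance from the body surface, mm
#'   (default 3).
#' @param prvMargin OAR-to-PRV margin, mm (default 3).
#' @param distantMin required clearance of distant OARs from the PTV, mm.
#' @return A case-spec list.
#' @export
caseSpec <- function(name, body, ctvs, phases, oars, ptvMargin,
                     trimMargin = 3, prvMargin = 3, distantMin = 60) {
  stopifnot(all(startsWith(names(ctvs), "CTV")),
            all(phases$ctv %in% names(ctvs)),
            all(phases$coverage %in% c("D50", "D95")))
  # fraction counts are derived from the prescription statements
  nFx <- numeric(nrow(phases))
  for (i in seq_len(nrow(phases))) {
    ref <- phases$ref[i]
    base <- if (nzchar(ref)) {
      j <- match(ref, phases$label)
      if (is.na(j)) stop(sprintf("unknown reference phase '%s'", ref))
      phases$prescription[j]
    } else 0
    dose <- phases$prescription[i] - base
    fx <- dose / phases$fractionDose[i]
    if (fx <= 0 || abs(fx - round(fx)) > 1e-9)
      stop(sprintf(
        "phase '%s': (%.1f - %.1f) Gy at %.1f Gy/fraction is not a positive integer fraction count",
        phases$label[i], phases$prescription[i], base,
        phases$fractionDose[i]))
    nFx[i] <- round(fx)
  }
  phases$nFractions <- nFx
  list(name = name, body = body, ctvs = ctvs, phases = phases, oars = oars,
       ptvMargin = ptvMargin, trimMargin = trimMargin,
       prvMargin = prvMargin, distantMin = distantMin)
}

#' Built-in synthetic case templates
#'
#' Three templates emulating the geometric structure of a plan-robustness
#' audit: `brainlike` (one phase, 60 Gy to 50% of the PTV in 2 Gy
#' fractions, 5 mm CTV-PTV margin), `hn-unilateral` (two phases: 50 Gy
#' elective + 70 Gy boost, each to 95% of the respective PTV, 3 mm
#' margins) and `hn-bilateral` (three phases: 50 / 66 / 70 Gy, 3 mm
#' margins). Each case has a serial OAR abutting the PTV, a parallel OAR
#' lateral to the target and a distant OAR far from the beam path; the
#' head-and-neck cases carry a 3 mm PRV around the serial OAR.
#'
#' @param name one of `"brainlike"`, `"hn-unilateral"`, `"hn-bilateral"`.
#' @return A case-spec list (see [caseSpec()]).
#' @export
builtinCase <- function(name = c("brainlike", "hn-unilateral",
                                 "hn-bilateral")) {
  name <- match.arg(name)
  if (name == "brainlike") {
    caseSpec(
      name = name,
      body = shapeEllipsoid(c(0, 0, 0), c(80, 95, 90)),
      ctvs = list(CTV = shapeSphere(c(20, 10, 0), 12.5)),
      phases = data.frame(
        label = "primary", ctv = "CTV", coverage = "D50",
        prescription = 60, fractionDose = 2, ref = "",
        stringsAsFactors = FALSE),
      oars = list(
        list(name = "brainstem", role = "oar_serial",
             shape = shapeCapsule(c(-1.8, 10, -35), c(-1.8, 10, 25), 4)),
        list(name = "hippocampus", role = "oar_parallel",
             shape = shapeEllipsoid(c(-38, 5, -5), c(10, 8, 14))),
        list(name = "eye", role = "oar_parallel", distant = TRUE,
             shape = shapeSphere(c(-25, 58, -58), 5))),
      ptvMargin = 5)
  } else if (name == "hn-unilateral") {
    caseSpec(
      name = name,
      body = shapeCylinder(c(0, 0, 0), 65, 85),
      ctvs = list(
        CTV_elective = shapeCapsule(c(28, 8, -50), c(28, 8, 10), 15),
        CTV_boost = shapeSphere(c(28, 8, -10), 12)),
      phases = data.frame(
        label = c("elective", "boost"),
        ctv = c("CTV_elective", "CTV_boost"),
        coverage = c("D95", "D95"),
        prescription = c(50, 70), fractionDose = c(2, 2),
        ref = c("", "elective"), stringsAsFactors = FALSE),
      oars = list(
        list(name = "spinal_cord", role = "oar_serial", prv = TRUE,
             shape = shapeCapsule(c(11.8, -8.2, -80), c(11.8, -8.2, 80),
                                  4.5)),
        list(name = "parotid_contra", role = "oar_parallel",
             shape = shapeEllipsoid(c(-42, 5, 5), c(11, 13, 18))),
        list(name = "eye", role = "oar_parallel", distant = TRUE,
             shape = shapeSphere(c(-18, 42, 72), 5))),
      ptvMargin = 3)
  } else {
    caseSpec(
      name = name,
      body = shapeCylinder(c(0, 0, 0), 65, 85),
      ctvs = list(
        CTV_elective = shapeCapsule(c(-30, 8, -20), c(30, 8, -20), 14),
        CTV_boost1 = shapeSphere(c(25, 8, -20), 12),
        CTV_boost2 = shapeSphere(c(25, 8, -20), 8)),
      phases = data.frame(
        label = c("elective", "boost1", "boost2"),
        ctv = c("CTV_elective", "CTV_boost1", "CTV_boost2"),
        coverage = c("D95", "D95", "D95"),
        prescription = c(50, 66, 70), fractionDose = c(2, 2, 2),
        ref = c("", "elective", "boost1"), stringsAsFactors = FALSE),
      oars = list(
        list(name = "spinal_cord", role = "oar_serial", prv = TRUE,
             shape = shapeCapsule(c(0, -13.9, -80), c(0, -13.9, 80), 4.5)),
        list(name = "parotid_right", role = "oar_parallel",
             shape = shapeEllipsoid(c(-52, -2, 0), c(10, 12, 16))),
        list(name = "eye", role = "oar_parallel", distant = TRUE,
             shape = shapeSphere(c(-18, 42, 72), 5))),
      ptvMargin = 3)
  }
}

#' Generate a phantom and structure set from a case specification
#'
#' Rasterizes all shapes by voxel-centre inclusion. PTVs are the isotropic
#' `ptvMargin` expansion of their CTV trimmed `trimMargin` from the body
#' surface; PRVs are the `prvMargin` expansion of their serial parent.
#' OAR masks are clipped to the body.
#'
#' @param spec a case spec from [builtinCase()] or [caseSpec()].
#' @param spacing voxel size, mm (scalar or length 3); default 2.5 mm.
#' @param padding grid padding around the body bounding box, mm.
#' @return A [Phantom-class].
#' @export
generatePhantom <- function(spec, spacing = 2.5, padding = 5) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  bb <- .shapeBBox(spec$body)
  origin <- bb[1, ] - padding
  dims <- as.integer(ceiling((bb[2, ] + padding - origin) / spacing)) + 1L
  geom <- structureMask("body", "body",
                        array(TRUE, dims), origin, spacing)
  pts <- gridCoordinates(geom)

  bodySdf <- sdfShape(spec$body, pts)
  bodyArr <- array(bodySdf <= 0, dims)
  body <- structureMask("body", "body", bodyArr, origin, spacing)

  structures <- list()
  for (cn in names(spec$ctvs)) {
    csdf <- sdfShape(spec$ctvs[[cn]], pts)
    cArr <- array(csdf <= 0, dims)
    if (any(cArr & !bodyArr) || any(bodySdf[cArr] > -1e-9))
      stop(sprintf("CTV '%s' touches the body surface", cn))
    structures[[cn]] <- structureMask(cn, "target_ctv", cArr, origin, spacing)
    pn <- sub("^CTV", "PTV", cn)
    pArr <- array(csdf <= spec$ptvMargin & bodySdf <= -spec$trimMargin, dims)
    structures[[pn]] <- structureMask(pn, "target_ptv", pArr, origin, spacing)
  }
  for (o in spec$oars) {
    osdf <- sdfShape(o$shape, pts)
    oArr <- array(osdf <= 0, dims) & bodyArr
    structures[[o$name]] <- structureMask(o$name, o$role, oArr, origin,
                                          spacing)
    if (isTRUE(o$prv)) {
      pn <- paste0(o$name, "_prv")
      pArr <- array(osdf <= spec$prvMargin, dims) & bodyArr
      structures[[pn]] <- structureMask(pn, "prv", pArr, origin, spacing)
    }
  }
  new("Phantom", body = body, structures = structures, spec = spec)
}

# Beam's-eye-view projection of points onto the isocenter plane for a
# given gantry angle: returns columns a (leaf travel) and b (leaf rows).
.bevProject <- function(pts, gantry, isocenter, sad) {
  g <- .deg2rad(gantry)
  n0 <- c(sin(g), cos(g), 0)
  src <- isocenter + sad * n0
  u <- c(cos(g), -sin(g), 0)
  v <- c(0, 0, 1)
  w <- -n0
  d <- sweep(pts, 2, src)
  lam <- sad / as.numeric(d %*% w)
  q <- sweep(d * lam, 2, src + (-isocenter), "+")  # src + lam*d - iso
  cbind(a = as.numeric(q %*% u), b = as.numeric(q %*% v))
}

#' Generate a conformal arc plan for a case
#'
#' Per phase, control points are spaced evenly over the arc span and each
#' aperture conforms to the beam's-eye-view projection of the phase PTV
#' plus an aperture margin, per leaf row. MU is uniform across control
#' points before normalization. Apertures are geometric (no inverse
#' optimization); the result is deterministic for a given seed.
#'
#' @param phantom a [Phantom-class].
#' @param spec the case spec used to generate it.
#' @param nControlPoints control points per arc (default 36).
#' @param seed integer seed recorded with the plan.
#' @param arcSpan arc length in degrees (default 360).
#' @param apertureMargin margin around the projected target, mm.
#' @param leafWidth MLC leaf width at isocenter, mm.
#' @param model the [BeamModel-class] to attach.
#' @return A [Plan-class] (not yet normalized).
#' @export
generateArcPlan <- function(phantom, spec, nControlPoints = 36, seed = 1,
                            arcSpan = 360, apertureMargin = 5,
                            leafWidth = 5, model = beamModel()) {
  set.seed(as.integer(seed))
  firstPtv <- sub("^CTV", "PTV", spec$phases$ctv[1])
  ptv1 <- phantomStructure(phantom, firstPtv)
  if (!any(ptv1@members)) stop(sprintf("target '%s' is empty", firstPtv))
  coords <- gridCoordinates(ptv1)
  iso <- colMeans(coords[as.vector(ptv1@members), , drop = FALSE])

  nPairs <- 40L
  bankOffset <- -nPairs * leafWidth / 2
  angles <- seq(0, arcSpan, length.out = nControlPoints + 1)[1:nControlPoints]

  phases <- vector("list", nrow(spec$phases))
  for (i in seq_len(nrow(spec$phases))) {
    ptvName <- sub("^CTV", "PTV", spec$phases$ctv[i])
    tgt <- phantomStructure(phantom, ptvName)
    if (!any(tgt@members)) stop(sprintf("target '%s' is empty", ptvName))
    tpts <- gridCoordinates(tgt)[as.vector(tgt@members), , drop = FALSE]
    cps <- vector("list", nControlPoints)
    for (j in seq_len(nControlPoints)) {
      ab <- .bevProject(tpts, angles[j], iso, model@sad)
      row <- pmin(nPairs, pmax(1L,
               floor((ab[, "b"] - bankOffset) / leafWidth) + 1L))
      left <- rep(0, nPairs)
      right <- rep(0, nPairs)
      for (r in unique(row)) {
        sel <- row == r
        left[r] <- min(ab[sel, "a"]) - apertureMargin
        right[r] <- max(ab[sel, "a"]) + apertureMargin
      }
      cps[[j]] <- controlPoint(gantry = angles[j], mu = 1,
                               leafLeft = left, leafRight = right,
                               leafWidth = leafWidth,
                               bankOffset = bankOffset)
    }
    phases[[i]] <- planPhase(cps, spec$phases$nFractions[i],
                             spec$phases$label[i])
  }
  rtPlan(phases, iso, model)
}

# nearest-rank dose of the hottest pct% from a plain dose vector
.rankDosePct <- function(d, pct) {
  n <- length(d)
  k <- max(1L, min(n, ceiling(pct / 100 * n - 1e-9)))
  sort(d, decreasing = TRUE)[k]
}

#' Normalize a plan to the case's prescription statements
#'
#' Phase by phase in prescription order, all MU of the phase are scaled by
#' one factor so that the phase's coverage statement holds on the nominal
#' accumulated dose: `D50%(PTV) = prescription` for a `D50` phase,
#' `D95%(PTV) = prescription` for `D95` phases, with earlier phases' dose
#' included when evaluating boost coverage (prescriptions are statements
#' about the summed plan).
#'
#' @param plan a [Plan-class] from [generateArcPlan()].
#' @param phantom the matching [Phantom-class].
#' @param spec the case spec.
#' @param rayStep,fluenceRes engine resolution parameters, mm.
#' @return list(plan, phaseDoses, nominal, scale): the normalized plan, the
#'   scaled per-phase dose grids, the summed nominal dose and the per-phase
#'   MU scale factors.
#' @export
normalizePlan <- function(plan, phantom, spec, rayStep = 1,
                          fluenceRes = 0.5) {
  body <- phantomBody(phantom)
  nPhases <- length(plan@phases)
  stopifnot(nPhases == nrow(spec$phases))
  baseVals <- NULL
  scale <- numeric(nPhases)
  phaseDoses <- vector("list", nPhases)
  newPhases <- vector("list", nPhases)
  for (i in seq_len(nPhases)) {
    ptvName <- sub("^CTV", "PTV", spec$phases$ctv[i])
    tgt <- phantomStructure(phantom, ptvName)
    presc <- spec$phases$prescription[i]
    pct <- if (spec$phases$coverage[i] == "D50") 50 else 95
    d <- computeDose(plan@phases[[i]], body, plan@beamModel,
                     plan@isocenter, rayStep = rayStep,
                     fluenceRes = fluenceRes)
    tsel <- as.vector(tgt@members)
    phaseT <- d@values[tsel]
    if (all(phaseT <= 0))
      stop(sprintf("zero dose in target '%s'; cannot normalize", ptvName))
    baseT <- if (is.null(baseVals)) numeric(length(phaseT)) else
      baseVals[tsel]
    f <- function(s) .rankDosePct(baseT + s * phaseT, pct) - presc
    s0 <- (presc - .rankDosePct(baseT, pct)) /
      max(.rankDosePct(phaseT, pct), 1e-12)
    s <- uniroot(f, c(0, max(2 * s0, 1e-6)), extendInt = "upX",
                 tol = 1e-10)$root
    scale[i] <- s
    ph <- plan@phases[[i]]
    cps <- lapply(ph@controlPoints, function(cp) {
      controlPoint(cp@gantry, cp@mu * s, cp@leafLeft, cp@leafRight,
                   cp@leafWidth, cp@bankOffset)
    })
    newPhases[[i]] <- planPhase(cps, ph@nFractions, ph@label)
    # recompute with the scaled plan so the stored nominal is bitwise the
    # engine output of the normalized plan (not a scaled copy)
    scaled <- computeDose(newPhases[[i]], body, plan@beamModel,
                          plan@isocenter, rayStep = rayStep,
                          fluenceRes = fluenceRes)
    phaseDoses[[i]] <- scaled
    baseVals <- if (is.null(baseVals)) scaled@values else
      baseVals + scaled@values
  }
  list(plan = rtPlan(newPhases, plan@isocenter, plan@beamModel),
       phaseDoses = phaseDoses,
       nominal = doseGrid(baseVals, body@origin, body@spacing),
       scale = scale)
}

#' Generate a complete normalized case
#'
#' Convenience wrapper: phantom, conformal arc plan and prescription
#' normalization in one call.
#' @param name built-in case name (see [builtinCase()]) or a case spec.
#' @param spacing grid spacing, mm.
#' @param nControlPoints control points per arc.
#' @param seed integer seed.
#' @param ... passed to [generateArcPlan()].
#' @return list(spec, phantom, plan, phaseDoses, nominal, scale).
#' @export
generateCase <- function(name = "brainlike", spacing = 2.5,
                         nControlPoints = 36, seed = 1, ...) {
  spec <- if (is.character(name)) builtinCase(name) else name
  phantom <- generatePhantom(spec, spacing = spacing)
  plan0 <- generateArcPlan(phantom, spec, nControlPoints = nControlPoints,
                           seed = seed, ...)
  norm <- normalizePlan(plan0, phantom, spec)
  c(list(spec = spec, phantom = phantom), norm)
}
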
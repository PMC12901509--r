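# Simplified analytic divergent-beam dose engine.
#
# Dose model per control point: the MLC aperture (after an optional
# miscalibration delta) defines a fluence map at the isocenter plane,
# blurred by a Gaussian penumbra. Each body voxel receives
#   fluence(divergent projection) * exp(-mu * radiological depth)
#   * (sad / source distance)^2 * output.
# The build-up region is not modelled; the phantom is water-equivalent.
# Patient-setup scenarios move the BEAM FRAME by the inverse patient
# transform while the voxel grid stays fixed, so no dose-grid
# interpolation is ever performed.

.gridSlot <- function(x) if (is(x, "DoseGrid")) x@values else x@members

#' Check lattice congruence of grids/masks
#'
#' @param a,b `DoseGrid` or `StructureMask` objects.
#' @param what label used in the error message.
#' @return Invisibly TRUE; error if not congruent.
#' @export
assertCongruent <- function(a, b, what = "grids") {
  ok <- identical(dim(.gridSlot(a)), dim(.gridSlot(b))) &&
    max(abs(a@origin - b@origin)) < 1e-9 &&
    max(abs(a@spacing - b@spacing)) < 1e-9
  if (!ok)
    stop(sprintf("%s are not congruent (origin/spacing/shape mismatch)", what))
  invisible(TRUE)
}

#' Perturb MLC leaf tips by a miscalibration delta
#'
#' A positive delta widens the field opening (left tips move by -delta,
#' right tips by +delta, i.e. the gap grows by 2*delta per pair); a negative
#' delta closes the MLC systematically. Over-closed pairs are clamped at the
#' gap midpoint. The delta applies to every pair, including parked/closed
#' ones, as a real bank miscalibration would.
#'
#' @param leafLeft,leafRight leaf-tip positions, mm.
#' @param delta miscalibration, mm.
#' @return list(left, right).
#' @export
perturbLeafTips <- function(leafLeft, leafRight, delta) {
  l <- leafLeft - delta
  r <- leafRight + delta
  over <- l > r
  if (any(over)) {
    mid <- (l[over] + r[over]) / 2
    l[over] <- mid
    r[over] <- mid
  }
  list(left = l, right = r)
}

#' Fluence map of a control point at the isocenter plane
#'
#' Builds the aperture indicator from the (optionally perturbed) leaf tips,
#' weights it by the control point's MU (1 inside the aperture,
#' `leafTransmission` outside), and convolves it with an isotropic Gaussian
#' of sd `penumbraSigma`. The map's `a` axis is the leaf-travel direction,
#' `b` the leaf-row direction (SI at gantry 0). Outside the stored extent
#' the fluence equals the closed-leaf transmission level.
#'
#' @param cp a [ControlPoint-class].
#' @param model a [BeamModel-class].
#' @param mlcDelta MLC miscalibration, mm (default 0).
#' @param resolution pixel size of the map, mm (default 0.5).
#' @return list(F, a0, b0, da, db, fallback) where `F[ia, ib]` is the
#'   fluence at `(a0 + (ia-1)*da, b0 + (ib-1)*db)`.
#' @export
fluenceMap <- function(cp, model, mlcDelta = 0, resolution = 0.5) {
  stopifnot(is(cp, "ControlPoint"), is(model, "BeamModel"))
  tips <- perturbLeafTips(cp@leafLeft, cp@leafRight, mlcDelta)
  npair <- length(tips$left)
  w <- cp@leafWidth
  sig <- model@penumbraSigma
  pad <- 4 * sig + 2 * resolution

  aMin <- min(tips$left) - pad
  aMax <- max(tips$right) + pad
  bMin <- cp@bankOffset - pad
  bMax <- cp@bankOffset + npair * w + pad
  aa <- seq(aMin, aMax, by = resolution)
  bb <- seq(bMin, bMax, by = resolution)

  base <- cp@mu * model@leafTransmission
  F <- matrix(base, length(aa), length(bb))
  # leaf row of each b pixel (0 => outside the bank)
  row <- floor((bb - cp@bankOffset) / w) + 1
  inRow <- row >= 1 & row <= npair
  open <- tips$right > tips$left
  for (ib in which(inRow)) {
    i <- row[ib]
    if (!open[i]) next
    sel <- aa > tips$left[i] & aa < tips$right[i]
    F[sel, ib] <- cp@mu
  }

  if (sig > 0) {
    m <- ceiling(4 * sig / resolution)
    k <- stats::dnorm(seq(-m, m) * resolution, sd = sig)
    k <- k / sum(k)
    F <- .convolveEdge(F, k, base, along = 1)
    F <- .convolveEdge(F, k, base, along = 2)
  }

  list(F = F, a0 = aMin, b0 = bMin, da = resolution, db = resolution,
       fallback = base)
}

# 1-D convolution along rows (along = 1) or columns (along = 2) with
# constant extension at the given edge value.
.convolveEdge <- function(M, k, edge, along) {
  m <- (length(k) - 1) / 2
  if (along == 2) M <- t(M)
  n <- nrow(M)
  Mp <- rbind(matrix(edge, m, ncol(M)), M, matrix(edge, m, ncol(M)))
  out <- matrix(0, n, ncol(M))
  for (j in seq_along(k))
    out <- out + k[j] * Mp[j:(j + n - 1), , drop = FALSE]
  if (along == 2) t(out) else out
}

#' Integral fluence of a fluence map
#'
#' Sum of map values times pixel area; used for MLC monotonicity checks.
#' @param fm a fluence map from [fluenceMap()].
#' @export
integralFluence <- function(fm) sum(fm$F) * fm$da * fm$db

# Beam frame of a control point, moved by the inverse patient transform.
# Returns the fields the C++ kernel needs.
.beamFrame <- function(cp, isocenter, sad, minv) {
  g <- .deg2rad(cp@gantry)
  n0 <- c(sin(g), cos(g), 0)
  src0 <- isocenter + sad * n0
  u0 <- c(cos(g), -sin(g), 0)
  v0 <- c(0, 0, 1)
  w0 <- -n0
  R <- minv[1:3, 1:3]
  list(src = applyTransform(minv, src0),
       u = as.numeric(R %*% u0),
       v = as.numeric(R %*% v0),
       w = as.numeric(R %*% w0),
       iso = applyTransform(minv, isocenter))
}

#' Precompute fluence maps for a plan phase
#'
#' Fluence maps depend only on the MLC (and an optional delta), not on the
#' patient transform, so they are shared across fractions and scenarios.
#' @param phase a [PlanPhase-class].
#' @param model a [BeamModel-class].
#' @param mlcDelta MLC miscalibration, mm.
#' @param resolution fluence pixel size, mm.
#' @export
phaseFluence <- function(phase, model, mlcDelta = 0, resolution = 0.5) {
  lapply(phase@controlPoints, fluenceMap, model = model,
         mlcDelta = mlcDelta, resolution = resolution)
}

#' Compute the dose of one plan phase
#'
#' For each control point the beam frame (source position and isocenter
#' plane) is moved by the INVERSE of the patient transform while the voxel
#' grid stays fixed; contributions are summed over control points. Voxels
#' outside the body receive exactly zero.
#'
#' @param phase a [PlanPhase-class].
#' @param body the body [StructureMask-class]; defines the dose lattice.
#' @param model a [BeamModel-class].
#' @param isocenter numeric(3), mm.
#' @param transform the patient displacement as a [RigidTransform6D-class]
#'   or a 4x4 matrix (default: identity, the nominal scenario).
#' @param fluence optional precomputed [phaseFluence()] list.
#' @param mlcDelta MLC miscalibration passed to [fluenceMap()] when
#'   `fluence` is not supplied.
#' @param perFraction if TRUE, return the dose of a single fraction
#'   (full-phase dose divided by `nFractions`); default is the full phase.
#' @param rayStep ray-marching step for radiological depth, mm.
#' @param fluenceRes fluence map pixel size, mm.
#' @return A [DoseGrid-class] on the body lattice.
#' @export
computeDose <- function(phase, body, model, isocenter,
                        transform = rigidTransform(), fluence = NULL,
                        mlcDelta = 0, perFraction = FALSE, rayStep = 1,
                        fluenceRes = 0.5) {
  stopifnot(is(phase, "PlanPhase"), is(body, "StructureMask"),
            is(model, "BeamModel"))
  if (body@role != "body") stop("body mask must have role 'body'")
  m <- if (is.matrix(transform)) transform else
    transformMatrix(transform, isocenter)
  minv <- invertTransform(m)
  if (is.null(fluence))
    fluence <- phaseFluence(phase, model, mlcDelta, fluenceRes)
  cps <- vector("list", length(phase@controlPoints))
  for (i in seq_along(cps)) {
    fr <- .beamFrame(phase@controlPoints[[i]], isocenter, model@sad, minv)
    cps[[i]] <- c(fluence[[i]], fr)
  }
  dims <- dim(body@members)
  vals <- cpp_phase_dose(as.integer(dims), body@origin, body@spacing,
                         as.logical(body@members), cps, model@muWater,
                         model@sad, model@output, rayStep)
  if (perFraction) vals <- vals / phase@nFractions
  doseGrid(array(vals, dims), body@origin, body@spacing)
}

#' Voxel-wise weighted sum of dose grids
#'
#' The audited quantity is always the summed plan (primary + boost(s)).
#' @param grids list of congruent [DoseGrid-class] objects.
#' @param weights finite non-negative weights (default all 1).
#' @export
sumDoses <- function(grids, weights = rep(1, length(grids))) {
  stopifnot(length(grids) >= 1L, length(weights) == length(grids))
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and >= 0")
  for (g in grids[-1]) assertCongruent(grids[[1]], g, "dose grids")
  vals <- grids[[1]]@values * weights[1]
  for (i in seq_along(grids)[-1])
    vals <- vals + grids[[i]]@values * weights[i]
  doseGrid(vals, grids[[1]]@origin, grids[[1]]@spacing)
}

#' Summed nominal dose of a whole plan
#'
#' @param plan a [Plan-class].
#' @param body body mask.
#' @param transform patient transform (default identity).
#' @param ... passed to [computeDose()].
#' @return list(total = DoseGrid, phases = list of per-phase DoseGrids).
#' @export
planDose <- function(plan, body, transform = rigidTransform(), ...) {
  phases <- lapply(plan@phases, computeDose, body = body,
                   model = plan@beamModel, isocenter = plan@isocenter,
                   transform = transform, ...)
  list(total = sumDoses(phases), phases = phases)
}
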
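#' @import methods
#' @importFrom stats rnorm uniroot qnorm sd quantile
#' @importFrom utils write.csv head
#' @useDynLib rtrobust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.finite1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# ---------------------------------------------------------------------------
# RigidTransform6D
# ---------------------------------------------------------------------------

#' Rigid 6-DOF patient-setup transform
#'
#' Describes a rigid patient displacement relative to the planned setup:
#' three translations in millimetres along the LR/AP/SI patient axes and
#' three rotations in degrees (pitch about LR, yaw about AP, roll about SI).
#' The package convention is a right-handed frame with x = LR (+x toward
#' patient left), y = AP (+y anterior), z = SI (+z superior); rotations are
#' extrinsic and composed as roll then pitch then yaw applied to the point
#' last-to-first (`R = Rz(roll) Rx(pitch) Ry(yaw)`), about the isocenter.
#'
#' @slot tx,ty,tz translations in mm along LR, AP, SI.
#' @slot pitch,yaw,roll rotations in degrees about LR, AP, SI.
#' @export
setClass("RigidTransform6D",
  representation(tx = "numeric", ty = "numeric", tz = "numeric",
                 pitch = "numeric", yaw = "numeric", roll = "numeric"),
  prototype(tx = 0, ty = 0, tz = 0, pitch = 0, yaw = 0, roll = 0),
  validity = function(object) {
    v <- c(object@tx, object@ty, object@tz,
           object@pitch, object@yaw, object@roll)
    if (length(v) != 6L || !all(is.finite(v)))
      return("all six components must be finite scalars")
    TRUE
  })

#' Construct a rigid 6-DOF transform
#'
#' @param tx,ty,tz translations in mm (LR, AP, SI).
#' @param pitch,yaw,roll rotations in degrees (about LR, AP, SI).
#' @return A [RigidTransform6D-class] object.
#' @examples
#' rigidTransform(tx = 3)          # 3 mm shift toward patient left
#' rigidTransform(roll = -2)       # 2 degree clockwise roll
#' @export
rigidTransform <- function(tx = 0, ty = 0, tz = 0,
                           pitch = 0, yaw = 0, roll = 0) {
  new("RigidTransform6D", tx = tx, ty = ty, tz = tz,
      pitch = pitch, yaw = yaw, roll = roll)
}

setMethod("show", "RigidTransform6D", function(object) {
  cat(sprintf(
    "RigidTransform6D: t = (%.3f, %.3f, %.3f) mm, (pitch, yaw, roll) = (%.3f, %.3f, %.3f) deg\n",
    object@tx, object@ty, object@tz, object@pitch, object@yaw, object@roll))
})

#' @rdname rigidTransform
#' @param t a `RigidTransform6D`.
#' @export
transformParams <- function(t) {
  c(tx = t@tx, ty = t@ty, tz = t@tz,
    pitch = t@pitch, yaw = t@yaw, roll = t@roll)
}

#' Is a transform exactly the identity?
#' @param t a `RigidTransform6D`.
#' @export
isIdentityTransform <- function(t) all(transformParams(t) == 0)

# ---------------------------------------------------------------------------
# DoseGrid
# ---------------------------------------------------------------------------

#' Dose values on a regular 3-D voxel lattice
#'
#' The central currency of the pipeline: absorbed dose in Gy on a regular
#' lattice. `origin` is the centre of the first voxel (mm), `spacing` the
#' voxel pitch per axis (mm). Axis order is (x, y, z) = (LR, AP, SI).
#'
#' @slot values 3-D numeric array of non-negative, finite doses (Gy).
#' @slot origin numeric(3), mm.
#' @slot spacing numeric(3), mm, all positive.
#' @export
setClass("DoseGrid",
  representation(values = "array", origin = "numeric", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@values)) != 3L) return("values must be a 3-D array")
    if (length(object@origin) != 3L || !all(is.finite(object@origin)))
      return("origin must be numeric(3)")
    if (length(object@spacing) != 3L || !all(object@spacing > 0))
      return("spacing must be positive on all axes")
    if (anyNA(object@values) || any(!is.finite(object@values)))
      return("dose values must be finite")
    if (any(object@values < 0)) return("dose values must be non-negative")
    TRUE
  })

#' Construct a DoseGrid
#' @param values 3-D array of doses in Gy.
#' @param origin centre of the first voxel, mm.
#' @param spacing voxel pitch, mm.
#' @export
doseGrid <- function(values, origin = c(0, 0, 0), spacing = c(2.5, 2.5, 2.5)) {
  new("DoseGrid", values = values, origin = as.numeric(origin),
      spacing = as.numeric(spacing))
}

#' @rdname doseGrid
#' @param x a `DoseGrid` or `StructureMask`.
#' @export
gridOrigin <- function(x) x@origin

#' @rdname doseGrid
#' @export
gridSpacing <- function(x) x@spacing

#' @rdname doseGrid
#' @export
doseValues <- function(x) x@values

#' Voxel volume in cubic centimetres
#' @param x a `DoseGrid` or `StructureMask`.
#' @export
voxelVolumeCC <- function(x) prod(x@spacing) / 1000

setMethod("show", "DoseGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("DoseGrid: %d x %d x %d voxels, spacing (%.2f, %.2f, %.2f) mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  dose range [%.4g, %.4g] Gy\n",
              min(object@values), max(object@values)))
})

# ---------------------------------------------------------------------------
# StructureMask
# ---------------------------------------------------------------------------

.maskRoles <- c("target_ctv", "target_ptv", "oar_serial", "oar_parallel",
                "body", "prv", "helper")

#' Voxelized anatomical structure on the dose lattice
#'
#' @slot name structure name.
#' @slot role one of `target_ctv`, `target_ptv`, `oar_serial`,
#'   `oar_parallel`, `body`, `prv`, `helper`. Serial organs at risk are
#'   evaluated with near-maximum dose (D0.03cc), parallel ones with mean
#'   dose; PRVs inherit their serial parent's endpoint.
#' @slot members logical 3-D array of voxel membership (voxel-centre
#'   inclusion, no partial volumes).
#' @slot origin,spacing lattice geometry, must match the dose grid.
#' @export
setClass("StructureMask",
  representation(name = "character", role = "character", members = "array",
                 origin = "numeric", spacing = "numeric"),
  validity = function(object) {
    if (!object@role %in% .maskRoles)
      return(sprintf("unknown role '%s'", object@role))
    if (length(dim(object@members)) != 3L || !is.logical(object@members))
      return("members must be a logical 3-D array")
    if (length(object@spacing) != 3L || !all(object@spacing > 0))
      return("spacing must be positive")
    TRUE
  })

#' Construct a StructureMask
#' @param name structure name.
#' @param role structure role (see [StructureMask-class]).
#' @param members logical 3-D array.
#' @param origin,spacing lattice geometry in mm.
#' @export
structureMask <- function(name, role, members, origin, spacing) {
  new("StructureMask", name = name, role = role, members = members,
      origin = as.numeric(origin), spacing = as.numeric(spacing))
}

#' @rdname structureMask
#' @param x a `StructureMask`.
#' @export
maskMembers <- function(x) x@members

#' @rdname structureMask
#' @export
structureName <- function(x) x@name

#' @rdname structureMask
#' @export
structureRole <- function(x) x@role

#' Structure volume in cc
#' @param x a `StructureMask`.
#' @export
structureVolumeCC <- function(x) sum(x@members) * voxelVolumeCC(x)

setMethod("show", "StructureMask", function(object) {
  cat(sprintf("StructureMask '%s' (%s): %d voxels, %.2f cc\n",
              object@name, object@role, sum(object@members),
              structureVolumeCC(object)))
})

# ---------------------------------------------------------------------------
# Beam model / plan
# ---------------------------------------------------------------------------

#' Simplified analytic photon beam model
#'
#' Parameters of the divergent-beam dose engine: point source at
#' source-axis distance `sad`, MLC-defined aperture blurred by a Gaussian
#' penumbra, exponential depth attenuation in water and inverse-square
#' fall-off. The build-up region is deliberately not modelled; robustness is
#' always evaluated as differences to this engine's own nominal scenario, so
#' engine-specific depth-dose features cancel in the comparison.
#'
#' @slot sad source-axis distance, mm.
#' @slot penumbraSigma Gaussian fluence blur at the isocenter plane, mm.
#' @slot muWater effective linear attenuation coefficient, 1/mm.
#' @slot leafTransmission fractional transmission through closed leaves.
#' @slot output Gy per MU on the beam axis at the isocenter for zero depth.
#' @export
setClass("BeamModel",
  representation(sad = "numeric", penumbraSigma = "numeric",
                 muWater = "numeric", leafTransmission = "numeric",
                 output = "numeric"),
  validity = function(object) {
    if (!.finite1(object@sad) || object@sad <= 0) return("sad must be > 0")
    if (!.finite1(object@penumbraSigma) || object@penumbraSigma < 0)
      return("penumbraSigma must be >= 0")
    if (!.finite1(object@muWater) || object@muWater < 0)
      return("muWater must be >= 0")
    if (!.finite1(object@leafTransmission) ||
        object@leafTransmission < 0 || object@leafTransmission >= 1)
      return("leafTransmission must be in [0, 1)")
    if (!.finite1(object@output) || object@output <= 0)
      return("output must be > 0")
    TRUE
  })

#' Construct a beam model
#'
#' Defaults are generic 6 MV-like values: `sad` 1000 mm, 3 mm penumbra
#' sigma, 0.005/mm attenuation, 1.5% leaf transmission.
#' @param sad source-axis distance, mm.
#' @param penumbraSigma fluence blur at isocenter plane, mm.
#' @param muWater effective linear attenuation, 1/mm.
#' @param leafTransmission closed-leaf transmission fraction.
#' @param output Gy/MU at isocenter, zero depth.
#' @export
beamModel <- function(sad = 1000, penumbraSigma = 3, muWater = 0.005,
                      leafTransmission = 0.015, output = 0.01) {
  new("BeamModel", sad = sad, penumbraSigma = penumbraSigma,
      muWater = muWater, leafTransmission = leafTransmission, output = output)
}

#' One control point of an arc plan
#'
#' @slot gantry gantry angle in degrees; the source rotates about the SI
#'   axis, 0 = anterior (source at +AP), positive toward patient left.
#' @slot mu monitor units delivered at this control point (full phase).
#' @slot leafLeft,leafRight leaf-tip positions per leaf pair, mm at the
#'   isocenter plane along the leaf-travel axis; `leafLeft <= leafRight`.
#' @slot leafWidth leaf width (row pitch along SI at isocenter), mm.
#' @slot bankOffset position of the lower edge of the first leaf row, mm.
#' @export
setClass("ControlPoint",
  representation(gantry = "numeric", mu = "numeric",
                 leafLeft = "numeric", leafRight = "numeric",
                 leafWidth = "numeric", bankOffset = "numeric"),
  validity = function(object) {
    if (!.finite1(object@mu) || object@mu < 0) return("mu must be >= 0")
    if (!.finite1(object@leafWidth) || object@leafWidth <= 0)
      return("leafWidth must be > 0")
    if (length(object@leafLeft) != length(object@leafRight))
      return("leaf banks must have equal length")
    if (any(object@leafLeft > object@leafRight + 1e-12))
      return("leafLeft must be <= leafRight for every pair")
    TRUE
  })

#' Construct a control point
#' @param gantry gantry angle, degrees.
#' @param mu monitor units (>= 0).
#' @param leafLeft,leafRight leaf-tip positions, mm at isocenter plane.
#' @param leafWidth leaf width, mm.
#' @param bankOffset lower edge of first leaf row, mm (default centres the
#'   bank on the beam axis).
#' @export
controlPoint <- function(gantry, mu, leafLeft, leafRight, leafWidth = 5,
                         bankOffset = -length(leafLeft) * leafWidth / 2) {
  new("ControlPoint", gantry = gantry, mu = mu,
      leafLeft = as.numeric(leafLeft), leafRight = as.numeric(leafRight),
      leafWidth = leafWidth, bankOffset = bankOffset)
}

#' One plan phase (primary or boost course)
#'
#' Boost courses are separate phases, not simultaneous integrated boosts;
#' the audited quantity is always the summed plan.
#' @slot controlPoints list of [ControlPoint-class].
#' @slot nFractions number of fractions the phase is delivered in.
#' @slot label phase label.
#' @export
setClass("PlanPhase",
  representation(controlPoints = "list", nFractions = "numeric",
                 label = "character"),
  validity = function(object) {
    if (length(object@controlPoints) < 1L)
      return("a phase needs at least one control point")
    if (!all(vapply(object@controlPoints, is, TRUE, "ControlPoint")))
      return("controlPoints must all be ControlPoint objects")
    if (object@nFractions < 1 || object@nFractions != round(object@nFractions))
      return("nFractions must be a positive integer")
    TRUE
  })

#' @rdname PlanPhase-class
#' @param controlPoints list of control points.
#' @param nFractions integer >= 1.
#' @param label phase label.
#' @export
planPhase <- function(controlPoints, nFractions, label = "phase") {
  new("PlanPhase", controlPoints = controlPoints,
      nFractions = as.numeric(nFractions), label = label)
}

#' Multi-phase treatment plan
#' @slot phases list of [PlanPhase-class].
#' @slot isocenter shared isocenter, mm.
#' @slot beamModel the [BeamModel-class] used for dose computation.
#' @export
setClass("Plan",
  representation(phases = "list", isocenter = "numeric",
                 beamModel = "BeamModel"),
  validity = function(object) {
    if (length(object@phases) < 1L) return("plan needs at least one phase")
    if (!all(vapply(object@phases, is, TRUE, "PlanPhase")))
      return("phases must all be PlanPhase objects")
    if (length(object@isocenter) != 3L || !all(is.finite(object@isocenter)))
      return("isocenter must be numeric(3)")
    TRUE
  })

#' @rdname Plan-class
#' @param phases list of plan phases.
#' @param isocenter numeric(3), mm.
#' @param beamModel a `BeamModel`.
#' @export
rtPlan <- function(phases, isocenter, beamModel = rtrobust::beamModel()) {
  new("Plan", phases = phases, isocenter = as.numeric(isocenter),
      beamModel = beamModel)
}

setMethod("show", "Plan", function(object) {
  cat(sprintf("Plan: %d phase(s), isocenter (%.1f, %.1f, %.1f) mm\n",
              length(object@phases), object@isocenter[1],
              object@isocenter[2], object@isocenter[3]))
  for (ph in object@phases)
    cat(sprintf("  %s: %d control points, %d fractions\n",
                ph@label, length(ph@controlPoints), ph@nFractions))
})

# ---------------------------------------------------------------------------
# Scenario types
# ---------------------------------------------------------------------------

#' Random patient-setup uncertainty model
#'
#' Zero-mean Gaussian per-fraction setup errors: one sigma for the three
#' translational axes (mm) and one for the three rotational axes (degrees).
#' Defaults are the clinically motivated 2.0 mm / 0.5 degrees.
#' @slot sigmaTrans mm per translational axis.
#' @slot sigmaRot degrees per rotational axis.
#' @export
setClass("RandomSetupModel",
  representation(sigmaTrans = "numeric", sigmaRot = "numeric"),
  validity = function(object) {
    if (!.finite1(object@sigmaTrans) || object@sigmaTrans < 0)
      return("sigmaTrans must be >= 0")
    if (!.finite1(object@sigmaRot) || object@sigmaRot < 0)
      return("sigmaRot must be >= 0")
    TRUE
  })

#' @rdname RandomSetupModel-class
#' @param sigmaTrans mm (default 2.0).
#' @param sigmaRot degrees (default 0.5).
#' @export
randomSetupModel <- function(sigmaTrans = 2.0, sigmaRot = 0.5) {
  new("RandomSetupModel", sigmaTrans = sigmaTrans, sigmaRot = sigmaRot)
}

setClassUnion("RandomSetupModelOrNULL", c("RandomSetupModel", "NULL"))

.scenarioKinds <- c("random_only", "random_plus_translation",
                    "random_plus_rotation", "mlc_systematic")

#' A named uncertainty-scenario recipe
#'
#' One uncertainty scenario: either random setup errors only, random errors
#' combined with one systematic translation or rotation, or a systematic MLC
#' miscalibration (positive delta = wider field opening, negative =
#' systematic closing).
#'
#' @slot name unique scenario name.
#' @slot kind one of `random_only`, `random_plus_translation`,
#'   `random_plus_rotation`, `mlc_systematic`.
#' @slot group group label used for worst-case aggregation.
#' @slot systematic systematic setup component (zero unless applicable).
#' @slot mlcDelta MLC leaf-tip offset in mm (0 unless `mlc_systematic`).
#' @slot randomModel the random setup model, or NULL for MLC scenarios.
#' @export
setClass("UncertaintyScenario",
  representation(name = "character", kind = "character", group = "character",
                 systematic = "RigidTransform6D", mlcDelta = "numeric",
                 randomModel = "RandomSetupModelOrNULL"),
  validity = function(object) {
    if (!object@kind %in% .scenarioKinds)
      return(sprintf("unknown scenario kind '%s'", object@kind))
    p <- transformParams(object@systematic)
    if (object@kind == "mlc_systematic") {
      if (!all(p == 0)) return("mlc_systematic must have a zero systematic transform")
      if (!is.null(object@randomModel))
        return("mlc_systematic must have no random model")
    } else {
      if (object@mlcDelta != 0)
        return("setup scenarios must have mlcDelta == 0")
      if (object@kind == "random_only" && !all(p == 0))
        return("random_only must have a zero systematic transform")
      if (object@kind == "random_plus_translation" && !all(p[4:6] == 0))
        return("random_plus_translation must have zero rotations")
      if (object@kind == "random_plus_rotation" && !all(p[1:3] == 0))
        return("random_plus_rotation must have zero translations")
    }
    TRUE
  })

#' @rdname UncertaintyScenario-class
#' @param name unique scenario name.
#' @param kind scenario kind.
#' @param group group label.
#' @param systematic a `RigidTransform6D` (zero unless applicable).
#' @param mlcDelta MLC offset, mm.
#' @param randomModel a `RandomSetupModel` or NULL.
#' @export
uncertaintyScenario <- function(name, kind, group = kind,
                                systematic = rigidTransform(),
                                mlcDelta = 0, randomModel = NULL) {
  new("UncertaintyScenario", name = name, kind = kind, group = group,
      systematic = systematic, mlcDelta = mlcDelta, randomModel = randomModel)
}

setMethod("show", "UncertaintyScenario", function(object) {
  cat(sprintf("UncertaintyScenario '%s' [%s, group %s]\n",
              object@name, object@kind, object@group))
})

# ---------------------------------------------------------------------------
# Phantom container
# ---------------------------------------------------------------------------

#' Synthetic phantom with structure set
#'
#' @slot body the body [StructureMask-class].
#' @slot structures named list of structure masks (CTVs, PTVs, OARs, PRVs).
#' @slot spec the generating case specification (list form), kept for
#'   provenance.
#' @export
setClass("Phantom",
  representation(body = "StructureMask", structures = "list", spec = "list"))

#' @rdname Phantom-class
#' @param x a `Phantom`.
#' @param name structure name.
#' @export
phantomStructure <- function(x, name) {
  if (!name %in% names(x@structures))
    stop(sprintf("phantom has no structure '%s'", name))
  x@structures[[name]]
}

#' @rdname Phantom-class
#' @export
phantomBody <- function(x) x@body

#' @rdname Phantom-class
#' @export
structureNames <- function(x) names(x@structures)

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom '%s': grid %s, %d structures\n",
              object@spec$name %||% "custom",
              paste(dim(object@body@members), collapse = " x "),
              length(object@structures)))
  for (s in object@structures)
    cat(sprintf("  %-18s %-12s %8.2f cc\n", s@name, s@role,
                structureVolumeCC(s)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Endpoint / report
# ---------------------------------------------------------------------------

#' A dose-volume endpoint definition
#'
#' `D_percent` with parameter x is the minimum dose of the hottest x% of the
#' structure volume; `D_cc` with parameter v the minimum dose of the hottest
#' v cc; `D_mean` the arithmetic mean over member voxels.
#' @slot kind one of `D_percent`, `D_cc`, `D_mean`.
#' @slot parameter percent in (0, 100] or cc > 0; unused for `D_mean`.
#' @export
setClass("Endpoint",
  representation(kind = "character", parameter = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("D_percent", "D_cc", "D_mean"))
      return("kind must be D_percent, D_cc or D_mean")
    if (object@kind == "D_percent" &&
        (object@parameter <= 0 || object@parameter > 100))
      return("percent must be in (0, 100]")
    if (object@kind == "D_cc" && object@parameter <= 0)
      return("cc must be > 0")
    TRUE
  })

#' @rdname Endpoint-class
#' @param kind endpoint kind.
#' @param parameter percent or cc (ignored for `D_mean`).
#' @export
endpoint <- function(kind, parameter = NA_real_) {
  new("Endpoint", kind = kind, parameter = as.numeric(parameter))
}

#' @rdname Endpoint-class
#' @param ep an `Endpoint`.
#' @export
endpointLabel <- function(ep) {
  switch(ep@kind,
         D_mean = "Dmean",
         D_percent = sprintf("D%g%%", ep@parameter),
         D_cc = sprintf("D%gcc", ep@parameter))
}

#' Endpoint difference report
#'
#' Long-format table of per-scenario dose-volume endpoint values and their
#' signed differences to the nominal scenario, plus per-group worst-case
#' summaries (the signed difference of greatest absolute value).
#'
#' @slot nominal data.frame (structure, endpoint, nominal).
#' @slot rows data.frame (structure, endpoint, scenario, group, value, diff).
#' @slot worst data.frame (structure, endpoint, group, worstDiff, scenario).
#' @slot scenarios scenario manifest data.frame.
#' @slot meta list of provenance (seed, config echo).
#' @export
setClass("EndpointReport",
  representation(nominal = "data.frame", rows = "data.frame",
                 worst = "data.frame", scenarios = "data.frame",
                 meta = "list"))

setMethod("show", "EndpointReport", function(object) {
  cat(sprintf("EndpointReport: %d (structure, endpoint) pairs, %d scenarios\n",
              nrow(object@nominal),
              length(unique(object@rows$scenario))))
  if (nrow(object@worst)) {
    cat("Worst-case signed differences (Gy):\n")
    print(object@worst, row.names = FALSE)
  }
})

#' @rdname EndpointReport-class
#' @param x an `EndpointReport`.
#' @export
reportRows <- function(x) x@rows

#' @rdname EndpointReport-class
#' @export
reportNominal <- function(x) x@nominal

#' @rdname EndpointReport-class
#' @export
reportWorst <- function(x) x@worst
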
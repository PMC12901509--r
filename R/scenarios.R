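# Uncertainty-scenario suite construction and per-fraction sampling.
#
# The default suite mirrors a clinically motivated audit protocol:
# one random-only scenario (Gaussian sigma 2.0 mm translational / 0.5 deg
# rotational, redrawn every fraction), eighteen systematic translations
# (+/-2, +/-3, +/-5 mm in AP, SI or LR) each combined with the random
# model, twenty-four systematic rotations (+/-0.5, 1, 2, 3 deg in pitch,
# yaw or roll) likewise, and six systematic MLC miscalibrations
# (+/-0.5, 1, 2 mm): 49 scenarios in total.

.transAxes <- c(AP = "ty", SI = "tz", LR = "tx")
.rotAxes <- c(pitch = "pitch", yaw = "yaw", roll = "roll")

#' Configuration of the scenario suite
#'
#' @param transMm systematic translation magnitudes, mm (default 2, 3, 5).
#' @param rotDeg systematic rotation magnitudes, degrees
#'   (default 0.5, 1, 2, 3).
#' @param mlcMm MLC miscalibration magnitudes, mm (default 0.5, 1, 2).
#' @param randomModel the [RandomSetupModel-class] combined with every
#'   setup scenario.
#' @param includeRandomOnly include the random-only scenario (default TRUE).
#' @return A list understood by [buildScenarioSuite()].
#' @export
scenarioConfig <- function(transMm = c(2, 3, 5), rotDeg = c(0.5, 1, 2, 3),
                           mlcMm = c(0.5, 1, 2),
                           randomModel = randomSetupModel(),
                           includeRandomOnly = TRUE) {
  list(transMm = transMm, rotDeg = rotDeg, mlcMm = mlcMm,
       randomModel = randomModel, includeRandomOnly = includeRandomOnly)
}

.signChars <- function(s) ifelse(s >= 0, "+", "-")

#' Build the ordered uncertainty-scenario suite
#'
#' With the default configuration the suite contains exactly 49 scenarios:
#' 1 random-only + 18 translational (3 magnitudes x 3 axes x 2 signs)
#' + 24 rotational (4 x 3 x 2) + 6 MLC (3 x 2). Names and group labels are
#' unique and deterministic. Groups partition the suite into `random`,
#' `sys_trans`, `sys_rot` and `mlc`.
#'
#' @param config a [scenarioConfig()] list.
#' @return Ordered list of [UncertaintyScenario-class] objects.
#' @export
buildScenarioSuite <- function(config = scenarioConfig()) {
  if (any(vapply(list(config$transMm, config$rotDeg, config$mlcMm),
                 function(x) length(x) > 0 && any(x <= 0), TRUE)))
    stop("scenario magnitudes must be positive")
  suite <- list()
  if (isTRUE(config$includeRandomOnly)) {
    suite[["random"]] <- uncertaintyScenario(
      name = "random", kind = "random_only", group = "random",
      randomModel = config$randomModel)
  }
  for (axis in names(.transAxes)) {
    for (mag in sort(config$transMm)) {
      for (s in c(+1, -1)) {
        nm <- sprintf("trans_%s%s%.1fmm", axis, .signChars(s), mag)
        args <- list(0, 0, 0, 0, 0, 0)
        names(args) <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
        args[[.transAxes[[axis]]]] <- s * mag
        suite[[nm]] <- uncertaintyScenario(
          name = nm, kind = "random_plus_translation", group = "sys_trans",
          systematic = do.call(rigidTransform, args),
          randomModel = config$randomModel)
      }
    }
  }
  for (axis in names(.rotAxes)) {
    for (mag in sort(config$rotDeg)) {
      for (s in c(+1, -1)) {
        nm <- sprintf("rot_%s%s%.1fdeg", axis, .signChars(s), mag)
        args <- list(0, 0, 0, 0, 0, 0)
        names(args) <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
        args[[.rotAxes[[axis]]]] <- s * mag
        suite[[nm]] <- uncertaintyScenario(
          name = nm, kind = "random_plus_rotation", group = "sys_rot",
          systematic = do.call(rigidTransform, args),
          randomModel = config$randomModel)
      }
    }
  }
  for (mag in sort(config$mlcMm)) {
    for (s in c(+1, -1)) {
      nm <- sprintf("mlc%s%.1fmm", .signChars(s), mag)
      suite[[nm]] <- uncertaintyScenario(
        name = nm, kind = "mlc_systematic", group = "mlc",
        mlcDelta = s * mag)
    }
  }
  unname(suite)
}

#' Scenario manifest as a data frame
#'
#' @param suite list of scenarios from [buildScenarioSuite()].
#' @return data.frame with name, kind, group, systematic components,
#'   magnitude and MLC delta.
#' @export
scenarioManifest <- function(suite) {
  do.call(rbind, lapply(suite, function(s) {
    p <- transformParams(s@systematic)
    data.frame(name = s@name, kind = s@kind, group = s@group,
               magnitude = max(abs(p), abs(s@mlcDelta)),
               tx_mm = p[["tx"]], ty_mm = p[["ty"]], tz_mm = p[["tz"]],
               pitch_deg = p[["pitch"]], yaw_deg = p[["yaw"]],
               roll_deg = p[["roll"]], mlc_mm = s@mlcDelta,
               stringsAsFactors = FALSE)
  }))
}

#' Stable per-scenario random seed
#'
#' Derives a deterministic 31-bit stream seed from the master seed and the
#' scenario name, so adding scenarios to a suite never perturbs the draws
#' of the others.
#' @param masterSeed integer master seed.
#' @param name scenario name.
#' @export
scenarioSeed <- function(masterSeed, name) {
  h <- as.numeric(masterSeed) %% 2147483647
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Sample per-fraction setup transforms for a scenario
#'
#' Each fraction's transform is the composition systematic o random (the
#' systematic component applied last), with the random component drawn
#' independently per fraction from the scenario's Gaussian setup model.
#' MLC scenarios have no setup component and yield identity transforms.
#'
#' @param scenario an [UncertaintyScenario-class].
#' @param nFractions number of fractions (>= 1).
#' @param seed integer seed for the scenario's stream.
#' @return List of `nFractions` [RigidTransform6D-class] objects.
#' @export
sampleFractionTransforms <- function(scenario, nFractions, seed) {
  stopifnot(nFractions >= 1)
  if (scenario@kind == "mlc_systematic")
    return(replicate(nFractions, rigidTransform(), simplify = FALSE))
  rm <- scenario@randomModel
  st <- if (is.null(rm)) 0 else rm@sigmaTrans
  sr <- if (is.null(rm)) 0 else rm@sigmaRot
  msys <- transformMatrix(scenario@systematic, c(0, 0, 0))
  sysIsIdentity <- isIdentityTransform(scenario@systematic)
  set.seed(as.integer(seed))
  out <- vector("list", nFractions)
  for (f in seq_len(nFractions)) {
    tr <- if (st > 0) rnorm(3, 0, st) else c(0, 0, 0)
    ro <- if (sr > 0) rnorm(3, 0, sr) else c(0, 0, 0)
    rnd <- rigidTransform(tr[1], tr[2], tr[3], ro[1], ro[2], ro[3])
    out[[f]] <- if (sysIsIdentity) rnd else
      decomposeTransform(
        composeTransforms(msys, transformMatrix(rnd, c(0, 0, 0))),
        c(0, 0, 0))
  }
  out
}

#' Apply a systematic MLC miscalibration to a whole plan
#'
#' Every control point's left tips are shifted by `-delta` and right tips
#' by `+delta` (positive delta = wider field opening), clamped at the gap
#' midpoint; MU, gantry angles and phase structure are untouched and the
#' original plan is not modified.
#'
#' @param plan a [Plan-class].
#' @param delta miscalibration, mm.
#' @return A new perturbed [Plan-class].
#' @export
perturbPlanMlc <- function(plan, delta) {
  phases <- lapply(plan@phases, function(ph) {
    cps <- lapply(ph@controlPoints, function(cp) {
      tips <- perturbLeafTips(cp@leafLeft, cp@leafRight, delta)
      controlPoint(gantry = cp@gantry, mu = cp@mu,
                   leafLeft = tips$left, leafRight = tips$right,
                   leafWidth = cp@leafWidth, bankOffset = cp@bankOffset)
    })
    planPhase(cps, ph@nFractions, ph@label)
  })
  rtPlan(phases, plan@isocenter, plan@beamModel)
}

#' Write a scenario suite to JSON
#'
#' One object per scenario, with the systematic transform serialized as
#' `tx_mm` ... `roll_deg` fields.
#' @param suite scenario list.
#' @param path output file.
#' @export
writeScenarioSuite <- function(suite, path) {
  objs <- lapply(suite, function(s) {
    c(list(name = s@name, kind = s@kind, group = s@group,
           mlc_mm = s@mlcDelta),
      transformToList(s@systematic),
      if (!is.null(s@randomModel))
        list(sigma_trans_mm = s@randomModel@sigmaTrans,
             sigma_rot_deg = s@randomModel@sigmaRot))
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeScenarioSuite
#' @export
readScenarioSuite <- function(path) {
  objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(objs, function(x) {
    rm <- if (!is.null(x$sigma_trans_mm))
      randomSetupModel(x$sigma_trans_mm, x$sigma_rot_deg)
    uncertaintyScenario(
      name = x$name, kind = x$kind, group = x$group,
      systematic = transformFromList(x),
      mlcDelta = x$mlc_mm, randomModel = rm)
  })
}
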
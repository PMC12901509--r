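# Audit orchestration: nominal dose, scenario doses with fraction-wise
# accumulation, endpoint reporting and worst-case aggregation.

#' Compute the nominal scenario of a normalized case
#'
#' The summed plan (all phases) computed without any uncertainty, plus the
#' baseline dose-volume endpoints.
#'
#' @param plan a normalized [Plan-class].
#' @param phantom the matching [Phantom-class].
#' @param endpointPlan endpoint table (default from structure roles).
#' @param rayStep,fluenceRes engine resolution parameters, mm.
#' @return list(dose, phases, baseline): summed nominal [DoseGrid-class],
#'   per-phase grids, and a data.frame of baseline endpoint values.
#' @export
runNominal <- function(plan, phantom,
                       endpointPlan = defaultEndpointPlan(phantom@structures),
                       rayStep = 1, fluenceRes = 0.5) {
  pd <- planDose(plan, phantomBody(phantom), rayStep = rayStep,
                 fluenceRes = fluenceRes)
  eps <- .planEndpoints(endpointPlan)
  baseline <- data.frame(
    structure = endpointPlan$structure,
    endpoint = vapply(eps, endpointLabel, ""),
    nominal = vapply(seq_along(eps), function(i)
      evaluateEndpoint(pd$total,
                       phantom@structures[[endpointPlan$structure[i]]],
                       eps[[i]]), 0),
    stringsAsFactors = FALSE)
  list(dose = pd$total, phases = pd$phases, baseline = baseline)
}

#' Accumulated dose of a plan under one uncertainty scenario
#'
#' For setup scenarios the dose of every fraction of every phase is
#' computed with that fraction's sampled transform at per-fraction MU
#' (phase dose / nFractions) and summed over all fractions and phases;
#' random draws continue across the concatenated fraction sequence of all
#' phases and the systematic component is shared. For MLC scenarios the
#' full summed plan is computed once with the perturbed MLC and the
#' identity transform. Fractions whose sampled transforms are bitwise
#' identical (e.g. all of them when every sigma is zero) are computed once
#' and weighted by their multiplicity, which keeps the all-zero scenario
#' on the identical floating-point path as the nominal computation.
#'
#' @param plan a normalized [Plan-class].
#' @param phantom the matching [Phantom-class].
#' @param scenario an [UncertaintyScenario-class].
#' @param masterSeed master seed; the scenario stream is derived from it
#'   and the scenario name via [scenarioSeed()].
#' @param rayStep,fluenceRes engine resolution parameters, mm.
#' @return The accumulated [DoseGrid-class].
#' @export
runScenario <- function(plan, phantom, scenario, masterSeed = 1,
                        rayStep = 1, fluenceRes = 0.5) {
  body <- phantomBody(phantom)
  if (scenario@kind == "mlc_systematic") {
    pplan <- perturbPlanMlc(plan, scenario@mlcDelta)
    return(planDose(pplan, body, rayStep = rayStep,
                    fluenceRes = fluenceRes)$total)
  }
  nFx <- vapply(plan@phases, function(ph) ph@nFractions, 0)
  transforms <- sampleFractionTransforms(
    scenario, sum(nFx), scenarioSeed(masterSeed, scenario@name))
  total <- NULL
  offset <- 0L
  for (i in seq_along(plan@phases)) {
    ph <- plan@phases[[i]]
    flu <- phaseFluence(ph, plan@beamModel, 0, fluenceRes)
    trs <- transforms[(offset + 1L):(offset + nFx[i])]
    offset <- offset + as.integer(nFx[i])
    keys <- vapply(trs, function(t)
      paste(sprintf("%.17g", transformParams(t)), collapse = "|"), "")
    counts <- table(factor(keys, levels = unique(keys)))
    phaseVals <- NULL
    for (k in seq_along(counts)) {
      tr <- trs[[match(names(counts)[k], keys)]]
      d <- computeDose(ph, body, plan@beamModel, plan@isocenter,
                       transform = tr, fluence = flu, rayStep = rayStep)
      contrib <- d@values * (as.numeric(counts[k]) / ph@nFractions)
      phaseVals <- if (is.null(phaseVals)) contrib else phaseVals + contrib
    }
    total <- if (is.null(total)) phaseVals else total + phaseVals
  }
  doseGrid(total, body@origin, body@spacing)
}

#' Run a full robustness audit on a synthetic case
#'
#' Generates (or accepts) a normalized case, computes the nominal summed
#' dose, recomputes dose under every scenario of the suite with
#' fraction-wise accumulation, evaluates the endpoint differences and the
#' per-group worst cases, and optionally writes the report files.
#'
#' Worst-case groups follow the audit convention: `random`, systematic
#' translations up to 3 mm (`sys_trans_le3`, the headline group excluding
#' exploratory 5 mm shifts), all systematic translations (`sys_trans`),
#' systematic rotations (`sys_rot`, `sys_rot_le3`), and every MLC
#' miscalibration individually.
#'
#' @param case a built-in case name, a case spec, or the list returned by
#'   [generateCase()] (reused as-is).
#' @param spacing grid spacing, mm; 5 mm keeps the full 49-scenario suite
#'   at desk scale, 2.5 mm matches the audit's calculation voxel size.
#' @param nControlPoints control points per arc.
#' @param seed master seed; recorded in the report meta and used to derive
#'   every scenario stream.
#' @param scenarios a [scenarioConfig()]; `scenarioSet = "none"` skips all
#'   scenarios and reports the baseline only.
#' @param scenarioSet `"default"` or `"none"`.
#' @param outDir optional output directory for report files.
#' @param cache when an `outDir` is given, keep per-scenario dose files
#'   under `outDir/doses` keyed by a configuration hash and reuse them on
#'   reruns with the same configuration; set to FALSE to bypass.
#' @param rayStep,fluenceRes engine resolution parameters, mm.
#' @param verbose log stage/scenario progress lines.
#' @return An [EndpointReport-class] with worst-case summaries and meta.
#' @export
runAudit <- function(case = "brainlike", spacing = 5, nControlPoints = 24,
                     seed = 1, scenarios = scenarioConfig(),
                     scenarioSet = c("default", "none"), outDir = NULL,
                     cache = TRUE, rayStep = 1, fluenceRes = 0.5,
                     verbose = FALSE) {
  scenarioSet <- match.arg(scenarioSet)
  t0 <- Sys.time()
  say <- function(stage, ...) if (verbose)
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    sprintf(...)))

  cs <- if (is.list(case) && !is.null(case$plan)) case else
    generateCase(case, spacing = spacing,
                 nControlPoints = nControlPoints, seed = seed)
  phantom <- cs$phantom
  plan <- cs$plan
  say("case", "'%s' grid %s", cs$spec$name,
      paste(dim(phantom@body@members), collapse = "x"))

  endpointPlan <- defaultEndpointPlan(phantom@structures)
  for (st in unique(endpointPlan$structure))
    if (!any(phantom@structures[[st]]@members))
      stop(sprintf("structure '%s' in the endpoint plan is empty", st))

  nominal <- cs$nominal
  say("nominal", "summed dose ready")

  suite <- if (scenarioSet == "none") list() else
    buildScenarioSuite(scenarios)
  cacheDir <- NULL
  if (!is.null(outDir) && isTRUE(cache) && length(suite)) {
    cfgKey <- scenarioSeed(seed, paste(cs$spec$name, spacing,
                                       nControlPoints, rayStep,
                                       fluenceRes, sep = "|"))
    cacheDir <- file.path(outDir, "doses")
    dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
  }
  doses <- list()
  for (sc in suite) {
    cacheFile <- if (!is.null(cacheDir))
      file.path(cacheDir, sprintf("%08x_%s.dose", cfgKey, sc@name))
    if (!is.null(cacheDir) && file.exists(cacheFile)) {
      say("scenario", "%s (cached)", sc@name)
      doses[[sc@name]] <- readDoseGrid(cacheFile)
      next
    }
    say("scenario", "%s", sc@name)
    doses[[sc@name]] <- runScenario(plan, phantom, sc, masterSeed = seed,
                                    rayStep = rayStep,
                                    fluenceRes = fluenceRes)
    if (!is.null(cacheDir)) writeDoseGrid(doses[[sc@name]], cacheFile)
  }
  groups <- vapply(suite, function(s) s@group, "")
  names(groups) <- vapply(suite, function(s) s@name, "")
  report <- endpointDifferences(nominal, doses, phantom@structures,
                                endpointPlan, groups = groups)
  manifest <- if (length(suite)) scenarioManifest(suite) else data.frame()
  report@scenarios <- manifest
  report@meta <- list(case = cs$spec$name, seed = seed, spacing = spacing,
                      nControlPoints = nControlPoints,
                      scale = cs$scale,
                      wallTime = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))

  if (length(suite)) {
    worst <- list(worstCase(report, "random"))
    if (any(groups == "sys_trans")) {
      worst <- c(worst, list(worstCase(report, "sys_trans")))
      le3 <- manifest$name[manifest$group == "sys_trans" &
                             manifest$magnitude <= 3]
      if (length(le3))
        worst <- c(worst, list(worstCase(report, scenarios = le3,
                                         label = "sys_trans_le3")))
    }
    if (any(groups == "sys_rot")) {
      worst <- c(worst, list(worstCase(report, "sys_rot")))
      le3 <- manifest$name[manifest$group == "sys_rot" &
                             manifest$magnitude <= 3]
      if (length(le3))
        worst <- c(worst, list(worstCase(report, scenarios = le3,
                                         label = "sys_rot_le3")))
    }
    for (nm in manifest$name[manifest$group == "mlc"])
      worst <- c(worst, list(worstCase(report, scenarios = nm, label = nm)))
    report@worst <- do.call(rbind, worst)
  }

  if (!is.null(outDir)) writeAuditOutputs(report, outDir)
  say("done", "%.1f s", report@meta$wallTime)
  report
}

#' Write audit report files
#'
#' Writes `report.csv` (long-format endpoint rows), `nominal.csv`,
#' `worst.csv`, `report.json` (nominal, rows, worst and meta in one
#' object) and `manifest.json` (the scenario manifest).
#'
#' @param report an [EndpointReport-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeAuditOutputs <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report@rows, file.path(dir, "report.csv"), row.names = FALSE)
  write.csv(report@nominal, file.path(dir, "nominal.csv"),
            row.names = FALSE)
  write.csv(report@worst, file.path(dir, "worst.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(meta = report@meta, nominal = report@nominal, rows = report@rows,
         worst = report@worst),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  jsonlite::write_json(report@scenarios, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
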
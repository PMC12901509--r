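# Dose-volume histogram metrics and endpoint difference reporting.
#
# DVH convention: nearest-rank on voxel doses with full-voxel membership
# (voxel-centre inclusion, no partial-volume weighting). D_x% / D_vcc is
# the minimum dose of the hottest x% (or v cc) of the structure: sort
# member doses descending and take d(k), k = ceil(V / voxel volume)
# clamped to [1, n].

.memberDoses <- function(dose, mask) {
  assertCongruent(dose, mask, sprintf("dose and mask '%s'", mask@name))
  d <- dose@values[mask@members]
  if (length(d) == 0L)
    stop(sprintf("structure '%s' has no member voxels", mask@name))
  d
}

#' Evaluate a dose-volume endpoint
#'
#' `D_mean` is the arithmetic mean over member voxels. `D_percent(x)` and
#' `D_cc(v)` use the nearest-rank rule: with member doses sorted descending
#' d(1) >= ... >= d(n) and requested volume V = (x/100) * n * voxelVolume
#' (or v cc), the endpoint is d(k) with k = ceil(V / voxelVolume) clamped
#' to [1, n]. A requested volume exceeding the structure clamps to the
#' minimum dose with a warning.
#'
#' @param dose a [DoseGrid-class].
#' @param mask a congruent, non-empty [StructureMask-class].
#' @param ep an [Endpoint-class].
#' @return Dose in Gy.
#' @examples
#' # 100 equal voxels with doses 1..100 Gy: D98% is the 98th hottest = 3 Gy
#' @export
evaluateEndpoint <- function(dose, mask, ep) {
  d <- .memberDoses(dose, mask)
  if (ep@kind == "D_mean") return(mean(d))
  n <- length(d)
  vv <- voxelVolumeCC(mask)
  V <- if (ep@kind == "D_percent") (ep@parameter / 100) * n * vv else
    ep@parameter
  if (ep@kind == "D_cc" && V > n * vv + 1e-12) {
    warning(sprintf(
      "requested %g cc exceeds volume of '%s' (%.4g cc); clamping to D_min",
      ep@parameter, mask@name, n * vv))
  }
  k <- ceiling(V / vv - 1e-9)
  k <- max(1L, min(n, k))
  sort(d, decreasing = TRUE)[k]
}

#' Cumulative dose-volume histogram
#'
#' Relative volume receiving at least each dose level: a monotone
#' non-increasing curve starting at 1.0 at 0 Gy and reaching 0 beyond the
#' maximum member dose.
#'
#' @param dose a [DoseGrid-class].
#' @param mask a congruent, non-empty [StructureMask-class].
#' @param binWidth dose bin width, Gy.
#' @return data.frame(dose_gy, rel_volume).
#' @export
cumulativeDVH <- function(dose, mask, binWidth = 0.1) {
  d <- .memberDoses(dose, mask)
  bins <- seq(0, max(d) + binWidth, by = binWidth)
  ds <- sort(d)
  n <- length(ds)
  # volume with dose >= t: voxels strictly above t plus ties
  atLeast <- n - findInterval(bins, ds, left.open = TRUE)
  data.frame(dose_gy = bins, rel_volume = atLeast / n)
}

#' Default endpoint plan from structure roles
#'
#' CTVs get D98% and D2%; parallel OARs the mean dose; serial OARs (and
#' PRVs, which inherit their serial parent's endpoint kind) the near-max
#' dose D0.03cc.
#'
#' @param structures named list of [StructureMask-class] objects.
#' @return data.frame(structure, kind, parameter).
#' @export
defaultEndpointPlan <- function(structures) {
  rows <- list()
  for (s in structures) {
    eps <- switch(s@role,
      target_ctv = list(c("D_percent", 98), c("D_percent", 2)),
      oar_parallel = list(c("D_mean", NA)),
      oar_serial = list(c("D_cc", 0.03)),
      prv = list(c("D_cc", 0.03)),
      NULL)
    for (e in eps)
      rows[[length(rows) + 1L]] <- data.frame(
        structure = s@name, kind = e[1],
        parameter = as.numeric(e[2]), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.planEndpoints <- function(endpointPlan) {
  lapply(seq_len(nrow(endpointPlan)), function(i)
    endpoint(endpointPlan$kind[i], endpointPlan$parameter[i]))
}

#' Endpoint differences of scenario doses against the nominal scenario
#'
#' Evaluates every endpoint of the endpoint plan on the nominal dose and on
#' each scenario dose; the signed difference convention is
#' `scenario - nominal`.
#'
#' @param nominal the nominal [DoseGrid-class].
#' @param scenarioDoses named list of congruent scenario `DoseGrid`s.
#' @param structures named list of [StructureMask-class] objects.
#' @param endpointPlan data.frame(structure, kind, parameter); default
#'   derived from roles via [defaultEndpointPlan()].
#' @param groups optional named character vector mapping scenario name to
#'   group label (default: one group "scenario").
#' @return An [EndpointReport-class].
#' @export
endpointDifferences <- function(nominal, scenarioDoses, structures,
                                endpointPlan = defaultEndpointPlan(structures),
                                groups = NULL) {
  if (is.null(names(scenarioDoses)) && length(scenarioDoses) > 0)
    stop("scenarioDoses must be a named list")
  eps <- .planEndpoints(endpointPlan)
  labels <- vapply(eps, endpointLabel, "")
  nomVals <- numeric(nrow(endpointPlan))
  for (i in seq_len(nrow(endpointPlan))) {
    st <- endpointPlan$structure[i]
    if (!st %in% names(structures))
      stop(sprintf("endpoint plan references unknown structure '%s'", st))
    nomVals[i] <- evaluateEndpoint(nominal, structures[[st]], eps[[i]])
  }
  nomDf <- data.frame(structure = endpointPlan$structure, endpoint = labels,
                      nominal = nomVals, stringsAsFactors = FALSE)
  rows <- list()
  for (sc in names(scenarioDoses)) {
    g <- if (is.null(groups)) "scenario" else unname(groups[[sc]])
    dsc <- scenarioDoses[[sc]]
    if (is.null(dsc)) stop(sprintf("missing scenario dose for '%s'", sc))
    vals <- numeric(nrow(endpointPlan))
    for (i in seq_len(nrow(endpointPlan)))
      vals[i] <- evaluateEndpoint(dsc, structures[[endpointPlan$structure[i]]],
                                  eps[[i]])
    rows[[sc]] <- data.frame(
      structure = endpointPlan$structure, endpoint = labels, scenario = sc,
      group = g, value = vals, diff = vals - nomVals,
      stringsAsFactors = FALSE)
  }
  rowsDf <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structure = character(), endpoint = character(),
               scenario = character(), group = character(),
               value = numeric(), diff = numeric())
  rownames(rowsDf) <- NULL
  new("EndpointReport", nominal = nomDf, rows = rowsDf,
      worst = data.frame(), scenarios = data.frame(), meta = list())
}

#' Worst-case difference per (structure, endpoint) within a scenario group
#'
#' For each (structure, endpoint) pair returns the SIGNED difference of
#' greatest absolute value across the group's scenarios, together with the
#' scenario achieving it (ties broken by scenario order in the report).
#' Signed values keep hot and cold deviations distinguishable.
#'
#' @param report an [EndpointReport-class].
#' @param group group label present in the report rows, or a character
#'   vector of scenario names defining an ad-hoc group (with `scenarios=`).
#' @param scenarios optional character vector of scenario names overriding
#'   the group column.
#' @param label group label used in the output (defaults to `group`).
#' @return data.frame(structure, endpoint, group, worstDiff, scenario).
#' @export
worstCase <- function(report, group = NULL, scenarios = NULL,
                      label = group) {
  rows <- report@rows
  if (!is.null(scenarios)) {
    rows <- rows[rows$scenario %in% scenarios, , drop = FALSE]
    if (is.null(label)) label <- "custom"
  } else {
    if (is.null(group)) stop("either group or scenarios must be given")
    if (!group %in% rows$group)
      stop(sprintf("unknown scenario group '%s'", group))
    rows <- rows[rows$group == group, , drop = FALSE]
  }
  if (nrow(rows) == 0L) stop("group is empty")
  key <- paste(rows$structure, rows$endpoint, sep = "\r")
  out <- lapply(split(seq_len(nrow(rows)), factor(key, unique(key))),
                function(ix) {
    sub <- rows[ix, , drop = FALSE]
    k <- which.max(abs(sub$diff))  # first max: scenario order breaks ties
    data.frame(structure = sub$structure[1], endpoint = sub$endpoint[1],
               group = label, worstDiff = sub$diff[k],
               scenario = sub$scenario[k], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
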
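# helpers to build a tiny grid/mask pair holding given member doses
.dvhFixture <- function(doses, spacing = 2.5) {
  n <- length(doses)
  dims <- c(n, 1L, 1L)
  g <- doseGrid(array(doses, dims), spacing = rep(spacing, 3))
  m <- structureMask("s", "helper", array(TRUE, dims), c(0, 0, 0),
                     rep(spacing, 3))
  list(dose = g, mask = m)
}

test_that("uniform structures return the uniform dose for every endpoint", {
  f <- .dvhFixture(rep(10, 64))
  for (ep in list(endpoint("D_mean"), endpoint("D_percent", 98),
                  endpoint("D_percent", 2), endpoint("D_cc", 0.03)))
    expect_equal(evaluateEndpoint(f$dose, f$mask, ep), 10)
})

test_that("worked nearest-rank examples evaluate as documented", {
  # two voxels of 0.015625 cc (2.5 mm lattice): the hottest 0.03 cc spans
  # both, so its minimum dose is the colder voxel
  f <- .dvhFixture(c(20, 10), spacing = 2.5)
  expect_equal(voxelVolumeCC(f$mask), 0.015625)
  expect_equal(evaluateEndpoint(f$dose, f$mask, endpoint("D_cc", 0.03)), 10)
  # 100 equal voxels with doses 1..100: D98% is the 98th hottest
  f2 <- .dvhFixture(1:100)
  expect_equal(evaluateEndpoint(f2$dose, f2$mask, endpoint("D_percent", 98)),
               3)
  expect_equal(bruteForceEndpoint(1:100, voxelVolumeCC(f2$mask),
                                  "D_percent", 98), 3)
})

test_that("nearest-rank endpoints agree exactly with the brute-force walk", {
  set.seed(20)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    doses <- round(runif(n, 0, 70), 3)
    sp <- sample(c(1, 2, 2.5), 1)
    f <- .dvhFixture(doses, spacing = sp)
    vv <- voxelVolumeCC(f$mask)
    kind <- sample(c("D_percent", "D_cc", "D_mean"), 1)
    param <- switch(kind, D_percent = runif(1, 0.5, 100),
                    D_cc = runif(1, vv / 2, n * vv), D_mean = NA)
    got <- evaluateEndpoint(f$dose, f$mask, endpoint(kind, param))
    want <- bruteForceEndpoint(doses, vv, kind, param)
    if (kind == "D_mean") {
      expect_equal(got, want, tolerance = 1e-12)  # summation order only
    } else {
      expect_identical(got, want)  # rank selection must agree exactly
    }
  }
})

test_that("degenerate requests error or clamp as specified", {
  f <- .dvhFixture(c(5, 6, 7))
  empty <- structureMask("e", "helper", array(FALSE, c(3, 1, 1)),
                         c(0, 0, 0), rep(2.5, 3))
  expect_error(evaluateEndpoint(f$dose, empty, endpoint("D_mean")),
               "no member voxels")
  # volume beyond the structure clamps to D_min with a warning
  expect_warning(
    v <- evaluateEndpoint(f$dose, f$mask, endpoint("D_cc", 10)),
    "clamping")
  expect_equal(v, 5)
  other <- structureMask("o", "helper", array(TRUE, c(4, 1, 1)),
                         c(0, 0, 0), rep(2.5, 3))
  expect_error(evaluateEndpoint(f$dose, other, endpoint("D_mean")),
               "congruent")
})

test_that("cumulative DVH is a proper survival curve", {
  f <- .dvhFixture(rep(12, 50))
  dvh <- cumulativeDVH(f$dose, f$mask, binWidth = 1)
  expect_equal(dvh$rel_volume[dvh$dose_gy == 0], 1)
  expect_true(all(dvh$rel_volume[dvh$dose_gy <= 12] == 1))
  expect_true(all(dvh$rel_volume[dvh$dose_gy > 12] == 0))
  set.seed(4)
  doses <- runif(300, 0, 60)
  f2 <- .dvhFixture(doses)
  dvh2 <- cumulativeDVH(f2$dose, f2$mask, binWidth = 0.5)
  expect_true(all(diff(dvh2$rel_volume) <= 0))
  expect_equal(dvh2$rel_volume[1], 1)
  expect_equal(dvh2$rel_volume[nrow(dvh2)], 0)
  # the curve at the nearest-rank D50% dose covers >= 50% of the volume
  d50 <- evaluateEndpoint(f2$dose, f2$mask, endpoint("D_percent", 50))
  expect_gte(mean(doses >= d50), 0.5)
})

test_that("endpoint ordering invariants hold on random dose grids", {
  set.seed(9)
  for (i in 1:20) {
    f <- .dvhFixture(runif(sample(20:200, 1), 0, 75))
    d2 <- evaluateEndpoint(f$dose, f$mask, endpoint("D_percent", 2))
    d50 <- evaluateEndpoint(f$dose, f$mask, endpoint("D_percent", 50))
    d98 <- evaluateEndpoint(f$dose, f$mask, endpoint("D_percent", 98))
    dm <- evaluateEndpoint(f$dose, f$mask, endpoint("D_mean"))
    doses <- f$dose@values[f$mask@members]
    expect_true(d2 >= d50 && d50 >= d98)
    expect_true(min(doses) <= dm && dm <= max(doses))
  }
})

test_that("endpoint differences are signed scenario minus nominal", {
  dims <- c(4, 4, 4)
  nom <- doseGrid(array(runif(64, 10, 20), dims), spacing = rep(5, 3))
  same <- doseGrid(nom@values, nom@origin, nom@spacing)
  plus1 <- doseGrid(nom@values + 1, nom@origin, nom@spacing)
  mask <- structureMask("ctv", "target_ctv",
                        array(rep(c(TRUE, FALSE), 32), dims),
                        c(0, 0, 0), rep(5, 3))
  rep <- endpointDifferences(nom, list(same = same, plus1 = plus1),
                             list(ctv = mask))
  expect_true(all(rep@rows$diff[rep@rows$scenario == "same"] == 0))
  expect_equal(rep@rows$diff[rep@rows$scenario == "plus1"], c(1, 1),
               tolerance = 1e-12)
  expect_equal(rep@rows$value - rep@rows$diff,
               rep(rep@nominal$nominal, 2), ignore_attr = TRUE)
  expect_error(endpointDifferences(nom, list(x = NULL), list(ctv = mask)),
               "missing scenario dose")
})

test_that("worst case picks the signed maximum-absolute difference", {
  rows <- data.frame(
    structure = "ctv", endpoint = "D98%",
    scenario = c("a", "b", "c"), group = "g",
    value = 0, diff = c(2, -3, 1), stringsAsFactors = FALSE)
  rep <- new("EndpointReport", nominal = data.frame(), rows = rows,
             worst = data.frame(), scenarios = data.frame(), meta = list())
  w <- worstCase(rep, "g")
  expect_equal(w$worstDiff, -3)
  expect_equal(w$scenario, "b")
  # single-scenario group returns that scenario's difference
  w1 <- worstCase(rep, scenarios = "a", label = "solo")
  expect_equal(w1$worstDiff, 2)
  expect_error(worstCase(rep, "nope"), "unknown scenario group")
})

test_that("worst case equals a brute-force scan on randomized tables", {
  set.seed(31)
  for (i in 1:50) {
    nsc <- sample(2:12, 1)
    diffs <- round(rnorm(nsc, 0, 4), 3)
    rows <- data.frame(structure = "s", endpoint = "Dmean",
                       scenario = paste0("sc", seq_len(nsc)), group = "g",
                       value = 0, diff = diffs, stringsAsFactors = FALSE)
    rep <- new("EndpointReport", nominal = data.frame(), rows = rows,
               worst = data.frame(), scenarios = data.frame(), meta = list())
    w <- worstCase(rep, "g")
    oracle <- bruteForceWorst(diffs)
    expect_identical(w$worstDiff, oracle$value)
    expect_identical(w$scenario, paste0("sc", oracle$index))
  }
})
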
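# rtrobust

Dosimetric robustness auditing of intensity-modulated photon radiotherapy
plans.

Plan quality in photon radiotherapy is usually judged on the *nominal*
dose distribution only. During delivery, however, the patient is never set
up exactly as planned and the multi-leaf collimator (MLC) is never
calibrated exactly; both perturb the delivered dose, and the sensitivity
of a plan's dose-volume quality to those perturbations — its *robustness*
— is rarely quantified. `rtrobust` implements a complete, reproducible
robustness-audit pipeline for this question, aimed at medical physicists
and method developers who need a tested reference implementation of
scenario-based robustness evaluation without any clinical data:

* **Synthetic cases.** Analytic phantoms and structure sets (CTV,
  margin-expanded PTV, a serial OAR abutting the target, a parallel OAR
  lateral to it, a distant OAR) plus geometric conformal arc plans,
  normalized to their prescription statements — a single-phase 60 Gy
  brain-like case and multi-phase 70 Gy head-and-neck-like cases with
  separate boost courses.
* **Scenario suite.** 49 uncertainty scenarios: random per-fraction setup
  errors (Gaussian, σ = 2.0 mm translational / 0.5° rotational), 18
  systematic translations (±2/3/5 mm in AP, SI, LR) and 24 systematic
  rotations (±0.5/1/2/3° in pitch, yaw, roll) each combined with the
  random model, and ±0.5/1/2 mm systematic MLC miscalibrations.
* **Dose recomputation.** A simplified analytic divergent-beam engine
  (MLC fluence with Gaussian penumbra, exponential depth attenuation,
  inverse square; C++ kernel) recomputes the dose for every fraction with
  that fraction's rigid 6-DOF transform applied to the beam frame, and
  accumulates over fractions and phases. The evaluated quantity is always
  the summed plan.
* **Endpoint reporting.** Nearest-rank dose-volume endpoints — D98% and
  D2% of the CTV, Dmean for parallel OARs, near-max D0.03cc for serial
  OARs and PRVs — as signed differences to the nominal scenario, with
  worst-case aggregation per scenario group (the signed difference of
  greatest absolute value).

All quantities are differences to the engine's own nominal scenario, so
engine-specific depth-dose features cancel in the comparison; the
methodology vignette (`vignettes/robustness-audit-methods.Rmd`) documents
the model, conventions and limitations.

## Worked example

A complete audit of the built-in brain-like case at desk-scale resolution
(5 mm grid, 24 control points, full 49-scenario suite with 30-fraction
accumulation; a few minutes on one core):

```r
library(rtrobust)

cs <- generateCase("brainlike", spacing = 5, nControlPoints = 24, seed = 1)
cs$phantom
#> Phantom 'brainlike': grid 35 x 41 x 39, 5 structures
#>   CTV                target_ctv      10.12 cc
#>   PTV                target_ptv      22.38 cc
#>   brainstem          oar_serial       3.25 cc
#>   hippocampus        oar_parallel     4.75 cc
#>   eye                oar_parallel     0.50 cc

evaluateEndpoint(cs$nominal, phantomStructure(cs$phantom, "PTV"),
                 endpoint("D_percent", 50))
#> [1] 60    # the case-A prescription: 60 Gy to 50% of the PTV

rep <- runAudit(cs, seed = 1)
subset(reportWorst(rep), group %in% c("random", "sys_trans_le3"))
#>    structure endpoint         group worstDiff        scenario
#>          CTV     D98%        random  -0.12927          random
#>          CTV      D2%        random  -0.10528          random
#>    brainstem  D0.03cc        random  -0.24428          random
#>  hippocampus    Dmean        random  -0.15517          random
#>          eye    Dmean        random  -0.00026          random
#>          CTV     D98% sys_trans_le3  -2.52703  trans_SI+3.0mm
#>          CTV      D2% sys_trans_le3  -0.52555  trans_LR+3.0mm
#>    brainstem  D0.03cc sys_trans_le3 -10.68360  trans_LR-3.0mm
#>  hippocampus    Dmean sys_trans_le3  -1.12710  trans_SI-3.0mm
#>          eye    Dmean sys_trans_le3  -0.00135  trans_SI-3.0mm
```

Reading the table: under purely random setup errors every endpoint moves
by less than ±0.25 Gy — the 5 mm PTV margin and fraction-wise averaging
absorb them. Under a systematic 3 mm shift combined with the random
errors, CTV coverage (D98%) drops by up to 2.5 Gy and the near-max dose
of the brainstem, which abuts the PTV and sits in the steepest dose
gradient, changes by more than 10 Gy — the worst case names the scenario
responsible (`trans_LR-3.0mm`, a 3 mm left-right shift). The distant eye
barely moves in any scenario. A +0.5 mm opening of all MLC leaves raises
the brainstem near-max dose by ≈ 1.4 Gy on this conformal plan
(`subset(reportWorst(rep), group == "mlc+0.5mm")`).

`runAudit(..., outDir = "audit_out")` additionally writes `report.csv`
(one row per structure, endpoint and scenario), `nominal.csv`,
`worst.csv`, `report.json` and the scenario `manifest.json`. A thin
command-line wrapper is installed at `inst/cli/audit.R`
(`Rscript audit.R run --case brainlike --out audit_out`).

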
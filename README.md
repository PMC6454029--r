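# castrr

Phantom-calibrated mapping of the brain-blood partition coefficient
(BBPC) from multi-TR gradient-echo MRI, and voxel-wise BBPC correction of
arterial-spin-labeling (ASL) cerebral blood flow maps.

## The problem

ASL perfusion quantification needs the brain-blood partition coefficient
λ — the equilibrium ratio of water per gram of tissue to water per mL of
blood. Nearly every study substitutes the global constant λ = 0.9 mL/g,
although white matter holds measurably less water than gray matter; the
constant therefore flattens real gray-white perfusion contrast. `castrr`
implements a fast workflow that measures λ voxel-by-voxel in small-animal
imaging at high field:

1. **Recovery fitting** — a spoiled gradient-echo stack acquired at six
   repetition times (125–2000 ms) is fit per voxel to the
   saturation-recovery law `S(TR) = M0·(1 − exp(−TR/T1))` by bounded,
   weighted Levenberg–Marquardt, giving relative proton density `M0`.
2. **Phantom calibration** — five vials of known water content (60–100%
   water, deuterium-diluted, gadolinium-doped to tissue-like T1) scanned
   beside the head anchor the signal scale: an OLS line of ROI-mean `M0`
   against water fraction converts `M0` to relative water content.
3. **BBPC map** — `λ = wc_brain / (wc_blood × 1.04 g/mL)`, with the blood
   reference taken from a blood sample in the field of view.
4. **CBF correction** — pCASL control/label pairs are quantified with the
   single-compartment equation
   `CBF = 60·λ·ΔM·e^(PLD/T1b) / (2·α·T1b·M0·(1 − e^(−LD/T1b)))`
   (α = 0.85, T1b = 2.2 s, LD = 1.6 s, PLD = 0), first with λ = 0.9 and
   then with the measured BBPC map resampled onto the pCASL grid.
5. **ROI report** — regional means and gray-white contrast improvement on
   the two centermost hippocampal slices.

Because no public dataset accompanies the protocol, the package includes
a digital mouse-head phantom (`make_default_phantom()`) with exactly
known proton density, T1, BBPC and CBF per region, plus simulators for
both acquisitions — every stage is testable against ground truth. See the
methods vignette (`vignettes/castrr-methods.Rmd`) for models, parameter
defaults and limitations.

## Worked example

```r
library(castrr)
res <- run_pipeline(default_config(seed = 0), "run0")
print(res$report, row.names = FALSE, digits = 4)
```

```
          region   bbpc cbf_uncorrected cbf_corrected slices
       neocortex 0.9908           2.811         3.094    2,3
     hippocampus 0.9548           2.897         3.074    2,3
 corpus_callosum 0.9305           1.436         1.485    2,3
```

The run simulates the six-TR series at SNR 50 and 120 noisy pCASL pairs
from a phantom whose regional ground truths are BBPC 0.99 / 0.95 / 0.93
mL/g and uncorrected CBF 2.81 / 2.90 / 1.44 mL/g/min. The recovered
`bbpc` column lands within ±0.01 of the truths; `cbf_uncorrected`
recovers the flow truths; and `cbf_corrected` shows what the BBPC
correction does to contrast — gray-matter flow is revised upward
(0.99/0.9 ≈ +10%) while the corpus callosum moves far less, widening the
gray-white difference. All volumetric inputs and outputs are NIfTI; the
run directory also contains the calibration report (JSON/TSV), the ROI
table and a manifest with output checksums (a rerun with the same seed is
bit-identical).

The same stages are available from the shell via the thin wrapper
`exec/castrr`:

```sh
castrr run-all --out run0 --seed 0
castrr simulate --config config.yaml --out run1
```

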
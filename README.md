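# sozloc

Automated sorting of resting-state fMRI independent components (ICs) and
localization of the seizure onset zone (SOZ).

## The problem

Pre-surgical screening of refractory epilepsy with rs-fMRI requires sorting
hundreds of ICA components per patient into **NOISE** (~51%), resting-state
networks (**RSN**, ~43%) and the rare **SOZ** components (~5–6%) whose
activation pattern marks the tissue where seizures start. Manual sorting is
slow and subjective; purely supervised classifiers fail on the extreme SOZ
class imbalance. `sozloc` implements a hybrid pipeline for researchers in
fMRI-based epilepsy screening:

* a **CNN noise screen** — binary classifier (NOISE vs non-noise) over the
  rendered IC montage `I_R` (270 × 470 × 3), defaults: three 3 × 3 conv
  layers with (64, 64, 256) filters + 2 × 2 max pooling, dense 704 + ReLU,
  dropout 0.33, sigmoid output, Adam at 1e-4, binary cross-entropy, early
  stopping;
* an **expert-knowledge model** over four features
  `F = (f_clusters, f_wm_ventricle, activelet_gini, sine_gini)` — DBSCAN
  cluster count/asymmetry, gray-matter → white-matter → ventricle extension
  of activation, and two Gini sparsity measures of the BOLD time course
  (wavelet-domain and sine-dictionary in 0.01–0.1 Hz). Weights `ω` solve

      minimize  Σᵢ (1 − yᵢ · ω ∘ F̂ᵢ)²   subject to  Σⱼ ωⱼ = 1,

  with `F̂ = F/‖F‖`, `y = −1` (RSN) / `+1` (SOZ), after SMOTE balancing of
  the SOZ minority in feature space. The confidence of an IC being SOZ is
  `ρ = ω ∘ F / ‖F‖`;
* a **fusion rule** — if the CNN says non-noise, the expert label (RSN/SOZ)
  stands; if the CNN says NOISE, the expert call SOZ overrides only when
  `ρ > 0.9` (strict);
* **localization** — for each IC finally labeled SOZ, the SOZ is its
  largest retained activation cluster, `argmaxⱼ |Cⱼ|`, over DBSCAN clusters
  larger than 135 px, with the top-contribution feature `ωⱼFⱼ` reported as
  the explanation.

Because the clinical data this models is restricted, the package includes a
seeded synthetic IC generator (montages + BOLD series following the class
rules above), a leave-one-patient-out evaluation harness, a cost-sensitive
3-class CNN baseline, and a knowledge-ablation runner.

## Worked example

```r
library(sozloc)

cfg <- synthetic_config(seed = 42, n_patients = 3, ics_per_patient = 12)
cohort <- generate_cohort(cfg)
cohort
#> <synthetic_cohort> 3 patients, 36 ICs (NOISE=18, RSN=15, SOZ=3)

cf  <- cohort_features(cohort)       # montage + time-course features, one pass
rep <- loocv(cf, seed = 42)          # leave-one-patient-out, CNN + EKI + fusion
rep
#> <evaluation_report> mode=fused features=++++
#> <soz_metrics> n=36 acc=100.0% prec=100.0% sens=100.0% F1=100.0% (TP=3 FP=0 FN=0 TN=33)
#>   per-patient SOZ sensitivity: 100.0%

pred <- rep$predictions
pred[pred$final == "SOZ", c("ic_id", "dl_label", "eki_label", "rho", "final", "explanation")]
#>        ic_id  dl_label eki_label       rho final    explanation
#> 2  P01_IC002     NOISE       SOZ 0.9963623   SOZ f_wm_ventricle
#> 15 P02_IC003 NOISE-bar       SOZ 0.8193640   SOZ     f_clusters
#> 30 P03_IC006 NOISE-bar       SOZ 1.1682870   SOZ f_wm_ventricle

soz_ids <- pred$ic_id[pred$final == "SOZ"]
cl <- cf$clusters[match(soz_ids, cf$ics$ic_id)]; names(cl) <- soz_ids
localize_soz(cl)[[1]]
#> <soz_localization> IC P01_IC002: largest cluster 509 px, tile 8, centroid (71.8, 71.1); 8 cluster(s)
```

Reading the output: all three true SOZ ICs are recovered with no false
positives, and both fusion paths are visible. Two ICs pass the CNN screen
as non-noise and retain the expert label SOZ — one of them
(`P02_IC003`, ρ = 0.82) would have been lost had the noise screen rejected
it, since its confidence is below the 0.9 override. The third
(`P01_IC002`) *is* called noise by the CNN (trained on only 24 montages
per fold) but carries ρ = 0.996 > 0.9, so the expert override rescues it.
The explanation column names the expert feature with the largest weighted
contribution to each call, and the localization reports the largest
activation cluster (509 px in slice tile 8) as the SOZ estimate. At the
evaluation scale used by the tests (10 patients × 100 ICs) the fused
pipeline reaches SOZ-class F1 ≈ 0.99.

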
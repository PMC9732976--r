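# taguchidetect

Taguchi orthogonal-array tuning studies for blood-cell detection, end to
end and at desk scale.

Detecting and counting red blood cells (RBC), white blood cells (WBC) and
platelets in stained smear images is a standard task for deep object
detectors, and detector accuracy hinges on a handful of training
hyperparameters. Trying every combination of four three-level
hyperparameters would cost 81 GPU trainings; the Taguchi method gets the
answer from nine. `taguchidetect` is for analysts who want to *run* and
*verify* such a study: it implements the design, the scoring, the
inference and the diagnostics as ordinary R functions, and replaces the
expensive trained detector with a calibrated surrogate so the whole study
executes in seconds on one CPU.

The package provides:

* **Design** — the L9(3^4) orthogonal array, a pairwise-balance checker,
  and the mapping from array rows to concrete hyperparameter assignments
  (`l9_array()`, `verify_orthogonality()`, `build_plan()`,
  `ssd_factor_space()`).
* **Taguchi analysis** — replicate summaries with the
  deviation-from-target signal-to-noise ratio
  `eta = -10 log10((ybar - m)^2)` dB at target `m = 1` (a perfect mAP),
  the factor response table `E_fl = mean{eta_i : run i has factor f at
  level l}` with best-level inference, and the saturated-design ANOVA
  `SS_f = r * sum_l (E_fl - mean(eta))^2` with percentage contributions
  (`snr_target()`, `summarize_replicates()`, `response_table()`,
  `best_combination()`, `taguchi_anova()`).
* **Detection scoring** — greedy IoU matching, monotone-envelope average
  precision, mAP, and per-class counting accuracy
  (`evaluate_detections()`, `average_precision()`, `count_cells()`).
* **Synthetic data** — a BCCD-like smear-scene generator (diameter ratio
  platelet : RBC : WBC = 0.2 : 1 : 2, ~11 RBC / 1 WBC / 1 platelet per
  640 x 480 image, RBC overlap and platelet-on-RBC placement) plus a
  surrogate detector driven by a logistic quality model
  (`generate_scene()`, `quality_model()`, `surrogate_detect()`).
* **Annotation I/O** — Pascal VOC XML reading/writing with explicit
  1-based-inclusive to 0-based-half-open conversion, and the seeded 80/20
  train/test split (`read_voc_xml()`, `voc_to_internal()`,
  `split_dataset()`).
* **Pipeline** — the orchestrated study and the embedded reference result
  tables of a GPU-trained ResNet50-SSD study, every derived cell of which
  the package recomputes from raw replicate scores (`run_study()`,
  `reproduce_reference_study()`, `ssd_study_tables()`,
  `compare_conditions()`).

## Worked example

A complete surrogate study — design, simulation, scoring, response table,
validation, ANOVA — under one master seed:

```r
library(taguchidetect)
report <- run_study(study_config(seed = 42))
print(report)
```

```
Surrogate Taguchi study report
  runs: 9, replicates: 3, analysis set: test, seed: 42
Response table (mean eta, dB)
        Optimizer MiniBatchSize InitialLearnRate LearnRateDropPeriod
L1         3.3390        7.0528           6.8385              7.1039
L2         4.2946        6.7106           8.3416              8.1016
L3        14.3395        8.2096           6.7929              6.7676
Effect    11.0005        1.4990           1.5487              1.3340
Maximum   14.3395        8.2096           8.3416              8.1016
Best level: Optimizer=3, MiniBatchSize=3, InitialLearnRate=2, LearnRateDropPeriod=2
Best value: Optimizer=adam, MiniBatchSize=18, InitialLearnRate=1e-04, LearnRateDropPeriod=40

Validation at the best combination:
  dataset n   mean     sd     eta
     test 3 0.8952 0.0089 19.5957
 training 3 0.8762 0.0228 18.1428
Additive-model predicted eta (test set): 17.0192 dB

Taguchi ANOVA of per-run SNR (dB)
                          SS df        V expected_SS    pct
Optimizer           222.8231  2 111.4115    222.8231  95.19
MiniBatchSize         3.7025  2   1.8512      3.7025   1.58
InitialLearnRate      4.6596  2   2.3298      4.6596   1.99
LearnRateDropPeriod   2.8880  2   1.4440      2.8880   1.23
Error                 0.0000  0       NA          NA   0.00
Total               234.0731  8       NA          NA 100.00
```

Reading this: each of the nine design runs was replicated three times;
each replicate drew per-class detector quality from the (factor-dominant)
default quality model, simulated fresh training and test scene sets, ran
the surrogate detector and scored mAP. The response table averages each
run's test-set SNR by factor level: the optimizer's best level is 3
(`adam`), the mini-batch's 3 (18), and so on — here the study recovers the
quality model's designed optimum (3, 3, 2, 2). Validation re-runs that
combination (test-set mean mAP 0.8952, SNR 19.60 dB, above every design
run, and above the 17.02 dB the additive model predicts). The ANOVA
attributes 95.2% of the SNR variability to the optimizer, mirroring the
dominance built into the quality model.

The embedded reference tables reproduce from their raw replicate mAPs:

```r
reproduce_reference_study()
#> Reference-table reproduction: PASS (116/116 cells)
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/taguchidetect` (subcommands `design`, `simulate`,
`evaluate`, `study`, `reproduce-tables`, `compare`).

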
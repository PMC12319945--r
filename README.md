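# bundleseg

Computer-assisted detection and characterization of **fiber bundles** in
dark-field photomicrographs from anatomic tracer experiments.

Anatomic tracing labels axons projecting from a tracer injection site;
on histological sections the labeled fibers appear as bright curvilinear
texture on a dark background, and anatomists outline *fiber bundles* —
regions where labeled axons travel closely together. Manual charting is
the bottleneck: sections are annotated every 1.2 mm at best, and most
material stays uncharted. `bundleseg` is for neuroanatomists and
neuroimaging researchers who want to accelerate that charting and to
quantify fiber density along white-matter pathways, and for methods
researchers who need a tested, self-contained reference implementation of
the underlying semi-supervised segmentation machinery.

## Method

The detector is a dual-head network: a 2D U-Net segmentation backbone
(FSeg) and a patch-classification arm (FClass) attached to the encoder
bottleneck, sharing encoder weights. Training minimizes

* a **focal loss** on the per-pixel segmentation,
  FL(p_t) = −α_t (1 − p_t)^γ log p_t with α = 0.25, γ = 2, which handles
  the heavy fiber/background class imbalance, and
* an **NT-Xent contrastive loss** (temperature τ = 0.5) on FClass over
  anatomy-constrained positive pairs: the partner patch is cropped < 20 µm
  from the anchor, accepted by a white-matter plausibility criterion, then
  perturbed with noise and Gaussian blur (σ ∈ [0.05, 0.3]).

After `Np` supervised pretraining epochs, **temporal ensembling** brings
in unlabeled sections: each sample's pseudo-label is the average of its
predictions over the last r = 3 epochs, thresholded at 0.5, with the
pretrained model's prediction used during the first r epochs.

Whole sections are segmented by tiled inference (1024×1024 tiles) and
thresholded at 0.4. False positives are removed with a **cross-section
continuity prior** — a region is deleted if it lies > 0.5 mm from the
averaged bundle segmentation of the two nearest neighboring sections of a
coarsely aligned stack — plus morphological filters (area < 2 mm², border
distance < 0.5 mm). **Fiber density** (FD) inside each bundle is the
fraction of pixels above the 95th percentile of CLAHE-enhanced intensity,
and densities are compared across white-matter pathways (internal
capsule, corpus callosum, uncinate fasciculus) with a one-way ANOVA.
Detection is scored at region level: TPR, false positives per section
(FPavg), ΔFD between manual and predicted bundles, and FROC curves.

Because the original histological data are not publicly deposited, the
package includes a seeded **synthetic dark-field generator** producing
section stacks with bundle ground truth, white-matter and pathway masks,
and the confounders that matter (terminal-field speckle, glare, bright
borders); every stage of the pipeline is tested against it. See the
methods vignette (`vignettes/fiber-bundle-detection.Rmd`) for the full
account of the model, parameter choices and limitations.

## Worked example

```r
library(bundleseg)

# a complete scaled-down study: simulate -> pretrain -> temporal
# ensembling -> tiled inference -> continuity/morphology filtering ->
# detection + fiber-density evaluation
bench <- synthetic_benchmark(seed = 1)

round(c(tpr_raw = bench$tpr_raw,     fpavg_raw = bench$fpavg_raw,
        tpr_post = bench$tpr_post,   fpavg_post = bench$fpavg_post,
        delta_fd_pct = bench$delta_fd_pct), 3)
#>      tpr_raw    fpavg_raw     tpr_post   fpavg_post delta_fd_pct
#>        1.000       86.733        1.000        0.000       -0.045

aggregate(fd ~ pathway, bench$fd, function(v) round(100 * mean(v), 2))
#>   pathway    fd
#> 1      CC 10.34
#> 2      IC 13.37
#> 3      UF 10.53
bench$anova$F
#> [1] 69.29281
```

Reading this output: before postprocessing the raw probability maps
contain ~87 small false-positive components per held-out section; the
continuity and morphology filters remove all of them here without losing
a single true bundle (TPR stays 1.0). ΔFD (manual − predicted fiber
density, in percent) is a small negative number — predicted regions fit
the fibers slightly more tightly than the loose ground-truth outlines —
and the pathway comparison reproduces the expected ordering: bundles run
densest through the internal capsule (13.4%) compared with the corpus
callosum (10.3%) and uncinate fasciculus (10.5%), with a strongly
significant one-way ANOVA.

A YAML-driven end-to-end run (with outputs written to disk) is available
as `run_pipeline(system.file("extdata", "demo_config.yaml", package =
"bundleseg"))`, and a thin command-line wrapper with per-stage
subcommands (`simulate`, `run`, `infer`, `postprocess`, `density`) ships
in `inst/cli/bundleseg.R`.

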
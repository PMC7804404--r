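---
title: "chromshift: models, generator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromshift: models, generator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its statistics: the models and
their assumptions, the synthetic-data generator that makes them testable,
the defaults that matter, and the places where the design was genuinely
open and a choice had to be made.

## The setting

Immune-cell activation remodels chromatin at several scales at once:
point-to-point interactions (loops), topologically associating domains
(TADs) and their boundaries, megabase-scale A/B compartments, local
chromatin accessibility and transcription. With a replicated design — two
donors, resting and activated cells, profiled by Hi-C, ATAC-seq and
RNA-seq — each level can be tested for change *relative to the biological
variation between donors*, and the levels can be tested against each
other: do gained interactions connect opening chromatin to up-regulated
genes?

chromshift implements that analysis end to end and, because the real
sequencing data needed to reproduce published figures runs to hundreds of
millions of read pairs, ships a generator that plants all of those
structures at desk scale with exported ground truth.

## Count models

### The shared quasi-likelihood engine

All count-level tests (bin pairs, boundary ratios, ATAC peaks) share one
engine:

1. **NB GLM.** Counts $y_{gj}$ for feature $g$, sample $j$ follow
   $y_{gj} \sim \mathrm{NB}(\mu_{gj}, \phi_g)$ with
   $\log \mu_{gj} = \mathbf{x}_j^\top\boldsymbol\beta_g + o_{gj}$.
   Offsets $o_{gj}$ default to log effective library sizes and are
   replaced by LOESS normalization offsets for Hi-C. Fitting is Fisher
   scoring, vectorised across features (the weighted cross-products are
   computed for all features at once; only a small per-feature solve
   remains), to a relative deviance tolerance of 1e-8 or 50 iterations.
   Non-convergent features are flagged, never fatal.

2. **Dispersion trend.** Per-feature dispersions solve the Pearson moment
   equation $\sum_j (y_{gj}-\mu_{gj})^2/(\mu_{gj}(1+\phi\mu_{gj})) =
   \mathrm{df}_{\mathrm{res}}$ (monotone in $\phi$; solved by bisection on
   a log grid, means refreshed once at the estimate). The trend is binned
   medians against average log2-CPM (15 quantile bins), `lowess`-smoothed
   on the log scale (span 0.5) and linearly interpolated with constant
   extrapolation. This is deliberately simpler than adjusted
   profile-likelihood maximisation; it is an approximation chosen for
   transparency and testability, and its accuracy is itself under test
   (recovery of a known dispersion within ±30%).

3. **QL F-test.** The QL dispersion $s^2_g = \mathrm{deviance}_g/
   \mathrm{df}_{\mathrm{res}}$ is squeezed toward a second
   abundance trend by empirical Bayes: on $z_g = \log(s^2_g /
   \mathrm{trend}(A_g))$, the prior df solves
   $\mathrm{trigamma}(d_0/2) = \widehat{\mathrm{Var}}(z) -
   \mathrm{trigamma}(d_1/2)$ and the prior scale comes from the mean of
   $z$ with the exact chi-square bias correction
   $\psi(d_1/2)-\log(d_1/2)$. The spread moment is winsorized at the
   2.5% tails (median/MAD standardisation, with the analytic variance
   deflation of winsorizing a normal) so outlying features do not inflate
   the prior variance; the location moment is the plain mean, because a
   winsorized location on the left-skewed log-chi-square distribution is
   biased and made the test measurably conservative at one residual df.
   For the same reason the QL trend uses binned *means* of $s^2$ (unbiased
   under chi-square sampling), not medians. The F statistic is the
   deviance drop over the posterior dispersion, on
   $(1, d_1+d_0)$ df; BH adjustment gives FDR.

   `prior.df = 0` bypasses the squeeze entirely and reproduces the
   unmoderated deviance F-test — a limiting identity the tests verify
   against an explicit two-fit oracle.

### voom-style moderated t

Expression and eRNA use log2-CPM (prior count 0.5) with precision
weights: the square-root residual SD of an unweighted fit is smoothed
against average log2 count (`lowess`, span 0.5), each observation gets
weight $\widehat{sd}^{-4}$ at its fitted log-count, and the weighted LS
residual variances are squeezed by the same empirical-Bayes machinery
before forming moderated t statistics. At `prior.df = 0` the statistic is
ordinary weighted least squares, checked against direct linear algebra to
1e-8.

### TMM and filters

TMM normalization follows the canonical recipe: reference column = the
one whose upper-quartile CPM is closest to the mean upper quartile; trim
30% of M-values and 5% of A-values two-sided; precision-weighted mean of
retained M-values (delta-method weights); factors rescaled to geometric
mean 1. Expression filters are strict CPM thresholds (`> 1.5` in ≥2
samples for genes, `> 0.5` for eRNA with *fixed* library sizes equal to
total genome-aligned reads, so read gains inside one region cannot change
another's CPM).

## The Hi-C pipeline

**Counting and background.** Read pairs are binned by integer arithmetic
on the uniform grid (terminal bins truncated); inter-chromosomal pairs
never enter the table — they are pooled to estimate the background
ligation frequency as the average abundance of an inter-chromosomal 2 Mbp
bin pair, rescaled to the analysis bin width so it is directly comparable
with bin-pair abundances. All pooled abundances in the package go through
one helper so filters and background share a scale.

**Filtering** applies, in a fixed order: per-bin marginal-count filter
(pooled marginal count < 5 drops the bin and every pair touching it),
chromosome blocklist (e.g. sex chromosomes), blacklist overlap (any
overlap of an anchor bin), the first diagonal (|Δbin| ≤ 1, covering self
and adjacent pairs), and the strict sixfold-over-background abundance
rule. The diagonal width and the bin-count reading (per *bin*, not per
bin pair — the sentence is ambiguous and the bin-level reading is
implemented, configurable) are exposed as parameters.

**LOESS offsets.** Per distance stratum (gap below vs above 150 kbp —
short-range contacts have their own bias regime), each sample's M-value
against the across-sample mean profile is smoothed by `lowess` (span 0.3,
3 robustifying iterations) against abundance and converted to row-centred
natural-log offsets. The trend is fitted on the abundance *bulk* only
(1st–95th percentile) and extended as a constant beyond it: the extreme
tail is a handful of bin pairs — often the strongest loops, exactly the
features under test — and letting the local regression chase them
absorbs, or even sign-flips, their differential signal. Strata with fewer
than 50 pairs fall back to median offsets with a warning.

**Clustering and cluster FDR.** Significant bin pairs are connected when
their anchor boxes touch (±1 bin on both axes); oversized components are
split by tiling the interaction space from the component corner so no
bounding box exceeds the cap (500 kbp / 1 Mbp conventions). The member
threshold is the largest window-level FDR $t$ whose estimated
cluster-level FDR, $t \cdot n_{\mathrm{sig}} / n_{\mathrm{clusters}}$
(worst case: every false member its own cluster), stays at or below the
5% target; Simes' rule combines member p-values and BH across clusters
gives the reported cluster FDR.

## TADs, boundaries, compartments

**Insulation and calling.** The insulation score at boundary position $b$
is $\log_2$ of the observed total in the window×window square crossing
$b$ over its per-distance expectation (window default 10 bins); a zero
square is $-\infty$ — maximal insulation, not missing. Ends with
incomplete windows are `NA`. Boundaries are local minima with prominence
≥ 0.5 (log2 units); this prominence knob is the stand-in for an external
caller's confidence score, and the whole caller is this package's own
replacement for model-based breakpoint detection: what downstream
analyses need is the segmentation, not any particular caller's internals.
Replicate matrices are summed per condition before calling; the
per-sample counts are reserved for the boundary test.

**Boundary strength.** The tested quantity is the change in
$\log_2(\mathrm{down}/\mathrm{up})$ counts anchored at the 50 kbp
boundary region (one anchor inside, the partner within 1 Mbp up- or
downstream; both-inside pairs count for neither). The model has
per-sample intercepts (absorbing depth and regional coverage — the test
is exactly invariant to doubling all counts), a direction effect, and the
condition × direction interaction as the contrast. Because `callTads`
reports a boundary as the *first bin of the downstream TAD*, upstream
counts are the cross-boundary ones and a positive interaction means the
boundary strengthened. Regions below average log2-CPM 0.8 are removed
before testing. The boundary universe is the union of called boundary
bins from both conditions (the union-vs-intersection choice is not
externally fixed; union tests every candidate).

**Compartments.** Per chromosome, the O/E matrix (observed over
per-distance mean; 0/0 missing; self-entries excluded; bins with <10
informative entries masked) yields a Pearson correlation matrix whose
leading eigenvector is the compartment score. Entries closer than 2 Mbp
are excluded from the correlation: domain-scale structure lives below a
few megabases and otherwise contaminates the eigenvector with TAD
segmentation rather than the checkerboard. The sign is oriented by an
external open-chromatin covariate (per-bin accessibility coverage by
default; gene density works too — the orientation convention cannot be
derived from Hi-C alone). Scores are not comparable across chromosomes. A
flip requires both a label change and a negative cross-condition O/E
profile correlation (the conjunction; the label-only rule is a flag).

## Integration

Promoters are strand-aware −1 kb/+100 bp windows around the TSS, clipped
at chromosome ends. The gene-regulatory network attaches DA peaks
overlapping one anchor and promoters of expressed genes overlapping the
other, in both orientations, for every *tested* bin pair with distinct
anchors; the interaction class (gained / lost / unchanged at FDR 5%) is a
pure function of the DI row. Contingency tests count one unit per
interaction–gene link (per-gene collapsing available by flag: a
gene-level label permutation control is evaluated with gene-level
counting, the coherent pairing). The accessibility-by-class comparison
defaults to link-level observations, with a per-peak collapse (each peak
classified by its most significant interaction) available.

## The synthetic generator

The generator is the package's study design. Expected intra-chromosomal
intensity factorises as
$(d+1)^{-\alpha} \times \mathrm{tad} \times \mathrm{compartment}
\times \mathrm{loop}$, with NB noise, uniform read placement within bins,
and inter-chromosomal pairs at a constant expected rate per bin pair.
Defaults, chosen once as a realistic desk-scale study:

| parameter | default | rationale |
|---|---|---|
| genome | chr1 40 Mb + chr2 30 Mb, 50 kbp grid | two chromosomes so background ligation is estimable; ~1400 bins |
| decay exponent α | 1.0 | canonical contact-decay slope |
| TAD sizes | 0.8–2 Mb (mean ≈ 1.4 Mb) | resting T-cell domain scale |
| TAD enrichment | ×3 | recoverable at desk depth |
| boundary attenuation | strongest crossed boundary, strengths 2–3 | bounded attenuation; a product over boundaries would extinguish long-range counts |
| domain range | 3 Mb | insulation is local; beyond it only compartments act, so long-range O/E stays compartmental |
| compartments | alternating 1–3 Mb blocks, same-label ×1.5 | megabase-scale checkerboard |
| flips | 1.5% of bins | rare, as in activation |
| loops | 200; baseline ×2 both conditions; gained ×4 on activation, lost ×0.25; spans 0.2–0.8 Mb (gained) / 0.8–1.4 Mb (lost) | ratios carry the differential signal; the baseline keeps loop pairs above the sixfold filter; the span split plants the short-gained/long-lost contrast |
| splits | 50% of TADs, new boundary near the middle, sub-TAD boost solved for contact-mass conservation | partitioning concentrates contacts into the smaller domains; conservation stops every untouched pair from shifting compositionally under fixed depth |
| Hi-C design | 2 donors × resting/activated, 3×10⁶ intra pairs/sample (5×10⁶ for the null scenario) | the replicated 2v2 layout |
| omics | 5000 genes / 5000 peaks, 15% DE / 10% DA at &#124;log2FC&#124; = 2, NB dispersion 0.05, donor intercept SD 0.3 (log2) | desk-scale feature counts with a visible batch effect |

Couplings are wired explicitly and recorded in truth tables: each gained
loop carries a DA-up peak in one anchor and a cluster of three up-regulated
genes' promoters in the other (lost loops mirror this downward); flipped
compartment bins carry matching DA/DE effects; nucleosome occupancy is
elevated at boundaries whose insulation strengthens (including new split
boundaries); eRNA effects follow the DA effect of their peak (×0.8). The
random DA quota is placed 60% along a contact-change trend (up near
weakened boundaries, down near strengthened ones) and 40% balanced in
*neutral zones* untouched by any planted change, mirroring the genome-wide
co-location of accessibility and 3D remodelling while leaving a clean
"unchanged" population. Planted split boundaries are kept clear of
chromosome ends, where the insulation window is incomplete and no caller
can, by construction, score a boundary.

**What the generator does not emulate.** Restriction fragments and
sequence (no FASTQ, no enzyme-site bin rounding — bins are uniform, which
changes no downstream statistic's definition), mappability and GC biases,
nested/hierarchical domains, CTCF motif orientation, distance-dependent
batch effects (the donor effect in Hi-C is depth-scale only; in counts it
is a per-feature random intercept), and the sheer depth of real libraries.
Passing tests therefore demonstrate the statistical machinery's
correctness and calibration on data whose generative assumptions match
the models; they do not certify robustness to every artefact of real
Hi-C.

## Problem sizes and determinism

The test-suite scenarios use a 14 Mb two-chromosome genome at 6×10⁵
pairs/sample for unit tests, and the default 70 Mb genome (3–5 ×10⁶
pairs/sample) for the end-to-end acceptance checks; the acceptance script
runs one null scenario, three loops-only scenarios and one activation
scenario in a few minutes on a single core. Every source of randomness is
seeded: scenarios consume their seed at build time, and per-sample data
seeds derive deterministically from it, so identical seeds give
byte-identical read-pair tables and fixture trees.

## Known limitations

* The dispersion trend is a moment/median approximation, slightly
  downward-biased at very few residual df; the EB squeeze absorbs the
  scale, but individual dispersion estimates should not be interpreted.
* Cluster-level FDR control uses the worst-case false-cluster estimate;
  it is conservative when false members chain onto true clusters.
* Compartment calls need an external orientation covariate and enough
  long-range coverage; on sparse matrices the eigenvector dominance flag
  should be checked.
* When a large fraction of the genome is genuinely remodelled, any
  abundance-stratified normalization (including these LOESS offsets)
  loses its null anchor; the generator's contact-mass conservation keeps
  the synthetic scenarios inside the regime where the assumption holds,
  and real analyses at that level of remodelling would need external
  calibration.
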
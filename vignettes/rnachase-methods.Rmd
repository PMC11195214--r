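---
title: "rnachase: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rnachase: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the model
behind each analysis stage, the tunable parameters with their defaults
and why, what the simulator does and does not emulate, the numerical
choices, and the limitations a user should know before trusting a green
test. It states no empirical result that the test suite does not itself
compute.

## 1. The experiment being modeled

A short metabolic label (order 30 minutes) marks a cohort of nascent
RNA; sequencing the captured RNA immediately (0h) and after chases (2h,
6h) yields age-resolved transcriptomes. All analyses compare the same
cohort across its own lifetime, so class fractions, splicing indices and
count fold changes read out kinetics rather than steady-state levels.

The package's internal coordinates are 0-based half-open on both
strands; GTF (1-based closed) and SAM (1-based) are converted at the I/O
boundary. BED is already 0-based half-open.

## 2. Generative model (`sim_params`, `simulate_population`, `sample_fragments`)

The label window is collapsed to an instantaneous cohort born at t = 0:
the analyses operate on fragment counts, not polymerase positions, so
elongation during the label is out of scope.

**Splice state at birth.** Each molecule draws its state once at
synthesis. With probability `p_allnone` (default 0.8) it follows the
all-or-none mode: fully spliced with probability `q_spliced` (default
0.5), else fully unspliced. Otherwise each intron *i* is spliced
independently with probability `s_i` (default Beta(2, 2), mean 0.5).
The defaults encode the two dominant observations the analysis is meant
to recover: a transcriptome whose 0h median splicing index is near 0.5,
and pattern bins dominated by "all spliced" and "all unspliced" with
small intermediates.

**Survival.** Fully spliced molecules decay at a biphasic mature rate:
`k_early` over 0–2h and `k_late` afterwards, both drawn uniform on
(0, ln 2) per hour by default (half-lives of 1 hour and up; drawing the
two phases independently makes biphasic behavior the rule, not the
exception). Any not-fully-spliced molecule decays at `k_unspliced`
(default 1.0/h, a 40-minute half-life — unspliced transcripts are
purged much faster than mature ones) and converts to the fully spliced
pool at rate `r_post` (default 0.3/h, post-transcriptional splicing).
Conversion splices all remaining introns at once; partial
post-transcriptional maturation is not modeled. The two-compartment
closed form (`expected_abundance("converted", ...)`) is verified in the
tests against an RK4 integrator. Excised introns are separate molecules
born per co-transcriptionally spliced intron, decaying at `k_intron`
(default 1.4/h, a 30-minute half-life); introns released by later
conversion are not added — a deliberate simplification that slightly
undercounts late intronic signal.

**Non-genic classes.** PROMPT windows (4 kb antisense upstream of each
TSS; the biological bound is "short, under 4 kb"), readthrough windows
(10 kb sense past the gene end, clipped at the next same-strand gene)
and user/enhancer intervals are simulated as unspliced single-interval
molecules with class-level rates (defaults: PROMPT = eRNA = 1.4/h,
readthrough = 0.8/h — ordered as observed: promoter-upstream and
enhancer RNA are exosome substrates, readthrough somewhat more stable).

**Fragments.** Counts are Poisson around the closed-form expectations.
Fragment length is truncated Normal(450, 25) within
[2 × read length, molecule length] — sequenced fragments were 400–500 bp
with 150 nt paired ends — and starts are uniform along the molecule.
Molecules attract fragments proportional to `count × (length − 450 + 1)`
so per-base coverage is uniform across molecule classes; this is what
makes E[SI] equal the splicing probability (section 4). Two depth modes:
`"fixed"` (exactly `depth` fragments per sample — a standard library)
and `"anchored"` (constant capture per molecule, so the library shrinks
with the surviving cohort — a spike-in-calibrated library). Fragments
allotted to molecules shorter than 300 nt are skipped and tallied, so
`emitted + skipped = depth` in fixed mode.

**What the simulator does not emulate:** sequence content and errors,
mapping ambiguity (every fragment is born aligned, MAPQ 255), elongation
gradients, partial post-transcriptional splicing, biological replicate
variance beyond Poisson (replicates are independent draws from identical
parameters, and so are cell lines). A green recovery test therefore
establishes correctness of the estimators under count noise, not
robustness to alignment artifacts.

## 3. Read accounting

Classification (`classify_fragments`) uses the any-exon-overlap rule: a
unique fragment (MAPQ ≥ 255 by default; configurable for non-STAR
conventions) overlapping ≥2 genes on its own strand is *ambiguous*;
within a single gene it is *exon* if any block touches union-exon space,
else *intron*; the same rule applies antisense; otherwise *intergenic*.
Fractional counting (`fractional_counts`) is deliberately different: it
splits each fragment's mass per aligned base, strand-specifically, so a
partition of the genome conserves fragment count exactly (tested to
1e-6). Repeat counting follows the 1/n multimapper rule on a separate
alignment-hit table, since multimappers cannot be in the MAPQ-255
universe.

The relative stability of class *c* versus exons is
`(f_c(t)/f_c(0)) / (f_e(t)/f_e(0))`. The quantity is a ratio of class
fractions, not of absolute counts — it is therefore depth-free; the
double ratio (normalizing to exons) additionally removes the common
survival trend. This formula is an adopted convention (the field
reports the fold value without writing the estimator down); in a world
where a class decays at
`k_c` and mature RNA at `k_e` it equals `exp(−(k_c − k_e)t)` up to
composition effects, which the tests verify on pure-class worlds.

## 4. Splicing index and pattern bins

For intron *i*: `a` counts fragments with a within-mate split exactly
matching the intron with ≥ `min_overlap` (default 10) aligned bases on
both flanks; `b` and `c` count contiguous crossings of the intron's two
boundaries with the same flank rule; `SI = a/(a + (b+c)/2)`. The halved
(b+c) compensates for an unspliced intron presenting two crossable
boundaries versus one junction. A fragment contiguously covering an
entire short intron evidences both boundaries and counts once toward
`b` and once toward `c`. `b`/`c` are tallied at genomic start/end; SI
and the pattern bins are symmetric in them, so no strand relabeling is
needed. An SI is reported only when `jrsum = a+b+c ≥ min_jrsum`
(default 5) — the definition has no inherent threshold; this guards
against 0/0 and unstable small-count ratios. Only multi-intron genes
with a single annotated isoform are eligible, which keeps junction
evidence unambiguous.

**Edge geometry (a real property, not a bug).** E[SI] equals the
splicing probability only for junctions at least one fragment length
from the molecule ends. A terminal junction can be reached by only one
of the two mates, halving split-read positions, while the intron's far
boundary remains fully reachable — so SI is depressed at first/last
introns of short-exon transcripts (by ~0.05 at 150–400 bp exon
geometry). The independent-mode recovery test states its world with
600–1000 bp exons so all junctions are interior; users comparing SI
across intron positions in real data should expect the same terminal
depression.

Exon-spanning patterns require a fragment to report *both* flanking
junctions of an internal exon, each as split (S) or contiguous crossing
(U); conflicting evidence makes the fragment uninformative. This
requires the fragment span (~520 nt max at default geometry) to exceed
the exon plus flanks, so pattern analysis is informative for exons up to
roughly 400 nt — which is why the pattern worlds use standard short
exons while the SI world uses long ones.

## 5. Stability estimation

`size_factors` is DESeq2's median-of-ratios. `stability_log2fc` then
computes, per gene passing the expression filter (RPKM > 0.5 at the
earlier timepoint — the protocol's filter, with union-exon length and
raw library size), `log2((mean_later + 0.5)/(mean_earlier + 0.5))` on
normalized counts, a Wald p-value from
`Var(log mean) ≈ (1/μ + α)/n` per group with method-of-moments
dispersion `α` floored at 0.01 (with two replicates the moment estimate
is noisy; the floor dominates for well-behaved genes), and BH
correction. Volcano-style thresholds from the protocol
(−log10 padj > 2, |log2FC| > 1.5) are left to the user; the full table
is exported.

**Relative versus absolute.** Median-of-ratios equalizes the median
gene between samples. In a chase experiment *every* labeled transcript
decays, so the median reference is itself decaying and the resulting
log2FC is relative — which is exactly what a DESeq2-based chase analysis
reports, and why the quantity is called *relative* stability. Absolute
decay rates are recoverable only from abundance-anchored libraries
(spike-in calibration; the simulator's `depth_mode = "anchored"`), in
which case `normalization = "none"` preserves the scale. The decay-rate
recovery acceptance test uses that route; with the default
normalization the recovered values would be shifted by the median
gene's decay — a property of the method, not an implementation error.

`rescale_unit` is `(x − min)/(max − min)` per cell line (affine
invariant; errors on constant input). Trajectories are restricted to
genes passing the filter in all cell lines, and the across-line mean is
emitted as the "averaged" point. Cell-line similarity is Pearson r on
shared genes with average-linkage clustering of `1 − r`.

## 6. Isoform dynamics

Compatibility is splice-structure consistency per mate (blocks inside
the isoform's exons; within-mate gaps exactly matching its introns);
the insert between mates is unconstrained. Equivalence-class EM
maximizes `Σ_c n_c log Σ_{t∈c} θ_t/ℓ_t` with effective length
`ℓ = exonic length − mean fragment length + 1` (floored at 1), uniform
initialization, tolerance 1e-8 on `max|Δθ|`, 1000 iterations with a
warning flag on non-convergence. The likelihood is monotone under the
update (tested).

**Known bias.** This likelihood carries no per-class position counts.
When isoforms differ in length and unique-region share (e.g. a
skipped-exon pair), the isoform with the larger unique share is
overestimated — by up to ~0.1 at a 300 nt length difference in our
measurements. The EM recovery benchmark therefore states its world with
mutually exclusive equal-length exons, where the approximation is exact
by symmetry; dominance calls are robust to the bias because they
compare the same gene's percentages across timepoints. TPM converts
`θ` to a molar rate (`count × θ / Σ θℓ`) normalized to 1e6 across genes.

Genes enter the isoform analysis with ≥ 2 annotated isoforms and
≥ 1 TPM at 0h; an isoform with ≥ 50% at a timepoint is dominant. AD
requires dominance at all three timepoints; GD/LD are anchored at the
0h and 6h endpoints (the 2h value deliberately does not affect them —
the wording "during the time course" is ambiguous and the endpoint rule
is the reproducible choice). A gene can be GD and LD simultaneously
through different isoforms, so the AD/GD/LD summary fractions count
flags and need not sum to 1.

## 7. Pipeline and determinism

`run_all` executes simulate (or load) → account → splicing → stability →
isoforms, writing TSVs, a JSON manifest of every parameter used, and a
markdown summary; a stage failure aborts with the stage name, keeping
earlier outputs. All randomness derives from the run seed through
`derive_seed(seed, tag)` (tag = stage/sample), so outputs are
byte-identical across reruns — TSVs are written with fixed separators
and rounding, and the sample sheet stores relative paths. Replicates
are merged before junction counting and before isoform quantification,
matching the source protocol; stability uses replicates unmerged.

## 8. Degenerate inputs and numerical choices

Empty samples raise explicit errors (class profiles), as do constant
vectors (rescaling), all-zero reference genes (size factors, with a
pointer to a pseudo-reference fallback), and negative rates
(kinetics). The conversion closed form uses an `expm1`-safe integral
with a series limit for |λ| < 1e-12, so equal-rate degeneracies are
exact. SI is NA (not 0) below the evidence floor. EM returns its last
iterate with `converged = FALSE` rather than failing.

## 9. Limitations

Beyond the simulator scope above: the readthrough window is a
fixed-length proxy for proper readthrough-segment classification; PROMPT
length is a single configurable window, not a per-gene estimate;
the NB test has no shrinkage or independent filtering, so its p-values
are more conservative than DESeq2's at low counts; pattern bins are
blind to exons longer than the fragment span; and the EM ignores
position weights (section 6). All are deliberate, documented trade-offs
within the package's scope.
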
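---
title: "Methods and modeling choices in piscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling choices in piscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piscreen)
```

`piscreen` turns a multi-compound PI-polyamide expression screen into a
reproducible pipeline. This vignette documents the science behind each
stage, the defaults and why they were chosen, the numerical conventions,
and what the synthetic-data tests do and do not demonstrate.

## From backbone to recognition motif

A hairpin polyamide is two arms of Py/Im/β monomers joined by a γ
(gamma-aminobutyric) turn, optionally capped (Ac-NH) and tailed (e.g. an
indole-*seco*-CBI alkylating warhead). Stacked ring pairs read base pairs
in the minor groove: Im paired against Py or β reads G; Py or β paired
against Im reads C; pairs containing only Py/β read A or T (IUPAC `W`).

The literature rarely prints the full pairing geometry alongside a
backbone, so the package fixes one convention and applies it uniformly:

* turn-proximal rings pair first — arm2 position $k$ stacks on arm1
  position $n_1 + 1 - k$;
* the motif is written 5′→3′ on the strand read by the C-terminal arm
  (N→C along arm2 runs 5′→3′ on that strand);
* the γ turn contributes one 5′-terminal `W`; unpaired arm1 overhang
  rings each read `W`;
* an indole-*seco*-CBI tail makes the motif end in `WWA`: the indole
  linker spans two `W` positions — these coincide with arm1-overhang
  positions when an overhang is present — and the terminal adenine is the
  alkylation site (`alkylation_index`, 0-based).

This is the unique convention in its family that maps the published
CCC-003 backbone `Ac-NH-PyPyPyPyβPyPyPy-γ-ImImβImImPy-COOH` (+ seco-CBI)
to its published motif `WGGWGGWWWA`:

```{r}
derive_motif(parse_backbone("Ac-NH-PyPyPyPybPyPyPy-g-ImImbImImPy-COOH",
                            tail = "IndoleSecoCBI"))
```

Two caveats are worth stating. First, whether a β/Im pair should read C
in *all* hairpins cannot be settled from a single worked exemplar; the
rule table assigns it C, which the exemplar constrains under this
orientation, and the choice is localized in one table should evidence
change. Second, compounds whose backbones are not modeled (KR12,
CCC-002) enter the registry as direct IUPAC motifs — deriving them is
not required for any downstream step.

### Mass utilities

`monoisotopic_mass()` uses hard-coded most-abundant-isotope masses
(IUPAC 2021) and returns full precision; display rounding is half-up to
match 2-decimal LC-MS reporting. For the CCC-003 formula
C₁₀₂H₁₀₅ClN₃₄O₁₈ the *neutral* monoisotopic mass is 2128.80 Da while
[M+H]⁺ is 2129.81: published characterizations sometimes label the
neutral value as [M+H]⁺, so the package computes both and leaves the
interpretation to the analyst.

## Duplex motif scanning

A minor-groove binder sees the duplex, not a strand, so a physical site
is counted once: `scan_duplex()` reports forward-strand matches of the
motif (orientation `+`) and forward-strand matches of its reverse
complement (orientation `−`), deduplicating positions that match both
(palindromic concrete matches, reported `+`). Conventions chosen for
deterministic counts: coordinates are 0-based half-open (BED native);
an `N` in the sequence never matches any motif symbol; soft-masked
(lowercase) sequence matches by default, with `respect_softmask = TRUE`
to exclude it. "Intragenic" means overlap of the whole gene-body
interval by at least one base, irrespective of gene strand; CDS-only
filtering is a matter of supplying CDS intervals as the annotation.

Genome-wide counts on a user-supplied assembly depend on assembly
version and counting convention; the package therefore asserts its scan
only against brute-force oracles and planted-truth genomes, never
against a published genome-wide figure.

## The expression screen

The screen compares each compound condition with the vehicle control on
a normalized log2 expression matrix (as deposited processed microarray
matrices are). The per-gene log2 fold change is the plain mean
difference. For the p-value, the default is a **moderated t**: per-gene
variances are shrunk toward a pooled prior estimated across all genes
(limma's empirical-Bayes machinery), the standard treatment for designs
with 2–3 replicates per arm. Plain Welch and pooled-variance t tests are
available (`method = "welch"` / `"pooled"`), but note their power at
n = 3 per arm is far too low for a raw p < 1e-4 cut: at noise sd 0.2 and
a −2.0 log2 effect, Welch power is ≈ 0.14, versus ≈ 1 for the moderated
statistic. A pipeline using the strict per-gene tests at these sample
sizes would discard most true positives, which is why moderation is the
default rather than an option.

Candidate selection keeps genes with log2FC < 0, p below the
significance threshold (default 1e-4, no multiple-testing correction —
the screen's historical convention; BH correction can be applied
downstream if desired), and log2FC at or below the `percentile` quantile
(default 0.20) of the fold changes **among downregulated genes** — the
percentile population is the downregulated set, not all genes. The
quantile is the linear-interpolation type-7 quantile and boundary ties
are kept, which makes the noiseless limit exact (all planted genes at
exactly the boundary are retained).

Zero-variance groups (possible in exactly noiseless synthetic data) use
a deterministic convention: p = 1 when the mean difference is zero,
p = 0 otherwise.

**Exclusivity.** "Affected only by the included compounds" admits two
readings; both are implemented. The default takes the union of the
included compounds' candidate sets minus the union of the excluded ones
(`exclusive_mode = "union"`); `"intersection"` requires every included
compound to hit the gene. Union is the default because it is the weaker
assumption — it keeps a gene silenced robustly by one included compound
— and the full Venn partition (`exclusivity_partition()`) is always
available for inspection.

## Candidate filters

**Pathway enrichment** is the exact hypergeometric upper tail
$P(X \ge k)$ for overlap $k$ between the candidate list (size $n$) and a
gene set (size $K$ inside the universe $N$), computed by `phyper` and
verified against exhaustive enumeration for all parameter combinations
with $N \le 12$. Results sort by p with a lexicographic `set_id`
tie-break for determinism. The "cancer-related" character of the
collection is the user's responsibility (any GMT works); the bundled
fixture GMT is synthetic.

**Binding-site filter**: a candidate survives iff its gene body contains
at least one site for any included compound's motif (absent from the
count table = zero sites).

**Survival filter**: per gene, patients are dichotomized at the median
expression (high = strictly above). The two groups are compared with a
hand-implemented standard log-rank test (tie-corrected hypergeometric
variance; cross-checked against `survival::survdiff` to 1e-10), and the
gene is kept iff p < `survival_alpha` (default 0.05) **and** the high
group has worse survival, judged by a smaller Kaplan–Meier area up to
the last follow-up common to both groups. The direction requirement
halves the null keep rate to ≈ α/2, which the calibration tests verify.
Median cutoffs and α = 0.05 are the most common conventions; both are
parameters because survival platforms differ on this. The KM-area
comparison was chosen over a fitted hazard model so the decision rule
has no parametric assumptions.

## Dose–response

Viability curves are fitted with the four-parameter logistic
$r(d) = b + (t - b) / (1 + (d/\mathrm{IC}_{50})^{h})$ on the log-dose
scale (the IC50 is fitted as its logarithm). Initialization is
deterministic — top = max response, bottom = min response,
log IC50 = mean log dose, hill = 1 — so fits are reproducible without
random restarts. Fitted parameters are normalized to top > bottom
(flipping the hill sign), so a positive hill always means response
falls with dose.

Because plate noise is close to constant-CV (multiplicative), the
default objective weights residuals by the model mean (equivalent to
1/Y² weighting in common curve-fitting software); `weighting = "none"`
gives plain unweighted least squares. The weighted objective alone has
a spurious optimum near the zero-response plateau for steep noiseless
curves, so the implementation first solves the unweighted problem and
uses its solution to seed the weighted refinement — this keeps the
noiseless limit exact (parameter recovery to ~1e-8 relative) while
improving noisy-IC50 accuracy (median relative error ≈ 4% at 5% CV with
8 log-spaced triplicate doses, versus ≈ 5–6% unweighted).

Zero-dose wells are used only to rescale responses to percent-of-control
and are excluded from the fit (the model lives on log dose). At least 4
distinct nonzero doses are required; constant responses raise a
"no dose effect" error rather than returning a meaningless fit.
`ic50_shift()` reports the mono/combo IC50 ratio; values above 1
indicate potentiation.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of (seed, parameters) — identical
seeds give byte-identical output — and emits a truth record validated
against the data it accompanies.

* `gen_expression()`: baselines ~ Normal(8, 2) log2 units (a reasonable
  sketch of normalized single-channel intensity distributions — a
  modeling choice, not an empirical claim), planted per-compound effects
  (default −2.0 log2, i.e. 4-fold knockdown at typical potency), and
  iid Normal(0, σ) replicate noise, σ = 0.2 by default. Defaults mirror
  the screen's design: 3 compounds + control, 3 replicates, 2000 genes,
  50 planted genes per compound with designed Venn overlaps
  (`venn_planted_sets()`).
* `gen_genome()`: iid uniform background with planted concrete motif
  expansions at recorded coordinates and orientations. The
  `scrub_unplanted` option rejection-resamples chance background matches
  so that truth = exact site list; the bundled end-to-end fixture uses
  it because its contract is exact planted-site recovery.
* `gen_survival()`: expression ~ Normal(0, 1); event times exponential
  with hazard multiplied by HRᵍ for each above-median planted gene;
  censoring times Uniform(0, horizon/λ₀), horizon 5 ⇒ ≈ 20% censoring.
* `gen_plate()`: 4PL means with multiplicative Gaussian noise (5% CV
  default), triplicate wells, 8 log-spaced doses spanning ±2 decades
  around the IC50.

None of the generators simulate probe-level artifacts, dye or batch
effects, correlated gene expression, chromatin accessibility, non-
proportional hazards, or plate-position effects. Passing recovery tests
therefore demonstrates correctness of the *statistics and plumbing*, not
robustness to every failure mode of real microarray, survival or
viability data. Real-data idiosyncrasies (probe-to-gene mapping,
normalization, cohort heterogeneity) are deliberately upstream of this
package's contract.

The bundled fixture (`gen_screen_fixture()`, recorded seed 20220943)
composes all generators into a 200-gene study whose filter chain narrows
18 → 16 → 5 → 3, with margins chosen so the outcome is structural rather
than borderline: decoy survival genes are strongly protective (HR 0.3)
rather than null, non-candidate pathways are weakly enriched by design,
and only the five binding-filter genes carry sites at all.

## Problem sizes and determinism in the shipped checks

The test-suite and acceptance computations use: 2000-gene matrices over
20 seeds for screen recall (plus one noiseless matrix for the exactness
check); 200 null and 100 HR = 3 survival cohorts of 100 patients; 200
noisy plates for IC50 recovery; ~1800 enumerated hypergeometric
parameter combinations (N ≤ 12); ≥ 100 random sequence/motif pairs (up
to 2 kb) against a brute-force duplex-scan oracle; and the fixed-seed
end-to-end fixture. These sizes give stable Monte-Carlo margins (the
measured quantities sit far from their acceptance boundaries) while
keeping a full run in tens of seconds.

## Known limitations

* The ring-pair table covers Py/Im/β hairpins with a single γ turn;
  cycles, tandem hairpins, and exotic monomers (e.g. hydroxypyrrole) are
  out of scope, as are binding free energies and mismatch tolerance.
* Motif scanning is exact-match on degenerate symbols — no affinity
  scores or accessibility weighting.
* The screen assumes a normalized log2 matrix; normalization, background
  correction and probe collapse happen upstream.
* The survival filter tests one gene at a time (no multivariate or Cox
  modeling) and one cohort at a time.
* Only single-agent 4PL fits and fixed-dose combination shift are
  modeled; synergy surfaces (Bliss/Loewe) are not.
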
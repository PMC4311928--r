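---
title: "Screening for ectopically expressed olfactory receptors with a dual-rank score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for ectopically expressed olfactory receptors with a dual-rank score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectorank)
library(dplyr)
```

## The problem

Olfactory receptors (ORs, the `olfr` gene family in mouse) are increasingly
detected outside the olfactory epithelium — in bladder, thyroid, thymus and
other tissues — where they appear to act as general chemosensors. Deciding
*which* of the >1,000 rodent OR genes are plausibly expressed in a given
non-olfactory tissue from a microarray expression atlas is harder than it
sounds: microarray intensities are noisy, and an OR that is dim in absolute
terms may still be the most specifically expressed receptor of a tissue.
Sorting a tissue's column by raw intensity therefore over-weights globally
bright probes and misses tissue-specific ones.

`ectorank` implements a screen built around a **dual-rank score** that
addresses exactly this: a gene is a good candidate for a tissue when it is
simultaneously *prominent within the tissue* and *preferential to the
tissue relative to the gene's other tissues*.

## The score

Let `M` be the m × n intensity matrix of m receptor genes over n tissues
(m = 352 valid ORs and n = 78 tissues in the atlas the method was designed
around), and let rank 1 always mark the highest intensity. For gene *i* and
tissue *j*:

* the **within-tissue rank** is the position of `M[i, j]` among all genes of
  tissue *j*;
* the **across-tissue rank** is the position of `M[i, j]` among all tissues
  of gene *i*;
* their **rank sum** combines the two criteria on equal footing;
* the final score **τ** is the ascending rank of the rank sum within the
  tissue, so τ is a permutation of `1..m` per tissue and the top-k
  candidates of every tissue are simply the genes with τ ≤ k (k = 25 by
  default).

A concrete reading: if a gene has the 6th highest intensity of a tissue and
that tissue gives the 58th highest intensity of the gene's own profile, its
rank sum is 64; if exactly six other genes of that tissue have strictly
smaller rank sums, its τ is 7 and it sits comfortably inside the top 25.
Because the score uses only ranks it is invariant under any strictly
increasing transform of the intensities — no log-transform or normalization
of the raw values changes the result.

```{r worked}
we <- build_worked_example(seed = 1)
rank_table(we$expression) |>
  filter(gene == we$focal_gene, tissue == we$focal_tissue)
```

### Tie handling

The atlas intensities are continuous, but ties still deserve a defined
behaviour. The two π rankings use **competition (min) ranking** — tied
values share the rank `1 + (number of strictly greater values)` — which
matches the ordinal language ("sixth highest") of the score's definition.
The final τ uses **ordinal ranking with the gene identifier as a byte-wise
tie key**, so τ is always an exact permutation and top-k selection is
deterministic and reproducible across platforms (byte order, not locale
collation). These tie policies are a design decision of this package; the
score's definition by itself does not fix them.

### Validity screening

Ranking is performed only on *valid* receptor genes. A pre-extracted
annotation record (symbol, accession, title, leading comment word) is valid
when the accession starts with `NM_` (curated mRNA), the comment's first
token — after stripping trailing `,` or `:` — is exactly `VALIDATED`
(case-sensitive, since the review status is printed in upper case), and the
title contains neither "partial" nor "pseudo" (case-insensitive, so
"Pseudogene" and "partial cds" both exclude). `assess_validity()` reports
every violated rule per record; `restrict_to_valid()` subsets the matrix
before ranking. The filter never touches the network: records arrive as a
table, because live annotation databases drift over time.

## Statistical validation of a selection

To check that a selection is not arbitrary, `compare_selected_vs_rest()`
runs a Welch (unequal-variance) t-test of the selected genes' intensities
in a tissue against all non-selected genes — with the 352-gene atlas and
k = 25 the groups are 25 and 327. Two-sided p-values are used throughout
and no multiple-testing correction is applied across tissues, matching the
screen's original usage. The Welch test is delegated to `stats::t.test()`;
the suite verifies its type-I calibration (p-values uniform under the
null).

`mann_whitney_u()` supports the small-sample group comparisons used
downstream of such screens (e.g. colocalization counts over 3–5 animals).
The statistic is `U = #\{a > b\} + ½·#\{a = b\}`. For pooled sizes up to
`exact_max_n` (default 16, i.e. at most `choose(16, 8) = 12870` labelings)
the two-sided p is computed by exhaustive enumeration of all group
labelings — doubling the smaller tail and capping at 1 — which remains
exact under ties; larger samples use the normal approximation with
tie-corrected variance and a ½ continuity correction. The default 16 keeps
enumeration instantaneous while covering the few-animals-per-group scale;
the suite checks the approximation tracks the exact p to within 0.02 at
n1 = n2 = 8.

## Absolute qPCR quantification

The screen's candidates are typically confirmed by absolute RT-qPCR
quantification against a plasmid standard: a 10-fold dilution series of
known concentration (fM) gives a least-squares line of Ct on
log10(concentration); amplification efficiency is `10^(-1/slope) − 1`
(100% at slope `−1/log10(2) ≈ −3.32`). `ct_to_concentration()` inverts the
line; `normalize_to_reference()` removes per-sample loading using a
reference transcript (eEF-2 in the original workflow) quantified on the
same scale, scaling each sample by the geometric mean of the reference
across samples so the result stays in absolute fM rather than becoming a
unitless ratio — the exact normalization arithmetic behind published fM
tables is rarely stated, so this convention is documented here and kept
fixed. `summarize_replicates()` reports mean ± SEM (`sd/√n`) over
biological replicates, with SEM 0 and a visible `n = 1` for singletons.
Note the geometric-mean convention recovers true absolute concentrations
exactly only when loading factors average (geometrically) to one;
otherwise a constant global scale remains, which cancels in any
between-sample comparison.

```{r qpcr}
pts <- tibble::tibble(concentration = 10^(1:5),
                      ct = 40 - 3.3219 * log10(10^(1:5)))
glance(fit_standard_curve(pts))
```

## Synthetic data: what it emulates and what it does not

No public release of the refined OR atlas exists, so the package ships
generators that reproduce the *statistical shape* of the inputs rather than
their values:

* `simulate_expression()` draws log-normal baseline intensities (meanlog 6,
  sdlog 1 by default — right-skewed with a heavy upper tail, the salient
  feature of microarray intensity distributions) and multiplies a chosen
  set of (gene, tissue) cells by a fold factor: planted ectopic signals
  with known ground truth. Defaults m = 352, n = 78 mirror the atlas scale.
* `build_worked_example()` *engineers* a 352 × 78 matrix realizing the
  worked example above by construction: five genes are placed above the
  focal intensity in the focal tissue and peak there (rank sums 2–6), one
  more low-sum gene lands at rank sum 8, the focal row gets exactly 57
  larger entries, and every remaining gene peaks away from the focal tissue
  so its rank sum is at least 86. Band values are random, so each seed
  yields a different matrix with an identical rank skeleton; the
  construction is verified against the brute-force oracle before being
  returned.
* `simulate_annotations()` produces records violating each validity rule in
  rotation; `simulate_qpcr()` produces Ct tables (standards, reference,
  unknowns) from a known curve, known concentrations and known loadings.

All generators are pure functions of their parameters and an integer seed.

What passing tests on these generators shows: the ranking, filtering and
quantification machinery is arithmetically correct, deterministic, and
recovers planted signal under realistic skew and noise. What it does not
show: performance on a real atlas, whose probe effects, cross-hybridization
and correlated tissue structure the generator deliberately does not model.

## Numerical and design choices

* **Dual implementation.** `rank_table()` (vectorized) and `tau_oracle()`
  (naive per-element counting, no shared ranking code) implement the same
  contract; the suite requires element-wise agreement on random matrices
  with and without ties. The oracle is quadratic and intended for testing,
  though it handles the full 352 × 78 scale in under a second.
* **Exactness.** TSV round-trips are bit-exact (full-precision doubles,
  tabs, `.` decimal point, byte-wise identifiers); pipeline artifacts carry
  no timestamps, so identical inputs and configuration give byte-identical
  outputs, recorded in a manifest with input digests.
* **Degenerate inputs** are errors, not silent results: empty matrices,
  duplicate identifiers (with the duplicate named), non-numeric or negative
  cells (with coordinates), genes lacking exactly one annotation record,
  zero-variance Welch groups, all-equal dilution series, non-finite Ct
  values. A fitted standard curve with non-negative slope is returned but
  flagged and warned about, since a broken assay is worth inspecting rather
  than hiding.
* **Problem sizes in the suite.** Property tests run on 15–30 gene matrices
  where exhaustive oracles are cheap; study-scale checks (planted recovery
  at 352 × 78 over 50 seeds, 2000-replicate Welch calibration, 100-seed
  noisy qPCR recovery) use sizes chosen to keep the whole suite well under
  a minute per file while leaving Monte-Carlo margins wide.
* **Noisy-recovery margins.** With Ct noise of 0.2 cycles, one normalized
  concentration carries ≈ 20% relative error (two log-scale noise sources
  of `0.2/3.32` decades each), so the mean over three replicates is within
  20% of truth roughly 93% of the time and is unbiased to ≈ 1–2%
  (log-normal convexity). The tests assert a ≥ 85% within-20% rate and
  ≤ 5% bias — bounds derived from that arithmetic, not tuned to runs.

## Limitations

* The screen outputs *candidates*; it attaches no significance level to τ
  itself, and the original workflow confirms candidates by RT-PCR, qPCR and
  immunostaining — none of which this package replaces.
* Per-tissue top-k ignores correlation between tissues; a gene can be
  selected in many tissues.
* The qPCR module assumes technical replicates were averaged upstream and
  that the standard's copy-number→fM conversion happened before entry.
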
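---
title: "Scoring ligand–receptor interactions with paired CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring ligand–receptor interactions with paired CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icscreen)
```

## The problem

A pooled CRISPR screen ranks the genes of *one* cell type. When the
phenotype of interest is intercellular — how well cytotoxic T lymphocytes
(CTLs) kill tumor cells — the signal is split across two screens: an
immune-cell screen run in the presence of tumor cells and a cancer-cell
screen run in the presence of CTLs. Each sees only its own side of every
ligand–receptor axis. `icscreen` fuses the two sides into one score per
interaction, oriented so that positive means CTL-activating and negative
means CTL-suppressive.

## From guide counts to gene scores

The per-screen statistic follows the drugZ family of analyses. For guide
$i$ in a treatment/control sample pairing, the log2 fold change is

$$\mathrm{fc}_i = \log_2\frac{t_i + p}{c_i + p},$$

with pseudocount $p$. Its standard deviation is not estimable from one
guide, so guides are ranked by control count and guide $i$ borrows the
empirical standard deviation of the fold changes within a window of
±`half_window` ranks (truncated at the boundaries): low-coverage guides,
whose fold changes are noisiest, are standardized against equally noisy
neighbours. The guide z-score is $z_i = \mathrm{fc}_i / \hat\sigma_i$ and
the gene score is the Stouffer sum

$$\mathrm{normZ}(g) = \frac{\sum_i z_i}{\sqrt{n_g}},$$

which is standard normal when the guide z-scores are. This calibration is
checked empirically: on a simulated null screen of 10,000 genes × 4
guides the normZ distribution passes a Kolmogorov–Smirnov test against
N(0,1) at $\alpha = 0.01$, and the fraction beyond ±1.96 sits within
0.05 ± 0.01.

Parameter defaults (all user-tunable in `guide_zscores()` /
`run_config()`):

| parameter | default | units | why |
|---|---|---|---|
| `pseudocount` | 5 | reads | stabilizes ratios at low counts; the drugZ convention |
| `target_total` | 1e7 | reads/sample | common library size before ratios |
| `half_window` | 500 | ranks | variance pooling width; small enough to track the strong mean–variance trend of NB counts |
| `sd_floor` | 1e-3 | log2 units | keeps z finite when a window is degenerate (all fold changes equal) |
| `fpkm_threshold` | 10 | FPKM | expression call cutoff, inclusive |
| `fdr_threshold` | 0.05 | — | classification and shortlist cutoff, strict `<` |
| `abs_z_threshold` | 3 | normZ | shortlist magnitude branch, strict `>` |

Replicate pairing: with equal numbers of treatment and control samples,
sample $i$ is paired with sample $i$; otherwise each treatment sample is
compared against the control mean. The source studies do not state their
pairing, so this is a package decision — it keeps the number of z entries
per gene well defined in both designs.

## Expression gating

Knockout phenotypes of genes a cell does not express cannot act through
that cell's surface, so before combination the normZ of every gene not
called expressed in a context (mean FPKM across replicates below 10, best
probe per gene) is set to zero. Genes absent from the call table are
zeroed too — a conservative choice that also absorbs symbol mismatches
between screen and expression platforms. Gating is idempotent and can
only shrink scores. Importantly, a gene gated out on the cancer side
remains discoverable through its partner on the CTL side: the final score
then collapses onto the CTL term alone (see below), which is how
checkpoint ligands expressed in only a subset of tumors stay visible.

## Combining the two sides

For catalog pair (ligand $L$, receptor $R$), both orientations across the
cell boundary are scored separately (ligand on the CTL, or on the cancer
cell). With CTL-side score $z_c$ and cancer-side score $z_\ell$ in cell
line $\ell$:

$$z_\ell' = \frac{z_c + z_\ell}{\sqrt2}, \qquad
z_{\mathrm{final}} = \frac{\sum_\ell z_\ell'}{\sqrt{n_{\mathrm{lines}}}}.$$

The `tolerant` method applies these formulas unconditionally. `strict`
zeroes $z_\ell'$ when $z_c$ and $z_\ell$ have opposite (nonzero) signs and
zeroes $z_{\mathrm{final}}$ when the cancer cell lines disagree among
themselves; `composite` applies the within-pair constraint only, on the
view that heterogeneous cancer lines may genuinely disagree. A gated zero
is sign-compatible with everything — treating it as a disagreement would
annihilate every gated interaction, defeating the purpose of gating.

Two structural notes on the sign rules, which the test suite pins down:

* the strict across-line check must act on the per-line cancer-side
  scores. Nonzero within-pair scores always inherit the sign of a nonzero
  $z_c$, so a check on the combined scores alone could never detect
  cell-line disagreement;
* $|z_{\mathrm{strict}}| \le |z_{\mathrm{composite}}|$ holds instance-wise,
  and composite equals tolerant whenever all within-pair signs agree, but
  $|z_{\mathrm{composite}}| \le |z_{\mathrm{tolerant}}|$ does **not** hold in
  general: zeroing one discordant pair can leave a larger absolute sum
  than tolerant cancellation. The methods nest by support (strict
  nonzero ⟹ composite nonzero ⟹ tolerant nonzero, almost surely), not by
  magnitude.

### Null calibration and its limits

Each $z_\ell'$ is exactly standard normal under the null, and the
single-line final score with it. With $n$ cell lines sharing one CTL
score, however, the across-line summands are correlated through $z_c$ and

$$z_{\mathrm{final}} = \frac{n\,z_c + \sum_\ell z_\ell}{\sqrt{2n}}
\quad\Rightarrow\quad
\mathrm{Var}(z_{\mathrm{final}}) = \frac{n+1}{2},$$

which is 1.5 for two cell lines.

The package follows the published two-stage rule as specified — the
formula's simplicity and comparability outweigh the calibration error —
but the vignette records the consequence: with two cell lines, two-sided
tail probabilities read from N(0,1) are understated by roughly the ratio
of normal tails at $z$ versus $z/\sqrt{1.5}$, so printed FDRs for
multi-line scores are optimistic in absolute terms while the *ranking* is
unaffected. The test suite asserts exact N(0,1) calibration per cell line
and pins the variance-1.5 behaviour for two lines.

### Significance and shortlist

One-sided p-values ($p = \Phi(-|z_{\mathrm{final}}|)$) are corrected by
Benjamini–Hochberg separately within the positive-score and
negative-score instance sets: activating and suppressive discovery are
separate problems, and each instance reports the FDR of its own
direction. Ranked tables sort by $|z_{\mathrm{final}}|$. The shortlist
keeps instances that are significant (`fdr < 0.05`) *or* large
(`|z| > 3`), whose nonzero gated scores are sign-concordant across all
screens, and whose CTL-side gene is expressed in CTLs; cancer-side
expression is deliberately not required. Concordance is checked on the
gated scores (the quantities actually combined), a declared reading where
the alternatives are ambiguous.

## Evaluation

Predictions at `fdr < 0.05` are three-class: activating, suppressive,
unknown. A curated standard pair matches scored instances as an
*unordered* gene set; when both orientations were scored, the one with
the larger $|z_{\mathrm{final}}|$ represents the pair. Macro precision,
recall and F1 average the two evaluated classes only — the unknown class
contributes false positives but is never scored itself, since it may
contain genuine but uncharacterized targets. Macro-F1 is the arithmetic
mean of the class F1 scores; on the reference confusion counts this
reproduces the published 0.70 / 0.26 / 0.35 triple, which the harmonic
alternative does not. AUROC discriminates activating from suppressive
standards using the signed score, computed by the Mann–Whitney rank-sum
with midranks for ties — the only binary task a two-label standard
supports, and the declared reading of the otherwise unspecified
"macro" AUROC.

## What the simulator emulates — and what it does not

`sim_config()` / `simulate_screen()` / `simulate_universe()` generate a
complete study: negative-binomial guide counts (dispersion 0.1) around a
log-normal per-guide baseline (median 500 reads, sdlog 1, emulating
pooled-library coverage heterogeneity), planted gene classes (5%
activating, 5% suppressive by default) shifting treatment means by
±2 log2 units, a catalog of 400 ordered pairs of which 10% are planted
concordant (these become the standard set), and per-context expression
calls with 30% of genes unexpressed per cancer line — including a forced
"checkpoint-ligand-like" gene, unexpressed in every cancer context but
effective through its CTL partner, to exercise the gating collapse. All
draws derive from one seed by fixed offsets (truth +0, CTL screen +1,
cell line $k$ +1+$k$, universe +100), so runs are bit-reproducible.

What it does not model: tumor-infiltration bottlenecks and clonal
dynamics, guide-efficiency differences, copy-number artifacts,
cross-screen batch structure, or any correlation between expression level
and knockout effect. Passing tests therefore demonstrate the *statistical
machinery* — calibration, recovery, orderings — not robustness to the
biological failure modes of real screens.

Problem sizes in the test suite are chosen for a laptop-scale run:
10,000 genes for the calibration checks, 2,000 genes × 4 guides × 3
screens for end-to-end recovery (planted pairs reach AUROC > 0.9 against
null pairs), and ≤ 200-record fixtures wherever an estimator is compared
exactly against a brute-force oracle.

## Known limitations

* The across-line variance inflation above: multi-line FDRs are
  approximate; per-line scores are exactly calibrated.
* Symbol-level matching: orthologs, complexes and multi-subunit receptors
  must be flattened to gene pairs upstream; mismatched symbols are
  silently treated as unexpressed (by design, but worth auditing via the
  logged zero counts).
* The window-based variance estimate assumes exchangeability of fold
  changes among guides with similar control counts; strong
  guide-composition artifacts would violate it.
* With a single treatment/control pair per screen there is no within-gene
  replication beyond guides; normZ remains calibrated but effect-size
  estimates are noisy.
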
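---
title: "Models and methods behind conjseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind conjseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjseq)
```

conjseq quantifies two things about a conjugative plasmid: *how often* it
transfers between bacteria (in culture and in the gut of a host animal), and
*which of its genes* that transfer depends on. This vignette explains the
statistical models, the tunable parameters, the synthetic-data generator the
tests rest on, and the numerical decisions taken where several reasonable
conventions exist.

## Gene essentiality from transposon insertion libraries

### The measurement model

A transposon-saturated plasmid library is passed through successive
selective steps: establishment in the donor (maintenance selection), a
conjugative transfer on solid medium, and a transfer inside the intestinal
tract. Insertion junctions are sequenced after each step. A gene required at
a step removes its insertion mutants from the population, so its read signal
collapses relative to the initial library.

The pipeline mirrors the standard processing chain:

1. **Trimming** (`trim_reads()`): sliding window of 4 bases, cut at the
   first window with mean Phred quality below 20, minimum surviving length
   30 — the common Trimmomatic setting. Within the failing window, leading
   bases that individually pass are kept, so the cut lands on the first
   genuinely low-quality base.
2. **Site calling** (`call_insertion_sites()`): alignments with MAPQ < 30
   are discarded; each surviving alignment is collapsed to the *middle base
   of the 9-bp Tn5 target-site duplication*. Tn5 duplicates 9 bp at its
   insertion point, so a junction read can start at either duplication copy;
   taking `start + 4` on the forward strand and `end − 4` on the reverse
   strand maps both read orientations of one physical insertion to the same
   coordinate. Sites supported by a single read are removed as noise.
3. **Normalization** (`normalize_depth()`): counts per million mapped reads.
   Any depth unit would do — every downstream statistic is a ratio — but CPM
   keeps browser tracks on a familiar scale.
4. **Gene counting** (`gene_read_counts()`): sites in the first 5% and last
   15% of each gene are excluded, because insertions near the termini can
   leave functional protein fragments. "First" means the 5′ end of the
   coding strand, so the window flips for minus-strand genes. With gene
   length $L$, a site at 1-based 5′ offset $o$ is counted when
   $\lfloor 0.05L \rfloor < o \le \lceil 0.85L \rceil$; floor/ceiling keep
   the window inclusive for short genes. Wrap-around genes on circular
   plasmids are unwrapped onto a doubled coordinate view.
5. **The ratio statistic** (`essentiality_ratio()`):
   $(x - x_1)/x_1$ for normalized gene counts $x$ (test condition) and
   $x_1$ (initial library). Genes with $x_1 = 0$ are reported `no_data`,
   never called: zero initial signal is indistinguishable from an
   unmappable region.
6. **Calibration and calls** (`calibrate_threshold()`,
   `call_essential()`): the threshold for a condition is the *maximum*
   ratio over a core set of genes positively known to be required in that
   condition. The comparison is inclusive (`ratio <= threshold`), the only
   reading under which the core genes that define the maximum are
   themselves called essential.

Replicates are handled by pairing test and initial libraries in order
within condition, computing per-pair ratios, and averaging over pairs with
data. Pooling counts instead would weight replicates by depth; averaging
ratios weights them equally, which matches how replicate animals are
usually treated.

Genes that never carry insertions in the *initial* library (replication,
partitioning, selection markers) cannot be scored by a ratio. The
`maintenance_screen()` flags them by insertion-site density: at the design
density of one site per ~5 bp (~200 sites/kb), a default cutoff of 10
sites/kb separates depleted loci sharply. The cutoff is exposed because it
is the formalisation of what is otherwise a manual coverage check; genuinely
unmappable regions will also trigger it and need inspection.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `window`, `min_mean_quality`, `min_length` | 4, 20, 30 | trimming |
| `mapq_min` | 30 | minimum mapping quality |
| `head_trim`, `tail_trim` | 0.05, 0.15 | gene-end exclusion fractions |
| `reference_depth` | 10⁶ | normalization unit (CPM) |
| `min_sites_per_kb` | 10 | maintenance-screen density cutoff |

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline is validated.

* **Plasmid** (`gen_plasmid()`): circular replicon of non-overlapping genes
  (default 300–1500 bp) separated by ≥ 10 bp spacers; each gene gets a
  ground-truth role — maintenance, in vitro transfer (T4SS/relaxosome), in
  situ transfer (type IV pilus / mating-pair stabilisation), or cargo. The
  default class fractions (20/30/20% with at least one gene each) echo the
  composition of an IncI-type conjugative plasmid, where transfer genes
  dominate the backbone.
* **Libraries** (`gen_insertion_library()`): insertion positions are drawn
  uniformly without replacement (site-level logic; read counts model only
  PCR/sequencing depth). Selection history is cumulative — the in vitro
  library descends from the initial one, the in situ library from the
  in vitro transconjugants — and the depletion factor acts per selective
  passage: a gene essential in $k$ of the passages a library has been
  through retains insertions with probability $(1/d)^k$. A maintenance
  mutant, for instance, is counter-selected at every step, while a pilus
  mutant is lost only at the in situ transfer. The default $d = 1000$
  reflects the near-complete depletion seen for transfer genes in real
  libraries; $d = \infty$ models absolute depletion.
* **Bottleneck** (`bottleneck_subsample()`): passage through a host is a
  multinomial draw of `bottleneck_size` cells over clones (conserving the
  total exactly); in situ read counts are proportional to post-bottleneck
  clone abundance. Real library complexity after gut passage is not
  published, so the bottleneck size is a free parameter (default 10⁵).
* **Reads** (`gen_reads()`): junction reads whose alignment start/end encode
  each site under the duplication-midpoint convention, written as FASTQ plus
  a minimal SAM; a configurable fraction of reads is downgraded below the
  MAPQ threshold and singleton noise sites can be injected. Sites within
  4 bp of the linearization origin are excluded at generation time so every
  site is representable by a contiguous SAM alignment.
* **CFU assays** (`gen_cfu_assay()`): per animal, log10 donor and recipient
  abundances vary normally with SD `mouse_cv` (default 0.5 — a typical
  animal-to-animal spread of one-third to one order of magnitude);
  transconjugant expectation is `recipient × true_rate`; colony counts per
  5 µL spot are Poisson across a full 1/10 dilution series. Log-normal
  abundance with Poisson counting is the standard microbiological model;
  `mouse_cv` is defined as the SD of log10 CFU because a coefficient of
  variation of a logarithm is not unit-free.
* **Plasmid families** (`gen_plasmid_family()`): children derive from a
  parent by per-gene loss and per-base substitution/1-bp-indel mutation;
  the expected retained-gene identity, about
  $1 - \text{sub} - \text{indel}$, is recorded as truth.

All generators draw from deterministic substreams of one integer seed, so
every output is byte-identical across runs and no generator perturbs
another's stream.

**What the generator does not emulate:** sequencing errors beyond MAPQ
downgrades, host-chromosome contamination (inputs are pre-filtered by
contract), shufflon rearrangements, within-gene insertion bias, and clonal
interference during colonization. Passing tests therefore demonstrate the
*analysis* is correct and calibrated, not that these upstream artefacts are
harmless in real data.

## Conjugation-rate statistics

`cfu_from_spots()` converts a spot series to CFU using the most dilute
dilution whose mean colony count lies in [1, 100] (replicate spots
averaged). Using the most dilute countable row avoids crowding bias at the
cost of Poisson noise; with triplicate 5 µL spots the resulting CFU
estimates carry roughly 25–45% error, which the tests propagate into their
tolerances. An all-zero series returns 0 with a below-detection flag; an
all-overgrown series is an error.

`transfer_rate()` reports transconjugants per recipient. When no
transconjugant colony appears, the sample is censored at
$\mathrm{LOD} = 1/(R \cdot m)$ — recipient abundance $R$ times the amount
$m$ of sample actually plated — the frequency at which exactly one colony
would have been expected. This is why plating ten-fold more material (e.g.
caecal content instead of feces) detects ten-fold rarer transfer.

Downstream summaries run on log10 frequencies: `anova_log()` (one-way
ANOVA), `log_r_squared()` (squared Pearson correlation of paired log
rates), `fold_change()` (geometric-mean ratio, equivalent to arithmetic
means on the log scale; an arithmetic option exists because published
summaries sometimes use it). Censored values are excluded from correlation
and ANOVA by default and can be substituted at their LOD bound, which is
the convention for fold-change figures built from non-transferring
plasmids; any fold change touching a censored value is flagged as a bound.

## Pan-genome classification

`global_align()` is an exact Needleman–Wunsch with linear gap costs
(defaults: match +1, mismatch −2, gap −1/base; the gap value is exposed
because only its linearity is fixed by convention). Among score-optimal
alignments the implementation returns the one with the most match columns,
then the fewest columns — both secondary objectives are additive, so the
lexicographic optimum is still a dynamic program — which makes percent
identity symmetric in its arguments; remaining ties prefer substitution
columns over gaps, then gaps in the first sequence. An enumeration oracle
(all increasing matchings, bit-encoded) verifies the scores exhaustively on
small alphabets in the test suite, and Biostrings' aligner cross-checks
longer pairs.

Identity defaults to matches over alignment columns (gaps in the
denominator); a score-rescaled variant is available since "identity" is
sometimes reported that way. `presence_matrix()` takes the best-scoring hit
of each query gene among a target's genes (ties: higher identity, then
lexicographic id) and thresholds identity at 100/70/50% cutoffs;
`categorize_genes()` applies the partition core = 100%, soft-core > 50%,
accessory < 50%, with exactly 50% assigned to accessory because soft-core
is defined strictly. Note that a 50% *nucleotide* identity cutoff is
weakly discriminative under global alignment — unrelated sequences of
similar length reach it occasionally — which is visible in synthetic
families as inflated presence at the lowest cutoff; the 70% cutoff is the
discriminative one for nucleotide mode, and protein mode is available.

## Problem sizes and validation

The test suite validates the pipeline at the reference design: a 10-gene
(~9 kb) plasmid, 2000 insertion sites (one per ~5 bp), mean depth 50,
1000× depletion, 3 replicates per condition, pooled over 20 seeds, with
micro-averaged F1 computed against the generator's truth. Genes flagged by
the maintenance screen are excluded from the transfer-condition evaluation
universe (they are unscoreable by construction), and `no_data` genes count
against neither set. Rate recovery uses 50 simulated 4-mouse assays at a
true frequency of 10⁻⁴; ANOVA calibration uses 1000 null replicates of 4×4
groups; the alignment oracle covers every ordered pair of sequences up to
length 6 on a two-letter alphabet. These sizes were chosen so each property
is measured with comfortable statistical margin while the whole suite runs
in about a minute.

## Known limitations

* Essentiality is a threshold call on a ratio; no uncertainty is attached
  per gene (no HMM or Bayesian site model), matching the calibrated-cutoff
  design rather than extending it.
* The ratio cannot score genes absent from the initial library; the density
  screen flags them but cannot distinguish essentiality from unmappability.
* Depth normalization assumes essential loci are a minority of the
  replicon; when a large fraction of a replicon is depleted,
  composition shifts bias all ratios upward (visible and quantified in the
  generator tests).
* CFU estimation from spot counts inherits the discreteness of the dilution
  grid; estimates are exact only up to Poisson error in the countable band.
* Global nucleotide alignment identity at the 50% cutoff admits chance
  hits; presence calls there should be treated as permissive.
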
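---
title: "Methods: pangenome orthology, ANIb phenetics and DE enrichment with orthani"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome orthology, ANIb phenetics and DE enrichment with orthani}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`orthani` reimplements, as one tested toolkit, the comparative-genomics and
transcriptomics chain used to characterise how a bacterial strain adapts to
toxic metal concentrations: which genes it shares with its relatives, how
its genome clusters with theirs, whether a candidate resistance gene
cluster (typically an RND-family efflux operon plus its regulator) is
conserved elsewhere, and which functions are over-represented among the
genes it switches on or off. This vignette records the models, the tunable
parameters, the numerical choices, and what the synthetic validation does
and does not demonstrate.

## Orthology: best reciprocal hits and the pangenome partition

All-vs-all protein similarity is computed either by the internal
Smith–Waterman search or ingested from standard 12-column tabular output
of an external search tool. Within-genome (paralog) hits are ignored
throughout. For every query gene and every other genome, the
top-scoring hit is *accepted* only if two gates pass:

* an e-value gate, `e <= 1e-5` (inclusive), applied when hits carry
  calibrated e-values (external input); internal raw-score hits use a
  score floor (default 50) instead;
* a distinctness gate: the second-best hit *from the same target genome*
  must score strictly below 90% of the best hit's score. A tie for best
  therefore rejects the pair — an ambiguous ortholog assignment is worse
  than none.

A pair (a, b) is a best reciprocal hit (BRBH) when each gene is the
other's accepted best in its genome. Clusters of orthologous genes (COGs)
are the connected components of the BRBH graph; components are the loosest
closure consistent with building groups out of pairwise reciprocal hits,
and a strict mode (`build_cogs(mode = "cliques")`) is available for
sensitivity analysis. A COG is **core** when it has exactly one member in
every genome analysed — a component with any genome represented twice is
accessory, not core. **Strain-specific** genes are, by default, genes with
no gate-passing hit to any other genome at all (`specific_mode =
"no_hit"`), which is deliberately stricter than "no BRBH partner": a gene
whose homologue is detectable but ambiguous is not "specific". The looser
criterion is available as `specific_mode = "no_brbh"`. Genes with hits but
no COG are reported separately as *unresolved* rather than silently folded
into either class.

## The internal aligner

Protein mode is Smith–Waterman with affine gaps under BLOSUM80
(gap open 10, extend 1; a gap of length L costs `open + L * extend`).
Identity and query coverage are measured on the optimal traceback.
Nucleotide mode scores match +2 / mismatch −3 with gap open 5 / extend 2
and searches both strands. These penalties are common search-tool
pairings; they are recorded in `align_params()` and overridable. Internal
hits report the raw alignment score in the `bitscore` column and a
length-normalised surrogate (`qlen * slen * 2^-score`) in the `evalue`
column, flagged by a `score_mode = "raw"` attribute: calibrated
Karlin–Altschul statistics are intentionally not computed, and the BRBH
e-value gate simply does not apply in internal mode. The all-vs-all
search prescreens gene pairs by shared 4-mers (at least 2 distinct shared
words by default) before running full dynamic programming; for long
nucleotide targets (> 5 kb) alignment is anchored on exact 11-mer matches
with diagonal voting, then completed by windowed dynamic programming.
Tests hold the anchored path to exact agreement with exhaustive dynamic
programming, and all protein scores to exact agreement with both an
independent textbook DP oracle and a reference pairwise aligner.

## ANIb

Average nucleotide identity follows the classic fragment recipe: each
query genome is cut, per contig, into consecutive 1020-nt windows
starting at position 1; a terminal remainder shorter than 100 nt is
dropped (a short contig below one fragment length is kept whole). Each
fragment is aligned to the subject genome on both strands, and fragments
whose best hit reaches ≥ 30% identity over ≥ 70% of the fragment
contribute their identity to the arithmetic mean. Both directions of a
genome pair are computed and kept asymmetric; directions are averaged
only at the distance step, `d(i, j) = 1 − mean(ANIb(i,j), ANIb(j,i))/100`.
When no fragment qualifies the pair's ANIb is an explicit `NA`, never 0:
averaging zeros would silently drag distances toward 1 for poorly
matched pairs, which is exactly the regime where ANIb is meaningless.

## Neighbor joining

The tree is built by the classical Saitou–Nei agglomeration on the
symmetric ANIb distance matrix: join the pair minimising
`Q(i,j) = (n−2) d(i,j) − Σ_k d(i,k) − Σ_k d(j,k)`, assign branch lengths
by the two-point formulas, reduce, and finish with a trifurcating root,
so the output is unrooted. Two policies are fixed where the classical
description is silent:

* **ties** on the minimal Q are broken by the lexicographically smallest
  label pair (clusters are labelled by their smallest leaf), making the
  output invariant to input row order — historical implementations are
  input-order dependent, and determinism wins here;
* **negative branch-length estimates** are clamped to zero with the
  deficit transferred to the sister branch, preserving the path length
  through the joined pair.

On additive matrices the implementation reproduces path lengths to
1e-9 (property-tested on random binary trees of 4–12 leaves), and any
figure-style rooting is treated as a display concern, out of scope.

## Cluster conservation

A reference gene cluster (e.g. an 11-gene Ni-resistance efflux operon) is
named by its ordered reference gene ids. A member is *present* in another
genome when its COG contains at least one gene of that genome; a genome
is `complete` when its presence fraction reaches the completeness
threshold (default 1.0), `absent` at zero, `partial` otherwise. The
default deliberately requires presence only; an optional contiguity mode
additionally demands that a "complete" genome carry the present orthologs
consecutively and co-oriented on one contig, since a scattered complement
is weaker evidence of a functional operon. The reference genome is
excluded from the counts. Member-wise nucleotide identities versus each
ortholog are computed with the local aligner using the full reference CDS
as the query fragment, with coverage reported alongside, because a local
alignment of the full CDS degrades gracefully when an ortholog is
truncated.

## Functional enrichment and the positional test

GO terms reach genes through their Pfam domains via a pfam2go mapping
(one domain may map to several terms; a gene's annotation is the union
over its domains). The background is **all** protein-coding genes of the
focal genome, annotated or not — restricting to annotated genes inflates
background term frequencies and was rejected as the default (available by
passing a restricted `genes` vector). For a study set of `n` genes out of
`N`, a term carried by `K` background and `k ≥ 1` study genes is tested
with the exact hypergeometric upper tail `P(X ≥ k)`; fold enrichment is
`(k/n)/(K/N)`. The Bonferroni multiplier is the number of terms actually
tested in that study set (terms never observed in the set are not tests),
and `p_adj` is capped at 1. Up- and down-regulated sets are tested
separately. DE genes are selected from a Cuffdiff-dialect table at a
strict `q < alpha` (default 0.05) threshold; a significant row with a
fold change of exactly zero joins neither direction and is surfaced in a
warning bucket.

The positional test builds the 2×2 table of DE/non-DE genes on two
contigs and applies Pearson's chi-squared with one degree of freedom,
without continuity correction by default and with Yates correction by
flag. The variant choice is exposed rather than hidden because the two
differ noticeably at moderate counts and published analyses often omit
which was used.

## The synthetic-data generator

The generator exists so every downstream stage can be validated against
planted truth without any external downloads. Its model, and the defaults
used by the validation scenarios:

* **Gene families.** Each family has a random ancestral CDS (mean 300 nt,
  length jitter of a few codons, always a multiple of 3, ≥ 33 nt; first
  codon ATG, no internal stops). Each carrying genome receives an
  independent copy mutated per site at the configured divergence
  (uniform substitution to one of the three other bases — Jukes–Cantor-
  like, no indels). Mutated codons that become stops are redrawn to sense
  codons so proteomes (bacterial translation table 11) stay valid.
* **Structure.** Core families appear once in every genome; accessory
  families in a random subset of 2..(n−1) genomes; strain-specific genes
  are fresh random CDS unique to one genome. Ancestral gene order and
  orientation are conserved across genomes — no rearrangement simulation
  — which keeps genomes locally collinear, the regime fragment-based ANI
  assumes. Genes are separated by random 20–100 nt spacers, placed with
  1-based inclusive coordinates, and split across the configured number
  of contigs at random breakpoints that never fall inside the planted
  cluster.
* **Planted cluster.** Cluster member families share one strand and sit
  contiguously in every genome flagged complete (the reference genome is
  always complete by construction); partial genomes carry a stated
  subset; other genomes lack the families entirely. The validation
  scenario mirrors a focal strain screened against a panel of downloaded
  genomes: a reference plus 10 comparison genomes with the full cluster
  in 2, a 4-member subset in 1, nothing in 7.
* **DE table.** Planted up/down genes receive q-values drawn uniformly
  below the significance threshold and log2 fold changes of the matching
  sign on (1, 4); all other genes draw q uniformly on (alpha, 1], so
  threshold selection is exact by construction (the default scenario
  plants 90 up and 28 down among 150 focal genes).
* **Annotations.** Twenty background Pfam/GO terms are carried
  independently of DE status at per-term rates drawn on [0.02, 0.10];
  an optional enriched term's Pfam is planted on DE genes at `frac_de`
  (0.5 in the validation runs) versus `frac_bg` (0.05) elsewhere.

Everything is deterministic given the config seed; re-running a
simulation reproduces outputs byte for byte.

**What passing these tests shows — and does not.** Exact planted-truth
recovery at divergence 0.05 demonstrates that the BRBH/COG/partition
logic, the cluster classifier and the DE/enrichment machinery implement
their definitions correctly, with calibrated alignment and ANIb in the
loop. It does not demonstrate robustness to features the generator omits:
indels, rearrangements, horizontal transfer, recent paralogy, codon-usage
bias, or assembly artifacts. In particular, with a raw-score floor of 50,
unrelated ~100-residue proteins occasionally share a short local
similarity above the floor, so the strict "no hit anywhere" specific-gene
criterion can drop an occasional truly unique gene — on real data this
conservatism is usually welcome, but it is why validation of *exact*
specific-gene recovery pins the seed.

## Problem sizes in the shipped validation

The test-suite scenarios use 10 genomes × 85 genes for partition
recovery, a reference plus 10 genomes × ~41 genes for cluster
conservation, 12-kb single-contig genomes for ANIb calibration at
divergences 0.01/0.05/0.10, 50 random trees of 4–12 leaves for
neighbor-joining additivity, a full enumeration sweep of hypergeometric
tails up to N = 60, and 200 null plus 100 planted-effect enrichment
simulations over 300-gene backgrounds. These sizes were chosen as the
smallest at which each property is sharply testable (e.g. core COGs of
exactly full size, family-wise error within the binomial 99% band).

## Known limitations

* Internal-mode e-values are surrogates; BRBH filtering in internal mode
  is score-floor based by design.
* COG formation by connected components can chain distinct families
  through a shared ambiguous member; the clique mode trades recall for
  that precision.
* ANIb between genomes with little conserved synteny returns `NA` for
  many fragments and eventually an undefined pair — a warning, not a
  number.
* GO annotation is transferred flat from Pfam; no GO-graph ancestor
  propagation is performed, so parent terms are only tested when
  directly mapped.
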
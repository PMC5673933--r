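---
title: "circfield: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circfield: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

circfield implements a complete circular-RNA discovery and interpretation
pipeline for a three-group gastric tissue design — patients without
cancer, matched tumor-adjacent tissue, and tumor — in which tumor-adjacent
tissue carries the richest circRNA signal (the field-cancerization, or
field-effect, pattern). This vignette documents the statistical model,
each stage's assumptions and tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
a maintainer would want spelled out.

## Back-splice junction detection

CircRNAs arise by back-splicing: a downstream splice donor joins an
upstream acceptor, so the junction-spanning sequence exists only in the
circular transcript. The caller works on single-end reads with an
exact-match anchor strategy:

1. Every forward-strand k-mer of the genome is hashed
   (`index_genome()`, default anchor `k = 20`). Queries are resolved on
   both strands through reverse complement.
2. For each read, the two terminal k-mers are looked up. Reads explained
   by one contiguous genome match are linear and ignored. Reads whose 5'
   anchor maps uniquely *downstream* of the uniquely-mapped 3' anchor on
   the same chromosome and strand (within `max_span`, default 2 Mb) carry
   the head-to-tail signature.
3. Both anchors are extended inward; any split point consistent with both
   extensions yields the same junction up to coordinate shifts in locally
   repetitive context. Ties are resolved to the *leftmost* genomic
   representation, the analogue of indel left-alignment.

Assumptions and consequences: anchors must map uniquely
(`min_unique = 1`); multi-mapping anchors discard the read rather than
enumerate loci. Reads shorter than `2k` are skipped. There is no indel
handling — the generator produces substitution-only errors, and the
caller tolerates substitutions anywhere except inside the two anchors and
immediately around the breakpoint. A GT–AG flank filter exists
(`require_gtag`) but is off by default because the synthetic genome does
not model splice motifs.

The consensus rule mirrors dual-algorithm calling practice: only
junctions found by both call sets survive (`consensus()`, exact endpoint
matching by default, `slack` for tolerant matching). The read count of a
consensus call is the minimum of the two callers' counts — a conservative
choice, since how real pipelines reconcile the two counts is generally
unstated. CIRI2-style TSV (1-based inclusive) and CIRCexplorer2-style BED
(0-based half-open) outputs can be ingested in place of either side; all
coordinates are normalized to 0-based half-open internally.

## Annotation

`assign_host()` prefers, among same-strand overlapping transcripts, one
whose exon boundaries coincide with both junction endpoints
(`boundary_match`), breaking ties by contained-exon count, contained
length, then transcript id. Origin classes form a total partition:

* `intergenic` — no overlapping transcript;
* `intronic` — both endpoints inside one intron (the ciRNA analogue);
* `exonic_cds` / `exonic_utr5` / `exonic_utr3` — boundary-matched circs,
  sub-typed by contained-exon overlap with the CDS (any CDS overlap wins;
  else entirely 5'UTR; else 3'UTR);
* `exon_intron` — everything else that touches a host (the EIciRNA
  analogue and all non-boundary-matched overlap shapes).

The precedence order and the CDS-over-UTR rule are this package's
explicit choices; origin taxonomies in the literature are rarely given as
formal definitions. Hosts without an annotated CDS are treated as coding
over their whole span for sub-typing.

Spliced length is the sum of exons fully contained in the junction
interval — the native definition. Because some public databases report
genomic spans instead (a 2-exon circ spanning tens of kilobases can carry
a deceptively large "length"), `length_mode = "genomic_span"` reproduces
span-based lengths. Both modes are exposed rather than guessing which
convention an external resource used.

## Differential expression

The count unit is the junction-supporting read. Library sizes default to
per-sample total junction reads, and normalization is library-size
equalization only: counts are scaled to the geometric-mean library size.
TMM-style composition correction is deliberately not applied — its
assumptions are hard to defend on sparse circRNA counts — and is noted as
a flag point for future work.

Dispersion estimation is method-of-moments: per circ and group,
`(s^2 - m) / m^2` on scaled counts, pooled across groups by residual
degrees of freedom, floored at zero. The common dispersion is the
count-weighted mean across circs; tagwise values shrink the per-circ
estimate toward the common one with weight `prior_df / (prior_df + d_g)`
(`prior_df = 10` by default — a moderate prior comparable in spirit to
weighted-likelihood shrinkage, chosen because the per-circ estimates at
n = 8 per group are noisy).

The test is a conditional exact test: under equal per-sample means, the
two side totals of a circ follow, given their grand total, the
distribution induced by sums of NB variables with side sizes
`n_i / phi`. The two-sided p-value sums the probabilities of all splits
at most as probable as the observed one; with `phi = 0` this reduces to
the exact binomial (Poisson conditional). Totals above 5,000 switch to a
normal approximation with continuity correction (the exact sum is
numerically stable but pointless at that scale). Zero-total circs get
p = 1 by convention. The default contrast pools tumor-adjacent and tumor
samples against no-cancer samples, the design's primary comparison;
pairwise contrasts are available. FDR control is Benjamini–Hochberg
(`stats::p.adjust`), and reports carry both raw p-values and FDR because
published tables often print raw p-values.

Note one subtlety: with unequal side sizes the equal-rate split is the
conditional *mean*, not necessarily the mode, so identical per-sample
counts on both sides give p = 1 exactly only for equal side sizes.

The matched no-cancer/tumor pairing of the underlying design is not
exploited (no paired modelling, no covariates) — matching the analysis
contract this package implements.

## Sponge candidates

The three-filter procedure nominates a (circRNA, miRNA) pair when (1) the
miRNA has a validated interaction with the circRNA's host gene, (2) at
least one seed-complement site occurs in the circ's spliced sequence, and
(3) the miRNA is on the supplied differentially-expressed miRNA list.
The DE-miRNA list is an *input*, not a computed product — it stands for a
companion small-RNA experiment.

The seed is mature positions 2–8 (7-mer) with exact Watson–Crick reverse
complement; no wobble pairing and no 8mer/7mer-A1 site grading, because
the procedure being modelled specifies only seed complementarity.
Scanning is wrap-aware by default: the sequence is extended by its own
first `seed_len - 1` characters so sites spanning the back-splice
junction are found (a circle has no ends); `circular = FALSE` disables
this. Overlapping occurrences count as distinct start positions —
documented explicitly because site-counting rules are usually unstated.

## Enrichment

`enrich()` is a plain upper-tail hypergeometric over-representation test
with Bonferroni correction over tested terms. It deliberately does *not*
replicate the EASE-modified Fisher score of web enrichment services. The
background defaults to all genes of the supplied annotation, not the
genome. Plot scores are `-log10` of the raw p-value, labelled as such.

## The synthetic study generator

The generator exists so every stage is testable offline with known truth.

* **Genome**: uniform random A/C/G/T, default 2 chromosomes. Uniform
  composition makes 20-mers essentially unique, which the anchor caller
  needs; no repeats, GC structure or splice motifs are modelled.
* **Gene models**: non-overlapping single-transcript genes, 3–6 exons of
  200–350 nt with 100–300 nt introns, alternating strand. The CDS covers
  interior exons so UTR classes are exercisable. Exons are kept at least
  as long as the default read (150 nt) so junction-read halves always lie
  within terminal exons — the simplification that lets an exact-match
  caller reach recall 1 on clean reads.
* **Truth circs**: runs of 1–4 consecutive exons; some genes receive two
  isoforms (circular alternative splicing is real — one gene in the
  motivating tissue data carried five isoforms). When the genome is
  supplied, candidate runs whose junction context is left-shift ambiguous
  (base before the acceptor equals the last donor base) are excluded, so
  the caller's left-aligned coordinate coincides with the exon-boundary
  representation and truth junctions are exactly recoverable.
* **Group structure**: the `field_effect` preset scales a per-circ base
  mean by (adjacent 1, tumor 0.35, no-cancer 0.1), following the roughly
  620:220:66 ratio of detected circRNAs across the three tissue groups
  that motivates the design. Base means default to a right-skewed
  mixture (exponential with mean 3 shifted by 0.5; a 10% tail is 8-fold
  higher) so most circs have single-digit junction-read expectations with
  a high tail, the shape seen in tissue. Counts are NB with dispersion
  0.2 under the field preset (Poisson under `null`); the value matches
  the test's model so parameter recovery is well-posed — the real
  distribution of circRNA junction counts is unknown.
* **Reads**: single-end 150 nt, error-free by default (substitutions
  only, no indels, rate capped at 5%). Junction reads position the
  breakpoint uniformly at least one anchor length from both ends. Linear
  mRNA reads are included as decoys. rRNA depletion, RNase R enrichment
  efficiency, adapter contamination and paired-end protocols are out of
  scope.
* **miRNA resources**: planted (circ, miRNA, k) triples are written into
  exon interiors of the target circ, at least a seed length from the
  breakpoints unless a wrap site is requested; each pair is verified
  against the scanner and the miRNA re-drawn on spurious extra matches.
  Negative controls cover each filter: site without interaction,
  interaction without site, and site + interaction without DE status.
  Because sites are written into the genome, the generator returns the
  updated genome, which downstream stages must use.

What passing tests show — and what they do not: recall/precision 1.0 on
this generator demonstrates the split-mapping and coordinate arithmetic
are correct, not that the caller matches production callers on real
tissue data (repeats, multi-mapping, indels, splice-motif filtering and
paired-end evidence are all absent). Likewise the calibration results
hold under the generator's NB model, not under unknown real-count
distributions.

At small per-seed study sizes the field-effect ordering of per-group
detected counts can tie between adjacent and tumor when both groups
detect every truth circ (saturation); this is a known limitation of
emulating detected-count ratios through abundance multipliers alone.

## Reference problem sizes

The shipped tests and the acceptance script use: detector fidelity on
3 × 8 samples with 50 truth circs at base means 20–60; calibration on
1,000 null circs (dispersion 0.2, mean 10) and power on 50 planted
4-fold changes at mean 50 (8 vs 16 samples); scanner checks on 1,000
random sequence/seed pairs; field-effect ordering over 20 seeds of
3 × 4-sample studies with 40 circs. These sizes were chosen to make the
statistical bands tight enough to be meaningful while keeping a full run
in the minutes range on one core.

## Degenerate inputs and edge rules

* Zero-total circs: p = 1; all-zero matrices are an error ("no expressed
  features").
* Empty call sets, empty truth, `n_mirna = 0`: empty outputs of the
  right shape, never errors.
* Circs whose spliced sequence is shorter than the read are skipped with
  a warning at simulation; circs lacking a spliced sequence are skipped
  with a warning at sponge scanning.
* `fold_change_spec` naming an unknown circ, negative `slack`, unknown
  groups/config keys, query genes outside the enrichment background:
  immediate errors naming the offender.
* p-value ties in the exact test are compared with a `1 + 1e-10`
  relative tolerance so equal-probability outcomes are included in the
  tail deterministically.
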
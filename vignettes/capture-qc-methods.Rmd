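---
title: "Methods: how capqc evaluates a targeted capture experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how capqc evaluates a targeted capture experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capqc)
```

## The measurement model

A capture experiment is summarised against a *target design* `D`: a sorted,
disjoint, non-bookended set of genomic intervals in BED coordinates
(0-based, half-open). `capqc` builds `D` as the base-level union of one or
more annotation tracks, with `bedtools merge` default semantics: intervals
that overlap *or* abut (distance 0) become one region. The union is
computed with `IRanges::reduce`; the test suite checks it against an
independent boolean-mask oracle, position by position, on random toy
genomes.

Every downstream statistic is a function of the per-target-base depth
profile of one sample: each retained read adds one to every design base in
its span. Retained means mapped and not flagged as a duplicate — depth is
computed after duplicate removal, and the duplicate flag is taken from the
input (SAM flag 0x400 or the TSV column); a coordinate-based marker
(`mark_duplicates()`, fragments sharing sample/chromosome/fragment span
beyond the first) is provided for plain tables that carry no flags.
Depth is per-read, not per-fragment: overlapping mates double-count, as in
a naive pileup. No base- or mapping-quality filtering is applied. In the
SAM/BAM path the reference-consuming CIGAR extent defines the span; the
plain-table path treats reads as ungapped `[start, end)` spans.

From the profile:

- mean sequencing depth = (sum of depth over all target bases) /
  design size, *including* zero-depth target bases;
- a region is *completely covered at t* when every one of its bases has
  depth ≥ t ("minimum coverage t");
- `% target bp covered (t)` = design bases with depth ≥ t, as a
  percentage;
- specificity = reads overlapping ≥ 1 design base / denominator reads.

## Tunable parameters that matter

| parameter | default | why |
|---|---|---|
| depth thresholds `t` | 1 and 5 | 1 = sequenced at all; 5 = the usual minimum for variant calling |
| on-target predicate | ≥ 1 bp overlap | the common HsMetrics-style convention; `min_overlap` configurable |
| specificity denominator | `remaining` | "reads on target / total reads" is ambiguous in the field; retained reads is the stated default and `mapped` / `total` are switchable |
| padding `min_len` | 100 bp | capture chemistry performs poorly below ~100 bp |
| region consistency predicate | `complete` | "covered in all samples" read as *completely* covered at t; `mode = "any"` relaxes to any base |
| pooling subset | fraction 0.25, 10 replicates | emulates four barcoded libraries pooled in one capture |

Padding is **centered**: the deficit is split equally, the odd base goes to
the right, and windows sticking out of the chromosome are shifted back
inside before clipping, so every padded region reaches
`min(min_len, chromosome length)`. Commercial kits do not document their
padding direction; centering is this package's choice and is the only
behaviour implemented (the amount is configurable).

Rounding in reports is half-up at the precision conventional for each
table: 1 decimal for remaining-% and the consistency percentages, 2
decimals for region/base completeness percentages. Full-precision values
are always carried alongside (`*_raw` fields), so rounding never feeds back
into a computation.

## What the synthetic generator emulates

`sim_config()` states the world the package is tested in, modelled on a
well-performing exome capture: a two-chromosome 2 Mb toy genome; 200 target
regions of 100–300 bp (~2% of the genome, as exome designs are); four
barcoded samples of 30,000 paired 100 bp reads with N(300, 50) fragment
lengths; 90% of fragments on target (typical published specificity); 7%
duplicates among mapped fragments and 6% unmapped fragments (both in the
5–10% range seen in practice); and 2.5% of regions designated capture
dropout — regions that receive no on-target fragments in any sample,
emulating baits discarded by uniqueness screening. With these defaults one
sample reaches a mean target depth of roughly 40–70x depending on the
fragment geometry; the regime, not the exact depth, is the point.

Three generator choices are deliberate identifiability decisions rather
than realism:

- **Off-target placement is conditioned off the design.** A fragment
  declared off-target is placed uniformly on the genome *rejecting any
  overlap with the design*, and an on-target fragment is re-drawn (midpoint
  and length together) until **both** mates overlap the design. The
  on-target state of a retained read is then exactly
  Bernoulli(`on_target_fraction`) at the fragment level, so specificity
  recovery can be tested against binomial standard errors. Unconditional
  placement would bias read-level specificity both up (accidental
  off-target hits, ~2% of the genome) and down (mates of long fragments
  hanging entirely off short regions) by amounts comparable to the
  tolerance being tested.
- **Duplicates are generated, not re-detected.** With probability
  `duplicate_rate` a mapped fragment is an exact coordinate copy of a
  random earlier fragment of the same sample and its reads are flagged
  directly, making duplicates/mapped exactly binomial. Applying the
  coordinate-based marker instead would add birthday-collision
  false-positives (independent fragments landing on identical
  coordinates — hundreds at 50,000 fragments on a 40 kb target), which is
  why the marker is a separate utility for unflagged real tables, not part
  of the generator.
- **Seeding**: one master seed; `derive_seeds()` seeds a Mersenne-Twister
  stream with it and draws one child seed per consumer (design, dropout
  set, each sample, each pooling replicate). Identical config + seed gives
  byte-identical output files; the RNG state of the calling session is
  never disturbed.

The generator does **not** model base-level sequence content, quality
scores, sequencing error, GC or mappability bias, bait tiling or
hybridization thermodynamics. A green parameter-recovery test therefore
establishes that the *estimators* are correct and unbiased under the
stated sampling model — not that any real capture kit behaves this way.

## Pooling simulation

The informatic analog of pre-capture pooling: members are combined
(multiset union, sample identity preserved), and each replicate is a
uniform sample **without replacement** of `⌊fraction × N⌋` fragments —
mates kept together, mirroring paired-aware seqtk-style subsampling. The
fragment (read pair) is the sampling unit; sampling single reads would
break downstream pairing, so the read-level variant is not offered. Exact
subset size (rather than per-fragment Bernoulli) keeps replicate sizes
reproducible. Deltas are reported as mean-over-replicates minus
mean-over-members; positive means the pooled subsets do better. Under the
default regime the deltas are fractions of a percent of the design — the
package asserts they stay below 2% of totals, the directional claim that
pre-capture pooling costs essentially nothing informatically.

## qPCR arithmetic

Efficiency comes from a least-squares fit of Ct on log10(quantity);
replicate wells at one quantity are averaged before fitting (the common
lab convention; the alternative — fitting all wells — changes nothing for
balanced designs). `E = 10^(−1/slope)`, so a slope of −3.3219 cycles per
tenfold dilution gives E = 2, perfect doubling. Fits require ≥ 3 distinct
positive quantities and a negative slope; anything else is rejected as
non-physical rather than silently reported. Fold enrichment is `E^ΔCt`
with `ΔCt = Ct_pre − Ct_post`, and the pass rule is ≥ 10-fold per locus,
with the across-locus mean also reported.

## Degenerate inputs and numerical conventions

- Empty designs: `design_stats` returns zeros; depth and specificity on an
  empty design raise errors rather than returning 0/0.
- Reads on chromosomes unknown to the design are skipped with a warning
  and counted, never silently dropped.
- Per-chromosome specificity with a zero denominator is `NA`, not 0.
- Single-sample consistency is allowed with a warning: every base is
  either consistent or never covered, variable is structurally 0.
- Chromosome names are taken verbatim from inputs; no "chr" normalisation
  is attempted — mismatches surface as unknown-chromosome warnings or
  errors naming both sides.
- All randomised behaviour flows from explicit seeds; nothing reads the
  global RNG state without restoring it.

## Known limitations

- Depth is per-read; a fragment-level (mate-overlap collapsed) mode is not
  implemented.
- The plain-table path cannot represent gapped alignments; CIGARs are
  honoured only via SAM/BAM input.
- The coordinate duplicate marker is deliberately simple (exact fragment
  span equality) and will under-mark duplicates with trimmed or clipped
  ends.
- Never-covered regions are reported as coordinates only; annotating them
  against gene models needs external data and is out of scope.
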
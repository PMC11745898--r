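---
title: "The Scalable Variant Call Representation: model, operations, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Scalable Variant Call Representation: model, operations, and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcr)
```

## The problem

A project VCF (PVCF) stores a dense variant-by-sample matrix: one row per
variant site, one genotype record per sample per row. As cohorts grow, each
new sample brings previously unseen singleton sites, so the number of variant
sites $M(N)$ grows with the number of samples $N$, and the dense matrix holds
$N \times M(N)$ genotype records — super-linear growth, almost all of it
homozygous-reference calls repeated verbatim. On top of that, allele-indexed
FORMAT fields grow with the *global* allele count at a site: the R-numbered
allele-depth field AD linearly, and the G-numbered genotype-likelihood field
PL quadratically, even though a diploid sample observes at most two alleles.

The Scalable Variant Call Representation (SVCR) removes both non-linearities
with two devices inherited from the single-sample GVCF:

* **Reference blocks** — per-sample runs of homozygous-reference calls stored
  once, at their start locus, with a `LEN` field and summary `DP`/`GQ`. All
  blocks of a sample must be pairwise disjoint.
* **Local allele indexing** — per-sample allele-indexed fields expressed over
  the small list of alleles that sample observed. The injective map `LA`
  connects local indices to the site's global allele list (reference always
  at global index 0, and the first element of `LA` is required to be 0).
  `LGT`, `LAD` and `LPL` are the locally indexed genotype, depths and
  likelihoods; their lengths follow the `LA`/`LR`/`LG` Number laws
  (`expected_length()`).

The stored record count of a dataset is then (variant genotype entries) +
(reference blocks), which is exactly additive under merging — the structural
source of linear scaling.

## Dataset layout

`svcr_dataset` keeps the split layout: a reference-block matrix and a variant
matrix (site table with global allele lists + entry table with per-sample
local fields) over a shared sample list, plus `max_ref_block_length`, the
dataset-level bound used by point queries. `validate_dataset()` checks the
representation's invariants (sorted unique loci, block disjointness, LA
injectivity and leading zero, LR/LG length laws, the length bound) and
returns violations as data rather than raising.

Coordinates are 1-based inclusive throughout, matching VCF `POS`/`END`
semantics; a block starting at `POS` with length `LEN` covers
`[POS, POS + LEN - 1]`, and GVCF import computes `LEN = END - POS + 1`.
Contig order is taken from header contig declarations (first-appearance order
when absent). Ploidy is per-call, inferred from the genotype string's arity;
only haploid and diploid calls are supported, since the G-number formulas
(`n` and `n(n+1)/2`) cover those. Phase separators are preserved verbatim
through every conversion.

## Conversion and combining

`import_gvcf()` performs the three-step lossless conversion: add identity
`LA`, L-prefix the allele-indexed fields, derive `LEN` from `END`. Rows are
classified by genotype: a row whose called alleles are all 0 is a reference
row (a hom-ref row without `END` becomes a block spanning its reference
allele, preserving column sparsity). The sample-local `<NON_REF>` allele can
be retained (`retain`, needed for exact round trips) or dropped (`drop`, the
default for combining, since `<NON_REF>` is meaningless in a global allele
list); dropping removes its AD entry and every PL entry involving it and
renumbers the rest. `export_gvcf()` inverts the transformation and refuses to
export an entry whose `LA` is not the identity, because silently reordering
alleles would be lossy — after merging, use `subset_samples()` then
`prune_alleles()`, which renumbers kept alleles by first local appearance and
therefore restores identity maps for a single sample.

`merge_datasets()` implements N+K combining. Reference blocks pass through
untouched at their start loci. At shared variant sites, `unify_alleles()`
harmonizes references by right-extension (the merged reference is the longest
input reference; inputs whose reference is not a prefix of it are rejected as
disagreeing on the underlying sequence) and unions alternates in
first-appearance order (input rank, then the input's own order) — a
deterministic choice the representation itself does not prescribe. Merging is
therefore associative only up to allele order, and tests compare merge trees
through densified matrices or normalized allele keys (`trim_shared_suffix()`
reverses right-extension). Symbolic alleles (`<NON_REF>`, `*`) unify by exact
match and are never extended. `remap_genotype()` rewrites only the `LA` map;
the local fields are translation-invariant, which is the entire point of the
indirection. No genotype adjustment of any kind is performed.
`plan_hierarchical()`/`execute_plan()` provide the scatter/gather tree
(e.g. 100 000 inputs at fanout 100 → 1000 + 10 + 1 merge tasks); any tree
yields the same dataset as a flat merge up to allele order.

## Densification and block splitting

Resolving the sparse form back to dense rows uses the projections
`project_lad_to_ad()` (unobserved alleles get depth 0 — zero informative
reads, following the read-count semantics of the representation),
`project_lpl_to_pl()` (genotypes involving unobserved alleles have no
likelihood: missing by default, a numeric sentinel on request) and
`project_lgt_to_gt()` (phase preserved). Hom-ref calls synthesized from
blocks are `0/0` with the block's `DP`/`GQ` and no AD/PL, since blocks carry
only summary fields; the ploidy of synthesized calls is configurable
(default diploid everywhere — the representation does not address sex
chromosomes).

`densify_at_locus()` is the point query: the backward search for an
overlapping block is restricted to start positions within
`max_ref_block_length - 1` bases, which is exactly what the dataset-level
bound buys. `densify_stream()` is the forward pass holding one active block
per sample (disjointness guarantees uniqueness) and emits rows identical to
the point query at every variant site.

Two splitting strategies bound block length by parameter `K`.
`split_size_threshold()` replaces each block of length $L > K$ by
$\lceil L/K \rceil$ pieces (minimal inflation);
`split_fixed_period()` cuts blocks at genome positions $p$ with
$(p-1) \bmod K = 0$, so partition $p$ covers $[(p-1)K+1,\ pK]$ — the
boundary phase is anchored to 1-based coordinates, a choice the
representation leaves open. After a fixed-period split, every block lies
inside one $K$-sized partition, so a partition's dense sub-matrix is
realizable from its own rows alone. We cut existing blocks only, rather than
additionally storing a fresh block for every covered sample at every
boundary: the partition-containment guarantee is the same, at lower
inflation. Both strategies preserve per-base coverage exactly
(`coverage_map()` is the test oracle) and never merge adjacent blocks, even
when `DP`/`GQ` agree — splitting stays a pure refinement.

## SVCR-VCF serialization

`write_svcr_vcf()` emits VCF 4.3 with FORMAT fields `LGT`, `LA`, `LEN`,
`LAD`, `LPL`, `DP`, `GQ` (locally indexed fields use `Number="."` since 4.3
has no LA/LR/LG codes; the reader enforces the length laws semantically) and
the header key `MAXIMUM_REFERENCE_BLOCK_LENGTH`. We write `LA` with its
leading zero — not the draft-4.5 `LAA` dialect — and always write `LGT`,
preferring exclusively locally indexed fields. One row per locus in either
matrix; a row existing only for block starts carries `ALT="."` and the
reference base recorded at import (`N` for positions with no recorded
sequence). `LGT` on blocks is available behind a writer flag and omitted by
default. Output is byte-stable. The reader rejects genotypes carrying both
`LEN` and `LA`, a header bound smaller than an observed block, and FORMAT
data strictly inside another of the same sample's blocks.

Per-sample `gvcf_info` payloads and record-level provenance (ID/QUAL/FILTER,
FORMAT key order) survive GVCF import/export but are not serialized into
SVCR-VCF, which has no per-sample INFO channel; `datasets_equal()` therefore
compares the genetic content. For GT-only consumers,
`export_hardcalls_pvcf()` writes the dense GT-only PVCF; `export_dense_pvcf()`
writes the full dense form and is intended for small regions — its size is
super-linear by design.

## The synthetic cohort generator

`simulate_cohort()` emulates GATK-style whole-genome GVCFs at desk scale. Its
defaults are the stated world of the package's verification suite:

* **Sharing structure.** Every sample draws from one shared pool of variants
  whose frequency spectrum has density $\propto 1/f$, truncated to
  $[1/P, 0.5]$ — the simplest neutral-spectrum shape under which site
  discovery is sub-linear. A diploid sample carries pool variant $i$ with
  probability $1-(1-f_i)^2$, het/hom by Hardy–Weinberg. The realized site
  exponent depends on the spectrum (and, in real data, on ancestry mix), so
  tests assert only its range $(0,1)$, never a specific value.
* **Calibration.** The pool size $P$ is solved (by `uniroot`) so the expected
  nonreference record count per sample equals `k_variants_per_sample`
  (default 500 — a desk-scale stand-in for the 3–6 million of a real
  genome, over a 100 kb genome rather than 3 Gb).
* **Alleles.** 15% of pool variants are indels (length ≤ 3), reference bases
  come from a deterministic hashed genome so overlapping deletion alleles
  stay consistent across samples, and pool position collisions (up to 4
  alternates per locus) create the multiallelic sites that exercise allele
  unification. Carried variants overlapping a previous record's reference
  span are skipped; real callers emit `*` alleles there, which the
  representation passes through but the generator does not produce.
* **Coverage.** Non-variant positions are tiled with GQ-banded blocks
  (bands 99/45/15 with mean lengths 1000/300/150 bp and weights
  0.7/0.2/0.1, echoing GQ-binned GVCF output and high-coverage WGS); depths
  are Poisson with mean 30. PL is 0 exactly at the called genotype and GQ is
  the second-smallest PL capped at 99, so generated records are internally
  consistent. The generator covers the whole genome; uncovered/missing
  samples are exercised by hand-built fixtures instead.
* **Seeding.** One root seed; sample $i$ derives a child seed from
  $(\text{seed}, i)$, so a cohort is extensible — adding sample $N+1$ does
  not change samples $1..N$, mirroring incremental joint calling, and
  nested sub-cohorts of one large simulation are exactly what smaller
  simulations would produce (`scaling_sweep()` exploits this).

What a green scaling test establishes: with this generator,
`fit_loglog()` of stored record counts over $N \in \{8,...,128\}$ gives an
exponent within $[0.95, 1.05]$, dense genotype records $\ge 1.1$, and sites
in $(0,1)$. It does not establish real-data exponents (those depend on
ancestry mix and caller behavior), byte-level compressor behavior (bytes are
reported as informational only), or population-genetic realism — there is no
linkage, recombination or mutation model.

## Numerical and degenerate-input choices

* `genotype_index(j, k)` requires $j \le k$; callers canonicalize unordered
  pairs. Verified against brute-force enumeration of the VCF ordering for
  all allele counts ≤ 6, both ploidies.
* A reference block's optional `LGT` is validated for arity only, not for
  being hom-ref — the representation does not constrain its allele values.
* Inputs that disagree on the reference base at a locus are rejected rather
  than guessed (corrupt or reference-mismatched inputs).
* Per-sample `gvcf_info` is stored per sample and never merged across
  samples, so INFO key collisions cannot lose data.
* Empty datasets round-trip everywhere (empty record streams, header-only
  exports).

## Known limitations

Polyploid genotypes, structural-variant VCF semantics, and a third
"missing genotypes" table are out of scope. Computation directly on the
sparse representation (without densification) is not attempted. Tabix/BCF
are delegated to standard tooling; gzip-compressed text is read and written
natively. `export_gvcf()` under `retain` requires identity `LA` rather than
re-sorting a site's alleles per sample; a site-local reordering export could
lift this at the cost of a weaker losslessness guarantee.
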
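---
title: "Discovering sex-specific indel markers from a male/female assembly pair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering sex-specific indel markers from a male/female assembly pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexmarkr)
```

## The problem and the model

Many fish and other non-model vertebrates carry sex chromosomes that are
cytologically almost indistinguishable, yet harbour large (>100 bp)
insertion/deletion differences between the sex-limited and the shared
haplotypes. When both a male and a female assembly exist, those differences
are directly observable: align the two assemblies, catalogue every large
indel, and each one is a candidate sex marker that can be typed on an
agarose gel with a single PCR.

The gel logic rests on the ploidy of the system. In a male-heterogametic
system (XY-like, including multiple systems such as
X~1~X~1~X~2~X~2~/X~1~X~2~Y), a male carries both the shared and the
male-limited haplotype; a female carries only the shared one. A primer pair
flanking an insertion therefore amplifies **two** products in males (one
per haplotype, differing by the insert length) and **one** in females.
`sexmarkr` implements the whole discovery chain:

1. **Bidirectional whole-genome scan** (`bidirectional_scan()`): unique
   k-mer anchors, collinear chaining, variant calls from inter-anchor
   gaps, each assembly used as reference in turn.
2. **Large-indel screen** (`screen_large_indels()`): keep INS/DEL strictly
   longer than 100 bp.
3. **Functional annotation** (`classify_point()`,
   `attribute_deletion_bases()`) and **repeat attribution**
   (`attribute_repeats()`).
4. **Long-read depth ranking** (`locus_depth()`, `find_trough()`,
   `tier_markers()`): a deletion that is truly hemizygous shows near-zero
   long-read depth when reads from the heterogametic sex are mapped to the
   reference carrying the locus.
5. **Bulk primer design** (`batch_design()`) with nearest-neighbor melting
   temperatures.
6. **Electronic PCR** (`predict_amplicons()`, `screen_single_band()`,
   `predict_band_pattern()`): genome-wide binding-site search, amplicon
   enumeration, gel-band collapse and the single-band screen.
7. **Marker catalog** (`build_markers()`): one ranked table with all
   evidence.

## The scan: anchors, chains, calls

The aligner is a transparent MUM-style procedure. Anchor seeds are k-mers
(default k = 21) that occur exactly once in each genome (both query strands
considered); runs of diagonal-consecutive seeds merge into maximal exact
anchors. Seed uniqueness can drop out in the middle of a perfect match when
a k-mer happens to recur elsewhere, so same-diagonal runs are rejoined
whenever the intervening sequence verifies as an exact match — without this
the anchors would not be maximal and breakpoints would blur.

Chaining is a weighted longest-increasing-subsequence over reference order
with query monotonicity; anchor length is the weight, ties break to the
leftmost reference then query start so results are deterministic. Chains
spanning less than `min_align_len_var_bp` are kept but not callable,
mirroring the separate coverage/calling alignment-length floors of the
published parameter set.

For each adjacent anchor pair with reference gap `g_r` and query gap `g_q`:
`g_q − g_r ≥ 1` with `g_r ≤ batch_size_bp` is an insertion of length
`g_q − g_r`; the symmetric case is a deletion; equal positive gaps are a
substitution; events whose two gaps both exceed `batch_size_bp` are flagged
`complex`. Internally every coordinate is 0-based half-open; files render
1-based inclusive positions (a deletion whose flanks end at 1-based `x` and
resume at `y` spans `[x+1, y−1]`, length `y − x − 1`).

Two published thresholds deserve comment. The ">100 bp" size cut is
implemented strictly (`length ≥ 101`); an `inclusive` switch exists because
the boundary is genuinely ambiguous in common usage. The "one in a
thousand" divergence setting of the original tool has no published
definition; it is surfaced as the documented `diff_per_kb` field but the
exact matcher does not need it.

## Depth ranking

Depth input is a plain per-base TSV so any aligner/depth tool can feed it.
A deletion's window is the deleted interval itself; an insertion's window
is its breakpoint ±250 bp (the breakpoint has no width on the reference, a
fixed flank captures spanning coverage). Missing positions count as zero —
for a hemizygous deletion, absence of coverage is signal, not missing data.

The locus-depth histogram (default bin 1.0×) is smoothed with a 3-bin
centred moving average; the trough is the first local minimum after the
first peak whose dip is ≥5% of that peak. On two-component cohorts (true
hemizygous loci near the mismapped background; everything else near genome
coverage) this lands between the component means; on a unimodal histogram
it correctly returns nothing and all markers tier `standard`. All three
parameters are exposed because only the resulting cuts, not the procedure,
are ever published; a manual `trough_override` reproduces any published
cut exactly.

## Primer design and electronic PCR

Candidates are enumerated from a 600-bp window on each side of the variant,
with primer3-like defaults: 18–27 nt (optimum 20), Tm 57–63 °C (optimum
60), GC 30–70%, homopolymers ≤4, no self-complementary 3′ run ≥5 bp, no
hairpin stem ≥6 with loop ≥3. Melting temperatures use the unified
nearest-neighbor thermodynamic parameters with the monovalent-salt entropy
correction and a CT/4 concentration term (50 mM Na⁺, 250 nM primer). The
admissible pair minimising `|Tm−60| + 0.5·|len−20| + 10·|GC−0.5|` summed
over both primers wins; ties go to the smaller product then the leftmost
forward primer, so the catalog is reproducible byte for byte. The only
externally anchored constraint is the 100–2,000 bp product window — the
range a standard agarose gel resolves.

e-PCR matches primers exactly by default (sites are searched with
`Biostrings::matchPattern()`; mismatch tolerance exists for
cross-population checks, with the 3′-terminal 3 bases always exact, and
`N` never matches). Product length is the 5′-to-5′ span inclusive of both
primer footprints — the band a gel shows. Amplicon lengths collapse into
one band when they differ by at most `max(10 bp, 2%)`, an approximation of
agarose resolving power. A marker passes the single-band screen when each
assembly yields exactly one band, both in the product window, differing by
more than the gel resolution.

The heterogametic sex's predicted pattern is the collapse of the union of
amplicons from **both** assemblies — the explicit model of a diploid that
carries both haplotypes. A marker is diagnostic when the two sexes' band
counts differ.

## What the synthetic data emulate — and what they do not

`simulate_genome_pair()` draws a female-like genome i.i.d. at GC 0.41
(typical of teleost assemblies) and derives the male genome by planting
indels. Defaults are the package's reference study conditions: two 500-kb
chromosomes, 10 insertions + 10 deletions of 101–2,000 bp, at least 5 kb
apart, repeat-free, seed 42. Planted breakpoints are made
alignment-stable (the allele's edge bases differ from the flanking base),
so exact breakpoint recovery is well-defined. Optional TE-library copies
and tandem arrays exercise repeat attribution and anchoring under
repeats. Depth simulation places Poisson read starts with lognormal
CLR-like lengths (mean 8 kb) along the source genome and projects them
through the true coordinate map; reference bases absent from the source
sex receive only a 5% mismapped background — which is why real hemizygous
loci sit at low-but-nonzero depth rather than zero.

Real assemblies differ in ways the generator deliberately omits: genuine
repeat landscapes and segmental duplications (which defeat unique-k-mer
anchoring locally), assembly errors and gaps, polymorphism within sexes,
inversions and translocations, and GC-dependent coverage bias. Passing the
synthetic suite therefore demonstrates correctness of the machinery, not
that recall on a real genome pair will be perfect; on real data the
external-aligner escape hatch (`read_paf()` feeding `chain_anchors()`) and
the cross-validation intersection (`intersect_external_calls()`) are the
intended guards.

## Numerical conventions and degenerate inputs

Printed percentages round half-up to two decimals throughout
(`round_half_up()`), matching how such tables are conventionally printed;
note 48/4,422 = 1.0855 → 1.09 under this rule. Region precedence when
features overlap is CDS > 5′ UTR > 3′ UTR > intron > intergenic —
annotation formats do not make the choice for us, and CDS-first maximises
functional interpretability; deletion-base attribution conserves length
exactly by construction. TE attribution uses a majority-overlap rule
(≥50% of allele bases inside masked intervals). Tandem detection is a
shift-identity heuristic (some period `p` aligning the allele with itself
at ≥80% identity over ≥50 bp or 80% of the allele); it stands in for a
full tandem-repeat finder and its thresholds are exposed. Empty catalogs,
annotation-free runs (everything intergenic, logged) and troughless
histograms all degrade explicitly rather than erroring.

Scan problem sizes in the tests — two 500-kb chromosomes and 100-kb e-PCR
oracle genomes — were chosen as the smallest scales at which every stage
(anchor dropout rejoining included) is genuinely exercised; all stages are
linear or near-linear in genome length except candidate enumeration in
primer design, which is bounded by the flank window.

## Known limitations

* The scan calls INS/DEL/SUB only; inversions, translocations and
  duplications are out of scope (an external caller's catalog can be
  intersected instead).
* Unique-k-mer anchoring goes blind inside long perfect repeats; variants
  there are recovered only if flanked by unique sequence within the chain
  gap limit.
* Dimer/hairpin screening is complementarity-run based, not a full
  secondary-structure energy model — adequate for screening, not for
  quantitative multiplexing.
* The depth model treats reads as intervals; no mapping-quality or
  GC-bias modelling.
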
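---
title: "Methods: auditing and designing P35S screening assays in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing and designing P35S screening assays in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliscreen)
```

## The problem

PCR screening assays for genetically modified organisms target sequence
elements shared by many transgenic constructs, most prominently the
Cauliflower mosaic virus 35S promoter (P35S). The promoter actually
carried by a given event is rarely identical to the CaMV genome: vector
construction truncates it, breeding introduces point substitutions, and
"double enhancer" constructs tandem-duplicate the enhancer sub-region.
An assay whose primer lands outside the fragment an event carries
amplifies nothing (a false negative); a SNP under a primer's 3' end or
under the probe degrades efficiency enough to spoil quantification.

`ampliscreen` provides the in-silico half of assessing and fixing this:
mapping promoter fragments onto the reference coordinate frame,
profiling conservation across a panel, extracting SNP-free conserved
segments, auditing published primer/probe sets against a panel,
designing new sets confined to the conserved segments, and computing
the qPCR statistics (standard curves, efficiency, ENGL criteria,
replicate precision, LOD/LOQ) by which a quantitative method is judged.

All coordinates are 1-based and inclusive, the convention of published
assay tables; the interval 7148-7342 therefore has length
`7342 - 7148 + 1 = 195`.

## Mapping and conservation

Fragment-to-reference mapping (`map_fragment()`) uses local affine-gap
alignment (match +2, mismatch -3, gap open -5, gap extend -2 — classic
blast2seq-era defaults, exposed in `align_params()`). The best local
alignment becomes a segment; unaligned overhangs of at least 50 bp are
re-aligned recursively, so a tandem-duplicated head appears as a second
segment. Two segments overlapping by 50 bp or more on the reference
trigger the double-enhancer call; published tables give only the
double-interval notation, so the 50 bp rule is this package's
quantitative codification and sits in `map_params()`.

Raw Smith-Waterman ends are untrustworthy at duplication junctions and
truncation points: the optimum happily extends a few chance matches
past the junction and reports phantom mismatches. Segment ends are
therefore trimmed back until they terminate in at least 8 consecutive
matches (`end_anchor`). The synthetic generator in turn never plants
edits within 12 bp of a fragment end — a terminal mismatch is
genuinely invisible to local alignment, not a defect of either side.

Conservation (`build_profile()`) is reference-anchored: each target is
pairwise-projected onto the reference rather than passed through a full
multiple alignment. This matches the pairwise-then-inspect workflow
that produced the published panel tables and keeps the cost linear in
panel size. Coverage is counted per distinct target (for the coverage
threshold) and per segment copy (so duplicated enhancers are visible).

`find_conserved_intervals()` scans left to right for maximal runs where
the coverage fraction is at least `min_coverage_fraction` (default 1:
present in every panel member) and the density of distinct variant
positions is at most `max_snp_density` (default 6/195 per bp, the
density of the P35S conserved region). Within an interval, SNP
positions partition it into SNP-free segments — the design space.

## Auditing assays

The binding-site scanner (`scan_oligo()`) is deliberately ungapped: a
primer that only fits a template with an indel is treated as not
binding, which reflects the observed failure modes (missing or shifted
binding sites cause outright non-amplification; point SNPs cause
inefficiency). Every placement on either strand with at most
`max_mismatch` mismatches is reported, with each mismatch's offset from
the oligo 3' end (offset 1 = terminal base). No mismatch threshold for
"binding" is standard in the literature; the default of 3 is a policy
value (`scan_policy()`), always reported, never silently applied.

Pairing is orientation-agnostic because published "forward/reverse"
labels do not consistently map to genome strands (several collected
assays print their forward primer downstream on the minus strand).
`predict_amplicons()` enumerates all inward-facing plus/minus site
pairs up to `max_product` (default 2000 bp); duplicated-enhancer
targets legitimately yield one product per copy — the basis of the
quantification-bias warning for such events — plus long cross-copy
pairings that matter only for conventional PCR. Nested assays are
evaluated pairing by pairing with the smallest product flagged as the
scored one.

`classify_coverage()` maps the audit onto three outcomes. NOT_COVERED
(predicted "fail"): a primer has no site or no inward pair forms.
Otherwise "inefficient" when a primer mismatch sits within the critical
3' window (default 4 bases — the documented failure configurations
involve offsets 2 and 3), when the probe carries 2+ mismatches, or when
the probe has no ungapped site at all (an indel under the probe);
otherwise "amplify". The three-level rule is a heuristic codification
of qualitatively described behaviour (normal curves, shallow slopes, no
gradient change); both thresholds are policy values.

## The synthetic coordinate frame and panel

Offline operation is a design requirement, so the package never
downloads sequences. Instead, `synth_reference_from_assays()` builds a
synthetic reference on which every printed oligo spells its printed
sequence at its printed interval (reverse-complemented on the minus
strand), bases flagged as mismatching the reference yielding to
unflagged oligos wherever both cover a position. Across the 25 bundled
assays this reconstruction is conflict-free, which is itself a
consistency check of the transcribed table. Uncovered positions are
seeded random fill. The result is explicitly a stand-in: correct for
every coordinate, binding-site and amplicon computation the toolkit
performs, not a reconstruction of the true genome.

`example_panel()` derives twelve synthetic targets from that frame,
emulating the published panel's variation structure: window extents
(including exact anchors at 7148 and 7342), four double-enhancer
layouts sharing their reference start, and SNPs inside and outside the
conserved region. SNP counts inside the conserved region are scaled to
six distinct union positions so that the default density threshold is
met exactly; members like the Bt176 fragment that do not cover the
conserved region are not part of the design panel, since a
coverage-fraction-1 criterion would otherwise be unsatisfiable — in
the published table that row's conserved-region columns are likewise
blank. Passing tests on this panel demonstrate the pipeline's
arithmetic and recovery behaviour, not concordance with the true
per-event alignments, which would require the deposited sequences.

`make_panel()` generates fully random panels with a truth ledger for
property-style testing: seed-deterministic, one guaranteed
double-enhancer target, one edit-free target, two anchor targets
abutting the protected window, insertions capped at 10 bp (observed
insertions in the motivating data are 2 bp) and kept 7 bp away from
SNPs, whose adjacency is alignment-degenerate.

## Designing primer/probe sets

`enumerate_candidates()` exhaustively enumerates (forward, probe,
reverse) window triples wholly inside SNP-free segments, under
`design_constraints()`: primer length 18-27 nt, probe 13-30 nt,
amplicon 60-200 bp, GC 20-80%, no probe 5' G, no reverse-complement
run longer than 8 between or within oligos of a set.

Melting temperatures use the unified nearest-neighbor model
(`tm_nearest_neighbor()`: enthalpy/entropy sums, terminal initiation
terms, entropic monovalent-salt correction, two-state formula at 50 mM
Na+ and 200 nM oligo). Two scale facts drive the feasibility windows.
First, this scale reads several degrees below the vendor calculators
behind the nominal 60/70 C targets, hence the primer tolerance of 6 C
about 60 C. Second, minor-groove-binder stabilisation is not modeled:
a 15-nt MGB probe reads roughly 15 C below its effective hybridisation
temperature. Probes no longer than 18 nt (the MGB synthesis regime)
are therefore credited a 15 C offset on their *effective* Tm, which
must lie within 5 C of 70 C. This is what lets the short probes that
fit between SNPs in a fragmented conserved region compete with
conventional 25-30 nt hydrolysis probes — exactly the design situation
the conserved-region method faces.

The penalty is a weighted sum of Tm deviations (1 per degree C,
probes on effective Tm), mean GC deviation from 50% (0.5 per percent)
and amplicon deviation from 100 bp (0.05 per bp). The published
conserved-region set was selected empirically, so the penalty's role
is ordering, not reproduction of that choice; `verify_candidate()`
supplies the decisive property ("universal": every oligo binds every
panel member exactly and every member yields a product), and
`rank_candidates()` puts universal candidates first, then ascending
penalty, ties broken by smaller amplicon then leftmost forward start.
On the bundled panel the enumeration over the 7148-7342 segments
returns about 4.2 million feasible triples (about half a GB as a data
frame; `top_candidate()` verifies lazily in penalty order for large
sets), and the published set — forward 7204-7226, probe (reverse
complement) 7268-7282, reverse 7308-7328, amplicon 125 bp — is among
them and verifies universal.

## qPCR statistics

`fit_standard_curve()` regresses Ct on log10(copies) over all replicate
points (per-level means optional — sources rarely state which; both
give identical slopes in balanced designs). Efficiency is
E = (10^(-1/slope) - 1) x 100; a slope of -3.3219 (perfect doubling) is
100%. `engl_verdict()` applies the ENGL minimums with inclusive
boundaries: -3.6 <= slope <= -3.1 and R^2 >= 0.98.

`replicate_stats()` uses the sample (n-1) standard deviation — the
published tables do not state the denominator, but their RSD cells
reproduce from printed mean/SD under either at the printed precision —
and follows the table convention of withholding statistics unless every
replicate amplified. The LOD is the lowest all-positive level with all
higher levels all-positive; a non-monotone hit pattern warns and the
LOD stays above the violation. Two LOQ rules are implemented and
neither is silently preferred: the RSD-threshold rule (lowest
all-positive level with RSD <= 25%) and the LOD-multiple rule
(factor x LOD, default 5) used by measurement-guidance documents; on
the bundled sensitivity table they give 10 and 50 copies respectively,
the spread the published discussion reflects.

## Numerical choices and problem sizes

Deterministic tie-breaking throughout: alignment traceback is
delegated to one aligner with fixed parameters; candidate ordering and
interval extraction are defined to be permutation-invariant; every
stochastic component takes an explicit integer seed. Property-style
tests run at sizes chosen to exercise the estimators' stated accuracy:
500 fuzzed scanner cases against a brute-force Hamming oracle, 200
random pairs against an independent DP oracle, 200 synthetic panels
for planted-truth recovery (SNP lists, duplication flags, conserved
window — 99% bar, allowing alignment-degenerate placements), 50
panels for design recovery, and 10 seeded replicate simulations per
truth value for efficiency recovery (the single-draw sampling SD at 5
levels x 3 replicates x 0.1 Ct noise is ~0.8 efficiency points, so the
1-point accuracy claim is asserted on the mean absolute error).

## Limitations

- The reference and panel shipped for examples are synthetic
  stand-ins; per-event identities and SNP coordinates of real deposited
  sequences require those sequences as input (any FASTA/GenBank file
  works with `read_fasta()` / `read_genbank_minimal()`).
- The scanner is ungapped and the audit thermodynamics-free: no duplex
  stability, dimer energetics, or fluorescence chemistry — mismatch
  position is the only efficiency proxy.
- The Tm model is monovalent-salt nearest-neighbor; divalent cations
  and MGB moieties enter only through the documented offsets.
- Quantification of unknowns against a curve is out of scope; the
  double-enhancer overestimation hazard is surfaced as a
  multiple-product flag in the audit summary instead.
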
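# ampliscreen

In-silico auditing and design of PCR screening assays for promoter
variant panels, built around the problem of detecting the Cauliflower
mosaic virus 35S promoter (P35S) across genetically modified crops.

The P35S promoter carried by a transgenic event is often not the CaMV
reference sequence: fragments are truncated, carry SNPs, or
tandem-duplicate the enhancer sub-region ("double enhancer"). A
screening assay whose primer binds outside the fragment an event
actually carries yields a false negative; a SNP near a primer's 3' end
or under the TaqMan probe degrades amplification efficiency. This
package audits assays against a panel of target sequences, finds the
conserved SNP-free segments that universal assays must target, designs
and ranks new primer/probe sets confined to them, and computes the
qPCR validation statistics by which a quantitative method is accepted.

All coordinates are 1-based, inclusive: an interval `[s, e]` contains
`e - s + 1` bases, and an amplicon spans from the leftmost primer
start to the rightmost primer end.

Core quantities:

- **Binding site**: an ungapped placement of an oligo on either strand
  of a target with at most `max_mismatch` mismatches; each mismatch is
  annotated with its offset from the oligo 3' end (offset 1 = terminal
  base). Mismatches with 3' offset <= 4 predict inefficient
  amplification.
- **Conserved interval**: a maximal reference interval covered by the
  required fraction of panel members (default: all) with distinct-SNP
  density at most 6/195 per bp; its SNP positions partition it into
  SNP-free design segments.
- **Standard curve**: ordinary least squares of Ct on log10(copies);
  efficiency E = (10^(-1/slope) - 1) x 100; ENGL acceptance requires
  -3.6 <= slope <= -3.1 and R^2 >= 0.98.
- **LOD / LOQ**: lowest all-positive dilution level (with all higher
  levels all-positive) / lowest level meeting an RSD threshold, or a
  fixed multiple of the LOD.

The package ships the table of 25 published P35S assays (M1-M24
collected from the literature and standards, plus the conserved-region
TaqMan set M25) as a plain-TSV fixture, and generates — it never
downloads — a synthetic reference frame and a twelve-member synthetic
promoter panel emulating the published variation structure. Everything
stochastic takes an explicit seed.

## Worked example

```r
library(ampliscreen)

assays <- p35s_assays()          # the 25 bundled assay definitions
assays$M25
#> <assay> M25 (taqman), 3 oligos, reported amplicon 125 bp
#>   forward  35SEF                  CATCATTGCGATAAAGGAAAGGC  [7204-7226]
#>   reverse  35SER                  TGCTTTGAAGACGTGGTTGGA  [7308-7328]
#>   probe    35SEP                  TCGTGGGTGGGGGTC  [7247-7268]

ex <- example_panel()            # synthetic reference + 12-member panel
map_fragment(ex$panel[ex$panel$event == "MON88913", ], ex$ref)
#> <homology_report> MON88913/1: 7090-7344,7090-7347  identity 100%  SNPs 0  double enhancer
```

The MON88913 cotton layout — a P35S fragment confined to reference
interval 7090-7347 with a duplicated 7090-7344 head — is the acid test
for the collected assays. Auditing all of them against such a target
with exact binding (`max_mismatch = 0`):

```r
tgt <- derive_variant(ex$ref,
                      variant_spec(7090, 7347, dup_start = 7090,
                                   dup_end = 7344),
                      event = "MON88913like")
cm <- coverage_matrix(assays, tgt, scan_policy(max_mismatch = 0))
cm$summary[cm$summary$n_fail == 0, ]
#>    assay_id n_fail n_inefficient n_amplify n_multiproduct
#> 2        M2      0             0         1              1
#> 12      M12      0             0         1              1
#> 18      M18      0             0         1              1
#> 25      M25      0             0         1              1
```

21 of the 24 collected assays are predicted to fail outright (at least
one primer has no binding site inside the fragment); only the assays
confined to the conserved region survive, each — note
`n_multiproduct` — amplifying once per enhancer copy, the reason
double-enhancer events risk overestimated GMO content. The conserved
region itself, recovered from the panel
(`find_conserved_intervals(build_profile(map_panel(ex$panel, ex$ref), ex$ref))`),
is reference interval 7148-7342: 195 bp, six SNP positions, seven
SNP-free segments, inside which `enumerate_candidates()` places the
M25 oligo triple among its feasible candidates and
`verify_candidate()` confirms it universal on the panel.

The qPCR side, from the bundled published summaries:

```r
efficiency_from_slope(-3.411)    # GTS-40-3-2 standard-curve slope
#> [1] 96.41
tab <- qpcr_sensitivity_table()
call_lod(tab[tab$event == "GTS-40-3-2", ])
#> [1] 10
call_loq(tab[tab$event == "GTS-40-3-2", ], "factor")
#> [1] 50
```

## Command line

A thin script over the same functions is installed under `exec/`:

```sh
ampliscreen simulate --seed 7 --n 8 --length 3000 --conserved-window 1200:1400 --out sim/
ampliscreen audit --assays assays.tsv --targets panel.fasta --out audit/
ampliscreen qpcr --table ct_values.tsv --out qpcr/
```

Subcommands: `simulate`, `map`, `conserve`, `audit`, `design`, `qpcr`.
Every run writes a `manifest.json` recording inputs, options and seed.

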
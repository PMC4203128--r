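---
title: "Methods: plant small-RNA processing and miRNA discovery in mirforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plant small-RNA processing and miRNA discovery in mirforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mirforge re-implements, as a tested and reusable pipeline, the standard
genome-wide plant microRNA discovery workflow: raw small-RNA reads are
quality-filtered, trimmed, collapsed to unique tags, screened against
structural ncRNA/repeat/organelle references, split into conserved calls
(by mismatch-bounded matching to a known mature set) and novel candidates
(by genome mapping, precursor excision, folding, and a deterministic
criteria checklist), clustered into families, annotated by genomic
context, matched to transcript targets by complementarity penalty, and
quantified across tissues after median-of-ratios normalization. A
synthetic-data generator plants hairpin loci with exact truth so every
stage can be validated end to end without downloads.

This vignette records the models, parameter choices, and numerical
decisions; it states no empirical result beyond what the package's tests
and `scripts/acceptance.R` themselves compute.

## The synthetic study

`sim_config()` defaults define the reference conditions used throughout
the tests: a 100 kb i.i.d.-uniform ACGT genome, 20 planted hairpin loci
(random strand, non-overlapping, 20 bp flank clearance), three tissue
libraries, exact per-tissue counts, constant Q30 qualities, and no
contaminant/jitter/mutation noise. Noise of each kind (stem mutations as
G:U wobbles or mismatches capped at 20% of stem pairs, contaminant reads
drawn from synthetic rRNA/tRNA/plastid sources, ±1 nt end jitter, a
low-quality read fraction, lognormal count sampling) is injectable but
off by default, so that zero-noise recovery is an exact, decidable
property.

Planted mature sequences are 20-24 nt with the 21-nt class most frequent
and a 5' uridine bias (0.6), matching the signature DCL1/AGO1 profile of
plant miRNA catalogues. Per-tissue counts cycle through four fixed
patterns — uniform 40, single-tissue 5000, preferential (800, 20, 20),
uniform 15 — chosen to cover the specificity categories and a realistic
order-of-magnitude dynamic range while keeping every locus at or above
the 10-read support threshold. Five loci are mirrored into a synthetic
known-miRNA set (half verbatim, half with one substitution) to exercise
the conserved branch; two further loci carry a 3-nt-longer variant of a
conserved mature — outside the 2-mismatch conserved radius but inside
the 90% family-identity radius — to exercise novel-isoform relabeling.

What the generator does *not* emulate: sequencing error models, ligation
bias, repeat-rich genomes (a repeat screen is exercised with synthetic
contaminant sources instead), multi-chromosome assemblies, and isomiR
spectra beyond ±1 nt. Passing tests therefore demonstrate algorithmic
correctness on idealized data, not robustness to every artifact of real
libraries.

### Hairpin geometry

`build_hairpin()` constructs `mature + loop + revcomp(mature) + 2 nt pad`
(5p arm) or `revcomp(mature) + loop + mature` (3p arm), with an
8 nt adenosine loop by default. The star strand follows the canonical
duplex rule: it spans the pairing partners of all but the last two mature
bases, extended two bases past the partner of the mature 5' end, so both
strands carry 2-nt 3' overhangs. For the 5p construction the pad supplies
the star overhang; for the 3p construction the overhang extends into the
loop, exactly as in genuine 3p-arm precursors.

## Preprocessing rules

A read is discarded when more than 30% of bases fall below Phred 20 (the
standard small-RNA QC rule), when it contains N (the underlying QC tool's
behaviour for Ns is unspecified, so the conservative choice is made), or
when it is empty. Trimming removes everything from the leftmost exact
match of a ≥6 nt adapter prefix, then a trailing run of ≥8 A's; reads
with no adapter match are kept untrimmed and flagged, since upstream
demultiplexing may pre-trim. Collapsing merges identical inserts with
summed counts and retains 18-30 nt; per-sample tag tables are merged only
at discovery, preserving per-sample counts.

## Folding

Two folders over nested canonical-pair structures (AU/UA/GC/CG/GU/UG,
hairpin loops ≥ 3 nt) are implemented in C++:

* `fold_maxpair()` — Nussinov maximum-cardinality pairing, with a
  deterministic traceback (each 5' base takes the smallest admissible
  partner) so dot-brackets are reproducible.
* `fold_energy()` — Zuker-style free-energy minimization under a reduced
  nearest-neighbor model: 16 Watson-Crick stack energies (Turner-style
  values), a flat −1.0 kcal/mol for wobble-containing stacks,
  hairpin/bulge/internal loop penalties by length with
  Jacobson-Stockmayer extrapolation, interior loops capped at 30
  unpaired bases, and a linear multiloop cost (3.4 close + 0.4 per
  branch). The open chain is the 0 kcal/mol reference. The table ships
  as an editable TSV (`energy_params()`).

Absolute energies approximate, rather than bit-match, a full
thermodynamic folder: dangling ends, coaxial stacking, sequence-dependent
loop terms, and wobble-stack detail are omitted. The −20 kcal/mol
precursor-stability figure is a reporting statistic in this pipeline,
never a hard filter, so the approximation is acceptable; the energy
table's symmetry guarantees that a perfect stem and its reverse
complement score identically.

**Which fold drives candidate evaluation.** The criteria checklist needs
the mature strand's pairing partners inside a 250 bp window that is
mostly random flank. Maximum-pairing optima on such windows are massively
degenerate — random RNA pairs most of its bases — and a deterministic
traceback can legitimately route mature-arm partners into the flanks,
destroying the duplex anatomy. The stacked helix of a genuine precursor,
by contrast, dominates the free-energy landscape. Candidate evaluation
therefore folds in energy mode by default (`discovery_thresholds()`);
max-pair mode remains available and is the mode pinned against the
enumeration oracle.

## The randomization test

`shuffle_pvalue()` implements the RANDfold-style empirical test:
`n_shuffles` dinucleotide-preserving shuffles (Altschul-Erickson Eulerian
walk), each folded, with the add-one p-value
`(1 + #{null at least as stable}) / (n + 1)`. "At least as stable" means
free energy ≤ observed in energy mode, pair count ≥ observed in max-pair
mode. The default of 99 shuffles is the smallest round count that
resolves p ≤ 0.05 with margin (the original study does not report its
shuffle count); at least 19 are required or the 0.05 threshold is
unreachable. Homopolymers have a single dinucleotide-preserving
arrangement, so their p-value is exactly 1.

The test runs on the putative precursor span (hairpin plus 5 nt padding),
not the whole 250 bp window — the window's random flanks would dilute the
signal and triple the cost.

## The criteria checklist

Candidate evaluation replaces the probabilistic log-odds score of the
original discovery tool with a deterministic pass/fail checklist of the
criteria that tool encodes; every verdict is recorded per candidate:

| verdict | rule |
|---|---|
| `arm` | mature wholly inside one arm, not the loop |
| `duplex14` | ≥ 14 paired positions between mature and star |
| `no_bifurcation` | exactly one hairpin loop in the mature-to-star span |
| `overhang_star` | a 2-nt 3'-overhang-consistent star is derivable from the fold |
| `len_diff6` | mature/star length difference ≤ 6 nt |
| `randfold` | shuffle p ≤ 0.05 |
| `dicer` | ≥ 50% of locus reads share the mature 5' start |
| `min_reads` | ≥ 10 reads summed over samples |

Star derivation tolerates up to 2 nt of unpaired anchor slack
(offset-compensated) so a single terminal mismatch does not void the
geometry. Star-read presence and seed conservation are recorded as
confidence flags, not gates — the source tool treats them as score
components, and the text enumerates criteria rather than score
arithmetic. The Dicer threshold of 0.5 quantifies "consistency with
Dicer processing", which is named but not numerically specified anywhere;
conserved-matched tags are passed back into the locus read stack as
context so that star reads at conserved loci face the correct
denominator. The minimum free energy of every candidate precursor is
computed and reported (with the fraction below −20 kcal/mol summarized),
but never filtered on.

Excision takes two 250 bp windows per mapped tag (tag 20 bp from the 5'
end, tag 20 bp from the 3' end), clipped at chromosome bounds,
reverse-complemented for minus-strand loci. Genome mapping is exact
full-length matching on both strands; tags with more than 15 placements
are excluded from novel prediction (the original run's multi-mapping
policy is unreported).

## Families, context, targets

Family clustering is greedy incremental: calls sorted by total count
(descending, ties lexicographic), each unassigned call either joins the
first seed with best-offset ungapped identity ≥ 0.90 (matches / shorter
length) or seeds a new family. Conserved members impose their reference
family name; novel calls landing in such families are relabeled
`novel_isoform`. The identity threshold mirrors common CD-HIT practice
for mature miRNAs.

Genomic context is classified with precedence CDS > UTR > intron
(intron = gene overlap without CDS/UTR overlap); intergenic means no gene
overlap. Tandem clusters are maximal runs of ≥ 2 loci with consecutive
gaps ≤ 10 kb.

Target prediction scores every ungapped or single-1-nt-gap alignment of
the miRNA against each transcript's reverse complement: mismatch 1.0,
G:U 0.5, gap 2.0, doubled at positions 2-13 from the miRNA 5' end; hits
require penalty ≤ 2.5; any non-match at positions 10-11 predicts
translational repression instead of cleavage. Only the cutoff is fixed by
the analysis being reproduced; the weight table follows the conventions
of the public plant-target server at defaults and ships as configuration.
Target-site accessibility (opening-energy) scoring is deliberately out of
the default pipeline — it requires partition-function folding.

## Expression

Size factors use the DESeq median-of-ratios convention: for rows positive
in every sample, `exp(median(log(count) − log(geometric mean)))` per
sample. The log-scale median is reciprocal-consistent, which makes the
normalized two-sample median ratio exactly 1; for three or more samples
the pairwise median ratio is only approximately 1 (medians of ratios do
not compose), which is why the property test pins the two-sample
identity. Rows containing zeros are excluded from the median; a
pseudo-count mode lifts degenerate fixtures.

Abundance categories are half-open order-of-magnitude bins at 10 / 100 /
1000 / 10000 normalized counts (the five labels are standard; the
breakpoints are not published, so they are configurable). Specificity
calls use three knobs, all reconstructions of a ranking method that is
cited rather than described: detection threshold 10 (normalized),
preferential when top ≥ 2 × second, specific when the top fraction is
≥ 0.90 *and* every other tissue is below detection. Ubiquitous calls are
returned with their log2(x+1) variance so the lowest-variance rows can
be short-listed as qPCR normalizer candidates.

qPCR quantification is the standard ΔΔCT: per-sample mean CT minus
reference-gene (U6) mean CT, re-based to a calibrator sample,
RQ = 2^(−ΔΔCT), with replicate SD propagated as
sqrt(sd²_target + sd²_ref). Cross-platform agreement is the Pearson
correlation of log2(normalized + 1) against log2(RQ) over matched pairs.
Because RQ is calibrated per target while sequencing abundance is
absolute, the pooled correlation is diluted by per-target calibration
offsets; the synthetic validation panel (the variable-expression loci, as
a validation experiment would choose) yields a clearly positive but not
unit correlation, and the per-target relationship is exact by
construction.

## Determinism and problem sizes

One master seed derives an independent stream per stage (genome, stems,
reads, transcripts, annotation, qPCR, shuffle tests), so identical
config + seed reproduce byte-identical outputs; the run manifest records
thresholds, seeds, and content hashes of every major table.

The shipped tests and the acceptance script run the reference study at
100 kb / 20 loci / 3 tissues, the folding oracle at n ≤ 12 over 200
random sequences, the conserved-matching oracle at 500 tags × 50
references, the target oracle on 200-300 nt transcripts, and determinism
on a 15 kb / 4 locus configuration — sizes at which exhaustive oracles
are exact and a full run completes in minutes on one core.

## Known limitations

* The energy model is reduced; absolute MFE values are approximate and
  should not be compared against full thermodynamic folders bit for bit.
* Exact-match genome mapping and exact-substring screening are
  appropriate for mutation-free synthetic genomes; real data would need
  mismatch-tolerant mapping (a config option exists for screening).
* The specificity ranking and abundance breakpoints are documented
  reconstructions, flagged as such in outputs.
* Multi-sample normalization equalizes scale in the median-of-ratios
  sense only; no dispersion estimation or differential testing is
  attempted.
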
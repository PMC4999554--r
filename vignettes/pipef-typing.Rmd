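---
title: "Typing the Enterococcus faecalis phage infection protein variable region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing the Enterococcus faecalis phage infection protein variable region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piptyper)
```

## The biological problem

Lytic bacteriophages that kill *Enterococcus faecalis* — a Gram-positive
gut commensal and opportunistic multidrug-resistant pathogen — depend on a
chromosomally encoded integral membrane protein, the phage infection
protein PIP_EF (locus EF0858 in strain V583), to inject their DNA.  The
protein is 888 amino acids long and well conserved across *E. faecalis*
strains except for a hypervariable segment, amino acids 342–494 of the
V583 protein, sitting in a large extracellular loop.  The sequence of this
variable region determines which phages can infect a strain (its
*tropism*): strains whose variable regions cluster together share a
phage-susceptibility pattern, and strains that become phage resistant do
so by breaking the PIP gene — frameshifts, premature stops, or insertion
of an IS element.

`piptyper` turns these observations into a reusable typing pipeline with
four analysis stages plus a ground-truth simulator:

1. **Variable-region extraction** (`extract_variable_region()`): anchored
   projection of the reference window onto any full-length PIP homolog.
2. **Clade typing** (`identity_matrix()`, `cluster_clades()`,
   `assign_clade()`, `predict_susceptibility()`): single-linkage clustering
   at 95 % nucleotide identity, and phenotype lookup for the phages
   φVPE25 and φVFW.
3. **Amplicon profiling** (`classify_reads()`, `summarize_abundance()`,
   `variant_profile()`): best-hit classification of variable-region
   amplicon reads against clade representatives, as used to survey
   enterococcal diversity in raw sewage.
4. **Resistance calling** (`call_variants()`, `annotate_consequence()`,
   `classify_resistance()`): alignment-based mutation calling on isolate
   gene sequences with a loss-of-function resistance rule.

## The typing model

Let $r_i$ be the variable region of strain $i$ (nucleotide level by
default).  For each pair the package computes a global alignment and the
identity

$$\mathrm{id}(r_i, r_j) = \frac{\text{matching columns}}{\text{columns, terminal gap runs excluded}}$$

Clades are the connected components of the graph joining pairs with
$\mathrm{id} \ge 0.95$ — i.e. single-linkage clustering cut at the 95 %
threshold.  Single linkage is deliberate: it reproduces the chaining
behaviour of "group everything at least this similar to something in the
group", is deterministic, and needs no choice of centroid.  Each clade is
represented by its medoid (the member with the highest mean identity to
its clade-mates); new sequences are assigned to the clade of their
best-matching representative when that identity reaches the threshold and
are otherwise reported `"novel"`.  Susceptibility prediction is a lookup
in the clade → phenotype map; the packaged 19-strain scheme
(`pipef_scheme()`) encodes five clades in which clades 1 and 4 are killed
by both phages, clades 2 and 3 only by φVPE25, and clade 5 only by φVFW
(12 + 3 + 4 = 19 strains).

Two published descriptions of the region's extent disagree slightly
("approximately 160 amino acids" versus the coordinates 342–494, which
span 153 aa).  The package fixes the coordinates at 342–494 and derives
the nucleotide window 1024–1482 by codon arithmetic
($\mathrm{start}_{nt} = 3\,\mathrm{start}_{aa} - 2$,
$\mathrm{end}_{nt} = 3\,\mathrm{end}_{aa}$); `region_length()` on the
reference therefore returns 153 aa / 459 nt.  Whether the published 95 %
cutoff excluded terminal gaps is likewise unstated; both identity modes
are exposed (`mode` argument), with terminal-gap exclusion as the default
so that partial sequences are not penalised for length.

## Alignment engine and scoring

All stages share one affine-gap Gotoh aligner (C++), with fixed traceback
tie-breaking (diagonal, then up, then left) so every result is
bit-reproducible.  Defaults:

| parameter | nucleotide | protein |
|---|---|---|
| match / mismatch | +1 / −1 | BLOSUM62 |
| gap open | −5 | −11 |
| gap extend | −2 | −1 |

The nucleotide gap-extension penalty is deliberately kept *above* the
mismatch cost.  If extension is cheaper than a mismatch (say −0.5), the
optimal global alignment of two unrelated DNA sequences degenerates into a
mosaic of short gap runs that harvests coincidental matches: random
2.7-kb sequences then read ≈ 0.51 identity, which would defeat any
homology floor.  Under the package defaults unrelated DNA aligns at
≈ 0.42 identity while a 20 %-diverged homolog still reads ≈ 0.80, so the
two guards in the pipeline are effective:

* `extract_variable_region()` rejects queries whose conserved flanks align
  below `min_flank_identity = 0.50` ("not a PIP homolog");
* `call_variants()` refuses isolates below 0.5 whole-gene identity
  ("not comparable").

Both floors sit far below the near-identity of true within-species PIP
homologs and above the ≈ 0.42 junk plateau.  The scheme is fully
configurable through `scoring_scheme()` for users who prefer other
conventions.

Reads are aligned in *overlap* mode ("glocal"): the read is consumed end
to end while unaligned reference prefix/suffix costs nothing, which is
read-mapping semantics for a 250-nt read inside the 459-nt region.  The
read — not the reference — must be fully aligned; otherwise a read could
count only its best few bases and appear identical to every
representative.  Ambiguity codes (`N`, `X`) never count as matches.

## Variant calling conventions

Isolate genes are globally aligned to the reference coding sequence.
Mismatch columns become SNPs; gap runs become insertions/deletions,
left-aligned through repeated context (the VCF convention) so positions
are deterministic and directly comparable across callers and the
simulator.  Insertions of at least `is_floor = 500` nt are reported as
IS-insertions: the published resistant isolates carried an IS*256*
element (~1.3 kb), but the element's identity is established by
annotation, not sequence, so the caller uses only a length criterion.

Consequences follow the genetic code: SNPs are synonymous / missense /
nonsense by codon translation; indels are frameshift when the net length
is not divisible by three, in-frame otherwise; IS-insertions are
IS-disruptions.  Nonsense and frameshift calls report the truncated
product length (residues before the first novel stop after applying the
call).  The resistance rule mirrors the published lesion spectrum: an
isolate is predicted **resistant** iff it carries a nonsense, frameshift
or IS-disruption call, or a deletion overlapping the variable region
(truncations there abolish infectivity regardless of position).
Missense-only genotypes are predicted sensitive — every published
resistant isolate carried a loss-of-function lesion — but the reason
string flags them for review rather than passing them silently.

## Cohort statistics

`percent_resistant()` is $100\,k/n$ with an exact Clopper–Pearson 95 %
interval: cohorts of 20 isolates per time point carry wide uncertainty
that a bare percentage hides.  `resistance_frequency()` is resistant
colonies per CFU challenged (observed values cluster at $10^{-5}$ to
$10^{-6}$); a zero count reports the rule-of-three upper bound $3/n$.
`fold_reduction()` is the control/treated load ratio.

## The simulator and what it does (not) emulate

`sim_config()` fixes every generator parameter; all outputs are pure
functions of the config, seed included, so equal configs give
byte-identical FASTA/FASTQ.  Defaults mirror the study system:

* gene geometry 1023 nt 5′ flank + 459 nt variable region + 1185 nt 3′
  flank (= 2667 nt, the EF0858 length);
* five clades with roster sizes 10/1/2/2/4 (the published 19-strain
  panel);
* within-clade variable-region identity 0.98, between-clade 0.80 —
  clearly either side of the 0.95 threshold, as in the real scheme;
  flanks held at 0.998 pairwise identity;
* 250-nt reads (MiSeq amplicon length) with 1 % substitution error by
  default, indels optional;
* one lesion per resistant isolate drawn from weights
  nonsense 0.25 / missense 0.05 / small indel 0.45 / IS cassette 0.25,
  echoing the published spectrum in which small indels dominate and a
  minority of isolates carry an IS insertion; the IS cassette is 1300 nt
  of random sequence (no mobile-element biology is simulated).

Divergence is substitution-only and applied almost entirely to the
variable region, mirroring the conserved-flanks/variable-centre
architecture that makes anchored extraction possible.  The per-branch
substitution rate is solved from the pairwise identity target accounting
for coincidental matches (two lineages mutated at rate $d$ from a common
ancestor disagree at $2d(1-d) + \tfrac{2}{3}d^2$ of sites), and realised
mean identities are verified within ±2 percentage points of target,
resampling otherwise.

What the simulator does **not** emulate — and hence what green tests do
not show about real data: coalescent or recombination structure,
quality-score-dependent error profiles, chimeric or paired-end reads,
copy-number variation, the second YhgE/PIP-domain paralog present in 8 of
the 19 published strains, and real IS elements with target-site
duplications.  Results on real amplicon data additionally depend on the
mapping tool and identity threshold used in the original study, which are
not stated; exact reproduction of the published sewage clade fractions is
therefore not guaranteed.

## The packaged reference is synthetic

The package does not redistribute the real EF0858 sequence.  The built-in
anchor (`reference_anchor()`) loads a *synthetic* stand-in
(`inst/extdata/synthetic_v583_pipef.fasta`, generated deterministically by
`data-raw/make_reference.R`) with the real gene's geometry: a 2667-nt ORF
encoding 888 aa plus stop, variable region at aa 342–494 / nt 1024–1482.
Every coordinate-dependent behaviour is exercised faithfully on it; users
analysing real isolates should pass the real V583 gene to
`reference_anchor(gene = ...)`.  Checks that require the real deposited
records (the 19 public PIP genes, the φVPE25 assembly) look for user-
supplied files under `inst/extdata/external/` and fail with a pointer
when absent.

## Numerical and degenerate-input choices

* Tie-breaking: alignment traceback prefers diagonal, then up, then left;
  equal-score overlap endpoints resolve toward the corner.  Clade
  numbering is by decreasing size, then first member in input order.
* An exact identity tie between clade representatives (assignment or read
  classification) is ambiguous by construction and yields
  `"novel"` / `"unassigned"` rather than an arbitrary winner.
* A boundary of the variable region landing on a query gap snaps inward,
  so reported coordinates always lie on the query.
* Sequences whose aligned span carries a net indel ≢ 0 (mod 3) are
  excluded from amino-acid variant profiles: they cannot be read in the
  reference frame.
* Abundance fractions are over assigned reads only; unassigned reads are
  reported separately.  Zero assigned reads yields an empty table with a
  warning, not an error.
* The default read-classification floor (`min_identity = 0.90`) sits
  below the 0.95 clade threshold to tolerate ~1 % sequencing error on
  250-nt reads; it is configurable.

## Problem sizes used by the test-suite and acceptance script

The package's own validation uses desk-scale simulations chosen to keep
the full suite fast while leaving no sampling ambiguity: 25-sequence
panels (5 clades × 5 members, three seeds) for exact partition recovery;
1000 reads at 1 % error for the 60/40 mixture experiment, judged against
exact binomial 99 % intervals; 201 planted isolate genotypes (three
seeds) for caller precision/recall; 500 random pairs of ≤ 8-nt sequences
for the exhaustive-enumeration alignment oracle; 10 seeds for identity
calibration.  `scripts/acceptance.R` re-runs the same computations from
scratch at those sizes and writes the resulting numbers as JSON.

## Known limitations

* The aligner is quadratic in sequence length; it is meant for genes and
  amplicons, not genomes.
* Read classification is unaware of base qualities (uniform placeholder
  qualities are emitted by the simulator).
* Paralog handling is at the record level: when several records of one
  strain pass the homology floor the caller keeps the best, but a single
  record containing two PIP-domain loci will yield only the
  globally-aligned one.
* Raw-read (pileup) variant discovery is out of scope; the caller expects
  assembled or Sanger-grade consensus gene sequences.
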
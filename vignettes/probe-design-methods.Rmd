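---
title: "Designing capture probes for targeted metagenomics: methods and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing capture probes for targeted metagenomics: methods and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Shotgun sequencing of an environmental sample spends most of its reads on
DNA you do not care about. Hybridization capture concentrates sequencing
effort on genes of interest: a pool of synthetic oligonucleotide probes
(here 50-mers) is hybridized to the fragment library and pulls down matching
fragments before sequencing. The design question is how to turn an arbitrary
user-collected set of target gene sequences — typically thousands of
homologs spanning many families, at very uneven abundance — into a compact
probe set in which (i) every target group is represented, (ii) each probe is
specific to its group within the input, and (iii) every probe is
manufacturable within the usual GC and melting-temperature constraints.

`probecap` implements this as a five-stage pipeline: length filtering,
greedy incremental clustering, group-specific probe design by spaced-seed
matching, a rescue stage for clusters that the primary design leaves empty,
and reporting with per-probe synthesis-cycle costing. Abundance bias is
neutralized by design: clustering collapses any highly redundant set of
sequences into one group, and probes are then selected per group.

```{r, eval = FALSE}
library(probecap)
d <- generate_dataset(10, 20, 1000, within_divergence = 0.03, seed = 1)
run <- run_pipeline(d$records, preset_config("paper"))
summary(run)
```

## Stage by stage

### Length filtering

Inputs longer than `max_len` (default 20,000 nt) are set aside as likely
genomic fragments (contigs, scaffolds) rather than single genes. No
published cutoff exists for this step; 20 kb was chosen because single genes
essentially never exceed it while even small contigs usually do, and the
value is a plain configuration key for users who disagree.

### Greedy incremental clustering

Sequences are sorted by decreasing length and processed in order; each
either joins the first cluster whose representative it matches at or above
`identity_threshold` (default 0.9), or founds a new cluster. With
`best_cluster` the highest-identity cluster is chosen instead, ties going to
the lowest cluster id; length ties in the processing order keep input order,
so the procedure is deterministic end to end.

Identity is computed from a banded global alignment (match +1, mismatch -1,
gap -2; traceback prefers diagonal, then gap-in-second, then gap-in-first).
Two definitional choices deserve note:

* **Denominator.** With `global_identity` (the default) identity is
  (identical aligned bases) / (length of the shorter sequence), the
  convention of the standard greedy clustering tools. With the flag off,
  the denominator is the aligned span excluding terminal gaps — a
  definition the flag's usual semantics only gesture at, so it is stated
  here explicitly.
* **Banding.** The alignment band (`band_width`, default 20) is always
  widened by the length difference of the pair, so the global end cell is
  reachable and the band restricts only lateral drift. For gene-family data
  the true path stays near the diagonal and banding is loss-free; the test
  suite verifies on randomized instances that banding plus the word
  prescreen reproduce the partition of an unbanded, prescreen-free greedy
  reference pass.

The word prescreen counts positions of the shorter sequence whose
`word_size`-mer (default 8) occurs in the longer one, and compares the count
against a run-length bound implied by the identity threshold: matched
columns form runs contiguous in both sequences, runs are broken by at most
`2 * floor((1-t) * L_short) + (L_long - L_short) + 1` events, and each run of
length `r` contributes `r - w + 1` shared words. Pairs below the bound — and
pairs sharing no word at all — are skipped without alignment. The bound is
exact for substitution-dominated divergence; a sufficiently adversarial
indel-dense alignment could in principle defeat the shared-word requirement,
which is why the equivalence property above is asserted on every test run
rather than assumed. Sequences shorter than the word size bypass the
prescreen entirely.

Reverse-complement members (when `both_strands` is on) are recorded with
strand `-` and flipped to the representative's forward strand before any
probe design, so probe coordinates always refer to that strand.

### Primary (group-specific) probe design

Candidates are all `probe_length` windows of all cluster members — member
sequences, not the consensus, so that genuinely present sequence is used.
A candidate survives if it passes the GC/Tm/no-`N` filter and is *specific*:
a spaced seed (default: four 10-base words separated by 2-base don't-cares,
pattern length 46) must find no match in any sequence of any other cluster.
Seed matching asks whether some placement of the pattern inside the
candidate agrees with some placement in the target at every care position;
don't-care gaps (always shorter than 3 bases) absorb scattered mismatches,
which is what lets one probe represent a moderately diverged group. The
seed's word length and word count are engineering choices tuned on synthetic
families — the narrower the words, the more divergence tolerated and the
more cross-matching risked.

Survivors are ranked and at most `max_probes_per_cluster` (default 3) are
kept: the first pick maximizes within-cluster coverage (members
seed-matched, ties broken by lower offset, then lexicographic sequence);
subsequent picks greedily maximize the minimum offset distance to the
already-selected set at equal coverage. The spread criterion deliberately
pushes later probes into different regions of the gene so that conserved and
variable segments are both represented. Selection is fully deterministic;
the exact rule is re-implemented independently in the test suite and checked
by exhaustive enumeration on small instances.

An empty result is legitimate — high within-group divergence, skewed base
composition, or cross-group similarity can disqualify every window — and
marks the cluster for rescue.

### Rescue design

Probe-less clusters with two or more members are aligned with a
deterministic center-star procedure (center = member with the highest summed
pairwise identity; others aligned to it globally; merges follow
once-a-gap-always-a-gap, coincident center-gap columns being merged), and a
consensus is called: per column, the most common base among non-gap
characters is emitted if its non-gap frequency reaches
`consensus_column_threshold` (default 0.9, inclusive; ties broken
alphabetically), otherwise `N`; columns that are more than half gaps are
dropped. The stated "90%" could alternatively be read as a pre-filter on
member identity before alignment; the column reading is implemented because
it acts exactly where ambiguity arises and degrades gracefully — ambiguous
columns become `N` and any window containing `N` is discarded rather than
synthesized. Singleton clusters skip alignment and are tiled directly.

Tiling lays windows at offsets `0, step, 2*step, ...` (default
`step = probe_length`, i.e. end-to-end) plus a final 3'-anchored window so
the gene end is always covered. Surviving windows are filtered, taken in
offset order, and capped at `max_probes_per_cluster`. The rescue stage may
run with its own parameter set (`step4` overrides): when a cluster failed
primary design precisely because its composition sits outside the standard
GC window, only a relaxed rescue window can recover it, and the choice to
relax is explicitly the user's.

Note the interaction between cluster size and the column threshold: with
fewer than 10 rows, a 0.9 threshold tolerates no deviation at all
(9/10 = 0.9 passes, 4/5 = 0.8 does not), so small diverged clusters tend to
produce `N`-dense consensus and few rescue probes. This is faithful to the
threshold's meaning; users with many small clusters should lower the
threshold or probe length deliberately rather than expect leniency.

### Filters and melting temperature

GC bounds (percent) and Tm bounds (°C) are inclusive on both ends. Two Tm
methods are exposed. The default is unified nearest-neighbor thermodynamics:
stack enthalpies and entropies summed over dinucleotides plus terminal
initiation terms, `Tm = 1000 ΔH / (ΔS + 0.368 (N-1) ln[Na+] + R ln(C_T/4)) - 273.15`,
at 50 mM monovalent salt and 0.25 µM total oligo by default. The quick
`gc_rule` (`64.9 + 41 (GC - 16.4) / L`) is retained as a fast alternative.
The nearest-neighbor default was chosen because a 55–65 °C acceptance window
for 50-mers is inconsistent with the GC rule (which maps 35–65% GC to
roughly 66–86 °C) and thus implies a thermodynamic method; the method and
conditions are recorded in the run manifest because the two scales are not
interchangeable. Under the default conditions the 55–65 °C window selects
the lower-GC portion of the 35–65% GC range — the two filters genuinely
interact, and that is visible in the per-run rejection tallies.

### Costing and reporting

Synthesis-cycle counts model cyclic base delivery (order `ACGT` repeating):
bases are coupled one at a time, each waiting for its reagent's next cycle,
and the count is the last cycle used. Synthesis direction is 3'→5' by
default and configurable by one flag, since the platform convention is not
something the probe sequence itself can tell you; the direction used is
recorded in run metadata. A probe of length L needs between L and 4L cycles;
the count is a manufacturing-cost proxy, not a price model.

Every run emits six files (two per-stage summaries, the two probe tables,
the cluster file, and the non-redundant probe set) plus a run manifest
echoing the fully resolved configuration. Deduplication keeps the first
occurrence of each probe sequence and records every contributing cluster on
the survivor. Summaries are key/value TSV with a stable key order, so runs
can be diffed byte for byte — the pipeline is deterministic given input and
configuration, and the test suite asserts byte-identical re-runs.

## The synthetic data generator

`generate_dataset()` plants gene families: each family draws an independent
random ancestor (GC fraction `gc_bias`, default 0.5) and derives members by
per-site substitution (`within_divergence`) plus rare short indels (length
1–3 at `indel_rate`). Independent ancestors put between-family identity at
the random background (roughly 25–40% under global alignment), far below any
sensible clustering threshold, while members stay within roughly twice the
within-family divergence of each other. Record ids are shuffled and encode
nothing; the planted truth is returned separately. A strongly skewed
`gc_bias` (e.g. 0.8, allowed per family) builds families whose windows fail
standard GC filters — the deliberate stress case for the rescue stage.

What this emulates is the *clustered* structure the pipeline assumes:
families of moderately diverged homologs. What it does not emulate —
phylogenetic correlation among members, codon structure, compositional
heterogeneity along a gene, truncated or chimeric records — means that
passing tests demonstrate correctness of the algorithms under the model's
assumptions, not field performance on any particular database export.

Default test and verification sizes were chosen to exercise each guarantee
at the scale it is stated for while staying quick: clustering equivalence on
twenty instances of up to 50 sequences (200–600 nt), planted-family
recovery on five replicates of 10 families × 20 members × 1 kb at 3%
divergence, filter soundness on 10,000 random 50-mers, cycle accounting on
10,000 random probes, and one full 1,000-sequence design at the standard
operating point. The rescue stress case uses 10 families × 12 members ×
800 nt at 2% divergence, half the families at GC 0.85, with a relaxed
`step4` override (GC 15–95, Tm 30–100 °C) — the documented mechanism for
recovering composition-skewed clusters.

## Degenerate inputs and tie-breaks, in one place

* Duplicate record ids, empty sequences and non-`ACGTN` characters are hard
  parse errors; `N` is accepted on input but never appears in an emitted
  probe.
* Empty record sets cluster to an empty partition; an empty post-filter
  input aborts the pipeline with the stage named.
* Equal-length sequences keep input order; equal-identity best-fit picks the
  lowest cluster id; alignment traceback prefers diagonal, then the gap in
  the second sequence; consensus ties pick the alphabetically first base;
  candidate ranking ties fall through offset, sequence, then source id.
* Sequences shorter than the probe length simply produce no windows;
  sequences shorter than the seed pattern can never be matched and thus
  never threaten specificity.

## Known limitations

Specificity is checked against the input sequences only — by construction,
and quickly, but nothing is known about off-target hybridization to
sequences outside the submitted set. There is no secondary-structure or
cross-hybridization free-energy screening. The clusterer is a faithful
greedy incremental implementation, not a bit-for-bit reproduction of any
particular external tool's heuristics. Probes are fully specified (no
IUPAC degeneracy), and rescue does not iterate: a cluster whose consensus
yields no admissible window after the stage-IV parameters is reported
probe-less rather than re-clustered.
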
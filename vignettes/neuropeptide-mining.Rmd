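---
title: "Mining and annotating neuropeptide precursors with npmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and annotating neuropeptide precursors with npmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npmine)
```

## The problem

Insect neuropeptide genes encode *prepropeptides*: a secretory signal
peptide followed by one or more short bioactive peptides separated by
spacer sequences and basic cleavage sites. Annotating them in a
transcriptome or genome assembly is a pipeline of small, well-defined
steps — find candidate loci by translated homology to known precursors,
delimit the open reading frame, predict where prohormone convertases cut,
infer the standard post-translational modifications, and (when mass
spectra of tissue extracts are available) confirm the predicted mature
peptides by mass. `npmine` implements this pipeline end to end, together
with a synthetic-data generator that produces inputs with complete ground
truth so that every stage can be validated quantitatively without any
external download.

## Translated homology mining

Candidate loci are found by aligning a panel of reference precursor
proteins against all six reading-frame translations of each subject
transcript — the in-package equivalent of a translated BLAST search.
The aligner is an exact Smith–Waterman with affine gaps (compiled core),
scored with BLOSUM62 and gap penalties of $-11$ (open) and $-1$ (extend),
mirroring standard protein-search defaults; stops in a frame translation
align through the `*` row of the matrix, as a translated search does.
Traceback is deterministic: diagonal over vertical over horizontal, and
among equal-scoring end cells the earliest subject position wins.

Raw scores, not E-values, gate acceptance. E-value calibration depends on
database size and was not needed at this scale; instead the threshold is
**calibrated on an empirical null**: every subject transcript is
dinucleotide-shuffled, the per-transcript maximum score of the shuffled
set is collected, a Gumbel distribution is fitted to those maxima (method
of moments — maxima of many local alignment scores are extreme values),
and the threshold is set where the probability that *any* of the $m$
transcripts in the intended search reaches it is $\alpha$ (default
$10^{-3}$). The observed null maximum is never undercut. This gives a
deterministic, dataset-adapted threshold with an explicit family-wise
error interpretation, and it is the procedure the acceptance metrics use.

A hit is extended to its maximal enclosing stop-to-stop ORF, and one hit
per (subject, family) is kept — Trinity-style assemblies carry splice
variants under one cluster, and double-counting them would inflate the
precursor tally. Mining can be run iteratively (newly accepted precursor
proteins are appended to the panel and the search repeats, bounded at
`max_rounds`), which is how "iterative" search loops are conventionally
closed when the original description leaves the loop unspecified.

## Cleavage rules

The convertase rule set is deterministic and exposed as `rule_config()`:

* contiguous K/R runs collapse into a single site at the run's C-terminal
  end (`basic_run` records the run length; runs of 3+ are reported as the
  tetrabasic kind);
* dibasic `KR`, `RR`, `RK` cleave; `KK` does not unless enabled;
* a lone `R` cleaves only with another basic residue at position $-4$,
  $-6$ or $-8$ from the scissile bond; a lone `K` never cleaves;
* proline immediately C-terminal to the bond blocks cleavage;
* no site inside the signal peptide or within 3 residues after it.

After trimming the flanking basics, a segment ending in glycine is
amidated (the Gly is consumed, $-0.984016$ Da against the free acid with
the Gly removed), and a segment starting with Gln is flagged as a
pyroglutamate candidate ($-17.026549$ Da); both modified and unmodified
forms stay available to the mass-matching stage, since tissue extracts
routinely contain both. Conversion of N-terminal Glu is off by default
(only pQ-from-Gln forms are typically reported in the heteropteran
literature) and can be enabled. Sub-3-residue segments are kept but
flagged `fragment` — spacer-like segments count as peptides in published
per-precursor tallies, and dropping them would change those counts.

The annotation is **conservative by construction**: concatenating signal
peptide, peptides, consumed glycines and trimmed basics must reproduce
the precursor exactly, and this invariant is fuzz-tested. A second,
independent implementation of the rules (a predicate enumerator that
looks at every K/R position in isolation) backs the engine in the test
suite.

## Signal peptides

The built-in predictor is a deliberate heuristic, not a reimplementation
of a machine-learned tool: it scans cleavage positions 15–45, requires
small/neutral residues (`A,G,S,C,T,V`) at $-3$ and $-1$, requires a
hydrophobic core (best 8-residue mean Kyte–Doolittle $\ge 1.6$ within
residues 3..end$-4$), and returns the highest-scoring position (earliest
on ties). This captures the classical signal-peptide architecture well
enough to resolve the generated boundaries exactly, and an
externally computed span (from a dedicated predictor) can be passed to
`annotate_precursor()` to override it. Absence of a signal peptide is a
valid result and flags the precursor as N-terminally incomplete — the
state in which truncated assemblies legitimately appear.

## Motif census

Family-diagnostic core motifs are written in a small restricted pattern
language — literals, `X`/`x` for any residue, character classes, bounded
repeats — compiled to a single-pass matcher. Unbounded repeats are
excluded on purpose: every shipped motif is a bounded pattern, and
decidable one-pass matching keeps the census deterministic. The default
library encodes the cores that diagnose the families handled by the
blueprint set: MIP `W(6x)W`/`W(7x)W`-amide, kinin `FXXWG`-amide and the
heteropteran `FSXWA`-amide, FMRF/FIRF-amide, sulfakinin GHMRF/GYMRF-amide,
FGL/LGL-amide allatostatin, the amidated ETH `PR[LIVM]` core, RY-amide
(the ambiguous `FY3(X)RY` prose notation is provisionally encoded as
`F Y x{3} R Y` and marked as such in its metadata), myosuppressin
FLRF-amide, and the AKH signature (pyroGlu start, Trp at position 8,
length 8–10). Family classification ranks by matched paracopy count with
an optional homology score as tie-breaker; ties are reported with equal
ranks, never broken silently.

## Mass matching

Peptide masses are monoisotopic residue sums plus water; modification
deltas are amidation $-0.984016$, pyroglutamate $-17.026549$, sulfation
$+79.956815$ per site; C-terminal truncation removes residues before
C-terminal modifications apply. Only singly protonated ions are modeled
(MALDI regime). Fragment ladders are plain b/y series; N-terminal
modifications shift b ions, C-terminal ones shift y ions, so the
complementarity identity $b_i + y_{n-i} - 2\,\mathrm{H^+}$ = precursor
mass holds in all modification states and is fuzz-tested to $10^{-4}$ Da.
Search tolerances default to 50 ppm (precursor) and 0.3 Da (fragments),
the usual MALDI-TOF/TOF working regime; both are configuration values,
declared stand-ins since instrument settings vary. Candidate states per
library peptide: amidation as annotated, pyroGlu on/off for N-terminal
Gln, truncation 0–1, sulfation up to the tyrosine count; matches are
ranked by fragment coverage, then absolute ppm error. Sulfation is never
auto-assigned to a site — it enters only as a search-time variable
modification.

## The synthetic-data generator

The generator is first-class code, not a fixture: blueprints describe
precursor architectures (signal length, core-peptide patterns with
amidation donors, spacer distribution, dibasic flanks), and
`generate_dataset()` assembles transcriptomes around them. The shipped
blueprint set emulates the characteristic pentatomid architectures — a
single pQLNFSPGW-amide AKH core, twelve MIP paracopies (six `W(6x)W` +
six `W(7x)W`), three ETH cores, seven FMRF-amide plus one FIRF-amide,
kinin with both core variants, GHMRF/GYMRF sulfakinins, six
FGL-allatostatins with the LGL first copy, a 22-segment NPLP1-like
precursor with three amidated segments, seven tachykinin cores, and
single 44- and 31-residue diuretic-hormone cores.

Construction is constrained so that the rule engine provably recovers the
truth: random fill avoids K, R, G, C and W (no spurious sites, amidation
donors, or tryptophan-motif hits), internal arginines of literal cores
sit at least 7 residues into their segment so the monobasic $-4/-6/-8$
supports can never reach a flanking dibasic, and every instantiated
precursor is re-annotated and accepted only if annotation equals
construction (bounded retries). Embedding back-translates with uniform
synonymous codon choice, plants an in-frame stop directly 5' of the start
codon (so ORF coordinates are exact), appends a stop codon and random
UTRs of 20–80 nt, and places half the loci on the reverse strand. Query
panels are BLOSUM-weighted mutated copies of the embedded precursors with
K/R/G/C positions masked, which keeps the family architecture
recognizable in the queries. Decoys are dinucleotide shuffles (uniform
edge shuffle with an Eulerian walk, bounded retries, first-order Markov
resampling as fallback) — the standard compositional null for sequence
search. Synthetic MS observations are theoretical masses of the true
mature peptides with seeded ppm jitter (SD 10 ppm, truncated at 3 SD) and
complete, lightly jittered b/y fragment lists.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: assembly fragmentation and chimerism,
sequencing error, splice variants, biased codon usage, genuinely novel
precursor architectures, and homologs whose divergence concentrates in
exactly the residues the mask protects. Recovery metrics on this
generator are a validation of the pipeline's logic, not a field estimate
of sensitivity on real assemblies.

## Worked example

```{r example}
d <- generate_dataset(n_precursors = 6, n_decoys = 12,
                      divergence = 0.3, seed = 42)
subjects <- c(d$transcripts, d$decoys)
null <- lapply(seq_along(subjects), function(j)
  transcript_record(paste0("null", j),
                    dinucleotide_shuffle(subjects[[j]]$seq, seed = j)))
cal <- calibrate_min_score(d$panel, null, n_searches = length(subjects))
res <- mine_sequences(subjects, d$panel, min_score = cal$min_score)
evaluate_mining(res, d$truth)[c("recall", "decoy_hits")]
```

```{r annotate}
m <- annotate_precursor(res[[1]]$orf$protein, family = res[[1]]$family)
summary(m)
```

## Problem sizes and numerical choices

The validation suite runs at desk scale by design: the acceptance
dataset is 20 precursors (about 12 families cycled twice) against 200
decoys at query divergence 0.30, the size at which the recall,
false-acceptance and re-identification metrics stabilize while the whole
suite stays fast on a single CPU. Alignment scores are integers; mass
arithmetic is double precision with a $10^{-4}$ Da test tolerance
(well below instrument accuracy); the Gumbel calibration uses
$\alpha = 10^{-3}$ and never undercuts the observed null maximum.
All randomness — generation, shuffling, divergence, jitter — is pinned to
a single Mersenne-Twister seed and restored afterwards, so identical
configurations reproduce outputs byte for byte.

## Known limitations

* The signal-peptide heuristic approximates the classical rules; a
  dedicated predictor's output should be preferred when available (the
  override channel exists for exactly that).
* Cleavage prediction is rule-based; probabilistic site scoring
  (logistic models trained on verified sites) is out of scope.
* The mass matcher models 1+ ions only and performs no FDR estimation —
  target-decoy search would be the natural extension.
* The mining stage reports raw scores, not E-values; thresholds must be
  recalibrated per dataset (the calibration function is part of the
  public interface).
* RBH orthology is the classical heuristic: best hits in both
  directions, lexicographic tie-break; it does not resolve paralogous
  expansions.
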
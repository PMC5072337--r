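---
title: "Delineating remote-homology membrane-protein families with famforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating remote-homology membrane-protein families with famforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famforge)
```

## The problem

Polytopic membrane-protein families such as the mitochondrial protein-import
carriers (Tim17, Tim22, Tim23 and their relatives) are short, hydrophobic and
fast-evolving, which puts many genuine members beyond the reach of ordinary
pairwise search. The standard remedy is iterative profile search: cluster the
known members, build a statistical profile per cluster, search the proteome
database with a deliberately permissive cutoff, and vet each candidate with a
more sensitive profile–profile comparison before admitting it to the family
and repeating.

Membrane families add a specific confound. Transmembrane helices are rich in
glycine zippers — the GxxxGxxxG helix-packing motif — and so are many
unrelated membrane proteins. A candidate can therefore look "similar" to the
family purely through its zipper. famforge addresses this the way the field
does: the glycine-zipper columns of the master alignment are detected and
*masked* (their score contribution forced to zero) during validation, so a
candidate is accepted only if its similarity survives removal of the motif
signal.

famforge implements the whole pipeline — greedy identity clustering,
profile construction and calibrated search, masked profile–profile
validation, the iterative expansion loop, motif scanning, hydropathy-based
transmembrane (TM) architecture analysis, tandem-domain splitting, and
neighbor-joining subfamily classification — together with a synthetic
benchmark generator that provides ground truth for every stage.

## The synthetic benchmark

Real proteome databases provide no ground truth, so the package is accepted
against generated superfamilies whose truth is known by construction.

The generator (`generate_superfamily()`) designs an ancestor of alternating
hydrophilic loops (25 residues by default, residues uniform over the 13
non-hydrophobic amino acids) and hydrophobic TM helices (20 sampled residues
from the weighted set L/I/V/F/A/M/G = 25/15/15/10/15/5/15). Each helix
receives one glycine zipper as a 9-residue insertion (glycines at offsets
0, 4, 8; hydrophobic x positions), and the loop between helices 2 and 3
carries one fixed lysine and one fixed aspartate, mirroring the conserved
charged pair of the real family. Because a designed membrane span that fails
a hydropathy criterion is not a membrane span, helices are rejection-sampled
until their mean Kyte–Doolittle value is at least 2.2, comfortably above the
classic 1.6 window threshold.

Evolution is a Poisson process: per-site substitution counts are Poisson in
the branch length, each substitution uniform over the 19 alternative
residues. Zipper glycines and the charged pair evolve at one tenth of the
background rate (conserved sites). Indels are restricted to loops at one
tenth of the substitution rate and are implemented as deletions only, which
keeps every member in the ancestor's column frame: the truth alignment, the
truth zipper columns and the TM helix bounds all share one coordinate
system. Subfamily ancestors sit `inter_sub_divergence/2` from the root
(default 1.0 between subfamilies); members radiate along a random coalescent
tree rescaled so each tip lies `intra_sub_divergence/2` from its subfamily
ancestor (default 0.3 across a subfamily). These defaults put sister
subfamilies near ~30% pairwise identity — remote but reachable, the regime
the iterative search exists for.

The benchmark database (`generate_benchmark()`) is three "proteomes", each
holding 20 members of each of three subfamilies, 20 glycine-zipper decoys
(i.i.d.-uniform random proteins carrying 2–4 exact GxxxGxxxG motifs and
nothing else in common with the family) and 200 uniform random background
proteins; tandem two-domain proteins (two family members joined by a
10–30-residue hydrophilic linker) can be added. All randomness flows from
one integer seed; identical configuration and seed give byte-identical
FASTA output.

What the generator does *not* emulate: site-heterogeneous rates beyond the
two-class conserved/background split, substitution biases (the uniform
19-alternative model erodes hydropathy at deep divergence faster than real
membrane proteins do, which is why TM architecture recovery is only claimed
near the family's intra-subfamily depth), insertions, compositional drift,
and real Tim17 sequences. Passing the benchmark therefore demonstrates that
the machinery is correct and calibrated on data matching its assumptions,
not that it will match any particular published family delineation.

## Profiles, scoring and calibration

A profile (`build_profile()`) keeps one frequency vector per match column —
alignment columns with under 50% gaps — using Henikoff position-based
sequence weights and background-proportional pseudocounts with mass 1. The
background is the source alignment's overall residue composition (floored at
1e-4). `X` is allowed everywhere and always scores as background.

Sequence-versus-profile scoring (`score_sequence()`) is a local
Smith–Waterman dynamic program over match/insert/delete states with emission
log-odds `log2(freq/background)` in bits, gap open 4 bits and gap extension
0.25 bits; masked columns emit 0. The same machine scores
profile-versus-profile comparison (`align_profiles()`) with the co-emission
column score `log2(sum_a q_i(a) m_j(a) / bg(a))` against the master's
background. Both cores are compiled (Rcpp) and are verified in the test
suite against exhaustive path enumeration on small instances. A fixed
simple-gap architecture was chosen over learned per-position transitions
deliberately: the search tool is treated as a calibrated ranking engine, and
a fixed architecture is testable by brute force.

E-values come from an explicit null: `calibrate()` scores a few hundred
i.i.d. background-composition random sequences of the median database length
and fits a Gumbel distribution by maximum likelihood;
`E = db_size * P(S >= s)` with `db_size` the number of sequences actually
searched. The package checks itself the way a user would: the mean number of
`e <= 1` hits against fresh 500-sequence null databases stays near one.

The validation probability deserves a note, because the published protocol
delegates it to an external profile-comparison tool whose probability scale
is not exportable. famforge defines its own calibrated scale: a
two-parameter logistic of the masked profile–profile raw score, fitted by
maximum likelihood to labeled examples. In the pipeline the positives are
the master's own rows *plus simulated remote homologs of those rows*
(Poisson substitution at a configurable depth, `calib_divergence = 1.5` by
default — the divergence horizon out to which validation should still accept
a family member); the negatives are generated zipper decoys plus
composition-preserving shuffles of the master rows. Without the simulated
remote positives the logistic boundary hugs near-identity scores and the
iteration can never cross to a sister subfamily; with them, acceptance at
the 0.9 threshold extends to the family's divergence horizon while shuffled
and decoy scores stay far below. The 0.9 threshold itself is kept from the
published protocol; only the scale behind it is the package's own.

## The iterative loop

`run_pipeline()` repeats, at most ten times (a cap, not a requirement):
cluster the current homolog set at 40% identity (greedy, longest-first,
identity denominator the shorter sequence — the convention of the standard
greedy clustering tool, so fragments still cluster); build and calibrate a
search profile per cluster from the members' master-alignment rows; search
the database at `e <= 1`; validate every new hit against the masked master
at probability 0.9; attach accepted hits to the master alignment via the
search traceback. The loop stops early at a fixed point (an iteration that
adds nothing), which on a finite database always arrives because the
homolog set grows monotonically.

The master's column frame is pinned to the seed alignment for the entire
run: attached sequences place residues into existing match columns, and
insert-state residues are recorded as annotations rather than new columns.
A fixed frame keeps zipper masks, trimming maps and envelope coordinates
comparable across iterations. Validation is performed against the evolving
master by default; `pin_seed_master = TRUE` pins it to the original seed
instead, for users who prefer the conservative variant.

## Motifs, architecture and tandem proteins

`scan_prat()` matches the 31-position preprotein-and-amino-acid-transporter
pattern `[GA]-x-x-[FY]-x(10)-R-x(3)-D-x(6)-[GAS]-G-x(3)-G`; `scan_zipper()`
matches GxxxGxxxG. Both report every overlapping window, and `x` matches
`X`.

`predict_tm()` computes the Kyte–Doolittle mean over every full 19-residue
window and marks a residue hydrophobic when it lies inside at least one
window whose mean exceeds 1.6 — the classic reading of a hydropathy peak, in
which the whole window is the candidate span. Marked runs separated by at
most 3 residues are merged and runs shorter than 15 residues are dropped.
The window-union convention matters: marking only window centers yields runs
of roughly `helix length − window + 1` residues, which for a 20–29-residue
helix falls under any reasonable minimum-length filter.

`split_tandem()` finds the best profile envelope, hard-masks it with `X`,
and rescores; a second envelope that also clears the e-value cutoff and
overlaps the first by fewer than 10 residues (local alignments fray at
their edges) makes the protein a two-domain tandem, reported in N-to-C
order, each domain contributing its own tree leaf (`id#N`, `id#C`). The
e-value needs a database size to be meaningful on a single sequence; the
default `db_size = 1000` corresponds to vetting candidates drawn from a
proteome-scale search.

## Classification

`trim_alignment()` keeps columns with at most 50% gaps and returns the
old-to-new column map so zipper masks survive trimming. Distances are
Poisson-corrected p-distances over mutually ungapped columns,
`d = -ln(1 - p)`, capped at 5 substitutions/site; pairs sharing fewer than
10 ungapped columns are an error rather than a silent zero. Trees are built
by canonical neighbor joining (via ape), with negative branch lengths
floored at zero and the deficit moved to the adjacent branch. Subfamily
labels propagate from user-supplied reference leaves: after midpoint rooting
(used solely to define nested clades), each leaf takes the majority
reference label of the smallest clade containing it and at least one
reference, with a 0.75 majority threshold guarding against a single
misplaced reference; mixed clades yield `unclassified`. The
proteome-by-subfamily `presence_absence()` matrix summarizes the result,
with tandem domain leaves crediting their source proteome.

Distance-based neighbor joining replaces likelihood and Bayesian tree
inference deliberately: the acceptance surface is recovery of known truth
on the synthetic benchmark, for which NJ on additive-consistent distances
is exact, testable, and fast.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere, the R and Bioconductor
  convention.
* Zipper detection requires a glycine fraction of 0.7 per column and
  tolerates spacing jitter (second anchor at +4±1, third at +8±2 in
  ungapped consensus coordinates) caused by loop indels; masking covers the
  anchors plus the intervening columns of each detected triple, i.e. the
  whole motif window. Masking anchors only is available
  (`zipper_mask_columns(expand = FALSE)`).
* Masked columns are zeroed, never deleted, so coordinates remain stable.
* Clustering ties break by descending length then ascending id; all
  stochastic steps derive child seeds deterministically from one integer
  seed; reruns are byte-identical.
* Degenerate inputs fail loudly: empty FASTA, ragged alignments, all-gap
  match masks, uncalibrated profiles in `search_db()`/`split_tandem()`,
  constant score vectors in either calibration.

## Known limitations

* The calibrated probability scale is the package's own; 0.9 here and 0.9
  on the external tool's scale used by the published protocol agree only by
  construction of intent, not numerically.
* Under plain emission log-odds scoring, uniform-background zipper decoys
  gain almost nothing from the motif itself (three glycine matches cannot
  pay for six x-position mismatches against hydrophobic columns), so their
  scores are chance-level with or without masking. Masking is therefore
  prophylactic here: it guards against motif-driven score inflation of the
  kind context-aware profile tools exhibit, but the package's decoy
  rejection is already decisive before masking. The test suite documents
  this honestly: decoy rejection and member acceptance pass at 100%, while
  "decoys lose more absolute score to masking than members do" does not
  hold on this score scale and is reported as measured.
* Hydropathy-based TM prediction assumes the uniform substitution model has
  not yet eroded helix hydrophobicity; at the benchmark's deep
  inter-subfamily divergences the erosion is real and architecture calls
  degrade, which is a property of the generator's neutral model rather than
  of the predictor.
* Problem sizes were chosen for a desk-scale benchmark: 840-sequence
  database, 205–241-residue proteins, profiles of ~200 columns,
  500-sequence calibration nulls. These keep a full end-to-end run in the
  low minutes on one core.
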
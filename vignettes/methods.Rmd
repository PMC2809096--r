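---
title: "Methods: glycoside hydrolase discovery from a compost metagenome"
author: "compostGH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycoside hydrolase discovery from a compost metagenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compostGH)
```

# Scope

compostGH implements the computational side of a targeted enzyme-discovery
workflow on a lignocellulose-degrading compost community: a feedstock
(switchgrass-type grass biomass) is inoculated with compost, incubated under
simulated thermophilic composting, and the adapted community is mined for
glycoside hydrolases (GHs). The package covers five analysis stages plus a
synthetic-data module:

1. **Amplicon community profiling** — demultiplexing, length filtering,
   phylotype tallying, relative abundance, Bray-Curtis dissimilarity between
   timepoints, and per-phylotype fold enrichment with a detection floor.
2. **GH inventory** — profile-HMM scanning of six-frame-translated assembly
   contigs, best-hit resolution per contig and family, read-depth weighting,
   and aggregation into five functional groups.
3. **Full-length enzyme recovery** — translated local search against an
   EC-annotated reference enzyme set, coverage/significance/function
   filters, homopolymer frameshift detection and single-base correction,
   ORF calling, truncation assessment.
4. **Respiration mass balances** — CO2 evolution rate (CER) and O2 uptake
   rate (OUR) from reactor gas streams, with trapezoid integration.
5. **Composition accounting** — ash-conservation solids loss and
   per-component/pooled loss percentages.

Everything runs offline: the synthetic module generates all inputs with
known ground truth, which is what the test suite exercises.

# Community profiling

Reads are assigned to samples by exact match of their first
`barcodeLength` (default 5) bases against the barcode map, then the barcode
is trimmed and reads shorter than `minLength` (default 220 nt, inclusive,
measured after trimming) are discarded. The length threshold is applied
after barcode trimming and is inclusive; neither choice is forced by the
upstream protocol description, so both are fixed here and documented.

Phylotype assignment is exact-label tallying: synthetic reads carry their
phylotype of origin in the read name. Real OTU clustering is deliberately
out of scope — an externally produced count table can be substituted
through `phylotypeTable()` and flows through everything downstream.

Bray-Curtis dissimilarity is computed on relative-abundance profiles,
`sum(|p - q|) / sum(p + q)` over the union of labels. It is symmetric and
bounded in [0, 1] but is not a metric; the tests assert only range,
identity and symmetry, and cross-check values against an independent
community-ecology implementation.

Fold enrichment between timepoints divides t1 by t0 relative abundance.
Below the detection floor `tau` (default 0.0009, i.e. 0.09% of sample
reads — interpreted as a proportion of total reads, the denominator being
otherwise unspecified) only the lower bound `p_t1 / tau` can be claimed;
such rows are flagged and rendered as `">=x"`. Phylotypes absent at t1 are
reported as enrichment 0 rather than dropped.

# Profile HMMs and the GH inventory

Profiles are position-specific models with 20-residue match emissions,
insert emissions, and node transitions (M/I/D), stored as probabilities
and scored in log-odds bits against a background (uniform 1/20 unless the
profile file provides one). A pragmatic subset of the HMMER3 ASCII format
is read and written, enough for standard Pfam-style single-domain files.

Scoring is single-hit local Viterbi in the Plan7 style: the alignment may
enter at any match state with uniform probability 1/L and exit from any
match state at no cost. `X` residues score 0 bits at any emitting state;
alignments never cross a stop (`*`). The score of the best path below 0
bits is reported as `-Inf` (no alignment). This scorer is validated
exhaustively against a path-enumeration oracle for all profile lengths up
to 4 and peptides up to 6 residues.

Scanning takes, per contig and profile, the best score over the six
reading frames; hits must reach `scoreThreshold` (default 25 bits). The
threshold is deliberately conservative and configurable; no E-value
calibration is attempted for HMM scores. For families modelled by several
profiles (2-domain families), only the best-scoring hit per
(contig, family) is kept; the same rule caps each contig at one count per
family, preventing double counting of a gene split across frames.

Contig depth weighting converts read counts to approximate fold coverage:
`weight = nReads x medianReadLength / contigLength`, with a median read
length of 400 nt. A family's weight is the summed weight of contigs
hitting it; percentages are taken over total GH weight and summed into
five functional groups (cellulases, endohemicellulases, cell wall
elongation, debranching, oligosaccharide-degrading). Percentages sum to
100 by construction; doubling every read count changes nothing, while
multiplying one contig's depth scales exactly its own contribution.
Unassembled singleton reads are not separately weighted; only contigs
enter the inventory. The gene-level statistic (percentage of called genes
overlapping a GH domain hit) is unweighted.

# Full-length recovery and frameshift correction

Contigs of at least 1 kb are searched against reference enzymes by
affine-gap Smith-Waterman (BLOSUM62, gap open 11 / extend 1) on every
stop-free segment of all six frame translations. Raw scores are converted
with the standard ungapped Karlin-Altschul constants
(`lambda = 0.3176`, `K = 0.134`) to bit scores
`S' = (lambda S - ln K) / ln 2` and E-values `E = m n 2^(-S')`, with `m`
the reference length and `n` the total translated length searched. These
constants are defaults, not fitted values; the upstream tool's exact
parameterisation is unstated, so the standard published values are used.

A (contig, reference) pair becomes a candidate when (i) the union of HSP
reference spans covers at least 90% of the reference (chained coverage —
a single HSP is not required), (ii) the best E-value is at most 1e-10,
and (iii) the reference has a known enzymatic function (EC number).

**Frameshift delineation.** Pyrosequencing miscalls homopolymer run
lengths, producing single-base indels that split a gene across reading
frames. Boundaries are the contig intervals between consecutive
reference-ordered HSPs whose frames differ on the same strand, padded by
`editPad` (12 nt). HSPs on both strands indicate a chimeric candidate and
are refused rather than corrected.

**Correction objective.** Candidate edits are scored by a chained
translated-alignment score: per stop-free segment HSPs from the three
same-strand frames are chained along the reference; overlapped reference
residues are penalised at 12 raw-score units each (an upper bound on any
single residue's contribution, so double counting can never pay), and
each chain junction costs `frameshiftPenalty` (25 raw-score units). The
junction cost is what gives greedy ascent a gradient — rejoining two
fragments reclaims it — while keeping a genuine distant frameshift
cheaper to correct than to "bridge" with a wrong-sign edit through
garbled codons. Two simpler objectives fail structurally: a naive sum of
per-frame best scores double-counts the overlap region around the break
and can rank the broken gene above the restored one, and a single-best-
alignment maximum lets one opposite-sign edit bridge two nearby same-sign
indels into a lossy full-length alignment.

**Greedy ascent.** Overlapping boundary windows are merged; within the
windows every single-base deletion and duplication is evaluated
(equivalent edits inside one homopolymer run are evaluated once), and
the edit with the maximal strictly-improved score is applied (ties
prefer the longer homopolymer run, then the leftmost position — the
pyrosequencing mechanism lives in runs). Boundaries are then re-detected
and the loop repeats until no boundary remains, no edit improves, or
`maxIterations` (10) is reached; a repeated sequence state stops the
search with a warning. Only HSPs above the chain floor define boundaries
or the search region — sub-floor alignments cannot move the objective,
so their windows cannot contain improving edits. Accepted edits never
decrease the score, and the procedure is idempotent on its own output.

**Identifiability.** Exact-site recovery requires a close reference: when
the reference diverges from the true gene (e.g. a family consensus ~86%
identical to the sampled gene), a frame-restoring edit one codon away can
genuinely out-score the true restoration by "improving" the protein
toward the reference, and no score-maximising method can tell them apart.
The recovery acceptance test therefore pairs each planted gene with its
parent enzyme (profiles with degenerate emissions), the regime the
coverage and significance filters select for in practice; correction
against diverged consensus references is still exercised for mechanics
(monotonicity, idempotence), but site-exact recovery is not asserted
there. Two further inherent limits are documented by the tests' design:
indels within ~20 codons of a gene end leave one flank too short to form
an HSP, so there is no junction evidence to delineate them; and two
compensating indels closer together than the delineation resolution are
not correctable by single strictly-improving edits — the synthetic
fixture therefore plants forced indels at least 60 nt apart and at least
60 nt from gene ends, sampling runs with the error model's run-length
weighting. Within a homopolymer run the exact edit position is
fundamentally ambiguous (all positions yield the same sequence), and
fourfold-degenerate codons occasionally allow a protein-identical
restoration one base outside the run; recovery is scored within the run
plus 1 nt.

**ORF calling.** The trained bacterial gene finder used upstream is
proprietary; a transparent ORF caller substitutes for it and its output
is flagged `caller = "orf-caller"`. Per frame and strand, maximal
stop-free intervals of at least 300 nt are located; the gene starts at
the most upstream ATG/GTG/TTG and runs through the terminating stop.
Coordinates are reported 1-based closed on the forward strand with a
strand flag, the IRanges/GRanges convention used throughout the package.

**Truncation.** When the alignment leaves reference residues uncovered at
an end and the alignment abuts the contig end (within 3 nt), the
uncovered length is reported as a potential truncation caused by the
contig edge; a shortfall with ample contig remaining is a genuine end.

# Respiration and composition

The reactor mass balances are `CER = F (CO2_out - CO2_in)` and
`OUR = F (O2_in - O2_out)` with `F` the air flow in mg air per day per
gram dry weight and concentrations as mass fractions of the air stream.
These are the unique balances consistent with the stated units; the
source's equations are reconstructed from its symbol definitions.
Integration is composite trapezoid over the sample times (nominally every
20 minutes); mixing events cause real, brief rate drops and are included,
and sensor gaps are spanned, not interpolated. On smooth profiles the
integration error falls quadratically with the sampling interval, which
the tests verify by halving the grid.

Composition accounting assumes mineral ash is conserved, so the rise in
ash fraction measures total-solids loss: `loss = 1 - ash_i / ash_f`.
Measured final compositions (per kg of final solids) are adjusted to the
initial-mass basis by multiplying with `ash_i / ash_f`. Per-component
losses are `100 (initial - final_adjusted) / initial`, rounded half away
from zero for table presentation (exact values are retained in machine
output). The pooled loss of several components is mass-weighted —
`100 (sum initial - sum final) / sum initial` — because the unweighted
mean of per-component percentages does not reproduce the published pooled
value; the two agree only when all initial masses are equal.

# The synthetic-data module

The generators produce every input with recorded ground truth:

* **Communities** are declared by taxon labels, t0 abundances, fold
  changes (both timepoint vectors must sum to 1) and a per-taxon GH gene
  complement. Phylotype tables are multinomial draws at a chosen depth.
* **Contigs** embed genes sampled from family profiles, reverse
  translated with uniformly sampled synonymous codons (standard code, ATG
  start, single stop). Every gene is insulated by a 24 nt guard segment
  carrying stops in all six frames (its own reverse complement), and
  intergenic spacers are kept at 50-250 nt with long background stretches
  interleaved with guards, so no spurious ORF can reach the 300 nt
  calling threshold and ORF calling recovers exactly the planted
  coordinates. Read counts are Poisson with mean
  `depthScale x abundance x length / 400` (floored at one read), the
  inverse of the depth-weighting formula.
* **Frameshifts** are planted per homopolymer run of length >= 2 with
  probability `0.002 x (runLength - 1)` capped at 0.05 — a plausible
  shape for pyrosequencing error growing with run length; the magnitude
  is a free simulator parameter, not an empirical estimate. A forced mode
  plants an exact number of indels per contig for recovery tests, with
  the spacing and margin constraints described above.
* **Gas series and composition tables** are constructed by inverting the
  respiration and ash formulas, so round trips recover the generating
  rates and losses to machine precision.

What the generator does not emulate: read-level quality profiles,
chimeras, assembly artefacts beyond read-count noise, strain-level
variation within a taxon, and real OTU clustering. Passing tests
therefore demonstrate the correctness of the implemented algorithms under
controlled conditions, not robustness to every artefact of real
pyrosequencing data.

# Problem sizes and determinism

Every generator is a pure function of its seed; reruns are
byte-identical. The test suite works at deliberately compact scales: 30-150
match-state profiles, single-gene contigs of 1-1.5 kb, communities of a
few thousand nt, amplicon depths of 1e5-1e6, 100 genes with 0-3 planted
indels for correction recovery, and several hundred random contigs for
the false-positive check. These sizes keep the full suite comfortably
reproducible on a single CPU while leaving each statistical check enough
resolution (multinomial and binomial tolerances are stated in sigma units
in the tests).

# Known limitations

* Exact-label tallying stands in for OTU clustering; taxonomy assignment
  and chimera detection are out of scope.
* HMM hits carry bit scores only; no E-value calibration, glocal or
  multi-hit modes.
* Correction consults a single best reference per contig; candidates with
  HSPs on both strands are reported as chimeric, not corrected.
* The greedy corrector cannot resolve compensating indel pairs closer
  than its delineation resolution, nor indels hard against gene ends.
* The bioprocess calculations assume concentrations are already mass
  fractions of the air stream; unit conversion from sensor output is the
  caller's responsibility.
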
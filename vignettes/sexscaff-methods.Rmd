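---
title: "Methods: sex-linked scaffold identification in sexscaff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-linked scaffold identification in sexscaff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexscaff)
```

## The problem

A draft genome assembly of a species with XY sex determination arrives as
thousands of unordered scaffolds. Downstream analyses — sex-biased
expression, gametologue evolution, anchoring to a chromosome-level
reference — need each scaffold labelled as autosomal, X-linked or Y-linked.
Direct assembly of the Y is notoriously hard (it is small, repeat-rich and
present in only one copy per male cell), so the identification has to come
from evidence layered on top of the assembly:

1. **Read-depth dosage.** A male is XY and a female is XX. With one
   short-read library per sex mapped to the same assembly, autosomal
   scaffolds receive equal depth from both, X scaffolds roughly twice as
   much from the female, and Y scaffolds essentially no female coverage.
2. **Homology.** Whole-genome alignment to a chromosome-level reference of
   a related species assigns scaffolds to chromosomes where the alignment
   is unambiguous.
3. **Marker genes.** A catalogue of known Y-linked genes, searched against
   the assembly, confirms which depth-candidate Y scaffolds are real.

`sexscaff` implements all three plus their reconciliation, and ships a
synthetic-data generator with per-scaffold truth labels so every stage can
be validated end to end.

## Stage 1: the AD-ratio

For scaffold $i$ with female mean depth $F_i$ and male mean depth $M_i$,
the **AD-ratio** (average-depth ratio) is

$$ r_i = \frac{F_i}{M_i} \cdot k $$

where $k$ is a genome-wide normalization factor correcting for unequal
sequencing effort between the two libraries. Two estimators of $k$ are
provided (`compute_normalization()`):

* `"median"` (default): $k$ is the reciprocal of the length-weighted
  median of the raw ratios $F_i/M_i$. Because most of the genome is
  autosomal, the weighted median of the raw ratios estimates the
  female:male effort ratio robustly, unaffected by the X and Y tails.
* `"total"`: $k = \sum_i M_i L_i / \sum_i F_i L_i$, the ratio of total
  aligned bases. Simpler, but biased slightly upward by the X (female
  bases on the X exceed male bases), so `"median"` is the default. The
  pipeline computes both and logs their relative difference as a QC check.

The **length-weighted median** is defined exactly: the smallest value $x$
such that the cumulative weight of ratios $\le x$ reaches half the total
weight. With integer weights this equals the ordinary median element (at
rank $\lceil n/2 \rceil$) of the expanded sample; `weighted_median()` is
tested against that expansion oracle.

### Classification bands

`classify_scaffolds()` applies fixed bands to $r_i$:

| class | rule |
|---|---|
| `AUTOSOME` | $0.7 < r_i < 1.3$ (open interval) |
| `X` | $1.7 < r_i < 2.3$ (open interval) |
| `Y` | $r_i \le 0.3$ (inclusive) |
| `UNASSIGNED` | anything else, or $M_i$ below `min_male_depth` |

The expected ratios are 1 (autosome), 2 (X) and ~0 (Y); the bands are
symmetric ±0.3 around the first two. Boundary semantics are deliberate and
tested: $r = 0.7$ or $1.3$ is `UNASSIGNED`, $r = 0.3$ is `Y`. The Y band
is inclusive because the natural candidate set is "at most 30% of the
expected autosomal female share" and residual female coverage on the Y
(mismapping from X gametologues and repeats) pushes ratios up against that
edge from below. Scaffolds with $r_i \le 0.01$ are additionally flagged
`high_confidence_y`. A male-depth floor (`min_male_depth`, default 1×)
guards the ratio against division by near-zero depth: such scaffolds get
an `NA` ratio and `UNASSIGNED`.

All defaults live in `ad_thresholds()` and are validated for ordering
(e.g. `y_max` must not reach into the autosomal band).

### Histogram

`ad_histogram()` bins ratios into half-open bins $[b, b + w)$ of width
`bin_width` (default 0.025) up to `range_max` (default 3), with a final
overflow bin. One numerical subtlety: a ratio lying exactly on a bin edge
can be computed as `0.99999999…` of the edge in floating point. The bin
index therefore snaps to the nearest integer when `r / bin_width` is
within `1e-9` of it, so $r = 1.025$ always lands in $[1.025, 1.05)$.
Empty bins are kept so histograms of equal settings are comparable
row-by-row.

## Stage 2: homology anchoring

Scaffolds are aligned to a chromosome-level reference of a related
species. `parse_alignments()` accepts three dialects — PAF, `nucmer`
`show-coords -T` output, and BLAST outfmt 6 — and normalizes all of them
to 0-based half-open scaffold coordinates (`q_start < q_end`).

For each (scaffold, chromosome) pair, `merged_coverage()` computes the
number of scaffold bases covered by at least one alignment block,
$B_{i,c}$, by merging overlapping and book-ended intervals
(`IRanges::reduce()`; a per-base brute-force oracle in the test suite
verifies the merge on thousands of random interval sets). Multiple
overlapping hits to the same chromosome therefore count once — raw summed
alignment length would double-count and inflate weak evidence.

`assign_chromosomes()` then applies a **best-hit dominance rule**. With
$T_i = \sum_c B_{i,c}$ the total merged evidence, scaffold $i$ is assigned
to $c^\* = \arg\max_c B_{i,c}$ if and only if all of:

* there is any evidence at all ($T_i > 0$; otherwise `NO_HITS`);
* the maximum is strict — an exact tie yields `NO_DOMINANT`;
* the winner dominates: $B_{i,c^\*} / T_i \ge$ `dominance_min`
  (default 0.5; otherwise `NO_DOMINANT`);
* the evidence is non-trivial: $T_i / L_i \ge$ `coverage_min`
  (default 0.05 of scaffold length; otherwise `LOW_COVERAGE`).

Each unassigned scaffold keeps its machine-readable reason. The defaults
say: assign when at least half of the alignment evidence points at one
chromosome and at least 5% of the scaffold aligns anywhere — permissive
enough to anchor diverged regions, strict enough that chimeric or
repeat-driven scatter stays unassigned.

## Stage 3: Y marker genes

A catalogue of known Y-linked genes and their X/autosomal homologs
(gametologue pairs such as SRY/SOX3, RBMY/RBMX) is searched against the
assembly; `read_marker_hits()` ingests BLAST outfmt-6 hits joined to a
gene manifest (`gene`, `gene_class`, `partner_gene`). Marker coordinates
stay 1-based inclusive, the native BLAST/GFF convention, unlike the
anchoring alignments above — the two evidence types never share a
coordinate pipeline.

`place_genes()`:

1. discards hits with e-value > `evalue_max` (default `1e-10`);
2. scores each (gene, scaffold) pair by its **summed** bitscore, so many
   exons on one scaffold accumulate support;
3. places the gene on its top-scoring scaffold only if that score is at
   least `ambiguity_margin` (default 1.2) times the runner-up's;
   otherwise the gene is `UNPLACED_AMBIGUOUS`.

Note a genuine non-monotonicity, deliberately kept: relaxing `evalue_max`
can admit a runner-up scaffold that pushes a previously placed gene under
the margin. The margin is doing its job — new evidence revealed the
placement was not clear-cut.

`confirm_y()` then confirms a scaffold as Y-linked only if all three lines
agree:

* at least one Y catalogue gene is placed on it;
* its AD-ratio is $\le$ `y_max` (0.3) — otherwise `AD_TOO_HIGH`;
* no placed gene on it has its homolog partner placed on the **same**
  scaffold — otherwise `HOMOLOG_SAME_SCAFFOLD` (a scaffold carrying both
  SRY and SOX3 is likely a misassembly or an X scaffold cross-hit).
  A homolog that is simply unplaced does **not** veto: absence of
  placement is absence of evidence, not evidence of co-location, and
  vetoing on it would make confirmation hostage to the homolog search's
  sensitivity.

Depth-candidate Y scaffolds with no placed gene are reported as
unconfirmed candidates (`NO_GENES`) rather than dropped — on real data
most of the Y is gene-free and those candidates are exactly what a curator
wants to see. `gene_map_report()` emits a GFF3-style gene track for
confirmed scaffolds.

## Stage 4: reconciliation

`reconcile()` compares the two independent assignments at the
**chromosome-group** level (`chrom_group()`: X, Y, or AUTOSOME — pooling
all autosomes, since depth alone cannot distinguish chr1 from chr2) and
partitions total assembly length into four exhaustive, disjoint buckets:
`agree_bp`, `conflict_bp`, `one_method_unassigned_bp`,
`both_unassigned_bp`. An internal assertion checks the partition sums
exactly.

`consensus_assignment()` resolves each scaffold by precedence:

1. marker-confirmed Y ⇒ `chrY` (markers are the most specific evidence);
2. both methods agree ⇒ the homology chromosome (`BOTH`);
3. homology only ⇒ its chromosome (`HOMOLOGY_ONLY`);
4. coverage only ⇒ `chrX`/`chrY`, or `autosome_unplaced` for the
   autosomal group (depth knows the group, not the chromosome)
   (`COVERAGE_ONLY`);
5. otherwise `CONFLICT` or `NONE`.

`write_bed()` exports the consensus as BED9 with evidence-graded scores
for genome-browser display.

## The synthetic-data generator

`simulate_dataset()` produces a fully labelled toy study: a fragmented
karyotype, per-sex mosdepth-style summaries, reference alignments, marker
hits and truth tables, all written by `write_simulation()` in the same
file formats the readers parse.

**Karyotype.** The default toy genome is 100 Mb: six autosomes with
lengths proportional to $6{:}5{:}\dots{:}1$ summing to 97.1 Mb, a 2.6 Mb
X and a 0.3 Mb Y, echoing the small-X/tiny-Y proportions of a typical
mammalian assembly while keeping runtimes in seconds. Each chromosome is
fragmented into scaffolds with log-normal lengths
(`scaffold_len_logmean = log(1e5)`, `logsd = 0.8`, floor
`min_scaffold_len = 1000`); the partition is exact — scaffold lengths
tile each chromosome with recorded offsets.

**Depths.** Male depth is 55× on autosomes and 27.5× on X and Y; female
depth is 55× on autosomes and X and `female_y_background` (default 0.02)
× 55 on the Y, representing mismapping onto the Y. Noise is the one place
the generator takes a stance. Per-scaffold depth is

$$ D_{i,s} = \mu_{i,s} \cdot b_i \cdot \varepsilon_{i,s} $$

where $b_i$ is a Gamma-distributed **bias shared by both sexes** (GC
content, mappability — properties of the scaffold, not of the library)
and $\varepsilon_{i,s}$ is a sex-independent Gamma residual with CV
`depth_cv_resid` (default 0.04). The two CVs combine so the marginal
per-sex CV equals `depth_cv` (default 0.10). This decomposition is what
makes the AD-ratio method work on real data: scaffold-level biases cancel
in the female:male ratio, leaving only the residual. A generator with
fully independent per-sex noise at CV 0.10 would give the ratio a spread
of $\sqrt{2}\,\mathrm{cv}$ (and $2\sqrt{2}\,\mathrm{cv}$ on the X),
misclassifying several percent of autosomes and a large fraction of X
scaffolds — behaviour real sex-pooled resequencing data do not show.
Setting `depth_cv_resid = depth_cv` recovers the fully independent model
if you want to stress-test the bands.

**Alignments.** Each scaffold gets 1–3 true blocks on its source
chromosome jointly covering 60–95% of its length, dropped entirely with
probability `aln_miss_prob` (0.05). Independently, with probability
`aln_chimera_prob` (0.05) a wrong-chromosome block covering 5–20% of the
scaffold is added. The two draws are independent — a chimeric block can
appear on a scaffold whose true alignment was missed, in which case the
dominance rule is *expected* to follow the only evidence it has. This
keeps the chimera rate exactly binomial and is tested as such.

**Markers.** `n_y_genes` (20) gametologue pairs from a built-in catalogue
are placed: Y genes on Y scaffolds with strong hits, homologs elsewhere.
A fraction `y_gene_ambiguous_frac` (0.05) of Y genes instead receive 2–4
partial hits on different scaffolds with bitscores within a factor <1.2
of each other, so they must come out `UNPLACED_AMBIGUOUS`.

**Determinism.** All randomness flows from `sim_config(seed = )` through
per-stage substreams (`stage_seed()` hashes the stage name into an
offset; `withr::with_seed()` scopes the RNG), so outputs are
byte-identical per configuration and no stage perturbs another's draws or
the caller's RNG state.

### What the generator does not emulate

* Read-level artefacts: duplicates, mapping quality filters, coverage
  dips at scaffold ends. Depth is drawn at scaffold granularity.
* Pseudoautosomal regions, X-inactivation-related coverage structure, or
  partial sex-linkage; every scaffold is wholly one class.
* Assembly chimeras spanning sex chromosomes and autosomes (alignment
  chimeras are simulated; truth labels are per-scaffold).
* Reference-side errors in the related species' chromosome assembly.

## Resolved design ambiguities

* **Y band boundary**: $r \le 0.3$ inclusive (see above), applied
  consistently in classification and in `confirm_y()`.
* **Normalization mode**: both estimators implemented; `"median"` is the
  default and the pipeline logs both for QC rather than silently choosing.
* **Homolog placement absence**: does not veto confirmation (absence of
  evidence; see Stage 3).
* **Chimera independence**: chimeric blocks are drawn independently of
  the miss event (see generator).
* **Ties**: an exact best-hit tie is `NO_DOMINANT` rather than broken
  arbitrarily; determinism by refusal, not by order-dependence. Hit-row
  order never affects any result (tested).

## Limitations

* One sample per sex; the method has no notion of replicate variance.
  With multiple libraries, merge them upstream before computing depth
  summaries.
* Bands are fixed, not fitted; assemblies with unusual effective coverage
  on the sex chromosomes (e.g. PAR-heavy X scaffolds) will land between
  bands and stay `UNASSIGNED`, which is the designed failure mode.
* Anchoring quality is bounded by the relatedness of the reference; at
  high divergence `coverage_min` removes most scaffolds before the
  dominance rule can err.
* Y confirmation is bounded by the marker catalogue: a Y scaffold with no
  catalogued gene can never be confirmed, only remain a depth candidate.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
paths <- write_simulation(simulate_dataset(cfg), tempfile("simdata"))

run <- run_config(
  male_depth = paths[["male_depth"]], female_depth = paths[["female_depth"]],
  alignments = paths[["alignments"]], lengths = paths[["lengths"]],
  marker_hits = paths[["marker_hits"]],
  marker_manifest = paths[["marker_manifest"]],
  outdir = tempfile("sexscaff_run"))
run_pipeline(run)
cat(render_summary(run$outdir))
```

The same pipeline is exposed as a command-line tool at
`system.file("cli", "sexscaff.R", package = "sexscaff")` with
subcommands `simulate`, `adratio`, `anchor`, `confirm-y`, `reconcile`,
`run-all` and `report`.
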
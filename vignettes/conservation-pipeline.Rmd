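---
title: "Methods: conservation scoring, the decision pipeline, and its calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation scoring, the decision pipeline, and its calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpcons)
```

`snpcons` classifies missense variants (nsSNPs) by combining evolutionary
conservation with curated variant literature, entirely from local files.
This vignette is the package's own account of the underlying model, the
concrete numerical choices made where the design was open, and what the
synthetic benchmark does and does not demonstrate.

## Inputs and coordinate conventions

All coordinates are 1-based and inclusive, in protein residues or spliced
CDS nucleotides. A gene is represented by a `GeneRecord` holding the
reference protein, the CDS including its stop codon, and the exon lengths
in spliced order; the constructor enforces that the CDS translates exactly
to the protein and that exon lengths sum to the CDS length, so all
downstream coordinate arithmetic can assume consistency. Exon structure is
supplied as spliced-CDS lengths rather than genomic coordinates because
the only thing the pipeline needs from it is the position of the last
exon–exon junction; genomic coordinates, strands and introns are out of
scope.

Queries may be given as protein substitutions (`p.R175H`), CDS
substitutions (`c.524G>A`), or a raw flanking sequence of at least 100 nt
beginning at the mutated nucleotide. The flank is located by restoring its
first nucleotide to each of the four possible reference bases and
requiring a unique exact match of the leading 100 nt in the CDS — 100 nt
is retained as the uniqueness window, and zero or multiple matches are
errors rather than guesses.

## Conservation scores

**WPC.** At the alignment column of position $i$, with $a_i$ homolog rows
matching the unmutated human residue and $n_h$ valid homolog rows,

$$\mathrm{WPC}_i = 100 \cdot a_i / n_h .$$

Two definitional choices were open and are fixed as follows. *Valid* rows
are non-human rows with a non-gap character at the column: a gap carries
no residue evidence, so gapped rows are excluded from both numerator and
denominator. The human row itself is excluded so that the score measures
homolog support rather than self-match. WPC is reported on the 0–100
percent scale, which is the only scale on which the calibrated cutoffs
(40 and 49) are meaningful. If every homolog is gapped at the column the
score is undefined and classification raises an error carrying the partial
evidence — silently defaulting would hide exactly the situations a user
must inspect.

**PSIC-style profile.** The profile score follows the
position-specific-independent-counts idea — a per-column, per-residue
log-odds value — but the original weighting scheme is not recoverable from
the published description, so the package fixes its own concrete variant
and documents it: each row is weighted by the reciprocal of the number of
identical aligned rows (an exact-duplicate redundancy discount), counts
get a pseudocount of 1 per residue, and the background is uniform $1/20$:

$$V(r, c) = \log \frac{20\,(m_{rc} + 1)}{n_c + 20},$$

with $m_{rc}$ the weighted count of residue $r$ at column $c$ and $n_c$
the total weight of ungapped rows there. This makes the profile finite
everywhere, exactly invariant under duplication of an existing row, and
symmetric for a uniformly occupied column. The substitution score is the
absolute difference $|V(\mathrm{ref}, c) - V(\mathrm{alt}, c)|$ —
symmetric, nonnegative, zero for identity. The conventional benign cutoff
1.03 is kept as the default but, because the weighting is this package's
own, the cutoff should be re-derived with the training tools when
calibrated behaviour matters; this is precisely what `optimize_cutpoints()`
is for.

**BLOSUM62** is shipped as a plain-text NCBI-format matrix and used for
reporting only: on the published benchmark data it was not an informative
pathogenicity classifier, and the pipeline never branches on it.

One combined ortholog+paralog protein alignment drives classification;
separate ortholog/paralog alignments of protein and CDS, when supplied,
appear only in the conservation report.

## Protein–DNA mapping and the stop-gain rule

To tie a protein position to its codon the package matches a ten-residue
anchor, beginning at the variant (taken backwards within ten residues of
the C terminus, shrunk for very short proteins), against the translation
of every nucleotide offset of the CDS, and requires a unique match. The
published procedure orders this search by human codon frequencies as a
speed-up; since correctness is defined by the unique-match contract the
result is order-independent and the implementation searches exhaustively.
All nine single-nucleotide edits of the reference codon are then
enumerated; if more than one produces the alternate residue the mapping is
*ambiguous*: no definitive DNA position exists, nucleotide-level
conservation is suppressed in reports, but protein-level classification is
unaffected.

A stop-gain is auto-called pathogenic when the stop codon lies more than
50 nt upstream of the last exon–exon junction (the nonsense-mediated-decay
heuristic). Two details were unstated and are fixed here: the distance is
measured from the *first* nucleotide of the stop codon, and stops at or
downstream of the junction (negative distances), stops within 50 nt, and
single-exon genes all fall through to the ordinary pipeline with the
comparison strictly greater than 50. For a fallen-through stop-gain, WPC
is still computed against the reference residue (a stop never matches a
column) and the PSIC step is skipped, since the profile does not score
`*`.

## Hotspots and phenotype

A functional hotspot is deliberately broad: one known disease-associated
variant (classification `pathogenic` or `unspecified_functional`) within
the window — 100 residues to either side by default, inclusive at both
boundaries — suffices. The query variant itself never vouches for its own
hotspot: it is excluded by exact substitution match when the residues are
known, by position otherwise. Each catalogued variant counts once,
regardless of how many publications mention it, which keeps one heavily
annotated variant from dominating the window.

Phenotype prediction tallies the named phenotypes of windowed
disease-associated records and returns the most frequent, unweighted by
distance (a weighting was considered and rejected as an undocumented free
parameter). Ties resolve to the phenotype of the record nearest the query,
then lexicographically — deterministic and documented rather than
order-dependent. Records with functional evidence but no named disease
contribute to the window total and can yield a `functional_only` status,
never a named phenotype; an empty window is `no_data`.

## The decision pipeline

The ordered rules are: stop-gain (if enabled) → hotspot screen → optional
PSIC benign filter (strictly below cutoff) → WPC decision (pathogenic at
or above cutoff). The operative WPC cutoff is 49 in the default
(PSIC-off) mode and 40 with the PSIC filter active, matching the two
calibrated operating points. The published description contains one
internal tension — a WPC ≥ 40 "classified pathogenic" sentence that could
be read as overriding the PSIC benign filter — and the package follows the
explicitly stated pipeline ordering instead: the PSIC filter, when
enabled, short-circuits first. Both the hotspot screen and the stop-gain
stage can be toggled off (`use_hotspot`, `use_stopgain`); with hotspot
screening off no `Benign(h)` label can occur and phenotype status is
always `no_data`.

## Calibration machinery

Pathogenic is the positive class throughout. `optimize_cutpoints()`
grid-searches WPC on integers 0–100 and PSIC in steps of 0.01 over the
observed range — resolutions chosen to match the precision of the
calibrated cutoffs (49 and 1.03) — maximizing the balanced accuracy of the
full pipeline on precomputed feature columns, with ties resolved to the
smallest WPC cutoff, then the smallest PSIC cutoff. `gene_grouped_kfold()`
shuffles genes with a seeded RNG and assigns each, in shuffled order, to
the currently lightest fold by variant count, so folds are balanced by
variant count (not gene count) and no gene ever spans folds.
`cross_validate()` trains on $k-1$ folds, evaluates on the held-out fold,
and traces a held-out ROC by sweeping the WPC cutoff with the upstream
stages frozen at their trained values (non-hotspot rows rank below
PSIC-filtered rows, which rank below all WPC values); the averaged curve
is a vertical (fixed-FPR) average on a 101-point grid, which the published
"multinomial ROC" names but does not define. ROC construction groups tied
scores at a single threshold and integrates by trapezoid; it agrees with
the Mann–Whitney pairwise statistic to numerical precision, which the test
suite asserts at $10^{-9}$.

## The synthetic benchmark

The generator emulates the *structure* of the real inputs — genes with
consistent protein/CDS/exons, combined alignments with controllable
per-column conservation, a known-variant table with planted hotspot
regions and phenotypes, and a truth-labeled evaluation dataset — under the
following default conditions, used by the test suite and the acceptance
script: 100 genes of 400 residues; 30 homologs per alignment with a 5 %
independent per-cell gap rate (exercising the valid-row denominator);
per-column target conservation drawn uniformly on $[0,1]$ per gene; two
disjoint hotspot regions per gene (roughly residues 20–180 and 220–380)
with distinct phenotypes, 25 planted pathogenic records each plus 15
scattered benign records; and 2000 evaluation variants drawn inside the
regions. Mismatching cells vary among two fixed column-specific
alternative residues rather than uniformly over all nineteen, mirroring
the small exchangeable-residue sets of real columns; half the evaluation
variants take an alternate residue actually observed in their column
(tolerated exchanges with low profile contrast) and half a novel one, so
the catalogue spans the WPC and PSIC axes separately instead of tying them
together. Truth labels apply the planted rule to the *realized*
conservation of the generated alignment (the measured WPC, and profile
score for the two-feature rule), so cutpoint recovery is a property of the
optimizer rather than of binomial sampling noise; recovery lands within
one grid step of the planted values (the tie-break settles at the bottom
of the empty score gap below the planted threshold).

What passing these tests shows: the scoring, mapping, windowing, decision
and training code do exactly what the model says on inputs whose ground
truth is known by construction. What they do not show: performance on real
variant catalogues. The generator has no phylogeny (homologs are
conditionally independent given the column profile), no indels in the
human row, uniform codon usage, no annotation noise, and hotspot regions
that are cleanly separated — so the near-perfect synthetic accuracies are
sanity ceilings, not forecasts of the published benchmark figures, which
were obtained on curated human datasets this package deliberately does not
bundle.

## Known limitations

Standard genetic code only (no selenocysteine); spliced-CDS space only (no
genomic coordinates or strand handling); isoform deduplication of
paralogous alignments is the caller's responsibility — alignments are
scored as given; the PSIC weighting is this package's own concrete scheme,
so the 1.03 default transfers only approximately and should be retrained
for calibrated use; dbSNP accession resolution and any live database
retrieval are out of scope by design — the package is offline-first, and
every reader consumes the documented local file dialects instead.
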
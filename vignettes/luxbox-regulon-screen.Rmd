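---
title: "Screening metagenomes for AHL quorum sensing and lux-box regulons"
author: "luxscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening metagenomes for AHL quorum sensing and lux-box regulons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luxscreen)
```

# The problem

Acyl-homoserine-lactone (AHL) quorum sensing couples bacterial gene
expression to population density: a LuxI-family synthase makes the AHL
signal, a LuxR-family receptor binds it, and the AHL-loaded receptor
activates transcription at a roughly 20 bp imperfect-palindromic operator
(the *lux box*) in the promoters of regulated genes. In a complex community
— activated sludge is the motivating case, with *Nitrospira*-driven nitrite
oxidation as the function of interest — the question is twofold: *which
organisms carry functional AHL circuits*, and *which genes do those circuits
regulate*. `luxscreen` answers the computational half of both questions
from an assembled metagenome plus standard annotation tables, and ships a
synthetic-community generator so that every stage can be validated by
parameter recovery against planted ground truth.

The package deliberately consumes *tables*, not raw databases: protein
search results (BLAST/DIAMOND 12-column tabular format, optionally extended
with `ko_id`, `function_label` and a `rank:name` lineage column) and a
Pfam-style domain-hit table. Running the searches themselves, assembling
the metagenome, and calling genes are out of scope; so is anything wet-lab.

# The gene screen

**Best-KO rule.** For each ORF the screen compares its best bitscore among
QS-associated KEGG Orthology groups — synthases K13060, K13061, K13062,
K18096; receptors K07782, K18098, K18099 — with its best bitscore among
*all other* hits. The ORF is a candidate only when the QS score is strictly
higher. Ties are rejected and logged rather than resolved arbitrarily:
"higher than" is read strictly, so a tie is evidence of an ambiguous gene,
not a QS gene. Hits with no KO label count on the non-QS side — they are
evidence for some other function. The rule is, by construction, invariant
under permutation and duplication of hit rows, and the tests re-check the
strict inequality against the raw table for every emitted candidate.

**Domain validation.** A synthase candidate is validated by an autoinducer
synthase domain hit (Pfam00765); a receptor needs *both* the
autoinducer-binding domain (Pfam03472) and the GerE helix-turn-helix domain
(Pfam00196). Default e-value cutoff: 1e-5, the conventional
domain-significance threshold. An empty domain table leaves candidates
`untested` rather than failing them.

**Residue audit.** Functional LuxR receptors conserve five acyl-binding
residues (W66, D79, P80, W94, G121) and three DNA-binding residues (E187,
L191, G197) in the numbering of a reference LuxR. The audit aligns each
candidate globally to an annotated reference (BLOSUM62, gap open 11, gap
extend 1 — standard protein-search settings, computed with
`Biostrings::pairwiseAlignment`) and reports the aligned residue at each
annotated position. Gaps are reported separately and never counted as
missense. The shipped default reference is **synthetic**: a fixed 210-aa
sequence with the expected residues planted at the annotated positions. It
exists so the audit machinery is testable out of the box; any real analysis
should supply the reference that defines its numbering scheme via
`luxr_reference(sequence)`. The reference is validated on construction — a
reference lacking an expected residue at an annotated position is a
configuration error.

**Cognate pairing.** *luxI*/*luxR* pairs in nature are usually adjacent and
often divergently transcribed. Pairing distance is not a published
constant, so it is a parameter: a synthase and receptor on the same contig
with at most `max_intervening = 3` ORFs between them may pair. Matching is
greedy nearest-first (deterministic tie-break by ORF id), each gene joins
at most one pair, and orientation is classified as divergent, convergent or
tandem from the strands in contig order. Receptors left over are *luxR*
solos — biologically interesting in their own right as putative
eavesdroppers.

# Taxonomy and contig binning

Each ORF's annotation uses its *Sbest window*: hits with bitscore at least
`0.95 × Sbest` (the best bitscore). The boundary hit is kept — "within 5 %
of the best" is implemented as `>=`, which is floating-point-safe; a
`strict` flag restores the exclusive reading. Within the window, the
consensus function requires a strict majority (>50 %) of the labelled hits;
anything less, including a tie, yields `"ambiguous"` rather than a silent
lexicographic pick. The taxon is the lowest common ancestor of the window's
lineages — the deepest lineage that is an element-wise prefix of every
hit's lineage. Both operations are checked against brute-force oracles on
thousands of random windows.

Contigs are called for the target taxon by a tiered ORF-fraction rule:

| ORFs on contig | required target fraction |
|---|---|
| > 6 | > 50 % |
| 4–6 | > 60 % |
| ≤ 3 | 100 % |

The published form of this rule leaves exactly three ORFs uncovered
("between 4 and 6" versus "fewer than 3"). The package extends the 100 %
tier to cover three ORFs — the conservative choice, since it demands
unanimity — and flags the call as tier `iii*` wherever that extension
fires, so downstream users can see it. "Between 4 and 6" is read inclusive.
Fraction thresholds in the first two tiers are strict: a 5-ORF contig with
exactly 60 % target ORFs is *not* called. Target membership is prefix-based
on the lineage, so a genus-level target matches any deeper classification
beneath it. The whole rule is tested against a frozen exhaustive truth
table over all `n_orfs` 0–10 and every feasible `n_target`, plus a
monotonicity property (raising `n_target` can never lose a call).

# Lux-box scanning

**The motif model.** The PWM is built directly from an aligned library of
equal-width lux-box sites (the field's libraries are already aligned
20-mers, so no de-novo motif discovery is needed):
`log_odds = log2(((counts + a) / (N + 4a)) / background)` with pseudocount
`a = 0.1` per cell. The pseudocount keeps log-odds finite for unobserved
bases without washing out a 54-site signal; both it and the background are
configurable. `N` in a scanned site contributes score 0 — the
background-expected contribution.

**Exact p-values.** A site's p-value is the probability that a random
width-*w* sequence drawn i.i.d. from the background scores at least as
high. The per-column score distributions are convolved by dynamic
programming. Two regimes:

* *width ≤ 10*: the convolution keeps every achievable score sum (support
  at most 4^w). Prefix sums are accumulated left-to-right in plain double
  precision — bit-identical to `score_site()`'s accumulation — so a query
  site's own score always lands exactly on its mass point and ties are
  resolved consistently. These p-values equal exhaustive enumeration over
  all 4^w sequences to within 1e-9 (in practice, exactly).
* *width > 10* (including the 20 bp lux box): per-column scores are
  discretized onto a shared integer scale with `granularity = 1000` bins
  spanning the widest column range, and the DP runs over integer totals.
  The tests compare the discretized tail with the exact one at width 8 and
  find agreement within 2 %; at the 1e-4 decision threshold the
  discretization error is far below the sampling noise of any real scan.

A score above the maximum achievable returns the distribution's minimum
positive mass, never 0, so log-transforms stay finite. The p-value is
monotone non-increasing in the score by construction.

**Scanning and filtering.** The 400 bp upstream region of each ORF
(strand-aware: positions `[start-400, start-1]` for + ORFs, the reverse
complement of `[end+1, end+400]` for − ORFs; clipped and flagged at contig
edges) is scanned at every offset on both strands. At one offset only the
better-scoring orientation is reported (tie → +): near-palindromic sites
would otherwise report themselves twice. Hits need `p < 1e-4` (strict) and
an imperfect-palindrome filter: at most 8 of 20 positions may differ from
the site's own reverse complement. That cap is a decided parameter, not a
published constant — it is the smallest even bound that admits both
experimentally studied sites (2 and 8 mismatches respectively) while still
rejecting the bulk of random high-scorers, and it is configurable
(`palindrome_max`). A perfect palindrome (0 mismatches) passes.

**Background model.** Whether the scan's null should use a global or local
base composition is genuinely open; the default estimates the background
from each region's own composition (add-one smoothed so no frequency is
zero), which adapts to local GC content, and can be switched to the model's
own background or a fixed vector via `regulon_config(background = ...)`.

**Promoter context.** Candidates are annotated with: intergenic/intragenic
location (any 1 bp overlap with any ORF interval is intragenic);
`distance_upstream`, counting the nucleotides strictly between the site's
proximal edge and the first base of the start codon (so "81 bp upstream"
means 81 intervening nucleotides — the convention used for reported lux-box
distances); σ70 −35/−10 hexamers (consensus TTGACA / TATAAT, ≤ 2 mismatches
each, spacer constrained to 15–19 bp, best compatible pair by total
mismatches with unpaired elements still reported); and a Shine–Dalgarno
element (≥ 4 consecutive matches to AGGAGG within the final 20 bp, ending
4–14 nt before the start codon). When one genomic site lies in the upstream
regions of two divergently transcribed ORFs, both candidates are emitted
and cross-referenced — the biologically important bidirectional-promoter
arrangement in which one lux box drives both a synthase gene and a
divergent neighbour.

# The synthetic-community generator

`generate_community()` is first-class, tested code, not a fixture dump. It
emulates the *inputs* of the screen: multi-kilobase contigs with i.i.d.
background sequence at a set GC content (default 0.5), strand-aware
non-overlapping ORF intervals at about 1 ORF/kb (typical bacterial gene
density), per-ORF hit rows that make the best-KO rule true for planted
genes (QS-KO bitscore 250 against decoys at 180 and 150 — comfortably
separated, as real full-length homolog hits are) and carry each contig's
lineage, Pfam rows for planted genes, receptor proteins derived from the
annotated reference (solos get 1–3 planted acyl-domain missense mutations,
matching the range reported for real solos), and a 54-site lux-box library
generated by mutating the experimentally characterised consensus
`ACCTGGCGGTTCCGCCAGGT` at 5 % per column — calibrated so the mean per-site
Hamming distance is about 1, i.e. "highly conserved, previously reported"
sites. Each cognate pair is divergently arranged with the lux box planted
exactly 81 bp upstream of the synthase start codon — the geometry of the
characterised synthase promoter — inside both genes' upstream regions, with
consensus −35/−10 elements (17 bp spacer) and a Shine–Dalgarno written in
literally.

Randomness policy: one mandatory root seed; each component (contigs, ORFs,
hits, boxes, proteins, library) draws from a deterministic child stream, and
the manifest records the seed and a config hash. Outputs are
byte-deterministic under the seed. The manifest is sufficient to score any
recovery experiment. `corrupt_hits()` degrades tables on purpose —
QS/non-QS score ties and whole-ORF dropouts at set rates — to exercise the
strict-inequality and empty-window edge cases.

What the generator does **not** emulate: codon structure (ORFs are
coordinate intervals; the pipeline never translates contig DNA), sequencing
error, assembly artifacts, chimeric contigs, horizontally transferred
composition, or realistic bitscore distributions. Passing recovery tests
therefore demonstrates that the *rules are implemented correctly and are
recoverable under clean conditions*, not that the screen is robust to every
pathology of real metagenomes.

# Numerical and design choices, in one place

* Tie between best QS and best non-QS score → **not** a candidate; logged.
* Sbest window boundary kept (`>=`); `strict` option available.
* Majority rule strict; ties → `"ambiguous"`.
* Tier gap at 3 ORFs closed conservatively (100 % required, flagged `iii*`);
  "between 4 and 6" inclusive.
* p-value DP exact to width 10, discretized (1000 bins/column) beyond;
  thresholds strict (`p < 1e-4`, fold `> 1.5`).
* Palindrome cap 8 of 20 — decided, configurable.
* Per-offset orientation collapse, tie to +.
* Pairing `max_intervening = 3`, greedy nearest-first, deterministic
  tie-breaks.
* Fold induction aggregates replicates as mean-of-ratios (normalize each
  replicate to its OD600, then average) — the aggregation order is not
  fixed by convention, and mean-of-ratios keeps each replicate's
  normalization honest; documented here once, implemented once.
* Degenerate inputs: empty hit tables, hitless ORFs, clipped or empty
  upstream regions, empty domain tables and zero-candidate screens all
  produce empty-but-well-formed results with warnings, not errors.

# Problem sizes used in the test suite

The suite validates: p-value exactness on 20+ random PWMs of width ≤ 6
against full 4^w enumeration; LCA/consensus on 1,000 random windows against
brute-force oracles; the contig-tier rule against the frozen 66-row truth
table; planted-box recovery on 100 seeded 400 bp regions (recall ≥ 0.9,
false-positive regions ≤ 5 % — observed: recall 1.0, 0–2 % false
positives); 50 residue-audit queries with planted missense sets; and
end-to-end recovery on communities of six ~5–12 kb contigs (~50 ORFs).
These sizes keep the default suite fast while leaving every scaling
dimension (motif width, window count, region count, contig count)
exercised well above its edge cases.

# Limitations

* The screen is only as good as its input tables: KO misannotation or a
  stale lineage column propagates directly.
* The best-KO rule is a point decision per ORF; no attempt is made to
  model paralogs or fragmented genes spanning contig breaks.
* The PWM assumes position independence; dinucleotide structure in real
  lux boxes is not modelled.
* No multiple-testing correction is applied across scanned regions — the
  screen intentionally uses the raw `p < 1e-4` threshold and relies on the
  palindrome filter and downstream experimental verification to control
  false positives.
* The residue audit depends on a user-supplied reference numbering; the
  shipped synthetic reference is a scaffold for testing, not a biological
  claim.
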
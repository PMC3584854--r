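---
title: "Local active-site matching: model, conventions, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local active-site matching: model, conventions, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salsar)
```

## The problem

Thousands of structural-genomics (SG) proteins have solved structures but
unknown or merely putative biochemical function, and transferring the
function of the nearest global sequence or fold match is notoriously
unreliable: common folds such as the TIM barrel host dozens of distinct
chemistries. This package implements a *local* test instead: does the
predicted catalytic site of the query protein look — residue types in
matching spatial positions — like the predicted catalytic sites of proteins
whose function is established? A strong local match supports a putative
annotation; a poor or negative one argues for misannotation and, when a
different subclass matches well, suggests a re-assignment.

The package does not predict functional residues itself. It consumes
per-residue functional-likelihood rankings (POOL-style output, i.e. an
ordered list of all residues by probability of active-site participation,
derived upstream from electrostatics, phylogeny and pocket geometry) and
treats the ranker as an exchangeable input.

## The pipeline

1. **Site extraction** (`select_top_fraction()`): the predicted site is the
   top `ceiling(fraction * N)` residues of a structure's ranking. The
   cut-off fraction is a per-run parameter (published analyses use 8–9%
   depending on the family; no selection rule is claimed, so no default
   heuristic is either). Ceiling rather than floor, so any nonzero
   fraction yields at least one residue.
2. **Correspondence** (`iterative_superpose()`, `map_site_positions()`):
   structures are superposed pairwise onto a reference (star topology, for
   determinism) by a Kabsch fit on sequence-aligned CA pairs, iteratively
   discarding pairs further apart than `trim_distance` (default 6 Å).
   Only the local region around the site needs to align well, which is
   exactly what the trimming converges to. Site residues are then clustered
   into *spatial positions*: every predicted residue of the reference
   anchors a position, residues of other structures are assigned
   one-to-one by minimum total side-chain-centroid distance within
   `threshold` (default 4 Å), and leftover predicted residues agglomerate,
   closest first, into unanchored positions. Alternatively, an externally
   computed multiple alignment can define the positions directly
   (`import_msa_positions()`), which is also how the packaged worked
   examples were transcribed.
3. **Table** (`build_salsa_table()`): rows are structures, columns are
   positions; cells carry the residue with a predicted flag (uppercase in
   the TSV rendering, lowercase when present but unpredicted) or a gap
   (`-`).
4. **Consensus** (`derive_consensus()`): a position enters the signature of
   a functional subclass iff *more than* `majority_threshold` (default
   0.5, i.e. a strict majority) of the reference rows carry a *predicted*
   residue of the modal amino-acid type there; a modal tie drops the
   position rather than guessing. With five references, 4/5 agreement
   passes and 2/5 does not.
5. **Scoring** (`score_match()`, `max_score()`): see below.

## The scoring convention

Let the signature positions carry consensus types $c_1 \dots c_k$ and the
query cells types $q_1 \dots q_k$. The raw score is

$$ S = \sum_{i=1}^{k} s_{62}(c_i', q_i') $$

with $s_{62}$ the BLOSUM62 half-bit matrix and the *effective* type $x'$
of a cell equal to its actual type when the residue is predicted and to
the ambiguity code `X` when it is present but unpredicted; a gap cell
contributes a fixed `gap_penalty` (default −3) instead. The maximum is the
signature's self-match $M = \sum_i s_{62}(a_i, a_i)$ over *actual* types
$a_i$ regardless of predicted status, and matches are reported as
$\mathrm{round}(100\,S/M)$ percent, halves away from zero.

Three details deserve justification, because the published descriptions
leave them implicit:

* **Unpredicted = X.** Scoring a present-but-unpredicted residue by its
  actual type would reward residues the ranker gave no functional weight;
  scoring it as a gap would ignore that a residue is physically there.
  The `X` column (NCBI convention: 0 vs A/S/T, −2 vs C/P/W, −1
  otherwise) is the standard "type unknown" compromise, and it is the
  single convention that reproduces every one of the published worked
  example scores shipped with the package (48, 39, 97, −5, 51, 30).
  Note that the BLOSUM62 copy distributed with Biostrings flattens the
  `X` column to a uniform −1; the package therefore embeds its own
  transcription (tested entrywise against Biostrings over the 20
  standard letters).
* **Maxima use actual types.** The perfect match is "the signature with
  itself", including any unpredicted residues a single-row signature
  carries; this is what makes a 14-position signature row with one
  lowercase cell have maximum 97 rather than 92.
* **Gap penalty −3.** No published value exists; −3 (roughly a bad
  mismatch) reproduces the published −5 example with three gaps and is
  configurable (`--gap-penalty`).

One published cross-comparison is *not* reproduced, deliberately: the
nine-position comparison between the characterized enoyl-CoA hydratase row
and the putative-hydratase query prints a raw score of 11 (22% of 51).
Under the package's uniform convention that comparison scores −3, and under
plain actual-type scoring 12; no single convention consistent with the
other four printed scores yields 11. The value is excluded from the
acceptance targets and asserted in the test suite at its convention value
(−3) so the discrepancy stays visible rather than silently "fixed".

When a single characterized structure serves as the comparison target
(too few characterized relatives for a consensus), `row_signature()` uses
its row directly; its unpredicted residues stay in the signature with
their actual types (counting toward the maximum) but are scored as `X`.
For the β-diketone-hydrolase worked example the seven-position query row
is the signature side (maximum 50), which is what makes its score of 30
equal 60% of maximum.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `top_fraction` | 0.09 | fraction | ranking cut defining the predicted site |
| `threshold` | 4.0 | Å | max centroid distance for residues to share a position |
| `trim_distance` | 6.0 | Å | CA–CA rejection cut in iterative superposition |
| `max_iter` | 10 | – | superposition refinement iterations |
| `majority_threshold` | 0.5 | fraction | strict-majority consensus rule |
| `gap_penalty` | −3 | score | contribution of a gap cell |

The 4 Å position threshold reflects that two catalytically equivalent
side chains superpose to within a few Å in a good local alignment, while
distinct positions in a real site are farther apart; 6 Å for backbone
trimming is looser because CA traces of homologs drift more than their
conserved side chains.

## What the synthetic generator emulates — and what it does not

`make_toy_family()` states a small, explicit world: a family of
`n_structures = 5` members of `n_residues = 50` residues sharing one
background sequence; a planted constellation of 8 catalytic-type residues
at fixed geometry (a 9 Å ring, so inter-position distances are safely
above the 4 Å threshold) with per-coordinate Gaussian jitter of σ = 0.3 Å
— the coordinate-precision regime of well-determined crystal structures;
10 decoy residues on a 14 Å shell that outrank the background but not the
site; the remaining residues on an idealized α-helical CA trace displaced
40 Å away. Rankings place the site residues in the top ranks (shuffled),
then everything else by distance to the site. All randomness flows from
one integer seed through R's generator, and coordinates are rounded to
PDB precision before use, so regeneration is byte-identical.

This exercises the full pipeline — parsing, ranking ingestion,
sequence-seeded superposition, assignment, consensus, scoring — against
known ground truth. It does **not** emulate real folds, side-chain
packing, sequence divergence of homologs (members share the background
sequence), alternative conformations, or any electrostatics; a green
recovery test therefore establishes the pipeline's correctness, not the
method's biological sensitivity or specificity. The discrimination test
(a family scored against the consensus of a disjoint-type family stays
below 50% of maximum) is likewise a qualitative sanity check, not a
calibrated error rate — published experience is that too few verified
cases exist to translate the percentage into a confidence.

## Numerical choices

* **Alignment.** Global Needleman–Wunsch/Gotoh, BLOSUM62, gap of length
  *L* costs 11 + *L* (the NCBI "open 11 / extend 1" convention), end gaps
  penalized. Traceback ties prefer substitution, then a gap consuming the
  first sequence. Identity = identical columns / full alignment length,
  gap columns in the denominator; published identity matrices may use a
  different denominator, so such values are treated as reference-only.
* **Kabsch.** SVD with the determinant correction for reflections;
  rank-deficient (collinear) point sets are flagged but still solved.
* **Assignment.** Exact minimum-cost matching (shortest augmenting path);
  distance ties are broken toward the earlier residue in the chain by an
  epsilon far below coordinate precision (10⁻⁹ Å). Gap (non-assignment)
  carries a cost exceeding any attainable match total, so match
  cardinality is maximized first.
* **Rounding.** Percentages round halves away from zero (81.25 → 81,
  −5.15 → −5, 21.6 → 22); base R's banker's rounding would differ at
  halves.
* **Degenerate inputs.** A fraction outside (0, 1], an empty sequence, a
  non-permutation ranking, fewer than 3 superposition pairs, a reference
  absent from the structure list, or a cell naming an unknown residue all
  raise typed, early errors rather than propagating.

## Known limitations

* Rigid-body superposition only; no flexibility, no domain decomposition.
* The correspondence seed is sequence-based; families with undetectable
  sequence similarity should use an imported structure-aware MSA.
* Multi-chain PDB files require an explicit chain choice (published
  analyses never state which chain was used, so none is guessed).
* The percent-of-maximum score is a ranking aid, not a calibrated
  probability; no acceptance threshold is asserted.
* mmCIF, NMR ensembles beyond model 1, hydrogens and B-factors are out of
  scope.
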
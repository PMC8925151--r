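---
title: "Analysing coding minisatellites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing coding minisatellites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minisatr)
```

# The problem

PRDM9 positions meiotic recombination hotspots by binding DNA through an
array of C2H2 zinc fingers, each encoded by one 84-bp unit of a coding
minisatellite. The array evolves fast — by point mutation concentrated at
the three DNA-contact codons, and by slippage that duplicates or deletes
whole units — so ordinary sequence phylogenetics and diversity statistics
do not apply directly: alleles differ in length, and the repeat units
within an allele are paralogous copies. `minisatr` implements the desk
pipeline for this situation: partition alleles into units, type the
encoded fingers, compare arrays with a slippage-aware edit distance, build
distance trees, and summarise diversity and differentiation on pools of
stacked repeat units. A forward-time simulator generates alleles with
known ground truth so every stage is testable without any external data.

# Repeat units, zinc fingers and masking

An allele is an ordered array of equal-length units (default 84 nt; the
array sequence must be an exact multiple after flank trimming, anything
else is an error naming the record). Units translate in frame 1 to
28-residue fingers; a configurable circular frame offset (default 0)
accommodates amplicons whose repeat phase is rotated relative to the
coding frame — tandem repetition makes phase a circular choice.

The DNA-contact residues sit at alpha-helix positions −1, +3 and +6,
i.e. unit amino acids 13, 16 and 19 (codons 37–39, 46–48, 55–57). These
positions evolve under diversifying selection, so all distance and
diversity computations can be run *masked*, with those nine nucleotides
excised (84 → 75 nt). A `mask_spec` makes the positions configurable;
the default follows the convention of masking exactly (−1, +3, +6).
Whether helix position +2 should ever be masked is genuinely open — some
structural accounts include it among DNA-binding residues — but the
default here masks only the three canonical contact positions, and a
custom `mask_spec(c(13, 15, 16, 19))`-style specification covers the
alternative.

Structural validity of a finger is checked by its C2H2 anchors: cysteines
at residues 8 and 11, histidines at 24 and 28, with no stop codon. The
anchor offsets are configuration; the defaults follow the canonical layout
of the conserved first array finger in baleen whales, represented here by
a synthetic consensus unit (`ancestral_unit()`, also shipped as
`inst/extdata/synthetic_reference_unit.fasta`). This is a constructed
sequence — valid anchors, contact code DSK — not a database record, and it
doubles as the simulator's ancestor. Profile-HMM scoring of fingers is
deliberately not reproduced; anchor validation is the package's stand-in
criterion.

Ambiguity is handled conservatively throughout: `N` mismatches every base
including another `N` in distances; codons containing `N` make a finger
invalid (its contact code is still reported when the three contact codons
themselves are unambiguous); a missing contact code matches nothing in
motif comparisons.

# Typing, naming and core motifs

Zinc-finger types are distinct by the full 28-residue sequence, not just
the contact triplet — fingers sharing a contact code can differ at other
residues. Types carried by more than one individual are *common*, the
rest *unique*. Allele variants collapse alleles with identical arrays of
unit translations (protein-level identity; a nucleotide-level switch gives
finer splitting) and are named `<HEM><total>_<letter>`, where the total
counts array units plus the proximal zinc knuckle (`knuckle_count`,
default 1, because the knuckle is part of the finger domain but not a
repeat unit). The naming order — descending member count, ties broken
lexicographically on the signature — is the package's own convention,
chosen so that names are deterministic and permutation-invariant; the
letter order itself carries no meaning.

The *core motif* of a variant is the ordered contact-code fingerprint of
array positions 3–6 (1-based on the array, knuckle excluded), the fingers
reported to matter most for DNA binding. Pairs of motifs classify as
`symmetric` (identical at every position), `asymmetric` (different at
every position) or `partial`; the thresholds are declared rather than
derived — the underlying biology is qualitative — so the per-position
match count is always attached for re-thresholding. Comparison is on
contact codes, not on predicted nucleotide binding motifs: motif
prediction from finger sequences is out of scope.

# The weighted repeat-array edit distance

The distance between two arrays is the minimum total cost over monotone
alignments of their units:

* aligning unit *i* of one array to unit *j* of the other costs
  `w_mut ×` (nucleotide Hamming distance between the units),
* an unaligned unit costs `w_indel`, reduced to `w_slippage` when the
  unit is an exact copy of an adjacent unit of its own array — the
  signature of replication slippage.

Defaults are `w_mut = 1`, `w_indel = 3.5`, `w_slippage = 1.75`, the
weighting scheme established for repeat-array comparison of this locus.
Unit Hamming counts are unnormalised (one unit mismatch = one nucleotide),
so a single-base substitution costs exactly 1.

Three design points deserve emphasis:

* **Slippage eligibility** is decided on the *original* arrays, against
  both neighbours, in the same comparison space (masked or unmasked) used
  for substitution costs. This keeps the cost of every alignment
  well-defined independent of alignment order, which is what makes an
  exhaustive oracle possible.
* **The oracle.** `brute_force_distance()` enumerates every monotone
  matching and applies the cost rules literally, sharing no code with the
  dynamic programme; the test suite sweeps all pairs of arrays up to four
  units over a three-unit alphabet (chosen so that masking changes both
  Hamming distances and slippage eligibility) in both mask settings and
  requires exact agreement.
* **Non-metricity.** Context-dependent gap costs can violate the triangle
  inequality, so no such property is asserted; neighbour joining accepts
  non-metric input. Ties in the traceback are broken deterministically
  (match > deletion > insertion) and carry no semantic weight — only the
  minimum cost is meaningful.

Masking can only remove mismatches and can only make slippage identity
easier, so masked distances are elementwise bounded by unmasked ones; the
suite checks this as a property.

# Trees

Distance matrices (optionally deduplicated to one representative per
distinct array) feed `nj_tree()`, which wraps the classic Saitou–Nei
neighbour joining and BIONJ; BIONJ is the default for the final trees and
plain NJ is retained as a cross-check. Negative branch-length estimates —
possible on non-additive input — are clamped to zero with a warning, the
pre-clamp values kept in an attribute. Rooting places the root at the
midpoint of the outgroup's pendant branch (fraction configurable), adding
only a degree-2 node so leaf-to-leaf path lengths are untouched. On
additive matrices both methods recover the generating topology and branch
lengths exactly, which the suite verifies on random trees of 5–12 taxa.

# Diversity and differentiation on stacked repeat pools

Because each unit is a paralogous copy, diversity is summarised on the
*repeat pool*: every unit of every allele of a population becomes one
pool member, kept with multiplicity. The alternative reading — collapse
identical whole alleles before pooling — is exposed as
`per_variant = TRUE` so both can be compared on real data.

For a pool of `n` units of compared length `L`:

* segregating sites `S`: columns with ≥ 2 observed non-`N` states;
* Watterson `θ = S / a₁`, `a₁ = Σ 1/i` for `i < n`, reported per locus
  and per site (both are emitted because the per-locus/per-site scale of
  published θ values for this locus is ambiguous);
* `π`: mean pairwise mismatch count divided by `L`, with sites where
  either sequence carries `N` skipped per pair; the reported ± is the
  standard error, the square root of Nei's (1987) variance of the
  estimate.

Differentiation uses per-site base frequencies per population with the
Nei & Chesser (1983) small-sample corrections (harmonic-mean sample size,
unweighted population means) — the corrections are what allow the small
negative Gst values typical of panmictic comparisons; uncorrected
estimators are available by flag. Site-wise Hs and Ht are averaged over
*all* compared sites, and `Gst = (Ht − Hs)/Ht`,
`D = ((Ht − Hs)/(1 − Hs)) · k/(k − 1)` are computed from the averages.
Sites where a population shows only `N` drop that population at that
site. One consequence of the per-site contract is worth knowing: Jost's
D, designed for whole-allele frequencies, is strongly diluted by
monomorphic sites under per-site averaging, so per-site D values are much
smaller than D computed on repeat-unit *allele* frequencies would be;
Gst, being a ratio of averaged heterozygosities, is insensitive to this
dilution.

# The synthetic-data generator

`simulate_minisat()` is a forward-time haploid Wright–Fisher simulation:
each population is a pool of `pop_size` gene copies; each generation the
pool is resampled multinomially, then point mutations (Poisson, rate `mu`
per nt, `hv_multiplier ×` inside the contact codons), slippage
duplications (copy inserted adjacent to its template) and unit deletions
are placed uniformly at rates per unit. The population tree
`((ANV:t1, ANIV:t1):t2, (NA:t1, NP:t1):t2)` is realised by copying the
pool at each split after a shared burn-in; `t2 ≫ t1` produces strong
between-hemisphere and weak within-hemisphere structure, mirroring a
two-species, four-population sampling design. At the end, `2·n_per_pop`
copies per population are paired into diploid individuals and emitted in
exactly the FASTA/TSV dialect the readers accept, along with a truth
record of every event.

Default parameters (one pool of 40 copies; burn-in 400; `t2 = 600`,
`t1 = 30` generations; `mu = 7×10⁻⁶`; contact codons 10× faster;
duplication = deletion = 10⁻⁴ per unit per generation; 9 ancestral units;
guards at 4 and 14 units) were chosen once, as follows. The mutation rate
sets pooled repeat diversity to the order observed in real minisatellite
pools (π of a few percent per site, masked values around 0.01–0.03); the
split-time ratio `t2 = 20·t1` encodes "strong between, weak within";
the indel rates keep sampled arrays mostly within the 6–11-unit range
seen on gels while letting slippage events actually occur; and the pool
size and times are scaled so that a replicate runs in about a second,
with the coalescent-time structure (and hence the agreement of θ and π in
expectation) intact. These are *scaled* populations — absolute rates are
far above per-generation point estimates for mammals; only the
dimensionless combinations (diversity levels, split-to-coalescent time
ratios, rate ratios) are meant to be realistic.

Because hypervariable sites evolve at `hv_multiplier ×` the background
rate, the expected per-locus diversity ratio between unmasked and masked
pools is `(75 + 9·m)/75`, i.e. 2.2 at the default `m = 10` — inside the
2–3-fold window reported for real repeat pools; the acceptance suite
checks the simulated mean against this analytic value, and checks that
the hemisphere split is recovered by BIONJ on variant representatives in
at least 95 of 100 replicates, that panmictic splits centre Gst on zero,
and that θ and π agree in expectation at neutral constant size.

What the generator does **not** emulate: unequal crossing-over between
homologues and gene conversion (the dominant homogenising forces on real
minisatellites — only slippage duplication/deletion is modelled, so
concerted evolution is weaker in simulation than in nature), selection on
binding sites, hotspot erosion, recurrent-length homoplasy at realistic
rates, sequencing error and phasing ambiguity. Passing the synthetic
checks therefore demonstrates that the *pipeline* recovers the signal
structure it assumes, not that real minke-whale data would behave this
way.

# Numerical and interface conventions

All user-facing coordinates are 1-based and closed. Distances are written
with 6 decimals (PHYLIP square and long TSV); Newick branch lengths with
6 significant digits. Symmetry of distance matrices is enforced to 1e−9.
Agglomeration and naming ties are broken lexicographically. The string
`"NA"` is a legitimate population label (North Atlantic), so every table
reader disables missing-value interpretation. Pipeline artifacts embed
the package version, a hash of the resolved configuration and the seed in
a `#` header line, and `run_stage("all", ...)` writes an md5 manifest;
reruns with a fixed configuration and seed are byte-identical.

# Limitations

* Anchor-based finger validation is weaker than profile-HMM scoring; a
  heavily mutated but anchor-intact unit still counts as a valid finger.
* The edit distance treats units as atoms: nucleotide-level alignment
  across unit boundaries, partial-unit indels and ancestral-state
  reconstruction are out of scope.
* Per-site Jost's D is not comparable to whole-allele D values (see
  above).
* The simulator's simplifications listed in the previous section mean
  quantitative transfer of thresholds (for example the 95/100 recovery
  rate) to real data is not implied.
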
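---
title: "Methods: comparing C-type lectin sugar-binding pockets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing C-type lectin sugar-binding pockets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lectinpocket)
```

## The question the package answers

C-type lectins of the Mincle family bind glycolipids through a
calcium site on the carbohydrate recognition domain (CRD). Three
features govern what a homologue can bind: the principal-site motif
(EPN for glucose/mannose-type specificity, QPD for galactose-type, EPD
an atypical variant), the WND motif contributing secondary calcium
coordination, and the *width* of the pocket around the calcium, which
decides whether a disaccharide such as trehalose fits or only a
monosaccharide does. `lectinpocket` turns that comparison into a
reproducible pipeline: screen candidate sequences for the motifs and
for retention of hydrophobic groove residues, superpose structures on
their pocket calcium, transplant a reference-bound ligand and classify
each pocket by steric clash, and place every homologue in a phylogeny
so pocket classes can be read against clades.

## Structural conventions

**Heavy atoms only.** Hydrogens are skipped on reading and never used;
crystallographic pocket comparisons are heavy-atom based, and all
cutoffs below are heavy-atom conventions.

**Alternate locations** resolve to the highest-occupancy conformer,
ties broken by altloc letter. Residue numbering is taken verbatim from
the file. A `chain` selector on `read_pdb()` picks one protomer of a
homodimeric crystal form; which protomer to measure is the user's
choice, not a package default.

**Contacts.** A coordination bond is any O/N atom within 2.8 Å of the
ion; a hydrogen bond is a ligand-O/N–protein-O/N pair within 3.5 Å
(donor–acceptor heavy-atom distance, no angle term). Both cutoffs are
standard crystallographic heuristics and are arguments, not constants.
Pairs in which both partners sit in the ion's coordination shell are
counted as coordination, not hydrogen bonding.

**Clash rule.** After rigid transplantation, ligand atom *i* and
receptor atom *j* clash when
`d(i, j) < r(i) + r(j) − tolerance`,
with Bondi radii (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å) and a
0.4 Å tolerance, the common all-atom clash convention; `tolerance = 0`
gives a strict hard-sphere test. The receptor set excludes the ion,
waters and any receptor-bound ligand. The pocket is *narrow* exactly
when the disaccharide probe clashes. Because published clash calls of
this kind are visual, the 0.4 Å tolerance is a documented choice;
`count_clashes()` exposes it so sensitivity can be reported.

**Calcium-anchored superposition.** A single ion cannot determine a
rotation, so the anchor set is the ion *plus* its O/N coordination
shell (3.0 Å by default, or an explicit atom table matched on residue
name/number/atom name). A Kabsch fit (closed-form SVD, reflections
always corrected to det +1) is followed by a residual translation that
puts the two calcium ions exactly on top of each other — this keeps
the "aligned by the pocket calcium" semantics while leaving the
rotation well-posed. With fewer than three anchor atoms the fit
degrades, with a warning, to a pure Ca-on-Ca translation.

## Sequence conventions

`global_align()` is a deterministic stand-in for the multiple-aligner
position mapping used with real data: Needleman–Wunsch with BLOSUM62
and affine gaps costing `gap_open + (L − 1) · gap_extend`
(defaults 11/1). Groove positions are always configuration — their
identity in real receptors is figure-encoded knowledge, so the package
takes them as a `groove_profile()` (reference indices, hydrophobic set
{A, V, L, I, F, M, W, Y}, retention threshold ⌈0.7·n⌉ by default; all
overridable). `find_sugar_motif()` searches the full sequence by
default so that motif reporting is unsurprising; the CRD-focused
restriction to the C-terminal 60% is applied where screening happens,
in `classify_candidate()`, and can be widened with `cterm_frac = 1`.
A candidate is Mincle-like iff it has EPN (QPD/EPD are reported but do
not qualify) *and* retains at least the threshold number of
hydrophobic groove residues.

## Phylogenetic model

The rate matrix is `Q[a,b] = s[a,b] π[b]` built from the published JTT
exchangeabilities and frequencies (taken at run time from phangorn,
which ships them), scaled to one expected substitution per site.
Transition probabilities come from the spectral decomposition of the
reversibility-symmetrized matrix, which is exact and fast enough that
no further caching is needed.

Rate variation uses K equal-weight discrete-gamma categories whose
rates are the means of equal-probability slices of Gamma(α, α), plus
an invariant class of weight `p_inv`:

```
L(site) = p_inv · 1{constant} · π(state) + (1 − p_inv)/K · Σ_k L_k(site)
```

Gamma rates are *not* rescaled by 1/(1 − p_inv); the total expected
rate is (1 − p_inv), matching the convention in which α and p_inv are
reported together. Defaults (α = 2.4398, K = 5, p_inv = 0.0727) are
the estimates reported for the 24-sequence Mincle homologue analysis,
so comparison runs reproduce that setting out of the box; both are
plain arguments for any other use.

**Distances** maximize `Σ log(π_a P(a→b; d))` over shared ungapped
columns by bracketed search on d ∈ [0, 10], under the unit-rate JTT
matrix (the convention for model-based pairwise distances feeding NJ).
The pair-count table is symmetrized before the search, which makes
`d(i, j) = d(j, i)` exact at floating-point level.

**Neighbor joining** is implemented deterministically: Q-criterion
ties break to the smallest (i, j) pair in the current node order, and
a negative branch length is clamped to zero with the deficit moved to
its sister branch. On additive matrices the generating tree is
recovered exactly.

**Tree search.** A full ML topology search is intentionally out of
scope. The pipeline's tree is NJ on ML distances followed by
coordinate-wise branch-length optimization (each branch bracketed in
[0, 10], sweeps until the gain is below 1e-6; the likelihood is
non-decreasing by construction because a candidate is only accepted
when it improves). `tree_loglik()` scores any externally supplied
topology, so trees from a dedicated ML search program can be compared
on equal footing.

**Clade assignment** roots at the outgroup and gives each leaf the
group of the anchors in its smallest ancestral clade containing any
anchor; clades mixing both anchor groups leave the leaf unassigned.
`split_by_score()` separates a 1-D similarity-score table at the
largest gap between sorted values (ties toward the lower gap), with
the threshold at the gap midpoint.

## What the synthetic data emulates — and what it does not

`ligand_template()` builds idealized heavy-atom sugars from internal
coordinates (chair-ring radii and puckering): glycerol (6 atoms),
glucose (12), trehalose (23, two glucopyranose rings sharing the
glycosidic oxygen). Bonded distances fall in standard covalent ranges
(C–C 1.50–1.56 Å, C–O 1.38–1.46 Å); torsions and anomeric
stereochemistry are simplified. No structure download is ever needed;
`extract_ligand()` substitutes real coordinates when a deposited
complex is available.

`make_toy_pocket()` emulates the geometry that matters for the
analysis: a Ca²⁺ ion, six cage oxygens at the 2.4 Å coordination
distance on the lower hemisphere (labelled as EPN/WND residue atoms so
anchor selectors resolve), two second-shell oxygens at 4.0 Å, and two
flanking walls of carbons at `x = ±aperture/2`. The walls sit in a z
window just beyond the reach of a bound monosaccharide
(glucose's deepest atom plus ≈ 3.3 Å), where only the second ring of a
transplanted disaccharide arrives. Consequences, by construction: the
defining wall pair is exactly `aperture` apart; glucose never clashes
at any aperture ≥ 4 Å; trehalose clashes in narrow pockets and stops
clashing exactly once as the aperture widens (at ≈ 8.9 Å for the
bundled template) — the mono- versus disaccharide discrimination the
real pockets show. The generator is a pure function of its parameters
and seed (bit-identical reruns).

`evolve_alignment()` draws root states from the JTT equilibrium,
assigns each site rate 0 with probability `p_inv` or a sampled gamma
category rate, and walks the tree with exact transition probabilities.
No indels are simulated: the pipeline removes gapped columns anyway
(complete deletion), and gap handling is tested with hand-written
alignments instead.

`simulate_cohort()` wires these together coherently — two clades with
planted EPN motifs and groove residues, narrow pockets in one clade
and broad in the other, and a score table separated by clade — so a
full `run_full()` has a known right answer.

What passing on these fixtures does **not** show: performance on real
electron-density-derived structures (side-chain flexibility, waters,
alternate conformations), on sequences whose alignment is genuinely
ambiguous, or on trees where the NJ topology differs from the ML
optimum. The synthetic pockets are geometric stand-ins, not folds.

## Numerical choices and degenerate inputs

- Orthonormality of rotations is enforced to 1e-8; Kabsch is
  closed-form (no iteration). Fewer than 3 points: translation-only
  fallback, flagged.
- `optimize()` brackets: distances d ∈ [1e-8, 10], branches [0, 10];
  identical sequences short-circuit to d = 0.
- Pattern compression merges identical alignment columns before
  pruning; all-missing columns contribute likelihood 1.
- Empty selections, empty motif scans and `clash(−)` reports are
  ordinary zero-row results, not errors; an empty alignment after
  complete deletion warns and is returned.
- PDB fixed columns cannot hold |coordinate| ≥ 10000 Å; writing such a
  structure is an explicit format-overflow error.

## Problem sizes used in the checks

The shipped verification suite runs at sizes chosen to finish quickly
while still being discriminating: clash parity on 50 random instances
up to 500×500 atoms; 100 random rigid transforms; likelihood
enumeration on all topologies with ≤ 4 leaves × {α = 0.5, 2.4398} ×
{p_inv = 0, 0.0727}; 20 additive matrices of 5–8 taxa; an aperture
sweep at 0.25 Å steps; distance recovery at 1000 sites and
branch-length recovery at 500 sites on 6 taxa; a 9-taxon end-to-end
cohort at 300 sites.

## Known limitations

- No ML topology search, model selection, or Bayesian inference.
- No docking, torsion sampling, or relaxation: the transplanted ligand
  is rigid, so a "clash" means *this pose* cannot fit, which is the
  superposition-only protocol's meaning as well.
- mmCIF input, crystallographic symmetry and assembly generation are
  out of scope; PDB format only.
- Bootstrap support is computed for the NJ pipeline, not for the
  branch-length-optimized tree (supports are topology properties of
  the resampled NJ trees).
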
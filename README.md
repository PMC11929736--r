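# lectinpocket

Comparative analysis of calcium-dependent sugar-binding pockets in
C-type lectin receptors.

Mincle-family lectins recognize glycolipids through a Ca²⁺ site on the
carbohydrate recognition domain (CRD): the EPN (Glu-Pro-Asn) motif
confers glucose/mannose-type binding, the WND (Trp-Asn-Asp) motif
contributes secondary Ca²⁺ coordination, and a hydrophobic groove binds
the lipid acyl chains. Whether a homologue can accommodate a
disaccharide such as trehalose — the sugar head group of mycobacterial
glycolipids — or only monosaccharide-bearing (often self-derived)
ligands depends on the width of that pocket. `lectinpocket` provides the
computational toolkit for tracing how this capacity changes across
homologues:

- **Sequence screen** (`find_sugar_motif`, `find_wnd`,
  `classify_candidate`): scans candidates for the EPN motif (or its
  QPD/EPD variants), the WND motif, and retention of hydrophobic groove
  residues mapped from a reference by global alignment
  (Needleman–Wunsch, BLOSUM62, affine gaps).
- **Calcium-anchored superposition** (`kabsch`,
  `ca_anchor_superpose`): closed-form least-squares rigid fit over the
  pocket anchor set (the Ca²⁺ ion plus its O/N coordination shell),
  followed by an exact Ca-on-Ca residual translation, so pockets are
  compared in a common frame defined by their calcium sites.
- **Steric-clash classification** (`transplant_ligand`,
  `count_clashes`, `classify_pocket`): carries a reference-bound ligand
  rigidly into a target pocket and flags every heavy-atom pair with
  distance < r₁ + r₂ − tolerance (Bondi radii, 0.4 Å tolerance). A
  pocket that clashes with the transplanted trehalose is *narrow*;
  otherwise *broad*.
- **Pocket geometry** (`coordination_contacts`, `hydrogen_bonds`,
  `pocket_apertures`): Ca²⁺ coordination bonds (≤ 2.8 Å),
  donor–acceptor hydrogen bonds (≤ 3.5 Å) and user-defined
  pocket-aperture distances.
- **Phylogenetics** (`complete_deletion`, `jtt_distance`, `nj_tree`,
  `tree_loglik`, `optimize_branch_lengths`, `assign_clades`,
  `bootstrap_support`, `split_by_score`): gap-free column filtering, ML
  pairwise distances under the JTT model, deterministic neighbor
  joining, Felsenstein-pruning log-likelihood under JTT + discrete
  gamma (K categories) + invariant sites, NJ-seeded branch-length
  optimization, outgroup-rooted clade assignment and largest-gap 1-D
  score clustering.
- **Synthetic data** (`make_toy_pocket`, `ligand_template`,
  `make_candidate_sequences`, `evolve_alignment`, `simulate_cohort`):
  parametric pockets with a Ca²⁺ coordination cage and walls at a
  chosen aperture, idealized glycerol/glucose/trehalose templates, and
  alignments evolved along known trees, so the entire pipeline runs
  without any structure or sequence download.
- **Pipeline** (`run_sequence_screen`, `run_structural_screen`,
  `run_full`): joins the three evidence streams into one summary table
  per homologue (clade, motif, pocket class, score cluster) with full
  provenance.

The model at the phylogenetic core: the reversible rate matrix is
`Q[a,b] = s[a,b] π[b]` from the published JTT exchangeabilities `s` and
frequencies `π`, scaled to one expected substitution per site; per-site
likelihood is

```
L(site) = p_inv · 1{site constant} · π(state)
        + (1 − p_inv) · (1/K) Σ_k L(site | rate r_k)
```

with `r_k` the means of K equal-probability slices of Gamma(α, α), and
`L(site | r)` computed by Felsenstein pruning with `P(t) = exp(Q r t)`.

## Worked example

Transplant a trehalose from a wide reference complex into a narrow
(5 Å) synthetic pocket:

```r
library(lectinpocket)

ref    <- make_toy_pocket(14, bound_ligand = "trehalose")
narrow <- make_toy_pocket(5)

pocket_apertures(narrow, toy_aperture_pairs())
#> <lp_pocket_metrics> 1 pair(s); min 5 A, mean 5 A

lig <- transplant_ligand(ref, narrow, "TRE")
count_clashes(lig, narrow)
#> <lp_clash_report> probe trehalose: clash(+), 32 clash pair(s),
#>   worst overlap 1.375 A (tolerance 0.4)
classify_pocket(count_clashes(lig, narrow))
#> [1] "narrow"
```

The 32 overlapping heavy-atom pairs (worst interpenetration 1.375 Å
beyond the van der Waals tolerance) mean the disaccharide cannot fit:
this pocket would be scored as monosaccharide-only. The same pocket
accepts a transplanted glucose with zero clashes, and sweeping the
aperture from 4 to 12 Å flips the classification from narrow to broad
exactly once (at ≈ 8.9 Å for the bundled trehalose template).

An end-to-end run on a synthetic cohort — two clades evolved under
JTT+Γ+I, narrow pockets planted in one clade, broad in the other:

```r
sim <- simulate_cohort("cohort_dir", seed = 1)
res <- run_full(sim$config)
res$summary[, c("id", "clade_group", "motif_kind", "pocket_class")]
#>          id     clade_group motif_kind pocket_class
#> 1  trMincle  trMincle_group        EPN         <NA>
#> 2    frog01  trMincle_group        EPN       narrow
#> ...
#> 6    toad01 mammalian_group        EPN        broad
```

Every member of the trMincle-like clade carries a narrow pocket and
every member of the mammalian-like clade a broad one — the planted
association is recovered with zero misassignments.

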
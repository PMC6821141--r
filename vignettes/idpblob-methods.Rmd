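---
title: "Methods: blob decomposition, the SAHP null model, and coupling tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blob decomposition, the SAHP null model, and coupling tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpblob)
```

## The problem

A long disordered protein explores a heterogeneous ensemble with no fixed
topology. Residue-level contact statistics are hopeless at realistic
sampling depths: a 91-residue chain has ~4,000 candidate contacts, each
formed in a small fraction of frames. `idpblob` addresses this with a
hierarchical, sequence-first coarse-graining (blobs → groups → regions)
and a polymer null model that says how often coarse contacts *should*
form in the absence of any specific tertiary interaction.

## Blob decomposition

Per-residue Kyte–Doolittle scores are mapped to `[0, 1]` via
`(KD + 4.5)/9` and smoothed with a centred 3-residue mean. At the chain
termini the window is truncated to the available residues, which keeps
the profile the same length as the sequence; the alternative (dropping
terminal positions) would make terminal blobs undetectable. The profile
is digitized at a strict `> 0.37`. Maximal super-threshold runs of at
least 4 residues are h blobs; maximal leftover stretches of at least 4
residues are p blobs; shorter leftovers (1–3 residues) are unassigned,
and when they fall between two h blobs they belong to the enclosing
group but to no blob. This complement-based reading (a short
super-threshold run adjacent to sub-threshold residues dissolves into
the surrounding linker) is what reproduces the reference decomposition
of the BDNF prodomain exactly: 8 h blobs + 3 p blobs covering 82 of 91
residues.

One subtlety: applying the decomposition to the Met66 variant sequence
moves the h2b boundary (the His window mean falls just below the cutoff
when Val is replaced by Met). The reference analysis evidently derives
blob boundaries once, from the Val66 sequence, and applies them to both
variants; the package does the same in its comparisons, and
`identify_blobs` output should be treated as sequence-specific.

### Sequence metrics

Charges are fixed at pH 7: D/E −1, K/R +1, histidine and the termini
neutral (required to reproduce the reference NCPR of the variant blob).
κ follows the Das–Pappu construction: windowed charge asymmetry
σ = (f₊ − f₋)²/(f₊ + f₋) over windows of 5 and 6 residues (σ = 0 for
uncharged windows), δ = mean squared deviation from the global σ, and
κ = δ/δ_max over rearrangements of the same composition. δ_max is found
exactly (full enumeration) for sequences of ≤ 10 residues; longer
sequences use a constructive search over block arrangements — the
segregated +/− blocks with the neutral block split around them, plus
arrangements with one charge species split across both termini —
refined by pairwise-swap hill climbing from the best few starts. The
test suite verifies the constructive path against full enumeration on
8-residue compositions. κ is reported as undefined (with a reason code)
for chains shorter than the largest window or without charges.

Phase regions use charge fractions only: FCR < 0.25 → region 1;
0.25 ≤ FCR ≤ 0.35 → 2; FCR > 0.35 with |NCPR| ≤ 0.35 → 3; otherwise 4
(net negative) or 5 (net positive). These breakpoints reproduce all
printed reference classifications. The Uversky boundary is the 2000
charge–hydropathy line `⟨H⟩ > (|NCPR| + 1.151)/2.785`, with boundary
points classed disordered; it reproduces every published side-of-boundary
statement for the prodomain blobs.

## Ensemble geometry and contact maps

Blob anchors are the mean of the blob's N-terminal backbone N and
C-terminal backbone O positions. Ensembles carrying only Cα fall back to
the mean of the terminal Cα positions, and the anchor mode is recorded in
every contact map so mixed conventions are detectable. Per-frame blob
radii of gyration enter the excess distance
`d_e = |r_i − r_j| − (R_g,i + R_g,j)`; a blob contact is `d_e < 0.55 nm`
(strict), a residue contact is Cα–Cα `≤ 0.8 nm` (inclusive) — the two
comparison senses are deliberately different, following the respective
definitions. Standard errors on any probability use the Bernoulli
convention √(p(1−p)/n) with an effective sample size that the caller can
set (for replica exchange: replicas × mean roundtrips, e.g. 64 × 17 =
1088).

The periodic-image QC masks frames whose box edge minus the molecule's
coordinate extent drops below 2 nm on any axis; it is optional because
synthetic ensembles have no box. Internal-distance scaling fits
`log⟨R(s)⟩ = log A + ν log s` over separations s ≥ 2 use the reference
prefactor A = 0.59 nm by default. With A fixed, an ideal freely-jointed
Cα chain (bond 0.38 nm, true prefactor ≈ 0.35 nm) fits to ν ≈ 0.33, not
0.5 — the biased exponent absorbs the prefactor mismatch — so the fit
also accepts `A = NULL` to estimate the prefactor, and the ideal-chain
recovery test uses that mode. Reported ν values should always be read
against the fixed-A convention of the reference lines (3/5, 1/2, 1/3).

## The SAHP null model

Each blob becomes a hard sphere of radius ⟨R_g,i⟩; bond i connects
monomers i−1 and i at fixed length (⟨R_etoe,i−1⟩ + ⟨R_etoe,i⟩)/2. Two
monomers at chain separation ≥ 2 overlap when their distance is below
a(R_i + R_j) with a = 0.3; bonded neighbours are exempt, since typical
bond lengths would otherwise be infeasible. Sampling is Metropolis Monte
Carlo: pick a bead i > 1, displace it by a 0.5 nm vector drawn uniformly
on the sphere, rescale the displaced position onto the bond sphere
around bead i−1, and translate the whole tail rigidly; moves causing
overlap are rejected, all others accepted. Because the proposal density
on the bond sphere depends only on the angle between the old and new
bond directions, it is symmetric, and the chain's stationary law is the
uniform freely-jointed measure restricted by the hard core — exactly
what the independent direct sampler (`sahp_direct_sample`: independent
uniform bond directions + outright rejection) draws from. The test suite
compares the two on 3- and 4-bead chains at 3 SE; a 2-bead chain is
checked against the closed form (contact probability 0 or 1 by
arithmetic).

Defaults: 5,000,000 steps, first 10% discarded as burn-in, one recorded
configuration every 100 steps. The burn-in is a package choice (the
reference procedure reports total steps only and insensitivity to more);
with it, the straight-line initial configuration cannot bias the
recorded sample. The straight start also doubles as a feasibility check:
it maximises every pairwise separation, so a hard-core violation there
means no valid configuration exists and the run errors out immediately.
The Monte Carlo core is compiled (Rcpp) and uses R's RNG, so a fixed
`set.seed` gives bit-identical samples.

SAHP contacts mirror the real-protein rule with ensemble-mean radii:
`|r_i − r_j| − (R_i + R_j) < 0.55 nm`. Enrichment is the elementwise (or
region-aggregated) ratio of real-protein to SAHP contact probability,
with errors propagated from both Bernoulli terms and an explicit
infinite-enrichment flag when the null probability is zero. Region
segmentation selects the interior p monomer with the minimal mean
contact probability between its upstream and downstream blocks; blobs
before it are Region I, the linker Region II, the rest Region III.
Swapping the segmenting monomer elsewhere in the chain relocates the
boundary with it — a property the tests verify at several positions.

## Secondary structure

Ramachandran regions: helix −100° < φ < −30° and −120° ≤ ψ ≤ 50°; β
φ < −80° with ψ > 50° or ψ < −120°. The second β bound is printed in the
source material as "ψ < 120°", which is vacuously true; the sign
correction to −120° is the unique reading disjoint from the helix band
and is recorded in the function documentation. Angles are normalised to
(−180°, 180°] first; missing terminal dihedrals give an "undefined"
state that breaks runs. A residue carries a state only when inside a
maximal run of ≥ 4 residues; the run-length map resolves the exact
maximal-run length per residue and marginalises back to the propensity
identically (an exact internal consistency the tests assert).

## Contact–β coupling

For an eligible blob pair (different groups, not sequence-adjacent),
frames split into four clusters by (contact formed?, β present in X?).
If the contact reflects paired strands, the β propensity over the
partner blob Y in the (contacting, present) cluster must exceed the
other three clusters; the reference analysis never quantifies
"significantly higher", so the package uses a z-score rule — the
cluster statistic is the mean β propensity over Y's residues, compared
at z = 3 pooled Bernoulli SEs (z is exposed as a parameter) — and
requires the reciprocal test with X and Y swapped to pass as well. The
nine-cluster decomposition labels two blobs helix/β/coil per frame
(frames where a blob carries both helix and β runs are excluded and
counted) and recomputes residue contact maps within each cluster.

## Synthetic ensembles: what they emulate, and what they do not

`gen_ensemble` builds freely-jointed Cα chains (bond 0.38 nm) with
per-blob spherical confinement (radius around the blob's first residue)
for compactness heterogeneity; the prodomain-like default layout
(`synth_spec_prodomain`) uses 11 blobs with compact h blobs (0.45 nm),
short compact linkers (0.55 nm) and a long unconfined central linker —
the qualitative structure of the reference chain. Contacts are planted
per frame by drawing the desired Bernoulli indicator and then pivoting
the chain tail at a hinge residue between the two blobs (falling back to
additional hinges and to straightening the inter-blob gap); every
operation preserves bond lengths, and the realised indicator is returned
as ground truth. Dihedrals come from a run-length state model whose
β-pairing event in the coupled blobs is conditioned on the contact
indicator at the declared odds ratio; dihedrals are otherwise
independent of the coordinates, which isolates exactly the correlation
the coupling detector must find. Study conditions for the coupling
benchmarks were fixed once: planted contact probability 0.35,
no-contact β-pairing probability q₀ = 0.10, background run rate
0.02/residue, 2,000 frames.

These ensembles are *statistical* stand-ins, not physical ones: no
excluded volume in the real chain, no solvent, no realistic backbone
geometry, and secondary structure uncorrelated with compactness except
through the planted coupling. Passing tests therefore demonstrate that
the estimators recover known statistical structure at realistic sampling
depths — not that any physical claim about a real protein is true.

## Problem sizes and numerical choices

The test-suite study sizes are chosen to make every stochastic check
sharp at its 3 SE tolerance while keeping the suite quick on a laptop:
2,000-frame ensembles for planted-contact and coupling recovery (50
seeds for the null false-positive rate at 1,000 frames), 10⁵ samples for
the direct-sampling oracle, full 5,000,000-step Monte Carlo for the
11-monomer segmentation analyses and 2,000,000 steps for the swap
variants (both regimes are far past mixing for these chain sizes, as
the oracle-agreement tests show). Planting margins of 0.1 nm around the
contact cutoff keep the planted indicator robust to the ≤ 0.08 nm anchor
shift introduced by pseudo-backbone atoms (offset 0.04 nm). Bond
constraints are enforced to 10⁻⁹ nm in the sampler tests. Degenerate
inputs fail loudly: empty sequences, chains shorter than a blob,
ensembles with no unmasked frames, infeasible hard-core geometries, and
κ on chains that cannot define it all raise informative errors or
reason-coded NA values rather than numbers.

## Known limitations

- Blob boundaries are sequence-specific; comparing variants requires
  fixing one partition (see above).
- κ's constructive δ_max for chains longer than 10 residues is a
  heuristic; it matches full enumeration on all tested compositions but
  carries no optimality proof, and a δ_max underestimate would inflate κ.
- The hinge-pivot contact planting requires planted pairs whose spans
  are disjoint; multiple planted pairs are processed from the most
  downstream hinge upward, which preserves earlier plants only when both
  blobs of a downstream pair lie beyond the upstream hinge.
- Trajectory input is multi-model PDB or a plain coordinate table;
  compressed MD formats should be converted upstream.
- Atom-level contact flavors (backbone, sidechain, hydrophobic,
  salt-bridge) expect role-annotated fixtures; no PDB chemistry
  perception is attempted.
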
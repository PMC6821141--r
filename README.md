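# idpblob

Hierarchical blob decomposition and tertiary-contact enrichment analysis
for long intrinsically disordered proteins (IDPs).

Long IDPs have no topology in the folded-protein sense: thousands of weak,
transient residue–residue contacts, each individually unmeasurable. This
package implements a sequence-first coarse-graining that makes tertiary
structure in such chains quantifiable:

1. **Blob decomposition.** The per-residue Kyte–Doolittle hydropathy is
   scaled to `[0, 1]`, smoothed over a 3-residue window, and digitized at
   `⟨H⟩ > 0.37`. Runs of ≥ 4 super-threshold residues are hydrophobic
   "h" blobs; remaining stretches of ≥ 4 residues are linker "p" blobs;
   consecutive h blobs form groups. Each blob carries sequence metrics:
   NCPR, FCR, f±, the Das–Pappu charge-patterning parameter
   κ = δ/δ<sub>max</sub> (window sizes 5 and 6), the five-region
   charge-fraction phase classification, and the Uversky
   charge–hydropathy boundary `⟨H⟩ > (|NCPR| + 1.151)/2.785`.
2. **Blob contact maps.** For a conformational ensemble, two blobs are in
   contact in a frame when their *excess distance*
   `d_e,ij = |r_i − r_j| − (R_g,i + R_g,j)` is below 0.55 nm, with blob
   anchors `r_i` at the mean of the N-terminal backbone N and C-terminal
   O atoms (Cα fallback). Residue-level maps use Cα–Cα ≤ 0.8 nm.
3. **SAHP null model.** A freely-jointed self-avoiding heteropolymer: one
   hard-sphere monomer per blob with radius `⟨R_g,i⟩`, bond lengths
   `(⟨R_etoe,i−1⟩ + ⟨R_etoe,i⟩)/2`, hard-core rejection when
   `|r_i − r_j| < a(R_i + R_j)` with `a = 0.3`, sampled by Metropolis
   Monte Carlo (5,000,000 constrained single-bead moves of magnitude
   0.5 nm). Contact **enrichment** = RP probability / SAHP probability
   detects specific tertiary interactions; the SAHP's most isolating
   linker segments the chain into Regions I/II/III.
4. **Secondary structure and coupling.** Ramachandran-region helix/β
   assignment (runs of ≥ 4 residues), per-residue propensities with
   Bernoulli standard errors, run-length maps, and cluster tests for
   correlated β strands: frames are split by (contact formed?, β present
   in blob X?) and a symmetric z-score rule flags blob pairs whose
   contacts are coupled to simultaneous strand formation.
5. **Synthetic ensembles.** A generator of Cα chains with per-blob
   confinement, planted contact probabilities and planted contact–β odds
   ratios, so every analysis is testable against known ground truth.

## Worked example

The package ships the 91-residue BDNF prodomain sequence (residues
23–113; reconstructed from published per-blob sequences — see the file
header) as `inst/extdata/prodomain_v66_reconstructed.fasta`:

```r
library(idpblob)
fa  <- system.file("extdata", "prodomain_v66_reconstructed.fasta", package = "idpblob")
rec  <- load_sequence(fa, offset = 23)   # author numbering starts at 23
part <- identify_blobs(rec)
print(part)
#> <blob_partition> 91 residues: 8 h blob(s), 3 p blob(s), 9 unassigned residue(s)
#>  label class  author length        sequence
#>     p1     p   23-30      8        EANIRGQG
#>    h1a     h   31-38      8        GLAYPGVR
#>    h1b     h   42-47      6          TLESVN
#>     p2     p   48-54      7         GPKAGSR
#>    h2a     h   55-63      9       GLTSLADTF
#>    h2b     h   65-72      8        HVIEELLD
#>     p3     p   73-87     15 EDQKVRPNEENNKDA
#>    h3a     h   88-91      4            DLYT
#>    h3b     h   93-97      5           RVMLS
#>    h3c     h  99-103      5           QVPLE
#>    h3d     h 105-111      7         PLLFLLE
```

The chain splits into 8 hydrophobic blobs and 3 linkers; the variant site
(author residue 66) sits inside `h2b`. Per-blob metrics
(`blob_table(part)`) show, e.g., that `h2b` is the only strongly net-charged
hydrophobic blob (NCPR −0.38, phase region 4, Uversky-disordered despite
⟨H⟩ = 0.54) and that the long linker `p3` is a well-mixed strong
polyampholyte (FCR 0.53, κ = 0.1).

Tertiary enrichment against the SAHP null model (here parameterized from
a synthetic heterogeneous ensemble; with real data pass your own
trajectory to `blob_geometry`):

```r
gen   <- gen_ensemble(synth_spec_prodomain(n_frames = 300), seed = 7)
geom  <- blob_geometry(gen$traj, gen$partition)
model <- sahp_parameterize(geom, classes = gen$partition$blobs$class)
samp  <- sahp_run(model, steps = 5e6, seed = 7, keep_positions = FALSE)
map   <- sahp_contact_map(samp)
seg   <- segment_regions(map, model)
model$labels[seg$linker]
#> [1] "p3"
enrichment(blob_contact_map(gen$traj, gen$partition), map, regions = seg$regions)
#>   region_a region_b rp_mean sahp_mean ratio    se
#> 1        I        I   0.778     0.989 0.787 0.006
#> 2        I       II   0.743     0.924 0.804 0.010
#> 3        I      III   0.183     0.350 0.524 0.013
#> 4       II      III   0.784     0.985 0.796 0.011
#> 5      III      III   0.849     1.000 0.849 0.008
```

The null model itself is segmented by the long expanded linker (`p3`):
cross-linker Region I–III contacts are several-fold rarer than
within-region contacts, so any *excess* of observed I–III contacts over
the SAHP expectation (a ratio above 1) indicates specific tertiary
structure. In this synthetic ensemble no cross-linker attraction was
planted, and the I–III ratio is accordingly below 1.

A thin command-line front end with `blobs`, `simulate`, `sahp` and
`analyze` subcommands is installed at `inst/cli/idpblob.R`.

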
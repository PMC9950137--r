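# paleofmo

Ancestral sequence reconstruction and enzyme kinetics for
flavin-containing monooxygenase (FMO) paleobiochemistry.

Tetrapod FMOs split, after a gene duplication, into a lineage of
heteroatom (S/N) oxygenases and a lineage retaining Baeyer–Villiger (BV)
oxidation. Resurrecting the ancestors around that duplication and
reverting a handful of historical substitutions is how the sequence
determinants of the two chemistries are dissected. This package implements
the computational core of that workflow for anyone doing
ASR-plus-enzymology studies:

- **Marginal ancestral reconstruction** on a fixed rooted phylogeny under
  empirical amino-acid models (JTT/WAG/LG) with discrete-gamma rate
  heterogeneity: per-site posteriors
  $P(x_v \mid \text{data}) \propto \sum_k \tfrac1K\, L^{\text{in}}_k(x_v)\,
  L^{\text{out}}_k(x_v)$ by Felsenstein pruning with inside–outside
  passes, per-node scaling, and a rerooting implementation kept as a
  cross-check.
- **Ancestor assembly**: Fitch parsimony on gap presence/absence fixes the
  ancestor length; the MAP ancestor takes the best state per present site;
  the AltAll ancestor swaps in the second-best state wherever its
  posterior probability exceeds 0.2.
- **Substitution funnel**: the historical substitutions along a branch are
  filtered by reconstruction confidence (PP > 0.8 at both nodes, or a
  credible conflicting alternative), by conservation (modal residue
  frequency ≥ 0.8 dataset-wide or within either lineage), and by
  structural environment, then composed into nested mutant sets
  (4x ⊆ 12x ⊆ 16x).
- **Enzyme kinetics**: Michaelis–Menten and O₂-affinity hyperbolae,
  initial rates from 340-nm NAD(P)H traces (ε₃₄₀ = 6.22 mM⁻¹cm⁻¹),
  single-exponential stopped-flow phases, and variable-projection
  deconvolution of photodiode-array matrices into the two-step scheme
  $a \xrightarrow{k_1} b \xrightarrow{k_2} c$ whose intermediate is the
  C4a-(hydro)peroxyflavin. Conversions, melting temperatures, and
  holoenzyme quantitation (ε₄₅₀ = 11.3 mM⁻¹cm⁻¹) round out the layer.
- **Synthetic-data generators** for every input — alignments evolved along
  a tree with clade-restricted indels, photodiode-array matrices,
  saturation designs, single traces, melt curves, conversion tables — each
  with recorded ground truth, so every stage is testable without any
  download.

## Worked example

The `analysis/` scripts are a complete narrative run on a synthetic
two-lineage system (an S/N clade, a BV clade, an outgroup; JTT,
α = 1.114, 4 categories; a 12-column deletion on the BV stem):

```sh
Rscript analysis/01_simulate_inputs.R
Rscript analysis/02_ancestral_reconstruction.R
Rscript analysis/03_substitution_funnel.R
Rscript analysis/04_steady_state_kinetics.R
Rscript analysis/05_stopped_flow_kinetics.R
```

`02` prints the reconstruction summary — the pre-duplication ancestor is
recovered at 92.3% with a calibrated confidence (mean PP 0.925 vs observed
accuracy 0.923), and the BV ancestor correctly loses the deleted block:

```
  anc_all  length 300  mean PP 0.925  ambiguous sites 31
  anc_SN   length 300  mean PP 0.991  ambiguous sites 3
  anc_BV   length 288  mean PP 0.988  ambiguous sites 5
root MAP recovery: 92.3% of 300 present sites
BV-ancestor columns 101-112 absent: TRUE
```

`03` walks the funnel down the focal branch (29 substitutions listed → 8
confidently reconstructed → 7 conserved → 5 after structural triage) and
prints the nested mutant sets. `04` and `05` re-fit synthetic kinetics
generated at the published constants:

```
NADPH: K_M = 15.6 +/- 0.9 uM
NADH:  K_M = 89 +/- 7 uM (6-fold weaker than NADPH)
MPTS:  k_cat = 1.00 s^-1, K_M = 1.05 mM, k_cat/K_M = 0.96 s^-1 mM^-1
k_red = 0.250 +/- 0.002 s^-1
k1 = 3.19 +/- 0.0063 s^-1, k2 = 0.00650 +/- 9.4e-06 s^-1
intermediate lambda_max = 380 nm (C4a-(hydro)peroxyflavin-like)
```

The recovered constants sitting on top of the generating ones (K_M 15.7
and 90 µM; k_red 0.25 s⁻¹; k₁ 3.2 and k₂ 0.0065 s⁻¹; efficiency
0.98 s⁻¹mM⁻¹) is the point: the fitters return the truth within their own
reported uncertainties.

For a single reconstruction the package surface is three calls:

```r
library(paleofmo)
aln   <- read_fasta("msa.fasta")
tree  <- read_newick("tree.nwk")
model <- build_model("JTT", alpha = 1.114, K = 4)
prof  <- marginal_posteriors(aln, tree, model, "anc_SN")
mask  <- fitch_gap_mask(aln, tree, "anc_SN")
map_sequence(prof, mask); altall_sequence(prof, mask); mean_pp(prof, mask)
```

See `vignettes/ancestral-fmo-methods.Rmd` for the model, the funnel rules,
the deconvolution algorithm and every numerical convention.

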
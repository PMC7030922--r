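---
title: "Validating and mining cross-linking mass spectrometry data with xlmstools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and mining cross-linking mass spectrometry data with xlmstools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`xlmstools` implements the downstream analysis of proteome-wide
cross-linking mass spectrometry (XL-MS) experiments performed with a
lysine-reactive, MS-cleavable cross-linker such as DSSO. The input is a
table of residue-resolved lysine-lysine cross-links (already identified
and FDR-controlled by a spectral search engine; spectral identification
is out of scope). On top of that table the package provides five
independent lines of evidence about dataset quality and biology:

1. **Distance-restraint validation.** A cross-link between two lysines
   constrains their Calpha-Calpha Euclidean distance to at most the
   spacer geometry plus conformational allowance. For DSSO this is
   23.4 Å + 10 Å = 33.4 Å, the package default (`threshold`, in
   Ångström, per-call override available — e.g. 27 Å is sometimes used
   for well-packed binary complexes, and 23.4 Å without allowance for
   docking-grade restraints). Links are mapped from UniProt coordinates
   onto structure chains through explicit alignment-derived chain maps.
   For homo-oligomers every placement of the two endpoints over the
   mapped copies is enumerated and the *minimum* distance is scored: a
   cross-link is explained if any copy pair explains it. Residues
   missing from the deposited model make a link *unmappable*; it is
   reported, never dropped or imputed (loop modelling is out of scope).
2. **Membrane-topology consistency.** With UniProt-style region
   annotations, a link joining a cytoplasmic and an extracellular
   residue is physically impossible in an intact vesicular preparation.
   The cross-side rate is the violation count over links whose *both*
   endpoints lie in annotated cytoplasmic or extracellular regions;
   transmembrane and unannotated positions drop a link from the
   denominator (UniProt topology is sparse; regions need not tile the
   protein).
3. **Interaction-network statistics.** Interprotein links aggregate into
   an undirected protein graph (edge weight = unique link count; weights
   are metadata — all topology statistics run on the unweighted graph,
   matching common practice). The package computes connected components
   (core + side modules of at least `k = 3` proteins), a log-log
   least-squares fit of the degree distribution, Girvan-Newman
   edge-betweenness clustering scored by Newman modularity
   `Q = sum_c (e_c/m - (d_c/2m)^2)`, degree-preserving rewired nulls
   (double-edge swaps, `10 |E|` attempts per permutation, 100
   permutations by default), co-annotation and path-distance statistics
   against those nulls, and one-sided Fisher term enrichment with
   Benjamini-Hochberg correction.
4. **External-evidence overlap and replication.** Evidence records from
   STRING/InWEB/BioGRID-style exports are tiered: STRING combined score
   < 400 low, 400-700 medium (right-open), >= 700 high; InWEB score
   absent or < 0.2 low, 0.2-0.7 medium, >= 0.7 high; BioGRID
   low-throughput evidence high, otherwise low. A protein pair is "high
   confidence" when any of its records is. Replicate agreement is
   summarized as the per-pair detection multiplicity, and two networks
   are compared edge-wise as direct / indirect (one shared neighbor) /
   unconnected over the shared protein set.
5. **Binding-site statistics.** Lysines map across species only when the
   destination sequence is identical up to the lysine position (prefix
   identity — deliberately conservative, no alignment heuristics).
   Interface enrichment is a two-sided Fisher test over a lysine
   background. Peptide tiling arrays are quantified per spot (background
   subtraction, positive-control normalization, negative-control tag
   subtraction, technical-replicate averaging, nonspecific-control
   subtraction, clipping at zero) and binding regions are called only
   where at least two above-threshold peptides overlap in sequence.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fdr_threshold` | 0.02 | fraction | identification-level FDR cap applied on read |
| `threshold` (restraints) | 33.4 | Å | DSSO spacer 23.4 Å + 10 Å in-solution flexibility |
| histogram `bin_width` | 5 | Å | conventional granularity of distance histograms |
| `min_identity` (chain map) | 0.30 | fraction | below this the chain likely is a different protein |
| side-module floor `k` | 3 | proteins | smallest component worth calling a module |
| `n_iter` (rewiring) | 100 | permutations | standard null ensemble size |
| `min_proteins` (co-annotation) | 50 | proteins | restrict to well-populated cellular-component terms |
| array threshold | mean + 2 SD of control | normalized signal | conventional positivity rule; the protocol filters "low-signal spots" without a numeric cutoff, so this is an explicit, configurable package choice |

Link identity is the unordered residue pair (accession, position);
chemistry and charge variants collapse, and all coordinates are 1-based
UniProt positions (structure author numbering is reconciled only inside
chain maps). Ambiguous shared-peptide links are kept and flagged but
excluded from protein-pair-level statistics unless
`include_ambiguous = TRUE`.

## What the synthetic worlds emulate

Every analysis stage is exercised end-to-end on generated ground truth
(`make_world()`, `simulate_world()`):

* **Toy complexes** are self-avoiding random walks with the 3.8 Å
  consecutive-Calpha spacing of real backbones, a 4 Å excluded volume
  and 15% lysine frequency. They reproduce the *geometry* a restraint
  checker sees (local proximity, chain packing), not protein secondary
  structure.
* **Cross-link sets** draw a controlled fraction of links beyond the
  restraint threshold (deterministic stratum sizes, sampling without
  replacement), so the violation rate is recoverable within exact
  binomial error.
* **Topology worlds** use a fixed region layout (cytoplasmic 1-100,
  transmembrane 101-120, extracellular 121-220) and Bernoulli cross-side
  draws.
* **Replicate detection** uses a logistic model
  `p = plogis(intercept + slope * log10(min partner abundance))`
  (defaults -9 and 1.5: a pair limited by a 1e6-abundance protein is a
  coin flip). The logistic form is a stand-in — the emulated phenomenon
  is only that detection probability increases with the abundance of the
  scarcer partner; no quantitative detection model is claimed.
* **Planted-partition graphs** (`p_in = 0.3`, `p_out = 0.01`, four
  modules of 25 by default) with module-aligned annotation terms plus a
  10% spill-over test clustering and the annotation statistics.
* **Evidence databases** sample a target tier per pair and draw a
  source/score pair inside that tier's range; the default world covers
  51% of network pairs with 39% of all pairs high-confidence.
* **Peptide arrays** plant binding regions of known amplitude on a tiled
  target with shared nonspecific signal and Gaussian noise.

Passing tests on these worlds demonstrates that the estimators recover
known parameters under the stated noise models. They do not demonstrate
robustness to the pathologies of real data — mis-assigned spectra,
heterogeneous conformations, incomplete structures, biased annotation
databases — beyond the specific mechanisms modelled (missing residues,
spill-over annotations, nonspecific array binding).

## Numerical and design choices

* **Girvan-Newman determinism.** Edge betweenness is recomputed after
  every removal; ties at the maximum (within a 1e-9 relative tolerance)
  break towards the lexicographically smallest edge, making the
  procedure fully reproducible. The partition maximizing `Q` over the
  removal sequence is returned; graphs that never beat the trivial
  partition (complete graphs) return one community with `Q = 0`.
  Published modularity values from other implementations may differ
  slightly because the tracked partition sequence depends on tie
  handling.
* **Component ties** resolve towards the component containing the
  lexicographically smallest protein accession, with a logged message.
* **Altloc handling** keeps the highest-occupancy alternate location
  (first on ties); residues without a Calpha are present-but-absent.
* **Chain-map alignment** uses global alignment with match +1,
  mismatch -1, gap -2 and keeps only identical aligned columns, so a
  mapped lysine is lysine on both sides by construction.
* **Degenerate inputs** fail loudly: undefined topology rate (nothing
  mapped), degenerate power-law fits (< 3 distinct degrees), constant
  abundance in correlations, positive control at or below background.
* **Seed fan-out.** A world's single seed derives per-generator streams
  by fixed offsets, so generators stay decoupled and every world is
  bit-reproducible; all generator RNG is scoped and restores the
  caller's RNG state.
* **Problem sizes.** The reference conditions used by the test-suite and
  the reproduction script are: an 8-chain, 100-residue complex with 400
  links; 2000 topology links; 500 replicate pairs over 3 replicates; a
  100-node planted network with 100 rewired permutations. These sizes
  hold every recovery check inside tight binomial intervals while the
  whole suite stays fast.

## A worked run

```{r, eval = FALSE}
library(xlmstools)
d <- tempfile("world")
simulate_world(d, seed = 1)
cfg <- world_config(d, seed = 1, n_null = 100)
report <- run_pipeline(cfg, verbose = TRUE)
report$stages$restraints$fraction_satisfied
report$stages$topology$rate_pct
report$stages$network$modularity
```

The same stages are exposed as a thin command line
(`inst/scripts/xlms simulate|run`) writing per-stage TSVs and a
schema-versioned `report.json` that embeds the seed and configuration;
reruns are byte-identical.

## Known limitations

* Euclidean Calpha distances only; no solvent-accessible-surface
  distances, no conformer morphing, no loop or homology modelling.
* Cross-species lysine mapping by prefix identity is conservative and
  will miss orthologs with upstream indels.
* Evidence parsing expects pre-extracted TSV exports, not live database
  dumps; tier rules are fixed to the three supported source types.
* The replicate-detection model is phenomenological (see above).
* Ambiguity handling is binary (flag and exclude); probabilistic
  shared-peptide assignment is not attempted, so pair counts on real
  data depend on how the upstream search reported shared peptides.
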
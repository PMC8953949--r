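# fdrscope

Find **function-determining residues** in a protein domain superfamily by
combining three lines of evidence:

1. **Subgroup-distinguishing sequence patterns.** A large multiple
   sequence alignment is partitioned into a hierarchy of subgroups, each
   defined by its *pattern residues* — columns whose residue sets are
   differentially conserved in the subgroup's foreground relative to its
   closest background. The column statistic is a hypergeometric tail,
   `s = -log10 P(X >= x_fg)` with `X ~ Hypergeom(n_fg + n_bg', x_fg + x_bg', n_fg)`
   (one background pseudocount), charged `log10 C(20, |set|)` for
   residue-set selection. The hierarchy is found by a seeded stochastic
   optimizer (split / adopt / reassign / prune sweeps) whose split
   acceptance is validated on held-out halves of the data.
2. **Spatial clustering of pattern residues.** Given a two-chain complex,
   the package asks whether a subgroup's pattern residues concentrate at
   the chain–chain interface, or within sequentially grown structural
   clusters, using a minimum-hypergeometric *initial cluster* scan over
   ordered residue lists: `p_min = min_k P(X >= x_k)` over prefixes, with
   a mark-permutation calibration `(1 + #{p_perm <= p_obs}) / (B + 1)`
   that absorbs both the prefix and (in core mode) the seed-choice
   multiplicity.
3. **Saturation binding.** Ligand–receptor curves are fitted to the
   one-site model `A = Amax / (1 + Kd/L)` (Hill generalization
   `A = Amax·L^h / (Kd^h + L^h)`) by Levenberg–Marquardt least squares,
   with Scatchard transforms (slope `-1/Kd`) and percent-inhibition
   summaries for competition assays — the workflow used to compare
   wild-type and point-mutant proteins.

Planted-truth generators (hierarchical MSAs, toy Cα complexes, noisy
binding curves) make every stage testable end to end with no downloads.
The package is aimed at computational biologists dissecting subfamily
specificity — which residues make one semaphorin subfamily bind and
signal differently from its siblings is the archetypal question.

## Worked example

```r
library(fdrscope)

# 1. A planted two-level superfamily: 2 families x 2 subfamilies,
#    200 sequences per leaf, 5 pattern columns per node at strength 0.95
g <- gen_hierarchical_msa(default_hierarchy_spec(seed = 7))
h <- sample_hierarchy(g$msa, sampler_config(seed = 1))
h
#> hierarchy: 7 nodes over 800 sequences, objective 4569.7
#>   node 1 (root): 0 direct members, 0 pattern positions
#>   node 2 (parent 1): 0 direct members, 20 pattern positions
#>   node 3 (parent 1): 0 direct members, 20 pattern positions
#>   node 4 (parent 2): 200 direct members, 10 pattern positions
#>   node 5 (parent 2): 200 direct members, 9 pattern positions
#>   node 6 (parent 3): 200 direct members, 10 pattern positions
#>   node 7 (parent 3): 200 direct members, 9 pattern positions
hierarchy_newick(h)
#> [1] "((4,5)2,(6,7)3)1;"
```

The recovered topology is exactly the planted one: two families (nodes 2
and 3), each with two subfamilies holding their 200 sequences. The top
of the pattern table shows family-defining columns scoring ~175 -log10
units (near-fixed in 400 foreground sequences, rare in the background):

```r
head(pattern_table(h)[order(-pattern_table(h)$score), ], 3)
#>    node_id column residues    score fg_matches fg_total bg_matches bg_total
#> 21       3     50        D 181.9894        386      400         17      400
#> 1        2     45        Y 177.8565        383      400         17      400
#> 22       3     20        E 176.5285        382      400         17      400

# 2. Do marked residues cluster at a chain-chain interface?
gc <- gen_complex_structure(default_complex_spec(seed = 1))
interface_sipris(gc$structure, "A", "B",
                 as.character(gc$truth$planted), n_perm = 999, seed = 1)
#> cluster_result: 8/8 marks in best prefix of 8
#>   (raw min p = 3.91e-10, adjusted p = 0.001, 999 perms)
```

All 8 planted residues are the 8 closest to the partner chain; no
permutation of the marks does better, so the adjusted p-value sits at its
floor 1/1000.

```r
# 3. Fit a noisy saturation curve planted at Kd = 19.9 nM
cv <- gen_binding_curve(binding_sim_spec(Amax = 1, Kd = 19.9,
                                         noise_sd = 0.02, seed = 2))
fit_binding(cv)
#> binding_fit: Kd = 19.91 nM, Amax = 1.015 OD, h = 1 (converged, n = 12)
```

`run_pipeline(pipeline_config(...))` chains the stages (filter →
partition → contrast alignments + PyMOL scripts → interface/core
clustering → binding fits) under one global seed and writes a manifest
plus machine-readable results; `read_pipeline_config()` loads the same
settings from YAML.

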
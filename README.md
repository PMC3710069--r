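# smrwalign

Probabilistic multiple alignment of protein–protein interaction (PPI)
networks in R.

Cross-species comparison of PPI networks asks which proteins play the same
role in different organisms. Multiple network alignment answers it by
grouping nodes from two or more networks into *equivalence classes* of
putative orthologs, combining node similarity (e.g. BLAST bit scores) with
interaction-pattern similarity. `smrwalign` implements a scalable
probabilistic pipeline for this problem, together with the field's
standard evaluation measures and a synthetic network-family generator with
known ground-truth orthology, so the whole method can be exercised without
external databases.

## The method

For each network pair, a **semi-Markov random walk** on the product graph
gives a global correspondence score with a closed form: the walk's
stationary law factorizes into the per-network weighted-degree
distributions, and holding a product state (x, y) for a mean time equal to
the similarity h(x, y) yields the long-run occupancy

    c(x, y) ∝ stat_a(x) · stat_b(y) · h(x, y)

renormalized over the (sparse) similarity support. Scores become symmetric
pairwise **alignment probabilities** by averaging their row- and
column-normalized forms,

    p(x, y) = ½ [ c(x, y)/Σ_y' c(x, y')  +  c(x, y)/Σ_x' c(x', y) ],

which are then sharpened by two **probabilistic consistency
transformations**: an intra-network pass mixing each entry with the
transition-weighted average of its neighbors' probabilities
(`q = α p + (1−α) T_a p T_bᵀ`, α = 0.9), and a cross-network pass that
routes evidence through every other network z as an intermediate,
weighting each by the estimated homology `w(a,z)·w(z,b)` (from
maximum-weight bipartite matchings). Finally, a **greedy
maximum-expected-accuracy** pass inserts node pairs in decreasing
probability order into equivalence classes, subject to a per-network cap
(ℓ = 10) and a coherence test (γ = 0.8) that keeps poorly fitting
same-network paralogs out. All pair matrices are sparse throughout; the
cost is polynomial in the number and size of the networks.

Evaluation measures: specificity (SPE), correct nodes (CN), mean
normalized entropy (MNE), conserved (orthologous) interactions (CI/COI),
coverage histograms, sensitivity, and pair accuracy against a reference
alignment.

## Worked example

Generate a 3-network family descending from a 50-node ancestor (crystal
growth model), simulate similarity scores with a large ortholog/background
separation, align, and score against the generator's truth:

```r
library(smrwalign)

fam  <- grow_family("CG", ancestor_size = 50,
                    target_sizes = c(90, 100, 110), seed = 42)
sims <- simulate_scores(fam, score_model(bias = 1500, sparsity = 0.01),
                        seed = 43)
run  <- align_networks(fam$networks, sims, run_config())
run$alignment
#> <network_alignment: 86 classes, 237 aligned nodes>

evaluate_alignment(run$alignment, family_annotations(fam),
                   fam$networks, truth = fam$truth)
#> SPE 100.00%  CN 150  MNE 0.0000 (x100: 0.00)  SEN 100.00%
#> CI 226  COI 222
#> pair accuracy 1.0000
#> class coverage: 1:0 2:26 3:60
```

Reading the output: all 86 equivalence classes whose members carry an
ancestral-family annotation are pure (SPE 100), the 150 annotated aligned
nodes all sit in correct classes (CN/SEN), 226 interactions are conserved
between class pairs across the three networks and 222 of them connect
correct classes, 60 classes span all three networks, and every
cross-network ortholog pair of the ground truth is recovered (pair
accuracy 1.0).

The first class, for instance, groups the three descendants of one
ancestral protein:

```r
run$alignment$classes[[1]]
#>    net node
#> 1 net1  p48
#> 2 net3  p48
#> 3 net2  p48
```

### Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
netalign=$(Rscript -e 'cat(system.file("cli/netalign", package = "smrwalign"))')
Rscript $netalign simulate --model cg --ancestor 50 --sizes 90,100,110 \
        --bias 1500 --sparsity 0.01 --seed 42 -o fam/
Rscript $netalign align -n fam/net1.tsv -n fam/net2.tsv -n fam/net3.tsv \
        -s fam/sim_net1_net2.tsv -s fam/sim_net1_net3.tsv \
        -s fam/sim_net2_net3.tsv -o out.clusters
Rscript $netalign evaluate -a out.clusters -g fam/annotations.tsv \
        -n fam/net1.tsv -n fam/net2.tsv -n fam/net3.tsv \
        -t fam/truth.clusters --report report.json
```

File formats are plain text: tab-separated edge lists
(`nodeA nodeB [weight]`), similarity lists (`nodeA nodeB score`),
annotation maps (`node group`), and one equivalence class per line
(`net::node` tokens) for alignments.

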
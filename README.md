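# ovrfsim

Exact stochastic simulation of nucleotide sequence evolution along a rooted
phylogeny for genomes with **overlapping reading frames** (OvRFs), in linear
or circular topology.

Overlapping genes are ubiquitous in viruses: the same nucleotides encode
protein in two or more frames, so one substitution can be synonymous in one
frame and non-synonymous in another. That coupling breaks the
independent-codon assumption behind standard dN/dS inference. `ovrfsim`
provides a ground-truth generator for studying this effect: it evolves a
root sequence along a tree under a per-site rate model

```
lambda_ij = mu_i * pi_j                     synonymous / non-coding transversion
          = mu_i * kappa * pi_j             synonymous / non-coding transition
          = mu_i * omega * pi_j             non-synonymous transversion
          = mu_i * omega * kappa * pi_j     non-synonymous transition
```

where the selective effect is evaluated in *all six* frame contexts
`{-2, -1, -0, +0, +1, +2}` of a site and combined multiplicatively:
`omega = prod(w)`, with `w[f] = 1` where the change is synonymous (or no ORF
lies in frame `f`) and `w[f]` equal to the site's dN/dS category for the ORF
in that frame otherwise. Rate heterogeneity in `omega` (per ORF) and `mu`
(global) comes from gamma or lognormal distributions discretized into
equal-probability categories represented by their conditional means
(shape-*scale* gamma convention: shape 2, scale 0.5 gives categories
0.293, 0.655, 1.070, 1.982 with mean exactly 1).

Candidate substitutions live in a hierarchical *event-probability tree*
(target nucleotide → transition class → mu category → ORF-membership region
→ omega-combination class) with cached subtree weights, giving fast
rate-proportional Gillespie sampling, incremental updates after every
substitution, and deep copies at internal nodes of the phylogeny. Sites in
the first or last codon of any ORF are protected from substitution so ORFs
are never disrupted. The sampling engine is compiled (Rcpp) and is validated
in the test suite against an independent pure-R flat enumeration of all
event rates — exactly (cached weights vs enumeration) and empirically
(multinomial test on 10^6 draws).

Inputs: a FASTA or GenBank root sequence (GenBank CDS features, including
`join(...)` across a circular origin and `complement(...)`, become ORFs), a
YAML run configuration (ORF coordinates, omega/mu distributions, kappa, pi,
global rate, circularity), and a rooted Newick tree with branch lengths.
Outputs: the tip alignment (FASTA), a substitution log (TSV) and a run
summary (JSON), plus Shannon-entropy diagnostics (per column, sliding
window, and per ORF-membership region).

## Worked example

Simulate a 1.2 kb circular genome with a hepatitis-B-like arrangement of
four overlapping ORFs (one wrapping the origin) over a random 20-tip tree,
under purifying selection (mean omega 0.5 per frame):

```r
library(ovrfsim)

orfs <- make_overlap_layout("hbv-like", 1200)
g    <- imprint_orf_signals(make_genome(1200, seed = 5, circular = TRUE), orfs)
phy  <- make_tree(20, total_depth = 0.75, seed = 5)

res <- ovrf_simulate(g, orfs, phy,
                     params = substitution_params(global_rate = 1),
                     seed = 99)
res$summary$n_events
#> [1] 2085
head(res$substitutions, 3)
#>   position from to        time branch
#> 1      836    T  G 0.001854743 node22
#> 2      144    A  T 0.002740883 node22
#> 3     1193    G  T 0.002791372 node22

h  <- alignment_entropy(res$alignment)
rs <- region_summary(h, partition_regions(g, orfs))
rs$regions
#>   region membership n_sites  mean    q1    q3
#> 1     R1          P     300 0.680 0.286 1.154
#> 2     R2        P,S     360 0.429 0.000 0.748
#> 3     R3        P,X      60 0.446 0.000 0.781
#> 4     R4          X      84 0.642 0.000 1.054
#> 5     R5                168 0.987 0.694 1.336
#> 6     R6          C     120 0.605 0.000 0.948
#> 7     R7        P,C     108 0.537 0.000 0.934
```

The 2085 substitutions are what survived selection over the whole tree; the
region table shows the signature of overlap: non-coding columns (region R5,
mean entropy 0.99 bits) are the most diverse, single-ORF coding regions are
intermediate (P alone 0.68, X 0.64, C 0.61), and overlap regions are the
most constrained (P∩S 0.43, P∩X 0.45, P∩C 0.54), because deleterious
effects multiply across frames. The built-in comparison confirms it:

```r
rs$overlap_vs_single
#> mean 0.453 (overlap) vs 0.656 (single-ORF), Wilcoxon p = 7.3e-11
```

The same run works from files alone (`run_simulation()`), or from a shell
via the thin CLI in `exec/`:

```sh
exec/ovrf-sim fixtures  --style hbv-like --out demo --length 1200 --tips 20 --seed 5
exec/ovrf-sim run       --seq demo/hbv-like.fasta --config demo/hbv-like.yaml \
                        --tree demo/hbv-like.nwk --out demo/run --seed 99
exec/ovrf-sim entropy   --alignment demo/run.fasta --out demo/entropy.tsv --circular
exec/ovrf-sim gb2config --in inst/extdata/synthetic_overlap.gb --out demo/config.yaml
```

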
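---
title: "Simulating sequence evolution in overlapping reading frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sequence evolution in overlapping reading frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovrfsim)
```

## The problem

Viral genomes are compact and frequently encode two or more proteins on the
same stretch of nucleotides. In such overlapping reading frames (OvRFs) a
single substitution can be synonymous in one frame and non-synonymous in
another, so the usual assumption that codons evolve independently breaks
down, and dN/dS-style inferences can be badly skewed. `ovrfsim` simulates
nucleotide-level evolution along a rooted phylogeny for linear or circular
genomes carrying any arrangement of ORFs — nested, overlapping on either
strand, or wrapping the origin of a circular genome — so that the impact of
overlap on sequence diversity can be studied under a known ground truth.

## The substitution model

The state of the simulation is a nucleotide sequence. The rate of replacing
the base at site $i$ with nucleotide $j$ is

$$
\lambda_{ij} =
\begin{cases}
\mu_i \pi_j & \text{synonymous or non-coding transversion,}\\
\mu_i \kappa \pi_j & \text{synonymous or non-coding transition,}\\
\mu_i \omega \pi_j & \text{non-synonymous transversion,}\\
\mu_i \omega \kappa \pi_j & \text{non-synonymous transition,}
\end{cases}
$$

where $\pi_j$ is the stationary frequency of the target nucleotide,
$\kappa$ a transition ($A \leftrightarrow G$, $C \leftrightarrow T$) rate
multiplier, and $\mu_i$ a per-site mutation-rate multiplier. Selection is
evaluated in *every* reading frame covering the site: the substitution's
effect is tracked in a six-slot vector $\mathbf w$ indexed by the frame
labels $\{-2,-1,-0,+0,+1,+2\}$ (sign = strand relation, digit = frame
shift). A slot is 1 where the change is synonymous or no ORF is present;
otherwise it carries the site's dN/dS category for the ORF in that frame.
Lacking empirical information on how selective effects combine across
frames, the model takes them to be multiplicative, $\omega = \prod \mathbf
w$, so a change that is deleterious in two frames at once is doubly
suppressed. A substitution that is synonymous in all frames, or non-coding,
has $\omega = 1$ exactly. When two ORFs happen to share a frame slot their
categories multiply within the slot, which leaves $\omega$ well defined.

Synonymy is judged against the standard genetic code
(`Biostrings::GENETIC_CODE`). A substitution that creates a premature
internal stop codon is allowed and treated as non-synonymous in that frame;
only each ORF's *terminal* codons are sacrosanct: all six nucleotides of
the first and last codon of every ORF are "protected" and excluded from the
event pool entirely, so an ORF can never lose its boundaries. A
consequence worth knowing: a genome tiled by two-codon ORFs has no
mutable site at all and is rejected as unsimulatable.

### Rate heterogeneity

Both $\omega$ (per ORF) and $\mu$ (global, with optional per-ORF
multipliers) are drawn from discretized gamma or lognormal distributions.
The continuous density is cut into `ncat` equal-probability quantile bins
and each bin is represented by its **conditional mean**, which preserves
the distribution mean exactly; with shape 2 and scale 0.5 the four gamma
categories are

```{r}
discretize(dist_spec("gamma", shape = 2, scale = 0.5, ncat = 4))$values
```

Two conventions deserve emphasis because they are easy to get wrong:

* **Gamma parameterization is shape--scale**, mean $=$ shape $\times$
  scale. (The shape-rate convention, mean shape/rate, gives the same mean
  here but different category values; the category values above are what
  pin the convention down.)
* **Lognormal** uses `sdlog = shape` and `meanlog = log(scale)`; the
  default `scale = 1` puts the median at 1. Bin conditional means are
  computed in closed form from shifted normal CDFs and are validated
  against adaptive quadrature in the test suite.

Category assignments are drawn once per run — every site draws a $\mu$
category, and one $\omega$ category per covering ORF — and stay fixed along
the whole tree. Sites covered by several ORFs hold independent categories
for each.

## The event-probability tree

A naive Gillespie implementation recomputes and linearly searches all $3L$
candidate rates at every step. Because the discretized model admits only
finitely many rate values, candidate events can instead be grouped by their
shared factors in a fixed hierarchy, root to tip:

1. target nucleotide $j$,
2. transition vs transversion class,
3. effective $\mu$ category,
4. membership *region* (maximal set of sites covered by an identical set
   of ORFs),
5. $\omega$-combination class (the multiset of (ORF, $\omega$ category)
   pairs in which the change is non-synonymous, canonicalized by ORF).

Every event at an unprotected site sits in exactly one tip subset, and all
members of a tip share one rate — this is asserted at build time. Each node
caches its subtree weight; the root weight is $\Lambda = \sum \lambda$. A
draw walks from the root choosing children with probability proportional to
their cached weights and finally picks uniformly within the tip, which
reproduces the flat distribution $\lambda_e / \Lambda$ *exactly*. The
region level's weight decomposes as $\sum_k \omega_k N_k$ over the
$\omega$-combination classes with $N_k$ member events, which the tests
recompute independently.

One design point was genuinely open: a prose description of such samplers
sometimes fixes the per-level probabilities a priori (e.g. choosing the
source class with probability $1/(1+2\kappa)$ vs $\kappa/(1+2\kappa)$), but
those constants are inconsistent with $\lambda_{ij}$ itself, under which
the transition *class weight* depends on $\kappa$, $\pi$ and the current
composition. We define correctness as exact equivalence with
$\lambda_e/\Lambda$ and let every traversal step use the cached weights;
the package's central property test compares the sampler's distribution
with a flat enumeration computed by an independent pure-R code path
(`enumerate_events()`), both exactly (weights, to $10^{-9}$) and
empirically ($10^6$ draws, multinomial $\chi^2$ at $\alpha = 10^{-3}$).

After an applied substitution the engine re-derives the events of the
mutated site and of every site sharing a codon with it in any frame —
deliberately conservative recomputation; the rebuild-equality property test
(incremental tree $\equiv$ fresh build after 100 random events) is what
licenses any future narrowing. Level order of the hierarchy affects only
efficiency, never the sampling distribution.

The engine is implemented in C++ (via Rcpp), as is usual for simulation
cores in this field; the R-level enumeration oracle is kept free of any
shared code with it.

## Branch simulation and tree traversal

Along a branch the simulator draws exponential waiting times with rate
$\Lambda$ (the standard Gillespie construction; an exponential *rate*, not
scale), applies sampled events, and stops as soon as the accumulated time
exceeds the branch duration, propagating the current sequence to the next
node. The phylogeny must be rooted, bifurcating at the root (a basal
polytomy is treated as unrooted unless explicitly allowed) and carry branch
lengths. Traversal is breadth-first from the root, and the whole state —
sequence plus event tree — is deep-copied for every child branch, so
lineages are fully independent.

**Time units.** Branch lengths are calibrated so that a fully neutral site
accumulates `global_rate` substitutions per unit branch length: all rates
are divided by the root-sequence average of the per-site neutral departure
rate $\mu_i \sum_{j \ne s_i} \kappa^{[\mathrm{ts}]} \pi_j$. With
`global_rate = 0.01` a branch of length 1 yields 0.01 substitutions per
site on average, by construction; the acceptance suite verifies this on a
100 kb neutral genome over 20 replicates.

**Reproducibility.** The master seed drives category assignment first; each
branch then gets its own stream, derived deterministically from the master
seed and the branch's clade signature (the sorted tip labels below it).
Identical inputs and seed give bit-identical alignments, and rotating
siblings — or adding tips elsewhere in the tree — does not perturb an
unrelated lineage's draws. This is tested.

## Entropy diagnostics

Output diversity is summarized by per-column Shannon entropy $H = -\sum_i
P_i \log_2 P_i$ (0 for a conserved column, 2 bits at equal base
frequencies), sliding-window means (default width 20, step 1; linear
alignments yield only complete windows, circular ones wrap), and
region-stratified summaries: mean and IQR per membership region plus a
two-sided Wilcoxon rank-sum comparison of overlapping vs single-ORF coding
columns. Quartiles use R's default linear-interpolation convention
(`quantile` type 7). Gap or ambiguous characters — possible in external
alignments, never in this simulator's output — are dropped from the column
frequencies with a warning.

Under purifying selection the simulations reproduce the qualitative
diversity ordering expected for overlap: non-coding columns are most
diverse, single-ORF coding columns intermediate, and overlap columns least
diverse, because $\omega$ multiplies across frames. The acceptance suite
requires this ordering in at least 18 of 20 replicate runs on the
`hbv-like` layout; the corresponding *numeric* entropy levels depend on the
(arbitrary) tree and rate scale and are not targets.

## Synthetic fixtures and what the tests do (and do not) show

All validation runs on synthetic data generated in-repo:

* `make_genome()` — i.i.d. sequences at a chosen composition;
* `make_overlap_layout()` — three deterministic ORF arrangements: `fig2`
  (an isolated ORF plus an overlapping pair; exactly five membership
  regions), `hbv-like` (four ORFs on a circular genome: a long
  origin-wrapping `P`, `S` nested in `P` at +1, `X` and `C` overlapping `P`
  at the segment boundaries, ~14% non-coding — the published HBV geometry's
  coordinate *relations* at an arbitrary scale, not its sequence), and
  `dense` (opposite-strand full-length ORFs; every site doubly coding).
  Layouts default to purifying selection, gamma(shape 2, scale 0.25; mean
  $\omega = 0.5$), a deliberate middle ground: strong enough for clear
  coding/non-coding contrast, weak enough that coding regions still vary;
* `make_tree()` — random rooted binary trees rescaled to a chosen depth.

Synthetic genomes are i.i.d. and, by default, compositionally uniform; real
genomes have local composition structure, codon usage bias and
non-stationary evolution, none of which the generator emulates. Passing
tests therefore demonstrate the *internal* correctness of the sampler and
its calibration under the stated model — not that the model captures any
particular virus. Validation problem sizes were chosen to keep the full
suite fast while leaving comfortable statistical power: oracle-equivalence
genomes of at most 60 nt with up to 3 ORFs (small enough for exhaustive
enumeration), $10^6$ sampler draws, a 100 kb neutral genome over 20
replicates for the calibration check, a $10^5$-site lineage of depth 20 for
stationarity ($\chi^2$ against $\pi = (0.1, 0.2, 0.3, 0.4)$ at $\alpha =
10^{-3}$), and twenty 1.2 kb, 20-tip replicates for the entropy ordering.

## Numerical choices and edge cases

* Coordinates are 1-based inclusive everywhere in the R interface, YAML
  and GenBank, matching R and GenBank convention; an origin-wrapping ORF is
  exactly two segments, listed in reading order and meeting at the origin.
* Ambiguous nucleotides in the root sequence are rejected, not randomized:
  every site must have well-defined rates. A root missing some base
  entirely has a degenerate empirical $\pi$ and is rejected unless $\pi$
  is supplied explicitly.
* ORFs need not literally start with ATG or end with a stop; a warning is
  emitted (the fixture generators imprint the signals to keep demos quiet).
* Cached weights are updated incrementally by exact deltas; weight
  conservation at every node is asserted to $10^{-9}$ relative in the
  tests. Weighted child selection falls back to the last positive-weight
  child if floating-point round-off lets the draw overshoot.
* $\mu$ levels in the event tree key on *effective* per-site values
  (global category times any per-ORF multipliers), preserving the
  equal-rate-within-tip invariant.
* Zero-length branches are legal and propagate the sequence unchanged;
  negative lengths are errors.

## Known limitations

No indels, recombination, or time/lineage-varying rates — the state space
is substitutions only, so alignment columns never move. Selection is
nucleotide-level HKY-like with multiplicative dN/dS categories: there is no
codon-frequency equilibrium model (F3x4/F61), and synonymous rates are
implicitly constrained to 1, so simulated dS shows less dispersion than
real data even when $\mu$ variation is added. ORF discovery is out of
scope (annotations come from the user, YAML or GenBank), as are spliced
ORFs beyond the single circular-origin wrap.
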
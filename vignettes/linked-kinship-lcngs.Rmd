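---
title: "Pedigree likelihood ratios from low-coverage sequencing reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree likelihood ratios from low-coverage sequencing reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinlink)
```

## The problem

Forensic and archaeological DNA samples are often degraded and present in
tiny amounts, so genome sequencing of such material yields *low-coverage*
data (roughly 10X allelic depth or less) with frequent allelic drop-out and
occasional drop-in reads. Deciding between two hypothesized pedigrees
relating a set of tested persons — say, "these two people are second
cousins" versus "they are unrelated" — requires a likelihood ratio

$$ \mathrm{LR} = \frac{\Pr(\text{data} \mid \text{pedigree}_1)}
                     {\Pr(\text{data} \mid \text{pedigree}_2)}, $$

and with low-coverage data the honest computation works directly on the
per-locus A/C/G/T read counts rather than on called genotypes. kinlink
implements such a likelihood over a panel of linked SNPs, together with the
simulator needed to study its behaviour.

The likelihood factors into three model layers, described next, joined by a
hidden Markov model over inheritance patterns.

## Observational model: reads given a genotype

A locus observation for one person is a count vector
$c = (c_A, c_C, c_G, c_T)$ with total depth $d$. Given the true genotype
$g = (g_1, g_2)$, two stochastic stages produce $c$:

1. **Template sampling.** The heterozygote balance is $q = k/m$ with
   $k \sim \mathrm{Binomial}(m, 1/2)$, where $m$ is the effective number of
   DNA templates founding PCR amplicons at the locus. Small $m$ (degraded,
   low-quantity samples; values 1–10 in practice) makes $q$ skewed or even
   0/1, which is what produces allelic drop-out.
2. **Reads.** Conditional on $q$, counts are multinomial with category
   probabilities $\beta_i = (1-e)\,(q\,I(g_1{=}i) + (1-q)\,I(g_2{=}i)) + e/4$,
   where $e$ is the per-read error probability (drop-in); an error read
   reports each nucleotide with probability $1/4$.

`read_likelihood()` sums the resulting multinomial over the $m+1$ binomial
states exactly. Useful consequences, both available as functions:

* the probability that all $d$ reads at a heterozygous locus support a
  single true allele (`dropout_probability()`), which for $d = 1$ is
  exactly $1 - e/2$ regardless of $m$; and
* the expected per-read drop-in rate for a genome with a proportion $h$ of
  homozygous loci, $h \cdot 3e/4 + (1-h) \cdot 2e/4$ (`dropin_rate()`).

Defaults are $m = 10$, $e = 0.02$, sensible for reduced-quality forensic
samples on current sequencers; both can instead be given discrete priors,
in which case the final likelihood is the prior-weighted mixture computed
on the natural scale.

## Population model: founder alleles

The alleles of the pedigree founders at one locus form one exchangeable
sequence drawn from a Dirichlet-multinomial: after $k$ of $s$ previous
draws showed allele $i$, the next draw is allele $i$ with probability

$$ \frac{\theta k + (1-\theta)\,f'_i}{1 + \theta(s-1)}, \qquad
   f' = f(1-\gamma) + \gamma \bar f, $$

where $f$ is the locus frequency vector, $\theta$ is the kinship/fixation
parameter ($F_{st}$, default 0.01), and $\gamma$ (default 0.001) smooths
$f$ towards background nucleotide probabilities $\bar f$ so that alleles
with population frequency zero are not impossible — without this, two deep
stacks of reads for an unseen allele in two samples would be explained away
as errors and the LR would be blind to them. With $\gamma = 0$ the formula
is the classical $F_{st}$ correction; $\theta = 0$ is the Hardy-Weinberg
limit. The model is equivalent to posterior-predictive sampling from a
database of size $(1/\theta - 1)(1-\gamma)$ with pseudo-counts
$(1/\theta-1)\gamma\bar f$.

$\bar f$ defaults to uniform $(1/4, 1/4, 1/4, 1/4)$; any analysis that
depends materially on $\bar f$ should set it from panel-wide frequencies.
Since every appearance of $\gamma$ is through $\gamma \bar f_i$, the LR is
insensitive to this choice for small $\gamma$ (a property the test suite
checks by analysing the same cases at $\gamma = 10^{-3}$ and $10^{-5}$).

A caveat worth stating: for a zero-frequency allele seen in both of two
samples, the unrelated-vs-half-sib LR is governed by the *third and fourth*
sequential draw probabilities of that allele, so it is of the order of, but
not equal to, the second-draw probability $\theta + (1-\theta)\gamma\bar f_i$;
the acceptance tests pin the exact closed form and check the order of
magnitude against that simpler expression.

## Inheritance model and IBD codes

A pedigree with $K$ retained parent-child meioses has $2^K$ *inheritance
patterns* $r \in \{0,1\}^K$: bit $j$ records whether the child of meiosis
$j$ received its parent's maternal (0) or paternal (1) allele. Each pattern
partitions the $2T$ allele slots of the $T$ typed persons into sets that
are identical by descent; `ibd_code()` canonicalizes that partition into an
integer labelling (first-occurrence ordering across persons, ties broken by
first slot index, within-person pairs sorted), and `ibd_distribution()`
tallies the exact distribution of codes under uniform patterns, with exact
dyadic probabilities.

Meioses that cannot influence IBD among typed persons are pruned before any
enumeration: a meiosis is dropped when its parent is an untyped founder
with exactly one child, since whichever allele such a parent transmits is
unique to that child's lineage. This pruning reproduces the natural $K$
for the classic example pedigrees (half siblings 2, uncle–nephew 5, two
uncles 7, incestuous half-sib mating 6, second cousins 8). Patterns for
pruned meioses are resolved with a fixed bit; the test suite proves the
result independent of that choice.

Across loci, each meiosis bit follows a two-state Markov chain: between
adjacent loci the bit flips with the recombination fraction $p_i$, obtained
from genetic map distances via the Haldane map
$p = (1 - e^{-2d_\mathrm{Morgan}})/2$ (the map function consistent with a
Poisson crossover model), with $p = 1/2$ across chromosome boundaries.
Bits are independent across meioses, so the pattern transition probability
is $p_i^{\,\delta}(1-p_i)^{K-\delta}$ with $\delta$ the Hamming distance.

## Symmetry compression of the forward pass

The plain forward (Lander-Green) recursion carries a probability per
pattern — $2^K$ states and a $2^K \times 2^K$ transition matrix. But any
permutation $g$ of the hypercube that preserves both the IBD-code map
($h \circ g = h$) and Hamming distances maps the forward vector onto
itself, so all patterns in one orbit of the group of such isometries carry
equal probability at every locus. kinlink finds this group by searching the
hyperoctahedral group — every Hamming isometry of the $K$-cube is a
coordinate permutation composed with coordinate flips, a classical fact —
with a backtracking search that assigns the permutation one coordinate at a
time and prunes on multiset agreement of IBD codes between source and
image slices of the cube. Each surviving candidate is, by construction of
the final level of the search, verified on all $2^K$ patterns; orbits come
from union-find over all verified isometries, so they are the orbits of
the full group, not of a partial generating set (the suite cross-checks
this against brute-force enumeration of the whole group for the small
pedigrees).

With $J$ orbits and representatives $v_{j}$, the compressed transition
matrix has entries that are integer-coefficient polynomials in $p$:

$$ M^*_{jk}(p) = \sum_{r=0}^{K} A_{jkr}\, p^r (1-p)^{K-r}, $$

where $A_{jkr}$ counts members of class $k$ at Hamming distance $r$ from
the representative of class $j$ (`transition_coefficients()`). $M^*$ is
row-stochastic, the identity at $p = 0$, and has constant columns
$n_k/2^K$ at $p = 1/2$. For second cousins this reduces 256 states to
$J = 21$; preprocessing takes well under a second here. The forward state
is initialized at $1/2^K$ per representative, multiplied termwise by
per-locus code likelihoods, propagated by $M^*$, rescaled by its maximum
every locus (accumulating log10), and finally summed with class-size
weights $n_j$ — the size weighting restores the sum over all patterns from
the per-representative values.

Per locus, the code likelihood marginalizes the founder lineages: for a
code with $F$ distinct labels it sums, over the $4^F$ nucleotide
assignments, the exchangeable founder-model probability times each typed
person's observation likelihood for the induced genotype. Untyped founders
are never enumerated; only the $F \le 2T$ lineages visible in the code
matter. Codes shared by several classes are computed once; the engine is
vectorized across loci.

## Comparison methods

Two deliberately amended variants of the likelihood are built in, because
their degradation is exactly what motivates the full method:

* **unlinked** — per-locus code-probability-weighted likelihoods multiplied
  across loci (equivalently, the forward pass with all $p_i = 1/2$; the
  suite verifies this identity to $10^{-10}$);
* **called** — each person-locus observation replaced by its MAP genotype
  (Hardy-Weinberg prior from the $\gamma$-smoothed frequencies, no $\theta$
  adjustment, times the read likelihood; ties broken lexicographically),
  then the full linked pass with certainty in the called genotype. Loci
  with zero reads stay uninformative instead of asserting the prior mode.

The calling prior deliberately omits the $\theta$ adjustment: $\theta$
couples alleles *between* founders, while calling is a single-individual
operation; using the smoothed frequencies alone is the cleanest reading of
"prior from allele frequencies", and no result here is sensitive to it.

## The simulator

`simulate_case()` generates data exactly through the three model layers:
founder alleles per locus from the sequential population model
($\theta = 0.01$, $\gamma = 0.001$ by default), gene dropping with
per-meiosis Markov bit chains along each chromosome (all meioses, including
pruned ones, transmit), depths per person-locus from a discretized Gamma
(shape $\mu^2/\sigma^2$, scale $\sigma^2/\mu$, rounded to nearest integer,
floor 0 — zero-depth loci remain in the panel as uninformative), and reads
from the observational model ($m = 10$, $e = 0.02$).

`synth_marker_panel()` supplies the panel: positions uniform over 22
autosomes with genetic lengths matching a standard ~35 Morgan map, and
biallelic SNPs whose minor-allele frequency is uniform on $(0.3, 0.5)$,
emulating forensic kinship panels (which select high-MAF SNPs; the
reference panel scale is 3929 markers). The unrelated hypothesis is
simulated as typed founders with the same $\theta$-coupled founder draws at
each locus.

What the simulator does *not* emulate — so what green tests do and do not
mean for real data: linkage disequilibrium between panel SNPs (the
population model draws loci independently), mutation, contamination,
base-quality variation, reference-bias in mapping, and real population
frequency misspecification. Because analysis and simulation share the same
model, comparative statements (full vs. amended methods) transfer to real
data more readily than absolute error rates do.

`run_study()` wraps the comparison experiment: $n$ cases per hypothesis,
log10 LRs per method, with `roc_points()`, `roc_auc()`,
`classification_rates()` and `autoplot()` for summaries. The test suite
runs it at desk scale — 100 + 100 cases on 500-marker panels, three seeds,
at mean depths 10 and 3 — and asserts the orderings on means across seeds:
the full method outperforms the unlinked variant, is at least as good as
calling, and calling loses more at depth 3 than at depth 10. At this scale
those AUC gaps are real but small (the panels are ~7 cM sparse, so
linkage carries less information than on a dense panel); per-seed sign
assertions would test Monte-Carlo noise rather than the method, hence the
averaging.

## Numerical and design choices

* Probabilities of IBD codes are dyadic rationals with denominator $2^K$,
  computed by exact counting — no floating-point accumulation.
* The forward pass rescales by the maximum of the state vector at every
  locus and accumulates log10; a 10,000-locus panel runs without underflow
  and equals the sum of chromosome-wise runs exactly.
* Impossible data (a state vector annihilated at some locus) yields
  `-Inf` with an `impossible` attribute rather than an error.
* Read likelihoods include the multinomial coefficient, so per-locus values
  are genuine probabilities (and sum to one over count vectors of fixed
  total); external genotype likelihoods (VCF PL fields, Phred-scaled,
  renormalized to maximum 1) can replace them, in which case results match
  the read-count route up to the per-locus constants, leaving LRs
  identical.
* Enumeration guards: IBD distributions up to $K \le 16$; the isometry
  search defaults to $K \le 12$. Both bounds are explicit errors, not
  silent truncation.
* Pedigree files may omit one parent; a fresh untyped founder is inserted
  per missing slot (children sharing only one named parent are therefore
  half siblings unless the spouse is named).
* Class representatives are lexicographic minima and classes are ordered by
  representative; published tables for the same pedigrees may list another
  ordering of the same classes, so table comparisons in the tests match up
  to relabelling within equal IBD codes.

## Limitations

Linkage disequilibrium is deliberately out of scope (treat tightly linked
panels with LD pruning before analysis). Mutation models and STR markers
are not supported. The isometry search and pattern enumeration are
exponential in $K$ and intended for the pedigree sizes typical of kinship
casework; the engine is single-threaded.
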
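---
title: "Phasing heterozygous variants from linked reads: models and design"
author: "matephase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing heterozygous variants from linked reads: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matephase)
```

## The problem

When a patient carries two heterozygous mutations in the same recessive
gene, the clinical interpretation hinges on their *phase*: in *trans* (one
mutation on each chromosome copy) both alleles are disabled and the
patient is affected; in *cis* (both on one copy) the other allele is
intact. Sanger sequencing cannot distinguish the two, and family
segregation studies are slow and sometimes uninformative.

Paired sequencing reads offer a direct route: the two reads of one
sequenced fragment come from one physical DNA molecule, so any variant
bases they report are in cis with each other. Short paired-end (PE)
fragments (~100–600 bp) link nearby positions; mate-pair (MP) libraries
(fragments of 500–5,000 bp, circularized so that the junction is
sequenced) link positions kilobases apart. `matephase` implements the
statistical machinery that turns such linked observations into quantified
phase calls: association matrices, a row-wise multinomial bootstrap, and a
Markov-chain extension across a whole amplicon.

## The association matrix and the bootstrap

For an ordered pair of heterozygous SNV positions $(h_i, h_j)$, every
fragment whose reads cover both positions contributes one ordered pair of
base calls. These are tallied into a $4\times 4$ count matrix $A$ over the
fixed base order A, C, G, T, rows indexed by the call at the upstream
site. In a clean diploid only two cells carry mass — the two haplotypes —
and the remaining cells are exactly what the error analysis measures, so
the full $4\times4$ table is kept rather than a $2\times2$ collapse.

Each row of the matrix is converted to a probability distribution over the
downstream base. With row counts $c_b$, row total $n$, and an injected
error mass $\varepsilon$ (default 0.01):

$$p_b = (1-\varepsilon)\,\frac{c_b}{n} + \frac{\varepsilon}{4}.$$

The $\varepsilon$ term keeps zero-count bases at a small positive
probability, modelling the background rate of random base-call error in
short-read data; the observed mass is scaled by $1-\varepsilon$ so the row
still sums to one. The split of $\varepsilon$ across the four bases is
uniform and deterministic — the minimal reading of "distributing" one
percent across a row — rather than re-randomized per resample.

Uncertainty is quantified by a multinomial bootstrap: each of
`n_iter = 1000` iterations draws $\mathrm{Multinomial}(n, p)$ counts with
the total fixed at the observed row total and converts them back to
proportions. The reported interval per base is the 1st and 99th
*nearest-rank* percentile of the 1000 proportion draws. Following the
source method's convention this band is labelled a "99% CI" even though
the nominal coverage of a 1st–99th percentile band is 98%; we implement
the literal percentile rule and document the discrepancy rather than
silently correcting it.

```{r bootstrap-example}
bs <- bootstrap_row(c(930, 0, 70, 0), error_mass = 0.01, seed = 1)
bs
```

## Pairwise calls and chained phasing

For one pair of sites, the rows corresponding to the upstream ref and alt
alleles are bootstrapped, and each row selects its highest-probability
downstream base (ties broken toward the lower base in A < C < G < T order
and additionally flagged ambiguous). Ref-with-ref plus alt-with-alt is
*cis*; ref-with-alt plus alt-with-ref is *trans*. A call is only reported
as confident when, in both rows, the selected base's CI lower bound clears
the CI upper bound of every rejected base.

When the two variants of interest lie farther apart than any fragment
spans, matrices over intermediate heterozygous sites are chained:
$A_1 = (h_0, h_1), A_2 = (h_1, h_2), \ldots$ Starting from one allele at
$h_0$ (by default the REF base; the rule is configurable), the selected
base at each junction becomes the conditioning row of the next matrix — a
Markov chain, since each matrix is built from a physically distinct set of
fragments. The second haplotype is phased by starting from the other base
at $h_0$, and the two chains are cross-checked for complementarity at
every site.

Confidence over distance is tracked by the cumulative probability
$P_k = \prod_{j \le k} p_{(j)}$ (the exact product of the selected step
probabilities) and a cumulative interval, computed by multiplying the
bootstrap draws of the selected bases across steps, iteration by
iteration, and taking the same 1st/99th percentiles. Because the steps'
fragment sets are independent, iterations are paired by index without
sorting; quantile-matched pairing would fabricate dependence that the
experiment does not have. A step's verdict is *confident* while the
cumulative lower bound stays above the CI upper bound of every rejected
base at that step; the first overlap marks the distance limit of the
chain, and later steps are reported but flagged as downstream of the
ambiguity.

### Phase sets

For the phased VCF (pipe genotypes with a `PS` tag), sites are grouped
into phase sets. A set breaks where the chain breaks (a zero-coverage
row) and at any junction whose *pairwise* step interval overlaps a
rejected base: relative phase across that junction is unsupported, so the
downstream site re-anchors a new set with a fresh cumulative product. The
chain report's verdict column, in contrast, stays anchored at the segment
start — the cumulative rule above — so a long chain can lose chain-wide
confidence while its individual junctions, and hence the re-anchored
phase sets, remain clean. Sets with fewer than two phased sites are
reported unphased, since phase is a relation between sites.

Junctions whose association matrix has fewer than `min_total = 20` linked
fragments are not used directly: the chain attempts to bridge to the next
site that restores coverage, and bridged-over sites are phased as side
branches from their upstream anchor (conditioning always runs downstream,
matching the row orientation of the matrices). The bridge threshold of 20
is a pragmatic floor below which a 1000-iteration bootstrap interval on a
row is too coarse to exclude rejected bases.

## The simulator

Because the method's accuracy claims are statistical, the package ships a
synthetic diploid amplicon generator so that every claim is testable
without external data. It emulates:

* a random background sequence of `region_length` (default 10 kb) with
  `n_sites` heterozygous SNVs, each allele assigned to haplotype 1 or 2
  (the truth phase);
* a fragment library mixing PE fragments (uniform on 100–600 bp) and MP
  fragments (log-normal truncated to 500–5,000 bp with mean 2,000 bp;
  `sdlog` fixed at 0.6 so the sizes span the support broadly, and the
  `meanlog` solved numerically for the truncated mean — the size law is
  switchable to uniform for analytic tests). The PE proportion defaults
  to 0.30: MP protocols co-purify a PE subpopulation but published
  accounts do not quantify it, so we chose a value that gives both
  library types visible weight in the linked-coverage profile;
* 101-bp reads from both fragment ends (reads are truncated when a
  fragment is shorter than a read, which also resolves the degenerate
  100-bp-fragment corner of the default PE range);
* fragment-level chimeras at rate 0.07: with that probability the
  template switches to the other haplotype at a uniformly placed internal
  breakpoint. This models recombination during long-range PCR, the
  dominant error source in amplicon MP libraries (observed at roughly
  5–7% of linked reads across input masses in the source experiments);
  the positional law is the least-informative choice since no positional
  information is published;
* random base-call error at rate 0.02 per het-site call per fragment (one
  call per fragment even where mates overlap). The knob is per-call
  rather than per sequenced base because that is how the error is
  measured downstream — as the fraction of linked observations that match
  neither allele.

Each randomness source (sizes, starts, haplotype choice, chimeras,
errors) draws from its own stream derived from the single user seed, so
one component can be varied while the others replay identically. Output
is a coordinate-sorted SAM (constant Q37 qualities; quality modelling is
out of scope), a truth VCF, and truth tables recording per-fragment
provenance, which power exact oracle tests (e.g. off-haplotype matrix
mass must equal the count of chimeric fragments whose breakpoint falls
between the sites).

### What `coverage` means

The simulator's `coverage` parameter is the target mean *linked* coverage
between adjacent heterozygous sites — the expected association-matrix
total, which is the depth scale on which phasing confidence actually
operates and the quantity plotted against CI width in coverage
simulations. It is not raw per-base read depth: for sites 2 kb apart
under this size mixture, only ~3–5 fragments in 10,000 link a given pair,
so a linked coverage of 500× corresponds to a raw sequence coverage in
the tens of thousands, consistent with the deep amplicon sequencing the
method is designed for. The fragment count needed to hit the target is
calibrated by a seeded pilot draw of 200,000 fragment placements, so the
realized linked coverage is accurate to a few percent.

### What the simulator does not model

No indels or structural variants, no per-cycle quality decay, no
duplicate fragments, no background (off-amplicon) reads, no
mapping ambiguity from pseudogenes or homologs. Passing tests therefore
demonstrate the statistical machinery under the stated error model; on
real data, alignment artefacts in homologous regions (the classic failure
mode for genes with pseudogenes) must be handled upstream by the mapper,
and copy-number changes violate the two-allele assumption outright.

## Numerical and degenerate-input choices

* Tolerances: the cumulative product identity is exact to 1e-12; row
  probabilities sum to 1 within 1e-12.
* Zero-coverage rows are a signal, not an error: a pairwise call becomes
  `unphaseable`, a chain records a break and restarts a fresh phase set
  at the next site (maximizing usable output, matching `PS` semantics).
* Argmax ties select the lower base in the fixed order and flag the step
  ambiguous.
* Intra-fragment disagreement between mates at one site drops that site's
  call for the fragment — conservative, since choosing a majority would
  manufacture certainty from a contradiction.
* Base calls are restricted to A, C, G, T; N or a deletion gap at a het
  site yields no observation (the matrix is 4×4 by construction).
* Linked-coverage profiles average the per-position link counts over the
  full region length, so profile × region length is a conserved integer
  incidence count; the default offset grid (101–3000 bp) starts above the
  read length and thus excludes intra-read pairs, but any grid is
  accepted.

## Problem sizes used in the shipped checks

The package's own verification uses scaled synthetic studies chosen to
exercise every claim: pairwise recovery over 200 replicate libraries (two
sites 2 kb apart in trans, linked coverage 500×, chimera rate 0.07, call
error 0.02), one 12-site 10-kb chained run at 1000×, exact enumeration
oracles for bootstrap rows of total ≤ 6, and brute-force positional
counting for the coverage profile on a 2-kb, 100-fragment instance. At
these sizes the full suite completes in minutes on one core while leaving
the stochastic assertions far from their pass thresholds (e.g. pairwise
trans recovery is 200/200 where ≥198 is required).

## Known limitations

* The CI-width-versus-coverage curve scales as $N^{-1/2}$ without a
  floor: the deterministic $\varepsilon$ adjustment shifts probabilities
  but adds no resampling variance, so the absolute width keeps halving
  per quadrupled coverage. "Diminishing returns" beyond 500× is real in
  absolute terms (the drop from 500× to 2000× is a sixth of the drop from
  50× to 500×) but the width itself does not plateau.
* The percentile rule (1st/99th of ranked draws) under-covers slightly at
  tiny row totals, where the proportion distribution is coarse; the
  enumeration oracle in the test suite quantifies the discreteness.
* Chaining is strictly sequential, as specified; no joint likelihood
  (HapCUT-style MEC) assembly is attempted, and no population reference
  panel is used.
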
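---
title: "Methods: simulating and measuring depth bias in intraspecies diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring depth bias in intraspecies diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdepth)
```

## The problem

Nucleotide diversity (π) and the average nucleotide identity of recruited
reads (ANIr) are the workhorse metrics for intraspecies ("micro") diversity
in metagenomics. Both are computed from reads recruited to a species
reference at ≥ 95 % identity, and both depend on sequencing depth: at low
depth, allele sampling is stochastic and rare single-nucleotide variants are
missed entirely, so π is typically underestimated — a bias that does not
vanish at the 10X threshold commonly used as a quality bar. `microdepth`
provides a controlled laboratory for this phenomenon: synthetic strain
mixtures in which the true diversity, the error load and the depth are all
known exactly, plus the profiling and rarefaction machinery to measure how
estimates degrade as reads are withheld.

## The simulation model

**Community.** An ancestor genome of length $L$ is drawn i.i.d. with a
target GC content. Strain $k$ differs from the ancestor by
$\mathrm{round}(d_k L)$ point substitutions at uniformly sampled distinct
positions, $d_k \sim U(d_{\min}, d_{\max})$; strain 1 is the ancestor
itself. The default divergence range $(0, 0.0249)$ keeps every strain within
~97.5–100 % ANI of the ancestor and every *pair* within ~95–100 % ANI — the
span of a metagenomic species under the 95 %-identity recruitment
convention, and the range observed for curated conspecific isolate
collections. Divergence beyond 5 % is rejected outright because such strains
would fall outside the recruitment regime being studied. Pairwise ANI is
computed exactly from the edit lists (substitutions are the only variation;
gene content differences and rearrangements are out of scope in this
version). Relative abundances follow a log-normal law,
$w \propto \exp(\mathcal{N}(0, \sigma^2))$ with $\sigma = 1$ by default: the
shape parameter of the original mixtures is not published, and $\sigma = 1$
gives the familiar few-dominant/long-tail rank-abundance structure of real
communities.

**Reads.** Each read picks its strain from $w$, its start uniformly and its
strand uniformly. Errors are applied per base: every base independently
suffers at most one event — insertion, deletion or mismatch — drawn from a
single categorical distribution. The five-tuple
$(p_{ins}, p_{del}, p_{mm}, p_{mm}^{start}, p_{mm}^{end})$ defines a
profile; within the first/last 10 bp (configurable) the mismatch probability
is elevated by the start/end terms, emulating the degraded base quality at
read ends. The presets are error-free $(0,0,0,0,0)$, Q20
$(0.001, 0.001, 0.006, 0.001, 0.001)$ and Q30
$(0.0001, 0.0001, 0.0006, 0.0001, 0.0001)$.

A deliberate modelling decision: the probabilities are interpreted **per
base**, not per read. Only the per-base reading is consistent with the
regime the presets are meant to produce — mean read identity
$\approx 1 - (p_{ins}+p_{del}+p_{mm})$, i.e. ANIr ≈ 99.2 % at Q20 and
≈ 99.9 % at Q30, matching the "one error per 1,000 / 10,000 bp" meaning of
the quality labels. A per-read interpretation would give ANIr ≈ 99.99 % at
Q20 and make the three profiles nearly indistinguishable.

Event drawing is vectorized without approximation: for each read segment
(start window, middle, end window) the number of affected (read, base) pairs
is Binomial(#pairs, $p_{tot}$) and the pairs are sampled without
replacement, which is algebraically identical to independent per-base
categorical draws.

**Ground truth.** Every read records its edits, its identity to the source
strain and its identity to the ancestor, with identity defined over aligned
columns: $\mathrm{id} = m / (m + mm + i + d)$, each inserted or deleted base
counting as one column (the NM-tag convention of common recruiters). The
truth SAM expresses reads against ancestor coordinates, composing strain
substitutions and error edits into CIGAR and NM, so the simulator's output
can be consumed by any downstream profiler without a mapper. Truth
alignments span the full read template; the rare deletion at a template edge
is emitted as a leading/trailing `D` operation, which htslib accepts and
which keeps the column algebra identical in every code path. Read length
defaults to 150 bp (the common short-read configuration); long-read
emulation is supported by shredding into 200 bp fragments with
`shred_reads()`. FASTQ qualities are a constant placeholder (`I`) — the
profiler is deliberately quality-blind.

## Profiling

Recruitment keeps reads with identity ≥ 0.95 (boundary inclusive), drops
reads whose mate maps to a different reference (vacuous for unpaired data),
and retains one best alignment per read (highest identity; ties to the
leftmost start, then lexicographic reference). Pileups count match/mismatch
columns only: insertions contribute nothing and deletions leave gaps rather
than being consensus-filled, since π is defined over observed nucleotide
frequencies.

Genome-wide π averages per-site π over positions with depth ≥ `min_cov`
(default 5); when no site qualifies the value is `NA`, never a silent 0. The
plugin estimator is used **without** the $n/(n-1)$ correction: at a site
with true heterozygosity $\pi$ sampled to depth $n$,
$E[\hat\pi] = \frac{n-1}{n}\pi$, and this bias — verified in the test suite
by Monte-Carlo at $n \in \{5, 10, 50, 200\}$ — is the mechanism behind the
residual underestimation of diversity even above 10X. ANIr is the
read-weighted mean identity (each read one vote); a base-weighted variant is
available via `profile_params(anir_weight = "bases")`. Mean depth divides
total counted bases by the full reference length (zeros included); breadth
is the percentage of positions with depth ≥ 1 and follows the
Lander–Waterman expectation $100(1 - e^{-c})$ under uniform placement.

For simulated input the pileup is assembled by sparse accounting (aggregate
coverage per strain plus per-event corrections) instead of expanding every
read; the test suite proves this equal, column for column, to the generic
CIGAR-walking pileup and to a pure-loop oracle.

## Rarefaction

Subsampling is exact by default — exactly $\lfloor fN \rfloor$ reads without
replacement, mirroring classic FASTA subsampling semantics — with Bernoulli
thinning as an option; pairs travel together. `rarefy_to_depth()` converts a
target depth into a fraction against the current mean depth and refuses
infeasible targets. The full-dataset profile is computed once and serves as
the fixed denominator for every replicate. The diversity ratio is
subsample/full (undefined, and excluded from summaries, when the full value
is 0, as for clonal error-free π); the average absolute error is the
*relative* error $100\,|x_{sub} - x_{full}|/x_{full}$ for both π and ANIr
(the alternative percentage-point reading for ANIr would differ only by a
factor ≈ ANIr/100 ≈ 1 here). Error summaries are binned at
{<10X, 10–50X, 50–200X, >200X}, the categories used when comparing observed
diversity across unevenly sequenced samples.

## The factorial design

`run_insilico_design()` crosses strain counts with error profiles; each cell
derives a strain set from a shared ancestor, simulates, profiles in full and
rarefies along the fraction grid (1 %–90 % by default). Child seeds are
derived from the master seed by hashing the cell labels, so the design is
reproducible end to end and any cell can be recomputed in isolation. The
default configuration — 200 kb ancestor, strain counts {1, 5, 20, 100},
three profiles, 400,000 reads (~300X) per metagenome, 3 replicates — is a
deliberately scaled-down instance chosen to run in minutes on one core;
the original-scale design (12 strain counts, 50M reads) is a parameter
change, not a code change. Test and acceptance workloads use genomes of
10–200 kb and 10⁴–7×10⁵ reads for the same reason; sizes enter only through
sampling-noise terms, so conclusions transfer across scale.

## What the simulation does and does not emulate

It emulates: strain mixtures with realistic ANI structure and abundance
skew, per-base error loads with degraded read ends, uniform read placement,
and ground-truth recruitment. It does **not** emulate gene-content
variation between strains (real conspecific isolates share only ~80 % of
genes), genomic rearrangements, GC- or motif-dependent coverage bias,
chimeras, or mapping ambiguity — truth alignments are exact, so conclusions
about mapper behaviour cannot be drawn. Passing tests therefore demonstrate
the depth-dependence of the estimators under ideal recruitment, which is
the intended object of study, not a claim that real recruitments are
unbiased in other respects.

## Numerical choices and degenerate inputs

* Identity filtering is inclusive at the boundary (≥ 0.95), and filtering is
  idempotent.
* Best-match ties break deterministically (leftmost start, then reference
  id) so outputs are byte-stable.
* A zero-depth column has no defined π (error), and a genome with no
  qualifying site yields `NA`, excluded from ratios and error summaries
  with an exclusion count.
* Seeds are 31-bit; all derived seeds stay below $2^{31}$.
* `rbinom` draws are chunked when a segment holds more than $2^{31}$
  read-base pairs, so original-scale (tens of millions of reads)
  configurations remain exact.

## Known limitations

Substitution-only strains slightly understate true π for a given ANI
because indel and gene-content variation are absent. ANIr here is measured
against the known ancestor; with a consensus (MAG) reference, reference
error adds a small constant offset that rarefaction analyses cancel but
absolute comparisons do not. The per-read error interpretation of the
five-tuple is not implemented, for the consistency reasons given above.
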
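---
title: "Ordering long reads by phase-signal correlation: model, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordering long reads by phase-signal correlation: model, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaseasm)
```

## The problem and the model

`phaseasm` addresses the *layout* stage of overlap-layout-consensus
assembly for long, single-end, forward-strand reads: given N reads with a
low error rate (at most about 1.5%) drawn from a repeat-free source, decide
which reads genuinely overlap and in what order they lie on the source. The
consensus stage — computing exact offsets and a base-level sequence — is
deliberately not part of the package; its output is an ordered set of
contigs, each an ordered list of reads asserted to overlap pairwise along
the chain.

The method rests on three ideas.

**1. Cumulated-phase encoding.** Each base maps to a complex number
(A: $1+j$, C: $-1-j$, G: $-1+j$, T: $1-j$); the complex argument of each
mapped base (an odd multiple of $\pi/4$) is accumulated along the read, so a
read becomes a real-valued signal with one value per base. The key property
is translation: if two reads share a substring, their signal windows over
that substring differ only by an additive constant (the accumulated phase up
to the window start).

**2. Maximum sliding-window Pearson correlation.** For a pair of reads the
signals are slid against each other and the Pearson coefficient
$\rho_{X,Y} = \mathrm{cov}(X,Y) / (\sigma_X \sigma_Y)$ is evaluated on the
overlapping windows at every shift; the maximum over shifts scores the pair.
Pearson correlation is invariant to additive constants, so error-free
overlapping reads score exactly 1 at the true shift, and errors degrade the
score smoothly. Whether each window is centred by its own mean is
analytically moot — Pearson centres both windows by construction — so the
implementation centres each full signal once, purely for numerical
conditioning.

**3. Read ordering as a TSP.** Correlations become costs
($(1-\rho)\times 1000$, then integer min–max scaling to $[0, 1000]$), and an
artificial vertex 0 with zero cost to every read removes the arbitrary
choice of a start: the minimum-cost Hamiltonian cycle through all reads and
vertex 0, with the artificial vertex cut out, is the read ordering. Because
a near-optimal tour may still join reads that do not overlap, the path is
finally cut wherever the edge cost exceeds a coverage-informed threshold.

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `min_overlap` | 100 bases | Smallest window a shift may score on. Tiny windows produce spurious $\rho \approx 1$; 100 bases keeps the false-positive rate negligible while detecting all genuine overlaps of the target datasets (whose weakest true overlap is several hundred bases). |
| `stride` | 1 | Shift sub-sampling with local refinement. The FFT path makes exhaustive shifts cheap, so the default is exhaustive. |
| `scale_max` | 1000 | Upper end of the integer cost range after min–max scaling. The solvers operate on integers; the reference tooling's range is not stated, so the $\times 1000$ step's natural scale is kept. |
| `A1`, `A2` | 1, $10^7$ | QUBO objective and constraint weights, as used by the reference annealer tool. With costs at most 1000 and $A_2/A_1 = 10^7$, no infeasible assignment can undercut a feasible one (verified exhaustively in the tests). |
| `max_cluster` | 7 | Largest sub-problem the QUBO route solves directly: a fully connected embedding on the targeted annealer generation caps at about 60 variables, and $8^2 = 64$ already exceeds it. |
| `n_sweeps`, `n_restarts` | 1000, 10 | Annealing schedule per sub-solve (geometric cooling from the largest coefficient magnitude down to 0.01). Calibrated once so the sampler recovers the exhaustive ground state on $N \le 4$ instances at least 99 times in 100 (a stated calibration target, verified in the acceptance tests). |
| contig threshold | coverage-derived | See below. |

## The synthetic-data generator

The generator emulates the reference experimental protocol: a random
circular source (i.i.d. uniform bases — which is what makes the repeat-free
assumption hold), 50 reads of 3000 bp with evenly spaced starts, and
per-read point mutations (insertion, deletion, substitution, duplication at
equal weights) at 0–1.5% of the pre-mutation length, with
`round(error_pct/100 * length)` events per read. Start positions are evenly
spaced rather than uniform-random because the emulated protocol specifies a
single consecutive-overlap value per dataset; the source length is derived
from the coverage identity `n_reads * read_len / coverage`.

Two deliberate simplifications relative to real long-read data: no
length/error-rate heterogeneity across reads (real simulators draw read
lengths from a distribution), and no reverse-complement or chimeric reads.
A green test on this generator therefore establishes that the pipeline
recovers *evenly tiled, forward-strand, repeat-free* layouts — not that it
handles the full messiness of a sequencing run.

The published overlap values {2700, 2500, 2300} for 50 reads of 3000 bp are
arithmetically inconsistent with exact circular tiling at the published
source lengths {30000, 15000, 10000}; the generator treats coverage and
source length as binding and the consecutive overlap as derived
(2400/2700/2800 for coverages 5/10/15), warning when a requested layout
cannot close the circle exactly.

## Numerical and algorithmic choices

* **Sliding correlation.** All shifts are evaluated at once from one FFT
  cross-product plus prefix sums of each signal and its square —
  $O(L \log L)$ per pair versus $O(L^2)$ naive — with per-read FFTs cached
  across the $\binom{N}{2}$ pairs. The naive per-shift evaluation is kept in
  the package as an independent oracle and the two are required to agree to
  $10^{-6}$. Signals store the accumulated quarter-turns as integers and
  scale by $\pi/4$ once, so signal values carry one rounding each regardless
  of read length. A zero-variance window (homopolymer stretch) is assigned
  $\rho = 0$: no evidence of a relation, and no division by zero.
* **Tie-breaks.** Among equally good shifts the smallest absolute shift
  (positive preferred) wins; nearest-neighbour construction breaks cost ties
  by lowest vertex index. Both make the classical path fully deterministic.
* **Classical solver.** Nearest neighbour from the artificial vertex,
  polished by alternating first-improvement 2-opt and Or-opt (segment
  relocation, lengths 1–3). Pure 2-opt alone left too many small instances
  above the brute-force optimum; adding Or-opt reaches the optimum on at
  least 95 of 100 random instances with $N \le 7$ and never exceeds it by
  more than 10% (tested against exhaustive enumeration).
* **QUBO construction.** Variables $x_{i,n}$ ("vertex $i$ visited $n$-th"),
  $N^2$ in total; depot edges enter as linear terms on positions 1 and $N$,
  consecutive-position products carry the edge costs, and the one-hot
  penalty $(1-\sum x)^2$ — the canonical choice that vanishes exactly on
  permutation matrices — is applied per vertex row and per position column.
  Feasible energies equal `A1 *` tour cost *exactly* (integer arithmetic in
  doubles), which the tests assert with `==`.
* **Annealer surrogate.** Single-bit-flip Metropolis with geometric cooling,
  run on the CPU in place of a QPU. The sampler returns the best state *ever
  visited*, not the final frozen state: with $A_2 = 10^7$ the feasible
  basins are separated by penalty barriers that single flips cannot cross at
  low temperature, so the chain's late phase cannot re-order tours by cost —
  but while warm it visits many feasible basins, and the running minimum
  over the trajectory recovers the ground state reliably.
* **Decomposition hybrid.** Vertices are partitioned by DBSCAN on the cost
  matrix (costs as distances, eps swept over distance percentiles,
  oversized clusters split recursively). When no eps separates the instance
  — typical for error-free data, where zero-cost edges chain every read
  into one density-connected component — the fallback cuts a cheap
  nearest-neighbour traversal into consecutive chunks of `max_cluster`.
  Cluster sub-tours are solved through the QUBO route with the artificial
  vertex as free endpoints and concatenated greedily at their cheapest
  junctions; the merge rule is this package's construction, as the
  reference tool does not document its own. The construction is then
  iterated (re-cutting the incumbent tour at every chunk offset and
  re-solving) until one full iteration brings no improvement, mirroring the
  reference tool's convergence setting; five independent experiments are
  run and the best tour reported, mirroring its experimental protocol.
  Infeasible best samples are repaired greedily (unused vertices into free
  positions, cheapest-from-predecessor) rather than discarded, so the
  pipeline always yields a valid permutation; repairs are counted on the
  solution object.
* **Contig threshold.** The stated rule — a read should coincide with
  $COV - 1$ other reads — is operationalised per read as an order statistic
  of its off-diagonal costs, with the threshold the median of these across
  reads (a global threshold; a per-edge-local rule would be an alternative,
  flagged here). On a circular evenly tiled layout a read genuinely
  overlaps $COV - 1$ neighbours *in each direction*, so the order statistic
  used is $2(COV-1)$; the published $COV - 1$ figure undercounts by the
  factor two and, taken literally, cuts genuine overlaps at 0.5% error
  (measured during development). A safety multiplier (default 1.0) and an
  explicit threshold override are exposed.
* **Evaluation.** An evaluated edge is correct when its two reads' true
  intervals intersect on the source. For a circular truth the closing edge
  between the chain's two ends is evaluated too (the artificial vertex
  between them carries no sequence), so a perfect circular layout of N
  reads scores N correct overlaps out of N — accuracy 1.00 — and 45
  retained true overlaps out of 50 score 0.90, consistent with the
  reference tables' printed rows. Accuracy counts edges that are both
  *retained by the threshold* and true; "incorrect overlaps" are retained
  edges that are not true (false positives); "real" breaks are path edges
  that are not true regardless of retention; "calculated" breaks are the
  threshold cuts along the linear path.

## Degenerate inputs

Empty paths split into zero contigs; a single read forms one contig and a
zero-cost tour (both cycle edges touch the artificial vertex). A constant
correlation matrix min–max-scales to all-zero costs with a warning. A
coverage below 2 cannot drive the threshold rule and demands an explicit
threshold. Reads containing non-ACGT symbols are rejected by name, with an
opt-in seeded mapping of IUPAC ambiguity codes to concrete bases.

## Known limitations

* No reverse-complement or paired-end handling: overlaps are detected on
  the forward strand only.
* Repeats defeat the method by design (a repeat longer than `min_overlap`
  produces spurious high correlations); the generator's uniform sources
  cannot exercise this failure mode.
* The correlation stage is the $O(N^2 L \log L)$ bottleneck; no
  parallelisation is attempted.
* The stochastic solver's quality rests on best-of-k selection across
  restarts and experiments, not on the annealer equilibrating the cost
  scale (see the barrier argument above); on instances whose zero-cost
  structure the greedy merge cannot exploit, it can return tours costlier
  than the classical heuristic's.
* Real-genome inputs are supported only as external FASTA (plus optional
  truth files); no read simulator for heterogeneous lengths is included.

## A worked run

```{r example, eval = FALSE}
cfg <- pipeline_config(coverage = 10, error_pct = 0.5, solver = "classic",
                       seed = 101)
res <- run_pipeline(cfg, out_dir = "run_cov10_err05")
res$report
```

Every number this vignette relies on — the perfect error-free recovery, the
oracle agreements, the solver quality rates, the monotone degradation with
error rate — is computed by the package's test suite
(`tests/testthat/test-acceptance.R`) or by `scripts/acceptance.R`; nothing
is asserted here that those runs do not measure.
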
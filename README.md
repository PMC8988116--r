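# phaseasm

Overlap detection and read ordering for de novo assembly of long DNA reads,
using genomic signal processing and a travelling-salesman formulation — with
both a classical heuristic and a QUBO / simulated-annealing solver of the
kind used on quantum annealers.

## What it does, for whom

`phaseasm` is a proof-of-concept *layout* engine for the
overlap-layout-consensus approach: given long, single-end, forward-strand
reads with a low error rate (≤ ~1.5%) from a repeat-free source, it decides
which reads overlap and in what order they lie on the source. It is aimed at
people studying alternative formulations of the assembly problem —
signal-based overlap detection, TSP/QUBO orderings, annealer-style solvers —
rather than at production assembly. Consensus sequence construction is out
of scope; the output is a set of contigs, each an ordered list of
overlapping reads.

The pipeline:

1. **Encode** every read as a cumulated-phase signal: bases map to complex
   numbers (A: 1+j, C: −1−j, G: −1+j, T: 1−j), their arguments (odd
   multiples of π/4) are accumulated along the read.
2. **Score** every read pair by the maximum Pearson correlation
   ρ = cov(X,Y)/(σ_X σ_Y) of their signals over all relative shifts
   (windows ≥ `min_overlap` bases). Shared substrings give signal windows
   differing only by an additive constant, so error-free overlaps score
   exactly 1.
3. **Order** reads by solving a TSP on integer costs (1 − ρ) × 1000,
   min–max scaled to [0, 1000], with an artificial zero-cost vertex 0 as
   fixed start. Solvers: nearest neighbour + 2-opt/Or-opt (`classic`), or
   an N²-variable one-hot QUBO sampled by simulated annealing with a
   DBSCAN-style decomposition for instances beyond the ~60-variable direct
   embedding limit (`qubo-sa`).
4. **Split** the path into contigs wherever the edge cost exceeds a
   coverage-informed threshold.
5. **Evaluate** against the ground truth that the built-in simulator
   (random circular source, 50 × 3000 bp evenly tiled reads, point
   mutations) generates alongside the reads.

## Worked example

```r
library(phaseasm)

cfg <- pipeline_config(coverage = 10, error_pct = 0, solver = "classic",
                       seed = 11)
res <- run_pipeline(cfg, out_dir = "run1")
res$report
#>   path_cost real_contig_breaks calculated_contig_breaks correct_overlaps
#> 1         0                  0                        0               50
#>   incorrect_overlaps accuracy threshold
#> 1                  0        1         0
```

Reading the row: the tour has **path cost 0** (every junction joins reads
with perfect signal correlation), all **50** evaluated junctions of the
50-read circular layout are genuine overlaps (**accuracy 1.00**), no false
overlap is retained, and neither the truth (**real breaks**) nor the
threshold (**calculated breaks**) splits the path — a single contig
covering the source. With errors the same run degrades gracefully, e.g. at
0.5% mutations (`error_pct = 0.5`, seed 101) the row becomes path cost 414,
49/50 overlaps recovered (accuracy 0.98), still 0 incorrect overlaps.

The same pipeline is scriptable stage by stage:

```sh
Rscript inst/cli/phaseasm.R simulate --coverage 10 --error-pct 0 --seed 1 --out-dir run/
Rscript inst/cli/phaseasm.R overlap  --reads run/reads.fasta --out-dir run/
Rscript inst/cli/phaseasm.R order    --matrix run/cost.tsv --solver classic --out run/path.json
Rscript inst/cli/phaseasm.R contigs  --path run/path.json --matrix run/cost.tsv --coverage 10 --out run/contigs.tsv
Rscript inst/cli/phaseasm.R evaluate --path run/path.json --matrix run/cost.tsv \
        --truth run/truth.tsv --adjacencies run/adjacencies.json --coverage 10 --out run/report.json
```

External reads can enter through `read_fasta()` / `--reads`; evaluation
then needs matching truth files (`read_truth()`).

## Package layout

- `R/` — simulator, encoding, overlap matrix (FFT sliding correlation with
  a naive oracle path), cost transform, classical and QUBO/SA solvers,
  contig splitting, evaluation, pipeline orchestration.
- `src/` — the simulated-annealing inner loop (Rcpp).
- `tests/testthat/` — unit and property tests per module plus
  `test-acceptance.R`, the acceptance criteria at full scale.
- `vignettes/phase-correlation-assembly.Rmd` — model, parameter rationale,
  numerical choices, limitations.
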
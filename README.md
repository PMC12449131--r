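# wavealign

Actor-based, wavefront-parallel Smith–Waterman local sequence alignment
in R.

## What problem this solves

Smith–Waterman is the exact (non-heuristic) algorithm for local pairwise
alignment: given sequences *p* = p₁…p_m and *q* = q₁…q_n it finds the
highest-scoring pairing of *substrings* of the two, in O(mn) time. That
cost makes serial implementations impractical for datasets of hundreds of
gene-length sequences, so practical use needs parallelism. `wavealign`
parallelizes the exact algorithm at two levels without changing a single
score:

* **interalignment** — independent pair alignments run concurrently, a
  *manager actor* dispatching tasks to *pair actors*;
* **intraalignment** — within one alignment, the score matrix is tiled
  into blocks whose data dependencies point up, left and up-left, so all
  blocks on an antidiagonal (constant block-row + block-column) can be
  computed simultaneously by *block actors* sweeping a wavefront from the
  top-left corner.

Both levels sit on a small actor runtime (isolated state, asynchronous
messages, `spawn`/`send`/`become`, per-actor mailboxes, a scheduler with a
configurable number of worker lanes) that the package also exposes
directly. The package is for bioinformaticians who want exact local
alignment of small-to-medium nucleotide datasets from R or a shell, and
for anyone who wants a tested, self-contained reference for wavefront DP
decomposition and actor-style concurrency.

## The recursion

Scores are integers. With match/mismatch substitution score *s(a, b)* and
affine gap penalties (G_oe = open+extend of the first gapped position,
G_e = each extension), the Gotoh three-state recursion is

    H(i,j) = max{ 0, H(i−1,j−1) + s(p_i, q_j), E(i,j), F(i,j) }
    E(i,j) = max{ H(i,j−1) − G_oe, E(i,j−1) − G_e }     (gap in query)
    F(i,j) = max{ H(i−1,j) − G_oe, F(i−1,j) − G_e }     (gap in target)

with H(i,0) = H(0,j) = 0. The linear gap model is the special case
G_oe = G_e. The optimal local alignment score S is the maximum of H; the
alignment is recovered by backtracking from that cell to the first cell at
or below a threshold (default 0). Ties — in the cell recursion, in the
location of the maximum, and in backtracking — are broken by fixed orders,
which is what makes every parallel execution bitwise identical to the
serial kernel.

## Worked example

```r
library(wavealign)
sch <- scoring_scheme(match = 2, mismatch = -1, gap = -2)
align_serial("ATCGACTT", "GATATCTG", sch)
#> <sw_alignment> score 6  query 1-3  target 4-6  cigar 3M
#>   ATC
#>   |||
#>   ATC
```

The optimal local alignment pairs `ATC` (query positions 1–3) with `ATC`
(target positions 4–6): three matches at +2 each, score 6. A co-maximal
cell exists in the score matrix; the smallest-(i, j) tie rule selects this
one deterministically.

A whole job, all pairs of a synthetic dataset, two worker lanes, block
actors on 16×16 tiles:

```r
ds <- random_sequences(dataset_spec(4, 40, 60, seed = 42))
report <- run_job(ds, job_config(workers = 2, intra = TRUE,
                                 block_rows = 16, block_cols = 16))
report
#> <job_report> 6 task(s): 6 ok, 0 failed; 17651 cells; mode all_pairs, 2 worker(s), intra on
head(report_records(report), 3)
#>   query_id target_id score q_start q_end t_start t_end                            cigar status
#> 1     syn1      syn2    28       4    47       2    48 4M1D5M1D2M1D3M1I12M1I11M1D2M1D3M     ok
#> ...
```

Scores, coordinates (1-based inclusive) and CIGAR strings (`M` aligned
pair, `I` gap in target, `D` gap in query) are identical for any
`workers`, any block size, and intra on or off.

From a shell:

```sh
Rscript inst/cli/wavealign.R --in set.fa --mode all_pairs \
    --match 2 --mismatch -1 --gap -2 --workers 4 -o out.tsv
Rscript inst/cli/wavealign.R make-fixtures --dir fixtures --seed 1
```

## Package layout

* `align_serial()` — the reference kernel: fill, locate maximum, backtrack.
* `align_blockwise()` — the same result via block tiles in wavefront order.
* `actor_system()`, `spawn()`, `send()`, `become()`,
  `run_until_quiescent()` — the actor runtime.
* `run_job()` — manager/pair/block actor topology over a dataset.
* `read_fasta()`, `write_fasta()`, `write_results()`, `main()` — I/O and CLI.
* `dataset_spec()`, `random_sequences()`, `mutate_pair()` — seeded
  synthetic data.

See `vignettes/wavealign.Rmd` for the methods account: model assumptions,
parameter choices, tie-breaking, halo design, scheduler semantics and
known limitations.
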
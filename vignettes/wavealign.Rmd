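---
title: "Methods: exact local alignment on an actor-based wavefront"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact local alignment on an actor-based wavefront}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavealign)
```

## The model and its assumptions

`wavealign` computes exact Smith–Waterman local alignment with Gotoh's
three-state dynamic programme. The states are `H` (best score of a local
alignment ending at query position *i* and target position *j*), `E`
(best score ending with a gap in the query, i.e. a horizontal move) and
`F` (ending with a gap in the target, a vertical move):

$$H_{i,j} = \max\{0,\ H_{i-1,j-1} + s(p_i,q_j),\ E_{i,j},\ F_{i,j}\}$$
$$E_{i,j} = \max\{H_{i,j-1} - G_{oe},\ E_{i,j-1} - G_e\}$$
$$F_{i,j} = \max\{H_{i-1,j} - G_{oe},\ F_{i-1,j} - G_e\}$$

with zero boundary row and column for `H`. `F` is defined symmetrically
to `E`: both recursions chain their *own* state for gap extension. A gap
state can never legally extend the other gap state — that would let a
single gap switch sequences mid-run — so the `F` recursion extends
`F(i−1,j)`, not `E(i−1,j)`.

Assumptions worth making explicit:

* **Integer scoring only.** Scores, penalties and every matrix entry are
  integers; no floating point enters the kernel. This is what makes
  "identical across block sizes, schedules and worker counts" an exact
  claim rather than a tolerance.
* **Two-valued substitution.** Identical residues score `match`,
  differing residues `mismatch`; there is no substitution-matrix file
  support (BLOSUM/PAM are out of scope). The wildcard `N` scores as a
  mismatch against everything, including itself, because ambiguity codes
  carry no identity information.
* **Local semantics.** `H` is clamped at zero, and a matrix with no
  positive entry is reported as "no alignment" (score 0, coordinates 0,
  CIGAR `*`) rather than as a zero-length alignment at an arbitrary
  position.

## Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `match` | score added per identical pair | `2` | the scheme used throughout the test suite's worked examples |
| `mismatch` | score added per differing pair | `-1` | ditto |
| `gap` | signed linear gap value | `-2` | a single printed gap value is a linear model |
| `gap_open`, `gap_extend` | signed affine values (both or neither) | unset | affine mode is opt-in via the two flags |
| `threshold` | backtrack stop value | `0` | classic local traceback |
| `block_rows`, `block_cols` | tile size, cells | `256` | balances message count against per-block work at desk scale; any value ≥ 1 is exact |
| `workers` | scheduler lanes | `1` | deterministic single-lane event loop unless parallelism is requested |
| `max_in_flight` | live pair actors | `2 × workers` | bounds concurrent matrices (memory) while keeping lanes busy |

Sign convention: the CLI and `scoring_scheme()` accept gap values as they
are conventionally printed (negative); internally they are stored as
non-negative magnitudes that the recursion subtracts. `gap_open` is the
combined open-plus-extend cost of a gap's first position.

## Tie-breaking, coordinates, degenerate inputs

All ties are broken by fixed orders so that every execution mode is
bitwise reproducible:

* the cell maximum evaluates candidates as (zero | diagonal, E, F) — the
  order is irrelevant for the value, only traceback interprets it;
* the matrix maximum takes the smallest *i*, then smallest *j*, among
  co-maximal cells (the kernel's row-major strict `>` scan implements
  this, and per-block local maxima compose to the same global rule);
* backtracking prefers moves in `tie_order = (diagonal, up, left)` and
  follows the `E`/`F` chains through affine gaps, so an opened gap is
  extended at `G_e` rather than re-opened.

Matrices are stored with the zero row/column (0-based internally);
reported coordinates are 1-based inclusive on the original residues.
Empty sequences are legal and align to everything with score 0. Border
entries of `E`/`F`, where those states are undefined, are `NA` in R and
an impossible-state sentinel (−2²⁸, safely below any reachable score) in
the kernel.

## Blockwise wavefront evaluation

The interior cells are tiled by a `block_rows × block_cols` grid (ragged
last tiles allowed). A block needs exactly three kinds of imported state,
dictated by which recursion crosses which edge: `H` and `F` along its top
edge (vertical gaps cross row boundaries), `H` and `E` along its left
edge, and the single `H` value at its top-left diagonal. Those halos are
what block actors exchange; a finished block exports the mirror-image
halos for its down/right/diagonal neighbours.

Blocks with equal `I + J` form one wavefront level; all of a block's
dependencies live in strictly earlier levels, so levels are evaluated in
order but blocks *within* a level in any order or in parallel — the test
suite asserts order-independence by shuffling. Row strips
(`block_cols = n`) are the special case of a one-dimensional
decomposition; the general 2-D grid subsumes it and exposes more
parallelism for long sequences.

Traceback needs the full `H`/`E`/`F` matrices, so in traceback mode tiles
are assembled into one matrix as they finish (memory O(mn), the price of
an exact gapped alignment). `score_only` mode retains only the halos of
the last two levels — memory bounded by the wavefront, not the matrix —
and still reports the exact score and end coordinates.

## The actor runtime

The runtime implements the three classic actor actions — `send` (async,
exactly-once, FIFO per sender–receiver pair), `spawn` (actors may spawn
actors from handlers) and `become` (the in-flight message completes under
the old behavior) — with per-actor mailboxes, a ready queue on which an
actor appears at most once, and supervision: a handler error poisons only
that actor and routes an `actor_failed` message to its creator, and sends
to dead actors go to a dead-letter log rather than raising.

The design decision that shapes everything else: **handlers are
effect-based**. A handler receives (context, state, message) and returns
its new state; its sends, spawns and becomes are *recorded* on the
context, and the scheduler applies them afterwards in deterministic slot
order. Each scheduling round takes up to `workers` distinct actors and
processes one message per actor. Because handlers cannot mutate shared
runtime structures, the round can execute its handlers either in-process
(one lane) or on forked parallel lanes (`parallel::mclapply`) with
identical results — determinism is by construction, not by testing luck.
Spawn identifiers are granted deterministically per handler invocation,
so a forked handler can already address the actors it spawns.

Mailboxes are unbounded; back-pressure is the application's job, which
the alignment topology implements by capping in-flight pair actors.

## The alignment topology

One **manager actor** holds the task list, spawns at most `max_in_flight`
**pair actors**, and dispatches a pending task whenever a result (or a
failure notice) arrives, so one poisoned task costs exactly one failed
record and the job completes. A pair actor either runs the serial kernel
directly or spawns a pool of **block actors** — `min(workers,
min(grid_rows, grid_cols))` of them, since the widest wavefront level
bounds usable parallelism — releases block tasks level by level, becomes
a collecting behavior that accepts only block results, and assembles or
discards tiles according to the output mode. Block actors are reused
across blocks. Reports are ordered by task id, never by completion order,
which is why output bytes are identical for any worker count.

Task composition supports all-vs-all (default), query-vs-database and an
explicit pair list; which one a study needs is a property of the study,
so all three are explicit modes rather than a guessed default behavior.
The seed in a job configuration is echoed for provenance only — alignment
is deterministic and seed-free; seeds drive only synthetic data.

## Synthetic data: what it emulates and what it does not

The generator emulates the *shape* of real gene-set benchmarks — sequence
counts and length ranges, e.g. a BRCA1-like set reduced to 30 sequences
of 500–1050 nt — with lengths uniform over `[min, max]` and residues
uniform over `{A,C,G,T}`. Per-record seeds are derived by counter, so
growing a dataset never changes earlier records, and identical specs give
identical FASTA bytes. `mutate_pair()` derives a homologous partner with
chosen per-site substitution/insertion/deletion rates and records the
true edits, so tests can bound the optimal score from the known mutation
path (the optimum can only improve on the truth).

What passing tests on this data do **not** show: real genes have base
composition bias, repeats, and clustered indels, none of which uniform
sequences reproduce. The correctness claims (parallel ≡ serial, oracle
equivalence) are insensitive to sequence statistics; any claim about
alignment *quality* on real data would not follow from these tests.

## Problem sizes used by the test suite

Chosen as the package's own test scale: oracle equivalence on 200 random
pairs of length ≤ 40 (the independent oracle is a top-down
recursion-with-memoization, deliberately a different algorithm shape from
the iterative kernel); block equivalence on 50 pairs of length ≤ 300
across block sizes from 1×1 cells to one block per matrix; concurrency
determinism on a 50-task job under worker counts 1–8; and a scaling
smoke test on a job sized to run at least 20 s serially, which asserts
only the *ordering* of 1-lane vs 4-lane wall-clock time and therefore
requires a multi-core host to pass.

## Known limitations

* Traceback mode holds full integer matrices; aligning two 50 kb
  sequences wants ~30 GB across three matrices. Use `score_only` for
  long sequences, or smaller inputs for full tracebacks. A linear-memory
  (Hirschberg) traceback is out of scope.
* No SIMD/striped kernel and no banded or global/semiglobal modes; the
  kernel is a portable scalar implementation.
* The actor runtime is in-process only (no network transparency), and
  its forked lanes require a Unix-like OS for `mclapply` to fork.
* Nucleotide-oriented defaults; arbitrary alphabets are supported but
  there is no substitution-matrix support for proteins.
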
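---
title: "Striped profile-HMM filters: model, layout and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Striped profile-HMM filters: model, layout and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmstripe)
```

## The filter funnel

`hmmsearch`-style homology search scores a protein database against a
profile hidden Markov model through a funnel of increasingly expensive
filters. The first stages are deliberately crude: the **SSV** model
(single ungapped segment) keeps only Match states with uniform entry
and exit, and scores the best single ungapped diagonal of the dynamic
programming matrix. **MSV** (multiple ungapped segments) adds the J
state, which lets several high-scoring segments chain into one score.
Survivors reach the **Plan-7 Viterbi filter**, the full
Match/Insert/Delete model whose Delete-Delete transitions impose a
sequential dependency along each DP row. Only a small fraction of the
database survives to the expensive Forward stage, which is out of
scope here.

hmmstripe implements these three filters twice over the *same*
quantized integers:

* a **striped multi-lane engine** (`ssv_score()`, `msv_score()`,
  `viterbi_score()`) that mirrors the warp-wide SIMD evaluation order:
  saturating sub-word arithmetic, a closed-cycle lane reorder per row,
  a warp-wide max-reduction for the E state, and Lazy-F evaluation of
  the Delete recursion; and
* a **naive sequential oracle** (`naive_ssv()`, `naive_msv()`,
  `naive_viterbi()`) with an obviously-correct row-by-row,
  state-by-state recursion.

The package's headline property, enforced by the test suite across
hundreds of randomized (model, sequence, geometry) triples, is that
the two agree **bit-exactly**. Saturating arithmetic is not
associative, so this is only meaningful because both routes execute
the same per-cell operation DAG; the striping merely reorders *which
cells* are touched when, never the operations inside a cell.

## The striped layout

A warp of `S_warp` threads, each packing `alpha` sub-word lanes (4 for
the 8-bit filters, 2 for the 16-bit Viterbi), acts as a flat vector of
`lanes = alpha * S_warp` sublanes. Model state $k$ (1-based) lives at
lane $\lfloor (k-1)/Q \rfloor$, stripe iteration $(k-1) \bmod Q$, with

$$Q = \max\!\left(\left\lfloor\frac{L-1}{\alpha\,S_{warp}}\right\rfloor + 1,\; 2\right)$$

inner iterations per DP row. Cells beyond $L$ hold the `-Inf`
sentinel, so enlarging the geometry never changes a score
(padding-invariance is asserted end-to-end). Under this layout the
diagonal dependency `M[i-1][k-1]` is satisfied by a single one-lane
shift of the last stripe (`reorder()`), with the sentinel shifted into
lane 0 — 0 in the unsigned byte scheme, the `0x80` pattern in a
signed-byte reading, `-32768` in 16-bit. The geometry is fully
parameterizable so tests can run tiny warps; the defaults
(`32 x 4 = 128` lanes for MSV/SSV, `32 x 2 = 64` for Viterbi) match
the hardware scheme the layout models.

## Integer scoring schemes

**8-bit unsigned (MSV/SSV).** Path scores live at an offset `base`
(default 190); 0 is both the floor and the `-Inf` sentinel.
Quantization maps a log-odds score $s$ (bits) to
`clamp(round(scale * s) + bias, 0, 255)` with `scale = 3/ln 2` units
per bit and a bias chosen so the worst finite emission maps to at
least 1, keeping 0 unambiguous. Inside a row, emissions are applied
as two saturating operations — add a per-model byte `B` (the largest
emission delta), then subtract a per-symbol cost `C = B - delta`
(255 at sentinels) — so a `-Inf` emission floors its cell *exactly*
(the add clamps at 255 and subtracting 255 lands on 0). This
two-operation form is the reason an unsigned scheme can carry a true
sentinel at all, and it is the scheme in which SSV and MSV are
directly comparable on identical integers. A row whose maximum
reaches `255 - B` may have clipped; the record is flagged `saturated`
and always passes, since clipping can only underestimate.

**16-bit signed (Viterbi).** Emissions and transitions quantize at 16
units per bit with bias 0; `-32768` is the sentinel and finite values
clamp to `[-32767, 32767]`. With `base = 12000` the scheme has roughly
1300 bits of headroom, so saturation is essentially a guard rail. One
approximation is inherent and shared by both engine and oracle:
`-32768` absorbs further subtraction but not addition, so a "sentinel
plus large positive emission" is merely a very low finite value rather
than `-Inf`. Both evaluation routes perform the identical operations,
so bit-exactness is unaffected; the unsaturated oracle mode
(`saturating = FALSE`) uses genuine `-Inf` arithmetic and is the mode
in which clean model-theoretic properties (e.g. SSV $\le$ MSV) are
tested.

## Normative model semantics

The filter recurrences leave a few conventions open; hmmstripe fixes
them once, implements them identically in engine and oracle, and pins
them with an exhaustive path-enumeration oracle on tiny instances
(every legal state path of models with $L \le 3$ on sequences of
length $\le 4$ is scored explicitly and the maximum compared to the
DP):

* **Special transitions.** Per target sequence of length `n`,
  `tloop = log2(n/(n+3))`, `tmove = log2(3/(n+3))` (recomputed per
  sequence, overridable), uniform entry `tbm = log2(2/(L(L+1)))`, and
  `tec = tej = -1` bit. Logarithms are base 2 throughout so that
  `scale` is exactly "integer units per bit".
* **MSV/SSV loop charging.** The J state is charged `tloop` per
  looped residue; N and C loops are free (their byte cost rounds to 0
  at the default scale in any case). Charging C but not N would break
  the SSV $\le$ MSV dominance that the byte scheme is meant to
  preserve, so both are free.
* **E state.** Fed from Match states only; Delete states have no exit
  path. Inserts are scored at zero emission (filter convention);
  insert emissions read from profile files are carried but unused.
* **SSV width.** SSV runs in the same unsigned-offset byte scheme as
  MSV (shift-in 0). The signed-byte variant used by some
  implementations differs only by a constant offset; `reorder()`
  accepts any shift-in sentinel, including `0x80`, so that reading
  remains expressible.

## Lazy-F

Within a striped row the Delete recursion
`D[k] = max(M[k-1] + tMD, D[k-1] + tDD)` crosses lane boundaries. The
engine first computes each lane's within-stripe chain plus a carry
register; one unconditional merge pass reorders the carry across the
lane boundary and folds it in; then *check passes* repeat — reorder,
per-stripe `vmax`, re-propagate with `tDD` — only until a full pass
changes nothing. Because saturating addition is monotone and
distributes over `max`, the fixpoint equals the strict sequential
recursion exactly; a hard cap of `lanes` passes guards against bugs
(each pass extends the reach of a carry by one lane, so the cap is
unreachable by construction). When `tDD = -Inf` the chain is dead and
the first check pass terminates the loop, which the suite asserts via
the `lazy_passes` field of the returned record.

## The planner

The planner reproduces the hardware cost model rather than measuring
hardware. Warp `O` with completed-count `C` takes sequence
`O + C * N_warp * N_smx`; the schedule partitions any index range
exactly, and re-running the pipeline under a simulated partition
yields byte-identical reports. For the shared-memory kernel variant
the DP-row buffers cost `(Q+1) * S_warp * 4` bytes per warp for
MSV/SSV and `(3Q+1) * S_warp * 4` for Viterbi (three rows); the
resident warp count is maximized under the shared-memory and
resident-thread constraints and occupancy is
`P = N_warp * S_warp / S_thread * 100`. On the default device (15
SMX, 2048 threads and 48 KB per SMX, warp 32) this yields 100 %
occupancy for MSV at `L = 600` falling to 29.7 % at `L = 2405`, while
the local-memory variant with 32 launched warps stays at 50 %
regardless of `L`. Variant selection uses fixed empirical crossovers
(shared only up to `L = 300` for MSV/SSV, 200 for Viterbi) because the
crossover is a hardware measurement, not something a desk model should
re-derive; both variants are score-identical by construction, which
the suite asserts.

## Synthetic data

`gen_sequences()` draws i.i.d. uniform residues over the 20 standard
amino acids; `gen_model()` builds a profile with one consensus residue
per state at `motif_strength` bits (default 2) over a background of
uniform(-3, -0.5)-bit emissions, realistic Match/Insert/Delete
transition ranges, and an optional heavy Delete-Delete regime
(`dd_range` near 1) to stress Lazy-F; `plant_motif()` splices the
consensus into a background sequence by overwriting. These fixtures
exercise every code path the engine has, but they are not real
proteins: no compositional bias, no repeat structure, no homology at
intermediate identity. Passing tests therefore demonstrate
*arithmetic* fidelity of the engine — exactly what a striped
reimplementation must show — and the analytic planner numbers; they
say nothing about search sensitivity on biological data, which is a
property of the model files, not of this layout.

## Problem sizes and runtime choices

The randomized equivalence suites use 200 (model, sequence, geometry)
triples per filter with `L` in [3, 200], lengths in [0, 300] and warp
sizes from 2 to 32 with 1, 2 or 4 sublanes — large enough that every
stripe/lane/carry configuration (including `Q = 2` floors, all-padded
lanes and multi-lane Delete chains) occurs many times, while the full
suite stays around a minute of CPU. Every random draw is tied to a
fixed seed; reports embed their seed and configuration.

## Known limitations

* The HMMER3 profile reader supports the `HMMER3/f` ASCII dialect
  only, converts stored probabilities to log-odds against a fixed
  Swissprot-composition background, and ignores the optional
  annotation columns.
* Filters return scores only — no alignment traceback or coordinates,
  no Forward stage, no E-values; the P-value hook
  (`score_threshold_from_pvalue()`) converts user-supplied
  calibration constants but performs no calibration.
* Monotonicity of scores in a single emission holds exactly in
  unsaturated arithmetic and in the 16-bit scheme; in the byte scheme
  it can be violated by one unit at the clipping boundary when the
  bumped emission *is* the model maximum (the `B`/`C` decomposition
  shifts), which is precisely the regime the `saturated` flag marks.
* Memory-transaction layout (128-byte coalescing) is modelled only as
  the flat lane order; rows are padded to `Q * lanes` cells, not to a
  fixed byte width.
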
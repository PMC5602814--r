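---
title: "Methods: the top-R dynamic program for scaffold-based structure elucidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the top-R dynamic program for scaffold-based structure elucidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csccp)
```

## The model

A scaffold configuration `S = (n, K, W, P)` describes one admissible set
of `n` substitutable positions on a molecular scaffold: position `s`
offers `k_s` candidate sidechains with masses `w_{s,j}` (Da) and
attachment probabilities `p_{s,j}`. A compound is a selection
`x = (x_0, ..., x_{n-1})`, one sidechain per position; its total
sidechain mass is the sum `g(x)` and its probability the product
`f(x)`. Given a mass window `[w_min, w_max]` from an LC–MS peak at `D`
decimal digits of mass resolution, the task is to return the `R`
compounds with the highest `f(x)` among those with
`g(x) ∈ [w_min, w_max]`.

Two modelling assumptions matter:

* **Probabilities are independent across positions** — `f` is a plain
  product. Attachment correlations between positions are not modelled.
* **Probabilities are only bounded by `[0, 1]`.** They need not sum to
  one within a position, and the solver never renormalizes. Any
  normalization convention of the upstream scaffold database is
  therefore preserved exactly.

All masses are integerized by `10^D` (`integerize()`), with
round-to-nearest, ties away from zero. On conforming inputs — masses
written with at most `D` decimals — this is exact; otherwise a warning
reports each mass that loses precision. A round-trip therefore recovers
every mass to within half a unit of `10^-D` Da.

## The dynamic program

`dp_forward()` fills layers `c_{s,w,r}`: the `r`-th highest probability
over partial compounds on positions `0..s` with integer mass exactly
`w`. The virtual base layer is probability 1 at mass 0 (the empty
selection), invalid elsewhere — the seed is not prescribed by the
formulation itself, and this choice makes the first real layer come out
as the definition demands. Each update at `(s, w)` considers every
sidechain `k` and predecessor rank `r`, forming
`p_{s,k} · c_{s-1, w - w'_{s,k}, r}`, skips candidates that reach below
mass zero or extend an invalid cell, and keeps the top `R`. A cell with
probability 0 is "invalid": zero-probability sidechains can never appear
in output, so validity and positivity coincide and no separate validity
mask is needed.

Only two cost layers are live at a time (`C⁻`/`C⁺` rolling buffers),
which for `n` positions saves `100(1 - 2/n)`% of the cost-matrix memory
(`c_matrix_saving_fraction()`); retaining all layers
(`keep_all_C = TRUE`) is supported for diagnostics and verified to
change nothing.

**Tie-breaking.** The ranking order is deterministic everywhere:
probability descending, then sidechain index `k` ascending, then
predecessor rank ascending; the final ranking additionally breaks ties
by smaller mass, then smaller rank. The underlying formulation leaves
ties unspecified; fixing one shared rule is what makes the solver,
its two engines, both traceback modes and the brute-force oracle agree
*exactly*, not just up to tie permutations. Note what the per-state
rule induces globally: since position `n-1` is processed last, equal
probability compounds at the same mass are ordered by comparing
selections from the **last** position backwards. `brute_force_solve()`
sorts by exactly that induced order.

**Why per-state truncation to R is lossless.** Entries at a state are
pairwise-distinct selections (different `k` differ at the current
position; same `k`, different `r_prev` extend distinct predecessors, by
induction). If a compound belongs to the global top R, each of its
prefixes ranks within the top R of its own `(s, w)` state: were a
prefix displaced, the R displacing prefixes would extend — with the
identical suffix — to R compounds dominating it under the shared order.

**Engines.** The `"sequential"` engine is the reference: an explicit
loop over states calling `state_update()`. The `"vectorized"` engine
processes all masses of a position simultaneously with R's vectorized
primitives — the serial analogue of the accelerator design that assigns
one thread per mass value, the scheme with the highest degree of
parallelism (the alternatives, one thread per sidechain or per rank,
offer less and are not implemented). Both engines multiply the same
doubles in the same order, and the test suite holds them to
bit-identical tables. Probability arithmetic stays in the linear domain
in double precision, mirroring the direct products of the formulation;
for scaffolds with many tens of positions the products underflow, so a
log-domain variant would be needed — a documented limitation, not a
practical one at natural-product scale (`n` rarely exceeds ~10).

`finalize_top_r()` collects final-layer cells inside the integerized
window and `backtrack()` walks the per-position `(k, r_prev)` records
back to mass 0, erroring on any inconsistency rather than returning a
corrupt selection. Fewer than `R` reachable compounds simply yield a
shorter result — no padding.

## Traceback packing

For accelerator-scale instances the traceback matrix dominates memory:
raw storage needs `8·n·w'_max·R` bytes. Packing the whole chain of a
cell into two 32-bit words — one concatenating the `n` sidechain-index
fields (`⌊log2(k_s)⌋ + 1` bits each), one the `n` predecessor-rank
fields (uniform `⌊log2(R)⌋ + 1` bits) — cuts this to `8·w'_max·R`
bytes, a `100(1 - 1/n)`% saving. Packing is feasible iff each word's
fields sum to ≤ 32 bits (`check_compression_feasible()`). Two
deliberate choices:

* The width rule is kept **as stated**, although it wastes one bit for
  exact powers of two (`k_s = 4` gets 3 bits): the feasibility
  inequalities and the database feasibility statistics are defined in
  terms of this rule, so a tighter rule would change which instances
  count as packable.
* Bit order — position 0 at the least-significant end, documented in
  `docs/packing.md` — is fixed by this package; concatenation alone
  does not pin an endianness, and the layout is part of the ABI.

Words live in R doubles, which hold unsigned 32-bit values exactly and
avoid the sign bit of R's native integer type. Raw storage is the
default on CPU (it is simpler to inspect); `traceback = "packed"`
selects packing, and the suite verifies the two modes return identical
results and that pack/unpack are mutual inverses.

## Device resource model

The GPU formulation is memory-bound, and its feasibility accounting is
reproduced exactly: the rolling cost buffers plus packed traceback need
`16·R·w_max·10^D` bytes of global memory (`state_memory_bytes()`); the
largest processable target weight is
`⌊global_memory / (16·R·10^D)⌋` Da (`max_target_weight()`); and the
per-block ranking buffers (one `h·R`-entry buffer of 8 bytes per entry
per thread) bound the threads per block by the largest power of two
`T` with `8·T·h·R ≤ shared_memory`, capped at the hardware limit
(`max_threads_per_block()`). The 8-bytes-per-entry shared-memory model
is a reconstruction validated by agreement with all five published
(R, h) bounds, not a quoted formula. The default `device_profile()`
models a Tesla K40c-class card with 11 440 MiB global memory — of the
two circulating global-memory figures (11 439/11 440 MB) only this one
is consistent with the derived 2499/749 Da weight limits, and "GB" in
the published footprints reads as GiB (2.24/7.45) — 49 152 B shared
memory and 1024 threads.

`classify_feasibility()` labels an instance `feasible`,
`insufficient_global_memory`, `compression_impossible`, or
`both_problems`; `feasibility_report()` tabulates shares and category
counts over a configuration set per `D`, the database-level view of
what a device can process. On a CPU the limits are advisory:
`dp_forward()` refuses an infeasible instance only when given a device
profile, and `force = TRUE` overrides.

## Synthetic data

`generate_scaffold()` draws `n` uniformly from `n_range`, per-position
sidechain counts from `k_range`, masses uniformly from `weight_range`
rounded to exactly `digits` decimals — so integerization at `D ≥ digits`
is exact by construction — and probabilities either normalized per
position (default: attachment frequencies naturally sum to one) or raw
uniform (`uniform01`, exercising the weaker `[0, 1]`-only contract).
Defaults (`n` 2–6, `k` 1–4, masses ≤ 45 Da, 2 decimals) mirror the
gross statistics of natural-product scaffold databases, where the
typical maximum sidechain count per scaffold is about 4 and the average
total sidechain mass per compound is near 90 Da. `generate_peak_for()`
centres a window of random half-width on the mass of a random
selection, so every generated instance has at least one in-window
compound and is solvable.

What the generator does **not** emulate: real sidechain chemistry,
empirical (non-uniform) mass distributions, correlated attachment
probabilities, or the configuration multiplicity of real scaffolds.
Passing the oracle-equivalence suite on generated instances therefore
demonstrates algorithmic correctness of the DP on the full combinatorial
structure of the problem, not predictive accuracy on real mixtures —
the latter is a property of the upstream probability database, which
this package consumes as given.

## Numerical and design choices

* **Integerization**: round-to-nearest, ties away from zero (not
  truncation); exact on conforming inputs, warned otherwise.
* **Zero-mass sidechains** (e.g. treating "no substituent" as an
  explicit hydrogen entry) are legal inputs with no special handling.
* **Final layer**: positions are indexed `0..n-1` and the ranking reads
  the layer produced after position `n-1`.
* **Problem sizes in the suite**: the oracle-equivalence suites use
  `n ≤ 6`, `k_s ≤ 5`, `D ≤ 2`, windows under 100 Da — up to 15 625
  enumerable selections and DP tables up to ~10⁴ mass rows — chosen so
  exhaustive enumeration remains an independent, fast oracle while
  exercising every code path (both probability modes, `R ∈ {1, 3, 8}`,
  both traceback modes, both engines).
* **Work counter**: `dp_forward()` counts state updates at strictly
  positive mass. The origin column `w = 0` is the DP seed and can only
  ever hold all-zero-mass selections, so the counter both reflects the
  real work and scales exactly tenfold per unit of `D` at fixed
  `w_max`, which the suite asserts by counting, not timing — wall-clock
  comparisons are hardware statements, not algorithm properties, and
  are out of scope here.
* **Batch merging**: `run_batch()` merges the per-configuration top-R
  lists of a peak by probability, ties by scaffold id, configuration
  index, rank — the published pipeline only promises "a ranked
  candidate list", so the tie rule is this package's convention.

## Known limitations

* Linear-domain probabilities underflow for very large `n` (no
  log-domain path).
* Instances whose DP table exceeds host memory are refused rather than
  streamed out of core.
* The solver consumes scaffold probability data; it does not estimate
  it, parse any particular scaffold-database distribution format
  byte-for-byte, render structures, or convert raw m/z to neutral mass
  (adducts are the caller's responsibility).
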
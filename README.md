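# csccp

Top-R candidate enumeration for scaffold-based structure elucidation of
mass-spectrometry mixtures.

## The problem

Natural-product mixtures measured by LC–MS yield a list of molecular
weights, but a mass peak alone does not identify a structure. A practical
strategy decomposes known natural products into a core **scaffold** plus
terminal **sidechains**, and scores how often each sidechain attaches at
each substitutable position. A candidate structure for a peak is then a
scaffold with one sidechain chosen per position whose total sidechain
mass matches the peak's window, ranked by how probable that combination
is.

Formally this is the **chemical substituent core combinatorial problem
(CSCCP)**. A scaffold configuration is `S = (n, K, W, P)`: `n`
substitutable positions, `k_s` candidate sidechains at position `s`
(`h = max K`), masses `w_{s,j}` (Da) and attachment probabilities
`p_{s,j} ∈ [0,1]`. For a selection `x = (x_0, …, x_{n-1})`,

```
g(x) = Σ_s w_{s,x_s}        (total sidechain mass)
f(x) = Π_s p_{s,x_s}        (compound probability)
```

and the task is: given a mass window `[w_min, w_max]` resolved to `D`
decimal digits, find the `R` selections with the highest `f(x)` subject
to `g(x) ∈ [w_min, w_max]`. The problem is NP-complete, but after
integerizing all masses by `10^D` it admits a pseudo-polynomial top-R
dynamic program over states `(position, integer mass, rank)` whose work
is proportional to `w_max · 10^D`.

This package provides, for R users:

* the **top-R dynamic program** (`solve_csccp()`, with the building
  blocks `integerize()`, `dp_forward()`, `finalize_top_r()`,
  `backtrack()` exposed), with deterministic tie-breaking and two
  bit-identical engines (a vectorized all-masses-at-once update and a
  sequential reference loop);
* an exhaustive **brute-force oracle** (`brute_force_solve()`) sharing
  the same deterministic order, for verification on small instances;
* **traceback compression**: the whole per-compound traceback packed
  into two 32-bit words per DP cell (`pack_traceback()`,
  `unpack_traceback()`, `check_compression_feasible()`), as used to fit
  the traceback matrix into accelerator memory;
* a **device resource model** (`state_memory_bytes()`,
  `max_target_weight()`, `max_threads_per_block()`,
  `classify_feasibility()`, `feasibility_report()`) reproducing the
  memory-limited feasibility accounting of the GPU formulation;
* a deterministic **synthetic generator** (`generate_scaffold()`,
  `generate_peak_for()`) so everything is testable offline;
* **batch IO**: scaffold JSON, peak-list CSV, result TSV
  (`read_scaffold_json()`, `read_peaks_csv()`, `run_batch()`,
  `write_results_tsv()`), and a command-line wrapper
  (`inst/cli/csccp.R` / `csccp_cli()`).

## Worked example

Two configurations of a small synthetic scaffold and two peaks ship with
the package:

```r
library(csccp)
scaffolds <- read_scaffold_json(system.file("extdata", "example_scaffold.json", package = "csccp"))
peaks     <- read_peaks_csv(system.file("extdata", "example_peaks.csv", package = "csccp"))
res <- run_batch(scaffolds, peaks, run_config(rank = 3, digits = 2))
print(res, digits = 4)
```

```
  peak_id merged_rank scaffold_id config_index rank probability
1  peak_1           0 SYN-EXAMPLE            1    0     0.05951
2  peak_1           1 SYN-EXAMPLE            0    0     0.04699
3  peak_1           2 SYN-EXAMPLE            0    1     0.02803
4  peak_1           3 SYN-EXAMPLE            0    2     0.02459
5  peak_2           0 SYN-EXAMPLE            1    0     0.13654
6  peak_2           1 SYN-EXAMPLE            0    0     0.03229
7  peak_2           2 SYN-EXAMPLE            0    1     0.01101
  total_sidechain_mass     sidechain_ids
1                60.19 p0_s0;p1_s0;p2_s0
2                59.76 p0_s2;p1_s3;p2_s0
3                60.34 p0_s1;p1_s2;p2_s2
4                60.87 p0_s2;p1_s2;p2_s2
5                77.59 p0_s0;p1_s1;p2_s2
6                75.77 p0_s2;p1_s1;p2_s1
7                76.28 p0_s0;p1_s0;p2_s1
```

Each configuration contributes up to `rank` candidates per peak (a
scaffold with `N_r` configurations yields up to `rank × N_r` rows), and
the rows are merged into a per-peak ranking by probability. For
`peak_1` (window 59.74–60.94 Da) the best explanation is the rank-0
compound of configuration 1 with probability 0.0595 and total sidechain
mass 60.19 Da; `sidechain_ids` lists the chosen sidechain at each
position. A single instance can also be solved directly:

```r
solve_csccp(scaffolds[[1]], mass_peak(59.74, 60.94, D = 2), R = 3)
#>  rank probability total_mass selection
#>     0   0.0469948      59.76     2,3,0
#>     1   0.0280264      60.34     1,2,2
#>     2   0.0245889      60.87     2,2,2
```

Selections are zero-based sidechain indices, one per position.

The command line mirrors this pipeline:

```sh
Rscript inst/cli/csccp.R batch --scaffolds scaffold.json --peaks peaks.csv \
    --rank 3 --digits 5 --out results.tsv
```

Defaults (`rank = 3`, `digits = 5`, 500 Da sidechain-mass cap) follow
the parameter tuning adequate for natural-product scaffold databases;
see the methods vignette (`vignettes/csccp-methods.Rmd`) for why.

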
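# Packed traceback word layout

A traceback chain for one `(w, r)` cell of the final DP layer is the
sequence of `n` records `(k_s, r_prev_s)`, `s = 0 .. n-1`: the sidechain
index chosen at each position and the rank of the predecessor state the
choice extended. Packed storage concatenates the chain into two 32-bit
words per cell.

## Field widths

* Index word: field `s` is `floor(log2(k_s)) + 1` bits wide (the bit
  length of `k_s`, the sidechain count at position `s`). For exact powers
  of two this is one bit wider than the zero-based indices strictly need;
  the width is kept as defined because the feasibility inequalities are
  stated in terms of it.
* Rank word: every field is `floor(log2(R)) + 1` bits wide, uniform
  across positions.

Packing is feasible iff both words fit:

```
sum_{s=0}^{n-1} floor(log2(k_s) + 1) <= 32     (index word)
n * floor(log2(R) + 1)               <= 32     (rank word)
```

## Bit order

Position 0 occupies the least-significant bits of each word; position
`s` starts at offset `sum_{t<s} width_t` (index word) or `s * rank_width`
(rank word). Concatenation alone leaves endianness open; this LSB-first
layout is fixed by this package and is part of its ABI: words packed by
one version decode identically in any other.

## Representation in R

Words are carried in R doubles, which represent every unsigned 32-bit
value exactly; this avoids the sign bit of R's native 32-bit integer
type. `pack_traceback()` / `unpack_traceback()` implement the layout;
`check_compression_feasible()` implements the two inequalities.
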
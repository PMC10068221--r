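---
title: "Modelling telehealth accessibility with virtual catchment areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling telehealth accessibility with virtual catchment areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(e2svca)
```

## The model family

All three engines in this package are instances of one two-step scheme
over a sparse pairwise weight `W[k, j]` defined on demand–supply block
pairs inside a travel-time catchment (`d_kj <= d0`):

1. for every supply block `j`, the supply–demand ratio
   `R_j = S_j / sum_k D_k * W[k, j]`;
2. for every demand block `i`, the accessibility score
   `A_i = sum_j R_j * W[i, j]`.

`S_j` is the number of providers aggregated to block `j`, `D_k` the
population of block `k`. The methods differ only in how `W` is filled:

* **2SFCA** uses a distance-decay value (indicator by default, optional
  Gaussian), modelling physical visits;
* **2SVCA** uses the binary joint function: 1 iff both blocks have at
  least one internet provider with positive speeds in both directions;
* **E2SVCA** uses a step-wise function of
  `min(b_iu, b_id, b_ju, b_jd)` — the weakest of the demand block's
  upload/download and the supply block's upload/download speeds. A
  video call is a bidirectional stream, so the weakest of the four
  links binds.

Two properties of this formulation matter for testing. First, because
both steps share one `W`, population-weighted accessibility conserves
reachable supply exactly:
`sum_i D_i * A_i = sum_{j: denom_j > 0} S_j`. The test suite asserts
this identity to 1e-9 relative tolerance across hundreds of random
study areas; it is the principal engine check, and it is also why the
denominator must pair demand `k`'s broadband with supply `j`'s — any
other pairing breaks the identity. Second, when every block's four
speeds sit in the top weight tier, all three methods coincide exactly
with indicator-decay 2SFCA; the suite asserts bitwise equality in that
regime.

### Conventions and degenerate inputs

* **Catchment membership is binary in every method**, decided by travel
  time `<= d0`; both steps use the same `d0`. The virtual models carry
  no distance decay inside the catchment — broadband quality, not
  distance, is their impedance.
* **Absent OD pairs are unreachable**, never zero minutes. A pair
  missing from the sparse travel-time table belongs to no catchment.
* **A supply nobody can reach gets `R_j = 0`**, not NaN or an error: an
  unreachable clinic contributes no accessibility.
* **Blocks without broadband records get weight 0** in the broadband
  modes (provider-level extracts have gaps); the pair entry is kept so
  in-catchment membership remains visible.
* Block identifiers are opaque strings throughout; FIPS-style leading
  zeros survive every read/write round trip.

## The step-wise weight schedule

The default schedule follows one-to-one video-call bandwidth tiers:
weight 0 below 0.6 Mbps (no usable video), 0.33 from 0.6 Mbps
(standard quality), 0.66 from 1.2 Mbps (720p), 1.0 from 3.0 Mbps
(1080p; the slightly higher real-world upload requirement for 1080p is
rounded down to keep one symmetric threshold). Bins are closed on the
left and open on the right — `stepwise_weight(0.6)` is 0.33, not 0 —
because bandwidth requirements are stated as minima. The top bin
extends to infinity: published schedules sometimes print a large
sentinel (9999 Mbps) as the upper bound, and treating it literally
would make the function partial for gigabit-plus offerings. Schedules
are user-replaceable via `step_schedule()` or a JSON config; weights
must lie in [0, 1] and breakpoints must be strictly increasing and
positive.

## Per-block speed metrics

Deployment data list one record per provider per block, so each block
needs one representative speed per direction:

* `avg` — arithmetic mean of all offered speeds. Retained as the
  historical baseline, never the default: a block offering mostly
  single-digit Mbps plus one gigabit provider averages far above what a
  typical household there can buy. The implementation is the plain
  mean over all records; there is no outlier-trimming variant.
* `min_a` — minimum available speed; the worst-case subscriber.
* `min_f` / `max_f` — minimum and maximum of the *modal set*, the
  speeds attaining the maximal provider count. These describe the
  common case and the optimal common case.

When frequencies tie, every value with maximal count enters the modal
set; with all values distinct the modal set is the whole set, so
`min_f = min_a` and `max_f` is the overall maximum. This is the natural
completion of a definition usually stated only for a unique mode, and
it preserves `min_a <= min_f <= max_f` on every input (a property the
suite checks against brute-force enumeration). Mode counting uses exact
equality of the parsed decimals — advertised speeds are coarse
decimals, and an epsilon would merge genuinely distinct tiers.

Download and upload are aggregated independently: the modal download
speed and the modal upload speed of a block may come from different
providers. This is deliberate — the metrics describe the block's
market, not any single subscription.

## Travel times

The travel module is routing-engine-agnostic: edge traversal times are
minutes directly, and real deployments are expected to import a
precomputed OD matrix (`read_od()`). The built-in path computes
Dijkstra shortest paths (via igraph) between block centroids snapped to
their nearest road node, with a deterministic smallest-id tie-break.
Pruning at the largest catchment of interest (`cutoff`) is the
supported scaling strategy; a dense matrix over a county-scale block
set would hold tens of billions of pairs and is explicitly not a
target.

## Reporting

Computation always uses every block, including the buffer ring;
reporting restricts to `in_report_region` blocks. Min–max
normalization therefore takes its range over report-region blocks only
— buffer blocks would distort the extremes. If all in-scope scores are
equal the normalized scores are defined as 0, with a warning.
Classification uses half-open `[b_i, b_{i+1})` classes with a closed
top bound, applied to unrounded scores; map legends that print rounded
boundaries ("2.01–3.00") imply rounding before classing, which this
package does not do. Summary standard deviations default to the
population form (divisor `n`), describing the realized distribution;
`sample_sd = TRUE` switches to `n - 1`. Method comparison
(`difference()`) classes per-block deltas by sign with an exact-zero
default tolerance, the right choice when both results come from the
same pipeline; `zero_tol` exists for cross-implementation comparisons.

## The synthetic generator

`generate_scenario()` emulates the structure of a real block-level
study area so every stage is testable without downloads:

| feature | default | rationale |
|---|---|---|
| lattice | 10×10 unit blocks | smallest shape with interior/edge contrast |
| buffer ring | width 1 | edge-effect mitigation as in real studies |
| population | log-normal, meanlog 5, sdlog 1 | heavy right tail; median ≈ 150/block, block-like |
| supply | Poisson, intensity 8·exp(−d/1.5) from 2 centers | downtown-style provider clustering |
| providers/block | uniform 1–6 | multi-provider markets |
| broadband tiers | divide 8%; DSL/cable/fiber 25/45/30 of the rest | guarantees sub-0.6 Mbps blocks exist |
| edge minutes | uniform 2–6 | 30-min catchments cover part, not all, of the lattice |

The tier is drawn per block and providers draw speeds within the
tier's range, so digital-divide blocks have *every* offering below
0.6 Mbps — the zero-weight path of the schedule is always exercised
(one divide block is guaranteed whenever its probability is positive).
The same seed yields byte-identical tables.

What the generator does **not** emulate: real street topology (it uses
a lattice), polygon geometry, spatially correlated broadband quality,
population–broadband correlation (income effects), or provider-level
reporting artifacts. Passing tests on these scenarios therefore
demonstrate the correctness of the *computation*, not calibration
against any real region; county-scale empirical results depend on
external data acquisition that is out of scope here.

## Problem sizes and tolerances

The test suite runs on lattices between 5×5 and 10×10 and random
irregular fixtures of 8–25 blocks — large enough to contain
unreachable pairs, zero-supply and zero-population blocks, broadband
gaps and digital-divide blocks, small enough that an exhaustive
triple-loop reference implementation and exhaustive simple-path
enumeration stay instant. Engine-versus-oracle agreement is asserted to 1e-12,
conservation to 1e-9 relative; both bounds are far below any
substantive effect size and only absorb floating-point summation
order.

## Known limitations

* Broadband quality is advertised speed only: latency, jitter, packet
  loss and peak-hour contention are not modelled.
* Supply is a provider count; capacity, specialty and appointment
  availability are not represented.
* The binary and step-wise models share one catchment radius for both
  steps; supply-side and demand-side radii cannot differ.
* No cartography: exports are CSV and GeoJSON points, styling is left
  to GIS tools.
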
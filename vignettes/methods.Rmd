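---
title: "Methods: movement-based slaughter surveillance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement-based slaughter surveillance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovimove)
```

`ovimove` turns batch-level sheep movement records into the quantities a
slaughterhouse-based surveillance design needs: deduplicated slaughter
populations, plant catchment areas, survey-coverage scores, regional
origin–destination matrices and a batch-size model. This vignette describes
the statistical procedures, the choices made where the methods were
genuinely open, and what the synthetic-data generator does and does not
emulate.

## Data model

A **batch movement record** is one recorded move: departure CPH
(County/Parish/Holding identifier), optional read-location CPH, destination
CPH, date, number of animals, number of EID reads. A **read record** is one
individual EID detection at a Critical Control Point (CCP: a market or
slaughterhouse), linked to a batch record. The **premises registry** maps a
CPH to its type (farm, market, slaughterhouse, other), country (Scotland /
rest-of-GB), region, parish and planar coordinates in metres (a British
National Grid-like plane; no geodesy is performed anywhere in the package).

Every movement is classified by its endpoints: `WITHIN` (both Scottish),
`OUT_OF` (Scottish departure, rest-of-GB destination), `INTO` (the
reverse). Records with no Scottish endpoint are out of scope and rejected.
Records that cannot be parsed or resolved are *quarantined with reasons and
counted*, never silently dropped: missing geography and unresolvable
records are themselves findings that a data-quality report must carry.
Counts always include quarantined records; only spatial stages exclude
them.

## Market-leg deduplication

Sheep sold through a market on the way to slaughter generate two batch
records — (1) holding departure, market read location, slaughterhouse
destination; (2) market departure, slaughterhouse read location and
destination — so summing naively double-counts those sheep. A market-leg
record (market → slaughterhouse) is removed when a matching first leg
exists with the same market as read location, the same destination plant,
and a date within `window_days`, and either

* **EID basis**: the tag sets read at the two CCPs overlap, or
* **count basis** (lower confidence, used only when either side has no
  reads): equal animal counts.

Choices the recording system leaves open, decided here: `window_days`
defaults to **1** — lairage transit is same-or-next-day, and a wider window
only adds false joins; matching is **greedy in date order and one-to-one**,
with ties broken by record identifier so reruns are identical; EID overlap
always beats count equality. The variables used to join batch and read data
in national practice are not standardised; the basis hierarchy above is
this package's documented convention. Deduplication is idempotent, and on
synthetic data with no mis-reads it recovers the generator's duplicate
pairs and true slaughterhouse totals exactly (this is tested).

"Origin" of a slaughter move always means the departure premises of the
move immediately prior to slaughter; batch data do not support lifetime
tracing. The deduplicated records partition into SISP (Scottish origin,
Scottish plant), SOSP (Scottish origin, rest-of-GB plant) — together the
SSSP — and the excluded non-Scottish-origin sheep slaughtered in Scotland.

## Hexagonal catchment grid

Catchments are mapped on a tessellation of congruent regular hexagons of
fixed area *A* (default **115 km²**, the conventional cell size for
national-scale catchment mapping; any positive area is accepted). The
circumradius follows from A = (3√3/2)R². Defaults, recorded in output
metadata because any congruent tiling is equally valid: flat-top
orientation, origin at the extent's lower-left corner. Coastline trimming
is replaced by an optional planar clip polygon (cells whose centres fall
outside are dropped); no polygon means no trimming.

Point-in-cell assignment exploits the fact that a regular hexagon tiling is
the Voronoi diagram of its centres: the containing cell is found by
axial-coordinate rounding and verified against its six neighbours by
Euclidean distance. A point equidistant (within 10⁻⁷·R) from two or more
centres lies on a cell boundary and is assigned to the **lowest incident
cell id** — an arbitrary but deterministic convention, since no standard
exists for boundary-straddling holdings. Points outside the grid are
flagged and counted. Tests verify the assignment against an independent
brute-force point-in-polygon oracle over all cells.

Holdings are located by precise coordinates when present, else by parish
centroid, else flagged unmappable; each point carries its provenance tag.
A catchment cell's sheep count is expressed as a percentage of the
reference population (SISP by default, SSSP on request); quarterly layers
use the plant's *annual* throughput as denominator so the four quarters sum
to the mappable share of 100%.

## Survey representativeness

Given a catchment (the cells with at least one supplying holding — cells
outside it are never categorized) and a survey of n distinct sampled
holdings, proportional allocation gives expected counts E_i = n·h_i/Σh.
Each cell's statistic χ²_i = (O_i−E_i)²/E_i is compared with a fixed
cut-off, default **2** (appropriate when the statistic's overall degrees of
freedom are large enough for a normal approximation; the cut-off is a
config parameter, not recomputed from the data). Categories: `not_sampled`
(O = 0), `adequate` (χ² ≤ cut-off), `oversampled` (χ² > cut-off, O > E),
`undersampled` (χ² > cut-off, O < E). Whether departures below expectation
should be folded into "oversampled" is ambiguous in the two-way
adequate/oversampled reading common in practice, so the four-way scheme is
the default with a `merge_undersampled` switch. A cell with E = 0 but O > 0
has an undefined statistic and is categorized oversampled by convention and
flagged. The sampling unit is the **holding** (distinct sampled holdings
per cell); sample-level weighting is out of scope. Samples without a CPH
and holdings outside the study country are excluded and counted.

## Regional origin–destination matrices

Non-slaughter, within-country moves are aggregated into a matrix over the
14 agricultural regions (departure rows, destination columns; intra-region
moves on the diagonal). Region order is fixed alphabetically so the
normalized "heat-map twins" are comparable across runs. Two normalizations:
departure (rows sum to 100%; all-zero rows reported absent) and destination
(columns). Quartile categories for plotting use type-7 empirical quantiles
of the **nonzero** entries at 0.25/0.5/0.75 with half-open bins — zeros are
a separate `none` category rather than pooled, since an absent flow is
qualitatively different from a small one, and no standard method is
attached to "quartiles of the observed distribution". Quarterly matrices
partition the records, so they sum to the annual matrix exactly.

## Batch-size model

Batch sizes (counts ≥ 1) are modelled as Poisson with a log link on the
movement-class factor, fitted separately for all movements and the
slaughter subset. With class as the only covariate the model is saturated:
exp(intercept) equals the reference-class sample mean and each
exponentiated coefficient is the ratio of class means — this closed form is
the module's test oracle (agreement to 10⁻⁸ relative). The reference class
is `INTO` by default, and exponentiated coefficients are printed under the
conventional "odds ratio" label although they are rate ratios. Real batch
sizes are heavily overdispersed (maxima near 1,400 against means near 16),
so the plain-Poisson Wald standard errors are optimistic; the default
follows the conventional plain-Poisson analysis, and a
`family = "quasipoisson"` switch provides variance-inflated standard errors
(point estimates unchanged) for honest inference. Wald interval coverage is
verified by simulation (500 Poisson replicates of 2,000 batches; coverage
within 95% ± 3 points).

## The synthetic-data generator

The generator produces datasets with the statistical structure the
analysis assumes, plus ground truth for every downstream stage (true
classes, duplicate pairs, true slaughterhouse totals, per-holding supply).
Defaults are the study conditions the analysis emulates:

| parameter | default | meaning |
|---|---|---|
| `p_missing_coords` | 0.35 | farms with no coordinates (parish centroid still known) |
| `p_misread` | 0.04 | each CCP read lost independently |
| `p_batch_only_sheep` | 0.15 | batch animals with no reads at all |
| `p_via_market` | 0.5 | slaughter moves routed through a market (dual records) |
| `p_cross_border_out` / `_in` | 0.48 / 0.022 | class mix of moves |
| `batch_mean_by_class` | 15 / 15 / 56 | mean batch size, all moves (within/out/into) |
| `slaughter_batch_mean_by_class` | 24 / 13 / 107 | mean batch size, slaughter moves |
| `monthly_intensity` | Sep max, Mar secondary, Jun min | month allocation weights |
| `dispersion` | 0.6 | negative-binomial size parameter |

Batch sizes are zero-truncated negative binomial — observed maxima far
exceed Poisson tails — with the *untruncated* mean solved numerically
(uniroot, tolerance 10⁻¹⁰) so the truncated mean equals the configured
class mean exactly; a Poisson option exists for GLM parameter-recovery
studies. Months are allocated multinomially from the intensity weights and
dates drawn uniformly within month; the published seasonal description
fixes only the September peak, a smaller March peak and a June trough, so
the 12 default weights interpolate that shape qualitatively and are
user-overridable. Regions are a 14-way rectangular partition of a planar
extent with coordinates uniform per region block; about 35% of
slaughterhouses are placed in-country and rest-of-GB premises sit south of
the extent. One master seed feeds independently derived named substreams
(premises, movements, census, samples), so adding a component does not
shift the draws of the others; identical configs are byte-identical.

What the generator does **not** emulate — hence what passing tests do not
show about real data: real British geography and region shapes, actual CPH
county codes, demographic/age structure (lambs vs ewes), holding-level
heterogeneity in market use, cross-border recording asymmetries, duplicate
or recycled EID tags, and seasonal covariation between batch size and
month. Oracle tests prove the pipeline's arithmetic is correct under the
stated assumptions; they cannot prove those assumptions hold in any real
traceability system.

## Numerical conventions and problem sizes

Percentages are reported to 1 decimal place in printed tables (raw counts
always retained); summary-table totals may be supplied explicitly when a
published table's totals include unclassifiable records, and percentages
are then taken of those totals. Degenerate inputs are values, not errors,
wherever a report must carry them (zero reads → excess absent; missing
census year → share absent; zero-area parish → density absent with a
warning). Tie-breaks are deterministic throughout (hex boundary → lowest
cell id; ranking ties → lowest CPH; dedup candidate ties → earliest date
then lowest record id).

The test suite exercises the oracles at sizes chosen to make sampling error
negligible while keeping a full run under half a minute: 10,000-move
simulations for the dedup and conservation oracles, 10,000 random points
for the hex-assignment oracle, 500 GLM replicates of 2,000 batches for
interval coverage, and exhaustive O ∈ 0..10 × E ∈ {0.5,…,10} grids for the
representativeness rule table.

## Known limitations

* Only the move immediately prior to slaughter is observed, so catchments
  reflect immediate origins, not lifetime residence.
* Count-basis dedup matches can join coincidentally equal batches when
  reads are missing on both sides; such matches are logged as lower
  confidence rather than suppressed.
* The chi-square cut-off of 2 is a pragmatic convention, not a calibrated
  test; with small expected counts per cell its type-I behaviour varies
  across cells.
* Cross-border reconciliation with non-Scottish recording systems is out of
  scope; out-moves that return via non-Scottish markets are not traced.
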
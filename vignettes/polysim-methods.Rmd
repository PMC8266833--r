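---
title: "Simulating template-based polymerization: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating template-based polymerization: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The modeling problem

Replication, transcription and translation are template-based
polymerization processes: a polymerase or ribosome binds a specific site on
a template, then advances position by position, consuming a monomer carrier
chosen by the motif it is currently reading (the nucleotide complementary
to the template base, or the charged tRNA matching the codon), until an
annotated stop is reached and a product is released.  Writing such a
process as ordinary mass-action chemistry requires one species and one
reaction per polymerase position -- thousands of reactions per gene -- and
the network explodes long before a genome is covered.

`polysim` avoids the explosion with a hybrid pool/particle state:

* **Pools.**  Freely diffusing chemicals (`FreeChemical`) are plain
  molecule counts.  A *buffered* pool keeps a constant count: it gates
  propensities and is formally consumed, but firings never change it
  (events do).  Template populations (`ChemicalSequence`) are pools too:
  a count of identical, immutable copies carrying annotations.
* **Particles.**  A sequence-bound molecule (`BoundUnit`) is tracked
  individually but minimally: the sequence it sits on, its current reading
  position, the binding site it came from, and whether it has translocated
  away from that site yet.  Particles are grouped into named classes
  (`BoundChemical`, e.g. "polymerase in loading phase"); reactions address
  classes, never individual particles, so one reaction set serves every
  gene at once.

Two bookmarking structures keep particle subsets reaction-ready in O(1):
a *family filter* (particles still sitting on a binding site of a given
family -- the only ones allowed to unbind) and a *template filter*
(particles partitioned by the motif under their reading window -- the unit
of template-directed loading).  Both are maintained incrementally at every
particle mutation, and `check_consistency()` can recompute them from the
raw particle population to audit the incremental bookkeeping.

## Reaction classes

Six reaction classes cover the processes above; their propensities are:

| class | propensity |
|---|---|
| `ChemicalReaction` | $k \prod_i (n_i)_{s_i}$ (falling factorials) |
| `SequenceBinding` (forward) | $n_{\text{free}} \sum_{\text{sites}} k_{on}(s)\,\mathrm{avail}(s)$ |
| `SequenceBinding` (reverse) | $\sum_{\text{units on origin}} k_{off}(s)$ |
| `Translocation` | $k \cdot \lvert \text{class} \rvert$ |
| `Loading` (per motif $m$) | $k_m \cdot n_{\text{carrier},m} \cdot \lvert \text{partition}_m \rvert$ |
| `Release` | $k \cdot \lvert \text{class} \rvert$ |

Falling factorials (`A + A` with $n$ molecules fires at $k\,n(n-1)$) keep
duplicate reactants exact and make firing impossible with insufficient
molecules.  Availability of a site is `copies - occupied`, where a site
stays occupied until its unit's *first* translocation -- this is why the
aggregated gene model hops its polymerase +50 bases before anything else:
it frees the promoter for the next initiation.

Switches implement annotation-triggered state changes: when a
translocation lands a particle exactly on a `SwitchSite` whose switch
accepts the particle's current class, it is reassigned immediately.
Skipped intermediate positions are *not* scanned, so codon-stepping
processes must annotate stops on the reading frame (the genome generator
guarantees this).  Transcription terminators, translation stops and the
T-box pause site are all switches.  A `Release` destroys the particle and
chooses the product by the particle's origin-site family and current
position in a disjoint interval table -- one table row per gene, which is
how a single termination reaction produces the right transcript for every
promoter.  An unmatched release position is an error by default, because
silent product loss hides model bugs.

## The exact SSA and its three selection structures

The solver is Gillespie's exact algorithm: with total propensity $a_0$,
wait $\tau = -\ln u / a_0$, pick channel $j$ with probability $a_j/a_0$,
fire it, refresh dependents.  Channel selection is pluggable:

* **direct** -- linear scan for the smallest index whose cumulative sum
  reaches $u \cdot a_0$; O(R) per event, O(1) per update.
* **tree** -- binary partial-sum tree; O(log R) for both.
* **cr** (default) -- composition-rejection: channels live in groups by the
  binary exponent of their propensity ($a_j \in [2^g, 2^{g+1})$); a group
  is chosen by composition over group sums, a member by rejection with
  acceptance $a_j / 2^{g+1} \ge 1/2$, so the expected number of rejection
  draws is below 2 and per-event cost does not depend on R.  The group
  list is scanned linearly; its length is bounded by the spread
  $\log_2(a_{\max}/a_{\min})$ of positive propensities, which is small in
  practice, so no group hierarchy is kept.

All three draw from one seedable 64-bit random stream per run, in a fixed
documented order (waiting time, channel, then firing-internal choices:
site before unit, motif partition before unit).  Identical (model, seed,
solver) therefore reproduces a trajectory bit for bit.

Correctness of the incremental propensity updates rests on a dependency
graph keyed on three component kinds -- free pools, bound classes (any
membership or position change marks the class), and site families
(occupancy or copy-number changes).  After each firing exactly the
dependent channels are recomputed.  The graph must be superset-correct;
`run_simulation(..., check_every = k)` verifies it during a run by
comparing every stored propensity against a from-scratch recomputation.
Numerical hygiene: stored totals, tree sums and group sums are refreshed
from scratch every $10^6$ updates to bound floating-point drift; selection
uses the first-channel-to-reach-threshold rule so boundary ties are
deterministic; a drift-induced overshoot falls back to the last channel
with positive propensity.

Timed events (`ADD`, `SET`, `REMOVE_FREE`) interleave exactly: when
$t + \tau$ crosses the next event time, the clock advances to the event,
the event is applied, and $\tau$ is discarded and redrawn.  By
memorylessness of the exponential clock this is exact; rescaling the
residual would be equally exact, and we chose the redraw for simplicity.
`REMOVE_FREE` clamps at zero and touches only the free pool -- a wash-out
removes free antibiotic while sequestered complexes persist.

## Kinetic parameters

Defaults live in `expression_params()` (all rates in 1/s):

* **Transcription**: translocation 50 (limiting), polymerization 500,
  effective NTP loading 600-2100 depending on the nucleotide.  The
  realized cycle speed is the harmonic composition
  $1/\sum_i 1/k_i \approx 43.5$ nt/s -- 10-25% below the headline
  "50 nt/s", which names the limiting step, not the cycle.
  `elongation_speed_oracle()` returns the harmonic value and the
  validation suite holds the simulator to it within 2%.
* **Translation**: charged-tRNA loading ~20 (limiting), transpeptidation
  150, translocation 150 with a 3 nt step; ~15.8 codons/s realized.
* **Replication**: translocation 750 (limiting), polymerization 10,000,
  dNTP loading 1000-10,000.  Okazaki fragments of 1000 bp at 750 bp/s
  give one lagging-strand polymerase recruitment per 1.33 s, encoded as
  $|DNAP_{free}| \times r_{recruitment} = 3/4$ with 10 polymerase copies
  and $r = 0.1$; the fork builder exposes the product as a single
  constant-propensity recruitment channel of exactly 0.75/s.
* **Initiation/termination** last about 1 s (release rate 1/s); binding
  itself is treated as instantaneous, which is negligible against
  elongation times of seconds to minutes.
* **Counts**: the cell volume is fixed at $10^{-15}$ L, so 1 mM is
  $6\times 10^5$ molecules (`concentration_to_molecules()`).  NTPs are
  buffered at 1 mM each; dNTPs at $10^8$; loading *rate constants* are the
  effective rates divided by the carrier pool, so the effective per-base
  rates above hold at the initial pools.

Desk-scale pool sizes (50 polymerases, 300 ribosomes, $8\times10^4$ bulk
tRNA, 2000 tyrosine tRNA, $10^6$ tyrosine) were chosen once so that a
10-gene cell is visibly machine-limited (most ribosomes engaged), charging
keeps up with consumption at steady state, and the tyrosine-tRNA pool
drains within tens of seconds of an amino-acid shortage.  Messengers and
proteins are not degraded and accumulate.

## What the synthetic genome emulates -- and what it does not

`synthesize_genome()` replaces a real annotation set with random genes
over ACGT that carry the same feature classes: a 10 nt promoter, the
transcription start, a leader with the ribosome binding site, an ATG, a
codon body sampled from the 61 sense codons (no internal stops, so a
ribosome never stalls on an unreadable motif before its annotated stop),
a stop codon, and a terminator closing the transcript.  Every gene also
draws a transcription-unit multiplicity of 1-4 equal-strength tandem
promoters, emulating genes carried by several transcription units: with
strictly equal single promoters, every gene's expected output would be
identical and a rank comparison between model granularities would compare
nothing but noise; with multiplicities, expected output differs by known
integer factors while all promoter strengths remain equal.

The generator does **not** emulate operon structure (one transcript per
gene), strand asymmetry (genes sit on one strand of a single
`ChemicalSequence`; a second strand would simply be a second sequence in
its own reading orientation), realistic codon usage, GC bias, or UTR
structure.  Passing tests on these genomes therefore demonstrates the
*simulator's* bookkeeping and kinetics, not genome-scale biology: absolute
protein numbers here are thousands, not the millions of a full cell.

Granularities: `detailed` simulates every nucleotide and codon with one
generic reaction set shared by all genes; `aggregated` keeps sequence-based
binding, hops the polymerase +50 bases to free the site, and produces the
product in one release whose rate carries the remaining elongation time --
two reactions (one translocation, one release) per gene and per process;
`hybrid` applies the detailed path to a seeded random fraction (default
5%) of genes.  Metabolite renewal is `constant` (buffered NTPs) by
default; `detailed` regenerates each consumed nucleotide through a
pseudo-metabolic reaction, and `stacked` regenerates stacks of 100 via a
stoichiometry-100 reaction -- under falling-factorial kinetics that channel
behaves as a threshold trigger that fires as soon as a stack is complete,
which is the intended semantics, and its propensity is clamped at a large
finite value to keep the arithmetic safe.

## Case studies

**Tetracycline.**  The antibiotic competes with charged tRNAs for
ribosomes in loading phase: a reversible `ChemicalReaction` with one bound
reactant and one bound product sequesters `R_loading` particles (position
preserved) with slow dissociation (0.01/s).  The overlay adds only a
file's worth of records to the unchanged base model: the chemicals, the
sequestration, an injection event at t = 200 s and four wash events from
t = 400 s that clear the free pool only.  Doses of 0, 20,000 and
1,000,000 molecules give strictly decreasing final protein counts; the
sequestration constant ($10^{-6}$/s per molecule) was set so the small
dose inhibits partially rather than saturating.

**T-box attenuation.**  A switch site in the regulated gene's leader sends
the elongating polymerase into a paused `tbox_RNAP` state.  Uncharged
tyrosine tRNA resumes elongation; charged tyrosine tRNA diverts to an
aborting state whose release emits an annotated aborted transcript.
While tyrosine is abundant the charged pool dominates and full-length
messengers stay near zero; depleting tyrosine at t = 200 s stops charging,
translation drains the charged pool within tens of seconds, and
full-length transcripts accumulate until re-injection at t = 600 s
restores attenuation.  The miniature runs on the fully detailed base
model: with only the regulated gene detailed, no translation would consume
tyrosyl-tRNA and the charged pool could never drain.

## Validation oracles and problem sizes

Every stochastic component is held against an independent reference:
exact event counts of closed cascades (an n-cascade with $10^6/n$ initial
molecules fires exactly $10^6$ times, any solver, any seed);
Kolmogorov-Smirnov tests of waiting times against the exponential law;
selection frequencies of all three structures against $a_j/a_0$; terminal
counts of a reversible isomerization against the binomial stationary law
and against each other across solvers; the Erlang transit mean through a
cascade; the harmonic elongation law on a 10,000-base single-polymerase
raceway; and the 1.33 s recruitment interval of the Okazaki clock within
three standard errors over $10^4$ events.  Statistical decisions use
$\alpha = 0.01$ with Bonferroni correction inside `run_validation()`.

The shipped test and acceptance runs use desk-scale sizes chosen as a
deliberate study design: 10-gene genomes of 300-600 nt, 300 s expression
runs (600 s for tetracycline, 800 s for the T-box schedule), 20 replicates
for the granularity comparison, 2000 replicates for cross-solver
equivalence, and cascades up to $R = 10^5$ reactions for the
selection-structure scaling comparison, where composition-rejection
per-event cost stays within 3x while the direct method grows by orders of
magnitude.

## Known limitations

Bound particles do not interact: no polymerase or ribosome collisions, no
queueing along the template, no complex formation between particles.
Sequences are immutable -- no mutation, cleavage or degradation; products
accumulate.  A particle class may carry at most one template filter (one
loading motif length), and a release that both frees and re-creates bound
state is out of scope.  Replication is single-origin and single-fork;
multifork re-initiation is not modeled.  The model dialect is this
package's own, documented in `parse_model()`; it is deliberately not
claimed compatible with any other simulator's input format.
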
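---
title: "Reconstructing extended Petri nets from discrete time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing extended Petri nets from discrete time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrirec)
```

## Model and assumptions

`petrirec` treats a regulatory or signal-transduction system as an
*extended Petri net*: places hold integer token counts (one place per
measured component or component form), transitions move tokens along
weighted standard arcs, and two kinds of control arcs gate firing without
moving tokens — a *read arc* requires at least one token in its place
(catalysis: an enzyme, or a gene acting as a Berzelius-style catalyst of a
downstream reaction), an *inhibitory arc* requires its place to be empty.
The reconstruction problem is: given discrete time series of the places'
values from one or more experiments, return **every** minimal net of this
class able to replay the data.

The method rests on a small set of assumptions:

* **Discrete, discretised input.** Values are integers (usually 0/1).
  Discretisation and statistical preprocessing are deliberately outside the
  package: the readers reject non-integer values rather than binning them,
  so that no hidden modelling decision enters here.
* **Adequate sampling.** Consecutive measurements are assumed to capture
  every macroscopic change once; sub-sampling artefacts (missed transient
  pulses) are the experimenter's responsibility. Fast, unresolvable cycles
  such as individual enzyme–substrate turnovers are exactly what read arcs
  exist to abstract away.
* **Monotone steps.** Between two compiled states the system moves by a
  finite multiset of reaction firings whose effects do not cancel: each
  candidate reaction vector is sign-compatible with the observed
  difference.
* **Terminal states are dead.** A state flagged terminal enables no
  transition in any admissible net. This is the single most powerful
  constraint: it is what turns "which controls *could* exist" into "which
  controls *must* exist".

## The pipeline and its tunable parameters

`compile_state_matrix()` removes consecutive duplicates per experiment,
concatenates experiments (never interleaves; indices are global and
0-based in all output), and flags an experiment's last state terminal when
the raw series ends in a repeated measurement or the caller declares it so
(`terminal = TRUE`). Auto-detection exists because simulated data expose
dead states naturally; raw laboratory data cannot, hence the explicit
flag.

`difference_matrix()` lists each distinct nonzero consecutive difference
once, with all witnesses; differences are never taken across experiment
boundaries.

Parameters that matter, with defaults and rationale:

* **`capacity`** (default: the maximum value observed per component; 1 for
  boolean data). Capacities bound *applicability*: a reaction is
  applicable to a state iff the successor stays within `[0, capacity]`.
  The same bound is applied on the output side of the forward token game
  (a transition that would overfill a place is disabled). The data-driven
  default is the weakest bound consistent with the observations; it can be
  overridden in `run_config(capacity = ...)`.
* **Place invariants** (`auto_invariants`, `nominate`, `invariants`).
  A P-invariant is a non-negative weight vector whose weighted token sum
  is conserved by every reaction. We detect all 0/1 *place pairs* whose
  unweighted sum is constant **within each experiment segment** — the
  value may differ between experiments, because a deletion mutant starts
  without the protein whose two forms the invariant couples. (A globally
  constant definition would find nothing in mutant panels.) Larger sets
  must be nominated explicitly, and user-supplied weight vectors are
  verified against the data, never trusted. Invariants act as a
  pre-filter on candidate reaction vectors (`weights · r = 0`), which is
  the only reading under which they shrink the reaction vector matrix.
  Conservative by design: a wrongly assumed invariant silently removes
  true solutions, a missed one only costs enumeration time.
* **Combinatorial guards** (`max_candidates`, `max_decompositions`,
  `max_permutations`; default 10⁴ each). Dense difference vectors explode
  combinatorially; exceeding a guard is a hard, clearly attributed error
  (`petrirec_cap_error`, CLI exit 4), never silent truncation.
* **`qm_variable_cap`** (default 24). Exact minimisation only; beyond the
  cap the package refuses rather than approximates.

## Control-function derivation

For each surviving ordered sequence of reaction vectors, each reaction `r`
is applied at known markings (observed states plus the intermediate `y`
states of that sequence, pooled over all witnesses): there `f_r = 1`. At
every flagged terminal state where `r` is applicable, `f_r = 0`. Every
other marking is a **don't-care** — including non-terminal states where
`r` was applicable but not observed to fire. This preserves Petri-net
nondeterminism: the data say what *did* happen and what *cannot* happen at
dead states, nothing more. (The observed trajectories themselves justify
this: at many states several reactions were applicable and only one fired.)

Three groups result: reactions applicable at no terminal need no control
(`f ≡ 1`, group I — by minimality no control arcs are added); reactions
applied at a marking identical to an applicable terminal admit no function
(group II, the sequence is deleted); all others (group III) get **all**
minimum DNF covers over place presence/absence literals. Candidate
literals range over *all* places — control may emerge from anywhere — and
minimisation prunes the uninformative ones.

The minimiser is the exact Quine–McCluskey procedure specialised to this
encoding: for each on-state, the prime implicants covering it are the
minimal hitting sets of the per-off-state disagreement sets (a conjunction
of literals fixed by the on-state excludes an off-state iff it contains a
literal on a place where the two markings disagree); a Petrick-style
exhaustive selection then returns every cover with the minimum number of
terms and, among those, the minimum total literal count. **All** optima are
kept and ordered canonically (term count, literal count, lexicographic):
equally small covers are precisely the alternative molecular mechanisms
the method is designed to surface — catalysis by one component versus
inhibition by its counterpart form is the recurring biological pattern.
Control literals are presence/absence only; capacities above 1 in a
group III reaction would require threshold logic and are rejected with a
clear error.

## The catalog and composition

Each distinct difference vector owns a catalog column holding every
surviving alternative: one alternative = one ordered controlled-reaction
sequence with one concrete minimum cover per reaction. Any column-wise
selection composes into a net (transitions with identical standard and
control arcs merge); the enumeration order is a mixed-radix counter over
column indices, so "the first solution" is reproducible. Identical
reaction vectors appearing in *different* columns keep their per-column
controls by default; `merge = "strict"` pools their on-states and rejects
compositions that break on/off separation.

Every composed net is verified by replay: each observed step must fire
through exactly the selected sequence and its intermediates, and every
flagged terminal state must be dead. An empty column is a diagnosed
failure (`petrirec_infeasible_error`, CLI exit 3) naming the difference
vector — the package never invents additional places to rescue
feasibility; that extension is explicitly out of scope.

## What the synthetic generators emulate — and what they do not

`toy_net()` is a six-place didactic system *constructed* to exhibit the
canonical worked example (7 candidates for its first difference; a split
into `r4 + r5` with two orderings and distinct intermediates; exactly the
two controls `f = A` and `f = ¬F` for `r4`). Its wiring is a synthetic
stand-in satisfying those documented constraints, not a transcription.

`pho_regulon()` packages the phosphate-starvation regulon case:
16 components, 11 experiments encoded as initial-marking changes
(nutrient additions, gene deletions, phosphorylation-site deletions), 46
compiled states with 10 terminal flags. The state table is transcribed
from printed data and checksummed; the generating net is transcribed from
the published figure's narrative and validated by exact replay of all 46
states before being frozen into the fixture. Two transcription choices
were forced: the experiment segmentation (the printed header is
typographically ambiguous; we adopt the unique split whose first states
equal the documented initial markings and whose segments all replay), and
the split of the 19 printed reaction columns into 11 difference vectors
plus 8 decomposed parts (the 11 are exactly what recomputation from the
states yields).

`random_instance()` emulates small in-silico screens: boolean capacities,
distinct single-token reaction vectors, at most one control arc per
transition drawn outside the transition's own support, random token game
to deadlock. It does **not** emulate noise, missing observations,
multi-valued levels, multi-arc control conjunctions, or unobserved
components — a green round-trip test therefore establishes completeness
of the enumeration at oracle scale, not robustness to dirty data.

## Numerical and degenerate-input choices

Everything is exact integer arithmetic; there are no tolerances. Ties
among equally minimal covers are all kept (canonical order as above).
Degenerate inputs have defined behaviour: a single-state matrix gives a
zero-column catalog whose unique composition is the empty net; an empty
off-set gives the constant-true control; overlapping on/off sets are a
typed error that propagates to group II deletion; compiling an
already-compiled matrix is the identity.

## A published count the exhaustive algorithm cannot reproduce

The case study's published analysis — computed **manually** — reports
alternative wirings for exactly four reactions. The exhaustive
implementation finds alternatives in eight of the eleven catalog columns,
a strict superset containing those four. The discrepancy is provable from
the printed state table alone. Example: the transporter re-phosphorylation
reaction fires at exactly one state, where *both* phosphate pools are
marked (`pi-pp = pi-cp = 1`), and it is applicable at seven terminal
states, all of which have `pi-pp = pi-cp = 0`. The published control
(catalysis by periplasmic phosphate, `f = pi-pp`) and the unpublished one
(catalysis by cytoplasmic phosphate, `f = pi-cp`) separate these on/off
sets equally minimally; an exact minimiser must return both. The same
pattern adds covers to the PhoU-deactivation and PhoB-dephosphorylation
columns, and surviving two-part decompositions make the phosphotransfer
and organic-phosphate-degradation columns ambiguous as well. The
acceptance test asserts the published count of 4 and is left failing
deliberately, with this analysis as its documentation; the substantive
claims — the generating wiring is recovered by one column-wise selection,
every enumerated net replays, all published alternatives are present —
all hold and are tested. An independent prototype implementation produced
identical per-column counts (4·1·1·1·2·5·18·6·2·4·8).

## Known limitations

* No transition priorities or kinetics: the firing policy hook exists, but
  ranking alternative nets by rates is out of scope.
* No automatic introduction of hidden places when reconstruction is
  infeasible; the tool reports *which* difference vector failed instead.
* Control is presence/absence only (no thresholds, no weights on control
  arcs).
* Exhaustiveness is exponential by nature; the guards make the cost
  explicit rather than removing it. Dense multi-valued differences are
  outside the practical envelope.
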
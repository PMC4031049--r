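---
title: "Screening and classifying synthetic lethal reaction pairs in metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and classifying synthetic lethal reaction pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synlethal)
```

## The model and the question

A constraint-based metabolic model consists of a stoichiometric matrix
$S$ (rows: internal metabolites, columns: reactions), flux bounds
$l \le v \le u$ in mmol/(gDW·h), gene–protein–reaction (GPR) rules, and a
biomass pseudo-reaction whose flux $\nu$ is read as the growth rate. Flux
balance analysis (FBA) predicts a growth phenotype by solving

$$\max_v\; \nu \quad \text{s.t.}\quad S v = 0,\; l \le v \le u ,$$

a linear program. A reaction is *essential* when forcing its flux to zero
(both directions at once) drives the optimum below a small fraction of
wild-type growth. A *synthetic lethal* (SL) pair is two individually
dispensable reactions whose simultaneous deletion abolishes growth: the
network tolerates either failure alone but not both.

This package screens all candidate reaction pairs exhaustively and sorts
the SL pairs into two mechanisms:

* **PSL (plasticity)** — exactly one member carries flux in the reference
  optimum. The silent member is a *backup*: it activates only when its
  active partner is removed, generally at lowered growth, while removing
  the backup itself leaves growth untouched.
* **RSL (redundancy)** — both members carry flux in parallel. Removing
  either one caps growth at the surviving branch's capacity, so parallel
  use typically buys extra fitness (`fitness_increased`).

Predicted pairs can contradict in-vivo gene essentiality: if a member's
gene is experimentally essential yet regulates only that one reaction, the
prediction is flagged an inconsistency (`PSL_I`/`RSL_I`). A plasticity pair
whose two members are catalyzed by one multifunctional enzyme, or by the
same isoenzyme family, is likewise flagged: its reaction-level double
knockout does not correspond to any double gene knockout.

## Candidate space

Pairs are formed only over reactions that are

1. *gene-associated* — spontaneous and orphan reactions are excluded as
   knockout candidates, but their fluxes stay available to the network
   (deleting them outright would distort growth phenotypes; a flag
   reproduces the harsher reading);
2. *active-capable* — able to carry flux in the medium at **any**
   non-negative growth rate. This uses a deliberately conservative variant
   of flux variability analysis in which the biomass flux is left
   unconstrained ($\nu \ge 0$) rather than pinned near its optimum, so
   routes that only operate in low-growth states still qualify;
3. *non-essential* as single deletions.

## Alternate optima and the reference solution

Plain FBA optima are degenerate: which of several equivalent flux
distributions the solver returns is an artifact of its pivoting order, and
the PSL/RSL split reads per-reaction activity off that solution. The
default mode `flux_minimized` therefore fixes $\nu$ at its optimum and
minimizes total absolute flux (parsimonious FBA) via the split
$v = p - q$, $p, q \ge 0$. This makes activity calls deterministic and
backend-independent; `raw` mode exposes the first-stage vertex for
comparison. Growth *values* (wild type, single and double knockouts) do not
depend on the mode. A pair whose members are both at zero flux in the
reference solution contradicts its own candidacy and raises an error
rather than a silent call — it indicates `raw` mode on a degenerate
optimum.

## Linear-programming backends

The default backend is a dense two-phase primal simplex written for this
package, using Bland's anti-cycling rule throughout. Bland's rule is
slightly slower than steepest-descent pivoting but deterministic and
cycle-proof, which is what makes screen outputs byte-reproducible. The
alternative backend `"highs"` hands each problem to the HiGHS solver
through a small bundled Python helper and serves as an independent
cross-check; the test suite additionally re-implements the whole screen in
Python/scipy and compares every quantity on one hundred generated
fixtures. All bounds must be finite (models carry ±1000 defaults): an
unbounded FBA objective means a missing exchange constraint, not a
meaningful optimum.

Numerical choices: feasibility/pivot tolerance $10^{-9}$; zero-flux
threshold `flux_epsilon` $= 10^{-9}$ (absolute, bounds are $O(10)$);
no-growth threshold `growth_epsilon` $= 10^{-6}$ *relative* to wild-type
growth, so the call is invariant to the scale of the biomass equation.
Knockout means fixing both bounds to zero; reversible reactions are a
single signed variable whose two directions are removed together.

## Network distances and pathway entanglement

Metabolism is also represented as a bipartite directed graph: metabolite →
reaction when consumed, reaction → metabolite when produced, both
orientations for reversible reactions. The distance between two reactions
counts the *intermediate nodes* (metabolites and reactions, endpoints
excluded) on the shortest directed path, so two reactions coupled through
one shared metabolite are at distance 1. Pair distances are symmetrized by
taking the minimum over both orientations; this choice is configurable
(`symmetric = FALSE`). Note that in minimal toy models whose biomass is a
pure sink, parallel irreversible branches are mutually *unreachable* along
directed paths — finite distances require reversibility or downstream
re-use, which genome-scale networks have in abundance. No
currency-metabolite pruning happens by default, because hub metabolites
(ATP, water) shortcut paths; an explicit exclusion list is supported and
recorded in the graph's metadata.

The entanglement graph summarizes SL interactions at the pathway level:
every PSL pair adds weight 1 to a directed edge from the backup member's
pathway to the active member's pathway; every RSL pair adds weight 1 to an
undirected edge; intra-pathway pairs create self-loops. Edge weights per
subtype always sum to the number of annotated pairs of that subtype.

## Media machinery

A medium is a set of exchange lower bounds (uptake is negative flux;
unlisted exchanges close to zero uptake with secretion still allowed, and
applying a medium is idempotent). Minimal-media panels vary one elemental
source (C/N/P/S) at a time against a fixed salt background, filtering
inviable combinations by FBA. Enrichment adds compounds at
−10 mmol/(gDW·h) — the conventional uptake allowance — skipping compounds
the model cannot take up, and can only increase optimal growth (the
feasible region grows). Overconstraining reduces attainable growth in two
FVA-driven ways: fixing biomass at a fraction of its optimum and adopting
the salt uptakes that growth level requires, or scaling the maximal-growth
uptake limits of the four element sources. Media sensitivity re-tests each
pair's lethality in every panel medium and re-reads its subtype off that
medium's parsimonious solution, so subtype switches reflect the
environment rather than solver drift; "rescued" is decided on lethality
alone, and subtypes are compared only for conserved pairs.

## The synthetic-data generator

`make_toy_model()` composes small networks from motifs with closed-form
truth, each hanging off the shared biomass reaction through private
metabolites so truths compose; `fixture_specs()` / `fixture_suite()` build
seeded batteries of them. With the common uptake $u = 10$ mmol/(gDW·h):

| motif | algebra | planted truth |
|---|---|---|
| `linear_chain` | wild type $u$ | every chain reaction essential |
| `psl_backup` (yield ratio $r>1$) | active KO → $u/r$, backup KO → $u$ | PSL pair, roles known |
| `rsl_parallel` (capacities $c_1,c_2<u$, $c_1+c_2\ge u$) | single KO → surviving $c$ | RSL pair, `fitness_increased = TRUE` |
| `isoenzyme_pair` | as `psl_backup` | PSL pair flagged `PSL_I` |
| `dead_branch` | blocked | excluded from candidates |
| `medium_dependent_backup` | rescue nutrient opens a third route | pair lethal only in media lacking it |

Randomization permutes identifiers, row order and parameters within safe
ranges but never the motif topology, so truth stays derivable. Two design
notes: capacities at or above demand would make a "parallel" pair
degenerate — any vertex solver then routes all flux through one branch and
the pair is classified PSL (the equal-yield limit), which is why the
generator keeps capacities strictly below demand, and why a
fitness-unchanged RSL pair cannot arise from this motif family at all;
and a deliberately *entangled* variant (`toy_entangled_model()`, three
routes sharing one intermediate, no lethal pair) guards against
over-counting.

What the generator does **not** emulate: cofactor coupling, compartments,
thermodynamic constraints, realistic degree distributions, or GPRs beyond
small complexes and isoenzyme families. Passing the fixture battery
therefore validates the screening *logic* — candidate filters, exhaustive
enumeration, classification, bookkeeping — not the biological fidelity of
any particular genome-scale reconstruction, which enters solely through
the SBML-FBC/JSON/TSV readers.

## Problem sizes and determinism

The shipped tests run the full pipeline against an independent
Python/scipy re-implementation on 100 seeded fixtures (4–20 reactions
each), check 200 nested deletion sets for growth monotonicity, and
enumerate all pairwise distances against a hand-rolled BFS on several
fixtures — a few seconds each on one core. Identical configurations
reproduce byte-identical output tables in `flux_minimized` mode; tables are
ordered lexicographically and floats printed at full precision.

## Worked example

```{r example, eval = FALSE}
fx <- fixture_specs(1, 0)$kitchen_sink   # every motif type in one model
res <- run_full_analysis(fx$model, fx$medium, out_dir = tempfile(),
                         panel = fx$truth$media)
res$pairs[, c("rxn_a", "rxn_b", "subtype", "active_reaction")]
res$summary$class_counts
```

## Known limitations

* The isoenzyme/multifunctional detection is heuristic (identical
  single-gene GPRs, or identical OR-only families); curated calls can be
  supplied as an explicit pair list, which is the faithful path when an
  annotation exists.
* Gene-level (GPR-propagated) double knockouts are out of scope: the
  screen deletes reactions directly, and genes enter only through
  inconsistency flagging and reporting.
* The pure-R simplex targets the desk-scale models this package generates
  and reads; genome-scale screens (thousands of reactions, millions of
  pair LPs) want a compiled solver behind the same backend contract.
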
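---
title: "Methods: problem semantics, objectives and the reference simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: problem semantics, objectives and the reference simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem model

A parameter estimation problem couples four ingredients: a dynamical model
(SBML reaction network), a set of *experimental conditions* that each
override selected model entities, an *observation model* mapping model
states to measurable quantities with an explicit noise distribution, and
the *measurements* themselves, each linked to an observable, a simulation
condition, a time point, and optionally a pre-equilibration condition and
measurement-specific override parameters. A fifth table fixes which
parameters are estimated, on which scale, within which bounds, and with
which initialization prior. A YAML file groups the files; several
measurement, condition or observable files are concatenated in listed
order, which supports assembling problems from reusable parts.

`petabkit` keeps the tables as canonical data frames. Columns outside the
v1 vocabulary are preserved verbatim through read/write round-trips and
ignored otherwise; extension columns are how downstream methods attach
application-specific information without breaking other consumers. The
condition table is the exception: there, every non-identifier column *is*
semantic (an override target), so unknown targets are a lint error rather
than an extension.

Three table-cell conventions matter enough to state explicitly:

* Cells inside `observableParameters` / `noiseParameters` are
  semicolon-separated lists. TSV fields cannot contain tabs and decimal
  commas are never used, so `;` is the only safe list separator.
* An empty cell, the empty string and a literal `NaN` all mean "no value".
  TSV dialects written by spreadsheets and by pandas differ here, and the
  distinction carries no meaning in v1, so they are unified on read.
  Crucially, an *empty species cell* in a condition used with
  pre-equilibration is not zero: it requests carrying over the equilibrated
  state (see below).
* Measurement time `inf` (case-insensitive) denotes a steady-state
  measurement. It is evaluated at the post-equilibrated state of the
  simulation condition; this keeps the time field total without inventing
  new semantics.

# Override resolution

The value an entity takes during one simulation is resolved through a
fixed precedence, lowest to highest:

1. the default in the SBML model;
2. the parameter table, for model parameters that appear there — the
   nominal value if fixed, or the free parameter itself if estimated;
3. the condition table column for the simulated condition — a numeric cell
   is literal, an identifier cell chains exactly one step into the
   parameter table.

Placeholder symbols (`observableParameter{n}_<observableId>`,
`noiseParameter{n}_<observableId>`) are orthogonal to this chain: they
exist only inside observable and noise formulas and are bound per
measurement row from the corresponding override cells. Because their names
are reserved, a placeholder can never collide with a condition-table
target, so no tie-break between the two mechanisms is needed. The number
of list entries in an override cell must equal the highest placeholder
index in the formula; a mismatch is a lint error rather than a silent
recycling. Identifier chains deeper than one level (a condition cell
naming a parameter whose "value" would name another parameter) are
rejected — one indirection covers the intended use, and deeper chains are
almost always spreadsheet errors.

Measurements sharing a simulation job may carry different placeholder
bindings. The package therefore stores placeholder bindings per
measurement row inside the resolved mapping and evaluates observables
per row after one shared simulation; this is what makes time-point
specific overrides work without re-integrating the ODE.

Replicate measurements are independent rows everywhere: each contributes
its own residual to the objectives. `replicateId` only affects
visualization grouping. Averaging replicates before fitting changes the
statistical weight of time points and is deliberately not done.

# Pre-equilibration

Many experiments start from a system in a steady baseline state that is
not known in closed form. Such setups are modelled by integrating the
pre-equilibration condition to an apparent steady state, then switching to
the simulation condition. On the switch, exactly the species that the
simulation condition assigns a value (numeric or via parameter) are
reinitialized; all other states carry over. The steady state is found by
integration over geometrically growing horizons (initial horizon 100 time
units, factor 10, cap `1e10`) until
`max|dx/dt| < atol + rtol * max|x|` with defaults `atol = 1e-10`,
`rtol = 1e-8`. Long-time integration was chosen over Newton root-finding
because it is robust for the supported model subset, needs no Jacobian
machinery, and matches the "apparent steady state" reading; models without
a steady state (e.g. constant production) fail with a typed
equilibration error once the horizon cap is reached.

# Objectives

Residuals are computed on the observable's transformation scale, with the
noise parameter interpreted on that same scale, so that the chi-square is
exactly the exponent sum of the corresponding normal likelihood on every
scale. The per-point negative log-likelihood terms are

| scale | normal | Laplace |
| --- | --- | --- |
| lin | ½ln(2πσ²) + ½r² | ln(2σ) + \|r\| |
| log | ½ln(2πσ²y²) + ½r² | ln(2σy) + \|r\| |
| log10 | ½ln(2πσ²y²ln²10) + ½r² | ln(2σy·ln10) + \|r\| |

with r the transformed standardized residual. The y-dependent terms are
the change-of-variables Jacobians: without them the log-scale "likelihood"
would not be a density in the measured value. The test suite verifies all
six combinations by numeric quadrature (each density integrates to 1
within 1e-6) — an independent check that the formulas, not just their
implementation, are right.

Priors inform startpoint sampling only; they are not added to the
objective. Penalized/Bayesian use of priors belongs to downstream
optimizers and samplers, which are out of scope here, and silently mixing
a prior into `nllh` would make objective values incomparable across tools.
Startpoints are drawn per parameter (`parameterScale*` priors directly on
the estimation scale, the other priors on linear scale and then
transformed; no prior means uniform on the scaled bounds) and clipped to
bounds. Clipping slightly inflates boundary mass for wide priors; for the
usual case — bounds spanning several orders of magnitude — the effect is
negligible, and it guarantees feasible startpoints, which is what
optimizers need.

# The reference simulator

The simulator intentionally supports a restricted SBML subset: reactions
with kinetic laws, assignment rules (substituted symbolically into the
laws), constant compartments, concentrations (amounts are converted once
on load), initial assignments evaluated at load time. Events, algebraic
and rate rules, delays and function definitions mark a model as
non-simulatable while keeping it loadable for mapping and validation —
format validity must not depend on simulator capabilities. The ODE
right-hand side is assembled symbolically as
`d[s]/dt = (1/V_s) Σ_r n_{s,r} · rate_r`, compiled to R expressions, and
integrated with `deSolve::lsoda` at `rtol = 1e-8`, `atol = 1e-12`. These
tight defaults make the simulator reference-quality: fixture comparisons
use 1e-6 tolerances, three orders of magnitude above the integration
error, and a tolerance-halving check in the tests confirms convergence.

# The generated test problems

The sixteen problem categories (basic simulation; multiple conditions;
numeric/parametric initial concentrations, compartment sizes, and
condition overrides; numeric/parametric observable and noise overrides;
log and log10 observable transformations; full and partial
pre-equilibration; replicates; time-point specific overrides) are all
built on the reversible conversion A ⇌ B with defaults `k1 = 0.8`,
`k2 = 0.6`, `A(0) = 1`, `B(0) = 0` in a unit compartment. One linear model
everywhere is a deliberate choice: it admits exact closed forms for every
semantics variant — trajectory, steady state, and partially reinitialized
restart — so every expected value is analytic, and published minimal test
problems for this format follow the same pattern. Measurement values are
the closed-form outputs plus normal perturbations (SD 0.1, multiplicative
on log-scale cases) drawn under a per-case seed derived from one base
seed, so chi-square is nonzero, Jacobian terms are exercised, and
regeneration is byte-identical. Expected chi-square and likelihood values
are computed from the closed forms through `dnorm`-based densities — a
code path disjoint from the simulator and objective modules, which is the
point of the exercise.

What passing these fixtures does *not* show: behaviour on stiff or
high-dimensional models, on models with events or time-dependent inputs,
performance at scale, or identifiability of real problems. The fixtures
probe format semantics, not numerics of hard ODE systems.

Problem sizes are kept small by design — 4–6 measurements per case, a
two-state model, quadrature on six density combinations, 10 000 draws for
the sampling checks — so the complete test suite and the acceptance script
each finish in seconds on a single core.

# Numerical and design corner cases

* Numbers are written with up to 15 significant digits (`%.15g`),
  round-tripping doubles without visual noise like `0.30000000000000004`.
* The expression grammar is the intersection of SBML math and common infix
  notation; booleans are encoded 1/0, `piecewise(value, condition,
  otherwise)` may evaluate all three arguments (no short-circuit
  guarantee). Parsing is whitespace-insensitive with standard precedence
  and a right-associative power operator.
* The YAML schema (`format_version`, `parameter_file`, `problems:` list
  with `sbml_files`, `condition_files`, `measurement_files`,
  `observable_files`, optional `visualization_files`) is documented here
  as this package's dialect; the format's main description does not pin
  the key names.
* COMBINE archives are written as stored (uncompressed) zip entries with a
  standard OMEX manifest; the YAML problem file is the master entry.
  Compression buys little for kilobyte-sized TSVs, and stored entries keep
  the writer dependency-free and byte-reproducible.
* Lint severities: referential or structural breakage is an error;
  suspicious but runnable situations (nominal value outside bounds,
  estimated parameter never referenced, unknown plot type) are warnings.
  `assert_petab_valid()` blocks on errors only.

# Known limitations

* One SBML model per problem; multi-model problems are out of scope.
* No symbolic gradients or sensitivities — the package specifies and
  scores problems; fitting belongs to optimization toolboxes.
* Finite-horizon pre-incubation (equilibrating for a fixed duration rather
  than to steady state) is not implemented; pre-equilibration is
  steady-state only.
* The visualization table implements the time-course and dose-response
  plot families with mean ± sample-SD replicate aggregation; more exotic
  layouts are preserved as data but not rendered.
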
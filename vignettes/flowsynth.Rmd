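---
title: "Bounded workflow composition as satisfiability: the flowsynth method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded workflow composition as satisfiability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowsynth)
```

## The problem and the model

A *domain model* consists of a taxonomy and a set of annotated tools. The
taxonomy has one **operation dimension** and `k >= 1` **data dimensions**
(typically *data type* and *data format*); each dimension is a rooted DAG
of IRI-identified terms under subsumption, and the dimensions are disjoint
term sets. A tool is annotated with the operation terms it performs and
with ordered input and output **slots**; each slot carries, per data
dimension, a non-empty set of acceptable terms — more than one term is a
disjunction *within* that dimension (e.g. format "mzML or mzXML").
Cross-dimension alternatives ("type A with format F, or type B with format
G") are deliberately out of scope of one slot and require two tool
entries, matching the tabular style of registry annotations.

A *workflow specification* lists concrete available inputs (one term per
dimension), requested outputs (possibly abstract; an omitted dimension
means the dimension root, i.e. "anything"), constraints, and the bounds
`min_length`, `max_length`, `max_solutions`.

Disjunctive **outputs** are resolved before search: a tool with an output
disjunction can produce different concrete data depending on how it is
run, so each tool is expanded into **modes**, the full cross-product of
its output disjunctions, enumerated in lexicographic term-id order
(`msconvert@01..03` for a 3-way format disjunction). A solution's identity
is its step-wise *mode* sequence.

## Execution semantics

The engine uses a **cumulative shared memory**: all workflow inputs and
all outputs of earlier steps remain available to every later step, an
instance may feed several slots, and two slots of one step may read the
same instance. A step is executable when every input slot of its tool can
be bound to some available instance whose term in *every* dimension is
subsumed by an acceptable slot term (abstract terms are
descendant-closed). The specification is met when, at the end, every
requested output is matched by some memory instance under per-dimension
subsumption — workflow inputs included, which is why a 1-step workflow can
satisfy a request its input already fulfils; the default `min_length = 1`
merely forbids the empty workflow.

A useful consequence of cumulative memory, exploited throughout the
verification module: slots bind independently, so "an executable binding
exists" decomposes into per-slot existence checks. This is what makes the
brute-force oracle cheap and the `use_type` semantics crisp (below).

## CNF encoding

For each length `n` in `min_length..max_length`, `encode_problem()` emits:

* `tool(i, m)` with exactly-one (at-least-one + pairwise at-most-one) per
  step — one tool per step; data-level parallelism is recovered in the
  exported data-flow graph, not in the encoding;
* `bind(i, s, x)` with pairwise at-most-one per slot, at-least-one
  conditional on the chosen tool having slot `s`, availability support
  (the producing step's mode must actually have that many outputs), and
  per-dimension compatibility clauses conditional on the chosen tool
  (`¬tool ∨ ¬bind ∨ ⋁ attr(x, d, t)` over acceptable descendants `t`);
* `attr(x, d, t)` forced by the producing mode, pairwise at-most-one per
  instance and dimension;
* `match(r, x)` witnesses per requested output with an at-least-one
  clause; an unproducible request yields the empty clause (unsatisfiable),
  never silent failure.

Tool variables are registered first, in step-major, sorted-mode-id order.
The bundled DPLL solver branches on the lowest-indexed unassigned
variable, trying TRUE first, so the *first* model carries the
lexicographically smallest tool-mode sequence; blocking each model's tool
projection then yields all sequences in canonical order. This replaces
solver-dependent ordering with a reproducible one, and collapses models
that differ only in input bindings (the first decoded binding is kept) —
returning binding permutations as separate solutions would flood users
without changing which pipelines exist.

## Constraint templates and their trace semantics

The catalog (`list_templates()`) was chosen to cover the four clause
shapes a bounded-LTL-style compiler must handle — existence, absence,
ordering, final-step — plus one data-level template. Writing `perf(X)`
for "the step's tool is annotated with X or a taxonomic descendant":

| template | holds on `m_1..m_n` iff |
|---|---|
| `use_operation(X)` | some `i` with `perf(X)` at `i` |
| `avoid_operation(X)` | no such `i` |
| `use_tool(T)` | some step runs tool `T` |
| `last_operation(X)` | `perf(X)` at step `n` |
| `operation_before(X, Y)` | X never occurs, or `∃ i < j` with X at `i`, Y at `j` |
| `use_type(D)` | some executable binding has a slot consuming an instance whose term in D's dimension is subsumed by D |

`operation_before` deserves a note: the existential reading is pinned down
by its X = Y behaviour (satisfied iff X occurs at least twice, or never —
a per-occurrence reading would make X,X unsatisfiable by infinite
regress). The CNF form is one clause per occurrence candidate `(i, mX)`:
`¬tool(i,mX) ∨ (some X earlier) ∨ (some Y later)`; if all clauses hold and
X occurs, the clause at X's first occurrence forces a later Y, and
conversely a witness pair satisfies every clause — so the clause set is
exactly the predicate.

`use_type(D)` is binding-dependent. By slot independence it is equivalent
to "some slot of some step has an available, compatible instance matching
D", which is how the oracle evaluates it; the encoder introduces witness
variables `u → bind(i,s,x)` and `u → (attr of x in D's down-set)` with one
at-least-one clause over all witnesses, so any model's decoded bindings
actually exhibit the consumption, and `check_solution()` judges exactly
that.

An unsatisfiable constraint (e.g. `use_operation` of an operation no tool
performs) compiles to the empty clause; constraint arguments are
dimension-checked at instantiation time.

## Verification: checker, oracle, generator

The verification module shares no code with the encoder. `check_solution()`
re-derives subsumption by an upward parent walk and replays the graph:
availability, per-dimension slot compatibility, requested-output matching,
and every constraint's trace predicate (for `use_type`, on the solution's
actual bindings). `brute_force_enumerate()` does exhaustive DFS over mode
sequences with per-slot executability pruning, guarded to `1e6` sequence
nodes. Snapshot files for the packaged proteomics domain were produced
once by the oracle — never the engine — with two members verified by hand.

`generate_domain()` emulates the shape of real domain models: per
dimension a random tree of 8 terms (EDAM fragments relevant to one query
are of this order) with depth ≤ 3; a handful of tools with 1–2 input
slots; within-dimension disjunctions with probability 0.3 and abstract
input terms with probability 0.25 (both common in registry annotations);
and a **planted chain** of tools linking the generated inputs to the
requested outputs, so every generated specification is satisfiable within
its bounds. In `exclusive` mode the chain links through fresh terms no
other tool can produce, making the chain provably the unique solution at
its length — used to test exact recovery. What the generator does *not*
emulate: very deep ontologies, many-dimensional annotations (k > 2 by
parameter only), inconsistent or incomplete hand annotations. A green
suite therefore certifies the engine's logic, not robustness to dirty
real-world registries (validation of those is `validate_domain()`'s job,
and errors there are loud).

## Numerical and degenerate-input choices

* There is no floating point anywhere in the core: the encoding is purely
  combinatorial, so the only "tolerances" are structural guards — the
  oracle's `1e6` sequence-space guard and the solver's deterministic
  branching.
* Ties everywhere are broken by sorted ids (modes, clauses legend,
  CWL/YAML map keys), which is what makes rerun outputs byte-identical.
* Degenerate inputs: `n = 0` or an empty tool set is an encoding error; an
  empty solution list is a valid synthesis outcome (CLI exit 2); a tool
  slot omitting a declared dimension is not silently completed but
  reported by `validate_domain()` and refused by `synthesize()`.
* OWL reading uses only named classes and subclass axioms — the ontology
  is treated as a controlled vocabulary with subsumption, nothing more.
  Dimensions may be DAGs; a non-tree dimension loads with a warning.
  Dimension roots come from the configuration, never guessed.

## Export formats

Text and DOT are line-oriented and fully determined by the graph. Shell
export is all-or-nothing: if any step's tool lacks a command template the
result is a marker, never a partial script; placeholders `{inN}`/`{outN}`
resolve to `<instance-id>.<format-label>` filenames. The CWL v1.2 export
follows the abstract-workflow idiom: steps are descriptive containers
carrying `intent` (operation IRIs) and `doc`, not `baseCommand`s or Docker
hints — turning a discovered pipeline into an executable one is the
user's configuration task. Workflow inputs are annotated with their
format IRIs only (the type dimension is dropped; at runtime the format
suffices to wire files). Where one might expect a `run:` block, this
package keeps the step abstract by design; a tool-description mapping
(`doc` + `intent`) stands in for richer tool metadata. YAML is emitted
with sorted keys and fixed two-space indentation for byte stability.

## Known limitations

* One tool per step: no branching/parallel control flow in the encoding.
* No search heuristics or incremental SAT: fine for interactive domain
  sizes (tens of tools, lengths ≤ ~6); large registries would need the
  scalability work that is explicitly out of scope here.
* The bio.tools-style JSON schema accepted is this package's own
  documented subset, not a validator for the live registry's full schema.
* Solutions are deduplicated by tool-mode sequence; distinct data-flow
  wirings of the same sequence are represented by one canonical binding.
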
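# flowsynth

SAT-based automated composition of scientific workflows, in R.

Building a computational pipeline usually means knowing which tools exist,
which data types and formats they accept and emit, and how to chain them.
**flowsynth** automates the exploration step: given

1. a **semantic domain model** — an OWL ontology with an *operation*
   taxonomy and one or more disjoint *data* taxonomies (e.g. data type and
   data format), plus tools annotated bio.tools-style with the operations
   they perform and their typed/formatted input and output slots — and
2. a **loose workflow specification** — the available inputs, the requested
   outputs, and constraints instantiated from natural-language templates
   ("Use operation *X*", "End the workflow with operation *X*", …) —

it enumerates *all* tool sequences up to a length bound that satisfy the
specification **by construction**, and exports each one as a step listing,
a data-flow/control-flow graph (DOT), an executable shell script (when the
annotations carry commands) and an abstract CWL v1.2 document.

It is aimed at people who maintain semantically annotated tool collections
(EDAM/bio.tools-like registries, in any domain) and want to explore the
space of valid pipelines for a request instead of hand-picking one.

## The method

For each length bound *n* the composition problem is compiled into
propositional CNF over variables

- `tool(i, m)` — step *i* ∈ 1..*n* runs tool mode *m* (a *mode* is one
  concrete resolution of a tool's disjunctive output annotation; exactly
  one mode per step);
- `bind(i, s, x)` — input slot *s* of step *i* reads memory instance *x*;
  memory is cumulative (workflow inputs plus all earlier outputs), and a
  binding is admissible only if, in every dimension, the instance's term is
  subsumed by an acceptable slot term (an abstract ontology term stands for
  all its descendants);
- `attr(x, d, t)` — instance *x* carries term *t* in dimension *d*, forced
  by the producing mode;

plus clauses requiring every requested output to be matched by some final
memory instance, and the compiled bounded-trace semantics of every
constraint. A bundled deterministic DPLL solver enumerates models; each
model is blocked on its step-wise tool-mode projection, so solutions are
distinct tool-mode sequences, produced in canonical (lexicographic) order.
An independent checker and a brute-force enumerator — sharing no code with
the encoder — verify soundness and bounded completeness in the test suite.

## Worked example: a proteomics identification pipeline

The package ships a six-tool proteomics domain (Comet, msconvert,
Peptide Prophet, rt4, xml2tsv, SSRCalc) annotated against a synthetic
EDAM-style ontology fragment. The specification asks: starting from a
*mass spectrum* in *mzML* format, produce an *amino acid index
(hydropathy)* in any format, using tools that perform *peptide
identification* and *retention time prediction*.

```r
library(flowsynth)
dir <- system.file("extdata", "proteomics", package = "flowsynth")
cfg <- load_config(file.path(dir, "config.json"))
cfg$spec
#> WorkflowSpec: 1 input(s), 1 requested output(s), 2 constraint(s), length 1..3, up to 50 solutions
#>   - Use operation 'Peptide identification' in the workflow.
#>   - Use operation 'Retention time prediction' in the workflow.

sols <- synthesize(cfg$domain, cfg$spec)
length(sols)
#> [1] 33
cat(to_text(sols[[1]], cfg$domain))
#> # workflow solution (2 steps)
#> inputs: in1=Mass spectrum / mzML
#> outputs: s2o1=Amino acid index (hydropathy) / TSV
#> step 1: comet mode=comet@01 in=[in1] out=[s1o1]
#> step 2: rt4 mode=rt4@01 in=[s1o1] out=[s2o1]
```

The shortest solution identifies peptides with Comet (a *peptide database
search*, a taxonomic descendant of *peptide identification*, so the
constraint is satisfied descendant-closed) and feeds the pepXML
identifications to rt4 for retention-time prediction; the other 32
solutions at length 3 insert format conversions, re-scoring or redundant
steps. `to_dot()`, `to_shell()` and `to_cwl()` export any of them; the
independent `check_solution()` returns zero violations for each.

The same run from the command line:

```sh
Rscript inst/exec/flowsynth synthesize --config inst/extdata/proteomics/config.json \
        --output-dir /tmp/out            # exit 0; writes solution_*.txt/.dot/.sh/.cwl + solutions.json
Rscript inst/exec/flowsynth templates    # list the constraint catalog
```

Exit codes: 0 = solutions found, 2 = specification unsatisfiable (try
`config_raw_input.json`, whose Thermo-RAW input no packaged tool accepts),
1 = error.

## Synthetic benchmark generator

`generate_domain(gen_params(seed))` builds seeded random taxonomies and
tool sets with a *planted chain* guaranteeing satisfiability, and can write
them as OWL + JSON so the real file readers are exercised. The test suite
uses it for 200-domain soundness runs and for exact equality against
`brute_force_enumerate()`, the independent oracle.

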
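# hand-built solution graphs for negative checker tests
mk_node <- function(id, sig, producer = NULL) {
  structure(list(id = id, signature = sig, producer = producer,
                 consumers = list()), class = "TypeNode")
}
mk_step <- function(index, mode, ins, outs) {
  structure(list(index = index, tool_id = mode$tool_id, mode_id = mode$id,
                 label = mode$label, operations = mode$operations,
                 inputs = ins, outputs = outs), class = "ModuleNode")
}

test_that("check_solution flags subsumption failures and unmet outputs", {
  cfg <- proteomics_config()
  dom <- cfg$domain
  comet <- dom$modes[["comet@01"]]
  # bind a pepXML instance to Comet's mzML/mzXML-only slot
  pep <- mk_node("in1", stats::setNames(
    list(prot_iri("Peptide_identification_data"), prot_iri("pepXML")),
    prot_iri(c("Data", "Format"))))
  out <- mk_node("s1o1", stats::setNames(
    list(prot_iri("Peptide_identification_data"), prot_iri("pepXML")),
    prot_iri(c("Data", "Format"))), producer = 1)
  sol <- structure(list(
    steps = list(mk_step(1, comet, "in1", "s1o1")),
    types = list(in1 = pep, s1o1 = out),
    input_ids = "in1", output_ids = "s1o1",
    sequence = "comet@01"), class = "SolutionWorkflow")
  spec <- workflow_spec(
    inputs = list(stats::setNames(
      list(prot_iri("Peptide_identification_data"), prot_iri("pepXML")),
      prot_iri(c("Data", "Format")))),
    outputs = list(stats::setNames(
      list(prot_iri("Mass_spectrum"), prot_iri("Format")),
      prot_iri(c("Data", "Format")))),
    max_length = 1)
  v <- check_solution(sol, dom, spec)
  kinds <- vapply(v, function(x) x$kind, "")
  expect_true("subsumption-failure" %in% kinds)  # pepXML into mzML slot
  expect_true("unmet-output" %in% kinds)         # no mass spectrum produced
  expect_length(v, 2)
})

test_that("check_solution flags availability violations and constraint failures", {
  cfg <- proteomics_config()
  dom <- cfg$domain
  rt4 <- dom$modes[["rt4@01"]]
  comet <- dom$modes[["comet@01"]]
  ms <- mk_node("in1", stats::setNames(
    list(prot_iri("Mass_spectrum"), prot_iri("mzML")),
    prot_iri(c("Data", "Format"))))
  pep_late <- mk_node("s2o1", stats::setNames(
    list(prot_iri("Peptide_identification_data"), prot_iri("pepXML")),
    prot_iri(c("Data", "Format"))), producer = 2)
  aai <- mk_node("s1o1", stats::setNames(
    list(prot_iri("Amino_acid_index_hydropathy"), prot_iri("TSV")),
    prot_iri(c("Data", "Format"))), producer = 1)
  # step 1 (rt4) consumes the output of step 2 (comet): not yet available
  sol <- structure(list(
    steps = list(mk_step(1, rt4, "s2o1", "s1o1"),
                 mk_step(2, comet, "in1", "s2o1")),
    types = list(in1 = ms, s1o1 = aai, s2o1 = pep_late),
    input_ids = "in1", output_ids = "s1o1",
    sequence = c("rt4@01", "comet@01")), class = "SolutionWorkflow")
  tax <- cfg$taxonomy
  spec <- workflow_spec(
    inputs = list(stats::setNames(list(prot_iri("Mass_spectrum"),
                                       prot_iri("mzML")),
                  prot_iri(c("Data", "Format")))),
    outputs = list(),
    constraints = list(
      instantiate_template("last_operation",
                           prot_iri("Retention_time_prediction"), tax)),
    max_length = 2)
  v <- check_solution(sol, dom, spec)
  kinds <- vapply(v, function(x) x$kind, "")
  expect_true("unbound-input" %in% kinds)
  expect_true("constraint-failure" %in% kinds)  # last step is comet, not rt4
})

test_that("check_solution is insensitive to constraint order and certifies engine output", {
  cfg <- proteomics_config()
  sols <- synthesize(cfg$domain, cfg$spec)
  sol <- sols[[1]]
  spec_fwd <- cfg$spec
  spec_rev <- cfg$spec
  spec_rev$constraints <- rev(spec_rev$constraints)
  expect_length(check_solution(sol, cfg$domain, spec_fwd), 0)
  expect_length(check_solution(sol, cfg$domain, spec_rev), 0)
})

test_that("brute_force_enumerate handles degenerate cases and guards size", {
  tax <- toy_taxonomy()
  empty <- domain_model(tax, list())
  spec <- toy_spec()
  expect_length(brute_force_enumerate(empty, spec, 3), 0)

  dom <- toy_domain()
  spec1 <- toy_spec(max_length = 1)
  expect_equal(brute_force_enumerate(dom, spec1, 1), "t1@01")

  big <- generate_domain(gen_params(seed = 1, n_tools = 12,
                                    chain_length = 2))
  expect_error(brute_force_enumerate(big$domain, big$spec, 8),
               class = "fs_oracle_error")
})

test_that("the generator is seed-deterministic and self-consistent", {
  for (seed in c(2, 9)) {
    g1 <- generate_domain(gen_params(seed = seed))
    g2 <- generate_domain(gen_params(seed = seed))
    expect_identical(g1, g2)
    expect_equal(nrow(validate_domain(g1$domain$taxonomy, g1$domain$tools)),
                 0)
  }
  # chain length 1: solvable at n = 1 with the planted tool
  g <- generate_domain(gen_params(seed = 4, chain_length = 1))
  oracle <- brute_force_enumerate(g$domain, g$spec, 1)
  expect_true(g$planted %in% oracle)
})

test_that("planted chains are always found by the oracle", {
  for (seed in 1:25) {
    g <- generate_domain(gen_params(seed = 100 + seed, n_tools = 3,
                                    chain_length = 1 + seed %% 3))
    oracle <- brute_force_enumerate(g$domain, g$spec, g$spec$max_length)
    expect_true(g$planted %in% oracle,
                info = sprintf("seed %d", 100 + seed))
  }
})

test_that("generated domains round-trip through the real file readers", {
  g <- generate_domain(gen_params(seed = 13))
  dir <- tempfile("gen")
  cfg_path <- write_generated_domain(g, dir)
  cfg <- load_config(cfg_path)
  expect_equal(sort(names(cfg$taxonomy$terms)),
               sort(names(g$domain$taxonomy$terms)))
  expect_setequal(names(cfg$domain$modes), names(g$domain$modes))
  expect_equal(vapply(cfg$spec$inputs, function(s) unlist(s), character(2)),
               vapply(g$spec$inputs, function(s) unlist(s), character(2)))
  # identical synthesis results through the file round trip
  expect_identical(vapply(synthesize(cfg$domain, cfg$spec), solution_key, ""),
                   vapply(synthesize(g$domain, g$spec), solution_key, ""))
})
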
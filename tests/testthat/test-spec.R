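test_that("the template catalog is complete, unique and renderable", {
  cat_ <- list_templates()
  expect_setequal(names(cat_),
                  c("use_operation", "avoid_operation", "use_tool",
                    "last_operation", "operation_before", "use_type"))
  ids <- vapply(cat_, function(t) t$id, "")
  expect_false(anyDuplicated(ids) > 0)
  for (tpl in cat_) {
    shown <- do.call(sprintf, c(list(tpl$pattern),
                                as.list(paste0("<", tpl$params, ">"))))
    expect_match(shown, "<", fixed = TRUE)
    expect_false(grepl("%s", shown, fixed = TRUE))
  }
})

test_that("instantiate_template resolves, checks dimensions, and renders", {
  cfg <- proteomics_config()
  tax <- cfg$taxonomy
  con <- instantiate_template("use_operation",
                              prot_iri("Peptide_identification_op"), tax)
  expect_s3_class(con, "Constraint")
  expect_match(con$human_text, "Peptide identification")

  expect_error(instantiate_template("no_such_template", "x", tax),
               class = "fs_catalog_error")
  # a format term where an operation is required
  expect_error(instantiate_template("use_operation", prot_iri("mzML"), tax),
               class = "fs_signature_error")
  expect_error(instantiate_template("operation_before",
                                    prot_iri("Formatting"), tax),
               class = "fs_signature_error")
})

test_that("rendered constraints re-parse to the same template and arguments", {
  cfg <- proteomics_config()
  tax <- cfg$taxonomy
  cases <- list(
    list("use_operation", prot_iri("Peptide_identification_op")),
    list("avoid_operation", prot_iri("Filtering")),
    list("use_tool", "comet"),
    list("last_operation", prot_iri("Retention_time_prediction")),
    list("operation_before", prot_iri(c("Peptide_database_search",
                                        "Retention_time_prediction"))),
    list("use_type", prot_iri("Mass_spectrum")),
    list("use_type", prot_iri("pepXML")))
  for (cs in cases) {
    con <- instantiate_template(cs[[1]], cs[[2]], tax)
    back <- parse_constraint_text(con$human_text, tax)
    expect_equal(back$template_id, con$template_id)
    expect_equal(back$arguments, con$arguments)
  }
})

test_that("operation_before with X == Y means: X twice, or never", {
  # enumerate all traces of length <= 3 over {a = performs X, b = not}
  # and compare the trace predicate against the hand semantics
  tax <- toy_taxonomy()
  dom <- domain_model(tax, list(
    toy_tool("a", "opA", list(toy_sig("tX", "f1")),
             list(toy_sig("tX", "f1"))),
    toy_tool("b", "opB", list(toy_sig("tX", "f1")),
             list(toy_sig("tX", "f1")))))
  spec <- toy_spec(out_type = "Type", out_fmt = "Fmt")
  con <- instantiate_template("operation_before", c("opA", "opA"), tax)
  for (len in 0:3) {
    for (k in seq_len(2^len) - 1) {
      seq_ids <- sprintf("%s@01", c("a", "b")[1 + bitwAnd(k %/% 2^(seq_len(len) - 1), 1)])
      nX <- sum(seq_ids == "a@01")
      expect_equal(trace_predicate(con, seq_ids, dom, spec),
                   nX == 0 || nX >= 2,
                   info = paste(seq_ids, collapse = ","))
    }
  }
  # and the engine agrees: with X=Y constraint, solutions at n=2 must use a twice
  spec2 <- spec; spec2$constraints <- list(con)
  spec2$max_length <- 2L; spec2$max_solutions <- 100L
  keys <- vapply(synthesize(dom, spec2), solution_key, "")
  oracle <- brute_force_enumerate(dom, spec2, 2)
  expect_setequal(keys, oracle)
  expect_true("b@01" %in% keys)          # no X at all
  expect_true("a@01;a@01" %in% keys)     # X twice
  expect_false("a@01" %in% keys)         # X once is forbidden
  expect_false("a@01;b@01" %in% keys)
})

test_that("parse_spec resolves the RAW-input specification and applies defaults", {
  cfg <- proteomics_config("config_raw_input.json")
  spec <- cfg$spec
  expect_length(spec$inputs, 1)
  expect_equal(spec$inputs[[1]][[prot_iri("Format")]],
               prot_iri("Thermo_RAW_format"))
  expect_length(spec$outputs, 1)
  expect_length(spec$constraints, 3)
  expect_equal(spec$min_length, 1L)      # default
  expect_equal(spec$max_solutions, 100L) # default
  # omitted format dimension means "any format" = the dimension root
  expect_equal(spec$outputs[[1]][[prot_iri("Format")]], prot_iri("Format"))
})

test_that("parse_spec edge cases and errors", {
  tax <- toy_taxonomy()
  spec <- parse_spec(list(inputs = list(list(Type = "tX", Fmt = "f1"))), tax)
  expect_length(spec$constraints, 0)
  expect_equal(spec$max_length, 10L)
  # defaults for outputs: none requested is allowed
  expect_length(spec$outputs, 0)

  expect_error(parse_spec(list(inputs = list()), tax), class = "fs_spec_error")
  err <- tryCatch(
    parse_spec(list(inputs = list(list(Type = "tX", Fmt = "f1")),
                    constraints = list(list(template = "use_operation",
                                            args = "zzz"))), tax),
    error = function(e) e)
  expect_s3_class(err, "fs_spec_error")
  expect_match(conditionMessage(err), "constraints[1]", fixed = TRUE)
  # abstract (disjunctive) inputs are rejected
  expect_error(
    parse_spec(list(inputs = list(list(Type = c("tX", "tY"), Fmt = "f1"))),
               tax),
    class = "fs_spec_error")
  # max_solutions = 0 rejected at parse time
  expect_error(
    parse_spec(list(inputs = list(list(Type = "tX", Fmt = "f1")),
                    max_solutions = 0), tax),
    class = "fs_spec_error")
})
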
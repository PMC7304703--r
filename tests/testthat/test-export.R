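# a small pool of solutions shared by the export tests
export_pool <- local({
  pool <- NULL
  function() {
    if (is.null(pool)) {
      cfg <- proteomics_config()
      prot <- synthesize(cfg$domain, cfg$spec)[1:6]
      g <- generate_domain(gen_params(seed = 21, chain_length = 2))
      gen <- synthesize(g$domain, g$spec)
      pool <<- c(lapply(prot, function(s) list(sol = s, dom = cfg$domain)),
                 lapply(gen, function(s) list(sol = s, dom = g$domain)))
    }
    pool
  }
})

test_that("text export has the documented shape and round-trips the tool sequence", {
  for (p in export_pool()) {
    txt <- to_text(p$sol, p$dom)
    lines <- strsplit(txt, "\n")[[1]]
    expect_length(lines, length(p$sol$steps) + 3)  # 3 header lines
    expect_match(lines[1], "^# workflow solution")
    expect_match(lines[2], "^inputs: ")
    expect_match(lines[3], "^outputs: ")
    tools <- parse_solution_text(txt)
    expect_equal(tools, vapply(p$sol$steps, function(s) s$tool_id, ""))
  }
})

test_that("DOT export parses, has the right node count, and argument-position labels", {
  for (p in export_pool()) {
    dot <- to_dot(p$sol, p$dom, "dataflow")
    parsed <- parse_dot(dot)
    expect_length(parsed$nodes,
                  length(p$sol$types) + length(p$sol$steps))
    max_slots <- max(vapply(p$sol$steps, function(s)
      max(length(s$inputs), length(s$outputs)), 0L))
    labels <- as.integer(vapply(parsed$edges, function(e) e$label, ""))
    expect_true(all(labels >= 1 & labels <= max_slots))

    cf <- to_dot(p$sol, p$dom, "controlflow")
    pcf <- parse_dot(cf)
    expect_length(pcf$nodes, length(p$sol$steps))
    expect_length(pcf$edges, max(0, length(p$sol$steps) - 1))
  }
})

test_that("shell export runs and creates the declared files", {
  g <- generate_domain(gen_params(seed = 22, chain_length = 2))
  sols <- synthesize(g$domain, g$spec)
  expect_gt(length(sols), 0)
  for (sol in sols[seq_len(min(3, length(sols)))]) {
    sh <- to_shell(sol, g$domain)
    expect_false(is.na(sh))
    dir <- tempfile("shrun")
    dir.create(dir)
    script <- file.path(dir, "wf.sh")
    writeLines(sh, script, sep = "")
    status <- system(sprintf("cd %s && sh wf.sh", shQuote(dir)),
                     ignore.stdout = TRUE, ignore.stderr = TRUE)
    expect_identical(status, 0L)
    declared <- unlist(lapply(sol$steps, function(st)
      vapply(st$outputs, function(o)
        flowsynth:::instance_filename(sol$types[[o]], g$domain), "")))
    expect_true(all(file.exists(file.path(dir, declared))))
    unlink(dir, recursive = TRUE)
  }
})

test_that("shell export is all-or-nothing and filenames carry format labels", {
  cfg <- proteomics_config()
  sols <- synthesize(cfg$domain, cfg$spec)
  keys <- vapply(sols, solution_key, "")
  # ssrcalc has no command: any workflow through it gets the marker
  with_ssr <- sols[grepl("ssrcalc", keys)]
  expect_gt(length(with_ssr), 0)
  sh <- to_shell(with_ssr[[1]], cfg$domain)
  expect_true(is.na(sh))
  expect_match(attr(sh, "reason"), "ssrcalc")
  # a comet -> rt4 workflow exports; its pepXML intermediate is named so
  full <- sols[[which(keys == "comet@01;rt4@01")]]
  sh2 <- to_shell(full, cfg$domain)
  expect_match(sh2, "s1o1\\.pepXML")
  # malformed placeholder is an export error naming the tool
  dom2 <- cfg$domain
  dom2$modes[["comet@01"]]$command <- "cat {in9} > {out1}"
  err <- tryCatch(to_shell(full, dom2), error = function(e) e)
  expect_s3_class(err, "fs_export_error")
  expect_match(conditionMessage(err), "comet")
})

test_that("CWL export is schema-valid YAML with referential integrity", {
  for (p in export_pool()) {
    struct <- cwl_structure(p$sol, p$dom)
    expect_length(validate_cwl_workflow(struct), 0)
    expect_length(struct$steps, length(p$sol$steps))
    expect_length(struct$inputs, length(p$sol$input_ids))
    expect_length(struct$outputs, length(p$sol$output_ids))
    for (st in struct$steps) expect_gt(length(st$intent), 0)
    txt <- to_cwl(p$sol, p$dom)
    expect_match(txt, "cwlVersion: v1.2", fixed = TRUE)
    expect_match(txt, "class: Workflow", fixed = TRUE)
    expect_true(yaml_parses(txt))
  }
  # the validator does catch broken references
  p <- export_pool()[[1]]
  broken <- cwl_structure(p$sol, p$dom)
  broken$steps[[1]]$`in`[[1]] <- "nonexistent/source"
  expect_gt(length(validate_cwl_workflow(broken)), 0)
})

test_that("exporters are pure: identical output on repeated calls", {
  p <- export_pool()[[1]]
  expect_identical(to_text(p$sol, p$dom), to_text(p$sol, p$dom))
  expect_identical(to_dot(p$sol, p$dom, "dataflow"),
                   to_dot(p$sol, p$dom, "dataflow"))
  expect_identical(to_cwl(p$sol, p$dom), to_cwl(p$sol, p$dom))
})
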
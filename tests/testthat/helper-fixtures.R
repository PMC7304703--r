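# shared fixtures and independent mini-oracles for the test suite

PROT <- "http://flowsynth.example.org/proteomics#"
prot_iri <- function(x) paste0(PROT, x)

proteomics_dir <- function() {
  d <- system.file("extdata", "proteomics", package = "flowsynth")
  if (d == "") stop("proteomics fixture directory not found")
  d
}

# cached: loading the config parses OWL + JSON once per test run
.prot_cache <- new.env(parent = emptyenv())
proteomics_config <- function(name = "config.json") {
  hit <- get0(name, envir = .prot_cache)
  if (is.null(hit)) {
    hit <- load_config(file.path(proteomics_dir(), name))
    assign(name, hit, envir = .prot_cache)
  }
  hit
}

# small in-code taxonomy: operation dim (3 terms) + 2 data dims
toy_taxonomy <- function() {
  term <- function(id, dim, parents = character(0))
    list(id = id, label = id, dimension = dim, parents = parents)
  new_taxonomy(list(
    term("Op", "Op"),
    term("opA", "Op", "Op"), term("opB", "Op", "Op"),
    term("opA1", "Op", "opA"),
    term("Type", "Type"),
    term("tX", "Type", "Type"), term("tY", "Type", "Type"),
    term("tX1", "Type", "tX"),
    term("Fmt", "Fmt"),
    term("f1", "Fmt", "Fmt"), term("f2", "Fmt", "Fmt")
  ), operation_dimension = "Op", data_dimensions = c("Type", "Fmt"))
}

toy_tool <- function(id, ops, ins, outs, command = NULL) {
  structure(list(id = id, label = id, operations = ops,
                 inputs = ins, outputs = outs, command = command),
            class = "ToolAnnotation")
}

toy_sig <- function(type, fmt) {
  out <- list(type, fmt)
  names(out) <- c("Type", "Fmt")
  out
}

# one-tool domain: tool "t1" maps (tX, f1) -> (tY, f2)
toy_domain <- function(command = "cat {in1} > {out1}") {
  tax <- toy_taxonomy()
  domain_model(tax, list(
    toy_tool("t1", "opA", list(toy_sig("tX", "f1")),
             list(toy_sig("tY", "f2")), command = command)))
}

toy_spec <- function(tax = toy_taxonomy(), out_type = "tY", out_fmt = "f2",
                     ...) {
  workflow_spec(inputs = list(toy_sig("tX", "f1")),
                outputs = list(toy_sig(out_type, out_fmt)), ...)
}

# ---- independent checkers used as oracles --------------------------------

# transitive-closure membership by exhaustive path search over raw edges
edges_reach <- function(edges, from, to) {
  # edges: data.frame(child, parent); reachability child ->* parent
  if (from == to) return(TRUE)
  frontier <- from
  seen <- character(0)
  while (length(frontier)) {
    cur <- frontier[[1]]; frontier <- frontier[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    ps <- edges$parent[edges$child == cur]
    if (to %in% ps) return(TRUE)
    frontier <- c(frontier, ps)
  }
  FALSE
}

# minimal DOT well-formedness parser: digraph block, node statements with
# attrs, edge statements; returns nodes and edges (with label attr)
parse_dot <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  stopifnot(grepl("^digraph [A-Za-z0-9_]+ \\{$", lines[1]))
  stopifnot(identical(lines[length(lines)], "}"))
  body <- lines[-c(1, length(lines))]
  nodes <- character(0); edges <- list()
  node_rx <- '^\\s*"([^"]+)" \\[([^]]*)\\];$'
  edge_rx <- '^\\s*"([^"]+)" -> "([^"]+)"( \\[label="([^"]*)"\\])?;$'
  for (ln in body) {
    if (grepl("^\\s*rankdir", ln)) next
    if (grepl(node_rx, ln)) {
      nodes <- c(nodes, sub(node_rx, "\\1", ln))
    } else if (grepl(edge_rx, ln)) {
      m <- regmatches(ln, regexec(edge_rx, ln))[[1]]
      edges[[length(edges) + 1]] <- list(from = m[2], to = m[3],
                                         label = m[5])
    } else stop("unparseable DOT line: ", ln)
  }
  for (e in edges)
    if (!(e$from %in% nodes && e$to %in% nodes))
      stop("DOT edge references undeclared node")
  list(nodes = nodes, edges = edges)
}

# python-assisted YAML well-formedness check (pyyaml is part of the stack)
yaml_parses <- function(text) {
  f <- tempfile(fileext = ".yml")
  writeLines(text, f, sep = "")
  on.exit(unlink(f))
  status <- suppressWarnings(system2(
    "python", c("-c", shQuote("import sys,yaml; yaml.safe_load(open(sys.argv[1]))"), f),
    stdout = FALSE, stderr = FALSE))
  identical(status, 0L)
}

oracle_snapshots <- function() {
  jsonlite::fromJSON(test_path("fixtures", "proteomics_oracle_snapshots.json"))
}
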
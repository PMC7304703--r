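mk_rdfxml <- function(classes) {
  # classes: list of list(id, label = NULL, parents = chr())
  body <- vapply(classes, function(c_) {
    lab <- if (!is.null(c_$label))
      sprintf("    <rdfs:label>%s</rdfs:label>\n", c_$label) else ""
    sup <- paste(sprintf('    <rdfs:subClassOf rdf:resource="%s"/>\n',
                         c_$parents %||% character(0)), collapse = "")
    sprintf('  <owl:Class rdf:about="%s">\n%s%s  </owl:Class>\n',
            c_$id, lab, sup)
  }, "")
  paste0('<?xml version="1.0"?>\n<rdf:RDF ',
         'xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" ',
         'xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#" ',
         'xmlns:owl="http://www.w3.org/2002/07/owl#">\n',
         paste(body, collapse = ""), "</rdf:RDF>\n")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp_owl <- function(classes, ext = ".owl") {
  f <- tempfile(fileext = ext)
  writeLines(mk_rdfxml(classes), f)
  f
}

test_that("load_taxonomy reads subclass hierarchies from RDF/XML", {
  f <- write_tmp_owl(list(
    list(id = "urn:x:Operation"), list(id = "urn:x:Data"),
    list(id = "urn:x:Format"),
    list(id = "urn:x:mzML", parents = "urn:x:Format"),
    list(id = "urn:x:mzXML", label = "mzXML label", parents = "urn:x:Format")))
  tax <- load_taxonomy(f, c("urn:x:Operation", "urn:x:Data", "urn:x:Format"))
  expect_s3_class(tax, "DomainTaxonomy")
  expect_length(tax$terms, 5)
  fmt_terms <- Filter(function(t) t$dimension == "urn:x:Format", tax$terms)
  expect_length(fmt_terms, 3)
  expect_equal(tax$terms[["urn:x:mzML"]]$parents, "urn:x:Format")
  # labels: annotation when present, IRI fragment / final segment otherwise
  expect_equal(tax$terms[["urn:x:mzXML"]]$label, "mzXML label")
  expect_equal(tax$terms[["urn:x:mzML"]]$label, "urn:x:mzML")
})

test_that("roots-only ontology yields three single-term dimensions", {
  f <- write_tmp_owl(list(list(id = "urn:x:Operation"),
                          list(id = "urn:x:Data"), list(id = "urn:x:Format")))
  tax <- load_taxonomy(f, c("urn:x:Operation", "urn:x:Data", "urn:x:Format"))
  expect_length(tax$terms, 3)
  expect_length(tax$data_dimensions, 2)
  expect_true(all(vapply(tax$terms, function(t) length(t$parents) == 0, NA)))
})

test_that("load errors: bad document, missing root, disjointness", {
  bad <- tempfile(fileext = ".owl")
  writeLines("this is not XML <", bad)
  expect_error(load_taxonomy(bad, "urn:x:Op"), class = "fs_format_error")

  f <- write_tmp_owl(list(list(id = "urn:x:Operation")))
  expect_error(load_taxonomy(f, c("urn:x:Operation", "urn:x:Missing")),
               class = "fs_config_error")

  shared <- write_tmp_owl(list(
    list(id = "urn:x:A"), list(id = "urn:x:B"),
    list(id = "urn:x:c", parents = c("urn:x:A", "urn:x:B"))))
  expect_error(load_taxonomy(shared, c("urn:x:A", "urn:x:B")),
               class = "fs_format_error")
})

test_that("a non-tree dimension loads as a DAG with a warning", {
  f <- write_tmp_owl(list(
    list(id = "urn:x:Op"), list(id = "urn:x:D"),
    list(id = "urn:x:a", parents = "urn:x:D"),
    list(id = "urn:x:b", parents = "urn:x:D"),
    list(id = "urn:x:c", parents = c("urn:x:a", "urn:x:b"))))
  expect_warning(tax <- load_taxonomy(f, c("urn:x:Op", "urn:x:D")),
                 "not a tree")
  expect_true(subsumes(tax, "urn:x:a", "urn:x:c"))
  expect_true(subsumes(tax, "urn:x:b", "urn:x:c"))
})

test_that("the packaged proteomics fixture loads with k = 2 data dimensions", {
  cfg <- proteomics_config()
  tax <- cfg$taxonomy
  expect_length(tax$data_dimensions, 2)
  # independent count: generic XML query for owl:Class nodes, then an
  # independent downward reachability pass from each root
  doc <- xml2::read_xml(file.path(proteomics_dir(),
                                  "edam_fragment_synthetic.owl"))
  ns <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
          rdfs = "http://www.w3.org/2000/01/rdf-schema#",
          owl = "http://www.w3.org/2002/07/owl#")
  cls <- xml2::xml_find_all(doc, "//owl:Class", ns)
  ids <- xml2::xml_attr(cls, "about")
  child <- unlist(lapply(cls, function(nd)
    rep(xml2::xml_attr(nd, "about"),
        length(xml2::xml_find_all(nd, "rdfs:subClassOf", ns)))))
  parent <- unlist(lapply(cls, function(nd)
    xml2::xml_attr(xml2::xml_find_all(nd, "rdfs:subClassOf", ns), "resource")))
  edges <- data.frame(child = child, parent = parent,
                      stringsAsFactors = FALSE)
  roots <- c(cfg$operation_root, cfg$data_roots)
  reachable <- vapply(ids, function(i)
    any(vapply(roots, function(r) edges_reach(edges, i, r), NA)), NA)
  expect_equal(length(tax$terms), sum(reachable))
  # the Table-1 vocabulary is present
  for (nm in c("Mass_spectrum", "Peptide_identification_data",
               "Amino_acid_index_hydropathy", "mzML", "mzXML", "MGF",
               "pepXML", "mzIdentML", "TSV", "XML", "Textual_format"))
    expect_true(prot_iri(nm) %in% names(tax$terms))
})

test_that("subsumes is reflexive, follows edges, and rejects cross-dimension queries", {
  tax <- toy_taxonomy()
  for (id in names(tax$terms)) expect_true(subsumes(tax, id, id))
  expect_true(subsumes(tax, "Fmt", "f1"))
  expect_false(subsumes(tax, "f1", "Fmt"))
  expect_true(subsumes(tax, "Type", "tX1"))
  expect_error(subsumes(tax, "Op", "f1"), class = "fs_dimension_error")
  expect_error(subsumes(tax, "nope", "f1"), class = "fs_term_error")
})

test_that("subsumes equals brute-force transitive closure on a random 50-term DAG", {
  set.seed(42)
  n <- 50
  ids <- c("R", sprintf("n%02d", seq_len(n - 1)))
  terms <- list(list(id = "R", label = "R", dimension = "R",
                     parents = character(0)))
  edges <- data.frame(child = character(0), parent = character(0),
                      stringsAsFactors = FALSE)
  for (k in 2:n) {
    np <- sample(1:2, 1)
    parents <- sample(ids[seq_len(k - 1)], min(np, k - 1))
    terms[[k]] <- list(id = ids[k], label = ids[k], dimension = "R",
                       parents = parents)
    edges <- rbind(edges, data.frame(child = ids[k], parent = parents,
                                     stringsAsFactors = FALSE))
  }
  tax <- new_taxonomy(terms, operation_dimension = "R",
                      data_dimensions = character(0))
  pairs <- expand.grid(a = ids, d = ids, stringsAsFactors = FALSE)
  pairs <- pairs[sample(nrow(pairs), 400), ]
  for (k in seq_len(nrow(pairs))) {
    expect_equal(subsumes(tax, pairs$a[k], pairs$d[k]),
                 edges_reach(edges, pairs$d[k], pairs$a[k]),
                 info = sprintf("%s vs %s", pairs$a[k], pairs$d[k]))
  }
})

test_that("taxonomy serialization round-trips (load -> write -> load)", {
  cfg <- proteomics_config()
  f <- tempfile(fileext = ".owl")
  write_taxonomy_owl(cfg$taxonomy, f)
  tax2 <- load_taxonomy(f, c(cfg$operation_root, cfg$data_roots))
  expect_equal(sort(names(tax2$terms)), sort(names(cfg$taxonomy$terms)))
  for (id in names(cfg$taxonomy$terms)) {
    expect_equal(tax2$terms[[id]]$parents, cfg$taxonomy$terms[[id]]$parents)
    expect_equal(tax2$terms[[id]]$label, cfg$taxonomy$terms[[id]]$label)
    expect_equal(tax2$terms[[id]]$dimension, cfg$taxonomy$terms[[id]]$dimension)
  }
  # idempotence on the serialized form
  f2 <- tempfile(fileext = ".owl")
  write_taxonomy_owl(tax2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("the Turtle subset reader agrees with RDF/XML", {
  ttl <- tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix x: <urn:x:> .",
    "x:Operation a owl:Class .",
    "x:Data a owl:Class .",
    'x:ms a owl:Class ; rdfs:subClassOf x:Data ; rdfs:label "Mass spectrum" .',
    "x:pep rdfs:subClassOf x:ms ."), ttl)
  tax <- load_taxonomy(ttl, c("urn:x:Operation", "urn:x:Data"))
  expect_length(tax$terms, 4)
  expect_equal(tax$terms[["urn:x:ms"]]$label, "Mass spectrum")
  expect_true(subsumes(tax, "urn:x:Data", "urn:x:pep"))
})
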
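#' Construct a domain taxonomy
#'
#' A domain taxonomy holds one operation dimension and `k >= 1` data
#' dimensions (for example *data type* and *data format*).  Each dimension is
#' a rooted directed acyclic graph of terms related by subsumption; the
#' dimensions are disjoint term sets.  Terms are identified by IRI; labels
#' are display-only.
#'
#' @param terms list of term records, each a list with elements `id`,
#'   `label`, `dimension` and `parents` (character vector of parent ids,
#'   empty for a dimension root).
#' @param operation_dimension id of the operation dimension root.
#' @param data_dimensions character vector of data dimension root ids, in
#'   their canonical order.
#' @param check validate invariants (unique ids, parents in-dimension,
#'   acyclicity, root reachability).  Tests may disable this to construct
#'   deliberately broken taxonomies for [validate_domain()].
#' @return an object of class `DomainTaxonomy`.
#' @export
new_taxonomy <- function(terms, operation_dimension, data_dimensions,
                         check = TRUE) {
  ids <- vapply(terms, function(t) t$id, "")
  if (anyDuplicated(ids))
    stop_fs("fs_format_error", "duplicate term id: %s",
            ids[duplicated(ids)][1])
  names(terms) <- ids
  dims <- c(operation_dimension, data_dimensions)
  if (anyDuplicated(dims))
    stop_fs("fs_config_error", "dimension roots must be distinct")
  missing_roots <- setdiff(dims, ids)
  if (length(missing_roots))
    stop_fs("fs_config_error", "dimension root not present as a term: %s",
            missing_roots[1])

  tax <- structure(list(
    operation_dimension = operation_dimension,
    data_dimensions = data_dimensions,
    dimensions = dims,
    terms = terms,
    ancestors = NULL,
    descendants = NULL
  ), class = "DomainTaxonomy")

  if (check) check_taxonomy(tax)
  tax$ancestors <- closure_up(tax, check = check)
  tax$descendants <- invert_closure(tax$ancestors, ids)
  tax
}

check_taxonomy <- function(tax) {
  for (t in tax$terms) {
    is_root <- t$id %in% tax$dimensions
    if (!is_root && length(t$parents) == 0)
      stop_fs("fs_format_error", "non-root term '%s' has no parent", t$id)
    for (p in t$parents) {
      pt <- tax$terms[[p]]
      if (is.null(pt))
        stop_fs("fs_format_error", "term '%s' has unknown parent '%s'",
                t$id, p)
      if (pt$dimension != t$dimension)
        stop_fs("fs_format_error",
                "term '%s' (%s) has parent '%s' in another dimension",
                t$id, t$dimension, p)
    }
  }
  invisible(TRUE)
}

# Upward transitive closure (ancestors including self), iterative DFS with
# cycle detection.
closure_up <- function(tax, check = TRUE) {
  memo <- new.env(parent = emptyenv())
  onpath <- new.env(parent = emptyenv())
  visit <- function(id) {
    hit <- get0(id, envir = memo)
    if (!is.null(hit)) return(hit)
    if (check && !is.null(get0(id, envir = onpath)))
      stop_fs("fs_format_error", "subsumption cycle at term '%s'", id)
    assign(id, TRUE, envir = onpath)
    anc <- id
    for (p in tax$terms[[id]]$parents) {
      if (is.null(get0(p, envir = onpath)) || check) {
        anc <- union(anc, visit(p))
      }
    }
    rm(list = id, envir = onpath)
    res <- sort(anc)
    assign(id, res, envir = memo)
    res
  }
  res <- lapply(names(tax$terms), function(id) {
    # under check = FALSE a cycle would recurse forever; bound it
    if (!check) visit_nocycle(tax, id) else visit(id)
  })
  names(res) <- names(tax$terms)
  res
}

# ancestor closure tolerant of cycles (BFS with visited set)
visit_nocycle <- function(tax, id) {
  seen <- id
  frontier <- id
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(x)
      tax$terms[[x]]$parents), use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    nxt <- nxt[nxt %in% names(tax$terms)]
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

invert_closure <- function(anc, ids) {
  desc <- lapply(ids, function(i) character(0))
  names(desc) <- ids
  for (d in names(anc)) {
    for (a in anc[[d]]) desc[[a]] <- c(desc[[a]], d)
  }
  lapply(desc, sort)
}

#' Test taxonomy subsumption
#'
#' `TRUE` iff `descendant` equals `ancestor` or `ancestor` is reachable from
#' `descendant` by following parent links.  An abstract term stands for all
#' of its descendants.
#'
#' @param taxonomy a [new_taxonomy()] object.
#' @param ancestor,descendant term ids in the same dimension.
#' @export
subsumes <- function(taxonomy, ancestor, descendant) {
  ta <- taxonomy$terms[[ancestor]]
  td <- taxonomy$terms[[descendant]]
  if (is.null(ta) || is.null(td))
    stop_fs("fs_term_error", "unknown term: %s",
            if (is.null(ta)) ancestor else descendant)
  if (ta$dimension != td$dimension)
    stop_fs("fs_dimension_error",
            "subsumption query across dimensions (%s vs %s)",
            ta$dimension, td$dimension)
  ancestor %in% taxonomy$ancestors[[descendant]]
}

# union of descendants (incl. self) of a set of term ids
down_set <- function(taxonomy, ids) {
  sort(unique(unlist(taxonomy$descendants[ids], use.names = FALSE)))
}

term_label <- function(taxonomy, id) {
  t <- taxonomy$terms[[id]]
  if (is.null(t)) stop_fs("fs_term_error", "unknown term: %s", id)
  t$label
}

term_dimension <- function(taxonomy, id) {
  t <- taxonomy$terms[[id]]
  if (is.null(t)) stop_fs("fs_term_error", "unknown term: %s", id)
  t$dimension
}

#' Resolve a term reference (id or unique label) to a term id
#'
#' Matching is primarily by IRI; as a convenience a reference that is not a
#' known IRI is matched against labels, optionally restricted to one
#' dimension, and must be unambiguous.
#'
#' @param taxonomy a `DomainTaxonomy`.
#' @param ref character id or label.
#' @param dimension optional dimension id to restrict label search.
#' @export
resolve_term <- function(taxonomy, ref, dimension = NULL) {
  if (!is.null(taxonomy$terms[[ref]])) {
    if (!is.null(dimension) &&
        taxonomy$terms[[ref]]$dimension != dimension)
      stop_fs("fs_dimension_error",
              "term '%s' is not in dimension '%s'", ref, dimension)
    return(ref)
  }
  cand <- names(taxonomy$terms)[vapply(taxonomy$terms, function(t) {
    t$label == ref && (is.null(dimension) || t$dimension == dimension)
  }, NA)]
  if (length(cand) == 0)
    stop_fs("fs_term_error", "unresolved term reference: '%s'", ref)
  if (length(cand) > 1)
    stop_fs("fs_term_error", "ambiguous term label '%s' (%s)",
            ref, paste(cand, collapse = ", "))
  cand
}

iri_fragment <- function(iri) {
  frag <- sub("^.*#", "", iri)
  if (identical(frag, iri)) frag <- sub("^.*/", "", iri)
  frag
}

#' Load a domain taxonomy from an OWL document
#'
#' Reads named classes and `rdfs:subClassOf` axioms from an OWL file in
#' RDF/XML (or a line-oriented Turtle subset) and assembles the terms
#' reachable downward from each dimension root.  All other axioms are
#' ignored: the ontology is treated purely as a controlled vocabulary with
#' subsumption.  A class reachable from two roots violates dimension
#' disjointness and is an error.  Multiple parents are allowed (EDAM-style
#' DAGs) with a warning that the dimension is not a tree.
#'
#' @param path OWL file (`.owl`/`.rdf`/`.xml` RDF/XML, or `.ttl` Turtle).
#' @param dimension_roots character vector of root class IRIs, one per
#'   dimension; the first is the operation dimension unless
#'   `operation_root` says otherwise.
#' @param operation_root IRI of the operation dimension root.
#' @return a `DomainTaxonomy`.
#' @export
load_taxonomy <- function(path, dimension_roots,
                          operation_root = dimension_roots[[1]]) {
  dimension_roots <- as.character(unlist(dimension_roots))
  if (!operation_root %in% dimension_roots)
    stop_fs("fs_config_error", "operation root must be a dimension root")
  raw <- read_owl_graph(path)
  classes <- raw$classes      # named list iri -> label (or NA)
  parents <- raw$parents      # named list iri -> character parent iris

  for (r in dimension_roots) {
    if (!r %in% names(classes))
      stop_fs("fs_config_error",
              "dimension root '%s' not found in ontology", r)
  }

  children <- list()
  for (c in names(parents)) {
    for (p in parents[[c]]) {
      children[[p]] <- c(children[[p]], c)
    }
  }

  assigned <- character(0)   # iri -> dimension
  dim_of <- list()
  for (root in dimension_roots) {
    frontier <- root
    seen <- character(0)
    while (length(frontier)) {
      cur <- frontier[[1]]
      frontier <- frontier[-1]
      if (cur %in% seen) next
      seen <- c(seen, cur)
      prev <- dim_of[[cur]]
      if (!is.null(prev) && prev != root)
        stop_fs("fs_format_error",
                "class '%s' reachable from roots '%s' and '%s': dimensions must be disjoint",
                cur, prev, root)
      dim_of[[cur]] <- root
      frontier <- c(frontier, setdiff(children[[cur]] %||% character(0), seen))
    }
  }

  member <- names(dim_of)
  terms <- lapply(member, function(iri) {
    lab <- classes[[iri]]
    if (is.null(lab) || is.na(lab)) lab <- iri_fragment(iri)
    par <- intersect(parents[[iri]] %||% character(0), member)
    par <- par[vapply(par, function(p) dim_of[[p]] == dim_of[[iri]], NA)]
    list(id = iri, label = lab, dimension = dim_of[[iri]],
         parents = sort(unique(par)))
  })

  tax <- new_taxonomy(terms,
                      operation_dimension = operation_root,
                      data_dimensions = setdiff(dimension_roots,
                                                operation_root))
  for (d in tax$dimensions) {
    multi <- vapply(tax$terms, function(t)
      t$dimension == d && length(t$parents) > 1, NA)
    if (any(multi))
      warning(sprintf("dimension '%s' is not a tree (term with >1 parent); treated as a DAG", d),
              call. = FALSE)
  }
  tax
}

read_owl_graph <- function(path) {
  if (!file.exists(path))
    stop_fs("fs_config_error", "ontology file not found: %s", path)
  if (grepl("\\.ttl$", path, ignore.case = TRUE))
    return(read_turtle_graph(path))
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop_fs("fs_format_error", "cannot parse OWL document '%s': %s",
            path, conditionMessage(e)))
  ns <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
          rdfs = "http://www.w3.org/2000/01/rdf-schema#",
          owl = "http://www.w3.org/2002/07/owl#")
  nodes <- xml2::xml_find_all(
    doc,
    "//owl:Class[@rdf:about] | //rdf:Description[@rdf:about][rdf:type/@rdf:resource='http://www.w3.org/2002/07/owl#Class']",
    ns)
  classes <- list()
  parents <- list()
  for (nd in nodes) {
    iri <- xml2::xml_attr(nd, "about")
    lab_nd <- xml2::xml_find_first(nd, "rdfs:label", ns)
    lab <- if (inherits(lab_nd, "xml_missing")) NA_character_ else
      xml2::xml_text(lab_nd)
    if (is.null(classes[[iri]]) || is.na(classes[[iri]]))
      classes[[iri]] <- lab
    sup <- xml2::xml_attr(
      xml2::xml_find_all(nd, "rdfs:subClassOf[@rdf:resource]", ns),
      "resource")
    parents[[iri]] <- sort(unique(c(parents[[iri]] %||% character(0), sup)))
  }
  list(classes = classes, parents = parents)
}

# Pragmatic Turtle subset: @prefix lines plus simple triples with
# rdf:type owl:Class, rdfs:subClassOf and rdfs:label predicates.
read_turtle_graph <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("^\\s*#.*$", "", txt)
  prefixes <- c()
  stmts <- character(0)
  buf <- ""
  for (line in txt) {
    line <- trimws(line)
    if (line == "") next
    if (grepl("^@prefix", line)) {
      m <- regmatches(line,
        regexec("^@prefix\\s+([A-Za-z0-9_-]*):\\s*<([^>]*)>\\s*\\.", line))[[1]]
      if (length(m) == 3) prefixes[m[2]] <- m[3]
      next
    }
    buf <- paste(buf, line)
    if (grepl("\\.\\s*$", line)) {
      stmts <- c(stmts, sub("\\.\\s*$", "", buf))
      buf <- ""
    }
  }
  expand <- function(tok) {
    tok <- trimws(tok)
    if (grepl("^<.*>$", tok)) return(substr(tok, 2, nchar(tok) - 1))
    if (tok == "a") return("http://www.w3.org/1999/02/22-rdf-syntax-ns#type")
    m <- regmatches(tok, regexec("^([A-Za-z0-9_-]*):(.*)$", tok))[[1]]
    if (length(m) == 3 && m[2] %in% names(prefixes))
      return(paste0(prefixes[[m[2]]], m[3]))
    tok
  }
  RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  OWL_CLASS <- "http://www.w3.org/2002/07/owl#Class"
  SUBCLASS <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
  LABEL <- "http://www.w3.org/2000/01/rdf-schema#label"
  classes <- list()
  parents <- list()
  for (s in stmts) {
    m <- regmatches(s, regexec(
      "^[[:space:]]*(<[^>]*>|[A-Za-z0-9_-]*:[^[:space:]]+)[[:space:]]+(.*)$",
      s))[[1]]
    if (length(m) != 3) next
    subj <- expand(m[2])
    for (po in strsplit(m[3], ";", fixed = TRUE)[[1]]) {
      pm <- regmatches(po, regexec(
        "^[[:space:]]*(a|<[^>]*>|[A-Za-z0-9_-]*:[^[:space:]]+)[[:space:]]+(.*?)[[:space:]]*$",
        po, perl = TRUE))[[1]]
      if (length(pm) != 3) next
      pred <- expand(pm[2])
      obj <- pm[3]
      if (pred == RDF_TYPE && expand(obj) == OWL_CLASS) {
        if (is.null(classes[[subj]])) classes[[subj]] <- NA_character_
      } else if (pred == SUBCLASS) {
        parents[[subj]] <- sort(unique(c(parents[[subj]] %||% character(0),
                                         expand(obj))))
        if (is.null(classes[[subj]])) classes[[subj]] <- NA_character_
      } else if (pred == LABEL) {
        lab <- sub('^"(.*)"(@[A-Za-z-]+)?$', "\\1", trimws(obj))
        classes[[subj]] <- lab
      }
    }
  }
  for (p in unlist(parents, use.names = FALSE)) {
    if (is.null(classes[[p]])) classes[[p]] <- NA_character_
  }
  list(classes = classes, parents = parents)
}

#' Serialize a taxonomy as OWL (RDF/XML)
#'
#' Writes named classes with `rdfs:label` annotations and
#' `rdfs:subClassOf` axioms; the output round-trips through
#' [load_taxonomy()].
#'
#' @param taxonomy a `DomainTaxonomy`.
#' @param path output file.
#' @export
write_taxonomy_owl <- function(taxonomy, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#">')
  for (id in sort(names(taxonomy$terms))) {
    t <- taxonomy$terms[[id]]
    lines <- c(lines, sprintf('  <owl:Class rdf:about="%s">', esc(id)),
               sprintf('    <rdfs:label>%s</rdfs:label>', esc(t$label)))
    for (p in sort(t$parents))
      lines <- c(lines,
                 sprintf('    <rdfs:subClassOf rdf:resource="%s"/>', esc(p)))
    lines <- c(lines, '  </owl:Class>')
  }
  lines <- c(lines, '</rdf:RDF>')
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.DomainTaxonomy <- function(x, ...) {
  cat("DomainTaxonomy:", length(x$terms), "terms in",
      length(x$dimensions), "dimensions\n")
  for (d in x$dimensions) {
    n <- sum(vapply(x$terms, function(t) t$dimension == d, NA))
    kind <- if (d == x$operation_dimension) "operation" else "data"
    cat(sprintf("  %s [%s]: %d terms\n", iri_fragment(d), kind, n))
  }
  invisible(x)
}
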
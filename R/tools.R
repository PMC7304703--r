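#' Data signatures
#'
#' A data signature characterizes a data instance or requirement along every
#' data dimension of the taxonomy: a named list mapping a dimension id to a
#' non-empty set of acceptable term ids.  A set with more than one term is a
#' disjunction within that dimension (e.g. format "mzML or mzXML").  A
#' signature is *concrete* when every dimension carries exactly one term.
#'
#' @param taxonomy a `DomainTaxonomy`.
#' @param spec named list `dimension -> character vector of term ids/labels`;
#'   dimensions may also be referenced by root label.  Missing dimensions are
#'   filled with the dimension root (i.e. "anything") when `fill_root` is
#'   `TRUE`, otherwise they are an error.
#' @param fill_root fill omitted dimensions with the dimension root.
#' @param concrete require exactly one term per dimension.
#' @return named list keyed by data dimension id, values sorted term ids.
#' @export
data_signature <- function(taxonomy, spec, fill_root = TRUE,
                           concrete = FALSE) {
  out <- list()
  used <- character(0)
  for (nm in names(spec)) {
    dim <- tryCatch(resolve_term(taxonomy, nm), error = function(e) NULL)
    if (is.null(dim) || !dim %in% taxonomy$data_dimensions)
      stop_fs("fs_schema_error", "unknown data dimension: '%s'", nm)
    terms <- vapply(unlist(spec[[nm]]), function(r)
      resolve_term(taxonomy, r, dimension = dim), "")
    if (length(terms) == 0)
      stop_fs("fs_schema_error", "empty term set for dimension '%s'", nm)
    out[[dim]] <- sort(unique(unname(terms)))
    used <- c(used, dim)
  }
  for (dim in setdiff(taxonomy$data_dimensions, used)) {
    if (!fill_root)
      stop_fs("fs_schema_error", "signature omits dimension '%s'", dim)
    out[[dim]] <- dim  # dimension root: any term acceptable
  }
  out <- out[taxonomy$data_dimensions]
  if (concrete && any(lengths(out) != 1))
    stop_fs("fs_schema_error", "signature must be concrete (one term per dimension)")
  out
}

#' Is a data signature concrete (exactly one term per dimension)?
#' @param sig a signature from [data_signature()].
#' @export
sig_is_concrete <- function(sig) all(lengths(sig) == 1)

#' Match a concrete instance signature against an acceptable-set signature
#'
#' `TRUE` iff in every dimension some acceptable term subsumes the
#' instance's term.
#'
#' @param taxonomy a `DomainTaxonomy`.
#' @param instance concrete signature (one term per dimension).
#' @param accepted possibly-disjunctive signature of acceptable terms.
#' @export
sig_matches <- function(taxonomy, instance, accepted) {
  for (dim in names(accepted)) {
    t <- instance[[dim]]
    ok <- any(vapply(accepted[[dim]], function(a)
      subsumes(taxonomy, a, t), NA))
    if (!ok) return(FALSE)
  }
  TRUE
}

sig_label <- function(taxonomy, sig) {
  paste(vapply(names(sig), function(d) {
    paste(vapply(sig[[d]], function(t) term_label(taxonomy, t), ""),
          collapse = "|")
  }, ""), collapse = " / ")
}

#' Parse bio.tools-style JSON tool annotations
#'
#' The annotation document is a JSON object
#' `{"functions": [ {...tool...}, ... ]}` where each tool carries
#' `id`, optional `label`, `operation` (array of operation term ids or
#' labels), `inputs` and `outputs` (arrays of objects mapping a dimension
#' id/label to an array of term ids; more than one term is a within-dimension
#' disjunction), and an optional
#' `implementation: {"shell_command": "..."}` whose command template may use
#' the numbered placeholders `{in1}`, `{in2}`, ..., `{out1}`, ...
#'
#' @param path JSON file.
#' @param taxonomy a `DomainTaxonomy` used to resolve every term reference.
#' @return list of `ToolAnnotation` objects.
#' @export
parse_tool_annotations <- function(path, taxonomy) {
  if (!file.exists(path))
    stop_fs("fs_config_error", "tool annotation file not found: %s", path)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop_fs("fs_schema_error",
                                "cannot parse tool annotations: %s",
                                conditionMessage(e)))
  funs <- doc$functions
  if (is.null(funs))
    stop_fs("fs_schema_error", "annotation document lacks 'functions'")
  tools <- lapply(funs, function(entry) parse_tool_entry(entry, taxonomy))
  ids <- vapply(tools, function(t) t$id, "")
  if (anyDuplicated(ids))
    stop_fs("fs_schema_error", "duplicate tool id: %s",
            ids[duplicated(ids)][1])
  names(tools) <- ids
  tools
}

parse_tool_entry <- function(entry, taxonomy) {
  id <- entry$id %||% entry$label
  if (is.null(id))
    stop_fs("fs_schema_error", "tool entry without 'id'")
  ops <- unlist(entry$operation)
  if (is.null(ops) || length(ops) == 0)
    stop_fs("fs_schema_error", "tool '%s': missing 'operation'", id)
  op_dim <- taxonomy$operation_dimension
  ops <- vapply(ops, function(o) {
    tryCatch(resolve_term(taxonomy, o, dimension = op_dim),
             error = function(e) stop_fs(
               "fs_term_error", "tool '%s': unresolved operation '%s'",
               id, o))
  }, "")
  parse_slots <- function(raw, what) {
    if (is.null(raw)) return(list())
    lapply(seq_along(raw), function(k) {
      tryCatch(
        data_signature(taxonomy, raw[[k]], fill_root = FALSE),
        fs_schema_error = function(e) {
          # keep the slot as-given (coverage gaps are validate_domain's job)
          tryCatch(partial_signature(taxonomy, raw[[k]], id, what, k),
                   error = function(e2) stop(e2))
        },
        fs_term_error = function(e) stop_fs(
          "fs_term_error", "tool '%s', %s slot %d: %s",
          id, what, k, conditionMessage(e)))
    })
  }
  tool <- list(
    id = id,
    label = entry$label %||% id,
    operations = sort(unique(unname(ops))),
    inputs = parse_slots(entry$inputs, "input"),
    outputs = parse_slots(entry$outputs, "output"),
    command = entry$implementation$shell_command %||% NULL
  )
  class(tool) <- "ToolAnnotation"
  tool
}

# signature kept with only the dimensions present in the document
partial_signature <- function(taxonomy, spec, tool_id, what, k) {
  out <- list()
  for (nm in names(spec)) {
    dim <- tryCatch(resolve_term(taxonomy, nm), error = function(e)
      stop_fs("fs_term_error", "tool '%s', %s slot %d: unknown dimension '%s'",
              tool_id, what, k, nm))
    terms <- vapply(unlist(spec[[nm]]), function(r) {
      tryCatch(resolve_term(taxonomy, r, dimension = dim),
               error = function(e) stop_fs(
                 "fs_term_error", "tool '%s', %s slot %d: %s",
                 tool_id, what, k, conditionMessage(e)))
    }, "")
    out[[dim]] <- sort(unique(unname(terms)))
  }
  out
}

#' Serialize tool annotations to the JSON schema read by
#' [parse_tool_annotations()]
#'
#' @param tools list of `ToolAnnotation`.
#' @param taxonomy a `DomainTaxonomy` (dimension keys are written as ids).
#' @param path output file.
#' @export
write_tool_annotations <- function(tools, taxonomy, path) {
  entries <- lapply(tools, function(t) {
    e <- list(id = t$id, label = t$label, operation = as.list(t$operations),
              inputs = lapply(t$inputs, function(s) lapply(s, as.list)),
              outputs = lapply(t$outputs, function(s) lapply(s, as.list)))
    if (!is.null(t$command))
      e$implementation <- list(shell_command = t$command)
    e
  })
  jsonlite::write_json(list(functions = entries), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Expand a tool annotation into concrete modes
#'
#' A tool whose output annotation is disjunctive (e.g. format
#' "MGF or mzXML or mzML") can produce different concrete data depending on
#' how it is run.  A *mode* resolves every output slot to exactly one term
#' per dimension; the set of modes is the full cross-product of the output
#' disjunctions, enumerated in lexicographic term-id order so that mode ids
#' are deterministic.  Inputs stay disjunctive.
#'
#' @param tool a `ToolAnnotation`.
#' @return list of `ToolMode` objects with ids `<tool>@NN`.
#' @export
expand_modes <- function(tool) {
  choices <- list()  # flat list of sorted term vectors, slot-major
  keys <- list()     # (slot, dim)
  for (s in seq_along(tool$outputs)) {
    sig <- tool$outputs[[s]]
    for (d in names(sig)) {
      choices[[length(choices) + 1L]] <- sort(sig[[d]])
      keys[[length(keys) + 1L]] <- c(s, d)
    }
  }
  combos <- if (length(choices)) {
    do.call(expand.grid, c(rev(lapply(choices, seq_along)),
                           stringsAsFactors = FALSE))
  } else data.frame(row.names = 1)
  n <- nrow(combos)
  lapply(seq_len(n), function(k) {
    outs <- lapply(tool$outputs, function(sig)
      stats::setNames(vector("list", length(sig)), names(sig)))
    if (length(choices)) {
      idx <- rev(as.integer(combos[k, ]))
      for (j in seq_along(choices)) {
        slot <- keys[[j]][1]; dim <- keys[[j]][2]
        outs[[as.integer(slot)]][[dim]] <- choices[[j]][idx[j]]
      }
    }
    mode <- list(
      id = sprintf("%s@%02d", tool$id, k),
      tool_id = tool$id,
      label = tool$label,
      operations = tool$operations,
      inputs = tool$inputs,
      outputs = lapply(outs, function(o) lapply(o, identity)),
      command = tool$command
    )
    class(mode) <- "ToolMode"
    mode
  })
}

#' Assemble a domain model
#'
#' Bundles a taxonomy and tool annotations, expanding all tool modes in
#' canonical (sorted mode id) order.
#'
#' @param taxonomy a `DomainTaxonomy`.
#' @param tools list of `ToolAnnotation`.
#' @export
domain_model <- function(taxonomy, tools) {
  modes <- unlist(lapply(tools, expand_modes), recursive = FALSE) %||% list()
  ord <- order(vapply(modes, function(m) m$id, ""))
  modes <- modes[ord]
  names(modes) <- vapply(modes, function(m) m$id, "")
  names(tools) <- vapply(tools, function(t) t$id, "")
  structure(list(taxonomy = taxonomy, tools = tools, modes = modes),
            class = "DomainModel")
}

#' @export
print.DomainModel <- function(x, ...) {
  cat("DomainModel:", length(x$tools), "tools,", length(x$modes),
      "modes,", length(x$taxonomy$terms), "taxonomy terms\n")
  invisible(x)
}

#' Validate a domain model
#'
#' Structural well-formedness report: unresolved terms, parent cycles,
#' empty dimensions, slots that do not cover every data dimension, and
#' tools whose inputs no workflow could ever satisfy (no taxonomy term and
#' no tool output matches a slot).  Problems are report entries, not
#' errors; an empty report means the model is well-formed.
#'
#' @param taxonomy a `DomainTaxonomy`.
#' @param tools list of `ToolAnnotation`.
#' @return data.frame with columns `kind`, `where`, `detail`.
#' @export
validate_domain <- function(taxonomy, tools) {
  rep <- list()
  note <- function(kind, where, detail)
    rep[[length(rep) + 1L]] <<- data.frame(kind = kind, where = where,
                                           detail = detail,
                                           stringsAsFactors = FALSE)

  for (d in taxonomy$dimensions) {
    n <- sum(vapply(taxonomy$terms, function(t) t$dimension == d, NA))
    if (n == 0) note("empty-dimension", d, "dimension has no terms")
  }
  # parent cycles: a term that is its own proper ancestor
  for (id in names(taxonomy$terms)) {
    anc <- visit_nocycle(taxonomy, id)
    for (p in taxonomy$terms[[id]]$parents) {
      if (id %in% visit_nocycle(taxonomy, p)) {
        note("cycle", id, sprintf("term participates in a parent cycle via '%s'", p))
        break
      }
    }
  }
  for (t in tools) {
    for (o in t$operations) {
      if (is.null(taxonomy$terms[[o]]))
        note("unresolved-term", t$id, sprintf("operation '%s' not in taxonomy", o))
    }
    slots <- c(t$inputs, t$outputs)
    slot_kind <- c(rep("input", length(t$inputs)),
                   rep("output", length(t$outputs)))
    for (k in seq_along(slots)) {
      sig <- slots[[k]]
      miss <- setdiff(taxonomy$data_dimensions, names(sig))
      if (length(miss))
        note("coverage-violation", t$id,
             sprintf("%s slot omits dimension(s): %s", slot_kind[k],
                     paste(vapply(miss, iri_fragment, ""), collapse = ", ")))
      for (d in names(sig)) for (term in sig[[d]]) {
        if (is.null(taxonomy$terms[[term]]))
          note("unresolved-term", t$id,
               sprintf("%s slot term '%s' not in taxonomy", slot_kind[k], term))
      }
    }
  }
  # reachability: every input slot satisfiable by some taxonomy term that
  # some tool output (or any term at all, for workflow inputs) could carry
  producible <- list()
  for (t in tools) for (sig in t$outputs) for (d in names(sig))
    producible[[d]] <- unique(c(producible[[d]], sig[[d]]))
  for (t in tools) {
    for (k in seq_along(t$inputs)) {
      sig <- t$inputs[[k]]
      for (d in names(sig)) {
        if (is.null(taxonomy$terms[[d]])) next
        ok_terms <- tryCatch(down_set(taxonomy, intersect(sig[[d]],
                                                          names(taxonomy$terms))),
                             error = function(e) character(0))
        if (length(ok_terms) == 0)
          note("unreachable-tool", t$id,
               sprintf("input slot %d unsatisfiable in dimension %s", k,
                       iri_fragment(d)))
      }
    }
  }
  if (length(rep) == 0)
    return(data.frame(kind = character(0), where = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rep)
}
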
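#' The constraint template catalog
#'
#' Workflow constraints are instantiated from a fixed catalog of
#' natural-language templates.  Each template has a parameter signature
#' (the dimension each argument must come from) and precise bounded-trace
#' semantics over the sequence of tool modes `m_1 .. m_n` of a candidate
#' workflow ("performs X" means the tool is annotated with operation X or
#' any taxonomic descendant of X):
#'
#' * `use_operation(X)` — some step performs X.
#' * `avoid_operation(X)` — no step performs X.
#' * `use_tool(T)` — some step runs tool T.
#' * `last_operation(X)` — step n performs X.
#' * `operation_before(X, Y)` — either X is never performed, or there are
#'   steps `i < j` with X performed at i and Y performed at j.  (With
#'   `X == Y` this requires X to occur at least twice, or never.)
#' * `use_type(D)` — some step consumes an instance whose term in D's
#'   dimension is subsumed by D.
#'
#' @return named list of templates; each has `id`, `params` (argument
#'   kinds: `"operation"`, `"tool"` or `"data"`), and `pattern` (a
#'   natural-language pattern with `%s` placeholders).
#' @export
list_templates <- function() {
  tpl <- function(id, params, pattern)
    list(id = id, params = params, pattern = pattern)
  list(
    use_operation = tpl("use_operation", "operation",
                        "Use operation '%s' in the workflow."),
    avoid_operation = tpl("avoid_operation", "operation",
                          "Do not use operation '%s' in the workflow."),
    use_tool = tpl("use_tool", "tool",
                   "Use tool '%s' in the workflow."),
    last_operation = tpl("last_operation", "operation",
                         "End the workflow with operation '%s'."),
    operation_before = tpl("operation_before", c("operation", "operation"),
                           "If operation '%s' is used, use operation '%s' at a later step."),
    use_type = tpl("use_type", "data",
                   "Use data matching '%s' as an input to some step.")
  )
}

#' Instantiate a constraint template
#'
#' @param template_id key in [list_templates()].
#' @param arguments character vector of term ids (or unique labels); for
#'   `use_tool`, a tool id.
#' @param taxonomy a `DomainTaxonomy` used to resolve and dimension-check
#'   the arguments.
#' @return a `Constraint` (list with `template_id`, `arguments`,
#'   `human_text`).
#' @export
instantiate_template <- function(template_id, arguments, taxonomy) {
  cat_ <- list_templates()
  tpl <- cat_[[template_id]]
  if (is.null(tpl))
    stop_fs("fs_catalog_error", "unknown constraint template '%s'",
            template_id)
  arguments <- as.character(unlist(arguments))
  if (length(arguments) != length(tpl$params))
    stop_fs("fs_signature_error",
            "template '%s' expects %d argument(s), got %d",
            template_id, length(tpl$params), length(arguments))
  resolved <- character(length(arguments))
  shown <- character(length(arguments))
  for (k in seq_along(arguments)) {
    kind <- tpl$params[k]
    if (kind == "tool") {
      resolved[k] <- arguments[k]
      shown[k] <- arguments[k]
    } else {
      id <- resolve_term(taxonomy, arguments[k])
      dim <- term_dimension(taxonomy, id)
      if (kind == "operation" && dim != taxonomy$operation_dimension)
        stop_fs("fs_signature_error",
                "template '%s' argument %d must be an operation term (got '%s' from %s)",
                template_id, k, arguments[k], iri_fragment(dim))
      if (kind == "data" && !dim %in% taxonomy$data_dimensions)
        stop_fs("fs_signature_error",
                "template '%s' argument %d must be a data term", template_id, k)
      resolved[k] <- id
      shown[k] <- term_label(taxonomy, id)
    }
  }
  structure(list(template_id = template_id,
                 arguments = resolved,
                 human_text = do.call(sprintf,
                                      c(list(tpl$pattern), as.list(shown)))),
            class = "Constraint")
}

#' Re-parse a rendered constraint back into template and arguments
#'
#' Inverse of the `human_text` rendering of [instantiate_template()];
#' labels are resolved within the dimension declared by the template
#' signature, so identical labels in different dimensions do not clash.
#'
#' @param text rendered constraint text.
#' @param taxonomy a `DomainTaxonomy`.
#' @return a `Constraint`.
#' @export
parse_constraint_text <- function(text, taxonomy) {
  for (tpl in list_templates()) {
    rx <- paste0("^", gsub("%s", "(.+?)",
                           gsub("([.?()\\[\\]])", "\\\\\\1", tpl$pattern)),
                 "$")
    m <- regmatches(text, regexec(rx, text))[[1]]
    if (length(m) == length(tpl$params) + 1) {
      args <- m[-1]
      resolved <- vapply(seq_along(args), function(k) {
        if (tpl$params[k] == "tool") return(args[k])
        dim <- if (tpl$params[k] == "operation")
          taxonomy$operation_dimension else NULL
        resolve_term(taxonomy, args[k], dimension = dim)
      }, "")
      return(instantiate_template(tpl$id, resolved, taxonomy))
    }
  }
  stop_fs("fs_catalog_error", "text matches no constraint template: %s", text)
}

#' Parse a workflow specification from JSON
#'
#' Expected keys: `inputs` (array of concrete signatures, objects keyed by
#' dimension id/label), `outputs` (array of possibly-abstract signatures; an
#' omitted dimension means "any", i.e. the dimension root), `constraints`
#' (array of `{"template": id, "args": [...]}`), and the synthesis
#' parameters `min_length` (default 1), `max_length` (default 10) and
#' `max_solutions` (default 100).
#'
#' @param x path to a JSON file, a JSON string, or an already-parsed list.
#' @param taxonomy a `DomainTaxonomy`.
#' @return a `WorkflowSpec`.
#' @export
parse_spec <- function(x, taxonomy) {
  doc <- spec_document(x)
  if (is.null(doc$inputs) || length(doc$inputs) == 0)
    stop_fs("fs_spec_error", "specification requires at least one entry at $.inputs")
  inputs <- lapply(seq_along(doc$inputs), function(k) {
    tryCatch(
      data_signature(taxonomy, doc$inputs[[k]], fill_root = FALSE,
                     concrete = TRUE),
      fs_error = function(e) stop_fs(
        "fs_spec_error", "$.inputs[%d]: %s", k, conditionMessage(e)))
  })
  outputs <- lapply(seq_along(doc$outputs %||% list()), function(k) {
    tryCatch(
      data_signature(taxonomy, doc$outputs[[k]], fill_root = TRUE),
      fs_error = function(e) stop_fs(
        "fs_spec_error", "$.outputs[%d]: %s", k, conditionMessage(e)))
  })
  constraints <- lapply(seq_along(doc$constraints %||% list()), function(k) {
    c_ <- doc$constraints[[k]]
    if (is.null(c_$template))
      stop_fs("fs_spec_error", "$.constraints[%d]: missing 'template'", k)
    tryCatch(
      instantiate_template(c_$template, unlist(c_$args), taxonomy),
      fs_error = function(e) stop_fs(
        "fs_spec_error", "$.constraints[%d]: %s", k, conditionMessage(e)))
  })
  workflow_spec(inputs = inputs, outputs = outputs,
                constraints = constraints,
                min_length = doc$min_length %||% 1L,
                max_length = doc$max_length %||% 10L,
                max_solutions = doc$max_solutions %||% 100L)
}

spec_document <- function(x) {
  if (is.character(x) && length(x) == 1) {
    out <- tryCatch(
      jsonlite::fromJSON(x, simplifyVector = FALSE),
      error = function(e) stop_fs("fs_spec_error",
                                  "cannot parse specification: %s",
                                  conditionMessage(e)))
    return(out)
  }
  if (is.list(x)) return(x)
  stop_fs("fs_spec_error", "specification must be a JSON file, string or list")
}

#' Construct a workflow specification
#'
#' @param inputs list of concrete data signatures (the available workflow
#'   inputs).
#' @param outputs list of requested (possibly abstract) data signatures.
#' @param constraints list of `Constraint` objects.
#' @param min_length,max_length inclusive bounds on the number of steps.
#' @param max_solutions maximum number of workflows to return.
#' @export
workflow_spec <- function(inputs, outputs, constraints = list(),
                          min_length = 1L, max_length = 10L,
                          max_solutions = 100L) {
  min_length <- as.integer(min_length)
  max_length <- as.integer(max_length)
  max_solutions <- as.integer(max_solutions)
  if (length(inputs) == 0)
    stop_fs("fs_spec_error", "at least one workflow input is required")
  if (!all(vapply(inputs, sig_is_concrete, NA)))
    stop_fs("fs_spec_error", "workflow inputs must be concrete")
  if (is.na(min_length) || min_length < 1L || min_length > max_length)
    stop_fs("fs_spec_error", "need 1 <= min_length <= max_length")
  if (is.na(max_solutions) || max_solutions < 1L)
    stop_fs("fs_spec_error", "max_solutions must be >= 1")
  structure(list(inputs = inputs, outputs = outputs,
                 constraints = constraints,
                 min_length = min_length, max_length = max_length,
                 max_solutions = max_solutions),
            class = "WorkflowSpec")
}

#' @export
print.WorkflowSpec <- function(x, ...) {
  cat(sprintf("WorkflowSpec: %d input(s), %d requested output(s), %d constraint(s), length %d..%d, up to %d solutions\n",
              length(x$inputs), length(x$outputs), length(x$constraints),
              x$min_length, x$max_length, x$max_solutions))
  for (c_ in x$constraints) cat("  -", c_$human_text, "\n")
  invisible(x)
}
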
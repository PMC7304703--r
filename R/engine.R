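#' Enumerate models of an encoded problem
#'
#' Runs the bundled DPLL solver.  After each model a blocking clause over
#' the step-wise tool-mode projection is added, so no two returned models
#' share a tool-mode sequence.  Because the solver branches on the
#' registry's tool variables first (lowest index, `TRUE` first), models
#' arrive in canonical order: lexicographic by tool-mode id sequence.
#'
#' @param cnf a `CNFProblem`.
#' @param limit maximum number of models.
#' @return list of models; each is an integer 0/1 vector indexed by
#'   variable.
#' @export
enumerate_models <- function(cnf, limit = 100L) {
  limit <- as.integer(limit)
  if (is.na(limit) || limit < 0L)
    stop_fs("fs_engine_error", "limit must be a non-negative count")
  if (limit == 0L) return(list())
  project <- as.integer(cnf$tool_var)
  tryCatch(
    .sat_enumerate(cnf$nvars, cnf$clauses, project, limit),
    error = function(e) stop_fs("fs_engine_error", "solver failure: %s",
                                conditionMessage(e)))
}

#' Decode a solver model into a workflow graph
#'
#' Reconstructs the directed data-flow graph: one module node per step in
#' execution order, one type node per workflow input and per produced
#' output instance, and binding edges labelled with argument position.
#' Type nodes record their producer (empty for workflow inputs) and their
#' consumers.  Workflow outputs are resolved deterministically: each
#' requested output is assigned the first memory instance (inputs first,
#' then step outputs in step/slot order) whose signature it subsumes.
#'
#' @param model an integer 0/1 model vector from [enumerate_models()].
#' @param cnf the `CNFProblem` it satisfies.
#' @return a `SolutionWorkflow`.
#' @export
decode_model <- function(model, cnf) {
  domain <- cnf$domain
  tax <- domain$taxonomy
  n <- cnf$n
  truthy <- function(v) !is.null(v) && model[v] == 1L

  seq_modes <- character(n)
  for (i in seq_len(n)) {
    on <- cnf$mode_ids[model[cnf$tool_var[i, ]] == 1L]
    if (length(on) != 1)
      stop_fs("fs_internal_error",
              "model assigns %d tool modes to step %d", length(on), i)
    seq_modes[i] <- on
  }

  types <- list()
  for (k in seq_along(cnf$input_ids)) {
    id <- cnf$input_ids[k]
    types[[id]] <- list(id = id,
                        signature = cnf$input_terms[[id]],
                        producer = NULL, consumers = list())
  }
  steps <- vector("list", n)
  for (i in seq_len(n)) {
    md <- domain$modes[[seq_modes[i]]]
    outs <- character(length(md$outputs))
    for (o in seq_along(md$outputs)) {
      id <- sprintf("s%do%d", i, o)
      outs[o] <- id
      types[[id]] <- list(id = id,
                          signature = lapply(md$outputs[[o]], identity),
                          producer = i, consumers = list())
    }
    ins <- character(length(md$inputs))
    for (s in seq_along(md$inputs)) {
      cand <- names(types)
      bound <- NULL
      for (inst in cand) {
        v <- cnf$var_of(paste("bind", i, s, inst, sep = "|"))
        if (truthy(v)) { bound <- inst; break }
      }
      if (is.null(bound))
        stop_fs("fs_internal_error", "step %d slot %d unbound", i, s)
      ins[s] <- bound
      types[[bound]]$consumers[[length(types[[bound]]$consumers) + 1L]] <-
        list(step = i, slot = s)
    }
    steps[[i]] <- list(index = i, tool_id = md$tool_id, mode_id = md$id,
                       label = md$label, operations = md$operations,
                       inputs = ins, outputs = outs)
    class(steps[[i]]) <- "ModuleNode"
  }
  for (id in names(types)) class(types[[id]]) <- "TypeNode"

  out_ids <- character(length(cnf$spec$outputs))
  for (r in seq_along(cnf$spec$outputs)) {
    req <- cnf$spec$outputs[[r]]
    hit <- NULL
    for (id in names(types)) {
      if (sig_matches(tax, types[[id]]$signature, req)) { hit <- id; break }
    }
    if (is.null(hit))
      stop_fs("fs_internal_error", "requested output %d unmatched in model", r)
    out_ids[r] <- hit
  }

  structure(list(steps = steps, types = types,
                 input_ids = cnf$input_ids, output_ids = out_ids,
                 sequence = seq_modes),
            class = "SolutionWorkflow")
}

#' Synthesize workflows for a specification
#'
#' Iterates the length bound from `min_length` to `max_length`; at each
#' bound the composition problem is encoded to CNF and models are
#' enumerated (blocking each found tool-mode sequence) until
#' `max_solutions` workflows have been collected in total.  Solutions are
#' ordered by length, then canonically (lexicographically by tool-mode id
#' sequence); no two share a tool-mode sequence.  Workflows that differ
#' only in their input bindings are collapsed to the first decoded
#' binding.
#'
#' @param domain a [domain_model()]; it is validated first and a
#'   non-empty [validate_domain()] report is an error.
#' @param spec a `WorkflowSpec`.
#' @param validate set to `FALSE` to skip domain validation.
#' @return list of `SolutionWorkflow` (possibly empty).
#' @export
synthesize <- function(domain, spec, validate = TRUE) {
  if (validate) {
    rep <- validate_domain(domain$taxonomy, domain$tools)
    if (nrow(rep) > 0)
      stop_fs("fs_config_error",
              "domain fails validation (%d problem(s)); first: [%s] %s: %s",
              nrow(rep), rep$kind[1], rep$where[1], rep$detail[1])
  }
  solutions <- list()
  for (n in seq(spec$min_length, spec$max_length)) {
    remaining <- spec$max_solutions - length(solutions)
    if (remaining <= 0) break
    cnf <- encode_problem(domain, spec, n)
    models <- enumerate_models(cnf, remaining)
    for (m in models)
      solutions[[length(solutions) + 1L]] <- decode_model(m, cnf)
  }
  solutions
}

#' @export
print.SolutionWorkflow <- function(x, ...) {
  cat(sprintf("SolutionWorkflow: %d step(s): %s\n", length(x$steps),
              paste(vapply(x$steps, function(s) s$tool_id, ""),
                    collapse = " -> ")))
  invisible(x)
}

#' Tool-mode sequence of a solution, as a single key
#' @param solution a `SolutionWorkflow`.
#' @export
solution_key <- function(solution) paste(solution$sequence, collapse = ";")
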
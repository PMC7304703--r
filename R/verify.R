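#' @title Independent workflow verification
#'
#' @description
#' The functions here form the semantics oracle for the synthesis engine.
#' They interpret workflow graphs and tool-mode sequences directly and
#' deliberately share no code with the CNF encoder: subsumption is
#' re-derived by an upward parent walk, availability by replaying the
#' cumulative memory, and constraints by evaluating their trace
#' predicates.
#' @name verification
NULL

# upward-reachability subsumption, independent of the precomputed closure
chk_subsumes <- function(taxonomy, ancestor, descendant) {
  frontier <- descendant
  seen <- character(0)
  while (length(frontier)) {
    cur <- frontier[[1]]
    frontier <- frontier[-1]
    if (cur == ancestor) return(TRUE)
    if (cur %in% seen) next
    seen <- c(seen, cur)
    frontier <- c(frontier, taxonomy$terms[[cur]]$parents)
  }
  FALSE
}

chk_sig_ok <- function(taxonomy, instance_sig, accepted_sig) {
  for (d in names(accepted_sig)) {
    t <- instance_sig[[d]]
    if (is.null(t)) return(FALSE)
    if (!any(vapply(accepted_sig[[d]], function(a)
      chk_subsumes(taxonomy, a, t), NA))) return(FALSE)
  }
  TRUE
}

# does mode m perform operation X (descendant-closed)?
chk_performs <- function(taxonomy, mode, X) {
  any(vapply(mode$operations, function(o) chk_subsumes(taxonomy, X, o), NA))
}

#' Evaluate a constraint's trace predicate on a tool-mode sequence
#'
#' `use_type` additionally needs the memory contents along the trace; the
#' predicate holds if the sequence is executable with at least one binding
#' in which some slot consumes a matching instance.  Since slots bind
#' independently in the cumulative-memory model, that reduces to one slot
#' having a matching compatible available instance.
#'
#' @param constraint a `Constraint`.
#' @param mode_seq character vector of mode ids.
#' @param domain a [domain_model()].
#' @param spec the `WorkflowSpec` (supplies the workflow inputs that seed
#'   memory for `use_type`).
#' @return logical.
#' @export
trace_predicate <- function(constraint, mode_seq, domain, spec) {
  tax <- domain$taxonomy
  modes <- domain$modes[mode_seq]
  a <- constraint$arguments
  occurs <- function(X) vapply(modes, function(m)
    chk_performs(tax, m, X), NA)
  switch(constraint$template_id,
    use_operation = any(occurs(a[1])),
    avoid_operation = !any(occurs(a[1])),
    use_tool = any(vapply(modes, function(m) m$tool_id == a[1], NA)),
    last_operation = length(modes) > 0 &&
      chk_performs(tax, modes[[length(modes)]], a[1]),
    operation_before = {
      oX <- which(occurs(a[1])); oY <- which(occurs(a[2]))
      length(oX) == 0 || any(vapply(oX, function(i) any(oY > i), NA))
    },
    use_type = {
      D <- a[1]
      d <- term_dimension(tax, D)
      mem <- lapply(spec$inputs, function(sig) lapply(sig, function(x) x[[1]]))
      hit <- FALSE
      for (m in modes) {
        for (sig in m$inputs) {
          for (inst in mem) {
            if (chk_sig_ok(tax, inst, sig) &&
                chk_subsumes(tax, D, inst[[d]])) { hit <- TRUE; break }
          }
          if (hit) break
        }
        if (hit) break
        for (out in m$outputs) mem[[length(mem) + 1L]] <- out
      }
      hit
    },
    stop_fs("fs_catalog_error", "unknown template '%s'",
            constraint$template_id)
  )
}

#' Check a solution workflow against domain and specification
#'
#' Interprets the graph directly: every binding must respect availability
#' (producer strictly earlier, or a workflow input) and per-dimension
#' subsumption against the bound tool's slot annotation; every requested
#' output must be matched by some memory instance; and every constraint's
#' trace predicate must hold.  Problems are returned as `Violation`
#' records, so an empty list certifies the solution.
#'
#' @param solution a `SolutionWorkflow`.
#' @param domain a [domain_model()].
#' @param spec a `WorkflowSpec`.
#' @return list of violations, each a list with `kind`
#'   (`unbound-input`, `subsumption-failure`, `unmet-output` or
#'   `constraint-failure`), `step`, `detail`.
#' @export
check_solution <- function(solution, domain, spec) {
  tax <- domain$taxonomy
  v <- list()
  bad <- function(kind, step, detail)
    v[[length(v) + 1L]] <<- list(kind = kind, step = step, detail = detail)

  for (st in solution$steps) {
    md <- domain$modes[[st$mode_id]]
    if (is.null(md)) {
      bad("unbound-input", st$index,
          sprintf("unknown tool mode '%s'", st$mode_id))
      next
    }
    if (length(st$inputs) != length(md$inputs))
      bad("unbound-input", st$index,
          sprintf("tool '%s' expects %d input(s), got %d",
                  st$tool_id, length(md$inputs), length(st$inputs)))
    for (s in seq_along(md$inputs)) {
      inst_id <- if (s <= length(st$inputs)) st$inputs[s] else NA
      node <- if (!is.na(inst_id)) solution$types[[inst_id]] else NULL
      if (is.null(node)) {
        bad("unbound-input", st$index, sprintf("slot %d not bound", s))
        next
      }
      prod <- node$producer
      if (!is.null(prod) && prod >= st$index) {
        bad("unbound-input", st$index,
            sprintf("slot %d bound to instance '%s' not yet available",
                    s, inst_id))
        next
      }
      if (!chk_sig_ok(tax, node$signature, md$inputs[[s]]))
        bad("subsumption-failure", st$index,
            sprintf("instance '%s' does not satisfy slot %d of tool '%s'",
                    inst_id, s, st$tool_id))
    }
  }
  for (r in seq_along(spec$outputs)) {
    req <- spec$outputs[[r]]
    ok <- any(vapply(solution$types, function(node)
      chk_sig_ok(tax, node$signature, req), NA))
    if (!ok)
      bad("unmet-output", NA_integer_,
          sprintf("requested output %d matched by no instance", r))
  }
  for (k in seq_along(spec$constraints)) {
    con <- spec$constraints[[k]]
    ok <- if (con$template_id == "use_type") {
      # judge the actual bindings of this solution
      D <- con$arguments[1]
      d <- term_dimension(tax, D)
      any(vapply(solution$steps, function(st)
        any(vapply(st$inputs, function(inst_id)
          chk_subsumes(tax, D,
                       solution$types[[inst_id]]$signature[[d]]), NA)), NA))
    } else {
      trace_predicate(con, solution$sequence, domain, spec)
    }
    if (!ok)
      bad("constraint-failure", NA_integer_, con$human_text)
  }
  v
}

#' Exhaustively enumerate all valid tool-mode sequences
#'
#' Depth-first enumeration over sequences of modes up to `max_length`,
#' replaying cumulative memory and requiring each step to be executable
#' (every input slot has at least one compatible available instance — in
#' the cumulative shared-memory model slots bind independently, so
#' per-slot existence is equivalent to the existence of a full binding).
#' Sequences within the spec's length bounds whose final memory matches
#' every requested output and which satisfy every constraint's trace
#' predicate are collected.
#'
#' @param domain a [domain_model()].
#' @param spec a `WorkflowSpec`; its `min_length` and constraints are
#'   honoured, `max_solutions` is ignored (the oracle is exhaustive).
#' @param max_length maximum sequence length.
#' @param guard maximum size of the mode-sequence space; larger instances
#'   raise an oracle-too-large error.
#' @return sorted character vector of sequences (mode ids joined by
#'   `";"`).
#' @export
brute_force_enumerate <- function(domain, spec, max_length,
                                  guard = 1e6) {
  modes <- domain$modes
  M <- length(modes)
  space <- sum(vapply(seq_len(max_length), function(l) M^l, 0))
  if (space > guard)
    stop_fs("fs_oracle_error",
            "mode-sequence space %.3g exceeds the oracle guard %.3g",
            space, guard)
  tax <- domain$taxonomy
  inputs <- lapply(spec$inputs, function(sig) lapply(sig, function(x) x[[1]]))

  step_ok <- function(mode, mem) {
    for (sig in mode$inputs) {
      ok <- any(vapply(mem, function(inst)
        chk_sig_ok(tax, inst, sig), NA))
      if (!ok) return(FALSE)
    }
    TRUE
  }
  final_ok <- function(seq_ids, mem) {
    if (length(seq_ids) < spec$min_length) return(FALSE)
    for (req in spec$outputs) {
      ok <- any(vapply(mem, function(inst)
        chk_sig_ok(tax, inst, req), NA))
      if (!ok) return(FALSE)
    }
    for (con in spec$constraints) {
      if (!trace_predicate(con, seq_ids, domain, spec)) return(FALSE)
    }
    TRUE
  }

  found <- character(0)
  recurse <- function(seq_ids, mem) {
    if (length(seq_ids) > 0 && final_ok(seq_ids, mem))
      found[[length(found) + 1L]] <<- paste(seq_ids, collapse = ";")
    if (length(seq_ids) == max_length) return()
    for (mid in names(modes)) {
      m <- modes[[mid]]
      if (!step_ok(m, mem)) next
      recurse(c(seq_ids, mid), c(mem, m$outputs))
    }
  }
  recurse(character(0), inputs)
  sort(unlist(found))
}
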
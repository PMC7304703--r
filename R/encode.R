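#' @title Propositional encoding of bounded workflow composition
#'
#' @description
#' For a fixed number of steps `n`, workflow composition is encoded as a
#' CNF formula whose models correspond (up to data-binding symmetry) to
#' executable length-`n` workflows:
#'
#' * `tool(i, m)` — step `i` runs tool mode `m`; exactly one per step.
#' * `bind(i, s, x)` — input slot `s` of step `i` reads memory instance
#'   `x`; exactly one per used slot, and only instances available before
#'   step `i` (workflow inputs and outputs of strictly earlier steps)
#'   whose term in every dimension is subsumed by an acceptable slot term.
#' * `attr(x, d, t)` — instance `x` carries term `t` in dimension `d`;
#'   forced by the producing mode, at most one per dimension.
#' * `match(r, x)` — requested output `r` is satisfied by instance `x`
#'   (per-dimension subsumption); at least one per request.
#'
#' Compiled constraint clauses are appended.  Memory is cumulative: all
#' workflow inputs and all earlier outputs stay available to every later
#' step and may be consumed by several slots.
#'
#' @param domain a [domain_model()].
#' @param spec a `WorkflowSpec`.
#' @param n number of steps (>= 1).
#' @return a `CNFProblem`: variable registry, clause list, and decode
#'   metadata.
#' @export
encode_problem <- function(domain, spec, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    stop_fs("fs_encode_error", "length bound must be >= 1")
  modes <- domain$modes
  if (length(modes) == 0)
    stop_fs("fs_encode_error", "domain has no tool modes")
  tax <- domain$taxonomy
  dims <- tax$data_dimensions
  mode_ids <- names(modes)
  n_in <- vapply(modes, function(m) length(m$inputs), 0L)
  n_out <- vapply(modes, function(m) length(m$outputs), 0L)
  max_in <- max(n_in)
  max_out <- max(n_out)

  reg <- new.env(parent = emptyenv())
  reg$nvars <- 0L
  reg$tags <- character(0)
  reg$map <- new.env(parent = emptyenv())
  newvar <- function(tag) {
    v <- get0(tag, envir = reg$map)
    if (!is.null(v)) return(v)
    reg$nvars <- reg$nvars + 1L
    reg$tags[reg$nvars] <- tag
    assign(tag, reg$nvars, envir = reg$map)
    reg$nvars
  }
  getvar <- function(tag) get0(tag, envir = reg$map)

  clauses <- vector("list", 1024L)
  n_cl <- 0L
  add <- function(lits) {
    n_cl <<- n_cl + 1L
    if (n_cl > length(clauses))
      length(clauses) <<- 2L * n_cl  # grow geometrically
    clauses[[n_cl]] <<- as.integer(lits)
  }
  amo <- function(vars) {
    if (length(vars) < 2) return()
    for (a in seq_len(length(vars) - 1L))
      for (b in seq((a + 1L), length(vars)))
        add(c(-vars[a], -vars[b]))
  }

  # --- tool variables first: canonical order drives model enumeration ---
  tool_var <- matrix(0L, nrow = n, ncol = length(modes),
                     dimnames = list(NULL, mode_ids))
  for (i in seq_len(n)) for (m in mode_ids)
    tool_var[i, m] <- newvar(paste("tool", i, m, sep = "|"))
  for (i in seq_len(n)) {
    add(tool_var[i, ])
    amo(tool_var[i, ])
  }

  # --- instances ----------------------------------------------------------
  n_inputs <- length(spec$inputs)
  input_ids <- sprintf("in%d", seq_len(n_inputs))
  input_terms <- lapply(spec$inputs, function(sig)
    lapply(sig, function(ts) ts[[1]]))
  names(input_terms) <- input_ids
  step_of <- function(inst) as.integer(sub("^s(\\d+)o\\d+$", "\\1", inst))
  slot_of <- function(inst) as.integer(sub("^s\\d+o(\\d+)$", "\\1", inst))
  step_inst <- function(i, o) sprintf("s%do%d", i, o)
  all_step_insts <- if (max_out > 0)
    unlist(lapply(seq_len(n), function(i)
      vapply(seq_len(max_out), function(o) step_inst(i, o), "")))
  else character(0)

  # possible terms an output-slot instance can carry, per dimension
  poss <- lapply(seq_len(max_out), function(o) {
    res <- lapply(dims, function(d) {
      sort(unique(unlist(lapply(modes, function(m) {
        if (length(m$outputs) >= o) m$outputs[[o]][[d]] else NULL
      }), use.names = FALSE)))
    })
    names(res) <- dims
    res
  })

  attr_var <- function(inst, d, t)
    getvar(paste("attr", inst, d, t, sep = "|"))
  for (inst in all_step_insts) {
    o <- slot_of(inst)
    for (d in dims) {
      vars <- vapply(poss[[o]][[d]], function(t)
        newvar(paste("attr", inst, d, t, sep = "|")), 0L)
      amo(vars)
    }
  }
  # attributes forced by the producing mode
  for (i in seq_len(n)) for (m in mode_ids) {
    md <- modes[[m]]
    for (o in seq_len(n_out[m])) for (d in dims) {
      t <- md$outputs[[o]][[d]]
      if (is.null(t))
        stop_fs("fs_encode_error",
                "tool '%s' output slot %d omits dimension %s (validate the domain first)",
                md$tool_id, o, iri_fragment(d))
      add(c(-tool_var[i, m], attr_var(step_inst(i, o), d, t)))
    }
  }

  producers_of <- function(inst) {
    # tool vars that make a step-output instance exist
    j <- step_of(inst); o <- slot_of(inst)
    tool_var[j, n_out >= o]
  }

  # --- bindings -----------------------------------------------------------
  bind_var <- function(i, s, inst)
    getvar(paste("bind", i, s, inst, sep = "|"))
  avail <- function(i) {
    c(input_ids,
      if (i > 1 && max_out > 0)
        unlist(lapply(seq_len(i - 1L), function(j)
          vapply(seq_len(max_out), function(o) step_inst(j, o), "")))
      else character(0))
  }
  down_cache <- new.env(parent = emptyenv())
  downs <- function(terms) {
    key <- paste(terms, collapse = "\r")
    hit <- get0(key, envir = down_cache)
    if (is.null(hit)) {
      hit <- down_set(tax, terms)
      assign(key, hit, envir = down_cache)
    }
    hit
  }

  for (i in seq_len(n)) {
    av <- avail(i)
    for (s in seq_len(max_in)) {
      bvars <- vapply(av, function(inst)
        newvar(paste("bind", i, s, inst, sep = "|")), 0L)
      amo(bvars)
      sup <- tool_var[i, n_in >= s]
      for (k in seq_along(av)) {
        inst <- av[[k]]
        add(c(-bvars[k], sup))  # slot only used if some tool has it
        if (grepl("^s", inst))
          add(c(-bvars[k], producers_of(inst)))  # instance must exist
      }
      for (m in mode_ids[n_in >= s]) {
        add(c(-tool_var[i, m], bvars))  # slot must be bound
        sig <- modes[[m]]$inputs[[s]]
        for (d in dims) {
          acc <- sig[[d]]
          if (is.null(acc))
            stop_fs("fs_encode_error",
                    "tool '%s' input slot %d omits dimension %s (validate the domain first)",
                    modes[[m]]$tool_id, s, iri_fragment(d))
          dn <- downs(acc)
          for (k in seq_along(av)) {
            inst <- av[[k]]
            if (grepl("^in", inst)) {
              if (!input_terms[[inst]][[d]] %in% dn)
                add(c(-tool_var[i, m], -bvars[k]))
            } else {
              ok <- intersect(dn, poss[[slot_of(inst)]][[d]])
              if (length(ok) == 0) {
                add(c(-tool_var[i, m], -bvars[k]))
              } else {
                add(c(-tool_var[i, m], -bvars[k],
                      vapply(ok, function(t) attr_var(inst, d, t), 0L)))
              }
            }
          }
        }
      }
    }
  }

  # --- requested outputs --------------------------------------------------
  all_insts <- c(input_ids, all_step_insts)
  for (r in seq_along(spec$outputs)) {
    req <- spec$outputs[[r]]
    mvars <- integer(0)
    for (inst in all_insts) {
      if (grepl("^in", inst)) {
        conc <- input_terms[[inst]]
        if (sig_matches(tax, conc, req))
          mvars <- c(mvars, newvar(paste("match", r, inst, sep = "|")))
      } else {
        o <- slot_of(inst)
        sets <- lapply(dims, function(d)
          intersect(downs(req[[d]]), poss[[o]][[d]]))
        if (all(lengths(sets) > 0)) {
          mv <- newvar(paste("match", r, inst, sep = "|"))
          mvars <- c(mvars, mv)
          add(c(-mv, producers_of(inst)))
          for (di in seq_along(dims))
            add(c(-mv, vapply(sets[[di]], function(t)
              attr_var(inst, dims[di], t), 0L)))
        }
      }
    }
    add(mvars)  # empty => unsatisfiable request
  }

  cnf <- structure(list(
    nvars = 0L, clauses = NULL, tags = NULL,
    n = n, domain = domain, spec = spec,
    mode_ids = mode_ids, n_in = n_in, n_out = n_out,
    max_in = max_in, max_out = max_out,
    input_ids = input_ids, input_terms = input_terms,
    tool_var = tool_var,
    var_of = NULL
  ), class = "CNFProblem")

  # --- constraints --------------------------------------------------------
  helpers <- list(newvar = newvar, getvar = getvar, add = add,
                  downs = downs, poss = poss, avail = avail,
                  attr_var = attr_var)
  base_clauses <- n_cl
  for (con in spec$constraints)
    compile_constraint_impl(con, cnf, helpers)

  cnf$base_clauses <- base_clauses
  cnf$nvars <- reg$nvars
  cnf$tags <- reg$tags[seq_len(reg$nvars)]
  cnf$clauses <- clauses[seq_len(n_cl)]
  cnf$var_of <- function(tag) get0(tag, envir = reg$map)
  cnf
}

#' Compile one constraint into clauses for a length bound
#'
#' Clause forms per template (writing `perf(X)` for the modes of tools
#' annotated with X or a descendant of X):
#' * `use_operation(X)`: one disjunction over all steps and `perf(X)`.
#' * `avoid_operation(X)`: a unit `-tool(i,m)` per step and performing mode.
#' * `use_tool(T)`: disjunction over all steps and T's modes.
#' * `last_operation(X)`: disjunction over `perf(X)` at the final step.
#' * `operation_before(X,Y)`: per occurrence candidate `(i, mX)`, either an
#'   earlier X occurrence exists or Y occurs later.
#' * `use_type(D)`: a fresh witness variable per binding candidate implies
#'   the binding and a D-subsumed attribute; at least one witness holds.
#'
#' An unsatisfiable constraint (e.g. `use_operation` of an operation no
#' tool performs) compiles to the empty clause.
#'
#' @param constraint a `Constraint`.
#' @param cnf a `CNFProblem` under construction (as built by
#'   [encode_problem()], which calls this for every spec constraint).
#' @param helpers internal closure bundle provided by [encode_problem()].
#' @return invisibly, the number of the compiled constraint's clauses.
#' @keywords internal
compile_constraint_impl <- function(constraint, cnf, helpers) {
  tax <- cnf$domain$taxonomy
  modes <- cnf$domain$modes
  n <- cnf$n
  tv <- cnf$tool_var
  perf <- function(X) {
    dn <- helpers$downs(X)
    names(modes)[vapply(modes, function(m)
      any(m$operations %in% dn), NA)]
  }
  a <- constraint$arguments
  added <- 0L
  addc <- function(l) { helpers$add(l); added <<- added + 1L }
  switch(constraint$template_id,
    use_operation = {
      p <- perf(a[1])
      addc(as.integer(tv[, p, drop = FALSE]))
    },
    avoid_operation = {
      p <- perf(a[1])
      for (i in seq_len(n)) for (m in p) addc(-tv[i, m])
    },
    use_tool = {
      p <- names(modes)[vapply(modes, function(m)
        m$tool_id == a[1], NA)]
      addc(as.integer(tv[, p, drop = FALSE]))
    },
    last_operation = {
      p <- perf(a[1])
      addc(as.integer(tv[n, p]))
    },
    operation_before = {
      pX <- perf(a[1]); pY <- perf(a[2])
      for (i in seq_len(n)) for (m in pX) {
        earlierX <- if (i > 1)
          as.integer(tv[seq_len(i - 1L), pX, drop = FALSE]) else integer(0)
        laterY <- if (i < n)
          as.integer(tv[seq(i + 1L, n), pY, drop = FALSE]) else integer(0)
        addc(c(-tv[i, m], earlierX, laterY))
      }
    },
    use_type = {
      D <- a[1]
      d <- term_dimension(tax, D)
      if (!d %in% tax$data_dimensions)
        stop_fs("fs_signature_error", "use_type argument must be a data term")
      dn <- helpers$downs(D)
      witnesses <- integer(0)
      for (i in seq_len(n)) {
        av <- helpers$avail(i)
        for (s in seq_len(cnf$max_in)) {
          for (inst in av) {
            bv <- helpers$getvar(paste("bind", i, s, inst, sep = "|"))
            if (is.null(bv)) next
            if (grepl("^in", inst)) {
              if (!cnf$input_terms[[inst]][[d]] %in% dn) next
              u <- helpers$newvar(paste("use_type", D, i, s, inst, sep = "|"))
              addc(c(-u, bv))
            } else {
              o <- as.integer(sub("^s\\d+o(\\d+)$", "\\1", inst))
              ok <- intersect(dn, helpers$poss[[o]][[d]])
              if (length(ok) == 0) next
              u <- helpers$newvar(paste("use_type", D, i, s, inst, sep = "|"))
              addc(c(-u, bv))
              addc(c(-u, vapply(ok, function(t)
                helpers$attr_var(inst, d, t), 0L)))
            }
            witnesses <- c(witnesses, u)
          }
        }
      }
      addc(witnesses)
    },
    stop_fs("fs_catalog_error", "unknown constraint template '%s'",
            constraint$template_id)
  )
  invisible(added)
}

#' Compile a constraint into step-indexed propositional clauses
#'
#' Convenience wrapper around the compilation performed inside
#' [encode_problem()]: encodes the executability core for `spec` with the
#' single given constraint and returns only the clauses the constraint
#' contributed (integer literal vectors over the problem's variable
#' registry; the empty clause marks an unsatisfiable constraint).
#'
#' @param constraint a `Constraint`.
#' @param domain a [domain_model()].
#' @param spec a `WorkflowSpec` providing inputs/outputs context.
#' @param n length bound.
#' @return list with `clauses` (the constraint's clauses) and `cnf` (the
#'   full problem, for interpreting variable indices via its `tags`).
#' @export
compile_constraint <- function(constraint, domain, spec, n) {
  spec$constraints <- list(constraint)
  cnf <- encode_problem(domain, spec, n)
  idx <- seq_len(length(cnf$clauses))
  idx <- idx[idx > cnf$base_clauses]
  list(clauses = cnf$clauses[idx], cnf = cnf)
}

#' Write a CNF problem in DIMACS format
#'
#' A debugging aid: comment lines carry the variable legend
#' (`c var <index> <semantic tag>`).
#'
#' @param cnf a `CNFProblem`.
#' @param path output file.
#' @export
write_dimacs <- function(cnf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("c bounded workflow composition, n = %d", cnf$n), con)
  writeLines(sprintf("c var %d %s", seq_len(cnf$nvars), cnf$tags), con)
  writeLines(sprintf("p cnf %d %d", cnf$nvars, length(cnf$clauses)), con)
  writeLines(vapply(cnf$clauses, function(cl)
    paste(c(cl, 0L), collapse = " "), ""), con)
  invisible(path)
}

#' @export
print.CNFProblem <- function(x, ...) {
  cat(sprintf("CNFProblem: %d variables, %d clauses (length bound %d)\n",
              x$nvars, length(x$clauses), x$n))
  invisible(x)
}
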
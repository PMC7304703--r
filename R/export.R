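#' @title Solution exporters
#' @description All exporters are pure functions of the solution (and the
#'   domain model): the same solution always yields byte-identical output.
#' @name exporters
NULL

sanitize_id <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

# the "format" dimension used for file extensions and CWL annotations:
# by convention the last data dimension (type first, format last, as in
# the proteomics model); with a single dimension it is that dimension.
format_dimension <- function(taxonomy) {
  taxonomy$data_dimensions[length(taxonomy$data_dimensions)]
}

instance_filename <- function(node, domain) {
  fd <- format_dimension(domain$taxonomy)
  fmt <- node$signature[[fd]]
  sprintf("%s.%s", node$id,
          sanitize_id(term_label(domain$taxonomy, fmt)))
}

#' Render a solution as a plain-text step listing
#'
#' One line per step (index, tool, mode, input instance ids, output
#' instance ids) preceded by a three-line header listing the workflow
#' inputs and outputs with their signatures.
#'
#' @param solution a `SolutionWorkflow`.
#' @param domain a [domain_model()].
#' @return a single character string (lines joined by `\n`).
#' @export
to_text <- function(solution, domain) {
  tax <- domain$taxonomy
  show_inst <- function(id)
    sprintf("%s=%s", id, sig_label(tax, solution$types[[id]]$signature))
  lines <- c(
    sprintf("# workflow solution (%d steps)", length(solution$steps)),
    paste("inputs:", paste(vapply(solution$input_ids, show_inst, ""),
                           collapse = "; ")),
    paste("outputs:", paste(vapply(solution$output_ids, show_inst, ""),
                            collapse = "; ")),
    vapply(solution$steps, function(st)
      sprintf("step %d: %s mode=%s in=[%s] out=[%s]",
              st$index, st$tool_id, st$mode_id,
              paste(st$inputs, collapse = ","),
              paste(st$outputs, collapse = ",")), "")
  )
  paste(lines, collapse = "\n")
}

#' Recover the tool-id sequence from a text export
#' @param text output of [to_text()].
#' @return character vector of tool ids in execution order.
#' @export
parse_solution_text <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  steps <- grep("^step [0-9]+: ", lines, value = TRUE)
  sub("^step [0-9]+: ([^ ]+) mode=.*$", "\\1", steps)
}

#' Render a solution as a Graphviz DOT graph
#'
#' The `dataflow` flavor draws data instances as ellipses and operation
#' executions as rectangles; edges into a step are labelled with the
#' argument position of the slot they feed, edges out of a step with the
#' output slot position.  The `controlflow` flavor is the plain execution
#' chain.
#'
#' @param solution a `SolutionWorkflow`.
#' @param domain a [domain_model()].
#' @param flavor `"dataflow"` or `"controlflow"`.
#' @return DOT document as a character string.
#' @export
to_dot <- function(solution, domain, flavor = c("dataflow", "controlflow")) {
  flavor <- match.arg(flavor)
  tax <- domain$taxonomy
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c(sprintf("digraph %s {", flavor), "  rankdir=LR;")
  if (flavor == "controlflow") {
    for (st in solution$steps)
      lines <- c(lines, sprintf("  %s [shape=box, label=%s];",
                                q(sprintf("step%d", st$index)),
                                q(sprintf("%d: %s", st$index, st$label))))
    if (length(solution$steps) > 1)
      for (i in seq_len(length(solution$steps) - 1L))
        lines <- c(lines, sprintf("  %s -> %s;",
                                  q(sprintf("step%d", i)),
                                  q(sprintf("step%d", i + 1L))))
  } else {
    for (id in names(solution$types)) {
      node <- solution$types[[id]]
      lines <- c(lines, sprintf("  %s [shape=ellipse, label=%s];", q(id),
                                q(sprintf("%s\\n%s", id,
                                          sig_label(tax, node$signature)))))
    }
    for (st in solution$steps) {
      sid <- sprintf("step%d", st$index)
      lines <- c(lines, sprintf("  %s [shape=box, label=%s];", q(sid),
                                q(sprintf("%d: %s", st$index, st$label))))
      for (s in seq_along(st$inputs))
        lines <- c(lines, sprintf("  %s -> %s [label=%s];",
                                  q(st$inputs[s]), q(sid), q(as.character(s))))
      for (o in seq_along(st$outputs))
        lines <- c(lines, sprintf("  %s -> %s [label=%s];",
                                  q(sid), q(st$outputs[o]), q(as.character(o))))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Render a solution as an executable shell script
#'
#' Requires every step's tool to carry a shell command template (numbered
#' placeholders `{in1}`, `{out1}`, ...).  Placeholders are substituted
#' with deterministic per-instance filenames
#' (`<instance-id>.<format-label>`).  If any tool lacks a command the
#' script is *not available*: `NA` is returned (with a `reason`
#' attribute) rather than a partial script.
#'
#' @param solution a `SolutionWorkflow`.
#' @param domain a [domain_model()].
#' @return character script, or `NA_character_` with attribute `reason`.
#' @export
to_shell <- function(solution, domain) {
  tools <- vapply(solution$steps, function(st) st$tool_id, "")
  missing <- unique(tools[vapply(solution$steps, function(st)
    is.null(domain$modes[[st$mode_id]]$command), NA)])
  if (length(missing)) {
    out <- NA_character_
    attr(out, "reason") <- sprintf("no shell command for tool(s): %s",
                                   paste(missing, collapse = ", "))
    return(out)
  }
  fname <- function(id) instance_filename(solution$types[[id]], domain)
  lines <- c("#!/bin/sh",
             "# generated by flowsynth; workflow input placeholders are",
             "# created empty if the real files are absent",
             "set -e")
  for (id in solution$input_ids)
    lines <- c(lines, sprintf('[ -e "%s" ] || : > "%s"', fname(id), fname(id)))
  for (st in solution$steps) {
    cmd <- domain$modes[[st$mode_id]]$command
    for (s in seq_along(st$inputs))
      cmd <- gsub(sprintf("{in%d}", s), fname(st$inputs[s]), cmd,
                  fixed = TRUE)
    for (o in seq_along(st$outputs))
      cmd <- gsub(sprintf("{out%d}", o), fname(st$outputs[o]), cmd,
                  fixed = TRUE)
    left <- regmatches(cmd, gregexpr("\\{(in|out)[0-9]+\\}", cmd))[[1]]
    if (length(left))
      stop_fs("fs_export_error",
              "tool '%s': unknown placeholder(s) %s in shell command",
              st$tool_id, paste(left, collapse = ", "))
    lines <- c(lines, sprintf("# step %d: %s", st$index, st$label), cmd)
  }
  paste(c(lines, ""), collapse = "\n")
}

#' Abstract CWL v1.2 structure for a solution
#'
#' Builds the R-level structure behind [to_cwl()]: `inputs` from the
#' workflow-input type nodes annotated with their format IRIs (the type
#' dimension is intentionally dropped — at runtime the format suffices),
#' one abstract step per module node whose `in` sources reference the
#' producing step's output or a workflow input, whose `out` lists the
#' produced instance ids and whose `intent` lists the tool's operation
#' term IRIs, and `outputs` with `outputSource` references.
#'
#' @param solution a `SolutionWorkflow`.
#' @param domain a [domain_model()].
#' @return nested list mirroring the CWL document.
#' @export
cwl_structure <- function(solution, domain) {
  tax <- domain$taxonomy
  fd <- format_dimension(tax)
  step_name <- function(i)
    sprintf("step%d_%s", i, sanitize_id(solution$steps[[i]]$tool_id))
  source_of <- function(inst_id) {
    prod <- solution$types[[inst_id]]$producer
    if (is.null(prod)) inst_id else sprintf("%s/%s", step_name(prod), inst_id)
  }
  inputs <- list()
  for (id in solution$input_ids)
    inputs[[id]] <- list(type = "File",
                         format = solution$types[[id]]$signature[[fd]])
  steps <- list()
  for (st in solution$steps) {
    ins <- list()
    for (s in seq_along(st$inputs))
      ins[[sprintf("in%d", s)]] <- source_of(st$inputs[s])
    steps[[step_name(st$index)]] <- list(
      doc = sprintf("%s (%s)", st$label, st$tool_id),
      intent = as.list(st$operations),
      `in` = ins,
      out = as.list(st$outputs))
  }
  outputs <- list()
  for (r in seq_along(solution$output_ids)) {
    id <- solution$output_ids[r]
    outputs[[sprintf("out%d", r)]] <- list(
      type = "File",
      format = solution$types[[id]]$signature[[fd]],
      outputSource = source_of(id))
  }
  list(cwlVersion = "v1.2", class = "Workflow",
       doc = "Abstract workflow generated by flowsynth",
       inputs = inputs, steps = steps, outputs = outputs)
}

#' Render a solution as an abstract CWL v1.2 YAML document
#'
#' Serialization uses sorted map keys and fixed two-space indentation, so
#' the output is byte-stable.
#'
#' @inheritParams cwl_structure
#' @return YAML document as a character string.
#' @export
to_cwl <- function(solution, domain) {
  paste(c(emit_yaml(cwl_structure(solution, domain), 0L), ""),
        collapse = "\n")
}

#' Structurally validate an abstract CWL workflow
#'
#' Checks the contract this package emits: `cwlVersion: v1.2`,
#' `class: Workflow`, non-empty `inputs`, `steps` with `in`/`out`/`intent`,
#' `outputs` with `outputSource`, and referential integrity — every `in`
#' source and every `outputSource` must reference a declared workflow
#' input or a declared `step/output` pair.
#'
#' @param x a structure from [cwl_structure()].
#' @return character vector of problems; empty when valid.
#' @export
validate_cwl_workflow <- function(x) {
  probs <- character(0)
  say <- function(...) probs <<- c(probs, sprintf(...))
  if (!identical(x$cwlVersion, "v1.2")) say("cwlVersion must be 'v1.2'")
  if (!identical(x$class, "Workflow")) say("class must be 'Workflow'")
  if (length(x$inputs) == 0 || is.null(names(x$inputs)))
    say("inputs must be a non-empty map")
  declared <- names(x$inputs)
  for (sn in names(x$steps)) {
    st <- x$steps[[sn]]
    if (length(st$out) == 0) say("step '%s' has no outputs", sn)
    if (length(st$intent) == 0) say("step '%s' has empty intent", sn)
    declared <- c(declared, sprintf("%s/%s", sn, unlist(st$out)))
  }
  check_src <- function(src, where) {
    if (!src %in% declared)
      say("%s references undeclared source '%s'", where, src)
  }
  seen <- names(x$inputs)
  for (sn in names(x$steps)) {
    st <- x$steps[[sn]]
    if (length(st$`in`) == 0) say("step '%s' has no inputs", sn)
    for (k in names(st$`in`)) check_src(st$`in`[[k]],
                                        sprintf("steps.%s.in.%s", sn, k))
    seen <- c(seen, sprintf("%s/%s", sn, unlist(st$out)))
  }
  if (length(x$outputs) == 0) say("outputs must be non-empty")
  for (on in names(x$outputs)) {
    src <- x$outputs[[on]]$outputSource
    if (is.null(src)) say("output '%s' lacks outputSource", on)
    else check_src(src, sprintf("outputs.%s", on))
  }
  probs
}

# --- minimal deterministic YAML emitter ------------------------------------

yaml_scalar <- function(x) {
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.numeric(x)) return(format(x, scientific = FALSE))
  s <- as.character(x)
  if (grepl("[:#{}\\[\\],&*?|>!%@`\"']|^[\\s-]|\\s$|^$|^(true|false|null|~)$",
            s, perl = TRUE))
    paste0('"', gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", s)), '"')
  else s
}

emit_yaml <- function(x, indent) {
  pad <- strrep("  ", indent)
  if (is.list(x) && !is.null(names(x)) && length(x) > 0) {
    out <- character(0)
    for (k in sort(names(x))) {
      v <- x[[k]]
      key <- yaml_scalar(k)
      if (is.list(v) && length(v) > 0) {
        out <- c(out, paste0(pad, key, ":"), emit_yaml(v, indent + 1L))
      } else if (is.list(v)) {
        out <- c(out, paste0(pad, key, ": []"))
      } else if (length(v) == 1) {
        out <- c(out, paste0(pad, key, ": ", yaml_scalar(v)))
      } else {
        out <- c(out, paste0(pad, key, ":"),
                 vapply(v, function(e)
                   paste0(strrep("  ", indent + 1L), "- ", yaml_scalar(e)), ""))
      }
    }
    return(out)
  }
  # sequence
  unlist(lapply(x, function(e) {
    if (is.list(e) || length(e) > 1) {
      sub <- emit_yaml(e, indent + 1L)
      c(paste0(pad, "-"), sub)
    } else {
      paste0(pad, "- ", yaml_scalar(e))
    }
  }))
}
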
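#' Load a run configuration
#'
#' One self-contained JSON file drives a synthesis run.  Required keys:
#' `ontology_path`, `tool_annotations_path`, `operation_root`,
#' `data_roots`, `inputs`.  Optional: `outputs`, `constraints`,
#' `min_length` (1), `max_length` (10), `max_solutions` (100),
#' `output_dir` (`"."`), `exports` (toggles; `text` and `dot` default on,
#' `shell` and `cwl` off), `log_level` (`"info"`).  Relative paths are
#' resolved against the configuration file's directory and
#' existence-checked; the ontology and annotations are loaded and the
#' embedded workflow specification fully resolved.
#'
#' @param path JSON configuration file.
#' @return a `RunConfig` with the loaded `taxonomy`, `tools`, `domain`
#'   and resolved `spec`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop_fs("fs_config_error", "configuration file not found: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop_fs(
                    "fs_config_error", "cannot parse configuration: %s",
                    conditionMessage(e)))
  base <- dirname(normalizePath(path))
  need <- function(key) {
    v <- doc[[key]]
    if (is.null(v))
      stop_fs("fs_config_error", "configuration misses required key '%s'",
              key)
    v
  }
  resolve_path <- function(p, key) {
    p <- as.character(p)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    if (!file.exists(p))
      stop_fs("fs_config_error", "'%s' points to a missing file: %s", key, p)
    p
  }
  ontology_path <- resolve_path(need("ontology_path"), "ontology_path")
  tools_path <- resolve_path(need("tool_annotations_path"),
                             "tool_annotations_path")
  operation_root <- as.character(need("operation_root"))
  data_roots <- as.character(unlist(need("data_roots")))

  taxonomy <- load_taxonomy(ontology_path,
                            dimension_roots = c(operation_root, data_roots),
                            operation_root = operation_root)
  tools <- parse_tool_annotations(tools_path, taxonomy)
  spec <- parse_spec(list(inputs = need("inputs"),
                          outputs = doc$outputs,
                          constraints = doc$constraints,
                          min_length = doc$min_length,
                          max_length = doc$max_length,
                          max_solutions = doc$max_solutions),
                     taxonomy)
  exports <- list(text = TRUE, dot = TRUE, shell = FALSE, cwl = FALSE)
  for (k in names(doc$exports %||% list())) {
    if (!k %in% names(exports))
      stop_fs("fs_config_error", "unknown export toggle '%s'", k)
    exports[[k]] <- isTRUE(doc$exports[[k]])
  }
  structure(list(
    ontology_path = ontology_path,
    tool_annotations_path = tools_path,
    operation_root = operation_root,
    data_roots = data_roots,
    taxonomy = taxonomy,
    tools = tools,
    domain = domain_model(taxonomy, tools),
    spec = spec,
    output_dir = as.character(doc$output_dir %||% "."),
    exports = exports,
    log_level = as.character(doc$log_level %||% "info")
  ), class = "RunConfig")
}

fs_log <- function(config, level, fmt, ...) {
  levels <- c(debug = 0L, info = 1L, warn = 2L, error = 3L, quiet = 4L)
  lv <- config$log_level %||% "info"
  threshold <- if (lv %in% names(levels)) levels[[lv]] else 1L
  if (levels[[level]] >= threshold)
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Execute a complete synthesis run
#'
#' Validates the domain, synthesizes up to `max_solutions` workflows, and
#' writes per-solution files into the output directory: `solution_i.txt`
#' and `solution_i.dot` (plus `solution_i.sh` and `solution_i.cwl` when
#' toggled on and, for shell, when every tool carries a command), and a
#' run summary `solutions.json` listing the tool sequences.
#'
#' @param config a [load_config()] result (the output directory may be
#'   overridden by changing `config$output_dir` first).
#' @return invisibly, a list with `status` (0 when at least one solution
#'   was found, 2 when none), `solutions` and `files`.
#' @export
run_synthesis <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  tax <- config$taxonomy
  per_dim <- vapply(tax$dimensions, function(d)
    sum(vapply(tax$terms, function(t) t$dimension == d, NA)), 0L)
  fs_log(config, "info", "domain: %s terms (%s); %d tools, %d modes",
         length(tax$terms),
         paste(sprintf("%s=%d", vapply(tax$dimensions, iri_fragment, ""),
                       per_dim), collapse = ", "),
         length(config$tools), length(config$domain$modes))
  fs_log(config, "info",
         "spec: %d input(s), %d output(s), %d constraint(s), lengths %d..%d",
         length(config$spec$inputs), length(config$spec$outputs),
         length(config$spec$constraints), config$spec$min_length,
         config$spec$max_length)

  solutions <- synthesize(config$domain, config$spec)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name, content) {
    f <- file.path(config$output_dir, name)
    writeLines(content, f, sep = "")
    files <<- c(files, f)
  }
  summary <- list()
  for (i in seq_along(solutions)) {
    sol <- solutions[[i]]
    if (config$exports$text)
      emit(sprintf("solution_%d.txt", i),
           paste0(to_text(sol, config$domain), "\n"))
    if (config$exports$dot)
      emit(sprintf("solution_%d.dot", i),
           paste0(to_dot(sol, config$domain, "dataflow"), "\n"))
    if (config$exports$shell) {
      sh <- to_shell(sol, config$domain)
      if (!is.na(sh)) emit(sprintf("solution_%d.sh", i), sh)
      else fs_log(config, "info", "solution %d: %s", i, attr(sh, "reason"))
    }
    if (config$exports$cwl)
      emit(sprintf("solution_%d.cwl", i), to_cwl(sol, config$domain))
    summary[[i]] <- list(
      id = i, length = length(sol$steps),
      tools = lapply(sol$steps, function(s) s$tool_id),
      modes = as.list(sol$sequence))
  }
  sfile <- file.path(config$output_dir, "solutions.json")
  jsonlite::write_json(summary, sfile, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, sfile)
  fs_log(config, "info", "%d solution(s) written to %s",
         length(solutions), config$output_dir)
  invisible(list(status = if (length(solutions)) 0L else 2L,
                 solutions = solutions, files = files))
}

cli_help <- function() {
  paste(
    "usage: flowsynth <command> [options]",
    "",
    "commands:",
    "  synthesize       run automated workflow composition",
    "  validate-domain  check the domain model and report problems",
    "  templates        list the constraint template catalog",
    "",
    "options:",
    "  --config PATH         JSON run configuration (required)",
    "  --max-solutions N     override max_solutions",
    "  --output-dir DIR      override output_dir",
    "",
    "exit status: 0 = at least one solution; 2 = no solution; 1 = error",
    sep = "\n")
}

#' Command-line entry point
#'
#' Drives the synthesizer from a self-contained JSON configuration.
#' Subcommands: `synthesize`, `validate-domain`, `templates`.  A wrapper
#' script is installed at `exec/flowsynth` in the package directory.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process arguments).
#' @return integer exit status, invisibly: 0 with at least one solution,
#'   2 with none, 1 on error.
#' @export
fs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0 || args[1] %in% c("-h", "--help", "help")) {
      cat(cli_help(), "\n")
      return(invisible(0L))
    }
    cmd <- args[1]
    opts <- parse_cli_flags(args[-1])
    if (cmd == "templates") {
      for (tpl in list_templates()) {
        shown <- do.call(sprintf, c(list(tpl$pattern),
                                    as.list(paste0("<", tpl$params, ">"))))
        cat(sprintf("%-18s %s\n", tpl$id, shown))
      }
      return(invisible(0L))
    }
    if (is.null(opts$config))
      stop_fs("fs_config_error", "--config is required for '%s'", cmd)
    config <- load_config(opts$config)
    if (!is.null(opts$`max-solutions`))
      config$spec$max_solutions <- as.integer(opts$`max-solutions`)
    if (!is.null(opts$`output-dir`))
      config$output_dir <- opts$`output-dir`
    if (cmd == "validate-domain") {
      rep <- validate_domain(config$taxonomy, config$tools)
      if (nrow(rep) == 0) {
        cat("domain model is well-formed\n")
        0L
      } else {
        for (k in seq_len(nrow(rep)))
          cat(sprintf("[%s] %s: %s\n", rep$kind[k], rep$where[k],
                      rep$detail[k]))
        1L
      }
    } else if (cmd == "synthesize") {
      run_synthesis(config)$status
    } else {
      stop_fs("fs_config_error", "unknown command '%s'", cmd)
    }
  }, fs_error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--[a-z-]+=", a)) {
      key <- sub("^--([a-z-]+)=.*$", "\\1", a)
      opts[[key]] <- sub("^--[a-z-]+=", "", a)
    } else if (grepl("^--[a-z-]+$", a)) {
      key <- sub("^--", "", a)
      if (i == length(args))
        stop_fs("fs_config_error", "flag '%s' needs a value", a)
      i <- i + 1L
      opts[[key]] <- args[i]
    } else {
      stop_fs("fs_config_error", "unrecognized argument '%s'", a)
    }
    i <- i + 1L
  }
  opts
}
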
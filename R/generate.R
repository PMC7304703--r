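#' Parameters for the synthetic domain generator
#'
#' The generator emulates the shape of real semantic domain models: a
#' handful of moderately deep taxonomy trees (EDAM-like dimensions), tools
#' annotated with abstract terms and within-dimension disjunctions, and a
#' specification that is satisfiable by construction thanks to a planted
#' chain of tools leading from the workflow inputs to the requested
#' outputs.
#'
#' @param seed integer seed fixing all randomness.
#' @param n_data_dims number of data dimensions (default 2: type, format).
#' @param terms_per_dim taxonomy terms per dimension, excluding the root.
#' @param depth maximum taxonomy depth below the root.
#' @param n_tools number of random (non-planted) tools.
#' @param max_slots maximum input slots per tool.
#' @param p_disjunction probability that an output dimension annotation is
#'   disjunctive (and that an input annotation lists two alternatives).
#' @param p_abstract probability that an input annotation uses an abstract
#'   (non-leaf) term.
#' @param chain_length length of the planted tool chain.
#' @param exclusive if `TRUE`, the planted chain links through fresh terms
#'   no random tool can produce, making the chain the unique solution at
#'   its length.
#' @param with_commands annotate every tool with a runnable stub shell
#'   command.
#' @export
gen_params <- function(seed = 1L, n_data_dims = 2L, terms_per_dim = 8L,
                       depth = 3L, n_tools = 5L, max_slots = 2L,
                       p_disjunction = 0.3, p_abstract = 0.25,
                       chain_length = 3L, exclusive = FALSE,
                       with_commands = TRUE) {
  stopifnot(n_data_dims >= 1, terms_per_dim >= 1, depth >= 1,
            n_tools >= 0, max_slots >= 1, chain_length >= 1)
  structure(list(seed = as.integer(seed), n_data_dims = as.integer(n_data_dims),
                 terms_per_dim = as.integer(terms_per_dim),
                 depth = as.integer(depth), n_tools = as.integer(n_tools),
                 max_slots = as.integer(max_slots),
                 p_disjunction = p_disjunction, p_abstract = p_abstract,
                 chain_length = as.integer(chain_length),
                 exclusive = isTRUE(exclusive),
                 with_commands = isTRUE(with_commands)),
            class = "GeneratorParams")
}

with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded synthetic domain, tools and specification
#'
#' Same seed, same output — the generator is fully deterministic.  The
#' planted chain is guaranteed executable from the generated workflow
#' inputs and to produce the requested outputs, so the specification is
#' always satisfiable within its length bounds.
#'
#' @param params a [gen_params()] object.
#' @return list with `domain` (a [domain_model()]), `spec`
#'   (a `WorkflowSpec`), `planted` (the chain's mode-id sequence key) and
#'   `params`.
#' @export
generate_domain <- function(params = gen_params()) {
  stopifnot(inherits(params, "GeneratorParams"))
  with_local_seed(params$seed, generate_domain_impl(params))
}

generate_domain_impl <- function(p) {
  op_root <- "urn:flowsynth:op:Operation"
  data_roots <- sprintf("urn:flowsynth:d%d:Dim%d",
                        seq_len(p$n_data_dims), seq_len(p$n_data_dims))
  terms <- list()
  add_term <- function(id, label, dim, parents) {
    terms[[id]] <<- list(id = id, label = label, dimension = dim,
                         parents = parents)
  }
  grow_dim <- function(root, prefix, n) {
    add_term(root, iri_fragment(root), root, character(0))
    ids <- character(n)
    depth <- c(0L); names(depth) <- root
    for (k in seq_len(n)) {
      id <- sprintf("%s:t%02d", prefix, k)
      shallow <- names(depth)[depth < p$depth]
      parent <- if (length(shallow) == 1) shallow else sample(shallow, 1)
      add_term(id, sprintf("%s_t%02d", iri_fragment(root), k), root, parent)
      depth[id] <- depth[[parent]] + 1L
      ids[k] <- id
    }
    ids
  }
  op_terms <- grow_dim(op_root, "urn:flowsynth:op", p$terms_per_dim)
  data_terms <- lapply(seq_len(p$n_data_dims), function(d)
    grow_dim(data_roots[d], sprintf("urn:flowsynth:d%d", d),
             p$terms_per_dim))
  names(data_terms) <- data_roots

  all_parents <- unlist(lapply(terms, function(t) t$parents),
                        use.names = FALSE)
  leaf_terms <- lapply(data_terms, function(ids)
    ids[!ids %in% all_parents])
  pick <- function(x, n = 1) if (length(x) == 1) rep(x, n) else sample(x, n, replace = FALSE)
  rand_in_sig <- function(pool) {
    sig <- list()
    for (d in data_roots) {
      cand <- pool[[d]]
      if (stats::runif(1) >= p$p_abstract && length(leaf_terms[[d]]) > 0)
        cand <- leaf_terms[[d]]
      k <- if (stats::runif(1) < p$p_disjunction && length(cand) > 1) 2 else 1
      sig[[d]] <- sort(pick(cand, k))
    }
    sig
  }
  rand_out_sig <- function(pool) {
    sig <- list()
    for (d in data_roots) {
      k <- if (stats::runif(1) < p$p_disjunction && length(pool[[d]]) > 1)
        sample(2:min(3, length(pool[[d]])), 1) else 1
      sig[[d]] <- sort(pick(pool[[d]], k))
    }
    sig
  }
  stub_command <- function(id, n_in, n_out) {
    ins <- paste(sprintf("{in%d}", seq_len(n_in)), collapse = " ")
    cmd <- sprintf("cat %s > {out1}", ins)
    if (n_out > 1)
      cmd <- paste(c(cmd, sprintf("cp {out1} {out%d}", seq(2, n_out))),
                   collapse = " && ")
    cmd
  }
  mk_tool <- function(id, ops, ins, outs) {
    t <- list(id = id, label = id, operations = sort(unique(ops)),
              inputs = ins, outputs = outs,
              command = if (p$with_commands)
                stub_command(id, length(ins), length(outs)) else NULL)
    class(t) <- "ToolAnnotation"
    t
  }

  tools <- list()
  for (j in seq_len(p$n_tools)) {
    n_in <- sample(seq_len(p$max_slots), 1)
    n_out <- if (stats::runif(1) < 0.2) 2 else 1
    tools[[length(tools) + 1L]] <- mk_tool(
      sprintf("tool%02d", j),
      pick(op_terms, sample(1:2, 1)),
      lapply(seq_len(n_in), function(s) rand_in_sig(data_terms)),
      lapply(seq_len(n_out), function(s) rand_out_sig(data_terms)))
  }

  # planted chain: link terms are either sampled (default) or fresh
  # children of each dimension root (exclusive mode)
  L <- p$chain_length
  link_terms <- function(i) {
    if (p$exclusive) {
      sig <- list()
      for (d in seq_along(data_roots)) {
        id <- sprintf("urn:flowsynth:d%d:planted%02d", d, i)
        add_term(id, sprintf("planted%02d_d%d", i, d), data_roots[d],
                 data_roots[d])
        sig[[data_roots[d]]] <- id
      }
      sig
    } else {
      sig <- list()
      for (d in data_roots) sig[[d]] <- pick(data_terms[[d]], 1)
      sig
    }
  }
  spec_in <- list()
  for (d in data_roots) spec_in[[d]] <- pick(data_terms[[d]], 1)
  prev <- spec_in
  chain_ids <- character(L)
  for (i in seq_len(L)) {
    out_sig <- link_terms(i)
    id <- sprintf("chain%02d", i)
    chain_ids[i] <- id
    tools[[length(tools) + 1L]] <- mk_tool(
      id, pick(op_terms, 1),
      ins = list(prev),
      outs = list(out_sig))
    prev <- out_sig
  }
  spec_out <- list()
  for (d in data_roots) {
    t <- prev[[d]][[1]]
    if (!p$exclusive && stats::runif(1) < 0.3) {
      par <- terms[[t]]$parents
      if (length(par)) t <- par[[1]]
    }
    spec_out[[d]] <- t
  }

  tax <- new_taxonomy(unname(terms), operation_dimension = op_root,
                      data_dimensions = data_roots)
  domain <- domain_model(tax, tools)
  spec <- workflow_spec(
    inputs = list(spec_in),
    outputs = list(spec_out),
    constraints = list(),
    min_length = 1L,
    max_length = L,
    max_solutions = 100L)
  planted <- paste(sprintf("%s@01", chain_ids), collapse = ";")
  list(domain = domain, spec = spec, planted = planted, params = p)
}

#' Write a generated domain to disk as OWL + JSON (+ config)
#'
#' Exercises the real file readers with generated fixtures: the taxonomy
#' is serialized as RDF/XML OWL, the tools as annotation JSON, the spec
#' and paths as a run configuration JSON.
#'
#' @param gen result of [generate_domain()].
#' @param dir output directory (created if needed).
#' @return the config file path.
#' @export
write_generated_domain <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tax <- gen$domain$taxonomy
  write_taxonomy_owl(tax, file.path(dir, "ontology.owl"))
  write_tool_annotations(gen$domain$tools, tax, file.path(dir, "tools.json"))
  cfg <- list(
    ontology_path = "ontology.owl",
    tool_annotations_path = "tools.json",
    operation_root = tax$operation_dimension,
    data_roots = as.list(tax$data_dimensions),
    inputs = lapply(gen$spec$inputs, function(sig) lapply(sig, as.list)),
    outputs = lapply(gen$spec$outputs, function(sig) lapply(sig, as.list)),
    constraints = lapply(gen$spec$constraints, function(c_)
      list(template = c_$template_id, args = as.list(c_$arguments))),
    min_length = gen$spec$min_length,
    max_length = gen$spec$max_length,
    max_solutions = gen$spec$max_solutions,
    output_dir = "out"
  )
  path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  path
}
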
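#' Parse one function formula
#'
#' Function formulas are universally quantified implications in an ASCII
#' predicate-logic dialect:
#'
#' ```
#' forall p. SPa(p) & MDPa(p) & MAPa(p) & DPa(p) -> HT(p)
#' ```
#'
#' `&` conjoins antecedent literals, `|` disjoins them (a formula uses one
#' connective, not both). Unicode input is accepted and normalized
#' (`∀p·(...)`, `∧`, `∨`, `⟶`). The quantifier and
#' patient variable are validated and then discarded: every formula is
#' implicitly universal over the record. An antecedent whose name ends in a
#' lowercase `a`/`b`/`c` suffix is a symptom-condition literal (the suffix is
#' the condition band); any other antecedent names another formula's
#' hypothesis.
#'
#' @param text One formula.
#' @return A `function_formula`: list with `antecedents` (each
#'   `list(type, name, symptom, suffix)`), `connective` (`"and"`/`"or"`) and
#'   `consequent`.
#' @export
parse_formula <- function(text) {
  orig <- text
  # normalize the unicode dialect to ASCII
  text <- gsub("∀", "forall ", text)
  text <- gsub("·|⋅", ".", text)
  text <- gsub("∧", "&", text)
  text <- gsub("∨", "|", text)
  text <- gsub("⟶|→|⇒", "->", text)
  text <- trimws(text)
  m <- regexec("^forall\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*[.]\\s*(.*)$", text)
  g <- regmatches(text, m)[[1]]
  if (!length(g)) stop_domain("syntax error at position 1: expected 'forall <var>.' in: ", orig)
  var <- g[2]
  body <- trimws(g[3])
  # strip one optional layer of wrapping parentheses around the implication
  if (startsWith(body, "(") && endsWith(body, ")")) {
    inner <- substr(body, 2, nchar(body) - 1)
    if (balanced_parens(inner)) body <- trimws(inner)
  }
  arrow <- regexpr("->", body, fixed = TRUE)
  if (arrow < 0) stop_domain("syntax error: missing '->' in: ", orig)
  lhs <- trimws(substr(body, 1, arrow - 1))
  rhs <- trimws(substr(body, arrow + 2, nchar(body)))
  if (!nzchar(lhs)) stop_domain("empty antecedent list in: ", orig)
  has_and <- grepl("&", lhs, fixed = TRUE)
  has_or <- grepl("|", lhs, fixed = TRUE)
  if (has_and && has_or)
    stop_domain("mixed '&' and '|' connectives are not supported in: ", orig)
  connective <- if (has_or) "or" else "and"
  parts <- trimws(strsplit(lhs, if (has_or) "|" else "&", fixed = TRUE)[[1]])
  if (any(!nzchar(parts))) stop_domain("empty antecedent literal in: ", orig)
  antecedents <- lapply(parts, parse_literal, var = var, orig = orig)
  consequent <- parse_literal(rhs, var = var, orig = orig, consequent = TRUE)
  if (consequent$name %in% vapply(antecedents, `[[`, "", "name"))
    stop_domain("consequent ", consequent$name, " appears among its own antecedents")
  structure(list(antecedents = antecedents, connective = connective,
                 consequent = consequent$name, source = trimws(orig)),
            class = "function_formula")
}

balanced_parens <- function(s) {
  depth <- 0L
  for (ch in strsplit(s, "")[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") { depth <- depth - 1L; if (depth < 0L) return(FALSE) }
  }
  depth == 0L
}

parse_literal <- function(tok, var, orig, consequent = FALSE) {
  m <- regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*\\(\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*\\)$",
               tok)
  g <- regmatches(tok, m)[[1]]
  if (!length(g)) stop_domain("syntax error near '", tok, "' in: ", orig)
  if (g[3] != var)
    stop_domain("literal ", g[2], " quantifies '", g[3], "' but the formula binds '",
                var, "' in: ", orig)
  name <- g[2]
  if (consequent) return(list(type = "hypothesis", name = name))
  suffix <- substring(name, nchar(name))
  prefix <- substring(name, 1, nchar(name) - 1)
  if (suffix %in% c("a", "b", "c") && nchar(prefix) &&
      grepl("^[A-Z]", prefix)) {
    list(type = "symptom", name = name, symptom = prefix, suffix = suffix)
  } else {
    list(type = "hypothesis", name = name)
  }
}

#' Build a staged inference net from function formulas
#'
#' Assembles the hierarchical multistage inference net: one stage-0 symptom
#' node per distinct (symptom, condition-suffix) literal, one logic node per
#' formula (conjunction or disjunction of its antecedents), and one hypothesis
#' node per consequent. When several formulas share a consequent their logic
#' nodes are joined by an implicit disjunction node. A hypothesis literal used
#' as an antecedent links that hypothesis in as an intermediate node, making
#' the net multistage. Stages are assigned by longest-path layering (symptom
#' nodes are always stage 0); the graph must be acyclic and every hypothesis
#' literal must have a defining formula.
#'
#' @param formulas List of [parse_formula()] results (or character vector of
#'   formula text).
#' @return An object of class `inference_net` with elements `nodes` (named
#'   list; each node has `name`, `type` in symptom/logic/hypothesis, `stage`,
#'   and for hypothesis nodes `prior`, `ls`, `ln`), `edges` (data frame
#'   `from`/`to`) and `formulas`.
#' @export
build_net <- function(formulas) {
  if (is.character(formulas)) formulas <- lapply(formulas, parse_formula)
  if (!length(formulas)) {
    return(structure(list(nodes = list(),
                          edges = data.frame(from = character(), to = character()),
                          formulas = list()),
                     class = "inference_net"))
  }
  stopifnot(all(vapply(formulas, inherits, logical(1), "function_formula")))
  # deterministic ordering regardless of input order
  key <- vapply(formulas, function(f) paste(f$consequent, f$source), "")
  formulas <- formulas[order(key)]
  consequents <- vapply(formulas, `[[`, "", "consequent")

  nodes <- list()
  edges <- list()
  add_node <- function(name, type, ...) {
    if (is.null(nodes[[name]]))
      nodes[[name]] <<- c(list(name = name, type = type), list(...))
    invisible(name)
  }
  add_edge <- function(from, to)
    edges[[length(edges) + 1L]] <<- data.frame(from = from, to = to)

  for (h in unique(consequents))
    add_node(h, "hypothesis", prior = NULL, ls = NULL, ln = NULL)

  for (idx in seq_along(formulas)) {
    f <- formulas[[idx]]
    h <- f$consequent
    n_for_h <- sum(consequents == h)
    which_of_h <- sum(consequents[seq_len(idx)] == h)
    logic_name <- if (n_for_h > 1L)
      paste0(h, ":", f$connective, which_of_h) else paste0(h, ":", f$connective)
    add_node(logic_name, "logic", op = f$connective)
    for (lit in f$antecedents) {
      if (lit$type == "symptom") {
        add_node(lit$name, "symptom", symptom = lit$symptom, suffix = lit$suffix)
        add_edge(lit$name, logic_name)
      } else {
        if (!(lit$name %in% consequents))
          stop_config("dangling hypothesis literal '", lit$name,
                      "' has no defining formula")
        add_edge(lit$name, logic_name)
      }
    }
    if (n_for_h > 1L) {
      or_name <- paste0(h, ":or")
      add_node(or_name, "logic", op = "or")
      add_edge(logic_name, or_name)
      if (which_of_h == n_for_h) add_edge(or_name, h)
    } else {
      add_edge(logic_name, h)
    }
  }
  edges <- do.call(rbind, edges)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = names(nodes))
  if (!igraph::is_dag(g)) {
    cyc <- tryCatch({
      comp <- igraph::components(g, mode = "strong")
      paste(names(comp$membership)[comp$membership %in%
              which(comp$csize > 1)], collapse = " -> ")
    }, error = function(e) "")
    stop_config("cyclic dependency among formulas: ", cyc)
  }
  # longest-path layering in topological order; symptom nodes pinned to 0
  topo <- names(igraph::topo_sort(g, mode = "out"))
  stage <- setNames(integer(length(nodes)), names(nodes))
  for (v in topo) {
    preds <- edges$from[edges$to == v]
    stage[[v]] <- if (length(preds)) max(stage[preds]) + 1L else 0L
  }
  for (nm in names(nodes)) nodes[[nm]]$stage <- stage[[nm]]
  # order nodes by (stage, name) for reproducible traversal
  ord <- order(stage[names(nodes)], names(nodes))
  nodes <- nodes[ord]
  structure(list(nodes = nodes, edges = edges, formulas = formulas),
            class = "inference_net")
}

#' @export
print.inference_net <- function(x, ...) {
  types <- vapply(x$nodes, `[[`, "", "type")
  cat("<inference_net> ", sum(types == "symptom"), " symptom, ",
      sum(types == "logic"), " logic, ", sum(types == "hypothesis"),
      " hypothesis nodes; ",
      if (length(x$nodes)) max(vapply(x$nodes, `[[`, 0L, "stage")) else 0,
      " stages\n", sep = "")
  invisible(x)
}

net_hypotheses <- function(net)
  names(Filter(function(n) n$type == "hypothesis", net$nodes))

net_symptom_nodes <- function(net)
  Filter(function(n) n$type == "symptom", net$nodes)

# Direct parents of a node (antecedent -> consequent edges point upward).
node_parents <- function(net, name) net$edges$from[net$edges$to == name]
node_children <- function(net, name) net$edges$to[net$edges$from == name]

# All hypothesis nodes reachable downstream of a node.
downstream_hypotheses <- function(net, name) {
  seen <- character(); frontier <- name
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, node_children, net = net)))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  Filter(function(v) net$nodes[[v]]$type == "hypothesis", seen)
}

# Direct consequents: hypotheses reached through exactly one logic layer.
direct_consequents <- function(net, name) {
  out <- character()
  for (l in node_children(net, name)) {
    for (v in node_children(net, l)) {
      if (net$nodes[[v]]$type == "hypothesis") out <- c(out, v)
      else out <- c(out, Filter(function(w) net$nodes[[w]]$type == "hypothesis",
                                node_children(net, v)))
    }
  }
  sort(unique(out))
}

#' Load the bundled knowledge base
#'
#' Reads the package's formula file (12 formulas covering hypertension and
#' related hemodynamic pathologies) and returns the parsed formulas.
#'
#' @param path Optional path to a knowledge-base file (one formula per line,
#'   `#` comments); default the bundled file.
#' @return List of `function_formula`s.
#' @export
read_knowledge_base <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "formulas.txt", package = "hbfin",
                        mustWork = TRUE)
  if (!file.exists(path)) stop_config("knowledge base file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_formula)
}

#' The bundled inference net
#'
#' [build_net()] applied to [read_knowledge_base()].
#' @return An `inference_net`.
#' @export
default_net <- function() build_net(read_knowledge_base())

#' Serialize / deserialize an inference net
#'
#' Lossless JSON round trip of topology, stages, priors and likelihoods.
#'
#' @param net An `inference_net`.
#' @param path JSON file path.
#' @return `net_to_config` returns `path` invisibly; `config_to_net` the net.
#' @export
net_to_config <- function(net, path) {
  stopifnot(inherits(net, "inference_net"))
  obj <- list(
    nodes = lapply(unname(net$nodes), function(n) {
      n[vapply(n, is.null, logical(1))] <- NULL
      n
    }),
    edges = net$edges,
    formulas = vapply(net$formulas, `[[`, "", "source"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname net_to_config
#' @export
config_to_net <- function(path) {
  if (!file.exists(path)) stop_config("net file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  net <- build_net(vapply(obj$formulas, identity, ""))
  # restore quantification
  for (n in obj$nodes) {
    nm <- n$name
    if (is.null(net$nodes[[nm]]))
      stop_config("net config at /nodes: unknown node '", nm, "'")
    for (f in c("prior", "ls", "ln"))
      if (!is.null(n[[f]])) net$nodes[[nm]][[f]] <- as.numeric(n[[f]])
  }
  for (e in obj$edges)
    if (!nrow(merge(net$edges, data.frame(from = e$from, to = e$to))))
      stop_config("net config at /edges: edge ", e$from, " -> ", e$to,
                  " does not match the rebuilt topology")
  net
}
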
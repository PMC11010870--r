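# Boolean network representation and the BoolNet-dialect file format.

#' Construct a Boolean network
#'
#' A Boolean network is an ordered set of named nodes, each carrying one
#' update rule over the node names.  Rules use the operators `!` (NOT),
#' `&` (AND), `|` (OR), parentheses and the constants `0`/`1`.  Node order
#' is significant: it defines the bit positions used when states are
#' printed or hashed as 0/1 strings.
#'
#' @param rules named character vector or named list mapping each node name
#'   to its rule text (or an already-parsed language object).
#' @return an object of class `boolean_network` with fields `nodes`
#'   (character vector in declaration order), `rules` (named list of
#'   language objects) and `inputs` (nodes whose rule is themselves or a
#'   constant).
#' @examples
#' toggle <- boolean_network(c(A = "!B", B = "!A"))
#' toggle
#' @export
boolean_network <- function(rules) {
  if (length(rules) == 0L) stop("a network needs at least one node",
                                call. = FALSE)
  nodes <- names(rules)
  if (is.null(nodes) || any(!nzchar(nodes)))
    stop("every rule must be named by its node", call. = FALSE)
  if (anyDuplicated(nodes))
    stop("duplicate rule for node(s): ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "),
         call. = FALSE)
  bad <- nodes[!grepl("^[A-Za-z_.][A-Za-z0-9_.]*$", nodes)]
  if (length(bad))
    stop("invalid node name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  parsed <- lapply(seq_along(rules), function(i) {
    r <- rules[[i]]
    if (is.character(r)) parse_rule(r) else {
      check_rule_grammar(r, deparse_rule(r))
      r
    }
  })
  names(parsed) <- nodes
  for (nm in nodes) {
    refs <- rule_symbols(parsed[[nm]])
    undeclared <- setdiff(refs, nodes)
    if (length(undeclared))
      stop("rule for '", nm, "' references undeclared node(s): ",
           paste(undeclared, collapse = ", "), call. = FALSE)
  }
  net <- structure(
    list(nodes = nodes, rules = parsed, inputs = character(0)),
    class = "boolean_network")
  net$inputs <- compute_inputs(net)
  net
}

compute_inputs <- function(net) {
  is_input <- vapply(net$nodes, function(nm) {
    r <- net$rules[[nm]]
    (is.symbol(r) && as.character(r) == nm) || is.numeric(r)
  }, logical(1))
  net$nodes[is_input]
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network:", length(x$nodes), "nodes\n")
  for (nm in x$nodes)
    cat("  ", nm, " <- ", deparse_rule(x$rules[[nm]]), "\n", sep = "")
  if (length(x$inputs))
    cat("inputs:", paste(x$inputs, collapse = ", "), "\n")
  pins <- pinned_values(x)
  if (length(pins))
    cat("pinned:", paste(names(pins), pins, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
format.boolean_network <- function(x, ...) {
  paste0("<boolean_network: ", length(x$nodes), " nodes>")
}

n_nodes <- function(net) length(net$nodes)

#' Parse a network from BoolNet-dialect text
#'
#' Reads the de facto standard logical-model text format: an optional
#' header line `targets, factors`, then one `node, rule` line per node.
#' Comment lines starting with `#` and blank lines are ignored.
#'
#' @param text character scalar with the file content, or a character
#'   vector of lines.
#' @return a [boolean_network()].
#' @seealso [serialize_bnet()], [read_bnet()]
#' @examples
#' parse_bnet("targets, factors\nA, !B\nB, !A")
#' @export
parse_bnet <- function(text) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- trimws(text)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("empty model text", call. = FALSE)
  if (grepl("^targets\\s*,\\s*factors$", lines[1L], ignore.case = TRUE)) {
    lines <- lines[-1L]
    lineno <- lineno[-1L]
  }
  if (!length(lines)) stop("model text declares no rules", call. = FALSE)
  comma <- regexpr(",", lines, fixed = TRUE)
  if (any(comma < 0L))
    stop("line ", lineno[which(comma < 0L)[1L]],
         ": expected 'node, rule'", call. = FALSE)
  nodes <- trimws(substr(lines, 1L, comma - 1L))
  exprs <- trimws(substr(lines, comma + 1L, nchar(lines)))
  if (anyDuplicated(nodes)) {
    dup <- unique(nodes[duplicated(nodes)])
    stop("duplicate rule for node(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  rules <- vector("list", length(nodes))
  names(rules) <- nodes
  for (i in seq_along(nodes)) {
    rules[[i]] <- tryCatch(parse_rule(exprs[i]), error = function(e) {
      stop("line ", lineno[i], ": ", conditionMessage(e), call. = FALSE)
    })
    refs <- setdiff(rule_symbols(rules[[i]]), nodes)
    if (length(refs))
      stop("line ", lineno[i], ": rule for '", nodes[i],
           "' references undeclared node(s): ",
           paste(refs, collapse = ", "), call. = FALSE)
  }
  boolean_network(rules)
}

#' Serialize a network to BoolNet-dialect text
#'
#' Round-trips with [parse_bnet()]: `parse_bnet(serialize_bnet(net))`
#' reproduces `net` exactly, and the output is byte-stable across runs.
#'
#' @param net a [boolean_network()].
#' @return a single character string (LF line endings, trailing newline).
#' @export
serialize_bnet <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  if (!length(net$nodes)) stop("empty network", call. = FALSE)
  body <- vapply(net$nodes, function(nm)
    paste0(nm, ", ", deparse_rule(net$rules[[nm]])), character(1))
  paste0(paste(c("targets, factors", body), collapse = "\n"), "\n")
}

#' Read / write .bnet model files
#'
#' @param path file path.
#' @return `read_bnet` returns a [boolean_network()]; `write_bnet`
#'   invisibly returns `path`.
#' @rdname bnet_io
#' @export
read_bnet <- function(path) {
  parse_bnet(readLines(path, warn = FALSE))
}

#' @param net a [boolean_network()].
#' @rdname bnet_io
#' @export
write_bnet <- function(net, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(serialize_bnet(net), con, eos = NULL, useBytes = TRUE)
  invisible(path)
}

#' Specify a perturbation (set of pinned nodes)
#'
#' Pinning fixes a node permanently at ON (1) or OFF (0), modelling a
#' sustained pharmacological activation or inhibition.
#'
#' @param ... named values, e.g. `perturbation(P = 1, X = 0)`, or a single
#'   named vector/list.
#' @return object of class `perturbation`: a named integer vector of 0/1.
#' @export
perturbation <- function(...) {
  pins <- c(...)
  if (is.list(pins)) pins <- unlist(pins)
  if (!length(pins)) {
    pins <- integer(0)
  } else {
    if (is.null(names(pins)) || any(!nzchar(names(pins))))
      stop("all pinned values must be named by node", call. = FALSE)
    if (!all(pins %in% c(0, 1)))
      stop("pinned values must be 0 or 1", call. = FALSE)
  }
  structure(as.integer(pins), names = names(pins), class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  if (!length(x)) cat("<perturbation: none>\n")
  else cat("<perturbation: ",
           paste(names(x), unclass(x), sep = "=", collapse = ", "),
           ">\n", sep = "")
  invisible(x)
}

#' Apply a perturbation to a network
#'
#' Each pinned node's rule is replaced by the pinned constant; all other
#' rules are unchanged.  The pin set is recorded on the returned network so
#' that simulation entry points clamp pinned bits in every initial state —
#' a pinned node's state therefore never changes during any update.
#'
#' @param net a [boolean_network()].
#' @param pert a [perturbation()] (or named 0/1 vector).
#' @return a `boolean_network` with constant rules at the pinned nodes.
#' @export
apply_perturbation <- function(net, pert) {
  stopifnot(inherits(net, "boolean_network"))
  if (!inherits(pert, "perturbation")) pert <- perturbation(pert)
  if (!length(pert)) return(net)
  missing <- setdiff(names(pert), net$nodes)
  if (length(missing))
    stop("cannot pin undeclared node(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  rules <- net$rules
  for (nm in names(pert)) rules[[nm]] <- as.numeric(pert[[nm]])
  out <- boolean_network(stats::setNames(rules, net$nodes))
  prev <- pinned_values(net)
  merged <- c(prev[setdiff(names(prev), names(pert))],
              stats::setNames(as.integer(pert), names(pert)))
  attr(out, "pinned") <- merged[order(match(names(merged), out$nodes))]
  out
}

#' Pinned nodes of a network
#'
#' @param net a [boolean_network()].
#' @return named integer vector of pinned values (possibly empty).
#' @export
pinned_values <- function(net) {
  p <- attr(net, "pinned")
  if (is.null(p)) integer(0) else p
}

#' Specify phenotype markers
#'
#' Markers score attractors: positive weights mark desirable readouts
#' (e.g. an antisurvival/apoptosis node), negative weights undesirable
#' ones (e.g. prosurvival).  An attractor's preference is the weighted
#' mean marker activity over its states, optionally normalised by the
#' total absolute weight so scores live in \[-1, 1\].
#'
#' @param ... named numeric weights, e.g.
#'   `phenotype_spec(antisurvival = 1, prosurvival = -1)`, or one named
#'   vector.
#' @param normalize logical; divide by `sum(abs(weights))` (default TRUE).
#' @return object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(..., normalize = TRUE) {
  w <- c(...)
  if (is.list(w)) w <- unlist(w)
  if (!length(w)) stop("at least one marker is required", call. = FALSE)
  if (is.null(names(w)) || any(!nzchar(names(w))))
    stop("all marker weights must be named by node", call. = FALSE)
  if (anyDuplicated(names(w)))
    stop("duplicate marker: ",
         paste(unique(names(w)[duplicated(names(w))]), collapse = ", "),
         call. = FALSE)
  structure(list(weights = as.numeric(stats::setNames(w, names(w))) ,
                 markers = names(w), normalize = isTRUE(normalize)),
            class = "phenotype_spec")
}

#' @export
print.phenotype_spec <- function(x, ...) {
  cat("<phenotype_spec: ",
      paste(x$markers, sprintf("%+g", x$weights), sep = "", collapse = ", "),
      if (x$normalize) ", normalized" else "", ">\n", sep = "")
  invisible(x)
}

check_markers <- function(net, spec) {
  stopifnot(inherits(spec, "phenotype_spec"))
  missing <- setdiff(spec$markers, net$nodes)
  if (length(missing))
    stop("marker node(s) not in network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
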
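# Signed interaction digraph derived from the update rules.

#' Construct a signed directed graph
#'
#' @param nodes character vector of node names.
#' @param edges data.frame with columns `from`, `to`, `sign` (+1/-1).
#' @return object of class `signed_graph`.
#' @export
signed_graph <- function(nodes, edges) {
  edges <- as.data.frame(edges)
  if (!nrow(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        sign = integer(0))
  }
  stopifnot(all(c("from", "to", "sign") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$sign <- as.integer(edges$sign)
  if (!all(edges$sign %in% c(-1L, 1L)))
    stop("edge signs must be +1 or -1", call. = FALSE)
  bad <- setdiff(c(edges$from, edges$to), nodes)
  if (length(bad))
    stop("edge endpoint(s) not in node set: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  key <- paste(edges$from, edges$to, edges$sign)
  if (anyDuplicated(key)) edges <- edges[!duplicated(key), ]
  rownames(edges) <- NULL
  structure(list(nodes = as.character(nodes), edges = edges),
            class = "signed_graph")
}

#' @export
print.signed_graph <- function(x, ...) {
  cat("<signed_graph: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " signed edges>\n", sep = "")
  invisible(x)
}

#' Derive the signed interaction graph of a network
#'
#' For every rule and every regulator appearing in it, the rule's
#' monotonicity in that regulator is decided by evaluating the rule over
#' all assignments of its regulators: monotonically increasing gives an
#' activating (+1) edge, decreasing an inhibiting (-1) edge, and a
#' non-monotone dependency gives both ("dual") edges.  Regulators the rule
#' does not actually depend on contribute no edge.
#'
#' @param net a [boolean_network()].
#' @return a [signed_graph()] whose edge set is exactly the set of
#'   functional rule dependencies.
#' @export
derive_signed_graph <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  from <- character(0); to <- character(0); sgn <- integer(0)
  for (nm in net$nodes) {
    expr <- net$rules[[nm]]
    regs <- intersect(net$nodes, rule_symbols(expr))
    if (!length(regs)) next
    k <- length(regs)
    if (k > 20L)
      stop("rule for '", nm, "' has ", k,
           " regulators; monotonicity check over 2^k assignments refused",
           call. = FALSE)
    grid <- as.matrix(expand.grid(rep(list(0:1), k)))
    colnames(grid) <- regs
    env <- lapply(seq_len(k), function(j) as.logical(grid[, j]))
    names(env) <- regs
    vals <- eval_rule_batch(expr, env, nrow(grid))
    for (j in seq_len(k)) {
      on <- grid[, j] == 1L
      # expand.grid enumerates contexts identically within each half, so
      # rows pair up positionally: same context, regulator 0 vs 1
      v0 <- vals[!on]
      v1 <- vals[on]
      inc <- any(v1 > v0)
      dec <- any(v1 < v0)
      if (inc) { from <- c(from, regs[j]); to <- c(to, nm); sgn <- c(sgn, 1L) }
      if (dec) { from <- c(from, regs[j]); to <- c(to, nm); sgn <- c(sgn, -1L) }
    }
  }
  signed_graph(net$nodes, data.frame(from = from, to = to, sign = sgn))
}

#' Convert a signed graph to igraph
#'
#' @param g a [signed_graph()].
#' @return an [igraph::graph] with a `sign` edge attribute.
#' @export
as_igraph_signed <- function(g) {
  stopifnot(inherits(g, "signed_graph"))
  ig <- igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                      vertices = data.frame(name = g$nodes))
  ig
}

#' Export a signed graph as SIF
#'
#' Three-column simple interaction format: source, relation
#' (`activates`/`inhibits`), target.  UTF-8, LF line endings.
#'
#' @param g a [signed_graph()].
#' @param path output file path.
#' @export
write_sif <- function(g, path) {
  stopifnot(inherits(g, "signed_graph"))
  rel <- ifelse(g$edges$sign > 0, "activates", "inhibits")
  lines <- paste(g$edges$from, rel, g$edges$to, sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(paste0(paste(lines, collapse = "\n"),
                   if (length(lines)) "\n" else ""),
            con, eos = NULL, useBytes = TRUE)
  invisible(path)
}

#' Export a signed graph as GraphML
#'
#' @param g a [signed_graph()].
#' @param path output file path.
#' @export
write_graphml_signed <- function(g, path) {
  ig <- as_igraph_signed(g)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
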
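# boolean_network: ordered nodes, one rule per non-source node, and a frozen
# 0/1 (or free, NA) assignment for each designated source node. The node
# order is the canonical bit order of state encodings (leftmost digit of a
# state string = first node).

#' Construct a Boolean network
#'
#' @param rules named list of Boolean expressions (or rule strings), one per
#'   non-source node.
#' @param sources named integer vector of source nodes frozen at 0/1; use
#'   `NA` for a free (unfrozen) input.
#' @param nodes optional node order; defaults to sources followed by rule
#'   targets in the given order.
#' @return an object of class `boolean_network`.
#' @examples
#' boolean_network(
#'   rules = list(A = "NOT B", B = "NOT A"),
#'   sources = c(S = 1)
#' )
#' @export
boolean_network <- function(rules, sources = integer(), nodes = NULL) {
  if (length(rules) == 0L) abort("no rules")
  rules <- lapply(rules, function(r) if (is.character(r)) parse_rule(r) else r)
  src_names <- names(sources) %||% character()
  nodes <- nodes %||% c(src_names, names(rules))
  if (anyDuplicated(nodes)) {
    abort(sprintf(
      "duplicate node name(s): %s",
      paste(unique(nodes[duplicated(nodes)]), collapse = ", ")
    ))
  }
  if (length(intersect(src_names, names(rules))) > 0L) {
    abort("a node cannot be both a source and have a rule")
  }
  used <- unique(unlist(lapply(rules, rule_vars)))
  unknown <- setdiff(used, nodes)
  if (length(unknown) > 0L) {
    abort(sprintf(
      "rule(s) reference undeclared node(s): %s",
      paste(unknown, collapse = ", ")
    ))
  }
  sources <- vapply(sources, function(v) {
    if (is.na(v)) NA_integer_ else as.integer(as.logical(v))
  }, integer(1))
  structure(
    list(nodes = nodes, rules = rules[intersect(nodes, names(rules))],
         sources = sources),
    class = "boolean_network"
  )
}

#' @export
print.boolean_network <- function(x, n = 10, ...) {
  cat(sprintf(
    "<boolean_network> %d nodes (%d sources, %d rules)\n",
    length(x$nodes), length(x$sources), length(x$rules)
  ))
  if (length(x$sources) > 0L) {
    cat("sources:", paste0(
      names(x$sources), "=",
      ifelse(is.na(x$sources), "free", x$sources)
    ), "\n")
  }
  shown <- utils::head(names(x$rules), n)
  for (nm in shown) {
    cat(sprintf("  %s* = %s\n", nm, write_rule(x$rules[[nm]])))
  }
  if (length(x$rules) > length(shown)) {
    cat(sprintf("  ... %d more rules\n", length(x$rules) - length(shown)))
  }
  invisible(x)
}

#' @export
as_tibble.boolean_network <- function(x, ...) {
  tibble(
    node = x$nodes,
    type = ifelse(x$nodes %in% names(x$sources), "source", "regulated"),
    frozen = vapply(x$nodes, function(n) {
      if (n %in% names(x$sources)) x$sources[[n]] else NA_integer_
    }, integer(1)),
    rule = vapply(x$nodes, function(n) {
      if (n %in% names(x$rules)) write_rule(x$rules[[n]]) else NA_character_
    }, character(1))
  )
}

#' Free (non-frozen) nodes of a network
#'
#' Nodes that take part in state updates: all regulated nodes plus any free
#' sources.
#' @param net a `boolean_network`.
#' @return character vector in node order.
#' @export
free_nodes <- function(net) {
  frozen <- names(net$sources)[!is.na(net$sources)]
  setdiff(net$nodes, frozen)
}

#' Frozen source assignment of a network
#'
#' @param net a `boolean_network`.
#' @return named integer vector of the frozen sources.
#' @export
frozen_assignment <- function(net) {
  s <- net$sources[!is.na(net$sources)]
  stats::setNames(as.integer(s), names(s))
}

#' Signed interaction edges of a Boolean network
#'
#' Derives the signed digraph from the literal polarities of the canonical
#' rules: a plain literal contributes an activating edge, a negated literal
#' an inhibiting edge.
#'
#' @param net a `boolean_network`.
#' @return a tibble with columns `from`, `to`, `sign` (+1/-1).
#' @export
signed_edges <- function(net) {
  rows <- purrr::map(names(net$rules), function(tgt) {
    e <- simplify_rule(net$rules[[tgt]])
    if (is.logical(e)) {
      return(NULL)
    }
    cl <- to_canonical(e, target = tgt)
    lits <- unique(unlist(cl$clauses))
    tibble(
      from = sub("^~", "", lits),
      to = tgt,
      sign = ifelse(startsWith(lits, "~"), -1L, 1L)
    )
  })
  dplyr::distinct(dplyr::bind_rows(rows))
}

#' Encode / decode network states
#'
#' States are bit strings in node order of the free nodes (leftmost digit =
#' first node), e.g. `"110000"`.
#'
#' @param bits integer 0/1 vector or matrix (rows = states).
#' @return `state_string()`: character vector; `state_bits()`: integer
#'   matrix.
#' @export
state_string <- function(bits) {
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1L)
  apply(bits, 1L, paste, collapse = "")
}

#' @param x character vector of bit strings.
#' @rdname state_string
#' @export
state_bits <- function(x) {
  t(vapply(
    strsplit(x, ""),
    function(ch) as.integer(ch),
    integer(nchar(x[[1]]))
  ))
}

# substitute frozen sources into every rule (rules referencing only free
# nodes afterwards); used throughout dynamics and reduction
substituted_rules <- function(net, extra = integer()) {
  part <- c(frozen_assignment(net), extra)
  lapply(net$rules, simplify_rule, partial = part)
}
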
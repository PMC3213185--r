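# Random Boolean networks with the structural features the analyses assume:
# frozen source nodes, bounded in-degree, mixed activation/inhibition, and
# (optional) self-loops. Rules are emitted directly in OR-of-ANDs form.

#' Generate a random Boolean network
#'
#' Every non-source node receives a rule in OR-of-ANDs form over randomly
#' chosen regulators with random polarities; sources are frozen at random
#' values. Identical arguments and seed give an identical network.
#'
#' @param n total number of nodes.
#' @param n_sources number of frozen source nodes.
#' @param max_in_degree maximum number of distinct regulators per rule.
#' @param p_negate probability that a literal is negated.
#' @param max_clauses maximum number of AND-clauses per rule (the count is
#'   uniform on `1:max_clauses`).
#' @param p_self probability that a node's own state appears among its
#'   regulators (a self-loop).
#' @param seed optional integer seed (uses and restores the RNG state).
#' @return a [boolean_network()] with nodes `S1..` (sources) and `N1..`.
#' @examples
#' random_boolean_network(8, n_sources = 2, seed = 7)
#' @export
random_boolean_network <- function(n, n_sources = 1, max_in_degree = 3,
                                   p_negate = 0.3, max_clauses = 2,
                                   p_self = 0, seed = NULL) {
  if (n_sources >= n) abort("need n > n_sources")
  if (max_in_degree < 1) abort("max_in_degree must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  srcs <- if (n_sources > 0) paste0("S", seq_len(n_sources)) else character()
  regs <- paste0("N", seq_len(n - n_sources))
  all_nodes <- c(srcs, regs)
  rules <- lapply(regs, function(nd) {
    pool <- setdiff(all_nodes, nd)
    k <- sample.int(max_in_degree, 1L)
    regulators <- sample(pool, min(k, length(pool)))
    if (p_self > 0 && stats::runif(1) < p_self) {
      regulators <- unique(c(regulators, nd))
    }
    nc <- sample.int(max_clauses, 1L)
    clauses <- purrr::map(seq_len(nc), function(i) {
      sz <- sample.int(length(regulators), 1L)
      lits <- sample(regulators, sz)
      neg <- stats::runif(length(lits)) < p_negate
      paste0(ifelse(neg, "~", ""), lits)
    })
    canonical_to_expr(new_canonical_rule(nd, clauses))
  })
  names(rules) <- regs
  sources <- stats::setNames(
    as.integer(stats::runif(n_sources) < 0.5), srcs
  )
  boolean_network(rules, sources)
}

#' Canned regulatory motifs with known attractor structure
#'
#' \describe{
#'   \item{`mutual-inhibition`}{`A* = NOT B, B* = NOT A`: the classic
#'     toggle, fixed points `10` and `01`.}
#'   \item{`negative-feedback-2`}{`A* = NOT B, B* = A`: a single 4-state
#'     complex attractor.}
#'   \item{`self-activation`}{`A* = A`: fixed points `0` and `1`.}
#'   \item{`chain-k`}{`chain-3` etc.: a source feeding a linear cascade,
#'     which mediator elimination collapses to a single edge.}
#' }
#'
#' @param name motif name (see details).
#' @return a [boolean_network()].
#' @export
motif_network <- function(name) {
  if (grepl("^chain-[0-9]+$", name)) {
    k <- as.integer(sub("^chain-", "", name))
    if (k < 2) abort("chain length must be >= 2")
    nodes <- paste0("C", seq_len(k))
    rules <- stats::setNames(
      lapply(seq_len(k - 1L), function(i) as.symbol(nodes[[i]])),
      nodes[-1L]
    )
    return(boolean_network(rules, sources = stats::setNames(NA_integer_, nodes[[1L]])))
  }
  switch(name,
    "mutual-inhibition" = boolean_network(
      list(A = quote(!B), B = quote(!A))
    ),
    "negative-feedback-2" = boolean_network(
      list(A = quote(!B), B = quote(A))
    ),
    "self-activation" = boolean_network(list(A = quote(A))),
    abort(sprintf("unknown motif '%s'", name))
  )
}
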
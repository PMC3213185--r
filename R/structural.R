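# Expanded-network structural analysis. The expanded network makes the sign
# and the combinatorics of regulation explicit: every negated regulator is
# routed through a complementary vertex ("~X", the sustained-OFF state of
# X), and every multi-literal AND clause becomes a composite vertex whose
# inputs are jointly required. All edges of the expanded network denote
# activation; multiple edges into an original/complementary vertex combine
# by OR, edges into a composite vertex by AND.
#
# For survival-type models (every rule carrying a global "AND NOT <death>"
# clause) the construction additionally:
#   * prunes by stabilization: after logical steady state analysis under the
#     frozen sources, originals of stabilized-OFF nodes and complements of
#     stabilized-ON nodes can never be activated and are omitted;
#     complements of stabilized-OFF nodes are activated by the death node
#     (the negation of the printed rule);
#   * attaches the survival clause as one overlay edge ~death -> v per
#     vertex (and death -> ~v on complements). Overlay edges carry path
#     flow but are not sustaining regulators: cascading deletion ignores
#     them.

#' Expand a Boolean network into its unsigned expanded network
#'
#' @param net a `boolean_network` (all sources frozen; see `free_inputs`).
#' @param free_inputs frozen sources kept as symbolic input vertices (path
#'   sources), e.g. `"PDGF"`.
#' @param outputs extra vertices to materialize, e.g. `"~Apoptosis"`.
#' @param survival_node the death node whose `AND NOT <node>` conjunct every
#'   other rule carries; `NULL` for ordinary networks (no overlay edges).
#' @param prune apply stabilization pruning (requires frozen sources).
#' @return an object of class `expanded_network`: list with `vertices`
#'   (named list; each has `class`, `kind` (`"rule"`, `"stub"`, `"input"`),
#'   `clauses` (list of literal vertex-name vectors), `overlay` (logical per
#'   clause)) plus `inputs` and `outputs`.
#' @export
expand_network <- function(net, free_inputs = character(),
                           outputs = character(),
                           survival_node = NULL, prune = !is.null(survival_node)) {
  stripped <- if (!is.null(survival_node)) {
    strip_survival_clause(net, survival_node)
  } else {
    net
  }
  frozen <- frozen_assignment(net)
  stab <- integer()
  if (prune) {
    if (length(frozen) == 0L) {
      abort("stabilization pruning requires frozen sources")
    }
    tr <- logical_steady_state(stripped)
    stab <- tr$stabilized
  }
  input_nodes <- union(
    free_inputs,
    names(net$sources)[is.na(net$sources)]
  )
  keep_frozen <- frozen[setdiff(names(frozen), input_nodes)]
  simp <- lapply(stripped$rules, simplify_rule, partial = keep_frozen)

  vertices <- list()
  overlay_to <- function(vname, neg) {
    # overlay survival clause: ~death -> original, death -> complement
    if (is.null(survival_node)) {
      return(NULL)
    }
    base <- sub("^~", "", vname)
    if (base == survival_node) {
      return(NULL)
    }
    if (neg) survival_node else paste0("~", survival_node)
  }

  cls_for <- function(vname) {
    neg <- startsWith(vname, "~")
    base <- if (neg) substring(vname, 2L) else vname
    if (base %in% input_nodes) {
      # an unfrozen source counts as a present (ON) signal
      val <- if (base %in% names(frozen)) frozen[[base]] else 1L
      active <- (val == 1L) != neg
      return(if (active) list(kind = "input", clauses = list(), overlay = logical())
             else list(kind = "dead"))
    }
    if (base %in% names(keep_frozen)) {
      active <- (keep_frozen[[base]] == 1L) != neg
      return(if (active) list(kind = "stub", clauses = list(), overlay = logical())
             else list(kind = "dead"))
    }
    if (!(base %in% names(simp))) {
      return(list(kind = "dead"))
    }
    if (base %in% names(stab)) {
      if ((stab[[base]] == 1L) == neg) {
        return(list(kind = "dead"))
      }
      if (neg && stab[[base]] == 0L) {
        # complement of a permanently-OFF node: constantly realizable;
        # in survival models it is activated by the death node (the
        # negation of the printed rule), as an overlay edge
        ov <- overlay_to(vname, neg)
        if (!is.null(ov)) {
          return(list(kind = "rule", clauses = list(ov), overlay = TRUE))
        }
        return(list(kind = "stub", clauses = list(), overlay = logical()))
      }
    }
    e <- simp[[base]]
    if (is.logical(e)) {
      active <- isTRUE(e) != neg
      return(if (active) list(kind = "stub", clauses = list(), overlay = logical())
             else list(kind = "dead"))
    }
    if (neg) e <- call("!", e)
    cls <- new_canonical_rule(NULL, dnf_clauses(e))$clauses
    out <- list()
    for (cl in cls) {
      lits <- character()
      skip <- FALSE
      dropped_self <- FALSE
      for (l in sort(cl)) {
        if (l == vname) {
          dropped_self <- TRUE
          next
        }
        if (l == flip_vertex(vname)) {
          skip <- TRUE
          break
        }
        lits <- c(lits, l)
      }
      if (skip) next
      if (length(lits) == 0L) {
        if (dropped_self) next
        # tautological clause: constantly active
        return(list(kind = "stub", clauses = list(), overlay = logical()))
      }
      out[[length(out) + 1L]] <- lits
    }
    out <- unique(out)
    if (length(out) == 0L) {
      return(list(kind = "dead"))
    }
    ov <- overlay_to(vname, neg)
    overlay <- rep(FALSE, length(out))
    if (!is.null(ov)) {
      out[[length(out) + 1L]] <- ov
      overlay <- c(overlay, TRUE)
    }
    list(kind = "rule", clauses = out, overlay = overlay)
  }

  todo <- unique(c(outputs, names(simp)))
  while (length(todo) > 0L) {
    v <- todo[[1L]]
    todo <- todo[-1L]
    if (v %in% names(vertices)) next
    rec <- cls_for(v)
    if (identical(rec$kind, "dead")) {
      vertices[[v]] <- list(kind = "dead")
      next
    }
    vertices[[v]] <- rec
    for (cl in rec$clauses) {
      todo <- c(todo, setdiff(cl, names(vertices)))
    }
  }

  # iterative cleanup: clauses through dead vertices die; a rule vertex with
  # no remaining clauses dies
  repeat {
    changed <- FALSE
    dead <- names(vertices)[vapply(vertices, function(v) {
      identical(v$kind, "dead")
    }, logical(1))]
    for (v in names(vertices)) {
      rec <- vertices[[v]]
      if (!identical(rec$kind, "rule")) next
      keep <- vapply(rec$clauses, function(cl) !any(cl %in% dead), logical(1))
      if (!all(keep)) {
        rec$clauses <- rec$clauses[keep]
        rec$overlay <- rec$overlay[keep]
        if (length(rec$clauses) == 0L) {
          vertices[[v]] <- list(kind = "dead")
        } else {
          vertices[[v]] <- rec
        }
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  vertices <- vertices[!vapply(vertices, function(v) {
    identical(v$kind, "dead")
  }, logical(1))]
  for (v in names(vertices)) {
    vertices[[v]]$class <- if (startsWith(v, "~")) "complementary" else "original"
  }
  structure(
    list(
      vertices = vertices,
      inputs = intersect(input_nodes, names(vertices)),
      outputs = intersect(outputs, names(vertices))
    ),
    class = "expanded_network"
  )
}

#' @export
print.expanded_network <- function(x, ...) {
  cls <- vapply(x$vertices, function(v) v$class, "")
  ncomp <- sum(vapply(x$vertices, function(v) {
    sum(lengths(v$clauses) >= 2L)
  }, integer(1)))
  cat(sprintf(
    "<expanded_network> %d original + %d complementary vertices, %d composite nodes\n",
    sum(cls == "original"), sum(cls == "complementary"), ncomp
  ))
  invisible(x)
}

# edge list with composite vertices materialized; overlay flag per edge
expanded_edges <- function(exp) {
  rows <- list()
  live <- names(exp$vertices)
  for (v in live) {
    rec <- exp$vertices[[v]]
    for (k in seq_along(rec$clauses)) {
      cl <- rec$clauses[[k]]
      if (!all(cl %in% live)) next
      ov <- rec$overlay[[k]]
      if (length(cl) >= 2L) {
        cv <- sprintf("comp:%s:%d", v, k)
        rows[[length(rows) + 1L]] <- tibble(
          from = c(cl, cv), to = c(rep(cv, length(cl)), v),
          overlay = ov
        )
      } else {
        rows[[length(rows) + 1L]] <- tibble(from = cl, to = v, overlay = ov)
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(from = character(), to = character(), overlay = logical()))
  }
  dplyr::bind_rows(rows)
}

#' Vertices of an expanded network as a tibble
#'
#' @param x an `expanded_network`.
#' @param ... unused.
#' @return tibble with `vertex`, `class` (original / complementary /
#'   composite), `kind`.
#' @export
as_tibble.expanded_network <- function(x, ...) {
  ed <- expanded_edges(x)
  comp <- unique(ed$from[startsWith(ed$from, "comp:")])
  dplyr::bind_rows(
    tibble(
      vertex = names(x$vertices),
      class = vapply(x$vertices, function(v) v$class, ""),
      kind = vapply(x$vertices, function(v) v$kind, "")
    ),
    tibble(vertex = comp, class = "composite", kind = "composite")
  )
}

#' Cascading deletion in an expanded network
#'
#' Removes the seed vertex, then iterates to a fixed point: any composite
#' vertex missing one of its inputs is deleted, and any original or
#' complementary vertex that had sustaining inputs and has lost all of them
#' is deleted. Overlay (survival-context) edges do not sustain a vertex.
#' The result is independent of deletion order.
#'
#' @param exp an `expanded_network`.
#' @param seed vertex to delete (original or complementary name).
#' @return the damaged `expanded_network`.
#' @export
cascading_delete <- function(exp, seed) {
  if (seed %in% exp$inputs || seed %in% exp$outputs) {
    abort("cannot delete an input or output vertex")
  }
  if (!(seed %in% names(exp$vertices))) {
    return(exp) # vertex not present: nothing to damage
  }
  verts <- exp$vertices
  sustaining <- lapply(verts, function(v) v$clauses[!v$overlay])
  had <- vapply(sustaining, function(cl) length(cl) > 0L, logical(1))
  dead <- seed
  repeat {
    changed <- FALSE
    for (v in setdiff(names(verts), dead)) {
      cls <- sustaining[[v]]
      keep <- vapply(cls, function(cl) !any(cl %in% dead), logical(1))
      if (!all(keep)) {
        sustaining[[v]] <- cls[keep]
      }
      if (had[[v]] && length(sustaining[[v]]) == 0L) {
        dead <- c(dead, v)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  verts <- verts[setdiff(names(verts), dead)]
  for (v in names(verts)) {
    rec <- verts[[v]]
    keep <- vapply(rec$clauses, function(cl) !any(cl %in% dead), logical(1))
    rec$clauses <- rec$clauses[keep]
    rec$overlay <- rec$overlay[keep]
    verts[[v]] <- rec
  }
  structure(
    list(
      vertices = verts,
      inputs = intersect(exp$inputs, names(verts)),
      outputs = intersect(exp$outputs, names(verts))
    ),
    class = "expanded_network"
  )
}

#' Count simple paths between two vertices of an expanded network
#'
#' Exact count of directed paths with no repeated vertex (composite
#' vertices count as path vertices). Exponential-time enumeration by
#' depth-first search in compiled code; only the count is kept.
#'
#' @param exp an `expanded_network`.
#' @param from,to vertex names.
#' @return the number of simple paths (0 when disconnected).
#' @export
count_simple_paths <- function(exp, from, to) {
  if (identical(from, to)) abort("`from` and `to` must differ")
  ed <- expanded_edges(exp)
  verts <- unique(c(names(exp$vertices), ed$from, ed$to))
  if (!(from %in% verts) || !(to %in% verts)) {
    return(0)
  }
  count_simple_paths_cpp(
    match(ed$from, verts), match(ed$to, verts),
    length(verts), match(from, verts), match(to, verts)
  )
}

#' Importance value of a vertex
#'
#' `1 - N_SP(damaged) / N_SP(intact)`, where `N_SP` counts the simple paths
#' from the input to the output and the damage is the vertex's cascading
#' deletion (or its plain removal with `cascade = FALSE`, the purely
#' topological variant).
#'
#' @param exp an `expanded_network`.
#' @param vertex vertex to disrupt.
#' @param from,to input and output vertices.
#' @param cascade propagate the deletion through lost indispensable
#'   regulators.
#' @return one-row tibble: `vertex`, `n_paths_intact`, `n_paths_damaged`,
#'   `importance`.
#' @export
importance_value <- function(exp, vertex, from, to, cascade = TRUE) {
  n0 <- count_simple_paths(exp, from, to)
  if (n0 == 0) {
    abort("no simple paths from input to output in the intact network")
  }
  dmg <- if (cascade) {
    cascading_delete(exp, vertex)
  } else {
    plain_delete(exp, vertex)
  }
  n1 <- count_simple_paths(dmg, from, to)
  tibble(
    vertex = vertex,
    n_paths_intact = n0, n_paths_damaged = n1,
    importance = 1 - n1 / n0
  )
}

plain_delete <- function(exp, vertex) {
  if (!(vertex %in% names(exp$vertices))) {
    return(exp)
  }
  verts <- exp$vertices[setdiff(names(exp$vertices), vertex)]
  for (v in names(verts)) {
    rec <- verts[[v]]
    keep <- vapply(rec$clauses, function(cl) !(vertex %in% cl), logical(1))
    rec$clauses <- rec$clauses[keep]
    rec$overlay <- rec$overlay[keep]
    verts[[v]] <- rec
  }
  structure(
    list(
      vertices = verts,
      inputs = intersect(exp$inputs, names(verts)),
      outputs = intersect(exp$outputs, names(verts))
    ),
    class = "expanded_network"
  )
}

#' Importance values for a set of candidate disruptions
#'
#' @param exp an `expanded_network`.
#' @param candidates tibble with columns `node` and `vertex` (see
#'   [perturbation_candidates()]), or a character vector of vertices.
#' @param from,to input and output vertices.
#' @param cascade propagate deletions (see [importance_value()]).
#' @return tibble with one row per candidate, sorted by decreasing
#'   importance. A candidate vertex absent from the expanded network scores
#'   0 (its loss disrupts no path).
#' @export
importance_scan <- function(exp, candidates, from, to, cascade = TRUE) {
  if (is.character(candidates)) {
    candidates <- tibble(node = sub("^~", "", candidates), vertex = candidates)
  }
  n0 <- count_simple_paths(exp, from, to)
  if (n0 == 0) {
    abort("no simple paths from input to output in the intact network")
  }
  rows <- purrr::map(seq_len(nrow(candidates)), function(i) {
    v <- candidates$vertex[[i]]
    dmg <- if (cascade) cascading_delete(exp, v) else plain_delete(exp, v)
    n1 <- count_simple_paths(dmg, from, to)
    tibble(
      node = candidates$node[[i]], vertex = v,
      n_paths_damaged = n1, importance = 1 - n1 / n0
    )
  })
  out <- dplyr::bind_rows(rows)
  out$n_paths_intact <- n0
  dplyr::arrange(out, dplyr::desc(.data$importance))
}

#' Candidate structural disruptions from a disease steady state
#'
#' Nodes ON in the disease state are disrupted by deleting their original
#' vertex (knockout); nodes OFF by deleting their complementary vertex
#' (over-expression of the original node).
#'
#' @param state named 0/1 vector of disease steady-state values.
#' @param nodes candidate node names (defaults to all names of `state`).
#' @return tibble with columns `node`, `value`, `vertex`.
#' @export
perturbation_candidates <- function(state, nodes = names(state)) {
  value <- as.integer(state[nodes])
  tibble(
    node = nodes,
    value = value,
    vertex = ifelse(value == 1L, nodes, paste0("~", nodes))
  )
}
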
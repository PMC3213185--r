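# General asynchronous (GA) dynamics: at each step one randomly chosen free
# node is updated. The state transition graph (STG) holds all 2^f states of
# the f free nodes with one labeled edge per node per state (self-loops
# retained when the update leaves the state unchanged).

state_matrix <- function(f) {
  idx <- 0:(2^f - 1L)
  m <- matrix(0L, nrow = length(idx), ncol = f)
  for (j in seq_len(f)) {
    m[, j] <- bitwAnd(bitwShiftR(idx, f - j), 1L) # leftmost digit = node 1
  }
  m
}

#' General-asynchronous successors of a state
#'
#' One successor per free node: the state with that node replaced by its
#' rule value. Frozen sources are never updated.
#'
#' @param net a `boolean_network`.
#' @param state named 0/1 vector over (at least) the free nodes, or a bit
#'   string in free-node order.
#' @return a tibble with columns `updated` (node) and `successor` (bit
#'   string); duplicated successor states appear once per updating node.
#' @export
ga_successors <- function(net, state) {
  fn <- free_nodes(net)
  if (is.character(state)) {
    state <- stats::setNames(as.integer(strsplit(state, "")[[1]]), fn)
  }
  assign <- c(as.list(state[fn]), as.list(frozen_assignment(net)))
  succ <- vapply(fn, function(n) {
    s <- unlist(state[fn])
    if (n %in% names(net$rules)) {
      s[[n]] <- eval_rule(net$rules[[n]], assign)
    } # a free source keeps its value
    paste(s, collapse = "")
  }, character(1))
  tibble(updated = fn, successor = unname(succ))
}

#' Build the general-asynchronous state transition graph
#'
#' Enumerates all `2^f` states over the free nodes and computes, for every
#' state, the successor under each single-node update (vectorized rule
#' evaluation over the whole state space).
#'
#' @param net a `boolean_network`.
#' @param cap maximum number of free nodes (the STG has `2^f` states).
#' @return an object of class `stg`: list with `free` (node names), `succ`
#'   (integer matrix `2^f x f` of 1-based successor state indices) and
#'   `network`.
#' @export
build_stg <- function(net, cap = 20L) {
  fn <- free_nodes(net)
  f <- length(fn)
  if (f > cap) {
    abort(sprintf(
      "state space too large (%d free nodes > cap %d); reduce the network first",
      f, cap
    ))
  }
  sm <- state_matrix(f)
  colnames(sm) <- fn
  assign <- c(
    lapply(seq_len(f), function(j) sm[, j]),
    as.list(frozen_assignment(net))
  )
  names(assign)[seq_len(f)] <- fn
  idx <- 0:(2^f - 1L)
  succ <- matrix(0L, nrow = 2^f, ncol = f)
  for (j in seq_len(f)) {
    n <- fn[[j]]
    newbit <- if (n %in% names(net$rules)) {
      eval_rule(net$rules[[n]], assign)
    } else {
      sm[, j] # free source: no rule, keeps its value
    }
    weight <- bitwShiftL(1L, f - j)
    succ[, j] <- idx - sm[, j] * weight + newbit * weight + 1L
  }
  structure(
    list(free = fn, succ = succ, network = net),
    class = "stg"
  )
}

#' @export
print.stg <- function(x, ...) {
  cat(sprintf(
    "<stg> %d states over %d free nodes (%s)\n",
    nrow(x$succ), length(x$free), paste(x$free, collapse = ", ")
  ))
  invisible(x)
}

stg_states <- function(stg) {
  state_string(state_matrix(length(stg$free)))
}

stg_igraph <- function(stg) {
  n <- nrow(stg$succ)
  from <- rep(seq_len(n), ncol(stg$succ))
  to <- as.vector(stg$succ)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  igraph::V(g)$name <- stg_states(stg)
  g
}

# strongly-connected-component membership + terminality
stg_scc <- function(stg) {
  g <- stg_igraph(stg)
  comp <- igraph::components(g, mode = "strong")$membership
  n <- nrow(stg$succ)
  terminal <- rep(TRUE, max(comp))
  for (j in seq_len(ncol(stg$succ))) {
    leaves <- comp != comp[stg$succ[, j]]
    terminal[unique(comp[leaves])] <- FALSE
  }
  list(membership = comp, terminal = terminal)
}

#' Attractors of a Boolean network
#'
#' For an `stg`, attractors are the terminal strongly-connected components
#' of the state transition graph: fixed points (single state, all updates
#' self-loops) or complex attractors (sets of states among which the system
#' oscillates). For a `boolean_network`, only the fixed points are computed
#' (see [fixed_points()]); fixed points are identical under every update
#' scheme.
#'
#' @param x an `stg` or `boolean_network`.
#' @param ... passed on to methods.
#' @return a tibble with one row per attractor: `attractor` (id), `class`
#'   (`"fixed-point"` or `"complex"`), `n_states`, `states` (list of bit
#'   strings) and `on_fraction` (list of named per-node mean ON fractions
#'   over member states).
#' @export
attractors <- function(x, ...) UseMethod("attractors")

#' @export
attractors.stg <- function(x, ...) {
  scc <- stg_scc(x)
  states <- stg_states(x)
  sm <- state_matrix(length(x$free))
  ids <- which(scc$terminal)
  rows <- purrr::map(seq_along(ids), function(k) {
    members <- which(scc$membership == ids[[k]])
    onf <- colMeans(sm[members, , drop = FALSE])
    names(onf) <- x$free
    tibble(
      attractor = k,
      class = if (length(members) == 1L) "fixed-point" else "complex",
      n_states = length(members),
      states = list(states[members]),
      on_fraction = list(onf)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(purrr::map_chr(out$states, 1)), ]
  out$attractor <- seq_len(nrow(out))
  out
}

#' @export
attractors.boolean_network <- function(x, ...) {
  fp <- fixed_points(x, ...)
  f <- length(free_nodes(x))
  rows <- purrr::map(seq_along(fp), function(k) {
    bits <- state_bits(fp[[k]])[1, ]
    onf <- stats::setNames(as.numeric(bits), free_nodes(x))
    tibble(
      attractor = k, class = "fixed-point", n_states = 1L,
      states = list(fp[[k]]), on_fraction = list(onf)
    )
  })
  dplyr::bind_rows(rows)
}

#' Fixed points of a Boolean network
#'
#' States mapped to themselves by every rule. Below `cap` free nodes the
#' state space is enumerated exhaustively (vectorized); above it a
#' branch-and-propagate constraint search is used. Fixed points are the
#' same for synchronous and asynchronous updating.
#'
#' @param net a `boolean_network`.
#' @param cap exhaustive-enumeration limit (number of free nodes).
#' @return character vector of fixed-point bit strings (free-node order).
#' @export
fixed_points <- function(net, cap = 20L) {
  fn <- free_nodes(net)
  f <- length(fn)
  if (f == 0L) {
    return(character())
  }
  if (f <= cap) {
    sm <- state_matrix(f)
    colnames(sm) <- fn
    assign <- c(
      lapply(seq_len(f), function(j) sm[, j]),
      as.list(frozen_assignment(net))
    )
    names(assign)[seq_len(f)] <- fn
    ok <- rep(TRUE, nrow(sm))
    for (j in seq_len(f)) {
      n <- fn[[j]]
      if (n %in% names(net$rules)) {
        ok <- ok & (eval_rule(net$rules[[n]], assign) == sm[, j])
      } # free sources are trivially fixed
    }
    return(state_string(sm[ok, , drop = FALSE]))
  }
  sols <- solve_fixed_points(net)
  sort(vapply(sols, function(s) paste(s[fn], collapse = ""), ""))
}

# branch & propagate over partial assignments
solve_fixed_points <- function(net) {
  fn <- free_nodes(net)
  base <- frozen_assignment(net)
  rules <- net$rules
  out <- list()
  recurse <- function(assign) {
    repeat {
      changed <- FALSE
      for (n in fn) {
        s <- simplify_rule(
          rules[[n]] %||% as.symbol(n),
          c(base, assign)
        )
        if (is.logical(s)) {
          v <- as.integer(s)
          if (n %in% names(assign)) {
            if (assign[[n]] != v) {
              return(invisible(NULL))
            }
          } else {
            assign[[n]] <- v
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    un <- setdiff(fn, names(assign))
    if (length(un) == 0L) {
      out[[length(out) + 1L]] <<- unlist(assign)
      return(invisible(NULL))
    }
    v <- un[[1L]]
    for (b in c(0L, 1L)) {
      a2 <- assign
      a2[[v]] <- b
      recurse(a2)
    }
  }
  recurse(stats::setNames(list(), character()))
  out
}

#' Basin-of-attraction partition of a state transition graph
#'
#' A state belongs to an attractor's *exclusive* basin when that attractor
#' is the only one reachable from it (attractor members are included: they
#' reach only themselves). All remaining states form the overlap region.
#' Membership is exact graph reachability, not sampling.
#'
#' @param stg an `stg`.
#' @param att attractor tibble from [attractors()]; computed if missing.
#' @return a list with `table` (tibble: one row per attractor with
#'   `n_members`, `n_exclusive`, `percent`) and `overlap` (`n`, `percent`),
#'   plus a logical matrix `reaches` (states x attractors).
#' @export
basin_partition <- function(stg, att = NULL) {
  att <- att %||% attractors(stg)
  states <- stg_states(stg)
  n <- length(states)
  reaches <- matrix(FALSE, nrow = n, ncol = nrow(att))
  for (k in seq_len(nrow(att))) {
    memb <- match(att$states[[k]], states)
    r <- rep(FALSE, n)
    r[memb] <- TRUE
    repeat {
      prev <- r
      for (j in seq_len(ncol(stg$succ))) {
        r <- r | r[stg$succ[, j]]
      }
      if (identical(r, prev)) break
    }
    reaches[, k] <- r
  }
  nexcl <- integer(nrow(att))
  only <- reaches & (rowSums(reaches) == 1L)
  for (k in seq_len(nrow(att))) nexcl[k] <- sum(only[, k])
  tbl <- dplyr::mutate(att,
    attractor_state = purrr::map_chr(.data$states, 1),
    n_members = .data$n_states,
    n_exclusive = nexcl,
    percent = 100 * nexcl / n
  )
  n_overlap <- n - sum(nexcl)
  structure(
    list(
      table = dplyr::select(
        tbl, "attractor", "class", "attractor_state",
        "n_members", "n_exclusive", "percent"
      ),
      overlap = list(n = n_overlap, percent = 100 * n_overlap / n),
      reaches = reaches,
      states = states
    ),
    class = "basin_report"
  )
}

#' @export
print.basin_report <- function(x, ...) {
  print(x$table)
  cat(sprintf(
    "overlap region: %d states (%.2f%%)\n", x$overlap$n, x$overlap$percent
  ))
  invisible(x)
}

#' @export
tidy.basin_report <- function(x, ...) x$table

#' @export
glance.basin_report <- function(x, ...) {
  tibble(
    n_states = length(x$states),
    n_attractors = nrow(x$table),
    n_overlap = x$overlap$n,
    percent_overlap = x$overlap$percent
  )
}

#' Absorption probabilities of the GA Markov chain
#'
#' Treats the state transition graph as a Markov chain in which each of the
#' `f` single-node updates has probability `1/f` (self-loops included) and
#' solves the standard absorbing-chain linear system for the probability of
#' reaching each fixed-point attractor from every transient state.
#'
#' @param stg an `stg`.
#' @param att attractor tibble; all attractors must be fixed points.
#' @return a tibble with one row per transient state: `state`, one
#'   `p_<attractor-state>` column per fixed point.
#' @export
absorption_probabilities <- function(stg, att = NULL) {
  att <- att %||% attractors(stg)
  if (any(att$class != "fixed-point")) {
    abort("absorption analysis requires all attractors to be fixed points")
  }
  states <- stg_states(stg)
  n <- length(states)
  f <- ncol(stg$succ)
  fps <- purrr::map_chr(att$states, 1)
  fp_idx <- match(fps, states)
  transient <- setdiff(seq_len(n), fp_idx)
  t_pos <- match(seq_len(n), transient)
  from <- rep(transient, f)
  to <- as.vector(stg$succ[transient, , drop = FALSE])
  keepQ <- !(to %in% fp_idx)
  Q <- Matrix::sparseMatrix(
    i = t_pos[from[keepQ]], j = t_pos[to[keepQ]],
    x = 1 / f, dims = c(length(transient), length(transient))
  )
  R <- Matrix::sparseMatrix(
    i = t_pos[from[!keepQ]], j = match(to[!keepQ], fp_idx),
    x = 1 / f, dims = c(length(transient), length(fp_idx))
  )
  B <- Matrix::solve(Matrix::Diagonal(length(transient)) - Q, R)
  B <- as.matrix(B)
  res <- max(abs(Matrix::rowSums(B) - 1))
  if (res > 1e-10) {
    warn(sprintf("absorption rows deviate from 1 by up to %.2e", res))
  }
  out <- tibble(state = states[transient])
  for (k in seq_along(fps)) {
    out[[paste0("p_", fps[[k]])]] <- B[, k]
  }
  out
}
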
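# Rule files use one line per node, `Node* = expr` (the `*` marks the future
# state), `#` comments, and `#@ source NAME = 0|1|free` directives declaring
# input nodes. Node order is the order of first appearance.

#' Read a Boolean network from a rule file
#'
#' @param path path to a rule file (or a character vector of lines via
#'   `text`).
#' @param text optional character vector of lines, used instead of `path`.
#' @return a [boolean_network()].
#' @export
read_boolean_network <- function(path = NULL, text = NULL) {
  lines <- text %||% readLines(path, warn = FALSE)
  rules <- list()
  sources <- integer()
  for (k in seq_along(lines)) {
    line <- trimws(lines[[k]])
    m <- regmatches(
      line,
      regexec("^#@\\s*source\\s+([A-Za-z0-9_]+)\\s*=\\s*(0|1|free)\\s*$", line)
    )[[1]]
    if (length(m) == 3L) {
      val <- if (m[3] == "free") NA_integer_ else as.integer(m[3])
      if (m[2] %in% names(sources)) {
        abort(sprintf("line %d: duplicate source declaration for '%s'", k, m[2]))
      }
      sources[[m[2]]] <- val
      next
    }
    line <- sub("#.*$", "", line)
    line <- trimws(line)
    if (!nzchar(line)) next
    m <- regmatches(line, regexec("^([A-Za-z0-9_]+)\\*\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) != 3L) {
      abort(sprintf("line %d: not a rule line: '%s'", k, lines[[k]]))
    }
    if (m[2] %in% names(rules)) {
      abort(sprintf("line %d: duplicate rule for node '%s'", k, m[2]))
    }
    rules[[m[2]]] <- tryCatch(
      parse_rule(m[3]),
      error = function(e) {
        abort(sprintf("line %d: %s", k, conditionMessage(e)))
      }
    )
  }
  if (length(rules) == 0L) abort("no rules in input")
  boolean_network(rules, sources)
}

#' Write a Boolean network to a rule file
#'
#' @param net a `boolean_network`.
#' @param path output path; with `path = NULL` the lines are returned.
#' @return (invisibly) the written lines.
#' @export
write_boolean_network <- function(net, path = NULL) {
  src <- vapply(
    names(net$sources),
    function(n) {
      v <- net$sources[[n]]
      sprintf("#@ source %s = %s", n, if (is.na(v)) "free" else v)
    },
    character(1)
  )
  rl <- vapply(
    names(net$rules),
    function(n) sprintf("%s* = %s", n, write_rule(net$rules[[n]])),
    character(1)
  )
  lines <- c(src, rl)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Bundled T-LGL leukemia survival network fixtures
#'
#' Three transcriptions of the T cell large granular lymphocyte (T-LGL)
#' leukemia survival signaling model:
#' \describe{
#'   \item{`tlgl60`}{the full 60-node / 142-edge network, with the six source
#'     nodes at their disease condition (Stimuli, IL15, PDGF ON; Stimuli2,
#'     CD45, TAX OFF).}
#'   \item{`tlgl18`}{the 18-node sub-network of nodes that do not stabilize
#'     under logical steady state analysis (survival clause restored).}
#'   \item{`tlgl6`}{the 6-node sub-network obtained by mediator elimination
#'     (node order S1P, FLIP, Fas, Ceramide, DISC, Apoptosis).}
#' }
#'
#' @param name one of `"tlgl60"`, `"tlgl18"`, `"tlgl6"`.
#' @return a [boolean_network()].
#' @examples
#' load_tlgl("tlgl6")
#' @export
load_tlgl <- function(name = c("tlgl60", "tlgl18", "tlgl6")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".bnet"),
    package = "boolsig", mustWork = TRUE
  )
  read_boolean_network(path)
}

#' Export a network or graph to standard graph formats
#'
#' Supports Boolean networks (signed interaction graph), state transition
#' graphs and expanded networks. Formats: GraphViz DOT, GraphML, and a plain
#' edge-list TSV. Vertex attributes carry the state bit string (STGs) or the
#' vertex class (expanded networks); output ordering is deterministic.
#'
#' @param x a `boolean_network`, `stg` or `expanded_network`.
#' @param path output file path.
#' @param format `"dot"`, `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(x, path, format = c("dot", "graphml", "tsv")) {
  format <- match.arg(format)
  g <- as_igraph(x)
  if (format == "tsv") {
    el <- igraph::as_data_frame(g, what = "edges")
    utils::write.table(el, path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  } else {
    igraph::write_graph(g, path, format = if (format == "dot") "dot" else "graphml")
  }
  invisible(path)
}

#' Convert package objects to igraph graphs
#'
#' @param x a `boolean_network`, `stg` or `expanded_network`.
#' @return an [igraph::graph] object.
#' @export
as_igraph <- function(x) UseMethod("as_igraph")

#' @export
as_igraph.boolean_network <- function(x) {
  ed <- signed_edges(x)
  g <- igraph::graph_from_data_frame(
    ed,
    directed = TRUE,
    vertices = data.frame(name = x$nodes)
  )
  g
}

#' @export
as_igraph.stg <- function(x) {
  stg_igraph(x)
}

#' @export
as_igraph.expanded_network <- function(x) {
  ed <- expanded_edges(x)
  verts <- as_tibble(x)[, c("vertex", "class")]
  names(verts) <- c("name", "class")
  if (nrow(ed) == 0L) {
    return(igraph::make_empty_graph(n = nrow(verts)) |>
      igraph::set_vertex_attr("name", value = verts$name) |>
      igraph::set_vertex_attr("class", value = verts$class))
  }
  igraph::graph_from_data_frame(ed[, c("from", "to")],
    directed = TRUE, vertices = verts
  )
}

#' Attractor / basin / perturbation report as JSON
#'
#' Serializes an analysis into a small JSON document (network name, node
#' order, attractor bit strings, basin counts and percentages).
#'
#' @param net the analyzed `boolean_network`.
#' @param attractors tibble from [attractors()].
#' @param basins optional tibble from [basin_partition()].
#' @param path output path; `NULL` returns the JSON string.
#' @param name network label stored in the report.
#' @return the JSON string, invisibly if written to a file.
#' @export
write_report <- function(net, attractors, basins = NULL, path = NULL,
                         name = "network") {
  doc <- list(
    network = name,
    node_order = free_nodes(net),
    attractors = lapply(seq_len(nrow(attractors)), function(i) {
      list(
        class = attractors$class[[i]],
        states = attractors$states[[i]]
      )
    })
  )
  if (!is.null(basins)) {
    doc$basins <- lapply(seq_len(nrow(basins)), function(i) {
      list(
        attractor = basins$attractor[[i]],
        exclusive_states = basins$n_exclusive[[i]],
        percent = basins$percent[[i]]
      )
    })
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
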
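#' @title Causal loop diagram of supply-chain sustainability challenges
#' @description A causal loop diagram (CLD) is a signed digraph over the
#'   challenges that threaten sustainable drug supply chain management in
#'   inpatient pharmacies. Each node is a challenge typed as a *cause* or an
#'   *effect* (the typing comes from an upstream expert-consensus elicitation);
#'   each edge carries a polarity (+1: the source pushes the target in the
#'   same direction; -1: opposite direction). Closed directed cycles are
#'   feedback loops: a loop with an even number of negative links is
#'   *reinforcing* (amplifies change), with an odd number *balancing*
#'   (self-correcting).
#' @name causal_graph
NULL

#' Construct a validated causal graph
#'
#' @param nodes data.frame with columns `id`, `label`, `role`
#'   (`role` one of `"cause"`, `"effect"`).
#' @param edges data.frame with columns `source`, `target`, `polarity`
#'   (`polarity` +1 or -1). Self-edges and duplicate `(source, target)` pairs
#'   are rejected.
#' @return object of class `causal_graph`.
#' @export
causal_graph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need_n <- c("id", "label", "role")
  need_e <- c("source", "target", "polarity")
  if (nrow(nodes) == 0 && !all(need_n %in% names(nodes)))
    nodes <- data.frame(id = character(), label = character(),
                        role = character(), stringsAsFactors = FALSE)
  if (nrow(edges) == 0 && !all(need_e %in% names(edges)))
    edges <- data.frame(source = character(), target = character(),
                        polarity = numeric(), stringsAsFactors = FALSE)
  if (!all(need_n %in% names(nodes)))
    stop("node table must have columns: ", paste(need_n, collapse = ", "))
  if (!all(need_e %in% names(edges)))
    stop("edge table must have columns: ", paste(need_e, collapse = ", "))

  if (anyDuplicated(nodes$id)) {
    dup <- unique(nodes$id[duplicated(nodes$id)])
    stop("duplicate node id(s): ", paste(dup, collapse = ", "))
  }
  bad_role <- which(!nodes$role %in% c("cause", "effect"))
  if (length(bad_role))
    stop("node row ", bad_role[1L], ": role must be 'cause' or 'effect', got '",
         nodes$role[bad_role[1L]], "'")

  edges$polarity <- suppressWarnings(as.numeric(edges$polarity))
  bad_pol <- which(!edges$polarity %in% c(-1, 1))
  if (length(bad_pol))
    stop("edge row ", bad_pol[1L], ": polarity must be +1 or -1")
  unknown <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(unknown))
    stop("edge references unknown node id(s): ", paste(unknown, collapse = ", "))
  self <- which(edges$source == edges$target)
  if (length(self))
    stop("edge row ", self[1L], ": self-edges are not allowed")
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicate edge (row ", d, "): ", edges$source[d], " -> ", edges$target[d])
  }

  structure(list(nodes = nodes, edges = edges), class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  cat("<causal_graph> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$role == "cause"), " cause / ",
      sum(x$nodes$role == "effect"), " effect), ",
      nrow(x$edges), " signed edges\n", sep = "")
  invisible(x)
}

#' Load a causal graph from node/edge CSV tables
#'
#' @param nodes_path CSV with header `id,label,role`.
#' @param edges_path CSV with header `source,target,polarity`.
#' @return a [causal_graph()].
#' @export
load_causal_graph <- function(nodes_path, edges_path) {
  nodes <- read_csv_checked(nodes_path, c("id", "label", "role"))
  edges <- read_csv_checked(edges_path, c("source", "target", "polarity"))
  causal_graph(nodes, edges)
}

read_csv_checked <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                    colClasses = "character"),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  missing <- setdiff(columns, names(df))
  if (length(missing))
    stop("malformed table ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

#' The packaged reference causal graph
#'
#' The source figure names the seventeen challenges and describes two of the
#' eight loops but does not print the full edge list or edge signs. The
#' packaged graph is therefore a documented *synthetic reconstruction*
#' (see `inst/extdata/causal_nodes_synthetic.csv`): nodes are the seventeen
#' challenges, roles follow the reported 10 cause / 7 effect split, and edges
#' are chosen so that the reconstruction realizes the described B1 and R1
#' loop narratives and contains exactly eight simple feedback loops.
#'
#' @return a [causal_graph()] with 17 nodes.
#' @export
reference_causal_graph <- function() {
  load_causal_graph(
    system.file("extdata", "causal_nodes_synthetic.csv", package = "pharmsd"),
    system.file("extdata", "causal_edges_synthetic.csv", package = "pharmsd"))
}

edge_polarity_lookup <- function(graph) {
  stats::setNames(graph$edges$polarity,
                  paste(graph$edges$source, graph$edges$target, sep = "\r"))
}

#' Polarity of a feedback loop
#'
#' A loop is *reinforcing* iff it has an even number of negative links,
#' *balancing* iff odd. Polarity is invariant under rotation of the cycle.
#'
#' @param loop_nodes ordered node ids of a simple directed cycle (first node
#'   not repeated at the end; closure is implied).
#' @param graph a [causal_graph()] containing every consecutive edge of the
#'   cycle.
#' @return `"reinforcing"` or `"balancing"`.
#' @export
loop_polarity <- function(loop_nodes, graph) {
  stopifnot(inherits(graph, "causal_graph"))
  if (length(loop_nodes) < 2L || anyDuplicated(loop_nodes))
    stop("loop_nodes must be a simple cycle of at least two distinct nodes")
  pol <- edge_polarity_lookup(graph)
  nxt <- c(loop_nodes[-1L], loop_nodes[1L])
  key <- paste(loop_nodes, nxt, sep = "\r")
  found <- pol[key]
  if (anyNA(found)) {
    i <- which(is.na(found))[1L]
    stop("not a cycle in the graph: missing edge ",
         loop_nodes[i], " -> ", nxt[i])
  }
  if (sum(found < 0) %% 2L == 0L) "reinforcing" else "balancing"
}

canonical_cycle <- function(nodes) {
  k <- which(nodes == min(nodes))[1L]
  if (k > 1L) nodes <- c(nodes[k:length(nodes)], nodes[seq_len(k - 1L)])
  nodes
}

#' Enumerate all simple feedback loops
#'
#' Finds every simple directed cycle exactly once (cycles equal up to rotation
#' are one loop; a cycle and its reverse are distinct unless both edge
#' directions exist). Enumeration is an ordered-start depth-first search:
#' cycles are rooted at their lexicographically smallest node, so each is
#' discovered once. Output ordering is deterministic: by smallest node id,
#' then cycle length, then the node sequence.
#'
#' @param graph a [causal_graph()].
#' @param annotations optional data.frame with columns `label` and `cycle`
#'   (node ids joined by `;`) attaching human labels (e.g. `"B1"`, `"R1"`) to
#'   known loops.
#' @return list of `feedback_loop` objects, each with `node_cycle`,
#'   `polarity` and `label` (possibly `NA`). Empty list for acyclic graphs.
#' @export
enumerate_feedback_loops <- function(graph, annotations = NULL) {
  stopifnot(inherits(graph, "causal_graph"))
  ids <- sort(graph$nodes$id)
  adj <- split(graph$edges$target, factor(graph$edges$source, levels = ids))
  adj <- lapply(adj, sort)
  cycles <- list()

  # DFS restricted to nodes >= root (lexicographic), so every cycle is found
  # exactly once, rooted at its smallest node.
  search <- function(root, node, path) {
    for (nb in adj[[node]]) {
      if (nb == root) {
        cycles[[length(cycles) + 1L]] <<- path
      } else if (nb > root && !nb %in% path) {
        search(root, nb, c(path, nb))
      }
    }
  }
  for (root in ids) search(root, root, root)

  ord <- order(vapply(cycles, `[[`, "", 1L),
               lengths(cycles),
               vapply(cycles, paste, "", collapse = "\r"))
  cycles <- cycles[ord]

  ann <- NULL
  if (!is.null(annotations)) {
    ann <- stats::setNames(annotations$label,
                           vapply(strsplit(annotations$cycle, ";", fixed = TRUE),
                                  function(x) paste(canonical_cycle(trimws(x)),
                                                    collapse = ";"), ""))
  }
  lapply(cycles, function(cyc) {
    label <- NA_character_
    if (!is.null(ann)) {
      hit <- ann[paste(cyc, collapse = ";")]
      if (!is.na(hit)) label <- unname(hit)
    }
    structure(list(node_cycle = cyc,
                   polarity = loop_polarity(cyc, graph),
                   label = label),
              class = "feedback_loop")
  })
}

#' @export
print.feedback_loop <- function(x, ...) {
  cat(if (!is.na(x$label)) paste0("[", x$label, "] ") else "",
      paste(c(x$node_cycle, x$node_cycle[1L]), collapse = " -> "),
      "  (", x$polarity, ")\n", sep = "")
  invisible(x)
}

#' Structural summary of a causal graph
#'
#' Counts nodes by role and enumerates feedback loops.
#'
#' @param graph a [causal_graph()].
#' @param annotations optional loop label table, see
#'   [enumerate_feedback_loops()].
#' @return list of class `structure_report`: `n_nodes`, `n_cause`, `n_effect`,
#'   `n_loops`, `loops`.
#' @export
structure_counts <- function(graph, annotations = NULL) {
  stopifnot(inherits(graph, "causal_graph"))
  loops <- enumerate_feedback_loops(graph, annotations)
  structure(list(
    n_nodes = nrow(graph$nodes),
    n_cause = sum(graph$nodes$role == "cause"),
    n_effect = sum(graph$nodes$role == "effect"),
    n_loops = length(loops),
    loops = loops
  ), class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  cat("<structure_report> ", x$n_nodes, " nodes (", x$n_cause, " cause / ",
      x$n_effect, " effect), ", x$n_loops, " feedback loops\n", sep = "")
  for (l in x$loops) print(l)
  invisible(x)
}

#' Loop label annotations for the reference graph
#'
#' @return data.frame with columns `label`, `cycle`, `polarity`.
#' @export
reference_loop_annotations <- function() {
  read_csv_checked(
    system.file("extdata", "causal_loops_synthetic.csv", package = "pharmsd"),
    c("label", "cycle", "polarity"))
}

#' Serialize a structure report to JSON
#'
#' @param report a `structure_report`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
structure_report_json <- function(report, path = NULL) {
  obj <- list(
    n_nodes = report$n_nodes, n_cause = report$n_cause,
    n_effect = report$n_effect, n_loops = report$n_loops,
    loops = lapply(report$loops, function(l)
      list(label = l$label, polarity = l$polarity, cycle = l$node_cycle)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
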
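# Small models and independent oracles shared across tests.

# one stock, one constant inflow
constant_inflow_model <- function() {
  sd_model("constant_inflow", list(
    sd_constant("rate", "units/month"),
    sd_flow("inflow", quote(rate), "units/month"),
    sd_stock("tank", initial = 0, inflows = "inflow", units = "units")
  ))
}

# dS/dt = -lambda * S
decay_model <- function() {
  sd_model("decay", list(
    sd_constant("lambda", "1/month"),
    sd_flow("leak", quote(lambda * tank), "units/month"),
    sd_stock("tank", initial = 100, outflows = "leak", units = "units")
  ))
}

# stock driven by a tabulated per-step flow schedule (can be negative)
schedule_model <- function(schedule, dt) {
  sd_model("schedule", list(
    sd_flow("net", bquote(step_lookup(sched, t, .(dt))), "units/month"),
    sd_stock("tank", initial = 5, inflows = "net", units = "units")
  ), data = list(sched = schedule))
}

# closed two-stock transfer system: material moves A -> B
transfer_model <- function() {
  sd_model("transfer", list(
    sd_constant("k", "1/month"),
    sd_flow("move", quote(k * a), "units/month"),
    sd_stock("a", initial = 30, outflows = "move", units = "units",
             non_negative = TRUE),
    sd_stock("b", initial = 12, inflows = "move", units = "units",
             non_negative = TRUE)
  ))
}

make_graph <- function(edge_str, roles = NULL) {
  # edge_str: c("A+B", "B-A") meaning A -> B (+1), B -> A (-1)
  src <- sub("[+-].*$", "", edge_str)
  tgt <- sub("^[^+-]*[+-]", "", edge_str)
  pol <- ifelse(grepl("\\+", edge_str), 1, -1)
  ids <- sort(unique(c(src, tgt)))
  if (is.null(roles)) roles <- rep("cause", length(ids))
  causal_graph(
    nodes = data.frame(id = ids, label = ids, role = roles),
    edges = data.frame(source = src, target = tgt, polarity = pol))
}

# Exhaustive brute-force simple-cycle oracle: try every subset of nodes and
# every cyclic ordering; independent of the package's DFS enumeration.
brute_force_cycles <- function(graph, max_len = length(graph$nodes$id)) {
  ids <- graph$nodes$id
  has_edge <- local({
    key <- paste(graph$edges$source, graph$edges$target)
    function(a, b) paste(a, b) %in% key
  })
  found <- list()
  seen <- character()
  sizes <- seq(2, min(max_len, length(ids)))
  for (k in sizes) {
    subsets <- utils::combn(ids, k, simplify = FALSE)
    for (sub in subsets) {
      first <- min(sub)
      rest <- setdiff(sub, first)
      perms <- all_permutations(rest)
      for (p in perms) {
        cyc <- c(first, p)
        nxt <- c(cyc[-1], cyc[1])
        if (all(mapply(has_edge, cyc, nxt))) {
          sig <- paste(cyc, collapse = ";")
          if (!sig %in% seen) {
            seen <- c(seen, sig)
            found[[length(found) + 1]] <- cyc
          }
        }
      }
    }
  }
  found
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in all_permutations(x[-i]))
      out[[length(out) + 1]] <- c(x[i], p)
  out
}

random_graph <- function(n_nodes, p_edge = 0.35) {
  ids <- LETTERS[seq_len(n_nodes)]
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- pairs[keep, ]
  edges$polarity <- sample(c(-1, 1), nrow(edges), replace = TRUE)
  causal_graph(
    nodes = data.frame(id = ids, label = ids, role = "cause"),
    edges = edges)
}

cycle_signature <- function(cycles) {
  sort(vapply(cycles, function(cyc) {
    k <- which(cyc == min(cyc))[1]
    if (k > 1) cyc <- c(cyc[k:length(cyc)], cyc[seq_len(k - 1)])
    paste(cyc, collapse = ";")
  }, ""))
}

# hand-built trajectory for comparison/report tests
fake_trajectory <- function(times, series) {
  structure(list(times = times, series = series, model_name = "fake",
                 dt = times[2] - times[1]),
            class = "sd_trajectory")
}
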
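test_that("graph construction validates nodes and edges", {
  empty <- causal_graph(data.frame(), data.frame())
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)

  g <- make_graph(c("A+B", "B-A"))
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 2)

  nodes <- data.frame(id = c("A", "B"), label = c("A", "B"),
                      role = c("cause", "effect"))
  expect_error(causal_graph(nodes,
    data.frame(source = "A", target = "C", polarity = 1)),
    "unknown node")
  expect_error(causal_graph(nodes,
    data.frame(source = "A", target = "A", polarity = 1)),
    "self-edges")
  expect_error(causal_graph(nodes,
    data.frame(source = c("A", "A"), target = c("B", "B"), polarity = c(1, -1))),
    "duplicate edge")
  expect_error(causal_graph(nodes,
    data.frame(source = "A", target = "B", polarity = 2)),
    "polarity")
  expect_error(causal_graph(
    data.frame(id = "A", label = "A", role = "driver"),
    data.frame()), "role")
})

test_that("loading from CSV reports malformed tables", {
  nodes_csv <- withr::local_tempfile(fileext = ".csv")
  edges_csv <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,label,role\nA,Node A,cause\nB,Node B,effect", nodes_csv)
  writeLines("source,target,polarity\nA,B,1\nB,A,-1", edges_csv)
  g <- load_causal_graph(nodes_csv, edges_csv)
  expect_equal(nrow(g$nodes), 2)

  writeLines("from,to\nA,B", edges_csv)
  expect_error(load_causal_graph(nodes_csv, edges_csv), "missing column")
})

test_that("loop polarity follows the negative-edge parity rule", {
  g_rr <- make_graph(c("A+B", "B+A"))
  expect_equal(loop_polarity(c("A", "B"), g_rr), "reinforcing")
  g_rb <- make_graph(c("A+B", "B-A"))
  expect_equal(loop_polarity(c("A", "B"), g_rb), "balancing")

  # rotation invariance
  g3 <- make_graph(c("A+B", "B-C", "C+A"))
  pols <- vapply(list(c("A", "B", "C"), c("B", "C", "A"), c("C", "A", "B")),
                 loop_polarity, "", g3)
  expect_true(all(pols == "balancing"))

  expect_error(loop_polarity(c("A", "C"), g3), "not a cycle")
  expect_error(loop_polarity("A", g3), "at least two")
})

test_that("flipping one edge sign on a loop flips its polarity", {
  set.seed(42)
  for (rep in 1:10) {
    g <- random_graph(5)
    loops <- enumerate_feedback_loops(g)
    if (!length(loops)) next
    loop <- loops[[sample.int(length(loops), 1)]]
    cyc <- loop$node_cycle
    # flip the sign of the first edge on the cycle
    i <- which(g$edges$source == cyc[1] &
                 g$edges$target == c(cyc[-1], cyc[1])[1])
    g$edges$polarity[i] <- -g$edges$polarity[i]
    flipped <- loop_polarity(cyc, g)
    expect_true(flipped != loop$polarity)
  }
})

test_that("cycle enumeration matches the brute-force oracle on random graphs", {
  set.seed(7)
  for (rep in 1:15) {
    g <- random_graph(5)
    got <- cycle_signature(lapply(enumerate_feedback_loops(g),
                                  `[[`, "node_cycle"))
    want <- cycle_signature(brute_force_cycles(g))
    expect_identical(got, want)
  }
})

test_that("enumeration is deterministic, acyclic-safe and rotation-unique", {
  chain <- make_graph(c("A+B", "B+C"))
  expect_identical(enumerate_feedback_loops(chain), list())

  two <- make_graph(c("A+B", "B+A"))
  loops <- enumerate_feedback_loops(two)
  expect_length(loops, 1)
  expect_identical(loops[[1]]$node_cycle, c("A", "B"))

  g <- random_graph(6)
  l1 <- enumerate_feedback_loops(g)
  l2 <- enumerate_feedback_loops(g)
  expect_identical(l1, l2)
})

test_that("structure counts summarize roles and loops", {
  empty <- causal_graph(data.frame(), data.frame())
  sc <- structure_counts(empty)
  expect_equal(sc$n_nodes, 0)
  expect_equal(sc$n_cause + sc$n_effect, 0)
  expect_equal(sc$n_loops, 0)

  tri <- make_graph(c("A+B", "B+C", "C+A"),
                    roles = c("cause", "cause", "effect"))
  sc <- structure_counts(tri)
  expect_equal(sc$n_nodes, 3)
  expect_equal(sc$n_cause, 2)
  expect_equal(sc$n_effect, 1)
  expect_equal(sc$n_loops, length(brute_force_cycles(tri)))
  expect_equal(sc$n_loops, 1)
})

test_that("the reference reconstruction matches the reported structure", {
  g <- reference_causal_graph()
  sc <- structure_counts(g, reference_loop_annotations())
  expect_equal(sc$n_nodes, 17)
  expect_equal(sc$n_cause, 10)
  expect_equal(sc$n_effect, 7)
  expect_equal(sc$n_loops, 8)
  # independent oracle up to length 5 (the enumerator reports none longer
  # than 4, so this covers every loop plus the first absent length)
  expect_lte(max(lengths(lapply(sc$loops, `[[`, "node_cycle"))), 4)
  expect_equal(length(brute_force_cycles(g, max_len = 5)), 8)

  labels <- vapply(sc$loops, `[[`, "", "label")
  pols <- vapply(sc$loops, `[[`, "", "polarity")
  expect_true("B1" %in% labels)
  expect_true("R1" %in% labels)
  expect_equal(unname(pols[labels == "B1"]), "balancing")
  expect_equal(unname(pols[labels == "R1"]), "reinforcing")
  # R1 is the financial-manager / liquidity / cost-analysis cycle
  r1 <- sc$loops[[which(labels == "R1")]]
  expect_setequal(r1$node_cycle, c("no_financial_manager",
                                   "liquidity_problems",
                                   "weak_cost_analysis"))
  js <- structure_report_json(sc)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$n_loops, 8)
})
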
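test_that("path enumeration and rollback agree with hand arithmetic on toy trees", {
  tree <- toy_tree()
  v <- c(p = 0.3)
  lc <- toy_leaf_costs(cost_a = 20, cost_b = 10)

  ep <- enumerate_paths(tree, v, lc)
  expect_equal(nrow(ep), 2)
  expect_equal(ep$path_prob[ep$leaf_id == "b"], 0.3)
  expect_equal(ep$cost[ep$leaf_id == "b"], 10)
  expect_equal(sum(ep$path_prob), 1)

  rb <- rollback(tree, v, lc)
  expect_equal(rb$cost, 0.3 * 10 + 0.7 * 20)

  # degenerate tree: a single terminal root
  solo <- tibble::tibble(
    node_id = "root", parent = NA_character_, node_type = "terminal",
    prob_ref = NA_character_, prob_op = NA_character_, bundle = "only"
  )
  expect_equal(
    rollback(solo, c(p = 1), tibble::tibble(bundle = "only", cost = 42))$cost,
    42
  )
})

test_that("probabilities multiply down a chain of chance nodes", {
  # three stacked binary chance nodes, continue with probability 0.5 each
  rows <- list(list(node_id = "n0", parent = NA_character_, node_type = "chance",
                    prob_ref = NA_character_, prob_op = NA_character_,
                    bundle = NA_character_))
  for (i in 1:3) {
    parent <- paste0("n", i - 1)
    rows <- c(rows, list(
      list(node_id = paste0("stop", i), parent = parent, node_type = "terminal",
           prob_ref = NA_character_, prob_op = "complement",
           bundle = paste0("stop", i)),
      list(node_id = if (i < 3) paste0("n", i) else "deep", parent = parent,
           node_type = if (i < 3) "chance" else "terminal",
           prob_ref = "p", prob_op = "param",
           bundle = if (i < 3) NA_character_ else "deep")
    ))
  }
  tree <- dplyr::bind_rows(rows)
  lc <- tibble::tibble(bundle = c("stop1", "stop2", "stop3", "deep"), cost = 0)
  ep <- enumerate_paths(tree, c(p = 0.5), lc)
  expect_equal(ep$path_prob[ep$leaf_id == "deep"], 0.125)
  expect_equal(sum(ep$path_prob), 1)
})

test_that("the packaged tree is well-formed and its leaves cover the topology", {
  study <- uganda_study()
  tree <- study$tree
  expect_equal(sum(tree$node_type == "terminal"), 288)

  v <- param_values(study$parameters)
  lc <- bundle_cost_table(study$bundles, v)
  ep <- enumerate_paths(tree, v, lc)
  expect_equal(nrow(ep), sum(tree$node_type == "terminal"))
  expect_equal(sum(ep$path_prob), 1, tolerance = 1e-9)

  # every probability the tree references exists in the table
  refs <- unique(tree$prob_ref[!is.na(tree$prob_ref)])
  expect_true(all(refs %in% study$parameters$id))

  # zero-probability branches keep the tree valid
  v0 <- v
  v0["p_comp_doctor"] <- 0
  ep0 <- enumerate_paths(tree, v0, lc)
  doctor_comp <- grepl("trained/doctor/success/comp", ep0$leaf_id, fixed = TRUE)
  expect_true(all(ep0$path_prob[doctor_comp] == 0))
  expect_equal(sum(ep0$path_prob), 1, tolerance = 1e-9)
})

test_that("a missing parameter fails the build with its name", {
  params <- uganda_parameters()
  expect_error(
    build_study_tree(params[params$id != "p_access", ], uganda_constants()),
    "p_access"
  )
})

test_that("rollback equals the enumeration oracle on the packaged study", {
  study <- uganda_study()
  v <- param_values(study$parameters)
  lc <- bundle_cost_table(study$bundles, v)
  rb <- rollback(study)
  ep <- enumerate_paths(study$tree, v, lc)
  ev <- colSums(ep$path_prob * as.matrix(ep[, rb$category]))
  expect_equal(max(abs(ev - rb$cost)), 0, tolerance = 1e-9)
})

test_that("expected costs are monotone and linear in terminal costs", {
  study <- uganda_study()
  v <- param_values(study$parameters)
  lc <- bundle_cost_table(study$bundles, v)
  base <- rollback(study$tree, v, lc)

  # doubling every leaf cost doubles every category total
  lc2 <- lc
  lc2[-1] <- lc2[-1] * 2
  expect_equal(rollback(study$tree, v, lc2)$cost, 2 * base$cost, tolerance = 1e-12)

  # raising one leaf's direct medical cost never decreases any total containing it
  lc3 <- lc
  lc3$direct_medical[5] <- lc3$direct_medical[5] + 10
  lc3$societal[5] <- lc3$societal[5] + 10
  after <- rollback(study$tree, v, lc3)
  expect_true(all(after$cost >= base$cost - 1e-12))
})

test_that("malformed trees are rejected", {
  tree <- toy_tree()
  cyc <- tree
  cyc$parent[cyc$node_id == "root"] <- "a" # cycle through the root
  expect_error(validate_tree(cyc), "exactly one root")
  dup <- dplyr::bind_rows(tree, tree[2, ])
  expect_error(validate_tree(dup), "duplicate")
  two_comp <- tree
  two_comp$prob_op[2] <- "complement"
  expect_error(validate_tree(two_comp), "complement")
  nobundle <- tree
  nobundle$bundle[2] <- NA
  expect_error(validate_tree(nobundle), "bundle")
  expect_error(
    enumerate_paths(tree, c(p = 1.7), toy_leaf_costs()),
    "outside \\[0, 1\\]"
  )
})

test_that("tree tables survive a serialization round-trip", {
  study <- uganda_study()
  f <- tempfile(fileext = ".csv")
  write_tree(study$tree, f)
  back <- read_tree(f)
  expect_tibble_equal(study$tree, back, tol = 0)
})
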
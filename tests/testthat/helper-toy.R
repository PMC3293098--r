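# Small hand-built fixtures used across test files.

# two-leaf tree: branch "a" with probability p (complement), branch "b" with
# parameter ref "p"
toy_tree <- function() {
  tibble::tibble(
    node_id = c("root", "b", "a"),
    parent = c(NA, "root", "root"),
    node_type = c("chance", "terminal", "terminal"),
    prob_ref = c(NA, "p", NA),
    prob_op = c(NA, "param", "complement"),
    bundle = c(NA, "b", "a")
  )
}

# direct leaf-cost table (any category columns work)
toy_leaf_costs <- function(cost_a = 20, cost_b = 10) {
  tibble::tibble(bundle = c("a", "b"), cost = c(cost_a, cost_b))
}

# a complete two-leaf coi_study: P(b) = p_mean, leaf costs c_zero / c_hundred
toy_study <- function(p_mean = 0.3, p_low = 0.1, p_high = 0.9,
                      cost = 100, cost_low = cost, cost_high = cost) {
  params <- tibble::tibble(
    id = c("p", "c_leaf"),
    label = c("toy probability", "toy cost"),
    kind = c("probability", "cost"),
    mean = c(p_mean, cost),
    low = c(p_low, cost_low),
    high = c(p_high, cost_high),
    source = "toy"
  )
  bundles <- dplyr::bind_rows(
    tibble::tibble(bundle = "a", item = "zero", category = "direct_medical",
                   payer = "patient", param = NA_character_, constant = 0,
                   multiplier = 1),
    tibble::tibble(bundle = "b", item = "leaf", category = "direct_medical",
                   payer = "patient", param = "c_leaf", constant = NA_real_,
                   multiplier = 1)
  )
  coi_study(params, uganda_constants(), toy_tree(), bundles, name = "toy")
}

expect_tibble_equal <- function(x, y, tol = 1e-12) {
  expect_equal(as.data.frame(x), as.data.frame(y), tolerance = tol)
}
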
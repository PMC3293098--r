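# Decision trees are stored as flat node tables (one row per node, with a
# parent reference), which keeps them pipe-friendly and serializable:
#   node_id   unique name
#   parent    parent node_id (NA for the root)
#   node_type "chance" or "terminal"
#   prob_ref  parameter id giving the probability of the incoming branch
#             (NA for the root and for complement branches)
#   prob_op   "param" or "complement"; a complement branch gets
#             1 - sum(sibling param branches), at most one per chance node
#   bundle    cost-bundle name (terminals only)

#' The cost categories tracked by the model
#'
#' Three economic categories (direct medical, direct non-medical, indirect),
#' two payer views (patient, government) plus an unallocated payer residual,
#' and the societal total (the sum of the three economic categories).
#'
#' @return Character vector of category names.
#' @export
cost_categories <- function() {
  c(
    "direct_medical", "direct_non_medical", "indirect",
    "patient", "government", "unallocated", "societal"
  )
}

#' Validate a decision-tree node table
#'
#' Checks the schema, the single root, parent references, acyclicity,
#' that terminals carry a bundle and no children, and that each chance node
#' has at most one complement branch.
#'
#' @param tree A tree node table (see [build_study_tree()]).
#' @return The tree as a tibble, invisibly usable downstream.
#' @export
validate_tree <- function(tree) {
  tree <- tibble::as_tibble(tree)
  required <- c("node_id", "parent", "node_type", "prob_ref", "prob_op", "bundle")
  missing_cols <- setdiff(required, names(tree))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("tree table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(duplicated(tree$node_id))) {
    rlang::abort(paste0(
      "duplicate node ids: ",
      paste(unique(tree$node_id[duplicated(tree$node_id)]), collapse = ", ")
    ))
  }
  roots <- tree$node_id[is.na(tree$parent)]
  if (length(roots) != 1) rlang::abort("tree must have exactly one root")
  orphan <- setdiff(tree$parent[!is.na(tree$parent)], tree$node_id)
  if (length(orphan) > 0) {
    rlang::abort(paste0("unknown parent ids: ", paste(orphan, collapse = ", ")))
  }
  # depth computation doubles as the acyclicity check
  depth <- node_depths(tree)
  if (anyNA(depth)) {
    rlang::abort("tree contains a cycle or unreachable nodes")
  }
  has_child <- tree$node_id %in% tree$parent
  bad_term <- tree$node_type == "terminal" & has_child
  if (any(bad_term)) {
    rlang::abort(paste0(
      "terminal nodes with children: ", paste(tree$node_id[bad_term], collapse = ", ")
    ))
  }
  no_bundle <- tree$node_type == "terminal" & is.na(tree$bundle)
  if (any(no_bundle)) {
    rlang::abort(paste0(
      "terminals without a cost bundle: ", paste(tree$node_id[no_bundle], collapse = ", ")
    ))
  }
  childless_chance <- tree$node_type == "chance" & !has_child
  if (any(childless_chance)) {
    rlang::abort(paste0(
      "chance nodes without children: ", paste(tree$node_id[childless_chance], collapse = ", ")
    ))
  }
  n_comp <- tapply(tree$prob_op == "complement", tree$parent, sum)
  if (any(n_comp > 1, na.rm = TRUE)) {
    rlang::abort("at most one complement branch per chance node")
  }
  tree
}

node_depths <- function(tree) {
  depth <- stats::setNames(rep(NA_real_, nrow(tree)), tree$node_id)
  depth[is.na(tree$parent)] <- 0
  # iterate: parents may appear after children in arbitrary tables
  for (i in seq_len(nrow(tree) + 1)) {
    new <- depth[tree$parent] + 1
    known <- !is.na(new) & is.na(depth[tree$node_id])
    if (!any(known)) break
    depth[tree$node_id[known]] <- new[known]
    if (i > nrow(tree)) return(rep(NA_real_, nrow(tree))) # cycle guard
  }
  as.numeric(depth[tree$node_id])
}

#' Extract base-case parameter values from a parameter table
#'
#' @param params A validated parameter tibble.
#' @return Named numeric vector of means keyed by parameter id.
#' @export
param_values <- function(params) {
  stats::setNames(params$mean, params$id)
}

# Resolve the probability of every incoming branch under a value vector.
# Returns a numeric vector aligned with tree rows (NA for the root).
resolve_branch_probs <- function(tree, values) {
  prob <- rep(NA_real_, nrow(tree))
  is_param <- !is.na(tree$prob_op) & tree$prob_op == "param"
  refs <- tree$prob_ref[is_param]
  unknown <- setdiff(refs, names(values))
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "branch probability references unknown parameters: ",
      paste(unique(unknown), collapse = ", ")
    ))
  }
  prob[is_param] <- as.numeric(values[refs])
  is_comp <- !is.na(tree$prob_op) & tree$prob_op == "complement"
  for (i in which(is_comp)) {
    sib <- tree$prob_op == "param" & !is.na(tree$parent) &
      tree$parent == tree$parent[i]
    prob[i] <- 1 - sum(prob[which(sib)])
  }
  bad <- which(!is.na(prob) & (prob < -1e-9 | prob > 1 + 1e-9))
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "branch probability outside [0, 1] at node(s): ",
      paste(tree$node_id[bad], collapse = ", ")
    ))
  }
  pmin(pmax(prob, 0), 1)
}

#' Enumerate all root-to-leaf paths of a decision tree
#'
#' The exhaustive-enumeration oracle: one record per leaf with the product of
#' branch probabilities along its path and the leaf's per-category costs.
#' Path probabilities over all leaves sum to 1 (checked to 1e-9).
#'
#' @param tree A tree node table.
#' @param values Named numeric vector of parameter values
#'   (see [param_values()]).
#' @param leaf_costs A bundle cost table from [bundle_cost_table()].
#' @return A tibble with `leaf_id`, `bundle`, `path_prob` and one column per
#'   cost category.
#' @export
enumerate_paths <- function(tree, values, leaf_costs) {
  tree <- validate_tree(tree)
  prob <- resolve_branch_probs(tree, values)
  check_chance_sums(tree, prob)
  depth <- node_depths(tree)
  ord <- order(depth)
  path_prob <- stats::setNames(rep(NA_real_, nrow(tree)), tree$node_id)
  for (i in ord) {
    p <- tree$parent[i]
    path_prob[i] <- if (is.na(p)) 1 else path_prob[p] * prob[i]
  }
  leaves <- tree$node_type == "terminal"
  out <- tibble::tibble(
    leaf_id = tree$node_id[leaves],
    bundle = tree$bundle[leaves],
    path_prob = as.numeric(path_prob[leaves])
  )
  if (abs(sum(out$path_prob) - 1) > 1e-9) {
    rlang::abort("leaf path probabilities do not sum to 1")
  }
  dplyr::left_join(out, leaf_costs, by = "bundle")
}

check_chance_sums <- function(tree, prob) {
  sums <- tapply(prob[!is.na(tree$parent)], tree$parent[!is.na(tree$parent)], sum)
  parents_type <- tree$node_type[match(names(sums), tree$node_id)]
  bad <- names(sums)[parents_type == "chance" & abs(sums - 1) > 1e-9]
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "branch probabilities do not sum to 1 at: ", paste(bad, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Expected cost per category by rollback
#'
#' Bottom-up expected-value computation over the tree: a terminal contributes
#' its bundle's category costs, a chance node the probability-weighted sum of
#' its children. Agrees with the path-enumeration oracle
#' ([enumerate_paths()]) to numerical precision.
#'
#' @param x A tree node table or a [coi_study] object.
#' @param ... Passed to methods.
#' @return A tibble with `category` and `cost` (expected 2010 US$ per case).
#' @export
rollback <- function(x, ...) UseMethod("rollback")

#' @rdname rollback
#' @param values Named numeric vector of parameter values.
#' @param leaf_costs A bundle cost table from [bundle_cost_table()].
#' @export
rollback.data.frame <- function(x, values, leaf_costs, ...) {
  tree <- validate_tree(x)
  prob <- resolve_branch_probs(tree, values)
  check_chance_sums(tree, prob)
  cats <- setdiff(names(leaf_costs), "bundle")
  cost_mat <- as.matrix(leaf_costs[, cats])
  rownames(cost_mat) <- leaf_costs$bundle
  children <- split(seq_len(nrow(tree)), factor(tree$parent, levels = tree$node_id))
  row_of <- stats::setNames(seq_len(nrow(tree)), tree$node_id)

  expected <- function(i) {
    if (tree$node_type[i] == "terminal") {
      b <- tree$bundle[i]
      if (!b %in% rownames(cost_mat)) {
        rlang::abort(paste0("no cost bundle named '", b, "' for terminal ", tree$node_id[i]))
      }
      return(cost_mat[b, ])
    }
    kids <- children[[tree$node_id[i]]]
    acc <- rep(0, length(cats))
    for (k in kids) acc <- acc + prob[k] * expected(k)
    acc
  }
  root <- which(is.na(tree$parent))
  ev <- expected(root)
  tibble::tibble(category = cats, cost = as.numeric(ev))
}

#' Read and write tree node tables
#'
#' Trees serialize to plain CSV with parent references, so a study topology
#' can be stored, diffed and edited without code changes.
#'
#' @param path CSV file path.
#' @return `read_tree()`: a validated tree tibble; `write_tree()`: `path`,
#'   invisibly.
#' @export
read_tree <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    node_id = readr::col_character(), parent = readr::col_character(),
    node_type = readr::col_character(), prob_ref = readr::col_character(),
    prob_op = readr::col_character(), bundle = readr::col_character()
  ))
  validate_tree(raw)
}

#' @rdname read_tree
#' @param tree A tree node table.
#' @export
write_tree <- function(tree, path) {
  cols <- c("node_id", "parent", "node_type", "prob_ref", "prob_op", "bundle")
  readr::write_csv(tree[, cols], path, na = "")
  invisible(path)
}
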
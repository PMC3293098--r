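# Vectorized evaluation engine used by the PSA. The tree is "compiled" once:
# leaf path probabilities are accumulated parent-to-child over a draw matrix,
# and leaf costs factor into (draw matrix) x (item multiplier map) plus a
# fixed offset for constant-valued items, so a 10,000-iteration run is a
# handful of matrix products.

compile_model <- function(tree, bundles) {
  tree <- validate_tree(tree)
  depth <- node_depths(tree)
  ord <- order(depth)
  parent_row <- match(tree$parent, tree$node_id)
  sib_refs <- lapply(seq_len(nrow(tree)), function(i) {
    if (is.na(tree$prob_op[i]) || tree$prob_op[i] != "complement") return(NULL)
    sib <- which(!is.na(tree$parent) & tree$parent == tree$parent[i] &
                   tree$prob_op == "param")
    tree$prob_ref[sib]
  })
  leaves <- which(tree$node_type == "terminal")

  cost_ids <- sort(unique(bundles$param[!is.na(bundles$param)]))
  cats <- cost_categories()
  bundle_levels <- tree$bundle[leaves]
  maps <- lapply(cats, function(cat) {
    keep <- switch(cat,
      direct_medical = bundles$category == "direct_medical",
      direct_non_medical = bundles$category == "direct_non_medical",
      indirect = bundles$category == "indirect",
      patient = !is.na(bundles$payer) & bundles$payer == "patient",
      government = !is.na(bundles$payer) & bundles$payer == "government",
      unallocated = !is.na(bundles$payer) & bundles$payer == "unallocated",
      societal = rep(TRUE, nrow(bundles))
    )
    M <- matrix(0, nrow = length(bundle_levels), ncol = length(cost_ids),
                dimnames = list(bundle_levels, cost_ids))
    off <- stats::setNames(rep(0, length(bundle_levels)), bundle_levels)
    sub <- bundles[keep, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      bnd <- sub$bundle[j]
      if (!bnd %in% bundle_levels) next
      if (is.na(sub$param[j])) {
        off[bnd] <- off[bnd] + sub$multiplier[j] * sub$constant[j]
      } else {
        M[bnd, sub$param[j]] <- M[bnd, sub$param[j]] + sub$multiplier[j]
      }
    }
    list(M = M, off = off)
  })
  names(maps) <- cats
  list(tree = tree, ord = ord, parent_row = parent_row, sib_refs = sib_refs,
       leaves = leaves, cost_ids = cost_ids, maps = maps)
}

# draws: matrix (iterations x parameters) with parameter-id colnames.
# Returns matrix (iterations x categories) of expected per-case costs.
evaluate_draws <- function(compiled, draws) {
  tree <- compiled$tree
  n <- nrow(draws)
  pathp <- vector("list", nrow(tree))
  for (i in compiled$ord) {
    pr <- compiled$parent_row[i]
    if (is.na(pr)) {
      pathp[[i]] <- rep(1, n)
      next
    }
    branch <- if (tree$prob_op[i] == "param") {
      draws[, tree$prob_ref[i]]
    } else {
      refs <- compiled$sib_refs[[i]]
      1 - rowSums(draws[, refs, drop = FALSE])
    }
    pathp[[i]] <- pathp[[pr]] * branch
  }
  P <- do.call(cbind, pathp[compiled$leaves]) # iterations x leaves
  C <- draws[, compiled$cost_ids, drop = FALSE]
  out <- sapply(compiled$maps, function(m) {
    rowSums(C * (P %*% m$M)) + as.numeric(P %*% m$off)
  })
  if (n == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(compiled$maps)))
  out
}

# One seeded generator, parameters drawn in table order: beta draws for
# probabilities, zero-truncated normal draws for costs, point mass if se = 0.
draw_parameters <- function(params, n) {
  cols <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    cols[[i]] <- switch(params$family[i],
      point = rep(params$mean[i], n),
      beta = stats::rbeta(n, params$shape1[i], params$shape2[i]),
      normal = pmax(stats::rnorm(n, params$mean[i], params$sd[i]), 0)
    )
  }
  matrix(unlist(cols), nrow = n, dimnames = list(NULL, params$id))
}

#' Summarize per-iteration category draws
#'
#' @param draws A matrix (iterations x categories) of per-iteration expected
#'   costs, with category column names.
#' @param percentiles Lower/upper credibility percentiles (default 2.5 and
#'   97.5). Empirical quantiles use linear interpolation.
#' @return A tibble with `category`, `mean`, `sd` (sample, n-1 denominator),
#'   `cr_low`, `cr_high`, `min`, `max`.
#' @export
summarize_draws <- function(draws, percentiles = c(2.5, 97.5)) {
  if (nrow(draws) < 1) rlang::abort("need at least one draw")
  if (percentiles[1] < 0 || percentiles[2] > 100 || percentiles[1] >= percentiles[2]) {
    rlang::abort("percentiles must satisfy 0 <= lower < upper <= 100")
  }
  qs <- apply(draws, 2, stats::quantile, probs = percentiles / 100, type = 7, names = FALSE)
  tibble::tibble(
    category = colnames(draws),
    mean = as.numeric(colMeans(draws)),
    sd = if (nrow(draws) > 1) as.numeric(apply(draws, 2, stats::sd)) else rep(0, ncol(draws)),
    cr_low = as.numeric(qs[1, ]),
    cr_high = as.numeric(qs[2, ]),
    min = as.numeric(apply(draws, 2, min)),
    max = as.numeric(apply(draws, 2, max))
  )
}

#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' Each iteration draws every uncertain parameter independently from its
#' fitted distribution (beta for probabilities, normal truncated at zero for
#' costs), re-evaluates the tree, and records the per-category expected cost.
#' Results are bit-reproducible for a fixed seed and iteration count:
#' parameters are drawn in table order from a single seeded generator.
#'
#' @param study A [coi_study] object.
#' @param iterations Number of Monte Carlo iterations (default 10000).
#' @param seed Integer seed.
#' @param percentiles Credibility-range percentiles (default `c(2.5, 97.5)`).
#' @param keep_draws Also keep the full parameter draw matrix (for audit);
#'   category draws are always kept.
#' @return A `coi_psa` object: `summary` tibble (mean, SD, credibility range,
#'   min, max per category), `category_draws`, `basecase`, settings, and
#'   optionally `parameter_draws`. See [tidy.coi_psa()], [autoplot.coi_psa()].
#' @export
run_psa <- function(study, iterations = 10000, seed = 1,
                    percentiles = c(2.5, 97.5), keep_draws = FALSE) {
  if (!inherits(study, "coi_study")) rlang::abort("`study` must be a coi_study object")
  if (iterations < 1) rlang::abort("`iterations` must be >= 1")
  params <- study$parameters
  if (!"family" %in% names(params)) rlang::abort("parameter distributions not fitted")

  set.seed(seed)
  draws <- draw_parameters(params, iterations)
  compiled <- compile_model(study$tree, study$bundles)
  # tree probability references not in the parameter table would fail here
  refs <- unique(study$tree$prob_ref[!is.na(study$tree$prob_ref)])
  unknown <- setdiff(refs, colnames(draws))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unfitted parameters referenced by the tree: ",
                        paste(unknown, collapse = ", ")))
  }
  cat_draws <- evaluate_draws(compiled, draws)
  structure(
    list(
      summary = summarize_draws(cat_draws, percentiles),
      category_draws = cat_draws,
      parameter_draws = if (keep_draws) draws else NULL,
      basecase = rollback(study),
      iterations = iterations, seed = seed, percentiles = percentiles,
      study_name = study$name
    ),
    class = "coi_psa"
  )
}

#' @export
print.coi_psa <- function(x, ...) {
  cat("<coi_psa> ", x$study_name, ": ", x$iterations, " iterations, seed ",
      x$seed, "\n", sep = "")
  s <- x$summary
  s[-1] <- lapply(s[-1], round, 2)
  print(as.data.frame(s), row.names = FALSE)
  invisible(x)
}

#' One-way (tornado) sensitivity analysis of the societal cost
#'
#' Each parameter in turn is set to its low and then its high bound, all
#' others held at base case, and the societal expected cost is re-evaluated
#' by rollback. Entries are ranked by descending spread (ties broken by
#' parameter-table order). Sweeps use the published low/high bounds, not
#' distribution percentiles.
#'
#' @param study A [coi_study] object.
#' @param top_k Number of entries to return (default 20); `Inf` for all.
#' @return A `coi_tornado` tibble: `parameter`, `label`, `low`, `high` (input
#'   bounds), `cost_low`, `cost_high` (societal outputs), `spread`, `rank`,
#'   with the base-case societal cost as attribute `basecase`.
#' @export
run_tornado <- function(study, top_k = 20) {
  if (!inherits(study, "coi_study")) rlang::abort("`study` must be a coi_study object")
  params <- study$parameters
  base_values <- param_values(params)
  compiled <- compile_model(study$tree, study$bundles)
  societal_at <- function(values) {
    d <- matrix(values, nrow = 1, dimnames = list(NULL, names(values)))
    evaluate_draws(compiled, d)[1, "societal"]
  }
  base_soc <- societal_at(base_values)
  sweep_one <- function(id, bound) {
    v <- base_values
    v[id] <- bound
    societal_at(v)
  }
  out <- tibble::tibble(
    parameter = params$id,
    label = params$label,
    low = params$low,
    high = params$high,
    cost_low = purrr::map2_dbl(params$id, params$low, sweep_one),
    cost_high = purrr::map2_dbl(params$id, params$high, sweep_one)
  )
  out$spread <- abs(out$cost_high - out$cost_low)
  out <- out[order(-out$spread, seq_len(nrow(out))), ]
  out$rank <- seq_len(nrow(out))
  out <- utils::head(out, top_k)
  structure(out, class = c("coi_tornado", class(out)), basecase = base_soc)
}
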
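# Random studies with a known analytic expected cost, for validating the
# evaluation engine and the Monte Carlo machinery independently of the
# packaged study. Structure (bounded probabilities with ranges bracketing the
# mean, nonnegative costs with ranges, a chance-node tree with complement
# branches) mirrors the real parameter tables; epidemiological realism is
# deliberately not attempted.

#' Generate a synthetic study with analytic ground truth
#'
#' Draws a random tree topology (depth and branching bounded), a parameter
#' table in the same schema as the packaged study (probability means are
#' normalized per chance node with the last branch a complement; ranges are
#' `mean +/- U(0.2, 1) * min(mean, 1 - mean)`; cost means are log-uniform on
#' `[1, 500]` with proportional ranges), random cost bundles per terminal,
#' and the exact per-category expected cost computed by an independent
#' exhaustive path enumeration at generation time. A small fraction of
#' probability parameters (about `clamp_fraction`) get a full `[0, 1]` range
#' around a small mean to deliberately exercise the beta moment-condition
#' clamp.
#'
#' @param seed Integer seed; generation is fully reproducible.
#' @param max_depth Maximum tree depth (chance-node levels, <= 6).
#' @param max_branching Maximum branches per chance node (<= 4, >= 2).
#' @param n_cost_params Size of the cost-parameter pool.
#' @param clamp_fraction Probability that a probability parameter is given a
#'   degenerate wide range to exercise the clamping path.
#' @return A `coi_synthetic` list: `study` (a [coi_study]), `ground_truth`
#'   (tibble `category`, `cost`), `seed`.
#' @export
generate_study <- function(seed, max_depth = 4, max_branching = 4,
                           n_cost_params = 6, clamp_fraction = 0.05) {
  if (max_depth < 1 || max_depth > 6) rlang::abort("max_depth must be in 1..6")
  if (max_branching < 2 || max_branching > 4) rlang::abort("max_branching must be in 2..4")
  set.seed(seed)

  cost_pool <- tibble::tibble(
    id = paste0("sc_", seq_len(n_cost_params)),
    label = paste0("synthetic cost ", seq_len(n_cost_params)),
    kind = "cost",
    mean = exp(stats::runif(n_cost_params, log(1), log(500))),
    source = "synthetic"
  )
  u <- stats::runif(n_cost_params, 0.1, 0.6)
  cost_pool$low <- cost_pool$mean * (1 - u)
  cost_pool$high <- cost_pool$mean * (1 + u)
  # values are rounded to 6 significant digits so written parameter files
  # round-trip exactly through the CSV reader
  cost_pool[c("mean", "low", "high")] <- lapply(cost_pool[c("mean", "low", "high")], signif, 6)

  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$items <- list()
  env$probs <- list()
  env$np <- 0L
  env$nt <- 0L

  new_prob_param <- function(mean) {
    env$np <- env$np + 1L
    id <- paste0("sp_", env$np)
    if (stats::runif(1) < clamp_fraction) {
      mean <- stats::runif(1, 0.02, 0.06)
      low <- 0; high <- 1 # wide range: se^2 can exceed m(1-m), exercising the clamp
    } else {
      delta <- stats::runif(1, 0.2, 1.0) * min(mean, 1 - mean)
      low <- max(0, mean - delta)
      high <- min(1, mean + delta)
    }
    mean <- signif(mean, 6)
    low <- min(signif(low, 6), mean)
    high <- max(signif(high, 6), mean)
    env$probs[[id]] <- tibble::tibble(
      id = id, label = id, kind = "probability",
      mean = mean, low = low, high = high, source = "synthetic"
    )
    list(id = id, mean = mean)
  }

  random_items <- function() {
    k <- sample(1:3, 1)
    lapply(seq_len(k), function(j) {
      cat <- sample(c("direct_medical", "direct_non_medical", "indirect"), 1)
      payer <- if (cat == "indirect") NA_character_ else sample(c("patient", "government"), 1)
      mult <- stats::runif(1, 0.5, 2)
      if (stats::runif(1) < 0.15) {
        it(paste0("const_item_", j), cat, payer, constant = stats::runif(1, 1, 100),
           multiplier = mult)
      } else {
        it(paste0("item_", j), cat, payer, param = sample(cost_pool$id, 1),
           multiplier = mult)
      }
    })
  }

  add <- function(id, parent, type, ref, op, bundle = NA_character_) {
    env$nodes[[length(env$nodes) + 1]] <- list(
      node_id = id, parent = parent, node_type = type,
      prob_ref = ref, prob_op = op, bundle = bundle
    )
  }

  grow <- function(id, parent, ref, op, depth) {
    terminal <- depth >= max_depth || (depth > 0 && stats::runif(1) < 0.4)
    if (terminal) {
      env$nt <- env$nt + 1L
      add(id, parent, "terminal", ref, op, bundle = id)
      env$items[[length(env$items) + 1]] <- items_tibble(random_items(), bundle = id)
      return(invisible(NULL))
    }
    add(id, parent, "chance", ref, op)
    k <- sample(2:max_branching, 1)
    w <- stats::runif(k, 0.05, 1)
    m <- w / sum(w)
    for (j in seq_len(k)) {
      if (j < k) {
        p <- new_prob_param(m[j])
        grow(paste0(id, "/b", j), id, p$id, "param", depth + 1)
      } else {
        grow(paste0(id, "/b", j), id, NA_character_, "complement", depth + 1)
      }
    }
  }
  grow("root", NA_character_, NA_character_, NA_character_, 0)

  tree <- validate_tree(dplyr::bind_rows(env$nodes))
  bundles <- dplyr::bind_rows(env$items)
  # complement branch means must mirror the generated means: they do by
  # construction (branch means sum to 1 per node)
  params <- validate_parameters(dplyr::bind_rows(c(env$probs, list(cost_pool))))
  constants <- synthetic_constants()
  study <- suppressWarnings(
    coi_study(params, constants, tree, bundles, name = paste0("synthetic seed ", seed))
  )
  gt <- synthetic_ground_truth(tree, bundles, param_values(params))
  structure(list(study = study, ground_truth = gt, seed = seed),
            class = "coi_synthetic")
}

synthetic_constants <- function() {
  list(
    gdp_per_capita = 100, discount_rate = 0.03, age_at_death = 30,
    remaining_life_expectancy = 30, annual_incidence = 1000,
    anc_attendance = 0.9, cesarean_rate = 0.1, facility_delivery_rate = 0.4
  )
}

# Independent oracle: exhaustive depth-first path enumeration with its own
# item arithmetic (shares no code with rollback()/enumerate_paths()).
synthetic_ground_truth <- function(tree, bundles, values) {
  cats <- cost_categories()
  kids <- lapply(tree$node_id, function(id) which(!is.na(tree$parent) & tree$parent == id))
  names(kids) <- tree$node_id
  bundle_cost <- function(bname) {
    rows <- bundles[bundles$bundle == bname, , drop = FALSE]
    v <- ifelse(is.na(rows$param), rows$constant, as.numeric(values[rows$param])) * rows$multiplier
    vapply(cats, function(cat) {
      keep <- switch(cat,
        patient = , government = , unallocated = !is.na(rows$payer) & rows$payer == cat,
        societal = rep(TRUE, nrow(rows)),
        rows$category == cat
      )
      sum(v[keep])
    }, numeric(1))
  }
  branch_p <- function(i) {
    if (is.na(tree$prob_op[i])) return(1)
    if (tree$prob_op[i] == "param") return(as.numeric(values[tree$prob_ref[i]]))
    sibs <- which(!is.na(tree$parent) & tree$parent == tree$parent[i] &
                    tree$prob_op == "param")
    1 - sum(as.numeric(values[tree$prob_ref[sibs]]))
  }
  acc <- stats::setNames(rep(0, length(cats)), cats)
  walk <- function(i, p) {
    p <- p * branch_p(i)
    if (tree$node_type[i] == "terminal") {
      acc <<- acc + p * bundle_cost(tree$bundle[i])
    } else {
      for (j in kids[[tree$node_id[i]]]) walk(j, p)
    }
  }
  walk(which(is.na(tree$parent)), 1)
  tibble::tibble(category = cats, cost = as.numeric(acc))
}

#' @export
print.coi_synthetic <- function(x, ...) {
  cat("<coi_synthetic> seed ", x$seed, "\n", sep = "")
  print(x$study)
  invisible(x)
}

#' Parameter-recovery experiment on a synthetic study
#'
#' Runs the PSA on a synthetic study and compares the per-category Monte
#' Carlo means with the analytic ground truth stored at generation time. The
#' acceptance band is three Monte Carlo standard errors (`3 * sd / sqrt(n)`)
#' from the run itself, plus a small absolute floor for categories the PSA
#' reproduces exactly.
#'
#' @param synth A `coi_synthetic` object from [generate_study()].
#' @param iterations,seed Passed to [run_psa()].
#' @return A tibble with `category`, `ground_truth`, `psa_mean`, `abs_error`,
#'   `mc_bound` (3 sigma), and logical `within`.
#' @export
recovery_experiment <- function(synth, iterations = 10000, seed = 1) {
  if (!inherits(synth, "coi_synthetic")) rlang::abort("`synth` must come from generate_study()")
  psa <- run_psa(synth$study, iterations = iterations, seed = seed)
  s <- psa$summary
  out <- dplyr::left_join(synth$ground_truth, s[, c("category", "mean", "sd")],
                          by = "category")
  out <- dplyr::rename(out, ground_truth = "cost", psa_mean = "mean")
  out$abs_error <- abs(out$psa_mean - out$ground_truth)
  out$mc_bound <- 3 * out$sd / sqrt(psa$iterations)
  out$within <- out$abs_error <= pmax(out$mc_bound, 1e-9)
  out[, c("category", "ground_truth", "psa_mean", "abs_error", "mc_bound", "within")]
}
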
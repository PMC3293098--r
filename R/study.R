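#' Assemble a cost-of-illness study object
#'
#' A `coi_study` ties together the validated parameter table (with fitted
#' sampling distributions), the economic constants, the decision tree and the
#' per-terminal cost bundles. All analysis functions ([rollback()],
#' [run_psa()], [run_tornado()], [basecase_report()]) accept it.
#'
#' @param parameters A parameter tibble (validated; distributions are fitted
#'   here if absent).
#' @param constants Economic constants list.
#' @param tree A tree node table.
#' @param bundles A bundle item tibble.
#' @param name Short study label used in printing.
#' @return An object of class `coi_study`.
#' @export
coi_study <- function(parameters, constants, tree, bundles, name = "study") {
  parameters <- if ("family" %in% names(parameters)) {
    validate_parameters(parameters)
  } else {
    fit_distributions(parameters)
  }
  constants <- validate_constants(constants)
  tree <- validate_tree(tree)
  used <- unique(tree$bundle[tree$node_type == "terminal"])
  missing <- setdiff(used, bundles$bundle)
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "terminals without bundle definitions: ",
      paste(utils::head(missing, 5), collapse = ", "),
      if (length(missing) > 5) ", ..."
    ))
  }
  structure(
    list(parameters = parameters, constants = constants, tree = tree,
         bundles = bundles, name = name),
    class = "coi_study"
  )
}

#' @export
print.coi_study <- function(x, ...) {
  n_leaf <- sum(x$tree$node_type == "terminal")
  cat(
    "<coi_study> ", x$name, "\n",
    "  parameters: ", sum(x$parameters$kind == "probability"), " probabilities, ",
    sum(x$parameters$kind == "cost"), " costs\n",
    "  tree: ", nrow(x$tree), " nodes (", n_leaf, " terminals)\n",
    sep = ""
  )
  invisible(x)
}

#' The packaged Uganda induced-abortion study
#'
#' Loads the packaged parameter and constants tables (or user-supplied files
#' with the same schema), builds the study tree and cost bundles, and returns
#' a ready-to-analyse [coi_study] object.
#'
#' @param params_path,constants_path Optional paths to replacement parameter /
#'   constants files; defaults to the packaged study configuration.
#' @param options Bundle options from [study_options()].
#' @return A `coi_study` object.
#' @examples
#' study <- uganda_study()
#' rollback(study)
#' @export
uganda_study <- function(params_path = NULL, constants_path = NULL,
                         options = study_options()) {
  params <- if (is.null(params_path)) uganda_parameters() else read_parameters(params_path)
  constants <- if (is.null(constants_path)) uganda_constants() else read_constants(constants_path)
  model <- build_study_model(params, constants, options)
  coi_study(params, constants, model$tree, model$bundles, name = "Uganda induced abortion")
}

#' @rdname rollback
#' @export
rollback.coi_study <- function(x, values = NULL, ...) {
  if (is.null(values)) values <- param_values(x$parameters)
  leaf_costs <- bundle_cost_table(x$bundles, values)
  rollback.data.frame(x$tree, values, leaf_costs)
}

#' Base-case per-case and national cost report
#'
#' Evaluates the tree at every parameter's point estimate (no sampling) and
#' scales the per-case breakdown by the annual incidence.
#'
#' @param study A [coi_study] object.
#' @param incidence Annual induced-abortion incidence; defaults to the
#'   study's `annual_incidence` constant.
#' @return A tibble with `category`, `per_case` (US$/case), `national`
#'   (US$/year) and `national_millions`.
#' @export
basecase_report <- function(study, incidence = NULL) {
  if (is.null(incidence)) incidence <- study$constants$annual_incidence
  breakdown <- rollback(study)
  tibble::tibble(
    category = breakdown$category,
    per_case = breakdown$cost,
    national = breakdown$cost * incidence,
    national_millions = breakdown$cost * incidence / 1e6
  )
}
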
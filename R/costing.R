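#' Human-capital valuation of premature mortality
#'
#' Values a maternal death as the discounted stream of future annual output
#' (GDP per capita as the wage proxy) over the remaining life expectancy:
#' `w * (1 - (1 + r)^(-L)) / r` for discount rate `r > 0`, and `w * L` in the
#' undiscounted limit. Attached as the indirect cost of every maternal-death
#' terminal.
#'
#' @param constants Economic constants list (see [read_constants()]); uses
#'   `gdp_per_capita`, `discount_rate`, `remaining_life_expectancy`.
#' @return Discounted productivity loss in 2010 US$.
#' @examples
#' mortality_productivity_cost(uganda_constants())
#' @export
mortality_productivity_cost <- function(constants) {
  w <- constants$gdp_per_capita
  r <- constants$discount_rate
  L <- constants$remaining_life_expectancy
  if (any(c(w, r, L) < 0)) rlang::abort("wage, discount rate and life expectancy must be nonnegative")
  if (r == 0) w * L else w * (1 - (1 + r)^(-L)) / r
}

#' Cost-bundle construction options
#'
#' Knobs for the compositions the study's source tables leave open: the unit
#' cost used when women self-medicate instead of accessing out-patient care
#' (no itemized row exists; default is the out-patient drugs row), whether the
#' out-of-pocket payment applies to hospital and/or out-patient episodes, and
#' an extra cost attached to perinatal-death branches (default 0: the
#' topology represents them but the source tables attach no perinatal cost).
#'
#' @param self_medication_param Cost parameter id used for self-medication.
#' @param oop_hospital,oop_outpatient Apply the out-of-pocket payment to
#'   hospital / out-patient complication episodes.
#' @param perinatal_extra_cost Extra direct medical cost (US$, government) on
#'   perinatal-death terminals.
#' @return A named list of options.
#' @export
study_options <- function(self_medication_param = "c_outpt_drugs",
                          oop_hospital = TRUE,
                          oop_outpatient = TRUE,
                          perinatal_extra_cost = 0) {
  list(
    self_medication_param = self_medication_param,
    oop_hospital = oop_hospital,
    oop_outpatient = oop_outpatient,
    perinatal_extra_cost = perinatal_extra_cost
  )
}

# one bundle item row
it <- function(item, category, payer = NA_character_, param = NA_character_,
               constant = NA_real_, multiplier = 1) {
  list(item = item, category = category, payer = payer, param = param,
       constant = constant, multiplier = multiplier)
}

# costs every abortion seeker incurs: procedure fee(s), procurement-episode
# productivity (once per attempt), and procurement transport/upkeep (once per
# seeker)
base_items <- function(fees, n_attempts) {
  c(
    lapply(fees, function(f) it(paste0("fee_", sub("^c_proc_", "", f)),
                                "direct_medical", "patient", param = f)),
    list(
      it("procedure_productivity", "indirect", param = "c_proc_productivity",
         multiplier = n_attempts),
      it("procurement_transport", "direct_non_medical", "patient", "c_transport"),
      it("procurement_upkeep", "direct_non_medical", "patient", "c_upkeep")
    )
  )
}

hosp_treat_items <- function(opts) {
  c(
    list(
      it("hosp_personnel", "direct_medical", "government", "c_hosp_personnel"),
      it("hosp_supplies", "direct_medical", "government", "c_hosp_supplies"),
      it("hosp_drugs", "direct_medical", "government", "c_hosp_drugs"),
      it("hosp_diagnostics", "direct_medical", "government", "c_hosp_diagnostics"),
      it("hosp_overhead", "direct_non_medical", "government", "c_hosp_overhead"),
      it("treatment_transport", "direct_non_medical", "patient", "c_transport"),
      it("treatment_upkeep", "direct_non_medical", "patient", "c_upkeep"),
      it("hosp_productivity", "indirect", param = "c_hosp_productivity")
    ),
    if (opts$oop_hospital) list(it("out_of_pocket", "direct_medical", "patient", "c_out_of_pocket"))
  )
}

outpt_treat_items <- function(opts) {
  c(
    list(
      it("outpt_personnel", "direct_medical", "government", "c_outpt_personnel"),
      it("outpt_supplies", "direct_medical", "government", "c_outpt_supplies"),
      it("outpt_drugs", "direct_medical", "government", "c_outpt_drugs"),
      it("outpt_diagnostics", "direct_medical", "government", "c_outpt_diagnostics"),
      it("outpt_overhead", "direct_non_medical", "government", "c_outpt_overhead"),
      it("treatment_transport", "direct_non_medical", "patient", "c_transport"),
      it("treatment_upkeep", "direct_non_medical", "patient", "c_upkeep"),
      it("outpt_productivity", "indirect", param = "c_outpt_productivity")
    ),
    if (opts$oop_outpatient) list(it("out_of_pocket", "direct_medical", "patient", "c_out_of_pocket"))
  )
}

selfmed_items <- function(opts) {
  list(
    it("self_medication", "direct_medical", "patient", opts$self_medication_param),
    it("outpt_productivity", "indirect", param = "c_outpt_productivity")
  )
}

death_item <- function(constants) {
  list(it("mortality_human_capital", "indirect",
          constant = mortality_productivity_cost(constants)))
}

perinatal_items <- function(opts) {
  if (opts$perinatal_extra_cost > 0) {
    list(it("perinatal_care", "direct_medical", "government",
            constant = opts$perinatal_extra_cost))
  } else {
    list()
  }
}

preg_items <- function(constants, facility) {
  c(
    list(it("antenatal_care", "direct_medical", "government", "c_anc",
            multiplier = constants$anc_attendance)),
    if (facility) list(it("hospital_delivery", "direct_medical", "government", "c_hospital_delivery"))
  )
}

#' Pregnancy care cost bundle
#'
#' The pregnancy-care component attached to birth terminals: the antenatal
#' care package weighted by the antenatal attendance rate, plus the hospital
#' delivery cost on facility-delivery terminals. Both are paid by the
#' government (pregnancy care, unlike abortion procurement, is provided by
#' the national health system).
#'
#' @param params A validated parameter tibble (must contain `c_anc` and
#'   `c_hospital_delivery`).
#' @param constants Economic constants list.
#' @param facility Whether the delivery happens in a health facility.
#' @return A bundle item tibble (`item`, `category`, `payer`, `param`,
#'   `constant`, `multiplier`).
#' @export
pregnancy_cost_bundle <- function(params, constants, facility = TRUE) {
  need <- c("c_anc", if (facility) "c_hospital_delivery")
  missing <- setdiff(need, params$id)
  if (length(missing) > 0) {
    rlang::abort(paste0("missing pregnancy cost parameters: ", paste(missing, collapse = ", ")))
  }
  items_tibble(preg_items(constants, facility))
}

items_tibble <- function(items, bundle = NULL) {
  out <- dplyr::bind_rows(lapply(items, tibble::as_tibble))
  if (!is.null(bundle) && nrow(out) > 0) out <- dplyr::mutate(out, bundle = bundle, .before = 1)
  out
}

#' Evaluate cost bundles into a per-bundle category table
#'
#' Resolves every bundle item (`multiplier * unit cost`, where the unit cost
#' is a parameter value or an embedded constant) and sums items into the
#' category ledger. `societal` is the sum over all items and equals
#' `direct_medical + direct_non_medical + indirect` exactly; `patient` and
#' `government` sum the healthcare (direct) items by payer tag.
#'
#' @param bundles A bundle item tibble from [build_cost_bundles()].
#' @param values Named numeric vector of cost parameter values.
#' @return A tibble with one row per bundle and one column per category in
#'   [cost_categories()].
#' @export
bundle_cost_table <- function(bundles, values) {
  unknown <- setdiff(bundles$param[!is.na(bundles$param)], names(values))
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "bundle items reference unknown cost parameters: ",
      paste(unique(unknown), collapse = ", ")
    ))
  }
  unit <- ifelse(is.na(bundles$param), bundles$constant, as.numeric(values[bundles$param]))
  val <- bundles$multiplier * unit
  if (any(val < 0)) rlang::abort("negative cost in a bundle item")
  agg <- function(keep) {
    vapply(split(val[keep], factor(bundles$bundle[keep], levels = unique(bundles$bundle))),
           sum, numeric(1))
  }
  all_rows <- rep(TRUE, nrow(bundles))
  tibble::tibble(
    bundle = unique(bundles$bundle),
    direct_medical = agg(bundles$category == "direct_medical"),
    direct_non_medical = agg(bundles$category == "direct_non_medical"),
    indirect = agg(bundles$category == "indirect"),
    patient = agg(!is.na(bundles$payer) & bundles$payer == "patient"),
    government = agg(!is.na(bundles$payer) & bundles$payer == "government"),
    unallocated = agg(!is.na(bundles$payer) & bundles$payer == "unallocated"),
    societal = agg(all_rows)
  )
}

#' Scale a per-case cost breakdown to national annual costs
#'
#' @param per_case A cost breakdown tibble (`category`, `cost`) as returned
#'   by [rollback()].
#' @param incidence Annual number of induced abortions (cases/year).
#' @return The breakdown with `cost` multiplied by `incidence` (US$/year).
#' @examples
#' \dontrun{
#' national_costs(rollback(uganda_study()), 362000)
#' }
#' @export
national_costs <- function(per_case, incidence) {
  if (incidence < 0) rlang::abort("incidence must be nonnegative")
  dplyr::mutate(per_case, cost = .data$cost * incidence)
}
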
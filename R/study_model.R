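# Builds the packaged study topology and, alongside it, the cost-bundle item
# list for every terminal (bundle name = terminal node id). The cohort flow:
# provider training -> provider -> failure/success -> complications ->
# hospital/out-patient care -> access -> mortality; failure with a trained
# provider leads to the pregnancy subtree, failure with an untrained provider
# to one retry with a trained provider.

new_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$nodes <- list()
  b$items <- list()
  b
}

add_node <- function(b, id, parent, type, ref = NA_character_,
                     op = NA_character_, bundle = NA_character_) {
  b$nodes[[length(b$nodes) + 1]] <- list(
    node_id = id, parent = parent, node_type = type,
    prob_ref = ref, prob_op = op, bundle = bundle
  )
  id
}

add_terminal <- function(b, id, parent, ref, op, items) {
  add_node(b, id, parent, "terminal", ref, op, bundle = id)
  b$items[[length(b$items) + 1]] <- items_tibble(items, bundle = id)
  id
}

# complication-consequences subtree: hospital vs out-patient need, access,
# and mortality; `base` carries the attempt costs already incurred
build_comp_subtree <- function(b, id, parent, ref, op, base, constants, opts) {
  add_node(b, id, parent, "chance", ref, op)
  hosp <- add_node(b, paste0(id, "/hosp"), id, "chance", "p_hospital_care", "param")
  acc <- add_node(b, paste0(hosp, "/access"), hosp, "chance", "p_access", "param")
  add_terminal(b, paste0(acc, "/die"), acc, "p_mort_hospital", "param",
               c(base, hosp_treat_items(opts), death_item(constants)))
  add_terminal(b, paste0(acc, "/survive"), acc, NA, "complement",
               c(base, hosp_treat_items(opts)))
  noacc <- add_node(b, paste0(hosp, "/noaccess"), hosp, "chance", NA, "complement")
  add_terminal(b, paste0(noacc, "/die_community"), noacc, "p_mort_community", "param",
               c(base, death_item(constants)))
  worsen <- add_node(b, paste0(noacc, "/worsen"), noacc, "chance", NA, "complement")
  add_terminal(b, paste0(worsen, "/die"), worsen, "p_mort_hospital", "param",
               c(base, hosp_treat_items(opts), death_item(constants)))
  add_terminal(b, paste0(worsen, "/survive"), worsen, NA, "complement",
               c(base, hosp_treat_items(opts)))
  outpt <- add_node(b, paste0(id, "/outpt"), id, "chance", NA, "complement")
  add_terminal(b, paste0(outpt, "/treated"), outpt, "p_access", "param",
               c(base, outpt_treat_items(opts)))
  add_terminal(b, paste0(outpt, "/selfmed"), outpt, NA, "complement",
               c(base, selfmed_items(opts)))
  id
}

# continued-pregnancy subtree after definitive abortion failure
build_pregnancy_subtree <- function(b, id, parent, ref, op, base, constants, opts) {
  add_node(b, id, parent, "chance", ref, op)
  births <- add_node(b, paste0(id, "/births"), id, "chance", "p_births", "param")
  for (setting in c("facility", "home")) {
    fac <- setting == "facility"
    mort_ref <- if (fac) "p_delivery_mort_facility" else "p_delivery_mort_community"
    dn <- add_node(b, paste0(births, "/", setting), births, "chance",
                   if (fac) "p_facility_delivery" else NA,
                   if (fac) "param" else "complement")
    preg <- preg_items(constants, fac)
    add_terminal(b, paste0(dn, "/maternal_death"), dn, mort_ref, "param",
                 c(base, preg, death_item(constants)))
    surv <- add_node(b, paste0(dn, "/maternal_survive"), dn, "chance", NA, "complement")
    add_terminal(b, paste0(surv, "/perinatal_death"), surv, mort_ref, "param",
                 c(base, preg, perinatal_items(opts)))
    add_terminal(b, paste0(surv, "/perinatal_survive"), surv, NA, "complement",
                 c(base, preg))
  }
  build_comp_subtree(b, paste0(id, "/misc_13_22"), id, "p_miscarriage_13_22",
                     "param", base, constants, opts)
  add_terminal(b, paste0(id, "/misc_early"), id, NA, "complement", base)
  id
}

# a single abortion attempt with one provider; failure goes to `on_fail`
build_attempt <- function(b, id, parent, ref, op, provider, trained, base,
                          constants, opts, on_fail) {
  fee <- paste0("c_proc_", provider)
  my_base <- base_items(c(base$fees, fee), base$n_attempts + 1)
  new_base <- list(fees = c(base$fees, fee), n_attempts = base$n_attempts + 1)
  add_node(b, id, parent, "chance", ref, op)
  fail_ref <- if (trained) "p_fail_trained" else "p_fail_untrained"
  on_fail(b, paste0(id, "/fail"), id, fail_ref, "param", new_base)
  succ <- add_node(b, paste0(id, "/success"), id, "chance", NA, "complement")
  build_comp_subtree(b, paste0(succ, "/comp"), succ, paste0("p_comp_", provider),
                     "param", my_base, constants, opts)
  add_terminal(b, paste0(succ, "/none"), succ, NA, "complement", my_base)
  id
}

# the trained-provider split; failure after a trained attempt means the
# pregnancy continues
build_trained_group <- function(b, id, parent, ref, op, base, constants, opts) {
  add_node(b, id, parent, "chance", ref, op)
  providers <- list(
    list("doctor", "p_doctor", "param"),
    list("clinical_officer", "p_clinical_officer", "param"),
    list("nurse_midwife", NA_character_, "complement")
  )
  for (p in providers) {
    build_attempt(
      b, paste0(id, "/", p[[1]]), id, p[[2]], p[[3]], p[[1]], TRUE, base,
      constants, opts,
      on_fail = function(b, fid, fparent, fref, fop, fbase) {
        build_pregnancy_subtree(b, fid, fparent, fref, fop,
                                base_items(fbase$fees, fbase$n_attempts),
                                constants, opts)
      }
    )
  }
  id
}

build_study_model <- function(params, constants, opts = study_options()) {
  check_study_ids(params)
  b <- new_builder()
  root <- add_node(b, "root", NA_character_, "chance")
  base0 <- list(fees = character(0), n_attempts = 0)
  build_trained_group(b, "root/trained", root, "p_trained", "param", base0,
                      constants, opts)
  untr <- add_node(b, "root/untrained", root, "chance", NA, "complement")
  providers <- list(
    list("dispenser", "p_dispenser", "param"),
    list("lay_practitioner", "p_lay_practitioner", "param"),
    list("self_induction", NA_character_, "complement")
  )
  for (p in providers) {
    build_attempt(
      b, paste0(untr, "/", p[[1]]), untr, p[[2]], p[[3]], p[[1]], FALSE, base0,
      constants, opts,
      # one retry with a trained provider; a second failure ends in pregnancy
      on_fail = function(b, fid, fparent, fref, fop, fbase) {
        build_trained_group(b, fid, fparent, fref, fop, fbase, constants, opts)
      }
    )
  }
  tree <- validate_tree(dplyr::bind_rows(b$nodes))
  bundles <- dplyr::bind_rows(b$items)
  list(tree = tree, bundles = bundles)
}

study_prob_ids <- function() {
  c(
    "p_trained", "p_doctor", "p_clinical_officer", "p_nurse_midwife",
    "p_dispenser", "p_lay_practitioner", "p_self_induction",
    "p_fail_trained", "p_fail_untrained",
    "p_comp_doctor", "p_comp_clinical_officer", "p_comp_nurse_midwife",
    "p_comp_dispenser", "p_comp_lay_practitioner", "p_comp_self_induction",
    "p_hospital_care", "p_access", "p_mort_hospital", "p_mort_community",
    "p_births", "p_miscarriage_13_22", "p_facility_delivery",
    "p_delivery_mort_facility", "p_delivery_mort_community"
  )
}

study_cost_ids <- function() {
  c(
    paste0("c_proc_", c("doctor", "clinical_officer", "nurse_midwife",
                        "dispenser", "lay_practitioner", "self_induction",
                        "productivity")),
    paste0("c_hosp_", c("personnel", "supplies", "drugs", "diagnostics",
                        "overhead", "productivity")),
    paste0("c_outpt_", c("personnel", "supplies", "drugs", "diagnostics",
                         "overhead", "productivity")),
    "c_anc", "c_hospital_delivery", "c_transport", "c_upkeep", "c_out_of_pocket"
  )
}

check_study_ids <- function(params) {
  missing <- setdiff(c(study_prob_ids(), study_cost_ids()), params$id)
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "cannot build the study tree; missing parameter(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Build the packaged study decision tree
#'
#' Constructs the full consequence tree of an induced abortion: trained vs.
#' untrained provider, provider type, procedure failure (with one retry by a
#' trained provider after an untrained failure), complications, hospital vs.
#' out-patient care need, access to care, mortality, and — after definitive
#' failure — the continued-pregnancy subtree (births by delivery setting with
#' maternal and perinatal mortality, and miscarriages). Branch probabilities
#' reference the parameter table by id; at every chance node one branch is
#' the complement of its siblings so probabilities stay normalized under
#' sampling.
#'
#' @param params A validated parameter tibble containing every referenced id.
#' @param constants Economic constants list.
#' @param options Bundle options from [study_options()].
#' @return A tree node table (see [validate_tree()]) whose terminal `bundle`
#'   names match [build_cost_bundles()].
#' @export
build_study_tree <- function(params, constants = uganda_constants(),
                             options = study_options()) {
  build_study_model(params, constants, options)$tree
}

#' Build the per-terminal cost bundles of the packaged study
#'
#' Every terminal's itemized costs: procedure fees and procurement transport/
#' upkeep for all abortion seekers (patient-paid; the government never pays
#' for abortion procurement), complication-treatment items (government-paid
#' medical and overhead costs, patient out-of-pocket, treatment transport and
#' upkeep), productivity losses per episode, self-medication when out-patient
#' care is not accessed, pregnancy care on birth terminals, and the
#' human-capital mortality cost on every maternal-death terminal.
#'
#' @inheritParams build_study_tree
#' @return A bundle item tibble (`bundle`, `item`, `category`, `payer`,
#'   `param`, `constant`, `multiplier`).
#' @export
build_cost_bundles <- function(params, constants = uganda_constants(),
                               options = study_options()) {
  build_study_model(params, constants, options)$bundles
}
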
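# Fetal-circulation flow assembly ---------------------------------------------

.required_flow_vessels <- c("UV", "DV", "AAo", "MPA", "DA", "DAo", "SVC",
                            "LPA", "RPA", "CCA_left", "CCA_right")

#' Derive the fetal-circulation haemodynamics from measured vessel flows
#'
#' Applies the combination rules of the fetal shunt circulation:
#' pulmonary blood flow `PBF = LPA + RPA`; right ventricular output
#' `RVCO = DA + PBF`; left ventricular output `LVCO = AAo` (coronary flow
#' excluded); combined ventricular output `CVO = RVCO + LVCO`; combined
#' carotid flow `CCA = CCA_left + CCA_right`. Two further flows are not
#' directly measurable and are derived here (both flagged `derived_estimate`
#' in the output): foramen-ovale flow `FO = LVCO - PBF` (left-heart inflow
#' minus pulmonary venous return) and lower-trunk flow `DAo - UV`
#' (descending-aortic flow minus placental return). Flow distribution is
#' expressed as a percentage of CVO.
#'
#' @param flows Named numeric vector or single-row data frame/list with
#'   entries (mL/min) for UV, DV, AAo, MPA, DA, DAo, SVC, LPA, RPA, CCA_left
#'   and CCA_right. By default, quantities whose input vessels are absent
#'   come back `NA`; with `strict = TRUE` any missing vessel is an error
#'   naming the vessel.
#' @param strict Require the full vessel set (default `FALSE`).
#' @return A `derived_haemodynamics` list: `pbf`, `rvco`, `lvco`, `cvo`,
#'   `cca_combined`, `fo_flow`, `lower_trunk_flow`, `distribution_pct`
#'   (named: FO, CCA, DA, PBF, DAo, SVC, UV, lower_trunk), and `flags`.
#' @export
derive_flows <- function(flows, strict = FALSE) {
  if (is.data.frame(flows)) {
    .check(nrow(flows) == 1, "flows data frame must have one row")
    flows <- unlist(flows)
  }
  flows <- unlist(flows)
  if (strict) {
    missing <- setdiff(.required_flow_vessels, names(flows))
    if (length(missing) > 0)
      stop("missing vessel flow(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  g <- function(v) if (v %in% names(flows)) unname(flows[[v]]) else NA_real_
  pbf <- g("LPA") + g("RPA")
  rvco <- g("DA") + pbf
  lvco <- g("AAo")
  cvo <- rvco + lvco
  cca <- g("CCA_left") + g("CCA_right")
  fo <- lvco - pbf
  lower_trunk <- g("DAo") - g("UV")
  flags <- character(0)
  if (isTRUE(fo < 0)) flags <- c(flags, "fo_flow_negative")
  if (isTRUE(cvo == 0))
    stop("combined ventricular output is zero: flow distribution undefined",
         call. = FALSE)
  dist <- c(FO = fo, CCA = cca, DA = g("DA"), PBF = pbf, DAo = g("DAo"),
            SVC = g("SVC"), UV = g("UV"), lower_trunk = lower_trunk) /
    cvo * 100
  structure(list(pbf = pbf, rvco = rvco, lvco = lvco, cvo = cvo,
                 cca_combined = cca, fo_flow = fo,
                 lower_trunk_flow = lower_trunk,
                 distribution_pct = dist,
                 derived_estimate = c("fo_flow", "lower_trunk_flow"),
                 flags = flags),
            class = "derived_haemodynamics")
}

#' Check conservation of flow in the assembled circulation
#'
#' Anatomy requires `MPA = DA + PBF` (the main pulmonary trunk splits into
#' the ductus arteriosus and the two lung arteries). The report gives the
#' relative discrepancy `|MPA - (DA + PBF)| / MPA` (absolute when MPA = 0)
#' and also verifies that the CVO partition
#' `DA + PBF (right ventricle) + FO + pulmonary venous return (= PBF)`
#' (left ventricle) accounts for 100% of CVO: the sum of the corresponding
#' distribution percentages, with PBF counted twice, must be 100 within
#' tolerance.
#'
#' @param flows As for [derive_flows()]; must include `MPA`.
#' @param derived Optional precomputed [derive_flows()] result.
#' @param tol_pct Tolerance, percent (default 1).
#' @return List: `mpa_discrepancy` (relative, or absolute when MPA = 0),
#'   `mpa_relative` (logical), `partition_sum_pct`, `pass`.
#' @export
check_conservation <- function(flows, derived = NULL, tol_pct = 1) {
  if (is.data.frame(flows)) flows <- unlist(flows[1, , drop = TRUE])
  flows <- unlist(flows)
  derived <- derived %||% derive_flows(flows)
  .check("MPA" %in% names(flows), "missing vessel flow(s): MPA")
  mpa <- unname(flows[["MPA"]])
  gap <- abs(mpa - (unname(flows[["DA"]]) + derived$pbf))
  relative <- mpa != 0
  disc <- if (relative) gap / mpa else gap
  part <- unname(derived$distribution_pct[["DA"]] +
                   2 * derived$distribution_pct[["PBF"]] +
                   derived$distribution_pct[["FO"]])
  pass <- (disc * ifelse(relative, 100, 1) <= tol_pct) &&
    abs(part - 100) <= tol_pct
  list(mpa_discrepancy = disc, mpa_relative = relative,
       partition_sum_pct = part, pass = pass)
}

#' Left-right ventricular saturation difference
#'
#' The difference in oxygen saturation between blood leaving the left
#' ventricle (ascending aorta) and the right ventricle (main pulmonary
#' artery), in percentage points.
#'
#' @param y_aao,y_mpa Saturation fractions in [0, 1].
#' @return Percentage points (vectorised).
#' @export
delta_so2 <- function(y_aao, y_mpa) {
  .check(all(y_aao >= 0 & y_aao <= 1) && all(y_mpa >= 0 & y_mpa <= 1),
         "saturations must lie in [0, 1]")
  (y_aao - y_mpa) * 100
}

#' Derive haemodynamics for every row of a cohort table
#'
#' @param cohort Data frame with `flow_<vessel>` columns (as produced by
#'   [make_cohort()] or the imaging pipeline) and `sat_AAo`/`sat_MPA`.
#' @return The input with derived columns appended: `pbf`, `rvco`, `lvco`,
#'   `cvo`, `cca_combined`, `fo_flow`, `lower_trunk_flow`,
#'   `pct_<component>` distribution percentages and `delta_so2_aao_mpa`.
#' @export
derive_flows_cohort <- function(cohort) {
  need <- paste0("flow_", .required_flow_vessels)
  missing <- setdiff(need, names(cohort))
  .check(length(missing) == 0,
         paste("missing flow columns:", paste(missing, collapse = ", ")))
  out <- cohort
  dvals <- lapply(seq_len(nrow(cohort)), function(i) {
    f <- unlist(cohort[i, need])
    names(f) <- sub("^flow_", "", names(f))
    derive_flows(f)
  })
  for (fld in c("pbf", "rvco", "lvco", "cvo", "cca_combined", "fo_flow",
                "lower_trunk_flow"))
    out[[fld]] <- vapply(dvals, function(d) d[[fld]], numeric(1))
  for (comp in names(dvals[[1]]$distribution_pct))
    out[[paste0("pct_", comp)]] <-
      vapply(dvals, function(d) d$distribution_pct[[comp]], numeric(1))
  if (all(c("sat_AAo", "sat_MPA") %in% names(cohort)))
    out$delta_so2_aao_mpa <- delta_so2(cohort$sat_AAo, cohort$sat_MPA)
  out
}
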
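# Compilation of a validated foodweb_model into the linear system
#   E x = f   (mass balance)
#   G x >= h  (physiology, isotopes, site bounds, nonnegativity)
# over the flow vector x (mmol C m-2 d-1), with per-row provenance tags.

new_row_set <- function() {
  list(idx = list(), coef = list(), rhs = numeric(0), type = character(0),
       provenance = character(0))
}

add_row <- function(rows, idx, coef, rhs, type, provenance) {
  keep <- coef != 0
  idx <- idx[keep]; coef <- coef[keep]
  if (length(idx) == 0) {
    # a row whose symbolic expression vanished entirely would be
    # meaningless; constant constraints are resolved here instead
    if ((type == "eq" && abs(rhs) > 1e-12) || (type == "ineq" && rhs > 1e-12)) {
      stop("constraint ", provenance,
           " reduces to an unsatisfiable constant row")
    }
    return(rows)
  }
  n <- length(rows$rhs) + 1L
  rows$idx[[n]] <- idx
  rows$coef[[n]] <- coef
  rows$rhs[n] <- rhs
  rows$type[n] <- type
  rows$provenance[n] <- provenance
  rows
}

merge_rows <- function(...) {
  out <- new_row_set()
  for (r in list(...)) {
    for (i in seq_along(r$rhs)) {
      n <- length(out$rhs) + 1L
      out$idx[[n]] <- r$idx[[i]]
      out$coef[[n]] <- r$coef[[i]]
      out$rhs[n] <- r$rhs[i]
      out$type[n] <- r$type[i]
      out$provenance[n] <- r$provenance[i]
    }
  }
  out
}

flow_idx <- function(model, source = NULL, sink = NULL) {
  f <- model$flows
  sel <- rep(TRUE, nrow(f))
  if (!is.null(source)) sel <- sel & f$source %in% source
  if (!is.null(sink)) sel <- sel & f$sink %in% sink
  f$index[sel]
}

model_tlim <- function(model) {
  env <- model$environment
  if (is.null(env) || is.na(env$temperature)) {
    stop("model environment must provide a temperature for ",
         "temperature-limited constraints")
  }
  tlim <- temperature_limitation(model$rules$q10, env$temperature)
  if (tlim <= 0) stop("temperature limitation factor must be > 0")
  tlim
}

#' Mass-balance equality rows
#'
#' One steady-state row per internal compartment: the sum of its inflows
#' minus the sum of its outflows equals zero. External pools (buried
#' detritus, external predation, DIC, water-column DOC and detritus) are
#' not balanced.
#'
#' @param model A validated [build_topology()] model.
#' @return An internal row-set (one `eq` row per internal compartment)
#'   consumed by [compile_lim()].
#' @export
compile_mass_balance <- function(model) {
  internals <- internal_ids(model)
  if (length(internals) == 0) stop("model has no internal compartments")
  rows <- new_row_set()
  for (id in internals) {
    i_in <- flow_idx(model, sink = id)
    i_out <- flow_idx(model, source = id)
    rows <- add_row(rows,
                    idx = c(i_in, i_out),
                    coef = c(rep(1, length(i_in)), rep(-1, length(i_out))),
                    rhs = 0, type = "eq",
                    provenance = paste0("mass_balance:", id))
  }
  rows
}

# classify the physiological role of an internal compartment
compartment_role <- function(comp_row) {
  modes <- split_modes(comp_row$feeding_modes)
  cls <- comp_row$taxon_class
  if (cls == "bacteria") {
    if ("chemoautotrophy" %in% modes) return("chemo_bacteria")
    return("het_bacteria")
  }
  if (cls %in% c("macrofauna", "megafauna")) {
    if (identical(modes, "symbiont_fixation")) return("symbiont_fauna")
    return("fauna")
  }
  "pool"
}

#' Physiological inequality rows
#'
#' Encodes the literature rule set as linear rows per internal
#' compartment. For feeding fauna with ingestion I, faeces D (flow to
#' detritus), respiration R (flow to DIC) and production P (flows to
#' predators and to external predation): assimilation `I - D` within
#' `ae_range * I`; faeces within `faecal_range * I`; production within
#' `nge_range * (I - D)`; production within `growth_coeff_range * Tlim *
#' biomass`; respiration at least `maintenance_coeff * Tlim * biomass`
#' and within `respiration_multiplier_range * biomass_specific_respiration
#' * Tlim * biomass`. Heterotrophic bacteria: production `U - R` within
#' `bge_range * U` of uptake U, and detritus return within
#' `viral_lysis_range` of production. Chemoautotrophs (including
#' endosymbiont-bearing fauna): net fixation `F - R` within
#' `chemo_efficiency_range * F` of DIC uptake F. Bacterial rates carry no
#' biomass term (biomass-specific microbial rates are deliberately not
#' imposed); faunal biomass rows additionally apply to symbiont-bearing
#' fauna.
#'
#' @param model A validated model; every faunal internal must carry
#'   biomass when `biomass_rows = TRUE`.
#' @param biomass_rows Emit the biomass- and temperature-dependent rows
#'   (growth, maintenance, respiration band). Disable to obtain only the
#'   dimensionless stoichiometric ratio rows.
#' @return An internal row-set of `ineq` rows (`G x >= h`).
#' @export
compile_physiological_constraints <- function(model, biomass_rows = TRUE) {
  rows <- new_row_set()
  comp <- model$compartments
  tlim <- if (biomass_rows) model_tlim(model) else NA_real_
  for (i in which(comp$locality == "internal")) {
    id <- comp$id[i]
    role <- compartment_role(comp[i, ])
    if (role == "pool") next
    i_resp <- flow_idx(model, source = id, sink = "DIC")
    i_det <- flow_idx(model, source = id, sink = "Det")
    i_fix <- flow_idx(model, source = "DIC", sink = id)
    i_food <- setdiff(flow_idx(model, sink = id), i_fix)
    i_prod <- setdiff(flow_idx(model, source = id), c(i_resp, i_det))

    if (role == "het_bacteria") {
      # bge: lo*U <= U - R <= hi*U   (U = uptake, R = respiration)
      bge <- model$rules$bge_range
      rows <- add_row(rows, c(i_food, i_resp),
                      c(rep(1 - bge[1], length(i_food)),
                        rep(-1, length(i_resp))),
                      0, "ineq", paste0("physiology:bge:", id))
      rows <- add_row(rows, c(i_food, i_resp),
                      c(rep(bge[2] - 1, length(i_food)),
                        rep(1, length(i_resp))),
                      0, "ineq", paste0("physiology:bge:", id))
      # viral lysis: lo*(U - R) <= L <= hi*(U - R)
      vl <- model$rules$viral_lysis_range
      rows <- add_row(rows, c(i_det, i_food, i_resp),
                      c(rep(1, length(i_det)),
                        rep(-vl[1], length(i_food)),
                        rep(vl[1], length(i_resp))),
                      0, "ineq", paste0("physiology:viral_lysis:", id))
      rows <- add_row(rows, c(i_food, i_resp, i_det),
                      c(rep(vl[2], length(i_food)),
                        rep(-vl[2], length(i_resp)),
                        rep(-1, length(i_det))),
                      0, "ineq", paste0("physiology:viral_lysis:", id))
      next
    }

    if (role %in% c("chemo_bacteria", "symbiont_fauna")) {
      if (length(i_fix) == 0) {
        stop("chemoautotrophic compartment ", id, " has no DIC uptake flow")
      }
      ce <- model$rules$chemo_efficiency_range
      # lo*F <= F - R <= hi*F
      rows <- add_row(rows, c(i_fix, i_resp),
                      c(rep(1 - ce[1], length(i_fix)),
                        rep(-1, length(i_resp))),
                      0, "ineq", paste0("physiology:chemo_efficiency:", id))
      rows <- add_row(rows, c(i_fix, i_resp),
                      c(rep(ce[2] - 1, length(i_fix)),
                        rep(1, length(i_resp))),
                      0, "ineq", paste0("physiology:chemo_efficiency:", id))
    }

    if (role == "fauna" && length(i_food) > 0) {
      cls <- model$rules[[comp$taxon_class[i]]]
      ae <- cls$ae_range; fe <- cls$faecal_range; nge <- cls$nge_range
      # assimilation: ae_lo*I <= I - D <= ae_hi*I
      rows <- add_row(rows, c(i_food, i_det),
                      c(rep(1 - ae[1], length(i_food)),
                        rep(-1, length(i_det))),
                      0, "ineq", paste0("physiology:assimilation:", id))
      rows <- add_row(rows, c(i_det, i_food),
                      c(rep(1, length(i_det)),
                        rep(ae[2] - 1, length(i_food))),
                      0, "ineq", paste0("physiology:assimilation:", id))
      # faeces: fe_lo*I <= D <= fe_hi*I
      rows <- add_row(rows, c(i_det, i_food),
                      c(rep(1, length(i_det)),
                        rep(-fe[1], length(i_food))),
                      0, "ineq", paste0("physiology:faecal:", id))
      rows <- add_row(rows, c(i_food, i_det),
                      c(rep(fe[2], length(i_food)),
                        rep(-1, length(i_det))),
                      0, "ineq", paste0("physiology:faecal:", id))
      # net growth efficiency: nge_lo*(I - D) <= P <= nge_hi*(I - D)
      rows <- add_row(rows, c(i_prod, i_food, i_det),
                      c(rep(1, length(i_prod)),
                        rep(-nge[1], length(i_food)),
                        rep(nge[1], length(i_det))),
                      0, "ineq", paste0("physiology:nge:", id))
      rows <- add_row(rows, c(i_food, i_det, i_prod),
                      c(rep(nge[2], length(i_food)),
                        rep(-nge[2], length(i_det)),
                        rep(-1, length(i_prod))),
                      0, "ineq", paste0("physiology:nge:", id))
    }

    if (role %in% c("fauna", "symbiont_fauna") && biomass_rows) {
      b <- comp$biomass[i]
      if (is.na(b)) {
        stop("faunal compartment ", id,
             " lacks the biomass needed for its physiological rows")
      }
      cls <- model$rules[[comp$taxon_class[i]]]
      g <- cls$growth_coeff_range
      # growth (secondary production): g_lo*Tlim*B <= P <= g_hi*Tlim*B
      rows <- add_row(rows, i_prod, rep(1, length(i_prod)),
                      g[1] * tlim * b, "ineq",
                      paste0("physiology:growth:", id))
      rows <- add_row(rows, i_prod, rep(-1, length(i_prod)),
                      -g[2] * tlim * b, "ineq",
                      paste0("physiology:growth:", id))
      # maintenance respiration: R >= m*Tlim*B
      rows <- add_row(rows, i_resp, rep(1, length(i_resp)),
                      cls$maintenance_coeff * tlim * b, "ineq",
                      paste0("physiology:maintenance:", id))
      # respiration band: mult_lo*B*r*Tlim <= R <= mult_hi*B*r*Tlim
      mult <- cls$respiration_multiplier_range
      r0 <- cls$biomass_specific_respiration
      rows <- add_row(rows, i_resp, rep(1, length(i_resp)),
                      mult[1] * b * r0 * tlim, "ineq",
                      paste0("physiology:respiration_band:", id))
      rows <- add_row(rows, i_resp, rep(-1, length(i_resp)),
                      -mult[2] * b * r0 * tlim, "ineq",
                      paste0("physiology:respiration_band:", id))
    }
  }
  rows
}

#' Stable-isotope diet-mixing inequality rows
#'
#' Linear mixing on flow-weighted source signatures: for each feeding
#' consumer j with sources i, the flow-weighted mean source signature
#' plus a single trophic discrimination factor `delta` must lie within
#' `k` consumer standard deviations of the consumer's mean signature.
#' Written linearly as two rows bounding
#' `sum_i f_ij (d13c_i + delta - d13c_j)` within
#' `+/- k * sd_j * sum_i f_ij`. Rows are emitted only for internal
#' compartments with a feeding mode in deposit/suspension/predation/
#' heterotrophy that carry both `d13c_mean` and `d13c_sd`; compartments
#' whose carbon derives from symbiont or chemoautotrophic fixation take
#' their signature from fixation, not diet mixing, and contribute no
#' rows.
#'
#' @param model A validated model.
#' @param delta Trophic discrimination factor (permil), default 1.
#' @param k Tolerance in consumer standard deviations, default 2.
#' @return An internal row-set of `ineq` rows.
#' @export
compile_isotope_constraints <- function(model, delta = 1, k = 2) {
  rows <- new_row_set()
  comp <- model$compartments
  d13c <- stats::setNames(comp$d13c_mean, comp$id)
  feeding <- c("deposit", "suspension", "predation", "heterotrophy")
  for (i in which(comp$locality == "internal")) {
    id <- comp$id[i]
    modes <- split_modes(comp$feeding_modes[i])
    if (!any(modes %in% feeding)) next
    if (is.na(comp$d13c_mean[i]) || is.na(comp$d13c_sd[i])) next
    i_fix <- flow_idx(model, source = "DIC", sink = id)
    i_food <- setdiff(flow_idx(model, sink = id), i_fix)
    if (length(i_food) == 0) {
      stop("consumer ", id, " has isotope data but no food flows")
    }
    src <- model$flows$source[match(i_food, model$flows$index)]
    if (any(is.na(d13c[src]))) {
      stop("food source(s) of ", id, " lack d13c_mean: ",
           paste(src[is.na(d13c[src])], collapse = ", "))
    }
    dj <- comp$d13c_mean[i]; sdj <- comp$d13c_sd[i]
    excess <- d13c[src] + delta - dj          # per-source signature excess
    # upper: sum f*(excess - k*sd) <= 0
    rows <- add_row(rows, i_food, -(excess - k * sdj), 0, "ineq",
                    paste0("isotope:", id))
    # lower: sum f*(excess + k*sd) >= 0
    rows <- add_row(rows, i_food, excess + k * sdj, 0, "ineq",
                    paste0("isotope:", id))
  }
  rows
}

#' Site-level constraint rows
#'
#' Bounds tied to the site environment: particulate detritus deposition
#' (`Det_w->Det`) within `poc_range`; the sum of all respiration flows
#' (internal compartments to DIC) within `scoc_range` (sediment community
#' oxygen consumption in carbon units); DOC efflux to the water column
#' within `doc_efflux_range` times total respiration; and burial
#' (`Det->Det_s`) within `burial_efficiency_range` times the gross
#' organic-matter input (all import flows: deposition, suspension
#' capture, DIC fixation).
#'
#' @param model A validated model with `scoc_range` and `poc_range` set.
#' @return An internal row-set of `ineq` rows.
#' @export
compile_site_constraints <- function(model) {
  env <- model$environment
  if (is.null(env) || is.null(env$scoc_range) || is.null(env$poc_range)) {
    stop("site constraints need an environment with scoc_range and ",
         "poc_range")
  }
  rows <- new_row_set()
  internals <- internal_ids(model)

  i_poc <- flow_idx(model, source = "Det_w", sink = "Det")
  if (length(i_poc) == 1) {
    rows <- add_row(rows, i_poc, 1, env$poc_range[1], "ineq", "poc")
    rows <- add_row(rows, i_poc, -1, -env$poc_range[2], "ineq", "poc")
  }

  i_resp <- model$flows$index[model$flows$sink == "DIC" &
                                model$flows$source %in% internals]
  if (length(i_resp) > 0) {
    rows <- add_row(rows, i_resp, rep(1, length(i_resp)),
                    env$scoc_range[1], "ineq", "scoc")
    rows <- add_row(rows, i_resp, rep(-1, length(i_resp)),
                    -env$scoc_range[2], "ineq", "scoc")
  }

  i_docw <- flow_idx(model, source = "DOC", sink = "DOC_w")
  de <- model$rules$doc_efflux_range
  if (length(i_docw) == 1 && length(i_resp) > 0) {
    # lo*resp <= DOC_w efflux <= hi*resp
    rows <- add_row(rows, c(i_docw, i_resp),
                    c(1, rep(-de[1], length(i_resp))),
                    0, "ineq", "physiology:doc_efflux")
    rows <- add_row(rows, c(i_resp, i_docw),
                    c(rep(de[2], length(i_resp)), -1),
                    0, "ineq", "physiology:doc_efflux")
  }

  i_bury <- flow_idx(model, source = "Det", sink = "Det_s")
  i_imp <- model$flows$index[
    model$flows$source %in% external_ids(model) |
      (model$flows$source == "DIC" & model$flows$sink %in% internals)]
  i_imp <- unique(i_imp)
  be <- model$rules$burial_efficiency_range
  if (length(i_bury) == 1 && length(i_imp) > 0) {
    rows <- add_row(rows, c(i_bury, i_imp),
                    c(1, rep(-be[1], length(i_imp))),
                    0, "ineq", "physiology:burial")
    rows <- add_row(rows, c(i_imp, i_bury),
                    c(rep(be[2], length(i_imp)), -1),
                    0, "ineq", "physiology:burial")
  }
  rows
}

#' Compile a food-web model into its linear constraint system
#'
#' Concatenates mass-balance equalities with physiological, isotope and
#' site inequality rows plus per-flow nonnegativity, producing the
#' system `E x = f`, `G x >= h` over the flow vector. Row provenance is
#' recorded for every row, so infeasibility certificates and
#' sensitivity checks can name the biological rule responsible.
#'
#' @param model A validated [build_topology()] model.
#' @param delta,k Isotope mixing options, see
#'   [compile_isotope_constraints()].
#' @param include Which row families to emit; default all.
#' @param biomass_rows Passed to [compile_physiological_constraints()].
#' @return An object of class `lim_system`: `E`, `f`, `G`, `h`,
#'   `flow_labels`, `eq_provenance`, `ineq_provenance`.
#' @export
compile_lim <- function(model, delta = 1, k = 2,
                        include = c("mass_balance", "physiology",
                                    "isotope", "site", "nonnegativity"),
                        biomass_rows = TRUE) {
  parts <- list()
  if ("mass_balance" %in% include) {
    parts <- c(parts, list(compile_mass_balance(model)))
  }
  if ("physiology" %in% include) {
    parts <- c(parts, list(
      compile_physiological_constraints(model, biomass_rows = biomass_rows)))
  }
  if ("isotope" %in% include) {
    parts <- c(parts, list(compile_isotope_constraints(model, delta, k)))
  }
  if ("site" %in% include) {
    parts <- c(parts, list(compile_site_constraints(model)))
  }
  rows <- do.call(merge_rows, parts)
  if ("nonnegativity" %in% include) {
    for (i in model$flows$index) {
      rows <- add_row(rows, i, 1, 0, "ineq",
                      paste0("nonnegativity:", model$flows$label[i]))
    }
  }
  assemble_system(rows, model)
}

assemble_system <- function(rows, model) {
  n <- nrow(model$flows)
  labels <- model$flows$label
  is_eq <- rows$type == "eq"
  build <- function(sel) {
    m <- matrix(0, nrow = sum(sel), ncol = n,
                dimnames = list(NULL, labels))
    ii <- which(sel)
    for (r in seq_along(ii)) {
      m[r, rows$idx[[ii[r]]]] <- rows$coef[[ii[r]]]
    }
    m
  }
  E <- build(is_eq)
  G <- build(!is_eq)
  stopifnot(ncol(E) == n, ncol(G) == n)
  if (nrow(E) > 0 && any(rowSums(abs(E)) == 0)) {
    stop("empty equality row after assembly")
  }
  if (nrow(G) > 0 && any(rowSums(abs(G)) == 0)) {
    stop("empty inequality row after assembly")
  }
  structure(
    list(E = E, f = unname(rows$rhs[is_eq]),
         G = G, h = unname(rows$rhs[!is_eq]),
         flow_labels = labels,
         eq_provenance = unname(rows$provenance[is_eq]),
         ineq_provenance = unname(rows$provenance[!is_eq])),
    class = "lim_system"
  )
}

#' @export
print.lim_system <- function(x, ...) {
  cat("<lim_system>", length(x$flow_labels), "flows,",
      nrow(x$E), "equalities,", nrow(x$G), "inequalities\n")
  invisible(x)
}

# append extra inequality rows (used by the synthetic generator)
augment_system <- function(system, G_extra, h_extra, provenance) {
  stopifnot(ncol(G_extra) == ncol(system$G),
            nrow(G_extra) == length(h_extra),
            length(provenance) == length(h_extra))
  colnames(G_extra) <- colnames(system$G)
  system$G <- rbind(system$G, G_extra)
  system$h <- c(system$h, h_extra)
  system$ineq_provenance <- c(system$ineq_provenance, provenance)
  system
}
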
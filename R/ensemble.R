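# Reduction of flow ensembles to summary statistics, diet compositions,
# organic-matter budget partitions and the fraction-of-solutions
# comparison statistic.

ensemble_matrix <- function(ensemble) {
  if (inherits(ensemble, "flow_ensemble")) return(ensemble$samples)
  as.matrix(ensemble)
}

#' Per-flow ensemble summary
#'
#' Sample mean, sample standard deviation (n - 1 denominator) and
#' coefficient of variation (CoV = SD / |mean|) per flow, plus the
#' counts of flows with CoV >= 1 (still highly uncertain), < 0.5 and
#' < 0.2. Flows whose ensemble mean is zero get an undefined (NA) CoV
#' rather than an infinity; a flow that is constant across the ensemble
#' has CoV 0.
#'
#' @param ensemble A [sample_polytope()] ensemble or sample matrix with
#'   at least two rows.
#' @return A list of class `ensemble_summary`: `table` (data.frame
#'   `flow`, `mean`, `sd`, `cov`), `mean_cov`, `n_cov_ge_1`,
#'   `n_cov_lt_0.5`, `n_cov_lt_0.2`, `n_cov_undefined`.
#' @export
ensemble_summary <- function(ensemble) {
  s <- ensemble_matrix(ensemble)
  if (nrow(s) < 2) stop("need at least two solutions")
  m <- colMeans(s)
  sd <- apply(s, 2, stats::sd)
  cov <- ifelse(abs(m) < 1e-12, NA_real_, sd / abs(m))
  tab <- data.frame(flow = colnames(s), mean = unname(m),
                    sd = unname(sd), cov = unname(cov),
                    stringsAsFactors = FALSE)
  structure(
    list(table = tab,
         mean_cov = mean(cov, na.rm = TRUE),
         n_cov_ge_1 = sum(cov >= 1, na.rm = TRUE),
         n_cov_lt_0.5 = sum(cov < 0.5, na.rm = TRUE),
         n_cov_lt_0.2 = sum(cov < 0.2, na.rm = TRUE),
         n_cov_undefined = sum(is.na(cov))),
    class = "ensemble_summary"
  )
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("<ensemble_summary>", nrow(x$table), "flows | mean CoV",
      signif(x$mean_cov, 3), "|", x$n_cov_ge_1, "flows with CoV >= 1\n")
  invisible(x)
}

#' Fraction-of-solutions comparison
#'
#' Compares two solution sets for a flow or derived statistic by the
#' fraction of cross pairs `(a, b)` with `a > b` (ties count zero).
#' Differences with a fraction above 0.95 are labelled significant and
#' above 0.98 highly significant. The fraction is computed exactly for
#' any ensemble size by a sorted scan over the cross pairs, which
#' equals exhaustive enumeration.
#'
#' @param a,b Numeric vectors (e.g. one flow column from two site
#'   ensembles), or ensembles/matrices together with `statistic`.
#' @param statistic Optional flow label selecting a column when `a`/`b`
#'   are ensembles.
#' @return A list of class `comparison_result`: `statistic`,
#'   `fraction_greater`, `verdict` (`none`/`significant`/
#'   `highly_significant`).
#' @export
fraction_greater <- function(a, b, statistic = NULL) {
  pick <- function(x) {
    if (inherits(x, "flow_ensemble") || is.matrix(x)) {
      m <- ensemble_matrix(x)
      if (is.null(statistic)) stop("statistic required for ensembles")
      if (!statistic %in% colnames(m)) {
        stop("statistic ", statistic, " not found in ensemble")
      }
      m[, statistic]
    } else {
      as.numeric(x)
    }
  }
  av <- pick(a); bv <- pick(b)
  if (length(av) == 0 || length(bv) == 0) stop("empty solution set")
  # #(pairs with a > b) = sum over a of #{b strictly below a}
  sb <- sort(bv)
  n_less <- findInterval(av, sb, left.open = TRUE)
  # findInterval(.., left.open = TRUE) counts sb < av exactly (ties to
  # the left interval); verified against enumeration in the test suite
  frac <- sum(as.numeric(n_less)) /
    (as.numeric(length(av)) * as.numeric(length(bv)))
  verdict <- if (frac > 0.98) "highly_significant"
             else if (frac > 0.95) "significant" else "none"
  structure(list(statistic = statistic %||% "value",
                 fraction_greater = frac, verdict = verdict),
            class = "comparison_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>", x$statistic, ": fraction greater =",
      signif(x$fraction_greater, 4), "->", x$verdict, "\n")
  invisible(x)
}

#' Diet composition of a consumer
#'
#' Mean percentage, over the solution ensemble, of each feeding inflow
#' in the consumer's total feeding intake. Feeding inflows are all
#' inflows except DIC fixation (detritus and suspended-detritus uptake,
#' bacterivory, predation); a compartment whose only input is symbiont
#' fixation has no diet and raises an error. Solutions with zero total
#' intake are excluded from the average and counted.
#'
#' @param model The model the ensemble was sampled from.
#' @param ensemble Ensemble or sample matrix.
#' @param consumer Compartment id.
#' @return A list of class `diet_composition`: `consumer`, `table`
#'   (`source`, `percent`), `n_zero_intake`.
#' @export
diet_composition <- function(model, ensemble, consumer) {
  s <- ensemble_matrix(ensemble)
  if (!consumer %in% model$compartments$id) {
    stop("unknown compartment ", consumer)
  }
  i_fix <- flow_idx(model, source = "DIC", sink = consumer)
  i_food <- setdiff(flow_idx(model, sink = consumer), i_fix)
  if (length(i_food) == 0) {
    if (length(i_fix) > 0) {
      stop(consumer, " has no feeding inflows: its only input is ",
           "symbiont/chemoautotrophic fixation")
    }
    stop(consumer, " has no inflows")
  }
  food <- s[, i_food, drop = FALSE]
  intake <- rowSums(food)
  ok <- intake > 1e-12
  if (!any(ok)) stop("total intake is zero in every solution")
  prop <- food[ok, , drop = FALSE] / intake[ok]
  pct <- 100 * colMeans(prop)
  src <- model$flows$source[match(i_food, model$flows$index)]
  structure(
    list(consumer = consumer,
         table = data.frame(source = src, percent = unname(pct),
                            stringsAsFactors = FALSE),
         n_zero_intake = sum(!ok)),
    class = "diet_composition"
  )
}

#' @export
print.diet_composition <- function(x, ...) {
  cat("<diet_composition>", x$consumer, "\n")
  for (i in seq_len(nrow(x$table))) {
    cat(sprintf("  %-8s %6.1f%%\n", x$table$source[i], x$table$percent[i]))
  }
  if (x$n_zero_intake > 0) {
    cat("  (", x$n_zero_intake, "zero-intake solutions excluded )\n")
  }
  invisible(x)
}

budget_flow_sets <- function(model) {
  internals <- internal_ids(model)
  comp <- model$compartments
  cls <- stats::setNames(comp$taxon_class, comp$id)
  i_poc <- flow_idx(model, source = "Det_w", sink = "Det")
  faunal <- comp$id[comp$taxon_class %in% c("macrofauna", "megafauna")]
  susp_feeders <- unique(model$flows$sink[model$flows$source == "Det_w" &
                                            model$flows$sink %in% faunal])
  fixers <- unique(model$flows$sink[model$flows$source == "DIC" &
                                      model$flows$sink %in% internals])
  i_susp <- model$flows$index[model$flows$source == "Det_w" &
                                model$flows$sink %in% susp_feeders]
  i_fix <- model$flows$index[model$flows$source == "DIC" &
                               model$flows$sink %in% internals]
  i_resp_all <- model$flows$index[model$flows$sink == "DIC" &
                                    model$flows$source %in% internals]
  resp_of <- function(ids) {
    model$flows$index[model$flows$sink == "DIC" &
                        model$flows$source %in% ids]
  }
  list(
    poc = i_poc,
    susp = i_susp,
    fix = i_fix,
    resp_all = i_resp_all,
    resp_susp = resp_of(susp_feeders),
    resp_fix = resp_of(fixers),
    resp_bacteria = resp_of(names(cls)[cls == "bacteria"]),
    resp_macro = resp_of(names(cls)[cls == "macrofauna"]),
    resp_mega = resp_of(names(cls)[cls == "megafauna"]),
    detritus_prod = model$flows$index[model$flows$sink == "Det" &
                                        model$flows$source %in% internals],
    burial = flow_idx(model, source = "Det", sink = "Det_s"),
    doc_efflux = flow_idx(model, source = "DOC", sink = "DOC_w"),
    predation = model$flows$index[model$flows$sink == "Predation"]
  )
}

#' Organic-matter budget of a solution ensemble
#'
#' Partitions each sampled solution into the site carbon budget and
#' averages: gross inputs (POC deposition, suspension-feeding capture,
#' chemosynthetic DIC fixation), net inputs (gross minus the respiration
#' of the mediating compartments: suspension feeders for the suspension
#' route, chemoautotrophs and symbiont-bearing fauna for fixation),
#' internal processing (total respiration and its partition by
#' bacterial/macrofaunal/megafaunal class; detritus production by all
#' internal compartments), and outputs (burial, DOC efflux, external
#' predation). Percentage shares of the organic-matter inputs use the
#' net values. Routes absent from the topology contribute zero.
#'
#' @param model The model the ensemble was sampled from.
#' @param ensemble Ensemble or sample matrix.
#' @return A list of class `budget_report` with elements `table`
#'   (data.frame `variable`, `mean`, `sd`), `shares` (named percentage
#'   means over net inputs) and `conservation_residual` (max over
#'   solutions of |gross inputs - respiration - outputs|).
#' @export
om_budget <- function(model, ensemble) {
  s <- ensemble_matrix(ensemble)
  fs <- budget_flow_sets(model)
  rs <- function(ii) if (length(ii) == 0) rep(0, nrow(s)) else
    rowSums(s[, ii, drop = FALSE])
  poc <- rs(fs$poc)
  gross_susp <- rs(fs$susp)
  gross_fix <- rs(fs$fix)
  net_susp <- gross_susp - rs(fs$resp_susp)
  net_fix <- gross_fix - rs(fs$resp_fix)
  net_total <- poc + net_susp + net_fix
  gross_total <- poc + gross_susp + gross_fix
  resp_total <- rs(fs$resp_all)
  det_prod <- rs(fs$detritus_prod)
  burial <- rs(fs$burial)
  doc_eff <- rs(fs$doc_efflux)
  predation <- rs(fs$predation)
  # whole-system conservation: gross inputs fund respiration + exports
  residual <- gross_total - resp_total - burial - doc_eff - predation
  vars <- list(
    "POC deposition" = poc,
    "Net Suspension Feeding" = net_susp,
    "Net Chemosynthesis" = net_fix,
    "Net Total OM Input" = net_total,
    "Gross Total OM Input" = gross_total,
    "Faunal Detritus Production" = det_prod,
    "Total C Respiration" = resp_total,
    "Bacterial Respiration" = rs(fs$resp_bacteria),
    "Macrofaunal Respiration" = rs(fs$resp_macro),
    "Megafaunal Respiration" = rs(fs$resp_mega),
    "Burial of Organic C" = burial,
    "DOC Efflux" = doc_eff,
    "External Predation" = predation
  )
  tab <- data.frame(
    variable = names(vars),
    mean = vapply(vars, mean, numeric(1)),
    sd = vapply(vars, stats::sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  ok <- net_total > 1e-12
  shares <- c(
    poc_deposition = mean(100 * poc[ok] / net_total[ok]),
    net_suspension = mean(100 * net_susp[ok] / net_total[ok]),
    net_chemosynthesis = mean(100 * net_fix[ok] / net_total[ok])
  )
  structure(
    list(table = tab, shares = shares,
         conservation_residual = max(abs(residual))),
    class = "budget_report"
  )
}

#' @export
print.budget_report <- function(x, ...) {
  cat("<budget_report> (mmol C m-2 d-1)\n")
  for (i in seq_len(nrow(x$table))) {
    cat(sprintf("  %-28s %8.3f (+/- %.3f)\n", x$table$variable[i],
                x$table$mean[i], x$table$sd[i]))
  }
  cat(sprintf("  OM input shares (net): POC %.1f%% | suspension %.1f%% | chemosynthesis %.1f%%\n",
              x$shares[1], x$shares[2], x$shares[3]))
  invisible(x)
}
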
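#' Standard compartment table for a sedimented-vent benthic food web
#'
#' Returns the canonical compartment set used by the site models: ten
#' internal pools (detritus, dissolved organic carbon, heterotrophic and
#' chemosynthetic bacteria, and six faunal functional groups) and five
#' external pools (buried detritus, megafaunal predation, dissolved
#' inorganic carbon, water-column DOC and the particulate detritus flux
#' from the water column). Biomass and carbon stable-isotope fields are
#' left `NA`; callers fill them from site data or from the synthetic
#' generator.
#'
#' @return A `data.frame` with columns `id`, `name`, `locality`
#'   (`"internal"`/`"external"`), `taxon_class`, `biomass` (mmol C m-2),
#'   `d13c_mean`, `d13c_sd` (permil vs VPDB) and `feeding_modes`
#'   (`;`-separated subset of `deposit`, `suspension`, `predation`,
#'   `symbiont_fixation`, `heterotrophy`, `chemoautotrophy`).
#' @export
default_compartments <- function() {
  data.frame(
    id = c("Det", "DOC", "Bac", "ChBac", "MacES", "MacDF", "MacSF",
           "MacPS", "MegDF", "MegSF",
           "Det_s", "Predation", "DIC", "DOC_w", "Det_w"),
    name = c("Detritus", "Dissolved organic carbon",
             "Heterotrophic bacteria", "Chemosynthetic bacteria",
             "Macrofauna with endosymbionts", "Macrofaunal deposit feeders",
             "Macrofaunal suspension feeders",
             "Macrofaunal predators/scavengers",
             "Megafaunal deposit feeders", "Megafaunal suspension feeders",
             "Buried detritus", "Megafaunal predation",
             "Dissolved inorganic carbon", "Water-column DOC",
             "Particulate detritus flux from the water column"),
    locality = c(rep("internal", 10), rep("external", 5)),
    taxon_class = c("detritus", "dissolved", "bacteria", "bacteria",
                    "macrofauna", "macrofauna", "macrofauna", "macrofauna",
                    "megafauna", "megafauna",
                    "detritus", "external", "dissolved", "dissolved",
                    "detritus"),
    biomass = NA_real_,
    d13c_mean = NA_real_,
    d13c_sd = NA_real_,
    feeding_modes = c("", "", "heterotrophy", "chemoautotrophy",
                      "symbiont_fixation", "deposit", "suspension",
                      "predation", "deposit", "suspension",
                      "", "", "", "", ""),
    stringsAsFactors = FALSE
  )
}

VALID_FEEDING_MODES <- c("deposit", "suspension", "predation",
                         "symbiont_fixation", "heterotrophy",
                         "chemoautotrophy")

split_modes <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Default edge rules mapping feeding modes to flows
#'
#' When no explicit flow list is supplied, [build_topology()] generates
#' edges from this fixed rule set (applied to whichever compartments are
#' present): water-column detritus settles and is captured by suspension
#' feeders; sediment detritus feeds bacteria, leaches to DOC, is buried
#' and is ingested by deposit feeders; DOC feeds bacteria and effluxes;
#' DIC is fixed by chemoautotrophs and endosymbiont hosts; bacteria
#' respire, return detritus (viral lysis) and are grazed; every faunal
#' group respires and produces detritus; endosymbiont-bearing and other
#' macrofauna are preyed on by predators/scavengers; epibenthic fauna are
#' cropped by external predators.
#'
#' @return A two-column `data.frame` of `source`, `sink` compartment ids.
#' @export
default_edge_rules <- function() {
  edges <- rbind(
    expand.grid(source = "Det_w", sink = c("Det", "MacSF", "MegSF")),
    expand.grid(source = "Det", sink = c("Bac", "DOC", "Det_s", "MacDF",
                                         "MegDF")),
    expand.grid(source = "DOC", sink = c("Bac", "DOC_w")),
    expand.grid(source = "DIC", sink = c("ChBac", "MacES")),
    expand.grid(source = "Bac", sink = c("DIC", "Det", "MacDF", "MacPS")),
    expand.grid(source = "ChBac", sink = c("DIC", "Det", "MacDF")),
    expand.grid(source = c("MacES", "MacDF", "MacSF", "MacPS", "MegDF",
                           "MegSF"), sink = c("DIC", "Det")),
    expand.grid(source = c("MacES", "MacDF", "MacSF"), sink = "MacPS"),
    expand.grid(source = c("MacDF", "MacSF", "MacPS", "MegDF", "MegSF"),
                sink = "Predation")
  )
  edges$source <- as.character(edges$source)
  edges$sink <- as.character(edges$sink)
  rownames(edges) <- NULL
  edges
}

#' Assemble and validate a food-web model
#'
#' Builds a [foodweb_model] from a compartment table, optional site-level
#' compartment absences, and either an explicit flow list or the default
#' edge rules ([default_edge_rules()]). Flows touching an absent
#' compartment are dropped; the remaining structure is validated (no
#' dangling endpoints, no self-loops, unique labels, every internal
#' compartment with at least one inflow and one outflow, positive biomass
#' where a faunal biomass is supplied).
#'
#' @param compartments Compartment `data.frame` as from
#'   [default_compartments()].
#' @param site_absences Character vector of compartment ids absent at the
#'   site (e.g. `"ChBac"` at the off-vent site).
#' @param flow_list Optional two-column `data.frame` (`source`, `sink`).
#'   When `NULL`, edges are generated from [default_edge_rules()].
#' @param environment Optional [site_environment()].
#' @param rules Physiological rule set, see [default_physiology_rules()].
#' @return An object of class `foodweb_model` with elements
#'   `compartments`, `flows` (with `index` and `label` columns),
#'   `environment` and `rules`.
#' @export
build_topology <- function(compartments, site_absences = character(0),
                           flow_list = NULL, environment = NULL,
                           rules = default_physiology_rules()) {
  stopifnot(is.data.frame(compartments), nrow(compartments) > 0)
  needed <- c("id", "locality", "taxon_class")
  missing_cols <- setdiff(needed, names(compartments))
  if (length(missing_cols) > 0) {
    stop("compartment table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(compartments$id)) {
    stop("duplicate compartment id(s): ",
         paste(unique(compartments$id[duplicated(compartments$id)]),
               collapse = ", "))
  }
  for (col in c("name", "biomass", "d13c_mean", "d13c_sd",
                "feeding_modes")) {
    if (is.null(compartments[[col]])) {
      compartments[[col]] <- if (col %in% c("name", "feeding_modes"))
        NA_character_ else NA_real_
    }
  }
  unknown <- setdiff(site_absences, compartments$id)
  if (length(unknown) > 0) {
    stop("site_absences name unknown compartment(s): ",
         paste(unknown, collapse = ", "))
  }
  comp <- compartments[!compartments$id %in% site_absences, , drop = FALSE]
  rownames(comp) <- NULL

  for (i in seq_len(nrow(comp))) {
    modes <- split_modes(comp$feeding_modes[i])
    bad <- setdiff(modes, VALID_FEEDING_MODES)
    if (length(bad) > 0) {
      stop("compartment ", comp$id[i], " has unknown feeding mode(s): ",
           paste(bad, collapse = ", "))
    }
    if (comp$locality[i] == "external" && isTRUE(comp$biomass[i] > 0)) {
      stop("external compartment ", comp$id[i], " must not carry biomass")
    }
    if (identical(comp$id[i], "MacES") &&
        !identical(modes, "symbiont_fixation")) {
      stop("MacES must have feeding_modes = symbiont_fixation only")
    }
    if (comp$locality[i] == "internal" &&
        comp$taxon_class[i] %in% c("bacteria", "macrofauna", "megafauna") &&
        !is.na(comp$biomass[i]) && comp$biomass[i] <= 0) {
      stop("compartment ", comp$id[i], " has non-positive biomass")
    }
  }

  if (is.null(flow_list)) flow_list <- default_edge_rules()
  stopifnot(is.data.frame(flow_list),
            all(c("source", "sink") %in% names(flow_list)))
  flows <- data.frame(source = as.character(flow_list$source),
                      sink = as.character(flow_list$sink),
                      stringsAsFactors = FALSE)
  # explicit lists must resolve; rule-generated edges are silently
  # restricted to the compartments present at the site
  if (missing(flow_list) || is.null(flow_list)) {
    flows <- flows[flows$source %in% comp$id & flows$sink %in% comp$id, ,
                   drop = FALSE]
  } else {
    keep <- !(flows$source %in% site_absences |
                flows$sink %in% site_absences)
    flows <- flows[keep, , drop = FALSE]
    dangling <- setdiff(c(flows$source, flows$sink), comp$id)
    if (length(dangling) > 0) {
      bad <- flows$source %in% dangling | flows$sink %in% dangling
      stop("flow(s) reference undeclared compartment(s): ",
           paste(paste0(flows$source[bad], "->", flows$sink[bad]),
                 collapse = ", "))
    }
  }
  if (any(flows$source == flows$sink)) {
    bad <- flows$source[flows$source == flows$sink]
    stop("self-loop flow(s) not allowed: ", paste(bad, collapse = ", "))
  }
  loc <- stats::setNames(comp$locality, comp$id)
  both_external <- loc[flows$source] == "external" &
    loc[flows$sink] == "external"
  if (any(both_external)) {
    stop("flow(s) with both endpoints external: ",
         paste(paste0(flows$source[both_external], "->",
                      flows$sink[both_external]), collapse = ", "))
  }
  flows$label <- paste0(flows$source, "->", flows$sink)
  if (anyDuplicated(flows$label)) {
    stop("duplicate flow(s): ",
         paste(unique(flows$label[duplicated(flows$label)]),
               collapse = ", "))
  }
  flows$index <- seq_len(nrow(flows))
  flows <- flows[, c("index", "source", "sink", "label")]
  rownames(flows) <- NULL

  internals <- comp$id[comp$locality == "internal"]
  for (id in internals) {
    if (!any(flows$sink == id)) {
      stop("internal compartment ", id, " has no inflow")
    }
    if (!any(flows$source == id)) {
      stop("internal compartment ", id, " has no outflow")
    }
  }

  model <- structure(
    list(compartments = comp, flows = flows, environment = environment,
         rules = rules),
    class = "foodweb_model"
  )
  model
}

#' Site environment descriptor
#'
#' @param site_id Short site label.
#' @param depth Water depth (m).
#' @param temperature Sediment temperature (degrees C), within [-2, 100].
#' @param scoc_range Two-element range (lo, hi) of total sediment
#'   community oxygen consumption in carbon units (mmol C m-2 d-1).
#' @param poc_range Two-element range of particulate organic carbon
#'   deposition (mmol C m-2 d-1).
#' @param advection Optional hydrothermal fluid advection (cm yr-1).
#' @param substrate_conc Optional named list of chemical concentrations
#'   (umol l-1); carried as metadata only.
#' @return A list of class `site_environment`.
#' @export
site_environment <- function(site_id, depth = NA_real_,
                             temperature = NA_real_,
                             scoc_range = NULL, poc_range = NULL,
                             advection = NA_real_,
                             substrate_conc = list()) {
  check_range <- function(r, what) {
    if (is.null(r)) return(NULL)
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
      stop(what, " must be a finite range with lo <= hi")
    }
    as.numeric(r)
  }
  if (!is.na(temperature) &&
      (temperature < -2 || temperature > 100)) {
    stop("temperature must lie within [-2, 100] degrees C")
  }
  structure(
    list(site_id = site_id, depth = depth, temperature = temperature,
         advection = advection,
         scoc_range = check_range(scoc_range, "scoc_range"),
         poc_range = check_range(poc_range, "poc_range"),
         substrate_conc = substrate_conc),
    class = "site_environment"
  )
}

#' @export
print.foodweb_model <- function(x, ...) {
  n_int <- sum(x$compartments$locality == "internal")
  n_ext <- sum(x$compartments$locality == "external")
  cat("<foodweb_model>", n_int, "internal +", n_ext,
      "external compartments,", nrow(x$flows), "flows\n")
  if (!is.null(x$environment)) {
    cat("  site:", x$environment$site_id,
        "| temperature:", x$environment$temperature, "degC\n")
  }
  invisible(x)
}

internal_ids <- function(model) {
  model$compartments$id[model$compartments$locality == "internal"]
}

external_ids <- function(model) {
  model$compartments$id[model$compartments$locality == "external"]
}
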
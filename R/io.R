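# Readers and writers: the declarative model file format, stocks CSV,
# ensemble CSV with JSON sidecar, and JSON reports.
#
# Model file dialect (UTF-8, '#' starts a comment):
#   ## COMPARTMENTS
#   id, name, internal|external, taxon_class, biomass, d13c_mean,
#   d13c_sd, feeding_modes (';'-separated)
#   ## FLOWS
#   source -> sink
#   ## PARAMETERS
#   name = value      or      name = [lo, hi]
#   (environment keys: site_id, depth, temperature, advection,
#    scoc_range, poc_range, substrate.<chem>; physiology keys: q10,
#    bge_range, ..., macrofauna.nge_range, ...)
#   ## CONSTRAINTS
#   linear expressions in flow labels, e.g. "2 Det->Bac + DOC->Bac < 1.5"

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", vapply(x, function(v)
    format(v, digits = 17, scientific = FALSE, trim = TRUE), ""))
}

#' Write a food-web model to a declarative model file
#'
#' @param model A validated `foodweb_model`.
#' @param path Output file path.
#' @return `path`, invisibly. Reading the file back yields a model that
#'   is structurally identical field-for-field.
#' @export
write_foodweb_model <- function(model, path) {
  lines <- c("# ventlim declarative model file", "## COMPARTMENTS")
  comp <- model$compartments
  for (i in seq_len(nrow(comp))) {
    lines <- c(lines, paste(
      comp$id[i], comp$name[i], comp$locality[i], comp$taxon_class[i],
      fmt_num(comp$biomass[i]), fmt_num(comp$d13c_mean[i]),
      fmt_num(comp$d13c_sd[i]),
      if (is.na(comp$feeding_modes[i]) || !nzchar(comp$feeding_modes[i]))
        "-" else comp$feeding_modes[i],
      sep = ", "))
  }
  lines <- c(lines, "## FLOWS",
             paste(model$flows$source, "->", model$flows$sink))
  lines <- c(lines, "## PARAMETERS")
  env <- model$environment
  pr <- function(name, value) {
    if (is.null(value) || (length(value) == 1 && is.na(value))) {
      return(character(0))
    }
    if (length(value) == 2) {
      paste0(name, " = [", fmt_num(value[1]), ", ", fmt_num(value[2]), "]")
    } else {
      paste0(name, " = ", if (is.character(value)) value else
        fmt_num(value))
    }
  }
  if (!is.null(env)) {
    lines <- c(lines, pr("site_id", env$site_id), pr("depth", env$depth),
               pr("temperature", env$temperature),
               pr("advection", env$advection),
               pr("scoc_range", env$scoc_range),
               pr("poc_range", env$poc_range))
    for (nm in names(env$substrate_conc)) {
      lines <- c(lines, pr(paste0("substrate.", nm),
                           env$substrate_conc[[nm]]))
    }
  }
  r <- model$rules
  lines <- c(lines, pr("q10", r$q10), pr("bge_range", r$bge_range),
             pr("viral_lysis_range", r$viral_lysis_range),
             pr("chemo_efficiency_range", r$chemo_efficiency_range),
             pr("burial_efficiency_range", r$burial_efficiency_range),
             pr("doc_efflux_range", r$doc_efflux_range))
  for (cls in c("macrofauna", "megafauna")) {
    for (nm in names(r[[cls]])) {
      lines <- c(lines, pr(paste(cls, nm, sep = "."), r[[cls]][[nm]]))
    }
  }
  if (!is.null(model$extra_constraints) &&
      length(model$extra_constraints) > 0) {
    lines <- c(lines, "## CONSTRAINTS",
               vapply(model$extra_constraints, `[[`, "", "text"))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

strip_comment <- function(x) {
  sub("#.*$", "", x)
}

parse_value <- function(txt, path, lineno) {
  txt <- trimws(txt)
  if (grepl("^\\[.*\\]$", txt)) {
    parts <- strsplit(gsub("^\\[|\\]$", "", txt), ",")[[1]]
    v <- suppressWarnings(as.numeric(trimws(parts)))
    if (length(v) != 2 || anyNA(v)) {
      stop(path, ":", lineno, ": malformed range '", txt, "'")
    }
    return(v)
  }
  num <- suppressWarnings(as.numeric(txt))
  if (!is.na(num)) num else txt
}

#' Read a declarative model file
#'
#' Parses and validates (via [build_topology()]) a model file in the
#' dialect documented in [write_foodweb_model()]. Syntax errors report
#' the file and line number.
#'
#' @param path Model file path.
#' @return A validated `foodweb_model`.
#' @export
read_foodweb_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  section <- ""
  comp <- list(); flows <- list(); params <- list(); cons <- list()
  param_lines <- integer(0)
  for (i in seq_along(raw)) {
    line <- trimws(raw[i])
    if (!grepl("^##", line)) line <- trimws(strip_comment(line))
    if (!nzchar(line)) next
    if (grepl("^##", line)) {
      section <- toupper(trimws(sub("^##", "", line)))
      if (!section %in% c("COMPARTMENTS", "FLOWS", "PARAMETERS",
                          "CONSTRAINTS")) {
        stop(path, ":", i, ": unknown section '", section, "'")
      }
      next
    }
    if (section == "COMPARTMENTS") {
      fields <- trimws(strsplit(line, ",", fixed = TRUE)[[1]])
      if (length(fields) != 8) {
        stop(path, ":", i, ": compartment row needs 8 fields, got ",
             length(fields))
      }
      if (!fields[3] %in% c("internal", "external")) {
        stop(path, ":", i, ": locality must be internal or external")
      }
      comp[[length(comp) + 1]] <- data.frame(
        id = fields[1], name = fields[2], locality = fields[3],
        taxon_class = fields[4],
        biomass = suppressWarnings(as.numeric(fields[5])),
        d13c_mean = suppressWarnings(as.numeric(fields[6])),
        d13c_sd = suppressWarnings(as.numeric(fields[7])),
        feeding_modes = if (fields[8] %in% c("-", "NA")) "" else fields[8],
        stringsAsFactors = FALSE)
    } else if (section == "FLOWS") {
      if (!grepl("->", line, fixed = TRUE)) {
        stop(path, ":", i, ": flow row must be 'source -> sink'")
      }
      parts <- trimws(strsplit(line, "->", fixed = TRUE)[[1]])
      if (length(parts) != 2 || !all(nzchar(parts))) {
        stop(path, ":", i, ": flow row must be 'source -> sink'")
      }
      flows[[length(flows) + 1]] <- data.frame(
        source = parts[1], sink = parts[2], stringsAsFactors = FALSE)
    } else if (section == "PARAMETERS") {
      kv <- regmatches(line, regexec("^([^=]+)=(.*)$", line))[[1]]
      if (length(kv) != 3) {
        stop(path, ":", i, ": parameter row must be 'name = value'")
      }
      params[[trimws(kv[2])]] <- parse_value(kv[3], path, i)
      param_lines[trimws(kv[2])] <- i
    } else if (section == "CONSTRAINTS") {
      cons[[length(cons) + 1]] <- parse_constraint_line(line, path, i)
    } else {
      stop(path, ":", i, ": content before any '## SECTION' header")
    }
  }
  if (length(comp) == 0) stop(path, ": no compartments declared")
  comp <- do.call(rbind, comp)
  flows <- if (length(flows) > 0) do.call(rbind, flows) else NULL

  rules <- default_physiology_rules()
  env_args <- list(site_id = params[["site_id"]] %||% "site")
  for (nm in c("depth", "temperature", "advection", "scoc_range",
               "poc_range")) {
    if (!is.null(params[[nm]])) env_args[[nm]] <- params[[nm]]
  }
  sub_keys <- grep("^substrate\\.", names(params), value = TRUE)
  if (length(sub_keys) > 0) {
    env_args$substrate_conc <- stats::setNames(
      lapply(sub_keys, function(k) params[[k]]),
      sub("^substrate\\.", "", sub_keys))
  }
  for (nm in names(params)) {
    if (nm %in% c("site_id", "depth", "temperature", "advection",
                  "scoc_range", "poc_range") ||
        grepl("^substrate\\.", nm)) next
    if (grepl("^(macrofauna|megafauna)\\.", nm)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      if (is.null(rules[[parts[1]]][[parts[2]]])) {
        stop(path, ":", param_lines[nm], ": unknown parameter '", nm, "'")
      }
      rules[[parts[1]]][[parts[2]]] <- params[[nm]]
    } else {
      if (is.null(rules[[nm]])) {
        stop(path, ":", param_lines[nm], ": unknown parameter '", nm, "'")
      }
      rules[[nm]] <- params[[nm]]
    }
  }
  validate_physiology_rules(rules)
  model <- build_topology(comp, flow_list = flows,
                          environment = do.call(site_environment,
                                                env_args),
                          rules = rules)
  if (length(cons) > 0) {
    for (cn in cons) {
      missing <- setdiff(names(cn$coef), model$flows$label)
      if (length(missing) > 0) {
        stop(path, ":", cn$line, ": constraint references unknown ",
             "flow(s): ", paste(missing, collapse = ", "))
      }
    }
    model$extra_constraints <- cons
  }
  model
}

# parse "2 A->B + C->D - 0.5 E->F >= 1.2" into coefficient map + op + rhs
parse_constraint_line <- function(line, path, lineno) {
  m <- regexec("^(.*?)(<=|>=|=|<|>)(.*)$", line)
  parts <- regmatches(line, m)[[1]]
  if (length(parts) != 4) {
    stop(path, ":", lineno, ": constraint must contain =, < or >")
  }
  lhs <- trimws(parts[2]); op <- parts[3]
  rhs <- suppressWarnings(as.numeric(trimws(parts[4])))
  if (is.na(rhs)) {
    stop(path, ":", lineno, ": right-hand side must be numeric")
  }
  op <- switch(op, "<" = "<=", ">" = ">=", op)
  tokens <- regmatches(lhs,
                       gregexpr("[+-]?[^+-]+(->[^+-]+)?", lhs))[[1]]
  # re-tokenise respecting that '->' contains no sign characters
  tokens <- trimws(tokens[nzchar(trimws(tokens))])
  coef <- c()
  for (tk in tokens) {
    sgn <- 1
    body <- tk
    if (startsWith(body, "+")) body <- trimws(substring(body, 2))
    if (startsWith(body, "-")) {
      sgn <- -1; body <- trimws(substring(body, 2))
    }
    mm <- regexec(paste0("^([0-9.eE]+)?[[:space:]]*\\*?[[:space:]]*",
                         "([A-Za-z_][^[:space:]]*->[^[:space:]]+)$"),
                  body)
    pp <- regmatches(body, mm)[[1]]
    if (length(pp) != 3 || !nzchar(pp[3])) {
      stop(path, ":", lineno, ": cannot parse term '", tk, "'")
    }
    cval <- if (nzchar(pp[2])) as.numeric(pp[2]) else 1
    coef[pp[3]] <- (coef[pp[3]] %||% 0) + sgn * cval
  }
  if (length(coef) == 0) {
    stop(path, ":", lineno, ": constraint has no flow terms")
  }
  list(coef = coef, op = op, rhs = rhs, text = line, line = lineno)
}

#' Read a stocks CSV
#'
#' Columns: `compartment_id`, `biomass`, `d13c_mean`, `d13c_sd`. Applied
#' to a model's compartment table with [apply_stocks_csv()].
#'
#' @param path CSV path.
#' @return A `data.frame` with column `id` plus the three data columns.
#' @export
read_stocks_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compartment_id", "biomass", "d13c_mean", "d13c_sd")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("stocks CSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  data.frame(id = tab$compartment_id, biomass = tab$biomass,
             d13c_mean = tab$d13c_mean, d13c_sd = tab$d13c_sd,
             stringsAsFactors = FALSE)
}

#' Replace a model's stocks and isotope data from a stocks table
#'
#' @param model A `foodweb_model`.
#' @param stocks A table from [read_stocks_csv()].
#' @return The model, revalidated.
#' @export
apply_stocks_csv <- function(model, stocks) {
  comp <- apply_stocks(model$compartments, stocks)
  build_topology(comp, flow_list = model$flows[, c("source", "sink")],
                 environment = model$environment, rules = model$rules)
}

#' Write a flow ensemble to CSV (with JSON sidecar)
#'
#' RFC-4180 CSV, '.' decimal separator, 17 significant digits so that
#' re-reading reproduces the ensemble bit-for-bit; sampler metadata
#' (seed, burn-in, jump length, iterations requested) goes to
#' `<path>.meta.json`.
#'
#' @param ensemble A [sample_polytope()] ensemble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "flow_ensemble"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  writeLines(paste(ensemble$flow_labels, collapse = ","), con)
  body <- apply(ensemble$samples, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(body, con)
  close(con)
  meta <- list(seed = ensemble$seed, n_burn_in = ensemble$n_burn_in,
               jump_length = ensemble$jump_length,
               n_iterations_requested = ensemble$n_iterations_requested)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a flow ensemble CSV written by [write_ensemble()]
#'
#' @param path CSV path; the `<path>.meta.json` sidecar is read when
#'   present.
#' @return A `flow_ensemble`.
#' @export
read_ensemble <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  samples <- as.matrix(tab)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(seed = NA_integer_, n_burn_in = NA_integer_,
         jump_length = NA_real_, n_iterations_requested = nrow(samples))
  }
  structure(
    list(samples = samples, flow_labels = colnames(samples),
         seed = meta$seed, n_burn_in = meta$n_burn_in,
         jump_length = meta$jump_length,
         n_iterations_requested = meta$n_iterations_requested),
    class = "flow_ensemble"
  )
}

#' Write an analysis report as JSON
#'
#' Serialises summary objects (budget reports, index tables, comparison
#' results, plain lists) to pretty-printed JSON.
#'
#' @param x Object to serialise.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(unclass_deep(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    x
  }
}
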
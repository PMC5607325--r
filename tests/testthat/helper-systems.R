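# Shared helpers: hand-built constraint systems and a brute-force
# rejection-sampling oracle, kept independent of the package's sampler.

toy_system <- function(E = NULL, f = numeric(0), G = NULL,
                       h = numeric(0), labels) {
  n <- length(labels)
  mk <- function(M) {
    if (is.null(M)) return(matrix(0, 0, n, dimnames = list(NULL, labels)))
    M <- rbind(M)
    dimnames(M) <- list(NULL, labels)
    M
  }
  structure(list(E = mk(E), f = f, G = mk(G), h = h, flow_labels = labels,
                 eq_provenance = paste0("eq", seq_along(f)),
                 ineq_provenance = paste0("ineq", seq_along(h))),
            class = "lim_system")
}

# uniform rejection sampling over a box, keeping points inside
# {Gx >= h}; independent oracle for sampler marginals (no equalities)
rejection_oracle <- function(G, h, lower, upper, n_keep, seed) {
  set.seed(seed)
  d <- length(lower)
  out <- matrix(NA_real_, 0, d)
  while (nrow(out) < n_keep) {
    X <- matrix(stats::runif(d * 20000, lower, upper), ncol = d,
                byrow = TRUE)
    keep <- colSums(G %*% t(X) >= h - 1e-12) == nrow(G)
    out <- rbind(out, X[keep, , drop = FALSE])
  }
  out[seq_len(n_keep), , drop = FALSE]
}

# small deterministic model: two internal pools fed by an import, used
# where a minimal but valid foodweb_model is needed
tiny_model <- function() {
  comp <- data.frame(
    id = c("A", "B", "In", "Out"),
    name = c("pool A", "pool B", "import", "export"),
    locality = c("internal", "internal", "external", "external"),
    taxon_class = c("detritus", "detritus", "detritus", "external"),
    biomass = NA_real_, d13c_mean = NA_real_, d13c_sd = NA_real_,
    feeding_modes = "", stringsAsFactors = FALSE)
  flows <- data.frame(source = c("In", "A", "B"),
                      sink = c("A", "B", "Out"),
                      stringsAsFactors = FALSE)
  build_topology(comp, flow_list = flows,
                 environment = site_environment("tiny", temperature = 10))
}
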
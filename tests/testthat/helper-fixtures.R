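# Shared fixtures, built in code at test time.

# Small expression panel: 2 tissues x 3 samples each.
tiny_panel <- function() {
  vals <- matrix(c(0, 1, 5, 0.2, 3, 7,
                   2, 2, 2, 0, 0, 9), nrow = 2, byrow = TRUE,
                 dimnames = list(c("gA", "gB"), paste0("s", 1:6)))
  expression_panel(vals, setNames(rep(c("liver", "lung"), each = 3),
                                  paste0("s", 1:6)))
}

# Random panel with named tissues, for oracle comparisons.
random_panel <- function(n_genes = 50, n_tissues = 4, spt = 6, seed = 11) {
  set.seed(seed)
  n_s <- n_tissues * spt
  vals <- matrix(rlnorm(n_genes * n_s, meanlog = 1, sdlog = 1.2),
                 nrow = n_genes,
                 dimnames = list(sprintf("g%02d", 1:n_genes),
                                 sprintf("s%03d", 1:n_s)))
  vals[sample(length(vals), length(vals) %/% 5)] <- 0
  expression_panel(vals,
                   setNames(rep(sprintf("t%02d", 1:n_tissues), each = spt),
                            colnames(vals)))
}

# Write an HPA-style annotation table; `counts` is a named list
# gene -> c(high, medium, low, nd).
write_hpa_table <- function(counts, path = tempfile(fileext = ".tsv")) {
  lev <- c("High", "Medium", "Low", "Not detected")
  rows <- do.call(rbind, lapply(names(counts), function(g) {
    cnt <- counts[[g]]
    if (sum(cnt) == 0) return(NULL)
    data.frame(Gene = g, `Gene name` = g,
               Tissue = "tissueA", `Cell type` = "cells",
               Level = rep(lev, cnt), Reliability = "Approved",
               check.names = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Fast configs for module-level tests (criteria that mandate full epochs
# use model_config() defaults instead).
quick_config <- function(epochs = 600, seed = 7, ...) {
  model_config(epochs = epochs, seed = seed, ...)
}

# Cache one mid-sized simulated dataset + calibration across tests.
.sim_env <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.sim_env$sim)) {
    spec <- simulation_spec(n_genes = 120, n_tissues = 12,
                            samples_per_tissue = 12, slides_per_gene = 40,
                            seed = 21)
    .sim_env$sim <- simulate_dataset(spec)
    .sim_env$cal <- calibrate(.sim_env$sim$X, .sim_env$sim$Y,
                              .sim_env$sim$Z, config = quick_config())
  }
  list(sim = .sim_env$sim, cal = .sim_env$cal)
}

shared_fit <- function() {
  sc <- shared_sim()
  if (is.null(.sim_env$fit)) {
    .sim_env$fit <- fit_specificity(sc$sim$X, sc$sim$Y, sc$sim$Z,
                                    config = quick_config(),
                                    calibration = sc$cal)
  }
  c(sc, list(fit = .sim_env$fit))
}
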
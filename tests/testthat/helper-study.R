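# shared fixtures, all generated in code

# minimal balanced design without technical replicates or missing histology
small_design <- function(n_control = 8, n_treated = 8, n_therapeutic = 0,
                         seed = 1L, ...) {
  study_design(n_control = n_control, n_treated = n_treated,
               n_therapeutic = n_therapeutic,
               tech_reps_control = 0, tech_reps_treated = 0,
               fibre_missing_treated = 0, fibre_missing_therapeutic = 0,
               seed = seed, ...)
}

# three-gene noise-only panel (all effects zero)
null_panel <- function(replicate_sd = 0.3) {
  dplyr::bind_rows(
    gene_spec("g1", baseline_cq = 22, replicate_sd = replicate_sd),
    gene_spec("g2", baseline_cq = 25, replicate_sd = replicate_sd),
    gene_spec("g3", baseline_cq = 28, replicate_sd = replicate_sd)
  )
}

# two well-separated Gaussian classes in p dimensions
separable_data <- function(n_per = 12, p = 5, delta = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = delta), n_per))
  rownames(x) <- sprintf("s%02d", seq_len(2 * n_per))
  colnames(x) <- sprintf("v%d", seq_len(p))
  list(x = x, classes = rep(c("control", "dex"), each = n_per))
}

# long Cq tibble from a wells-by-hand specification
cq_rows <- function(sample_id, target, cq, well = seq_along(cq),
                    class = "control", dilution = 1) {
  tibble::tibble(sample_id = sample_id, source_sample = sample_id,
                 class = class, target = target, well = well,
                 dilution = dilution, cq = cq)
}

# default-study pipeline products, computed once per test run
default_study_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      study <- generate_study(design = study_design(seed = 42))
      summ <- aggregate_replicates(study$cq_table)
      cache <<- list(study = study, summaries = summ)
    }
    cache
  }
})
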
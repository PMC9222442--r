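#' Gene panel specification
#'
#' A gene panel is a tibble with one row per qPCR target describing how that
#' target behaves in the synthetic study: its baseline quantification cycle
#' (Cq), the log2 fold-change planted in the illicitly treated class,
#' well-to-well technical noise, between-animal biological noise, the
#' probability of amplification failure (late Cq / no amplification, typical
#' of FFPE-degraded RNA), and an optional co-expression module membership.
#'
#' @param symbol Character, unique target identifier.
#' @param role `"biomarker"` or `"reference_candidate"`.
#' @param baseline_cq Baseline Cq in the control class (cycles, > 0;
#'   typically 18-33 for a preamplified FFPE assay).
#' @param log2_effect Planted log2 fold-change in the treated class.
#'   Positive = up-regulated (Cq drops by `log2_effect` cycles);
#'   negative = down-regulated. Reference candidates must stay within
#'   `stability_bound`.
#' @param replicate_sd Well-to-well Gaussian noise SD (cycles, >= 0).
#' @param sample_sd Between-animal biological noise SD (cycles, >= 0).
#' @param dropout_rate Probability in \[0, 1\] that a well fails to amplify
#'   below the Cq cutoff (the well is then drawn uniformly above the cutoff).
#' @param module Optional co-expression module label (`NA` = none).
#' @param module_loading Cycles of Cq shift per unit of the module's latent
#'   factor (shared across genes of a module; induces correlated structure).
#'
#' @return A one-row tibble (a panel fragment); bind rows to build a panel.
#' @seealso [default_panel()], [validate_panel()]
#' @export
gene_spec <- function(symbol, role = c("biomarker", "reference_candidate"),
                      baseline_cq, log2_effect = 0, replicate_sd = 0.6,
                      sample_sd = 0.25, dropout_rate = 0,
                      module = NA_character_, module_loading = 0) {
  role <- match.arg(role)
  tibble::tibble(
    symbol = as.character(symbol), role = role,
    baseline_cq = as.numeric(baseline_cq),
    log2_effect = as.numeric(log2_effect),
    replicate_sd = as.numeric(replicate_sd),
    sample_sd = as.numeric(sample_sd),
    dropout_rate = as.numeric(dropout_rate),
    module = as.character(module),
    module_loading = as.numeric(module_loading)
  )
}

#' Validate a gene panel
#'
#' @param panel Tibble of [gene_spec()] rows.
#' @param stability_bound Maximum |log2_effect| tolerated for reference
#'   candidates (a candidate planted with a larger class effect would not be
#'   a credible normaliser).
#' @return The panel, invisibly, after checks.
#' @export
validate_panel <- function(panel, stability_bound = 1) {
  stopifnot(is.data.frame(panel), nrow(panel) > 0)
  need <- c("symbol", "role", "baseline_cq", "log2_effect", "replicate_sd",
            "sample_sd", "dropout_rate", "module", "module_loading")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(panel$symbol)) {
    stop("duplicate gene symbols in panel: ",
         paste(unique(panel$symbol[duplicated(panel$symbol)]), collapse = ", "))
  }
  if (any(panel$baseline_cq <= 0)) stop("baseline_cq must be > 0")
  if (any(panel$dropout_rate < 0 | panel$dropout_rate > 1)) {
    stop("dropout_rate must lie in [0, 1]")
  }
  if (any(panel$replicate_sd < 0) || any(panel$sample_sd < 0)) {
    stop("noise SDs must be >= 0")
  }
  if (!all(panel$role %in% c("biomarker", "reference_candidate"))) {
    stop("role must be 'biomarker' or 'reference_candidate'")
  }
  ref <- panel$role == "reference_candidate"
  if (any(abs(panel$log2_effect[ref]) > stability_bound)) {
    stop("reference candidates must have |log2_effect| <= ", stability_bound)
  }
  invisible(panel)
}

#' Default 32-target synthetic panel
#'
#' Emulates a 32-target dexamethasone-exposure qPCR array: 28 transcriptional
#' biomarkers plus 4 reference-gene candidates (RPLP0, HSPA8, GAPDH, PPIA).
#' Twelve biomarkers carry a planted differential-expression effect
#' (8 up-regulated, 4 down-regulated in the treated class); the remaining 16
#' are null. Four low-expression targets (OXT, GALNT9, FSIP1, GAD1) sit near
#' the 32-cycle cutoff with a nonzero dropout rate, emulating the late-Cq /
#' no-amplification behaviour of degraded FFPE RNA. RPLP0 and HSPA8 are
#' planted as the most stable pair (no class effect, low biological noise);
#' GAPDH and PPIA carry small residual class effects so that stability
#' ranking has something to reject. Biomarkers are grouped into four
#' co-expression modules (myogenic, immune, stress, metabolic) sharing a
#' per-animal latent factor, which gives the feature matrix the strongly
#' correlated structure real expression panels show.
#'
#' @return A 32-row panel tibble.
#' @export
default_panel <- function() {
  p <- dplyr::bind_rows(
    # reference candidates ---------------------------------------------------
    gene_spec("RPLP0", "reference_candidate", 19.0, 0, 0.35, 0.10),
    gene_spec("HSPA8", "reference_candidate", 20.5, 0, 0.35, 0.10),
    gene_spec("GAPDH", "reference_candidate", 18.5, -0.7, 0.45, 0.30),
    gene_spec("PPIA",  "reference_candidate", 19.5, -0.6, 0.45, 0.30),
    # planted DE biomarkers: up-regulated in treated --------------------------
    gene_spec("MYF6",   baseline_cq = 24.0, log2_effect = 2.0,
              module = "myogenic", module_loading = 0.6),
    gene_spec("MYOG",   baseline_cq = 25.5, log2_effect = 1.8,
              module = "myogenic", module_loading = 0.6),
    gene_spec("MMP2",   baseline_cq = 23.0, log2_effect = 1.6,
              module = "stress", module_loading = 0.6),
    gene_spec("C1QA",   baseline_cq = 24.5, log2_effect = 2.2,
              module = "immune", module_loading = 0.6),
    gene_spec("CCDC80", baseline_cq = 25.0, log2_effect = 1.5,
              module = "stress", module_loading = 0.6),
    gene_spec("MYOC",   baseline_cq = 26.5, log2_effect = 1.7,
              module = "stress", module_loading = 0.6),
    gene_spec("GALNT9", baseline_cq = 30.5, log2_effect = 1.8,
              replicate_sd = 0.8, dropout_rate = 0.15,
              module = "metabolic", module_loading = 0.6),
    gene_spec("GAD1",   baseline_cq = 30.8, log2_effect = 1.8,
              replicate_sd = 0.8, dropout_rate = 0.15,
              module = "metabolic", module_loading = 0.6),
    # planted DE biomarkers: down-regulated in treated ------------------------
    gene_spec("FKBP5",  baseline_cq = 22.0, log2_effect = -2.0,
              module = "stress", module_loading = 0.6),
    gene_spec("RASD1",  baseline_cq = 24.0, log2_effect = -1.8,
              module = "stress", module_loading = 0.6),
    gene_spec("MT2A",   baseline_cq = 21.0, log2_effect = -2.2,
              module = "metabolic", module_loading = 0.6),
    gene_spec("CYP1A1", baseline_cq = 27.0, log2_effect = -1.6,
              module = "metabolic", module_loading = 0.6),
    # null biomarkers ----------------------------------------------------------
    gene_spec("FGL2",    baseline_cq = 23.5, module = "immune",    module_loading = 0.6),
    gene_spec("TBP",     baseline_cq = 25.0, module = "metabolic", module_loading = 0.6),
    gene_spec("C7",      baseline_cq = 26.0, module = "immune",    module_loading = 0.6),
    gene_spec("CRISPLD2", baseline_cq = 24.0, module = "stress",   module_loading = 0.6),
    gene_spec("SULT1A1", baseline_cq = 25.5, module = "metabolic", module_loading = 0.6),
    gene_spec("CCL24",   baseline_cq = 27.5, module = "immune",    module_loading = 0.6),
    gene_spec("PFKFB4",  baseline_cq = 26.0, module = "metabolic", module_loading = 0.6),
    gene_spec("MEDAG",   baseline_cq = 25.0, module = "stress",    module_loading = 0.6),
    gene_spec("IGF1",    baseline_cq = 22.5, module = "myogenic",  module_loading = 0.6),
    gene_spec("MYH1",    baseline_cq = 18.0, module = "myogenic",  module_loading = 0.6),
    gene_spec("MYOD1",   baseline_cq = 24.5, module = "myogenic",  module_loading = 0.6),
    gene_spec("MYF5",    baseline_cq = 25.5, module = "myogenic",  module_loading = 0.6),
    gene_spec("NR4A2",   baseline_cq = 27.0, module = "stress",    module_loading = 0.6),
    gene_spec("LIPG",    baseline_cq = 28.0, module = "metabolic", module_loading = 0.6),
    # low-expression null targets near the cutoff ------------------------------
    gene_spec("OXT",  baseline_cq = 31.0, replicate_sd = 0.8, dropout_rate = 0.2),
    gene_spec("FSIP1", baseline_cq = 31.2, replicate_sd = 0.8, dropout_rate = 0.2)
  )
  validate_panel(p)
  p
}

#' Planted differentially expressed genes of a panel
#'
#' @param panel A panel tibble.
#' @return Character vector of biomarker symbols with nonzero planted effect.
#' @export
planted_de_genes <- function(panel) {
  panel$symbol[panel$role == "biomarker" & panel$log2_effect != 0]
}

#' Study design for the synthetic generator
#'
#' Defaults reproduce the structure of the emulated animal trial: 12 control
#' and 23 illicitly treated animals with complete expression profiles, plus
#' 2 animals given a therapeutic dexamethasone dose (kept out of model
#' fitting, used for external prediction), triplicate wells per target,
#' 25 measured fibre diameters per sample, and 15 technical replicate
#' profiles (3 control + 12 treated) re-run at a tenfold cDNA dilution,
#' giving 52 expression profiles in total. Fibre morphometry is available
#' for all controls but only 22/23 treated and 1/2 therapeutic animals, so
#' the fused expression+histology dataset is smaller than the expression
#' dataset, as happens when not every paraffin block yields well-oriented
#' fibres.
#'
#' @param n_control,n_treated,n_therapeutic Animal counts per class.
#' @param wells_per_target Wells per (sample, target); default 3 (triplicate).
#' @param dilution_levels Dilution factors used for technical replicate
#'   profiles (a factor d shifts every Cq by +log2(d) cycles).
#' @param tech_reps_control,tech_reps_treated Number of technical replicate
#'   profiles drawn (at random, seeded) from each class.
#' @param fibres_per_sample Fibre diameters measured per sample.
#' @param fibre_missing_treated,fibre_missing_therapeutic Number of animals
#'   per class without usable fibre measurements.
#' @param seed Integer seed; fixes every random draw of the generator.
#' @return A `study_design` list.
#' @export
study_design <- function(n_control = 12, n_treated = 23, n_therapeutic = 2,
                         wells_per_target = 3, dilution_levels = 10,
                         tech_reps_control = 3, tech_reps_treated = 12,
                         fibres_per_sample = 25,
                         fibre_missing_treated = 1,
                         fibre_missing_therapeutic = 1,
                         seed = 1L) {
  d <- list(n_control = n_control, n_treated = n_treated,
            n_therapeutic = n_therapeutic,
            wells_per_target = wells_per_target,
            dilution_levels = dilution_levels,
            tech_reps_control = tech_reps_control,
            tech_reps_treated = tech_reps_treated,
            fibres_per_sample = fibres_per_sample,
            fibre_missing_treated = fibre_missing_treated,
            fibre_missing_therapeutic = fibre_missing_therapeutic,
            seed = as.integer(seed))
  counts <- unlist(d[c("n_control", "n_treated", "n_therapeutic",
                       "tech_reps_control", "tech_reps_treated",
                       "fibres_per_sample", "fibre_missing_treated",
                       "fibre_missing_therapeutic")])
  if (any(counts < 0)) stop("design counts must be >= 0")
  if (wells_per_target < 1) stop("wells_per_target must be >= 1")
  if (any(dilution_levels <= 0)) stop("dilution factors must be > 0")
  if (tech_reps_control > 0 && n_control == 0) {
    stop("cannot draw technical replicates from an empty control class")
  }
  class(d) <- "study_design"
  d
}
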
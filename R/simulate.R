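#' Generate a synthetic Cq table
#'
#' Simulates raw per-well quantification cycles for a qPCR panel run on an
#' FFPE study. The Cq of gene g in animal s is
#' `baseline + shift_s + biology_gs + module_gs - effect_g * treated_s`,
#' measured in each well with Gaussian replicate noise, where `shift_s` is a
#' per-sample global offset (RNA input / preamplification efficiency; it
#' cancels under reference-gene normalisation), `biology_gs` is gene-level
#' between-animal noise, and `module_gs` couples genes of a co-expression
#' module through a shared per-animal latent factor. Down-regulation
#' (negative `log2_effect`) raises Cq. With probability `dropout_rate` a
#' well fails and its Cq is drawn uniformly on (`cutoff`, `max_cycles`), so
#' the downstream cutoff filter is what removes it. Technical replicate
#' profiles re-measure a seeded random subset of animals at a cDNA dilution
#' d, adding `log2(d)` cycles (100% efficiency) plus fresh well noise.
#'
#' Therapeutic-dose animals are drawn from the control distribution (no
#' planted effect): the emulated study observed such samples to behave like
#' controls and used them only for external prediction.
#'
#' @param genes Panel tibble (see [gene_spec()]); validated on entry.
#' @param design A [study_design()].
#' @param cq_cutoff Cutoff above which a failed well is drawn (cycles).
#' @param sample_shift_sd SD of the per-sample global Cq offset (cycles).
#' @param response_sd SD of the per-animal treatment-response multiplier
#'   (treated animals scale every planted `log2_effect` by
#'   `max(0, N(1, response_sd))`: individual drug response varies, so some
#'   treated animals look nearly untreated — the hard-to-classify cases a
#'   residue-screening study has to live with).
#' @param max_cycles Instrument limit for failed wells.
#' @return Long tibble with columns `sample_id`, `source_sample`, `class`,
#'   `target`, `well`, `dilution`, `cq`. `sample_id` identifies a profile
#'   (technical replicates get their own id); `source_sample` the animal.
#' @export
generate_cq_dataset <- function(genes, design, cq_cutoff = 32,
                                sample_shift_sd = 0.4, response_sd = 0.35,
                                max_cycles = 40) {
  validate_panel(genes)
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  sim_cq(genes, design, cq_cutoff, sample_shift_sd, response_sd, max_cycles)
}

# internal: assumes RNG state already seeded
sim_cq <- function(genes, design, cq_cutoff, sample_shift_sd, response_sd,
                   max_cycles) {
  animals <- animal_frame(design)
  n_anim <- nrow(animals)
  ngene <- nrow(genes)

  # per-animal latent structure (shared by all profiles of an animal)
  shift <- stats::rnorm(n_anim, 0, sample_shift_sd)
  modules <- unique(stats::na.omit(genes$module))
  factors <- matrix(stats::rnorm(n_anim * length(modules)),
                    nrow = n_anim, dimnames = list(NULL, modules))
  biology <- matrix(stats::rnorm(n_anim * ngene, 0,
                                 rep(genes$sample_sd, each = n_anim)),
                    nrow = n_anim)

  # expected Cq per (animal, gene), before dilution and well noise
  treated <- as.numeric(animals$class == "dex")
  response <- treated * pmax(stats::rnorm(n_anim, 1, response_sd), 0)
  mu <- outer(rep(1, n_anim), genes$baseline_cq) +
    shift - outer(response, genes$log2_effect) + biology
  for (m in modules) {
    in_m <- which(!is.na(genes$module) & genes$module == m)
    mu[, in_m] <- mu[, in_m] +
      factors[, m] %o% genes$module_loading[in_m]
  }

  profiles <- profile_frame(animals, design)
  idx <- match(profiles$source_sample, animals$sample_id)
  W <- design$wells_per_target

  out <- vector("list", nrow(profiles))
  for (p in seq_len(nrow(profiles))) {
    base <- mu[idx[p], ] + log2(profiles$dilution[p])
    cq <- rep(base, each = W) +
      stats::rnorm(ngene * W, 0, rep(genes$replicate_sd, each = W))
    drop <- stats::runif(ngene * W) < rep(genes$dropout_rate, each = W)
    cq[drop] <- stats::runif(sum(drop), cq_cutoff, max_cycles)
    out[[p]] <- tibble::tibble(
      sample_id = profiles$sample_id[p],
      source_sample = profiles$source_sample[p],
      class = profiles$class[p],
      target = rep(genes$symbol, each = W),
      well = rep(seq_len(W), times = ngene),
      dilution = profiles$dilution[p],
      cq = round(cq, 4)
    )
  }
  dplyr::bind_rows(out)
}

animal_frame <- function(design) {
  tibble::tibble(
    sample_id = c(sprintf("CTRL%02d", seq_len(design$n_control)),
                  sprintf("DEX%02d", seq_len(design$n_treated)),
                  sprintf("THER%02d", seq_len(design$n_therapeutic))),
    class = rep(c("control", "dex", "therapeutic"),
                c(design$n_control, design$n_treated, design$n_therapeutic))
  )
}

# base profiles (dilution 1) plus seeded random technical replicates
profile_frame <- function(animals, design) {
  base <- tibble::tibble(sample_id = animals$sample_id,
                         source_sample = animals$sample_id,
                         class = animals$class, dilution = 1)
  reps <- list()
  pick <- function(class, k) {
    ids <- animals$sample_id[animals$class == class]
    if (k > length(ids)) stop("more technical replicates than ", class,
                              " animals")
    sample(ids, k)
  }
  chosen <- c(if (design$tech_reps_control > 0)
                pick("control", design$tech_reps_control),
              if (design$tech_reps_treated > 0)
                pick("dex", design$tech_reps_treated))
  if (length(chosen) > 0) {
    dil <- rep_len(design$dilution_levels, length(chosen))
    reps <- tibble::tibble(
      sample_id = sprintf("%s_d%gr%d", chosen, dil, seq_along(chosen)),
      source_sample = chosen,
      class = animals$class[match(chosen, animals$sample_id)],
      dilution = dil
    )
    base <- dplyr::bind_rows(base, reps)
  }
  base
}

#' Generate synthetic fibre-diameter measurements
#'
#' Two-level lognormal model: each animal gets a sample-level mean diameter
#' drawn from a lognormal with the group mean and between-sample SD `sd`
#' (moment-matched), and its measured diameters scatter lognormally around
#' that mean with within-sample SD `within_sd`. The between/within split
#' matters: group comparisons run on per-sample means, whose spread is
#' dominated by `sd`. Therapeutic animals are drawn from the control
#' distribution. Diameters are always positive.
#'
#' @param design A [study_design()].
#' @param control_mean,treated_mean Group mean fibre diameter (um).
#' @param sd Between-sample SD of per-sample mean diameters (um).
#' @param within_sd Within-sample SD of individual fibres (um).
#' @return Tibble with columns `sample_id`, `class`, `fibre_index`,
#'   `diameter_um`, covering the animals with usable fibre data.
#' @export
generate_fibre_data <- function(design, control_mean = 44.6,
                                treated_mean = 40.5, sd = 8, within_sd = 5) {
  stopifnot(inherits(design, "study_design"))
  if (control_mean <= 0 || treated_mean <= 0) stop("means must be > 0")
  if (sd < 0 || within_sd < 0) stop("SDs must be >= 0")
  set.seed(design$seed + 1L)
  sim_fibres(design, control_mean, treated_mean, sd, within_sd)
}

sim_fibres <- function(design, control_mean, treated_mean, sd, within_sd) {
  animals <- animal_frame(design)
  # drop seeded random animals without usable histology
  drop <- c(
    if (design$fibre_missing_treated > 0)
      sample(animals$sample_id[animals$class == "dex"],
             design$fibre_missing_treated),
    if (design$fibre_missing_therapeutic > 0)
      sample(animals$sample_id[animals$class == "therapeutic"],
             design$fibre_missing_therapeutic)
  )
  animals <- animals[!animals$sample_id %in% drop, , drop = FALSE]
  gmean <- ifelse(animals$class == "dex", treated_mean, control_mean)
  sample_mu <- rlnorm_ms(nrow(animals), gmean, sd)
  k <- design$fibres_per_sample
  diam <- rlnorm_ms(nrow(animals) * k, rep(sample_mu, each = k), within_sd)
  tibble::tibble(
    sample_id = rep(animals$sample_id, each = k),
    class = rep(animals$class, each = k),
    fibre_index = rep(seq_len(k), times = nrow(animals)),
    diameter_um = round(diam, 3)
  )
}

# lognormal draws parameterised by arithmetic mean and SD; degenerates to
# the mean exactly when sd = 0
rlnorm_ms <- function(n, mean, sd) {
  if (all(sd == 0)) return(rep_len(mean, n))
  sigma2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Generate a complete synthetic study
#'
#' Bundles the Cq table, fibre-diameter table, per-sample metadata and the
#' ground-truth panel into one object, using seeds derived from
#' `design$seed` so the whole study is reproducible. The default panel
#' plants 12 truly differential biomarkers among 28 and two stable
#' reference candidates (RPLP0, HSPA8) among four, so recovery of both is
#' testable downstream.
#'
#' @param panel Panel tibble; defaults to [default_panel()].
#' @param design A [study_design()]; defaults to [study_design()].
#' @param cq_cutoff,sample_shift_sd,response_sd Passed to
#'   [generate_cq_dataset()].
#' @param fibre_params List with `control_mean`, `treated_mean`, `sd`,
#'   `within_sd` for [generate_fibre_data()].
#' @return A `synthetic_study` list with elements `cq_table`, `fibre_table`,
#'   `metadata` (one row per expression profile), `truth` (the panel) and
#'   `design`.
#' @export
generate_study <- function(panel = default_panel(), design = study_design(),
                           cq_cutoff = 32, sample_shift_sd = 0.4,
                           response_sd = 0.35, fibre_params = list()) {
  validate_panel(panel)
  stopifnot(inherits(design, "study_design"))
  fp <- utils::modifyList(list(control_mean = 44.6, treated_mean = 40.5,
                               sd = 8, within_sd = 5), fibre_params)
  cq <- generate_cq_dataset(panel, design, cq_cutoff = cq_cutoff,
                            sample_shift_sd = sample_shift_sd,
                            response_sd = response_sd)
  fib <- generate_fibre_data(design, fp$control_mean, fp$treated_mean,
                             fp$sd, fp$within_sd)
  meta <- dplyr::distinct(cq, .data$sample_id, .data$source_sample,
                          .data$class, .data$dilution)
  if (!all(fib$sample_id %in% meta$source_sample)) {
    stop("fibre table contains samples absent from the Cq table")
  }
  structure(list(cq_table = cq, fibre_table = fib, metadata = meta,
                 truth = panel, design = design),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic qPCR study\n")
  cat(sprintf("  %d expression profiles (%d animals) x %d targets, %d wells each\n",
              nrow(x$metadata), length(unique(x$metadata$source_sample)),
              length(unique(x$cq_table$target)), x$design$wells_per_target))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$metadata$class)),
                            table(x$metadata$class)), collapse = ", ")))
  cat(sprintf("  fibre data: %d samples x %d diameters\n",
              length(unique(x$fibre_table$sample_id)),
              x$design$fibres_per_sample))
  invisible(x)
}
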
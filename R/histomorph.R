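#' Summarise fibre-diameter morphometry
#'
#' Computes per-sample descriptive statistics of the measured fibre
#' diameters, group-level descriptives over the per-sample means (the
#' experimental unit is the animal, not the fibre), a Shapiro-Wilk
#' normality check per group, and an unpaired two-sample t test between the
#' two requested groups on per-sample mean diameters.
#'
#' @param fibres Tibble with `sample_id`, `diameter_um` and a class label
#'   column `class` (or supply `classes`).
#' @param classes Optional named vector `sample_id -> class`.
#' @param groups The two groups compared (default dex vs control; other
#'   groups are summarised but not tested).
#' @param var_equal Student t (TRUE, default) or Welch t (FALSE).
#' @return List with `per_sample` (tibble: sample_id, class, n, mean, sd,
#'   median, min, max), `per_group` (tibble: class, n samples, mean, sd,
#'   sem, min, median, max of per-sample means, shapiro_w, shapiro_p) and
#'   `test` (tibble: groups, t, df, p_value, method).
#' @export
summarize_fibres <- function(fibres, classes = NULL,
                             groups = c("dex", "control"),
                             var_equal = TRUE) {
  stopifnot(is.data.frame(fibres), all(c("sample_id", "diameter_um") %in%
                                         names(fibres)))
  if (any(fibres$diameter_um <= 0, na.rm = TRUE)) {
    stop("fibre diameters must be > 0")
  }
  if (is.null(classes)) {
    if (!"class" %in% names(fibres)) stop("need a class column or `classes`")
  } else {
    fibres$class <- unname(classes[fibres$sample_id])
  }
  empty <- tapply(!is.na(fibres$diameter_um), fibres$sample_id, sum) == 0
  if (any(empty)) {
    warning("skipping sample(s) with no diameters: ",
            paste(names(empty)[empty], collapse = ", "))
    fibres <- fibres[!fibres$sample_id %in% names(empty)[empty], ]
  }

  per_sample <- fibres |>
    dplyr::filter(!is.na(.data$diameter_um)) |>
    dplyr::group_by(.data$sample_id, .data$class) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$diameter_um),
                     sd = stats::sd(.data$diameter_um),
                     median = stats::median(.data$diameter_um),
                     min = min(.data$diameter_um),
                     max = max(.data$diameter_um), .groups = "drop")

  per_group <- per_sample |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(n = dplyr::n(),
                     group_mean = mean(.data$mean),
                     group_sd = stats::sd(.data$mean),
                     group_sem = stats::sd(.data$mean) / sqrt(dplyr::n()),
                     group_min = min(.data$mean),
                     group_median = stats::median(.data$mean),
                     group_max = max(.data$mean),
                     shapiro_w = shapiro_or_na(.data$mean)["w"],
                     shapiro_p = shapiro_or_na(.data$mean)["p"],
                     .groups = "drop")

  x <- per_sample$mean[per_sample$class == groups[1]]
  y <- per_sample$mean[per_sample$class == groups[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop("each tested group needs >= 2 samples")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  test <- tibble::tibble(group1 = groups[1], group2 = groups[2],
                         t = unname(tt$statistic),
                         df = unname(tt$parameter),
                         p_value = tt$p.value, method = tt$method)
  list(per_sample = per_sample, per_group = per_group, test = test)
}

shapiro_or_na <- function(x) {
  if (length(x) < 3 || stats::sd(x) == 0) return(c(w = NA_real_, p = NA_real_))
  s <- stats::shapiro.test(x)
  c(w = unname(s$statistic), p = s$p.value)
}

#' Fuse expression profiles with morphometry summaries
#'
#' Restricts to samples present in both inputs and appends three histology
#' columns — per-sample fibre mean, median and SD — to the expression
#' feature matrix (30 expression + 3 histology = 33 variables for the
#' default panel). Profiles without morphometry (e.g. technical replicate
#' profiles, or animals without well-oriented fibres) are dropped and
#' reported, which is why the fused dataset is smaller than the
#' expression-only one.
#'
#' @param rq Samples x variables expression matrix (rownames = sample ids).
#' @param morpho `summarize_fibres()` output (or its `per_sample` tibble).
#' @return List with `matrix` (fused, complete), `dropped` (sample ids of
#'   profiles lacking morphometry).
#' @export
fuse_datasets <- function(rq, morpho) {
  if (is.list(morpho) && !is.data.frame(morpho)) morpho <- morpho$per_sample
  stopifnot(is.matrix(rq))
  if (nrow(rq) == 0 || ncol(rq) == 0) stop("expression matrix is empty")
  common <- intersect(rownames(rq), morpho$sample_id)
  if (length(common) == 0) stop("no overlapping samples between datasets")
  dropped <- setdiff(rownames(rq), common)
  idx <- match(common, morpho$sample_id)
  fused <- cbind(rq[common, , drop = FALSE],
                 fibre_mean = morpho$mean[idx],
                 fibre_median = morpho$median[idx],
                 fibre_sd = morpho$sd[idx])
  if (anyNA(fused)) stop("fused matrix contains missing values")
  list(matrix = fused, dropped = dropped)
}
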
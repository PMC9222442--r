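#' Aggregate qPCR replicate wells
#'
#' Filters and summarises raw wells into one Cq per (sample, target).
#' Processing order per replicate group: (1) wells with missing Cq or
#' `cq > cutoff` are excluded (late Cq / no amplification; for preamplified
#' FFPE cDNA the supplier-recommended cutoff is 32 cycles); (2) among the
#' surviving wells, any well deviating from the group median by more than
#' `outlier_limit` cycles is flagged as an outlier and excluded; (3) mean
#' and SD are computed over the survivors. Groups with no surviving well
#' are reported with `n_valid = 0` and a missing mean.
#'
#' @param table Long Cq tibble (`sample_id`, `target`, `well`, `cq`, plus
#'   any annotation columns, e.g. `class`, `dilution`, which are carried
#'   through).
#' @param cutoff Cq cutoff in cycles (> 0).
#' @param outlier_limit Maximum tolerated absolute deviation from the
#'   replicate median (cycles).
#' @return Tibble with one row per (sample, target): `mean_cq`, `sd_cq`,
#'   `n_valid`, `n_cutoff` (wells lost to the cutoff/missing), `n_outlier`
#'   (wells lost to the median rule).
#' @export
aggregate_replicates <- function(table, cutoff = 32, outlier_limit = 0.5) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (outlier_limit < 0) stop("outlier_limit must be >= 0")
  need <- c("sample_id", "target", "well", "cq")
  if (!all(need %in% names(table))) {
    stop("Cq table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(table[, c("sample_id", "target", "well")])) {
    stop("duplicate (sample_id, target, well) rows in Cq table")
  }
  anno <- intersect(c("class", "source_sample", "dilution"), names(table))

  key <- paste(table$sample_id, table$target, sep = "\r")
  first <- !duplicated(key)
  gi <- match(key, key[first])
  n_grp <- sum(first)
  cq <- table$cq

  ok <- !is.na(cq) & cq <= cutoff
  med <- rep(NA_real_, n_grp)
  med_by <- vapply(split(cq[ok], gi[ok]), stats::median, numeric(1))
  med[as.integer(names(med_by))] <- med_by
  survives <- ok & abs(cq - med[gi]) <= outlier_limit

  n_valid <- tabulate(gi[survives], n_grp)
  sum_cq <- rowsum_vec(cq * survives, gi, n_grp)
  mean_cq <- ifelse(n_valid > 0, sum_cq / n_valid, NA_real_)
  dev2 <- (cq - ifelse(is.na(mean_cq[gi]), 0, mean_cq[gi]))^2
  ss <- rowsum_vec(dev2 * survives, gi, n_grp)
  sd_cq <- ifelse(n_valid > 1, sqrt(ss / (n_valid - 1)),
                  ifelse(n_valid == 1, 0, NA_real_))

  out <- tibble::as_tibble(table[first, c("sample_id", anno, "target")])
  out$mean_cq <- mean_cq
  out$sd_cq <- sd_cq
  out$n_valid <- n_valid
  out$n_cutoff <- tabulate(gi[!ok], n_grp)
  out$n_outlier <- tabulate(gi[ok & !survives], n_grp)
  out
}

# sum of x per group index (1..n_grp), zeros for empty groups
rowsum_vec <- function(x, gi, n_grp) {
  out <- numeric(n_grp)
  s <- rowsum(x, gi)
  out[as.integer(rownames(s))] <- s
  out
}

#' Cq summaries as a sample-by-gene matrix
#'
#' @param summaries Output of [aggregate_replicates()].
#' @return Numeric matrix of mean Cq (samples x targets), `NA` where the
#'   replicate group had no valid well.
#' @export
cq_matrix <- function(summaries) {
  wide <- tidyr::pivot_wider(summaries[, c("sample_id", "target", "mean_cq")],
                             names_from = "target", values_from = "mean_cq")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sample_id
  m
}
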
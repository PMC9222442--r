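#' Read a long-format Cq table from CSV
#'
#' Expected columns: `sample_id`, `class`, `target`, `well`, `dilution`,
#' `cq`, optionally `source_sample` (defaults to `sample_id`). A Cq of
#' `NA` (or empty) is a missing well. Unknown columns, non-numeric Cq
#' values and duplicate (sample_id, target, well) rows are rejected with
#' the offending line numbers.
#'
#' @param path CSV file path.
#' @return Cq tibble as produced by [generate_cq_dataset()].
#' @export
read_cq_csv <- function(path) {
  if (!file.exists(path)) stop("Cq table not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("sample_id", "class", "target", "well", "dilution", "cq")
  known <- c(required, "source_sample")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  }
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  }
  if (!"source_sample" %in% names(raw)) raw$source_sample <- raw$sample_id
  num <- function(col, name, allow_na = FALSE) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !(allow_na & (is.na(col) | col == "NA")))
    if (length(bad) > 0) {
      stop("non-numeric ", name, " in ", path, " at data line(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    v
  }
  out <- tibble::tibble(
    sample_id = raw$sample_id, source_sample = raw$source_sample,
    class = raw$class, target = raw$target,
    well = as.integer(num(raw$well, "well")),
    dilution = num(raw$dilution, "dilution"),
    cq = num(raw$cq, "cq", allow_na = TRUE)
  )
  dup <- duplicated(out[, c("sample_id", "target", "well")])
  if (any(dup)) {
    stop("duplicate (sample_id, target, well) in ", path,
         " at data line(s): ", paste(utils::head(which(dup), 5), collapse = ", "))
  }
  out
}

#' Read fibre-diameter measurements from CSV
#'
#' Expected columns: `sample_id`, `fibre_index`, `diameter_um`, optionally
#' `class`.
#'
#' @param path CSV file path.
#' @return Fibre tibble as produced by [generate_fibre_data()].
#' @export
read_fibres_csv <- function(path) {
  if (!file.exists(path)) stop("fibre table not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("sample_id", "fibre_index", "diameter_um")
  known <- c(required, "class")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  }
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  }
  d <- suppressWarnings(as.numeric(raw$diameter_um))
  bad <- which(is.na(d) & !is.na(raw$diameter_um))
  if (length(bad) > 0) {
    stop("non-numeric diameter_um in ", path, " at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- tibble::tibble(sample_id = raw$sample_id,
                        fibre_index = as.integer(raw$fibre_index),
                        diameter_um = d)
  if ("class" %in% names(raw)) out$class <- raw$class
  out
}

#' Write / read a samples-by-variables matrix as CSV
#'
#' Round-trip identity: `read_matrix_csv(write_matrix_csv(m, p))` restores
#' the matrix, dimnames and values, to full precision.
#'
#' @param m Numeric matrix with sample rownames.
#' @param path Destination CSV.
#' @return `path`, invisibly (writer); the matrix (reader).
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(is.matrix(m))
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- readr::read_csv(path, col_types = readr::cols(
    sample_id = "c", .default = "d"), progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$sample_id
  m
}

#' Write a synthetic study to a directory
#'
#' Serialises the Cq table, fibre table and metadata of a
#' [generate_study()] result as plain CSV files.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_study_csv <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(cq = file.path(dir, "cq_table.csv"),
             fibres = file.path(dir, "fibre_table.csv"),
             metadata = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "panel_truth.csv"))
  readr::write_csv(study$cq_table, paths["cq"])
  readr::write_csv(study$fibre_table, paths["fibres"])
  readr::write_csv(study$metadata, paths["metadata"])
  readr::write_csv(study$truth, paths["truth"])
  invisible(paths)
}
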
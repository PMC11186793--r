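#' Construct a single-view sample-by-feature matrix
#'
#' A view is one data modality (a cell-type cluster's pseudobulk expression,
#' cytokines, plasma proteomics, ...) measured on a shared sample universe.
#' Values are stored as a dense numeric matrix with `NA` for entries that were
#' not measured; out-of-range ("OOR") cytokine readings are tracked in a
#' separate logical mask so that "missing", "OOR" and literal zero stay
#' distinct until the view-specific preprocessing decides what to do with them.
#'
#' @param values Numeric matrix, samples in rows, features in columns. Row and
#'   column names are required and become sample and feature ids.
#' @param view_name Single string naming the view.
#' @param oor Optional logical matrix of the same shape flagging out-of-range
#'   entries (their `values` must be `NA`).
#' @param mask Optional named logical vector marking which samples were
#'   assayed in this view. Defaults to all present.
#' @return An object of class `ifa_view`.
#' @export
view_matrix <- function(values, view_name, oor = NULL, mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (nrow(values) > 0 && is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry sample ids (rownames) and feature ids (colnames)")
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  stop_if_duplicated(rownames(values), sprintf("sample ids in view '%s'", view_name))
  stop_if_duplicated(colnames(values), sprintf("feature ids in view '%s'", view_name))
  if (is.null(oor)) {
    oor <- matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  stopifnot(identical(dim(oor), dim(values)))
  if (any(oor & !is.na(values))) {
    abort("entries flagged OOR must have NA values until substitution")
  }
  if (is.null(mask)) {
    mask <- setNames(rep(TRUE, nrow(values)), rownames(values))
  }
  structure(
    list(view_name = view_name, values = values, oor = oor,
         sample_ids = rownames(values), feature_ids = colnames(values),
         mask = mask),
    class = "ifa_view"
  )
}

#' @export
print.ifa_view <- function(x, ...) {
  cat(sprintf("<ifa_view '%s'> %d samples x %d features (%d present, %d OOR cells)\n",
              x$view_name, nrow(x$values), ncol(x$values), sum(x$mask), sum(x$oor)))
  invisible(x)
}

#' @export
dim.ifa_view <- function(x) dim(x$values)

#' Read a view table from TSV
#'
#' Expects a tab-delimited UTF-8 file with a header row of feature ids and the
#' sample id in the first column. Empty cells are parsed as missing and the
#' literal token `OOR` is preserved as an out-of-range sentinel (not zero, not
#' missing): the substitution mandated for cytokines happens later, in
#' [preprocess_cytokines()]. Any other cell that does not parse as a number is
#' a hard error naming the offending row and column.
#'
#' @param path Path to the TSV file.
#' @param view_name Name to give the view.
#' @return An `ifa_view`.
#' @export
read_view_table <- function(path, view_name) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character(), name_repair = "minimal")
  if (ncol(tab) < 2) abort(sprintf("view table '%s' has no feature columns", path))
  sample_ids <- tab[[1]]
  stop_if_duplicated(sample_ids, "sample ids")
  stop_if_duplicated(names(tab)[-1], "feature ids")
  raw <- as.matrix(tab[, -1, drop = FALSE])
  oor <- raw == "OOR"
  missing <- raw == ""
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals) & !oor & !missing, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                  sample_ids[bad[1, 1]], colnames(raw)[bad[1, 2]], path))
  }
  vals[oor | missing] <- NA_real_
  dimnames(vals) <- list(sample_ids, colnames(raw))
  dimnames(oor) <- dimnames(vals)
  view_matrix(vals, view_name, oor = oor)
}

#' Write a view table to TSV
#'
#' Inverse of [read_view_table()]: missing entries become empty cells and
#' out-of-range entries the literal token `OOR`. Numbers are written with full
#' precision (`%.15g`) so a write/read round trip is bit-identical.
#'
#' @param view An `ifa_view`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_view_table <- function(view, path) {
  vals <- view$values
  chr <- array(sprintf("%.15g", vals), dim = dim(vals))
  chr[is.na(vals)] <- ""
  chr[view$oor] <- "OOR"
  out <- cbind(sample_id = view$sample_ids, chr)
  colnames(out) <- c("sample_id", view$feature_ids)
  readr::write_tsv(as.data.frame(out), path, progress = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Metadata carries one row per sample: `sample_id`, `patient_id`,
#' `timepoint`, `group`, `delta_EF` (change in ejection fraction, may be
#' missing for controls). `(patient_id, timepoint)` must be unique.
#'
#' @param path TSV path.
#' @param timepoint_levels Ordered timepoint labels; defaults to
#'   `TP0 < TP1 < TP2 < TP3 < TP4`.
#' @return A tibble.
#' @export
read_sample_meta <- function(path, timepoint_levels = c("TP0", "TP1", "TP2", "TP3", "TP4")) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), patient_id = readr::col_character(),
    timepoint = readr::col_character(), group = readr::col_character(),
    delta_EF = readr::col_double()), progress = FALSE)
  validate_sample_meta(meta, timepoint_levels)
}

validate_sample_meta <- function(meta, timepoint_levels = NULL) {
  if (is.null(timepoint_levels)) {
    timepoint_levels <- if (is.factor(meta$timepoint)) levels(meta$timepoint) else c("TP0", "TP1", "TP2", "TP3", "TP4")
  }
  need <- c("sample_id", "patient_id", "timepoint", "group")
  if (!all(need %in% names(meta))) {
    abort(sprintf("metadata lacks columns: %s", paste(setdiff(need, names(meta)), collapse = ", ")))
  }
  stop_if_duplicated(meta$sample_id, "sample ids in metadata")
  stop_if_duplicated(paste(meta$patient_id, meta$timepoint), "(patient, timepoint) pairs")
  bad_tp <- setdiff(unique(meta$timepoint), timepoint_levels)
  if (length(bad_tp)) abort(sprintf("unknown timepoints: %s", paste(bad_tp, collapse = ", ")))
  meta$timepoint <- factor(meta$timepoint, levels = timepoint_levels, ordered = TRUE)
  if (!"delta_EF" %in% names(meta)) meta$delta_EF <- NA_real_
  tibble::as_tibble(meta)
}

#' Align views on a common sample universe
#'
#' The sample universe is the union of samples over all views; every sample
#' must be described in `meta`. Per view, a presence mask records which
#' universe samples were assayed; absent samples carry `NA` rows. Samples are
#' put in a canonical order (patient, then timepoint) so factor matrices are
#' comparable across runs.
#'
#' @param views A list of `ifa_view` objects (any sample order).
#' @param meta Sample metadata (see [read_sample_meta()]).
#' @return An object of class `ifa_dataset` with elements `views` (aligned
#'   `ifa_view`s) and `meta` (tibble restricted to the universe, canonical
#'   order).
#' @export
align_samples <- function(views, meta) {
  meta <- validate_sample_meta(meta)
  if (!length(views)) abort("no views supplied")
  if (is.null(names(views)) || any(names(views) == "")) {
    names(views) <- vapply(views, function(v) v$view_name, character(1))
  }
  for (v in views) {
    if (!nrow(v$values)) abort(sprintf("view '%s' is empty", v$view_name))
    extra <- setdiff(v$sample_ids, meta$sample_id)
    if (length(extra)) {
      abort(sprintf("view '%s' contains samples absent from metadata: %s",
                    v$view_name, paste(head(extra, 5), collapse = ", ")))
    }
  }
  universe <- sort(unique(unlist(lapply(views, `[[`, "sample_ids"))))
  meta <- meta[meta$sample_id %in% universe, , drop = FALSE]
  meta <- meta[order(meta$patient_id, meta$timepoint), , drop = FALSE]
  universe <- meta$sample_id
  aligned <- lapply(views, function(v) {
    vals <- matrix(NA_real_, length(universe), ncol(v$values),
                   dimnames = list(universe, v$feature_ids))
    oor <- matrix(FALSE, length(universe), ncol(v$values), dimnames = dimnames(vals))
    present <- intersect(universe, v$sample_ids)
    vals[present, ] <- v$values[present, , drop = FALSE]
    oor[present, ] <- v$oor[present, , drop = FALSE]
    # a sample is present when the view contains it AND its own mask says so
    mask <- setNames(rep(FALSE, length(universe)), universe)
    mask[present] <- v$mask[present]
    view_matrix(vals, v$view_name, oor = oor, mask = mask)
  })
  structure(list(views = aligned, meta = meta), class = "ifa_dataset")
}

#' @export
print.ifa_dataset <- function(x, ...) {
  cat(sprintf("<ifa_dataset> %d samples, %d views\n", nrow(x$meta), length(x$views)))
  for (v in x$views) {
    cat(sprintf("  %-12s %4d features, %3d/%d samples present\n",
                v$view_name, ncol(v$values), sum(v$mask), length(v$mask)))
  }
  invisible(x)
}

# ---- model bundle (de)serialization ---------------------------------------

BUNDLE_VERSION <- "1.0"

write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m),
                   array(sprintf("%.17g", m), dim = dim(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", colnames(m))
  readr::write_tsv(df, path, progress = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_double()), progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}

#' Serialize a fitted factor model to a bundle directory
#'
#' The bundle is a directory of TSV matrices plus a JSON manifest: language
#' neutral, diff-able, and sufficient to project new cohorts onto the factors
#' without the original data. Round trips preserve `Z`, every `W`, the noise
#' and ARD precisions and the feature order to better than 1e-12.
#'
#' @param fit An `ifa_gfa` fit (see [fit_gfa()]).
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
serialize_model <- function(fit, path) {
  stopifnot(inherits(fit, "ifa_gfa"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(fit$Z, file.path(path, "Z.tsv"))
  for (m in names(fit$W)) {
    write_matrix_tsv(fit$W[[m]], file.path(path, sprintf("W_%s.tsv", m)))
  }
  write_matrix_tsv(fit$alpha, file.path(path, "alpha.tsv"))
  readr::write_tsv(tibble::tibble(view = names(fit$tau),
                                  tau = sprintf("%.17g", fit$tau)),
                   file.path(path, "tau.tsv"), progress = FALSE)
  readr::write_tsv(fit$trace, file.path(path, "trace.tsv"), progress = FALSE)
  manifest <- list(bundle_version = BUNDLE_VERSION, K = fit$K,
                   views = names(fit$W), n_iter = fit$n_iter,
                   converged = fit$converged)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname serialize_model
#' @export
deserialize_model <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) abort(sprintf("not a model bundle (no manifest): %s", path))
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(manifest$bundle_version, BUNDLE_VERSION)) {
    abort(sprintf("model bundle version '%s' not supported (expected %s)",
                  manifest$bundle_version %||% "?", BUNDLE_VERSION))
  }
  needed <- c("Z.tsv", "alpha.tsv", "tau.tsv", sprintf("W_%s.tsv", manifest$views))
  missing <- needed[!file.exists(file.path(path, needed))]
  if (length(missing)) {
    abort(sprintf("model bundle truncated, missing: %s", paste(missing, collapse = ", ")))
  }
  Z <- read_matrix_tsv(file.path(path, "Z.tsv"))
  W <- lapply(setNames(manifest$views, manifest$views), function(m) {
    read_matrix_tsv(file.path(path, sprintf("W_%s.tsv", m)))
  })
  tau_df <- readr::read_tsv(file.path(path, "tau.tsv"),
                            col_types = readr::cols(view = readr::col_character(),
                                                    tau = readr::col_double()),
                            progress = FALSE)
  trace <- readr::read_tsv(file.path(path, "trace.tsv"),
                           col_types = readr::cols(.default = readr::col_double()),
                           progress = FALSE)
  new_gfa_fit(Z = Z, W = W, tau = setNames(tau_df$tau, tau_df$view),
              alpha = read_matrix_tsv(file.path(path, "alpha.tsv")),
              trace = trace, K = manifest$K, n_iter = manifest$n_iter,
              converged = isTRUE(manifest$converged))
}

# ---- cell matrices ---------------------------------------------------------

#' Construct a cell-level count matrix
#'
#' @param counts cell x gene matrix of non-negative integer counts
#'   (dense or `Matrix` sparse); rownames are cell ids, colnames gene symbols.
#' @param cell_meta Tibble with columns `cell_id`, `sample_id`, `cluster`
#'   mapping every cell to exactly one sample and one cluster.
#' @return An object of class `ifa_cells`.
#' @export
cell_matrix <- function(counts, cell_meta) {
  need <- c("cell_id", "sample_id", "cluster")
  if (!all(need %in% names(cell_meta))) abort("cell_meta needs cell_id, sample_id, cluster")
  stop_if_duplicated(cell_meta$cell_id, "cell ids")
  if (!identical(rownames(counts), cell_meta$cell_id)) {
    abort("rownames(counts) must equal cell_meta$cell_id in order")
  }
  if (any(counts < 0)) abort("counts must be non-negative")
  structure(list(counts = counts, cell_meta = tibble::as_tibble(cell_meta)),
            class = "ifa_cells")
}

#' @export
print.ifa_cells <- function(x, ...) {
  cat(sprintf("<ifa_cells> %d cells x %d genes, %d samples, %d clusters\n",
              nrow(x$counts), ncol(x$counts),
              dplyr::n_distinct(x$cell_meta$sample_id),
              dplyr::n_distinct(x$cell_meta$cluster)))
  invisible(x)
}

#' Write / read cell counts as MatrixMarket plus annotation TSV
#'
#' @param cells An `ifa_cells`.
#' @param dir Directory receiving `counts.mtx`, `genes.tsv` and `cells.tsv`.
#' @return `dir` (write) or an `ifa_cells` (read).
#' @export
write_cell_matrix <- function(cells, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(cells$counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "counts.mtx"))
  readr::write_tsv(tibble::tibble(gene = colnames(cells$counts)),
                   file.path(dir, "genes.tsv"), progress = FALSE)
  readr::write_tsv(cells$cell_meta, file.path(dir, "cells.tsv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_cell_matrix
#' @export
read_cell_matrix <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"),
                           col_types = readr::cols(gene = readr::col_character()),
                           progress = FALSE)
  meta <- readr::read_tsv(file.path(dir, "cells.tsv"), col_types = readr::cols(
    cell_id = readr::col_character(), sample_id = readr::col_character(),
    cluster = readr::col_character()), progress = FALSE)
  dimnames(m) <- list(meta$cell_id, genes$gene)
  storage.mode(m) <- "integer"
  cell_matrix(m, meta)
}

#' Extract a sample-by-feature matrix across views
#'
#' Assembles the requested features (any views) into one numeric matrix on
#' the dataset's sample universe; entries of absent samples are `NA`.
#'
#' @param dataset An `ifa_dataset`.
#' @param features Character vector of `view::gene` feature ids.
#' @param samples Optional subset of sample ids (default: all).
#' @return Numeric matrix, samples x features.
#' @export
feature_matrix <- function(dataset, features, samples = NULL) {
  samples <- samples %||% dataset$meta$sample_id
  out <- matrix(NA_real_, length(samples), length(features),
                dimnames = list(samples, features))
  for (v in dataset$views) {
    hit <- intersect(features, v$feature_ids)
    if (!length(hit)) next
    vals <- v$values[samples, hit, drop = FALSE]
    vals[!v$mask[samples], ] <- NA
    out[, hit] <- vals
  }
  missing <- features[colSums(!is.na(out)) == 0 & !features %in%
                        unlist(lapply(dataset$views, `[[`, "feature_ids"))]
  if (length(missing)) {
    warn(sprintf("features not found in any view: %s",
                 paste(head(missing, 5), collapse = ", ")))
  }
  out
}
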
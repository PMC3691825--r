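#' Read a genes-by-samples expression table
#'
#' Reads a delimited text file with gene identifiers in the first column and
#' one column per sample.  Tab-separated by default; comma-separated files
#' are auto-detected from a `.csv` extension.
#'
#' @param path Path to a TSV/CSV file.  The header row holds sample ids.
#' @return A tibble with a `gene_id` character column followed by one numeric
#'   column per sample.  The `uniformized` attribute is set to `FALSE`.
#' @details Duplicated gene or sample ids and non-numeric cells are hard
#'   errors naming the offending id or cell; missing values are rejected.
#' @seealso [uniformize()], [read_design()]
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", strip.white = TRUE)
  if (ncol(raw) < 2) stop("expected gene ids plus at least one sample column",
                          call. = FALSE)
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicated gene id: '", ids[duplicated(ids)][1], "'", call. = FALSE)
  }
  smp <- names(raw)[-1]
  if (anyDuplicated(smp)) {
    stop("duplicated sample id: '", smp[duplicated(smp)][1], "'",
         call. = FALSE)
  }
  vals <- lapply(seq_along(smp), function(j) {
    x <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- which(is.na(x) & !is.na(raw[[j + 1]]) &
                   !(raw[[j + 1]] %in% c("NA", "")))
    if (length(bad)) {
      stop("non-numeric value '", raw[[j + 1]][bad[1]], "' at gene '",
           ids[bad[1]], "' (row ", bad[1], "), sample '", smp[j],
           "' (column ", j + 1, ")", call. = FALSE)
    }
    if (anyNA(x)) {
      stop("missing value at gene '", ids[which(is.na(x))[1]], "', sample '",
           smp[j], "'; matrices with missing cells are rejected",
           call. = FALSE)
    }
    x
  })
  names(vals) <- smp
  out <- tibble::tibble(gene_id = ids, !!!vals)
  attr(out, "uniformized") <- FALSE
  out
}

#' Write an expression or result table to disk
#'
#' Plain TSV writer (comma-separated when `path` ends in `.csv`) that
#' round-trips numeric values exactly through [read_expression()].
#'
#' @param data A tibble, e.g. from [read_expression()] or [tidy()] on a fit.
#' @param path Output file path.
#' @return `data`, invisibly.
#' @export
write_results <- function(data, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- as.data.frame(data)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], format, digits = 17, trim = TRUE,
                    scientific = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(data)
}

#' Build a stage design
#'
#' A stage design pairs each sample with one tumor-progression stage and
#' fixes the stage order.  Progression order is semantic (e.g. Normal before
#' PIN before PCA before Met) and is never inferred from label sorting, so
#' `stage_order` is required whenever `stage` is not already an ordered
#' factor.
#'
#' @param data Data frame with columns `sample_id` and `stage`.
#' @param stage_order Character vector giving the progression order of the
#'   stage labels.
#' @return A tibble with `sample_id` (character) and `stage` (factor with
#'   levels in progression order).
#' @export
stage_design <- function(data, stage_order = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c("sample_id", "stage") %in% names(data))) {
    stop("design needs 'sample_id' and 'stage' columns", call. = FALSE)
  }
  if (is.null(stage_order)) {
    if (is.factor(data$stage)) {
      stage_order <- levels(data$stage)
    } else {
      stop("stage_order must be given explicitly; progression order cannot ",
           "be inferred from labels", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    sample_id = as.character(data$sample_id),
    stage = factor(as.character(data$stage), levels = stage_order)
  )
  check_design(out)
}

check_design <- function(design) {
  stopifnot(is.data.frame(design))
  if (!is.factor(design$stage)) {
    stop("design 'stage' must be a factor with levels in progression order; ",
         "use stage_design()", call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicated sample id in design: '",
         design$sample_id[duplicated(design$sample_id)][1], "'",
         call. = FALSE)
  }
  if (anyNA(design$stage)) {
    bad <- design$sample_id[is.na(design$stage)][1]
    stop("sample '", bad, "' has a stage outside the declared stage order",
         call. = FALSE)
  }
  n <- table(design$stage)
  if (any(n == 0)) {
    stop("stage '", names(n)[n == 0][1], "' has no samples", call. = FALSE)
  }
  if (nlevels(design$stage) < 2) {
    stop("at least two progression stages are required", call. = FALSE)
  }
  tibble::as_tibble(design)
}

#' Read a sample-to-stage design file
#'
#' Two-column delimited file (`sample_id`, `stage`).  The progression order
#' is taken from a `#stages:` directive line (e.g. `#stages: Normal,PIN,PCA,
#' Met`) if present, otherwise from `stage_order`.
#'
#' @param path Path to the design file.
#' @inheritParams stage_design
#' @return A stage-design tibble (see [stage_design()]).
#' @export
read_design <- function(path, stage_order = NULL) {
  lines <- readLines(path)
  dir_line <- grep("^#\\s*stages\\s*:", lines, value = TRUE)
  if (length(dir_line)) {
    stage_order <- trimws(strsplit(sub("^#\\s*stages\\s*:", "",
                                       dir_line[1]), ",")[[1]])
  }
  lines <- lines[!grepl("^#", lines)]
  raw <- read.delim(text = paste(lines, collapse = "\n"), sep = "",
                    header = TRUE, check.names = FALSE,
                    colClasses = "character", strip.white = TRUE)
  names(raw)[1:2] <- c("sample_id", "stage")
  stage_design(raw, stage_order = stage_order)
}

#' Per-sample quantile (rank) uniformization
#'
#' Maps each sample's expression values onto the unit interval by replacing
#' every value with its within-sample quantile, `rank / G` with average
#' ranks for ties, where `G` is the number of genes.  After the transform
#' every sample has an identical value distribution, so datasets from
#' different platforms become directly comparable and the discretization
#' cutoff `t` has the same meaning in every sample.
#'
#' @param data Expression tibble (`gene_id` plus one numeric column per
#'   sample).
#' @return A tibble of the same shape with values in `(0, 1]` and the
#'   `uniformized` attribute set to `TRUE`.
#' @details The transform is monotone within each sample and idempotent: the
#'   ranks of already-uniformized values are unchanged.  A constant sample
#'   maps to `(G + 1) / (2 G)` everywhere (the average rank).
#' @export
uniformize <- function(data) {
  m <- as_expr_matrix(data)
  G <- nrow(m)
  m[] <- apply(m, 2, function(x) rank(x, ties.method = "average") / G)
  out <- expr_tbl(m)
  attr(out, "uniformized") <- TRUE
  out
}

is_uniformized <- function(data) isTRUE(attr(data, "uniformized"))
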
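#' Validate a genes x samples expression matrix
#'
#' Checks the container invariants used throughout the package: a numeric
#' matrix with unique gene rownames and sample colnames, every entry
#' finite and non-negative (linear scale), no missing values. Missing
#' values are rejected rather than imputed.
#'
#' @param expr numeric matrix to validate.
#' @return the matrix, invisibly unchanged, for piping into other steps.
#' @export
validate_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression data must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(expr))) {
    stop("duplicate gene id", call. = FALSE)
  }
  if (anyDuplicated(colnames(expr))) {
    stop("duplicate sample id", call. = FALSE)
  }
  if (anyNA(expr) || any(!is.finite(expr))) {
    stop("expression matrix contains missing or non-finite values",
         call. = FALSE)
  }
  if (any(expr < 0)) {
    stop("expression matrix contains negative values", call. = FALSE)
  }
  expr
}

#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV text dump with gene ids in the first column and sample
#' ids in the header row (the canonical genes-as-rows layout; GEO/TCGA
#' dumps with samples as rows can be transposed at read time).
#'
#' @param path path to the delimited text file.
#' @param sep field separator; `NULL` (default) infers `","` for `.csv`
#'   files and tab otherwise.
#' @param orientation `"genes-rows"` (canonical) or `"samples-rows"`
#'   (transposed on read).
#' @return a validated numeric genes x samples matrix.
#' @export
read_expression_matrix <- function(path, sep = NULL,
                                   orientation = c("genes-rows",
                                                   "samples-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("expected an id column plus at least one value column",
         call. = FALSE)
  }
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    nm <- if (orientation == "genes-rows") "gene" else "sample"
    stop("duplicate ", nm, " id", call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  suppressWarnings(num <- vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1L) num <- matrix(num, nrow = 1L)
  if (anyNA(num)) {
    stop("non-numeric or missing cells in expression matrix", call. = FALSE)
  }
  m <- matrix(num, nrow = nrow(df),
              dimnames = list(ids, colnames(vals)))
  if (orientation == "samples-rows") m <- t(m)
  validate_expression_matrix(m)
}

# canonical group labels accepted out of the box, case-insensitive
.default_group_aliases <- c(
  initial = "initial", normal = "initial", ancestral = "initial",
  nd = "initial", control = "initial",
  final = "final", disease = "final", evolved = "final",
  ad = "final", tumor = "final", cancer = "final"
)

#' Read a sample metadata table
#'
#' Reads a delimited table with columns `sample_id`, `group` and
#' optionally `age` (years), and maps group labels onto the two canonical
#' states `initial` and `final`. Built-in aliases (case-insensitive):
#' normal/ancestral/ND/control map to `initial`; disease/evolved/AD/tumor/
#' cancer map to `final`. Additional labels are supplied via
#' `group_aliases`.
#'
#' @param path path to the delimited file (header required).
#' @param group_aliases named character vector mapping extra labels to
#'   `"initial"` or `"final"`; merged over the built-in aliases.
#' @param sep field separator; `NULL` infers as in
#'   [read_expression_matrix()].
#' @return data.frame with columns `sample_id` (character), `group`
#'   (factor with levels initial, final) and `age` (numeric, `NA` when
#'   absent).
#' @export
read_sample_table <- function(path, group_aliases = NULL, sep = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(df))) {
    stop("sample table needs columns sample_id and group", call. = FALSE)
  }
  build_sample_table(sample_id = as.character(df$sample_id),
                     group = as.character(df$group),
                     age = if ("age" %in% colnames(df))
                       as.numeric(df$age) else NA_real_,
                     group_aliases = group_aliases)
}

#' Assemble and validate a sample table from vectors
#'
#' @inheritParams read_sample_table
#' @param sample_id character vector of unique sample ids.
#' @param group character vector of group labels, resolved through the
#'   alias map.
#' @param age optional numeric vector of ages in years.
#' @return see [read_sample_table()].
#' @export
build_sample_table <- function(sample_id, group, age = NA_real_,
                               group_aliases = NULL) {
  if (anyDuplicated(sample_id)) {
    stop("sample listed twice: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  aliases <- .default_group_aliases
  if (!is.null(group_aliases)) {
    extra <- stats::setNames(tolower(unname(group_aliases)),
                             tolower(names(group_aliases)))
    bad <- setdiff(unique(unname(extra)), c("initial", "final"))
    if (length(bad) > 0L) {
      stop("aliases must map to 'initial' or 'final', got: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    aliases[names(extra)] <- extra
  }
  mapped <- aliases[tolower(group)]
  if (anyNA(mapped)) {
    stop("unmapped group label: ",
         paste(unique(group[is.na(mapped)]), collapse = ", "),
         call. = FALSE)
  }
  age <- suppressWarnings(as.numeric(age))
  if (length(age) == 1L) age <- rep(age, length(sample_id))
  if (any(!is.na(age) & age < 0)) {
    stop("negative age", call. = FALSE)
  }
  data.frame(sample_id = as.character(sample_id),
             group = factor(unname(mapped), levels = c("initial", "final")),
             age = age,
             stringsAsFactors = FALSE)
}

#' Sample ids of one group
#' @param samples sample table (see [read_sample_table()]).
#' @param group `"initial"` or `"final"`.
#' @return character vector of sample ids.
#' @export
group_ids <- function(samples, group = c("initial", "final")) {
  group <- match.arg(group)
  samples$sample_id[samples$group == group]
}

check_samples_cover <- function(expr, samples) {
  missing <- setdiff(colnames(expr), samples$sample_id)
  if (length(missing) > 0L) {
    stop("samples absent from metadata table: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
}
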
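#' Gene-by-sample count matrix with group labels
#'
#' The container consumed by the differential-expression stage: an integer
#' matrix of read counts (genes in rows, samples in columns) together with a
#' case/control label per sample (case = Treg, control = non-Treg in the
#' motivating application).
#'
#' @param counts Integer matrix, genes x samples, with unique row and column
#'   names. Negative or non-integer entries are rejected.
#' @param group Character or factor vector, one entry per sample (named or in
#'   column order), with values `"case"` and `"control"`. Both groups must be
#'   non-empty.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, group) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_field("counts", "must be a numeric matrix")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop_field("counts", "entries must be nonnegative integers")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop_field("counts", "row names must be present and unique")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop_field("counts", "column names must be present and unique")
  group <- as.character(group)
  if (!is.null(names(group))) group <- group[colnames(counts)]
  if (length(group) != ncol(counts) || any(is.na(group)))
    stop_field("group", "must label every sample")
  if (!all(group %in% c("case", "control")))
    stop_field("group", "labels must be 'case' or 'control'")
  if (!all(c("case", "control") %in% group))
    stop_field("group", "both groups must be non-empty")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, group = stats::setNames(group, colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write / read a count matrix and its sample metadata as TSV
#'
#' The counts file has a `gene` column followed by one column per sample; the
#' metadata file has columns `sample` and `group`.
#'
#' @param cm A [count_matrix()].
#' @param counts_path,meta_path File paths.
#' @export
write_counts_tsv <- function(cm, counts_path, meta_path = NULL) {
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- data.frame(sample = names(cm$group), group = unname(cm$group))
    utils::write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(counts_path)
}

#' @rdname write_counts_tsv
#' @param case,control Values in the metadata `group` column mapped to case
#'   and control (e.g. `"Treg"`, `"nonTreg"`).
#' @export
read_counts_tsv <- function(counts_path, meta_path,
                            case = "case", control = "control") {
  df <- utils::read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene")
    stop("counts TSV must have a leading 'gene' column", call. = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% colnames(meta)))
    stop("metadata TSV must have columns 'sample' and 'group'", call. = FALSE)
  grp <- ifelse(meta$group == case, "case",
                ifelse(meta$group == control, "control", NA))
  if (any(is.na(grp)))
    stop(sprintf("metadata group values must be '%s' or '%s'", case, control),
         call. = FALSE)
  count_matrix(counts[, meta$sample, drop = FALSE],
               stats::setNames(grp, meta$sample))
}
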
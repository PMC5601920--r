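#' Read a long-format plate grid CSV
#'
#' Expects the header `plate_id,condition,replicate,row,col,strain_id,size`
#' with 1-based rows and columns.
#'
#' @param path CSV file path.
#' @return validated tibble.
#' @export
read_plate_grid <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(df, c("plate_id", "condition", "replicate", "row", "col",
                       "strain_id", "size"), "plate CSV")
  if (any(df$row < 1) || any(df$col < 1)) {
    pb_abort("rows and columns are 1-based", "pb_bad_plate")
  }
  if (any(df$size < 0, na.rm = TRUE)) {
    pb_abort("colony sizes must be non-negative", "pb_bad_plate")
  }
  df
}

#' Read a differential-expression summary TSV
#'
#' Expects (possibly via renaming) the columns `gene_id`, `contrast`,
#' `timepoint`, `log2_ratio`, `p_value` and optionally `q_value`.
#'
#' @param path TSV file path.
#' @param column_map optional named character vector mapping the file's column
#'   names to the expected ones, e.g. `c(gene = "gene_id", log2FC = "log2_ratio")`.
#' @return validated tibble.
#' @export
read_expression_table <- function(path, column_map = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!is.null(column_map)) {
    for (from in names(column_map)) {
      names(df)[names(df) == from] <- column_map[[from]]
    }
  }
  assert_columns(df, c("gene_id", "contrast", "timepoint", "log2_ratio"),
                 "expression TSV")
  if (!any(c("p_value", "q_value") %in% names(df))) {
    pb_abort("expression table needs `p_value` or `q_value`",
             "pb_missing_pvalues")
  }
  df
}

#' Read growth curves from a long CSV
#'
#' Expects `strain_id,condition,replicate,time_h,od`.
#' @param path CSV file path.
#' @return validated tibble.
#' @export
read_growth_curves <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(df, c("strain_id", "condition", "replicate", "time_h", "od"),
                 "growth CSV")
  df
}

#' Read a two-column interaction network TSV
#'
#' Tab-delimited `gene_a<TAB>gene_b` pairs (a minimal BioGRID-style
#' projection); self-edges and duplicate undirected edges are dropped.
#'
#' @param path TSV file path (a header line `gene_a	gene_b` is expected).
#' @return cleaned edge tibble.
#' @export
read_network <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(df, c("gene_a", "gene_b"), "network TSV")
  clean_edges(df)
}

#' Read a plain-text gene list (one gene per line)
#'
#' @param path text file path.
#' @return character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path)
  unique(trimws(x[nzchar(trimws(x))]))
}
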
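# Plain-text readers/writers for the tables the pipeline exchanges.

#' Read / write an atlas table as TSV
#'
#' Columns: roi_id, name, hemisphere, tissue, network, R, A, S.
#'
#' @param atlas an `atlas_info` table.
#' @param path file path.
#' @return the atlas (invisibly for the writer).
#' @export
write_atlas_tsv <- function(atlas, path) {
  write.table(as.data.frame(atlas), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas_tsv
#' @export
read_atlas_tsv <- function(path) {
  atlas <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "name", "hemisphere", "tissue", "network", "R", "A", "S")
  if (!all(need %in% names(atlas))) {
    stop_invalid("atlas file must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(atlas$roi_id) || !identical(sort(atlas$roi_id),
                                                seq_len(nrow(atlas)) - 1L)) {
    stop_invalid("roi_id must be unique and contiguous from 0")
  }
  class(atlas) <- c("atlas_info", "data.frame")
  atlas
}

#' Read / write a cohort table as TSV
#'
#' Columns: subject_id, group, age, sex, csf_nfl.
#'
#' @param cohort a `cohort_table`.
#' @param path file path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  cohort <- read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(cohort$subject_id)) stop_invalid("duplicate subject_id")
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

#' Read / write a region-by-gene expression matrix as TSV
#'
#' Regions as rows (first column holds region names), genes as columns.
#'
#' @param m regions x genes matrix.
#' @param path file path.
#' @export
write_expression_tsv <- function(m, path) {
  write.table(as.matrix(m), path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  as.matrix(read.delim(path, row.names = 1L, check.names = FALSE))
}
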
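#' Write an expression cohort to TSV files
#'
#' The matrix file has a `gene_id` first column and one column per sample;
#' the annotation file has columns `sample`, `class`, `os_time`, `os_event`,
#' `myd88`.
#'
#' @param dataset an [expression_dataset()].
#' @param matrix_path,annotation_path output paths.
#' @export
write_expression_dataset <- function(dataset, matrix_path, annotation_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  tab <- data.frame(gene_id = rownames(dataset$matrix), dataset$matrix,
                    check.names = FALSE)
  write.table(tab, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$annotations, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(matrix_path)
}

#' Read an expression cohort from TSV files
#'
#' @param matrix_path genes x samples TSV, first column `gene_id`.
#' @param annotation_path sample annotations TSV (optional).
#' @param dataset_id cohort label; defaults to the matrix file base name.
#' @return an [expression_dataset()].
#' @export
read_expression_dataset <- function(matrix_path, annotation_path = NULL,
                                    dataset_id = NULL) {
  tab <- read.delim(matrix_path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  ann <- if (!is.null(annotation_path)) read.delim(annotation_path) else NULL
  if (!is.null(ann) && "myd88" %in% names(ann))
    ann$myd88 <- as.character(ann$myd88)
  expression_dataset(dataset_id %||% sub("\\.[^.]*$", "", basename(matrix_path)),
                     m, ann)
}

#' Write a gene-model table as TSV
#' @param genes a [gene_models()] table.
#' @param path output file.
#' @export
write_gene_models <- function(genes, path) {
  write.table(as.data.frame(genes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a gene-model table from TSV
#' @param path TSV with gene_id, chrom, strand, body_start, body_end
#'   (and optionally symbol, tss).
#' @return a [gene_models()] table.
#' @export
read_gene_models <- function(path) gene_models(read.delim(path))

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
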
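# Plain-text interchange: feature x sample matrices as TSV with a header
# row of sample identifiers and a first column of feature identifiers.

#' Read a features x samples matrix from TSV
#'
#' @param path file path; first column feature ids, header = sample ids.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a features x samples matrix to TSV
#'
#' @param x numeric matrix with dimnames.
#' @param path output file path.
#' @param id_col name of the feature-id column (default `"feature"`).
#' @export
write_matrix_tsv <- function(x, path, id_col = "feature") {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated cascade dataset to a directory of TSV files
#'
#' Emits genotype dosages, per-layer omics matrices, the phenotype, the true
#' DAG as a `parent<TAB>child` edge list, and the annotation tables.
#'
#' @param sim an `lrn_sim` from [simulate_lrn_cascade()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_cascade_tsv <- function(sim, dir) {
  stopifnot(inherits(sim, "lrn_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  emit <- function(x, name, id_col = "feature") {
    f <- file.path(dir, name)
    if (is.matrix(x)) write_matrix_tsv(x, f, id_col)
    else write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, f)
  }
  emit(sim$genotypes$dosage, "genotypes.tsv", "snp")
  emit(sim$genotypes$info, "genotype_info.tsv")
  for (layer in names(sim$omics))
    if (nrow(sim$omics[[layer]]) > 0)
      emit(sim$omics[[layer]], paste0(layer, ".tsv"))
  if (!is.null(sim$phenotype))
    emit(data.frame(sample = names(sim$phenotype), value = sim$phenotype),
         "phenotype.tsv")
  emit(igraph::as_data_frame(sim$true_dag)[, c("from", "to")],
       "true_dag.tsv")
  for (layer in names(sim$annotations))
    if (!is.null(sim$annotations[[layer]]))
      emit(sim$annotations[[layer]], paste0("annot_", layer, ".tsv"))
  invisible(files)
}
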
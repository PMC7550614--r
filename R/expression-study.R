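#' Construct an ExpressionStudy
#'
#' Container for a normalized log2 expression matrix (genes x samples) plus a
#' per-sample phenotype table carrying the four binary condition flags used
#' throughout the workflow: `PE`, `asthma`, `excess_BMI`, `vitD_insufficient`.
#' Additional numeric columns in `phenotypes` are treated as covariates.
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (colnames matching `phenotypes$sample`).
#' @param phenotypes data.frame with a `sample` column and the four 0/1 flags.
#' @return An object of class `ExpressionStudy`.
#' @export
expression_study <- function(values, phenotypes) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("gene identifiers (rownames) must be present and unique")
  if (anyNA(values)) stop("expression matrix contains missing values")
  flags <- c("PE", "asthma", "excess_BMI", "vitD_insufficient")
  if (!"sample" %in% names(phenotypes)) stop("phenotypes needs a 'sample' column")
  missing_flags <- setdiff(flags, names(phenotypes))
  if (length(missing_flags))
    stop("phenotypes missing condition flags: ", paste(missing_flags, collapse = ", "))
  if (!identical(as.character(phenotypes$sample), colnames(values)))
    stop("phenotypes$sample must match colnames(values) in order")
  for (f in flags) {
    v <- phenotypes[[f]]
    if (!all(v %in% c(0, 1, TRUE, FALSE)))
      stop("flag '", f, "' must be binary")
    phenotypes[[f]] <- as.integer(v)
  }
  structure(list(values = values, phenotypes = phenotypes),
            class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat("ExpressionStudy:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  flags <- c("PE", "asthma", "excess_BMI", "vitD_insufficient")
  counts <- vapply(flags, function(f) sum(x$phenotypes[[f]]), integer(1))
  cat("  positives:", paste(sprintf("%s=%d", flags, counts), collapse = ", "), "\n")
  invisible(x)
}

#' Genes of an ExpressionStudy
#' @param study an `ExpressionStudy`.
#' @return character vector of gene identifiers.
#' @export
study_genes <- function(study) rownames(study$values)

#' Split sample indices by a condition flag
#'
#' @param study an `ExpressionStudy`.
#' @param condition one of `PE`, `asthma`, `excess_BMI`, `vitD_insufficient`,
#'   or any binary column of the phenotype table.
#' @return list with integer vectors `case` and `control`.
#' @export
condition_groups <- function(study, condition) {
  ph <- study$phenotypes
  if (!condition %in% names(ph)) stop("unknown condition flag: ", condition)
  flag <- as.integer(ph[[condition]])
  list(case = which(flag == 1L), control = which(flag == 0L))
}

#' Write an ExpressionStudy as TSV files
#'
#' Writes the expression matrix (first column `gene`) and the phenotype table.
#'
#' @param study an `ExpressionStudy`.
#' @param expr_path path for the expression TSV.
#' @param pheno_path path for the phenotype TSV.
#' @return invisibly, the two paths.
#' @export
write_study_tsv <- function(study, expr_path, pheno_path) {
  dt <- data.table::data.table(gene = rownames(study$values))
  dt <- cbind(dt, data.table::as.data.table(study$values))
  data.table::fwrite(dt, expr_path, sep = "\t")
  data.table::fwrite(study$phenotypes, pheno_path, sep = "\t")
  invisible(c(expr_path, pheno_path))
}

#' Read an ExpressionStudy from TSV files
#'
#' @param expr_path expression TSV as written by [write_study_tsv()]
#'   (first column = gene ID, remaining columns = samples).
#' @param pheno_path phenotype TSV with `sample` plus the four condition flags.
#' @return An `ExpressionStudy`.
#' @export
read_study_tsv <- function(expr_path, pheno_path) {
  dt <- data.table::fread(expr_path, sep = "\t")
  genes <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- genes
  ph <- as.data.frame(data.table::fread(pheno_path, sep = "\t"))
  expression_study(m, ph)
}
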
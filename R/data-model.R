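#' @importFrom stats median mad cor sd quantile var anova aov lm pt pf pchisq
#'   rnorm runif setNames model.matrix p.adjust phyper wilcox.test kruskal.test
#'   ks.test cor.test optim hclust as.dist cutree complete.cases coef dhyper
#'   qf prcomp
#' @importFrom utils read.delim write.table head tail
NULL

VALID_DIETS <- c("HP", "HS")

#' Construct an ExpressionDataset
#'
#' The container every pipeline stage consumes: a features x samples matrix of
#' log2-scale normalized intensities, per-feature annotation (transcript
#' cluster ID and gene symbol), and per-sample metadata (strain, diet, week).
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids character vector of unique TC-IDs (row keys).
#' @param gene_symbols character vector of per-feature gene symbols; symbols
#'   may repeat across features (several TC-IDs can summarize one gene).
#'   Upper-cased on construction.
#' @param metadata data.frame with columns `sample_id`, `strain`, `diet`
#'   (one of `"HP"`, `"HS"`), `week`; one row per sample, in column order.
#' @return an object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(values, feature_ids, gene_symbols, metadata) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  feature_ids <- as.character(feature_ids)
  gene_symbols <- toupper(trimws(as.character(gene_symbols)))
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  rownames(values) <- feature_ids
  colnames(values) <- metadata$sample_id   # columns are aligned by position
  ds <- structure(
    list(values = values, feature_ids = feature_ids,
         gene_symbols = gene_symbols, sample_ids = colnames(values),
         metadata = metadata),
    class = "ExpressionDataset")
  validate_expression_dataset(ds)
  ds
}

validate_expression_dataset <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  v <- ds$values
  if (anyNA(v) || any(!is.finite(v)))
    stop("expression values contain missing or non-finite entries")
  if (anyDuplicated(ds$feature_ids))
    stop("duplicate feature id: ",
         paste(unique(ds$feature_ids[duplicated(ds$feature_ids)]), collapse = ", "))
  if (anyDuplicated(ds$sample_ids))
    stop("duplicate sample id: ",
         paste(unique(ds$sample_ids[duplicated(ds$sample_ids)]), collapse = ", "))
  if (length(ds$gene_symbols) != nrow(v))
    stop("gene_symbols length does not match feature count")
  md <- ds$metadata
  req <- c("sample_id", "strain", "diet", "week")
  miss <- setdiff(req, names(md))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (!identical(as.character(md$sample_id), ds$sample_ids))
    stop("metadata rows are not aligned with expression columns")
  if (anyNA(md$strain) || anyNA(md$diet) || anyNA(md$week))
    stop("every sample must have strain, diet and week assigned")
  bad <- setdiff(unique(as.character(md$diet)), VALID_DIETS)
  if (length(bad)) stop("unknown diet label: ", paste(bad, collapse = ", "))
  invisible(ds)
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  genes: %d unique symbols; strains: %d; diets: %s; weeks: %d\n",
              length(unique(x$gene_symbols)),
              length(unique(x$metadata$strain)),
              paste(sort(unique(as.character(x$metadata$diet))), collapse = "/"),
              length(unique(x$metadata$week))))
  invisible(x)
}

#' Number of features / samples in an ExpressionDataset
#' @param x an `ExpressionDataset`.
#' @return integer count.
#' @export
n_features <- function(x) nrow(x$values)

#' @rdname n_features
#' @export
n_samples <- function(x) ncol(x$values)

#' Subset an ExpressionDataset
#'
#' @param x an `ExpressionDataset`.
#' @param features logical/integer/character index over features (optional).
#' @param samples logical/integer/character index over samples (optional).
#' @return the subset `ExpressionDataset`, metadata kept aligned.
#' @export
subset_dataset <- function(x, features = NULL, samples = NULL) {
  fi <- if (is.null(features)) seq_len(nrow(x$values)) else features
  if (is.character(fi)) fi <- match(fi, x$feature_ids)
  si <- if (is.null(samples)) seq_len(ncol(x$values)) else samples
  if (is.character(si)) si <- match(si, x$sample_ids)
  expression_dataset(x$values[fi, si, drop = FALSE],
                     x$feature_ids[fi], x$gene_symbols[fi],
                     x$metadata[si, , drop = FALSE])
}

# ---- file I/O ---------------------------------------------------------------

#' Load an expression / metadata / phenotype TSV trio
#'
#' Files are tab-separated UTF-8 with a header row and '.' decimals. The
#' expression table's first column is the TC-ID, its second column the gene
#' symbol, remaining columns one per sample. Metadata rows are reordered to
#' expression column order; metadata rows for samples absent from the
#' expression matrix are dropped with a warning. Phenotype values may be
#' missing (empty cell or "NA").
#'
#' @param expression_path path to expression TSV.
#' @param metadata_path path to sample metadata TSV
#'   (columns sample_id, strain, diet, week).
#' @param phenotype_path path to phenotype TSV (column sample_id plus one
#'   numeric column per trait); optional.
#' @return list with elements `dataset` (an [expression_dataset()]) and
#'   `phenotypes` (data.frame keyed by sample_id, or `NULL`).
#' @export
load_dataset <- function(expression_path, metadata_path, phenotype_path = NULL) {
  ex <- read.delim(expression_path, check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(ex) < 3) stop("expression table needs TC-ID, gene symbol and >= 1 sample column")
  feature_ids <- ex[[1]]
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  gene_symbols <- ex[[2]]
  vals <- as.matrix(ex[, -(1:2), drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) stop("non-numeric or missing expression cells found")
  rownames(vals) <- feature_ids

  md <- read.delim(metadata_path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "strain", "diet", "week")
  miss <- setdiff(req, names(md))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  md$sample_id <- as.character(md$sample_id)
  absent <- setdiff(colnames(vals), md$sample_id)
  if (length(absent))
    stop("sample(s) present in expression but absent from metadata: ",
         paste(absent, collapse = ", "))
  extra <- setdiff(md$sample_id, colnames(vals))
  if (length(extra)) {
    warning("dropping ", length(extra), " metadata row(s) without expression: ",
            paste(extra, collapse = ", "))
    md <- md[md$sample_id %in% colnames(vals), , drop = FALSE]
  }
  md <- md[match(colnames(vals), md$sample_id), , drop = FALSE]
  rownames(md) <- NULL
  ds <- expression_dataset(vals, feature_ids, gene_symbols, md)

  ph <- NULL
  if (!is.null(phenotype_path)) {
    ph <- read.delim(phenotype_path, check.names = FALSE, na.strings = c("NA", ""),
                     stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(ph)) stop("phenotype table missing sample_id column")
    ph$sample_id <- as.character(ph$sample_id)
    unknown <- setdiff(ph$sample_id, ds$sample_ids)
    if (length(unknown))
      stop("phenotype sample(s) not in expression data: ", paste(unknown, collapse = ", "))
  }
  list(dataset = ds, phenotypes = ph)
}

#' Write the expression / metadata / phenotype TSV trio
#'
#' Numeric values are written with 17 significant digits so a load -> write ->
#' load round trip is bit exact.
#'
#' @param dataset an `ExpressionDataset`.
#' @param dir output directory (created if missing).
#' @param phenotypes optional phenotype data.frame keyed by sample_id.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir, phenotypes = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) sprintf("%.17g", x)
  ep <- file.path(dir, "expression.tsv")
  em <- cbind(data.frame(tc_id = dataset$feature_ids,
                         gene_symbol = dataset$gene_symbols,
                         stringsAsFactors = FALSE),
              as.data.frame(apply(dataset$values, 2, fmt), check.names = FALSE))
  write.table(em, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  mp <- file.path(dir, "metadata.tsv")
  write.table(dataset$metadata, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  pp <- NULL
  if (!is.null(phenotypes)) {
    pp <- file.path(dir, "phenotypes.tsv")
    pf <- phenotypes
    for (j in names(pf)) if (is.numeric(pf[[j]])) {
      fv <- fmt(pf[[j]]); fv[is.na(pf[[j]])] <- NA; pf[[j]] <- fv
    }
    write.table(pf, pp, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  }
  invisible(c(expression = ep, metadata = mp, phenotypes = pp))
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, `set_id TAB description TAB
#' member...`. Member symbols are upper-cased and whitespace-stripped.
#'
#' @param gmt_path path to a GMT file.
#' @return named list; each element has `description` and `genes`.
#' @export
read_gene_sets <- function(gmt_path) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT parse error at line ", i, ": expected >= 3 tab-separated fields")
    genes <- unique(toupper(trimws(f[-(1:2)])))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT parse error at line ", i, ": empty member list")
    out[[f[[1]]]] <- list(description = f[[2]], genes = genes)
  }
  out
}

#' Read a GWAS-catalog-style TSV and keep trait-matching rows
#'
#' Retains rows whose `DISEASE/TRAIT` label contains any of the supplied
#' keywords (case-insensitive, fixed strings). The raw `MAPPED_GENE` field is
#' kept untouched for downstream delimiter parsing by [match_gwas_genes()].
#'
#' @param path TSV with at least columns `DISEASE/TRAIT` and `MAPPED_GENE`.
#' @param trait_keywords character vector of keywords, e.g.
#'   `c("body mass", "obesity", "adipos")`. The study-defining keyword list is
#'   an input, not a constant of the method.
#' @return data.frame with columns `trait_label`, `mapped_gene_field`.
#' @export
read_gwas_catalog <- function(path, trait_keywords) {
  tb <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("DISEASE/TRAIT", "MAPPED_GENE")
  miss <- setdiff(req, names(tb))
  if (length(miss)) stop("GWAS catalog missing column(s): ", paste(miss, collapse = ", "))
  lab <- tolower(tb[["DISEASE/TRAIT"]])
  keep <- Reduce(`|`, lapply(tolower(trait_keywords),
                             function(k) grepl(k, lab, fixed = TRUE)),
                 accumulate = FALSE, init = rep(FALSE, nrow(tb)))
  data.frame(trait_label = tb[["DISEASE/TRAIT"]][keep],
             mapped_gene_field = tb[["MAPPED_GENE"]][keep],
             stringsAsFactors = FALSE)
}
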
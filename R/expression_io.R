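#' Construct a validated expression matrix
#'
#' An expression matrix holds log2-scale intensities with features (probe sets
#' or gene symbols) in rows and samples in columns. It is represented as a
#' base numeric matrix with dimnames plus a `feature_level` attribute, and is
#' the substrate of every downstream analysis in the package.
#'
#' @param values numeric matrix of log2 intensities; rownames are feature ids,
#'   colnames are sample ids.
#' @param feature_level `"probe"` or `"gene"`.
#' @return the validated matrix with class `expr_matrix` and attribute
#'   `feature_level`.
#' @export
expression_matrix <- function(values, feature_level = c("probe", "gene")) {
  feature_level <- match.arg(feature_level)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature ids as rownames and sample ids as colnames")
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f))
    stop("duplicate feature ids: ", paste(dup_f, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at feature '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  structure(values, feature_level = feature_level,
            class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features (%s level) x %d samples\n",
              nrow(x), attr(x, "feature_level"), ncol(x)))
  cat("log2 intensity range:",
      paste(signif(range(x), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' Read an expression matrix from delimited text
#'
#' Expects feature ids in the first column and sample ids in the header row;
#' all remaining cells must be numeric (log2 scale). Parsing uses the decimal
#' point only; no locale-dependent interpretation.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @param feature_level `"probe"` (default) or `"gene"`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, delimiter = "\t",
                            feature_level = c("probe", "gene")) {
  feature_level <- match.arg(feature_level)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 2) stop("expected at least one sample column in ", path)
  ids <- trimws(raw[[1]])
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
    if (nrow(bad)) {
      b <- bad[1, ]
      stop(sprintf("non-numeric cell '%s' at row %d (feature '%s'), column '%s'",
                   body[b[1], b[2]], b[1], ids[b[1]], colnames(body)[b[2]]))
    }
  }
  dimnames(num) <- list(ids, colnames(body))
  expression_matrix(num, feature_level = feature_level)
}

#' Write an expression matrix as delimited text
#'
#' Emits the same dialect [read_expression()] consumes: header row of sample
#' ids, first column `feature_id`. Full double precision is preserved.
#'
#' @param m an `expr_matrix` (or plain named matrix).
#' @param path output file path.
#' @param delimiter field separator, default tab.
#' @export
write_expression <- function(m, path, delimiter = "\t") {
  df <- data.frame(feature_id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read iCMS marker gene sets from a GMT file
#'
#' Each GMT line is: set name, description, then tab-separated gene symbols.
#' The four iCMS marker classes (iCMS2_up, iCMS2_down, iCMS3_up, iCMS3_down)
#' must all be present and pairwise disjoint; duplicate symbols within a line
#' are removed with a warning. Symbols are whitespace-trimmed and matched
#' case-sensitively throughout the package.
#'
#' @param path GMT file path.
#' @param required character vector of set names that must be present.
#' @return a named list of character vectors, class `icms_gene_sets`, in the
#'   order `required`.
#' @export
read_gmt <- function(path,
                     required = c("iCMS2_up", "iCMS2_down",
                                  "iCMS3_up", "iCMS3_down")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list()
  for (f in fields) {
    if (length(f) < 3)
      stop("malformed GMT line (need name, description, >=1 gene): ",
           f[[1]])
    nm <- trimws(f[[1]])
    genes <- trimws(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("gene set '%s': %d duplicate symbols removed",
                      nm, sum(duplicated(genes))))
      genes <- unique(genes)
    }
    if (!length(genes)) stop("gene set '", nm, "' is empty")
    sets[[nm]] <- genes
  }
  missing <- setdiff(required, names(sets))
  if (length(missing))
    stop(paste(missing, collapse = ", "), " missing from ", path)
  sets <- sets[required]
  # pairwise disjointness: a symbol in two classes would make scores ambiguous
  all_genes <- unlist(sets, use.names = FALSE)
  shared <- unique(all_genes[duplicated(all_genes)])
  if (length(shared))
    stop("gene sets overlap; shared genes: ", paste(shared, collapse = ", "))
  structure(sets, class = "icms_gene_sets")
}

#' @export
print.icms_gene_sets <- function(x, ...) {
  cat("iCMS marker gene sets:\n")
  for (nm in names(x)) cat(sprintf("  %-12s %d genes\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field per line (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' CSV with columns `sample_id`, `cell_line`, `model_system` and optionally
#' `group`. `model_system` must be one of `monolayer2D`, `spheroid`,
#' `xenograft`, `patient_tumor`, `normal_tissue`.
#'
#' @param path CSV file path.
#' @return a data.frame with validated columns.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' @rdname read_sample_metadata
#' @param meta a metadata data.frame to validate.
#' @export
validate_metadata <- function(meta) {
  needed <- c("sample_id", "cell_line", "model_system")
  missing <- setdiff(needed, names(meta))
  if (length(missing))
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "))
  levels_ok <- c("monolayer2D", "spheroid", "xenograft",
                 "patient_tumor", "normal_tissue")
  bad <- setdiff(unique(meta$model_system), levels_ok)
  if (length(bad))
    stop("unknown model_system value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  if (is.null(meta$group)) meta$group <- NA_character_
  meta
}

#' Write a sample metadata table
#' @param meta metadata data.frame.
#' @param path output CSV path.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean-collapse probe sets to gene symbols
#'
#' Each gene's expression row is the arithmetic mean, per sample, of the rows
#' of the probe sets mapped to it. Probes without a mapping are dropped (count
#' reported via message); probes mapped to several genes contribute to each.
#'
#' @param m probe-level `expr_matrix`.
#' @param mapping data.frame with columns `probe_id` and `gene`.
#' @return gene-level `expr_matrix` with one row per distinct mapped gene.
#' @export
collapse_probes <- function(m, mapping) {
  if (!all(c("probe_id", "gene") %in% names(mapping)))
    stop("mapping needs columns 'probe_id' and 'gene'")
  mapping <- mapping[mapping$probe_id %in% rownames(m), , drop = FALSE]
  if (!nrow(mapping))
    stop("no probe in the mapping matches the matrix")
  n_unmapped <- sum(!rownames(m) %in% mapping$probe_id)
  if (n_unmapped)
    message(n_unmapped, " unmapped probe(s) dropped")
  genes <- sort(unique(mapping$gene), method = "radix")
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(m),
                dimnames = list(genes, colnames(m)))
  split_probes <- split(mapping$probe_id, mapping$gene)
  for (g in genes) {
    out[g, ] <- colMeans(m[split_probes[[g]], , drop = FALSE])
  }
  expression_matrix(out, feature_level = "gene")
}
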
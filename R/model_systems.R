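#' Per-feature one-way F-test filter with FDR and fold-change cuts
#'
#' For every feature a one-way ANOVA F statistic across the metadata groups
#' is computed, p-values are adjusted across features with
#' Benjamini-Hochberg, and log2 fold changes are formed per contrast as the
#' difference of group means on the log2-scale data. A feature passes the
#' filter when its adjusted q-value is below `fdr` and its fold changes
#' exceed `lfc` in absolute value in at least one contrast (`lfc_rule =
#' "any"`, default) or in every contrast (`"all"`).
#'
#' Features that are constant across all samples have an undefined F
#' statistic and are excluded with a warning.
#'
#' @param m expression matrix (features x samples, log2 scale).
#' @param meta sample metadata; the grouping column is picked by `group_by`.
#' @param baseline group label used as fold-change baseline.
#' @param fdr FDR threshold on BH-adjusted q-values.
#' @param lfc absolute log2 fold-change threshold.
#' @param group_by metadata column defining groups (default `model_system`).
#' @param contrasts group labels compared against the baseline; default all
#'   non-baseline groups present.
#' @param lfc_rule `"any"` or `"all"` contrasts must exceed the cut.
#' @return data.frame of class `gene_filter` with per-feature `F`, `p`, `q`,
#'   one `lfc_<contrast>` column per contrast, and logical `pass`; the
#'   passing feature ids are in attribute `passing`.
#' @export
anova_filter <- function(m, meta, baseline, fdr = 0.01, lfc = 1.5,
                         group_by = "model_system", contrasts = NULL,
                         lfc_rule = c("any", "all")) {
  lfc_rule <- match.arg(lfc_rule)
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata does not cover every sample in the matrix")
  grp <- as.character(meta[[group_by]])
  if (!baseline %in% grp) stop("baseline group '", baseline, "' absent")
  counts <- table(grp)
  if (length(counts) < 2) stop("need at least 2 groups")
  if (any(counts < 2))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  if (is.null(contrasts)) contrasts <- setdiff(names(counts), baseline)

  x <- unclass(m)
  n <- ncol(x); k <- length(counts)
  gm <- vapply(names(counts), function(g)
    rowMeans(x[, grp == g, drop = FALSE]), numeric(nrow(x)))
  if (nrow(x) == 1) gm <- matrix(gm, nrow = 1, dimnames = list(rownames(x), names(counts)))
  grand <- rowMeans(x)
  ssb <- as.vector(gm^2 %*% counts) - n * grand^2
  sst <- rowSums(x^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  const <- sst < .Machine$double.eps * 100
  if (any(const))
    warning(sum(const), " constant feature(s) excluded from the F-test")
  Fstat <- ifelse(const, NA_real_, msb / msw)
  p <- stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  q <- rep(NA_real_, length(p))
  q[!const] <- stats::p.adjust(p[!const], method = "BH")

  lfcs <- vapply(contrasts, function(ct) gm[, ct] - gm[, baseline],
                 numeric(nrow(x)))
  if (nrow(x) == 1) lfcs <- matrix(lfcs, nrow = 1)
  colnames(lfcs) <- paste0("lfc_", contrasts)
  exceed <- abs(lfcs) > lfc
  lfc_ok <- if (lfc_rule == "any") rowSums(exceed) > 0 else
    rowSums(exceed) == ncol(exceed)
  pass <- !const & !is.na(q) & q < fdr & lfc_ok

  res <- data.frame(feature_id = rownames(x), F = Fstat, p = p, q = q,
                    lfcs, pass = pass, row.names = NULL,
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(res, "passing") <- res$feature_id[res$pass]
  attr(res, "baseline") <- baseline
  class(res) <- c("gene_filter", "data.frame")
  res
}

#' @export
print.gene_filter <- function(x, ...) {
  cat(sprintf("F-test filter: %d/%d features pass (baseline %s)\n",
              sum(x$pass), nrow(x), attr(x, "baseline")))
  invisible(x)
}

#' Classify cross-model-system expression patterns
#'
#' For each gene the mean log2 expression is computed per model system
#' (2D monolayer, spheroid, xenograft) and the two steps
#' step1 = mean(spheroid) - mean(2D) and step2 = mean(xenograft) -
#' mean(spheroid) are thresholded at `delta` (log2 units):
#' \itemize{
#'   \item both steps > delta: `increasing`
#'   \item both steps < -delta: `decreasing`
#'   \item step1 > delta, |step2| <= delta: `increase_then_plateau`
#'   \item step1 < -delta, |step2| <= delta: `decrease_then_plateau`
#'   \item otherwise: `none`
#' }
#' Genes in any category but `none` show a "characteristic" monotone or
#' saturating trajectory from monolayer through spheroid to xenograft; their
#' fraction is reported as attribute `characteristic_fraction`.
#'
#' @param m expression matrix over the genes to classify.
#' @param meta sample metadata covering the three in vitro/in vivo systems.
#' @param delta step threshold in log2 units (default 0.25).
#' @return data.frame of class `pattern_call` with per-gene system means,
#'   steps and `category`.
#' @export
pattern_classify <- function(m, meta, delta = 0.25) {
  if (delta < 0) stop("delta must be >= 0")
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  systems <- c("monolayer2D", "spheroid", "xenograft")
  missing <- setdiff(systems, unique(meta$model_system))
  if (length(missing))
    stop("missing model system(s): ", paste(missing, collapse = ", "))
  x <- unclass(m)
  mu <- vapply(systems, function(s)
    rowMeans(x[, meta$model_system == s, drop = FALSE]), numeric(nrow(x)))
  if (nrow(x) == 1) mu <- matrix(mu, nrow = 1, dimnames = list(rownames(x), systems))
  step1 <- mu[, "spheroid"] - mu[, "monolayer2D"]
  step2 <- mu[, "xenograft"] - mu[, "spheroid"]
  category <- rep("none", nrow(x))
  category[step1 >  delta & step2 >  delta] <- "increasing"
  category[step1 < -delta & step2 < -delta] <- "decreasing"
  category[step1 >  delta & abs(step2) <= delta] <- "increase_then_plateau"
  category[step1 < -delta & abs(step2) <= delta] <- "decrease_then_plateau"
  res <- data.frame(gene = rownames(x),
                    mean_2D = mu[, "monolayer2D"],
                    mean_spheroid = mu[, "spheroid"],
                    mean_xenograft = mu[, "xenograft"],
                    step1 = step1, step2 = step2,
                    category = category,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "characteristic_fraction") <- mean(category != "none")
  class(res) <- c("pattern_call", "data.frame")
  res
}

#' @export
print.pattern_call <- function(x, ...) {
  tab <- table(factor(x$category,
                      c("increasing", "decreasing", "increase_then_plateau",
                        "decrease_then_plateau", "none")))
  cat("expression-pattern taxonomy over", nrow(x), "genes:\n")
  print(tab)
  cat(sprintf("characteristic fraction: %.1f%%\n",
              100 * attr(x, "characteristic_fraction")))
  invisible(x)
}

#' Pearson similarity of model systems per cell line
#'
#' For each cell line the per-system mean profile over a gene set is formed
#' and the Pearson correlations r(spheroid, xenograft) and r(2D, xenograft)
#' are computed. The verdict states which in vitro system resembles the
#' xenograft more closely.
#'
#' @param m expression matrix.
#' @param meta sample metadata with `cell_line` and `model_system`.
#' @param genes feature ids defining the profile (default all rows).
#' @return data.frame of class `similarity_report` with per-line
#'   `r_spheroid_xeno`, `r_2D_xeno` and `closer` verdict.
#' @export
model_similarity <- function(m, meta, genes = rownames(m)) {
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  genes <- intersect(genes, rownames(m))
  if (length(genes) < 3) stop("need at least 3 genes for a correlation")
  x <- unclass(m)[genes, , drop = FALSE]
  lines <- unique(meta$cell_line[meta$model_system %in%
                                   c("monolayer2D", "spheroid", "xenograft")])
  rows <- lapply(lines, function(cl) {
    prof <- vapply(c("monolayer2D", "spheroid", "xenograft"), function(s) {
      sel <- meta$cell_line == cl & meta$model_system == s
      if (!any(sel)) return(rep(NA_real_, length(genes)))
      rowMeans(x[, sel, drop = FALSE])
    }, numeric(length(genes)))
    if (anyNA(prof)) return(NULL)
    if (any(apply(prof, 2, stats::sd) == 0))
      stop("constant profile for cell line ", cl)
    r_sx <- stats::cor(prof[, "spheroid"], prof[, "xenograft"])
    r_2x <- stats::cor(prof[, "monolayer2D"], prof[, "xenograft"])
    data.frame(cell_line = cl, r_spheroid_xeno = r_sx, r_2D_xeno = r_2x,
               closer = ifelse(r_sx > r_2x, "spheroid", "monolayer2D"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("similarity_report", "data.frame")
  res
}

#' Hierarchical clustering of samples (and genes) with newick export
#'
#' Agglomerative clustering with 1 - Pearson correlation distance and
#' average linkage by default (both configurable); the gene dendrogram is
#' computed over the same distance among gene rows. Leaf order is made
#' deterministic by ordering each merge's subtrees by their smallest member
#' id.
#'
#' @param m expression matrix.
#' @param genes feature ids to cluster on (default all).
#' @param distance `"pearson"` (1 - r) or `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @param cluster_genes also cluster the gene rows (default TRUE).
#' @return list of class `expr_clustering` with `sample_hclust`,
#'   `gene_hclust` (or NULL), `ordered` (the reordered matrix) and
#'   `newick` (sample dendrogram as newick text via [ape::write.tree()]).
#' @export
hierarchical_cluster <- function(m, genes = rownames(m),
                                 distance = c("pearson", "euclidean"),
                                 linkage = "average", cluster_genes = TRUE) {
  distance <- match.arg(distance)
  genes <- intersect(genes, rownames(m))
  x <- unclass(m)[genes, , drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 samples")
  if (anyNA(x)) stop("NA values among the selected genes")
  dfun <- function(mat) {
    if (distance == "pearson") stats::as.dist(1 - stats::cor(t(mat)))
    else stats::dist(mat)
  }
  hc_s <- stats::hclust(dfun(t(x)), method = linkage)
  hc_s <- stable_leaf_order(hc_s)
  hc_g <- NULL
  if (cluster_genes && nrow(x) >= 2) {
    hc_g <- stable_leaf_order(stats::hclust(dfun(x), method = linkage))
  }
  ordered <- x[if (is.null(hc_g)) seq_len(nrow(x)) else hc_g$order,
               hc_s$order, drop = FALSE]
  structure(list(sample_hclust = hc_s, gene_hclust = hc_g,
                 ordered = ordered,
                 newick = ape::write.tree(ape::as.phylo(hc_s))),
            class = "expr_clustering")
}

# Reorder an hclust so that at every merge the subtree containing the
# lexicographically smallest label comes first; removes platform-dependent
# tie ambiguity in leaf order.
stable_leaf_order <- function(hc) {
  n <- length(hc$labels)
  min_lab <- character(nrow(hc$merge))
  subtree <- vector("list", nrow(hc$merge))
  merge <- hc$merge
  for (i in seq_len(nrow(merge))) {
    pick <- function(j) {
      if (j < 0) list(lab = hc$labels[-j], ord = -j)
      else list(lab = min_lab[j], ord = subtree[[j]])
    }
    a <- pick(merge[i, 1]); b <- pick(merge[i, 2])
    if (a$lab <= b$lab) {
      subtree[[i]] <- c(a$ord, b$ord); min_lab[i] <- a$lab
    } else {
      subtree[[i]] <- c(b$ord, a$ord); min_lab[i] <- b$lab
      merge[i, ] <- merge[i, 2:1]
    }
  }
  hc$merge <- merge
  hc$order <- subtree[[nrow(merge)]]
  hc
}

#' @export
print.expr_clustering <- function(x, ...) {
  cat(sprintf("hierarchical clustering: %d samples, %d genes\n",
              ncol(x$ordered), nrow(x$ordered)))
  cat("sample leaf order:",
      paste(x$sample_hclust$labels[x$sample_hclust$order], collapse = " "),
      "\n")
  invisible(x)
}

#' @export
plot.expr_clustering <- function(x, ...) {
  plot(x$sample_hclust, ...)
  invisible(x)
}

#' Rank genes by two-group fold change
#'
#' Per gene, log2FC = mean(group A) - mean(group B) on the log2 data, with
#' the linear fold change 2^log2FC alongside; genes are sorted by descending
#' log2FC (ties broken by gene id). This is the screen used to nominate
#' resistance markers such as CAV1 from resistant-versus-sensitive model
#' comparisons.
#'
#' @param m expression matrix.
#' @param meta sample metadata with a `group` column.
#' @param group_a,group_b group labels (A - B orientation).
#' @return data.frame of class `marker_ranking`: `gene`, `log2fc`, `fold`,
#'   `rank`.
#' @export
rank_two_group_markers <- function(m, meta, group_a, group_b) {
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  sel_a <- !is.na(meta$group) & meta$group == group_a
  sel_b <- !is.na(meta$group) & meta$group == group_b
  if (!any(sel_a)) stop("no samples in group '", group_a, "'")
  if (!any(sel_b)) stop("no samples in group '", group_b, "'")
  x <- unclass(m)
  lfc <- rowMeans(x[, sel_a, drop = FALSE]) -
    rowMeans(x[, sel_b, drop = FALSE])
  ord <- order(-lfc, rownames(x), method = "radix")
  res <- data.frame(gene = rownames(x)[ord], log2fc = lfc[ord],
                    fold = 2^lfc[ord], rank = seq_along(ord),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("marker_ranking", "data.frame")
  res
}

#' @export
print.marker_ranking <- function(x, ...) {
  cat("two-group marker ranking, top genes:\n")
  print.data.frame(utils::head(x, 5))
  invisible(x)
}
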
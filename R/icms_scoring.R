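#' Sample-wise quantile ranks of a gene-level expression matrix
#'
#' Within each sample (column), genes are ranked ascending with average ranks
#' on ties, and ranks are divided by the number of genes, giving values in
#' (0, 1]. This convention keeps every class mean strictly positive, so the
#' ratio score below is always defined. Ranks depend only on the ordering of
#' expression values, so any strictly increasing per-sample transform of the
#' data leaves them unchanged.
#'
#' @param m gene-level `expr_matrix` (any named numeric matrix is accepted).
#' @return matrix of the same shape and dimnames with quantile ranks.
#' @export
quantile_ranks <- function(m) {
  if (nrow(m) < 2)
    stop("quantile ranks need at least 2 genes")
  if (!all(is.finite(m))) stop("non-finite expression values")
  q <- apply(unclass(m), 2, function(x) rank(x, ties.method = "average")) /
    nrow(m)
  dimnames(q) <- dimnames(m)
  q
}

#' iCMS2/iCMS3 scores from quantile ranks
#'
#' For each sample the quantile ranks are summarized over the four marker
#' classes as means (Mq2U, Mq2D, Mq3U, Mq3D) and sums (Sq2U, Sq2D, Sq3U,
#' Sq3D), computed over the genes of each class present in the matrix. Two
#' scores are derived:
#' \deqn{A = Mq2U/Mq2D - Mq3U/Mq3D}
#' \deqn{B = (Sq2U - Sq2D) - (Sq3U - Sq3D)}
#' Positive values of either score point to the iCMS2 epithelial state,
#' negative to iCMS3. Each score yields a call by sign; the consensus is the
#' shared call when both agree and `"discordant"` otherwise. A score of
#' exactly zero carries no class evidence: the consensus is forced to
#' `"discordant"` and flagged in the `zero_score` column.
#'
#' Score B is computed on raw rank sums exactly as defined, which makes it
#' scale with class sizes when the four classes differ in size;
#' `normalize_b = TRUE` divides each sum by its class size instead.
#'
#' @param q quantile-rank matrix from [quantile_ranks()] (genes x samples).
#' @param sets `icms_gene_sets` from [read_gmt()] (or a compatible named
#'   list with elements iCMS2_up, iCMS2_down, iCMS3_up, iCMS3_down).
#' @param normalize_b divide rank sums by class size before forming score B
#'   (default `FALSE`: raw sums).
#' @return data.frame of class `icms_scores`: one row per sample with the
#'   Mq/Sq summaries, `n_*` genes used per class, `score_A`, `score_B`,
#'   `call_A`, `call_B`, `consensus`, `zero_score`. Per-class coverage
#'   fractions are attached as attribute `coverage`.
#' @export
icms_scores <- function(q, sets, normalize_b = FALSE) {
  cls <- c(iCMS2_up = "2U", iCMS2_down = "2D",
           iCMS3_up = "3U", iCMS3_down = "3D")
  used <- coverage <- list()
  for (nm in names(cls)) {
    genes <- intersect(sets[[nm]], rownames(q))
    if (!length(genes))
      stop("no gene of class ", nm, " is present in the matrix")
    used[[cls[nm]]] <- genes
    coverage[[cls[nm]]] <- length(genes) / length(sets[[nm]])
  }
  Mq <- lapply(used, function(g) colMeans(q[g, , drop = FALSE]))
  Sq <- lapply(used, function(g) colSums(q[g, , drop = FALSE]))
  n  <- lengths(used)
  score_A <- Mq$`2U` / Mq$`2D` - Mq$`3U` / Mq$`3D`
  if (normalize_b) {
    score_B <- (Sq$`2U` / n["2U"] - Sq$`2D` / n["2D"]) -
      (Sq$`3U` / n["3U"] - Sq$`3D` / n["3D"])
  } else {
    score_B <- (Sq$`2U` - Sq$`2D`) - (Sq$`3U` - Sq$`3D`)
  }
  call_A <- ifelse(score_A > 0, "iCMS2", "iCMS3")
  call_B <- ifelse(score_B > 0, "iCMS2", "iCMS3")
  zero <- score_A == 0 | score_B == 0
  consensus <- ifelse(!zero & call_A == call_B, call_A, "discordant")
  res <- data.frame(
    sample_id = colnames(q),
    Mq2U = Mq$`2U`, Mq2D = Mq$`2D`, Mq3U = Mq$`3U`, Mq3D = Mq$`3D`,
    Sq2U = Sq$`2U`, Sq2D = Sq$`2D`, Sq3U = Sq$`3U`, Sq3D = Sq$`3D`,
    n_2U = n[["2U"]], n_2D = n[["2D"]], n_3U = n[["3U"]], n_3D = n[["3D"]],
    score_A = score_A, score_B = score_B,
    call_A = call_A, call_B = call_B,
    consensus = consensus, zero_score = zero,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "coverage") <- unlist(coverage)
  class(res) <- c("icms_scores", "data.frame")
  res
}

#' @export
print.icms_scores <- function(x, ...) {
  cat(sprintf("iCMS scoring of %d sample(s)\n", nrow(x)))
  tab <- table(factor(x$consensus, c("iCMS2", "iCMS3", "discordant")))
  cat("consensus calls: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  print.data.frame(utils::head(
    x[, c("sample_id", "score_A", "score_B", "consensus")], 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more)\n", sep = "")
  invisible(x)
}

#' Score a whole cohort from a gene-level expression matrix
#'
#' Convenience composition of [quantile_ranks()] and [icms_scores()].
#'
#' @inheritParams icms_scores
#' @param m gene-level expression matrix (log2 scale).
#' @return an `icms_scores` data.frame, one row per sample.
#' @export
score_cohort <- function(m, sets, normalize_b = FALSE) {
  icms_scores(quantile_ranks(m), sets, normalize_b = normalize_b)
}
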
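#' Build indicator templates for nearest-template prediction
#'
#' The template space is the union of the four iCMS marker classes
#' intersected with the matrix genes, in deterministic lexicographic (C
#' locale) order. Each class contributes a 0/1 indicator vector over that
#' union.
#'
#' @param sets `icms_gene_sets`.
#' @param m gene-level expression matrix.
#' @return list with `union_genes` and `templates` (named list of indicator
#'   vectors `2U`, `2D`, `3U`, `3D`).
#' @export
build_templates <- function(sets, m) {
  cls <- c(iCMS2_up = "2U", iCMS2_down = "2D",
           iCMS3_up = "3U", iCMS3_down = "3D")
  present <- lapply(sets[names(cls)], intersect, y = rownames(m))
  empty <- names(cls)[lengths(present) == 0]
  if (length(empty))
    stop("class(es) with no gene in the matrix: ",
         paste(empty, collapse = ", "))
  union_genes <- sort(unique(unlist(present, use.names = FALSE)),
                      method = "radix")
  templates <- lapply(present, function(g) as.numeric(union_genes %in% g))
  names(templates) <- cls[names(templates)]
  list(union_genes = union_genes, templates = templates)
}

#' Cosine distance between a sample profile and a template
#'
#' The profile is mean-centered over the template genes by default (so the
#' distance is invariant under additive shifts of the sample's overall
#' expression level) and the cosine distance d = 1 - cos(x, t) is returned,
#' lying in [0, 2]. A Euclidean alternative (on the unit-normalized profile)
#' is available.
#'
#' @param x numeric expression vector over the union genes.
#' @param t template indicator vector of equal length.
#' @param center mean-center `x` first (default TRUE).
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @return a single distance.
#' @export
sample_distance <- function(x, t, center = TRUE,
                            metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  if (length(x) != length(t)) stop("profile and template lengths differ")
  if (center) x <- x - mean(x)
  nx <- sqrt(sum(x^2))
  if (nx == 0) stop("constant profile: zero norm after centering")
  if (metric == "cosine") {
    nt <- sqrt(sum(t^2))
    1 - sum(x * t) / (nx * nt)
  } else {
    sqrt(sum((x / nx - t / sqrt(sum(t^2)))^2))
  }
}

#' iCMS call from the four template distances
#'
#' Decision rule: `D2U < D2D` and `D3U > D3D` gives iCMS2; `D2U > D2D` and
#' `D3U < D3D` gives iCMS3; every other constellation - including any
#' equality - is `unstable`. The source procedure prints the second operand
#' of each rule as "D3U" compared against itself, an evident typo read here
#' as D3D; the inequalities are strict, so ties never produce a class call.
#'
#' @param d2u,d2d,d3u,d3d distances to the iCMS2_up, iCMS2_down, iCMS3_up and
#'   iCMS3_down templates.
#' @return `"iCMS2"`, `"iCMS3"` or `"unstable"` (vectorized).
#' @export
ntp_call <- function(d2u, d2d, d3u, d3d) {
  stopifnot(all(is.finite(c(d2u, d2d, d3u, d3d))))
  ifelse(d2u < d2d & d3u > d3d, "iCMS2",
         ifelse(d2u > d2d & d3u < d3d, "iCMS3", "unstable"))
}

#' Nearest-template prediction over a cohort
#'
#' Computes, for each sample, the distance of its (centered) profile over the
#' union marker genes to each of the four class templates, and applies the
#' [ntp_call()] decision rule. When an `icms_scores` result is supplied the
#' agreement rate between the NTP call and the score consensus is attached.
#'
#' @param m gene-level expression matrix.
#' @param sets `icms_gene_sets`.
#' @param scores optional `icms_scores` result for the same samples.
#' @inheritParams sample_distance
#' @return data.frame of class `ntp_result` with columns `sample_id`, `D2U`,
#'   `D2D`, `D3U`, `D3D`, `call`; attribute `agreement` (fraction of samples
#'   where the NTP call equals the score consensus, over samples where both
#'   made a class call) when `scores` is given.
#' @export
ntp_cohort <- function(m, sets, scores = NULL, center = TRUE,
                       metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  tpl <- build_templates(sets, m)
  sub <- unclass(m)[tpl$union_genes, , drop = FALSE]
  D <- vapply(colnames(sub), function(s) {
    x <- sub[, s]
    vapply(tpl$templates, function(t)
      sample_distance(x, t, center = center, metric = metric), numeric(1))
  }, numeric(4))
  res <- data.frame(sample_id = colnames(sub),
                    D2U = D["2U", ], D2D = D["2D", ],
                    D3U = D["3U", ], D3D = D["3D", ],
                    row.names = NULL, stringsAsFactors = FALSE)
  res$call <- ntp_call(res$D2U, res$D2D, res$D3U, res$D3D)
  if (!is.null(scores)) {
    merged <- merge(res[, c("sample_id", "call")],
                    scores[, c("sample_id", "consensus")], by = "sample_id")
    both <- merged$call != "unstable" & merged$consensus != "discordant"
    attr(res, "agreement") <-
      if (any(both)) mean(merged$call[both] == merged$consensus[both]) else NA_real_
  }
  class(res) <- c("ntp_result", "data.frame")
  res
}

#' @export
print.ntp_result <- function(x, ...) {
  cat(sprintf("nearest-template prediction, %d sample(s)\n", nrow(x)))
  tab <- table(factor(x$call, c("iCMS2", "iCMS3", "unstable")))
  cat("calls: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (!is.null(attr(x, "agreement")))
    cat(sprintf("agreement with score consensus: %.3f\n",
                attr(x, "agreement")))
  invisible(x)
}
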
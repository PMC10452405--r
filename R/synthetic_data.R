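#' Simulate an expression cohort with planted iCMS structure
#'
#' Generates a gene-level log2 expression matrix of
#' `baseline + planted shift + N(0, sigma^2)`. Genes are partitioned into the
#' four iCMS marker classes plus unrelated background genes. A sample planted
#' as iCMS2 receives `+delta` on the iCMS2_up genes and `-delta` on the
#' iCMS2_down genes; an iCMS3 sample the analogue on the iCMS3 classes. The
#' noise is Gaussian on the log2 scale, emulating RMA-normalized microarray
#' intensities; the defaults (`delta = 1`, `sigma = 0.5`) give a clearly
#' recoverable but non-trivial separation.
#'
#' @param n_genes total genes (marker classes carved out of the front).
#' @param class_size genes per marker class (recycled to length 4:
#'   iCMS2_up, iCMS2_down, iCMS3_up, iCMS3_down).
#' @param n_per_label samples per planted label, `c(iCMS2, iCMS3)` (recycled).
#' @param delta planted log2 shift (>= 0).
#' @param sigma log2 noise SD (> 0).
#' @param baseline baseline log2 mean.
#' @param seed RNG seed.
#' @return list with `matrix` (an [expression_matrix()] at gene level),
#'   `labels` (named character vector of planted labels) and `sets` (the
#'   matching `icms_gene_sets`).
#' @export
simulate_cohort <- function(n_genes = 500, class_size = 40,
                            n_per_label = 100, delta = 1, sigma = 0.5,
                            baseline = 8, seed = 1) {
  stopifnot(delta >= 0, sigma > 0)
  class_size <- rep_len(class_size, 4)
  n_per_label <- rep_len(n_per_label, 2)
  if (sum(class_size) > n_genes)
    stop("marker classes do not fit into n_genes")
  set.seed(seed)
  cls_names <- c("iCMS2_up", "iCMS2_down", "iCMS3_up", "iCMS3_down")
  tags <- c("g2u", "g2d", "g3u", "g3d")
  sets <- lapply(seq_len(4), function(i)
    sprintf("%s_%03d", tags[i], seq_len(class_size[i])))
  names(sets) <- cls_names
  genes <- c(unlist(sets, use.names = FALSE),
             sprintf("bg_%04d", seq_len(n_genes - sum(class_size))))
  n_samples <- sum(n_per_label)
  labels <- rep(c("iCMS2", "iCMS3"), n_per_label)
  samples <- sprintf("s%03d_%s", seq_len(n_samples), labels)
  x <- matrix(stats::rnorm(n_genes * n_samples, baseline, sigma),
              nrow = n_genes, dimnames = list(genes, samples))
  shift <- matrix(0, n_genes, n_samples)
  rownames(shift) <- genes
  is2 <- labels == "iCMS2"
  shift[sets$iCMS2_up, is2] <- delta
  shift[sets$iCMS2_down, is2] <- -delta
  shift[sets$iCMS3_up, !is2] <- delta
  shift[sets$iCMS3_down, !is2] <- -delta
  names(labels) <- samples
  list(matrix = expression_matrix(x + shift, feature_level = "gene"),
       labels = labels,
       sets = structure(sets, class = "icms_gene_sets"))
}

#' Simulate a model-system cohort with planted expression patterns
#'
#' Emulates the 2D-monolayer / spheroid / xenograft design: a panel of cell
#' lines, each measured in the three systems, with genes planted in the five
#' trajectory categories of [pattern_classify()]. The default composition -
#' 64 increasing, 25 decreasing, 3 increase-then-plateau, 18
#' decrease-then-plateau and 42 unpatterned genes among 152 - mirrors the
#' taxonomy the pattern analysis is built for (characteristic fraction
#' 110/152). Pattern steps are shared across cell lines; cell lines differ by
#' a line-specific baseline offset per gene, which also makes the spheroid
#' profile sit between the 2D and xenograft profiles, as in the planted
#' "spheroid closer to xenograft" structure.
#'
#' @param counts named integer vector of planted genes per category
#'   (`increasing`, `decreasing`, `increase_then_plateau`,
#'   `decrease_then_plateau`, `none`).
#' @param step planted step size, log2 units (default 2).
#' @param n_cell_lines number of cell lines (default 10).
#' @param replicates samples per cell line and system (default 1).
#' @param sigma log2 noise SD; 0 gives noise-free data.
#' @param baseline baseline log2 mean.
#' @param seed RNG seed.
#' @return list with `matrix`, `meta` (sample metadata data.frame) and
#'   `categories` (named character vector of planted categories per gene).
#' @export
simulate_model_systems <- function(counts = c(increasing = 64,
                                              decreasing = 25,
                                              increase_then_plateau = 3,
                                              decrease_then_plateau = 18,
                                              none = 42),
                                   step = 2, n_cell_lines = 10,
                                   replicates = 1, sigma = 0.25,
                                   baseline = 8, seed = 1) {
  stopifnot(all(counts >= 0), step > 0, sigma >= 0)
  set.seed(seed)
  n_genes <- sum(counts)
  categories <- rep(names(counts), counts)
  genes <- sprintf("gene_%03d", seq_len(n_genes))
  names(categories) <- genes
  # per-system offsets per category; plateau step2 = 0
  sys_offset <- rbind(
    increasing            = c(0,  step,  2 * step),
    decreasing            = c(0, -step, -2 * step),
    increase_then_plateau = c(0,  step,  step),
    decrease_then_plateau = c(0, -step, -step),
    none                  = c(0, 0, 0))
  colnames(sys_offset) <- c("monolayer2D", "spheroid", "xenograft")
  lines <- sprintf("CL%02d", seq_len(n_cell_lines))
  meta <- expand.grid(replicate = seq_len(replicates),
                      model_system = colnames(sys_offset),
                      cell_line = lines, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_%s_r%d", meta$cell_line, meta$model_system,
                            meta$replicate)
  # line-specific per-gene baseline offsets (shared across that line's systems)
  line_base <- matrix(stats::rnorm(n_genes * n_cell_lines, 0, 1),
                      nrow = n_genes, dimnames = list(genes, lines))
  x <- matrix(NA_real_, n_genes, nrow(meta),
              dimnames = list(genes, meta$sample_id))
  for (i in seq_len(nrow(meta))) {
    mu <- baseline + line_base[, meta$cell_line[i]] +
      sys_offset[categories, meta$model_system[i]]
    noise <- if (sigma > 0) stats::rnorm(n_genes, 0, sigma) else 0
    x[, i] <- mu + noise
  }
  meta <- meta[, c("sample_id", "cell_line", "model_system", "replicate")]
  meta$group <- NA_character_
  list(matrix = expression_matrix(x, feature_level = "gene"),
       meta = meta, categories = categories)
}

#' Simulate a two-group cohort with a planted marker gene
#'
#' Emulates the resistant-versus-sensitive marker screen: background genes
#' with no group difference plus one marker gene shifted by `marker_lfc`
#' log2 units in the first group. The default shift of 8.64 log2 units
#' corresponds to a ~400-fold linear difference.
#'
#' @param n_genes background genes.
#' @param n_per_group samples per group.
#' @param marker_lfc planted log2 fold change of the marker gene.
#' @param marker_name id of the planted marker (default `"CAV1"`).
#' @param sigma log2 noise SD.
#' @param baseline baseline log2 mean.
#' @param groups labels, first is the shifted group.
#' @param seed RNG seed.
#' @return list with `matrix`, `meta` and `marker_name`.
#' @export
simulate_two_group <- function(n_genes = 200, n_per_group = 5,
                               marker_lfc = 8.64, marker_name = "CAV1",
                               sigma = 0.5, baseline = 8,
                               groups = c("resistant", "sensitive"),
                               seed = 1) {
  set.seed(seed)
  genes <- c(marker_name, sprintf("bg_%04d", seq_len(n_genes)))
  grp <- rep(groups, each = n_per_group)
  samples <- sprintf("x%02d_%s", seq_along(grp), grp)
  x <- matrix(stats::rnorm(length(genes) * length(grp), baseline, sigma),
              nrow = length(genes), dimnames = list(genes, samples))
  x[marker_name, grp == groups[1]] <-
    x[marker_name, grp == groups[1]] + marker_lfc
  meta <- data.frame(sample_id = samples, cell_line = samples,
                     model_system = "xenograft", group = grp,
                     stringsAsFactors = FALSE)
  list(matrix = expression_matrix(x, feature_level = "gene"), meta = meta,
       marker_name = marker_name)
}

#' Simulate a bioluminescence plate readout
#'
#' Generates the long-format plate table the dose-response stage consumes:
#' for each model and condition, a serial-dilution dose series (plus dose-0
#' controls) with endpoint signals `scale * 4PL(dose) * (1 + N(0, cv^2))`,
#' and a day-0 growth-linearity series over a seeded-cell dilution range
#' (default 150 to 20000 cells) with signal proportional to seeded cells.
#'
#' @param truth data.frame with one row per curve: `model_id`, `condition`,
#'   `top`, `bottom`, `hill`, `ic50` (uM). Default: one model, 2D IC50 0.08
#'   and spheroid IC50 0.49 uM - the magnitude of shift seen when a
#'   monolayer-sensitive line loses oxaliplatin response as spheroids.
#' @param top_dose highest dose, uM.
#' @param dilution serial dilution factor.
#' @param n_doses number of positive doses.
#' @param replicates replicate wells per dose (default 8 wells).
#' @param cv multiplicative noise coefficient of variation (default 0.05).
#' @param scale luminescence counts at full signal.
#' @param seeded_cells day-0 growth series of seeded cell amounts.
#' @param day endpoint day label (default 7).
#' @param seed RNG seed.
#' @return list with `plate` (long-format data.frame: `model_id`,
#'   `condition`, `dose_uM`, `replicate`, `day`, `signal`), `growth`
#'   (day-0 seeded-cells series: `model_id`, `cells`, `signal`) and `truth`.
#' @export
simulate_plate <- function(truth = data.frame(
                             model_id = "SW48",
                             condition = c("2D", "spheroid"),
                             top = 1, bottom = 0, hill = 1.2,
                             ic50 = c(0.08, 0.49),
                             stringsAsFactors = FALSE),
                           top_dose = 10, dilution = 3, n_doses = 8,
                           replicates = 8, cv = 0.05, scale = 1e5,
                           seeded_cells = c(150, 300, 500, 1500, 5000,
                                            10000, 20000),
                           day = 7, seed = 1) {
  stopifnot(cv >= 0, top_dose > 0, dilution > 1)
  set.seed(seed)
  doses <- c(0, top_dose / dilution^(seq_len(n_doses) - 1))
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    mu <- ifelse(doses == 0, tr$top,
                 pl4_response(doses, tr$top, tr$bottom, tr$hill,
                              log10(tr$ic50)))
    for (r in seq_len(replicates)) {
      noise <- if (cv > 0) stats::rnorm(length(doses), 0, cv) else 0
      rows[[length(rows) + 1]] <- data.frame(
        model_id = tr$model_id, condition = tr$condition,
        dose_uM = doses, replicate = r, day = day,
        signal = pmax(scale * mu * (1 + noise), 0),
        stringsAsFactors = FALSE)
    }
  }
  growth <- do.call(rbind, lapply(unique(truth$model_id), function(mid) {
    noise <- if (cv > 0) stats::rnorm(length(seeded_cells), 0, cv) else 0
    data.frame(model_id = mid, cells = seeded_cells,
               signal = pmax(scale / max(seeded_cells) * seeded_cells *
                               (1 + noise), 0),
               stringsAsFactors = FALSE)
  }))
  list(plate = do.call(rbind, rows), growth = growth, truth = truth)
}
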
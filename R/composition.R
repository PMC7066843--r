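#' Relative abundance (column-normalized) matrix
#'
#' @param mat Non-negative feature x sample matrix (e.g. from
#'   [taxon_biomass()], including its `"unassigned"` row).
#' @return Matrix whose columns sum to 1.
#' @export
relative_abundance <- function(mat) {
  stopifnot(is.matrix(mat))
  if (any(mat < 0)) stop("negative entries in abundance matrix", call. = FALSE)
  cs <- colSums(mat)
  if (any(cs == 0)) {
    stop(sprintf("all-zero sample column(s): %s",
                 paste(colnames(mat)[cs == 0], collapse = ", ")),
         call. = FALSE)
  }
  sweep(mat, 2L, cs, "/")
}

#' Per-individual log2 fold change versus control
#'
#' For every feature, individual, and compound:
#' `log2((x_drug + pseudocount) / (x_control + pseudocount))`, where
#' replicate wells are averaged within arm first. The default pseudocount is
#' half the smallest nonzero entry of the matrix, which keeps ratios defined
#' under left-censored missingness; with `pseudocount = 0`, a 0/0 ratio is
#' returned as `NA` and flagged.
#'
#' @param mat Feature x sample matrix.
#' @param design Sample design table.
#' @param pseudocount Non-negative pseudocount, or `NULL` for the default
#'   rule.
#' @return Long data frame: `feature`, `individual`, `compound`, `log2fc`,
#'   `undefined`.
#' @export
log2_fold_change_vs_control <- function(mat, design, pseudocount = NULL) {
  stopifnot(is.matrix(mat))
  design <- validate_design(design)
  design <- design[design$sample_id %in% colnames(mat), ]
  if (is.null(pseudocount)) {
    nz <- mat[mat > 0]
    pseudocount <- if (length(nz) > 0L) min(nz) / 2 else 0
  }
  stopifnot(pseudocount >= 0)
  ctrl <- design[design$is_control, ]
  drug <- design[!design$is_control, ]
  out <- list()
  for (ind in unique(design$individual)) {
    c_cols <- ctrl$sample_id[ctrl$individual == ind]
    if (length(c_cols) == 0L) next
    x_ctrl <- rowMeans(mat[, c_cols, drop = FALSE])
    for (cmp in unique(drug$compound[drug$individual == ind])) {
      d_cols <- drug$sample_id[drug$individual == ind & drug$compound == cmp]
      x_drug <- rowMeans(mat[, d_cols, drop = FALSE])
      undef <- (x_drug + pseudocount) == 0 | (x_ctrl + pseudocount) == 0
      l2 <- ifelse(undef, NA_real_,
                   log2((x_drug + pseudocount) / (x_ctrl + pseudocount)))
      out[[length(out) + 1L]] <- data.frame(
        feature = rownames(mat), individual = ind, compound = cmp,
        log2fc = l2, undefined = undef, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Wilcoxon rank-sum test
#'
#' Two-sample Mann-Whitney/Wilcoxon test: the p-value is exact (by
#' enumeration) when both groups have at most 8 observations and there are
#' no ties, and uses the normal approximation with tie and continuity
#' correction otherwise — the standard small-sample recipe for skewed,
#' non-normal LFQ-derived quantities.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param alternative `"two.sided"`, `"less"`, or `"greater"` (of `x`
#'   relative to `y`).
#' @return List with `statistic` (Mann-Whitney U of `x`), `p_value`, and
#'   `exact` (logical).
#' @export
rank_sum_test <- function(x, y, alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "less", "greater"))
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && length(x) <= 8L && length(y) <= 8L
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = use_exact,
                       correct = TRUE))
  p <- res$p.value
  # fully tied input degenerates the normal approximation (0/0); there is
  # no evidence of separation, so report p = 1
  if (is.na(p)) p <- 1
  list(statistic = unname(res$statistic), p_value = p, exact = use_exact)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_i = min_{j >= i} m p_(j) / j`, capped at 1 and
#' mapped back to input order. `NA` p-values propagate as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Bray-Curtis dissimilarity
#'
#' `sum(|x - y|) / sum(x + y)` for non-negative abundance vectors; 0 for
#' identical profiles, 1 for disjoint supports.
#'
#' @param x,y Non-negative numeric vectors of equal length, not both all
#'   zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) {
    stop("Bray-Curtis requires non-negative entries", call. = FALSE)
  }
  denom <- sum(x + y)
  if (denom == 0) stop("both vectors are all-zero", call. = FALSE)
  sum(abs(x - y)) / denom
}

#' Per-compound taxon differential test
#'
#' For each compound and each feature (taxon row), compares feature
#' intensities of all drug-treated samples against all control samples of
#' the same individuals by the Wilcoxon rank-sum test, then adjusts p-values
#' across features with Benjamini-Hochberg within each compound. Mean
#' per-individual log2 fold changes summarize direction and size.
#'
#' @param mat Feature x sample matrix (taxon biomass or function matrix).
#' @param design Sample design table.
#' @param alternative Test sidedness, per [rank_sum_test()]; `"less"` tests
#'   for depletion under drug.
#' @param pseudocount Passed to [log2_fold_change_vs_control()].
#' @param min_presence Minimum fraction of individuals in which a feature
#'   must be present (nonzero control intensity) to be tested; the standard
#'   report keeps features present in at least 80% of individuals.
#' @return Data frame: `feature`, `compound`, `mean_log2fc`, `statistic`,
#'   `p_value`, `q_value`, `direction`.
#' @export
taxon_differential <- function(mat, design, alternative = "two.sided",
                               pseudocount = NULL, min_presence = 0.8) {
  stopifnot(is.matrix(mat))
  design <- validate_design(design)
  design <- design[design$sample_id %in% colnames(mat), ]
  l2 <- log2_fold_change_vs_control(mat, design, pseudocount)
  ctrl <- design[design$is_control, ]
  n_ind <- length(unique(design$individual))
  # presence filter: nonzero in >= min_presence of individuals' controls
  ctrl_by_ind <- sapply(unique(design$individual), function(ind) {
    cols <- ctrl$sample_id[ctrl$individual == ind]
    rowSums(mat[, cols, drop = FALSE]) > 0
  })
  present <- rowMeans(ctrl_by_ind) >= min_presence
  features <- rownames(mat)[present & rownames(mat) != "unassigned"]

  out <- list()
  for (cmp in unique(design$compound[!design$is_control])) {
    d_cols <- design$sample_id[design$compound == cmp & !design$is_control]
    inds <- unique(design$individual[design$compound == cmp &
                                       !design$is_control])
    c_cols <- ctrl$sample_id[ctrl$individual %in% inds]
    stat <- p <- numeric(length(features))
    for (k in seq_along(features)) {
      tr <- rank_sum_test(mat[features[k], d_cols], mat[features[k], c_cols],
                          alternative)
      stat[k] <- tr$statistic
      p[k] <- tr$p_value
    }
    ml2 <- tapply(l2$log2fc[l2$compound == cmp],
                  l2$feature[l2$compound == cmp], mean, na.rm = TRUE)
    out[[cmp]] <- data.frame(
      feature = features, compound = cmp,
      mean_log2fc = as.numeric(ml2[features]),
      statistic = stat, p_value = p, q_value = bh_adjust(p),
      direction = ifelse(as.numeric(ml2[features]) >= 0, "up", "down"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bray-Curtis community-shift test per compound
#'
#' For each compound, computes the per-individual Bray-Curtis distance
#' between the drug-treated profile and the same individual's control
#' profile (on relative abundances; replicate wells averaged within arm),
#' then asks whether a compound's distance set is larger than a reference
#' distance distribution by a two-sided rank-sum test, BH-adjusted across
#' compounds.
#'
#' The reference set is (a) all control-vs-control replicate-pair distances
#' when the design has replicate controls, or otherwise (b) for each
#' compound, the pooled distances of all other compounds — so a compound
#' stands out only if it shifts the community more than the panel at large.
#'
#' @param mat Feature x sample matrix (taxon biomass or protein groups).
#' @param design Sample design table (>= 2 individuals).
#' @param reference `"auto"`, `"control_pairs"`, or `"pooled"`.
#' @return List with `distances` (long data frame: `individual`, `compound`,
#'   `distance`) and `test` (per compound: `median_distance`,
#'   `reference_median`, `p_value`, `q_value`).
#' @export
drug_shift_test <- function(mat, design,
                            reference = c("auto", "control_pairs", "pooled")) {
  reference <- match.arg(reference)
  stopifnot(is.matrix(mat))
  design <- validate_design(design)
  design <- design[design$sample_id %in% colnames(mat), ]
  if (length(unique(design$individual)) < 2L) {
    stop("need >= 2 individuals for the shift test", call. = FALSE)
  }
  rel <- relative_abundance(mat[, design$sample_id, drop = FALSE])
  ctrl <- design[design$is_control, ]
  drug <- design[!design$is_control, ]

  rows <- list()
  for (ind in unique(design$individual)) {
    c_cols <- ctrl$sample_id[ctrl$individual == ind]
    if (length(c_cols) == 0L) next
    c_prof <- rowMeans(rel[, c_cols, drop = FALSE])
    for (cmp in unique(drug$compound[drug$individual == ind])) {
      d_cols <- drug$sample_id[drug$individual == ind &
                                 drug$compound == cmp]
      d_prof <- rowMeans(rel[, d_cols, drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        individual = ind, compound = cmp,
        distance = bray_curtis(d_prof, c_prof), stringsAsFactors = FALSE)
    }
  }
  distances <- do.call(rbind, rows)

  has_ctrl_reps <- any(tapply(ctrl$sample_id, ctrl$individual, length) >= 2)
  use_pairs <- reference == "control_pairs" ||
    (reference == "auto" && has_ctrl_reps)
  if (use_pairs && !has_ctrl_reps) {
    stop("no replicate control samples; cannot build control-pair reference",
         call. = FALSE)
  }
  ref_pairs <- NULL
  if (use_pairs) {
    ref_pairs <- unlist(lapply(unique(ctrl$individual), function(ind) {
      cols <- ctrl$sample_id[ctrl$individual == ind]
      if (length(cols) < 2L) return(numeric(0))
      utils::combn(cols, 2L, function(pr) bray_curtis(rel[, pr[1]],
                                                      rel[, pr[2]]))
    }))
  }

  cmps <- unique(distances$compound)
  p <- med <- refmed <- numeric(length(cmps))
  for (k in seq_along(cmps)) {
    d <- distances$distance[distances$compound == cmps[k]]
    ref <- if (use_pairs) ref_pairs else
      distances$distance[distances$compound != cmps[k]]
    if (length(ref) == 0L) {
      stop("empty reference distance set for the shift test", call. = FALSE)
    }
    p[k] <- rank_sum_test(d, ref, "two.sided")$p_value
    med[k] <- stats::median(d)
    refmed[k] <- stats::median(ref)
  }
  test <- data.frame(compound = cmps, median_distance = med,
                     reference_median = refmed, p_value = p,
                     q_value = bh_adjust(p), stringsAsFactors = FALSE)
  list(distances = distances, test = test)
}
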
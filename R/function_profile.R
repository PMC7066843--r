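#' Long table to feature x sample matrix
#'
#' @param long Long quantification table with an id column, `sample_id` and
#'   `intensity`.
#' @param id Name of the feature id column (default `"group_id"`).
#' @param samples Optional sample order; samples without observations get an
#'   all-`fill` column.
#' @param fill Value for absent cells: 0 (summation semantics) or `NA`
#'   (missing semantics).
#' @return Numeric matrix features x samples.
#' @export
quant_matrix <- function(long, id = "group_id", samples = NULL, fill = 0) {
  require_columns(long, c(id, "sample_id", "intensity"), "`long`")
  mat <- tapply(long$intensity, list(long[[id]], long$sample_id), sum,
                default = fill)
  mat <- as.matrix(mat)
  if (!is.null(samples)) {
    extra <- setdiff(samples, colnames(mat))
    if (length(extra) > 0L) {
      mat <- cbind(mat, matrix(fill, nrow(mat), length(extra),
                               dimnames = list(NULL, extra)))
    }
    mat <- mat[, samples, drop = FALSE]
  }
  mat
}

#' Presence filter for protein groups
#'
#' A protein group is retained iff it is quantified (nonzero intensity in at
#' least one sample) in strictly more than `min_fraction` of the
#' individuals — the "appears in > 80% of the microbiomes" rule with its
#' strict inequality, so 4 of 5 individuals (exactly 80%) is removed.
#'
#' @param proteins Long protein-group table (`group_id`, `sample_id`,
#'   `intensity`).
#' @param design Sample design table.
#' @param min_fraction Presence threshold as a fraction of individuals
#'   (default 0.8).
#' @return The filtered long table (attribute `"retained"` holds the kept
#'   group ids).
#' @export
filter_protein_groups <- function(proteins, design, min_fraction = 0.8) {
  require_columns(proteins, c("group_id", "sample_id", "intensity"),
                  "`proteins`")
  design <- validate_design(design)
  stopifnot(min_fraction >= 0, min_fraction < 1)
  ind <- design$individual[match(proteins$sample_id, design$sample_id)]
  ok <- proteins$intensity > 0 & !is.na(ind)
  n_ind <- length(unique(design$individual))
  n_present <- tapply(ind[ok], proteins$group_id[ok],
                      function(x) length(unique(x)))
  keep_ids <- names(n_present)[n_present > min_fraction * n_ind]
  out <- proteins[proteins$group_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retained") <- keep_ids
  out
}

#' Log2 / quotient normalization
#'
#' Per cell `v = log2(x + pseudocount)`, then each sample (column) is
#' divided by its mean over features, so every sample's post-normalization
#' mean is exactly 1. This removes global per-sample intensity differences
#' while preserving within-sample feature structure.
#'
#' @param mat Non-negative feature x sample matrix.
#' @param pseudocount Non-negative pseudocount added before the log
#'   (default 1).
#' @return Normalized matrix.
#' @export
normalize_log_quotient <- function(mat, pseudocount = 1) {
  stopifnot(is.matrix(mat), pseudocount >= 0)
  if (any(mat < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  v <- log2(mat + pseudocount)
  m <- colMeans(v, na.rm = TRUE)
  if (any(m == 0 | !is.finite(m))) {
    stop("sample with zero or non-finite log-mean; cannot quotient-normalize",
         call. = FALSE)
  }
  sweep(v, 2L, m, "/")
}

#' Mean-impute missing cells within individual
#'
#' Empirical-Bayes batch adjustment needs a complete matrix; cells that are
#' `NA` after filtering are replaced by the feature's mean over the same
#' individual's samples (falling back to the feature's grand mean when an
#' individual has no observation at all). Imputed positions are returned so
#' downstream reports can flag them.
#'
#' @param mat Feature x sample matrix, possibly with `NA`s.
#' @param batch Batch (individual) label per column.
#' @return List with `mat` (complete) and `imputed` (logical matrix).
#' @export
impute_by_batch <- function(mat, batch) {
  stopifnot(is.matrix(mat), length(batch) == ncol(mat))
  imputed <- is.na(mat)
  if (!any(imputed)) return(list(mat = mat, imputed = imputed))
  grand <- rowMeans(mat, na.rm = TRUE)
  grand[!is.finite(grand)] <- 0
  for (b in unique(batch)) {
    cols <- which(batch == b)
    sub <- mat[, cols, drop = FALSE]
    bm <- rowMeans(sub, na.rm = TRUE)
    bm[!is.finite(bm)] <- grand[!is.finite(bm)]
    for (j in cols) {
      nas <- is.na(mat[, j])
      mat[nas, j] <- bm[nas]
    }
  }
  list(mat = mat, imputed = imputed)
}

#' Empirical-Bayes batch correction
#'
#' Location/scale batch adjustment of a (normalized) feature x sample
#' matrix across individual microbiomes: per-feature standardization,
#' batch-effect estimation, shrinkage through parametric normal /
#' inverse-gamma priors, and back-transformation, preserving per-feature
#' grand means. A single batch returns the input unchanged. Features whose
#' residual variance after batch-mean removal is numerically zero (the
#' pooled variance the standardization divides by) are adjusted by exact
#' batch-mean centering instead, which recovers pure location shifts
#' exactly.
#'
#' @param mat Complete feature x sample matrix (see [impute_by_batch()]).
#' @param batch Batch label per column; every batch needs >= 2 samples.
#' @param tol Variance threshold below which a feature is treated as
#'   location-only.
#' @return Adjusted matrix of the same shape.
#' @export
combat_adjust <- function(mat, batch, tol = 1e-10) {
  stopifnot(is.matrix(mat), length(batch) == ncol(mat))
  if (anyNA(mat)) {
    stop("matrix must be complete; impute first (impute_by_batch)",
         call. = FALSE)
  }
  batch <- as.character(batch)
  sizes <- table(batch)
  if (length(sizes) == 1L) return(mat)
  if (any(sizes < 2L)) {
    stop(sprintf("singleton batch(es): %s",
                 paste(names(sizes)[sizes < 2L], collapse = ", ")),
         call. = FALSE)
  }
  # per-feature batch means and pooled residual variance
  bm <- vapply(unique(batch), function(b)
    rowMeans(mat[, batch == b, drop = FALSE]), numeric(nrow(mat)))
  bm <- matrix(bm, nrow = nrow(mat),
               dimnames = list(rownames(mat), unique(batch)))
  resid <- mat - bm[, batch, drop = FALSE]
  v <- rowSums(resid^2) / ncol(mat)
  degenerate <- v < tol

  out <- mat
  if (any(degenerate)) {
    grand <- rowMeans(mat[degenerate, , drop = FALSE])
    out[degenerate, ] <- resid[degenerate, , drop = FALSE] + grand
  }
  if (any(!degenerate)) {
    sub <- mat[!degenerate, , drop = FALSE]
    adj <- tryCatch({
      out_txt <- utils::capture.output(
        res <- suppressMessages(sva::ComBat(dat = sub,
                                            batch = factor(batch))))
      res
    }, error = function(e) NULL)
    if (is.null(adj)) {
      # direct (non-EB) location/scale fallback for tiny feature sets
      sm <- vapply(unique(batch), function(b)
        rowMeans(sub[, batch == b, drop = FALSE]), numeric(nrow(sub)))
      sm <- matrix(sm, nrow = nrow(sub),
                   dimnames = list(rownames(sub), unique(batch)))
      adj <- sub - sm[, batch, drop = FALSE] + rowMeans(sub)
    }
    out[!degenerate, ] <- adj
  }
  out
}

#' Aggregate protein groups by functional annotation
#'
#' Sums member protein-group intensities into one feature per annotation
#' value at the requested level; groups without an annotation are pooled
#' into `"unannotated"`, so column totals are conserved at every level.
#'
#' @param mat Protein-group x sample matrix (rownames are group ids).
#' @param annotations Annotation map with `group_id` and the annotation
#'   columns (`cog_category`, `cog_id`, `ko_id`, `ec_id`).
#' @param level One of `"cog_category"`, `"cog_id"`, `"ko_id"`, `"ec_id"`.
#' @return Feature x sample matrix at the aggregation level.
#' @export
aggregate_by_annotation <- function(mat, annotations,
                                    level = c("cog_category", "cog_id",
                                              "ko_id", "ec_id")) {
  level <- match.arg(level)
  stopifnot(is.matrix(mat))
  require_columns(annotations, c("group_id", level), "`annotations`")
  lab <- annotations[[level]][match(rownames(mat), annotations$group_id)]
  lab[is.na(lab) | !nzchar(lab)] <- "unannotated"
  out <- rowsum(mat, group = lab, reorder = TRUE)
  as.matrix(out)
}

#' Differential features between drug and control
#'
#' Two modes mirroring the two screen designs. `"across_individuals"`
#' contrasts per-individual values (replicate wells averaged) of drug
#' versus control arms by the Wilcoxon rank-sum test — the cross-individual
#' screen readout. `"within_replicates"` contrasts replicate wells of one
#' individual by Welch's two-sample t-test on (already log-scale) values —
#' the personalized, replicate-culture readout. BH adjustment is applied
#' across features either way. When both arms are constant but different
#' (infinite-precision separation), the smallest representable p-value is
#' returned with a `degenerate` flag.
#'
#' @param mat Feature x sample matrix; for the replicate t-test mode the
#'   values are expected on the log scale (e.g. after
#'   [normalize_log_quotient()] or [combat_adjust()]).
#' @param design Sample design table.
#' @param compound Compound to contrast against control.
#' @param mode `"across_individuals"` or `"within_replicates"`.
#' @param individual Individual id (required for the replicate mode).
#' @param alternative Sidedness for the rank-sum mode.
#' @return Data frame: `feature`, `compound`, `mean_diff` (drug minus
#'   control mean), `statistic`, `p_value`, `q_value`, `direction`,
#'   `degenerate`.
#' @export
differential_features <- function(mat, design, compound,
                                  mode = c("across_individuals",
                                           "within_replicates"),
                                  individual = NULL,
                                  alternative = "two.sided") {
  mode <- match.arg(mode)
  stopifnot(is.matrix(mat))
  design <- validate_design(design)
  design <- design[design$sample_id %in% colnames(mat), ]

  if (mode == "across_individuals") {
    inds <- unique(design$individual[design$compound == compound])
    if (length(inds) < 2L) {
      stop("across-individuals mode needs >= 2 individuals", call. = FALSE)
    }
    d_val <- sapply(inds, function(ind) {
      cols <- design$sample_id[design$individual == ind &
                                 design$compound == compound]
      rowMeans(mat[, cols, drop = FALSE])
    })
    c_val <- sapply(inds, function(ind) {
      cols <- design$sample_id[design$individual == ind & design$is_control]
      rowMeans(mat[, cols, drop = FALSE])
    })
    d_val <- matrix(d_val, nrow = nrow(mat))
    c_val <- matrix(c_val, nrow = nrow(mat))
  } else {
    if (is.null(individual)) {
      stop("replicate mode needs `individual`", call. = FALSE)
    }
    d_cols <- design$sample_id[design$individual == individual &
                                 design$compound == compound]
    c_cols <- design$sample_id[design$individual == individual &
                                 design$is_control]
    if (length(d_cols) < 3L || length(c_cols) < 3L) {
      stop("replicate mode needs >= 3 replicates per arm", call. = FALSE)
    }
    d_val <- mat[, d_cols, drop = FALSE]
    c_val <- mat[, c_cols, drop = FALSE]
  }

  n <- nrow(mat)
  p <- stat <- numeric(n)
  degen <- logical(n)
  for (k in seq_len(n)) {
    x <- as.numeric(d_val[k, ])
    y <- as.numeric(c_val[k, ])
    if (mode == "across_individuals") {
      tr <- rank_sum_test(x, y, alternative)
      stat[k] <- tr$statistic
      p[k] <- tr$p_value
    } else {
      if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12) {
        if (abs(mean(x) - mean(y)) < 1e-12) {
          stat[k] <- 0; p[k] <- 1
        } else {
          stat[k] <- sign(mean(x) - mean(y)) * Inf
          p[k] <- .Machine$double.xmin
          degen[k] <- TRUE
        }
      } else {
        tt <- stats::t.test(x, y, var.equal = FALSE)
        stat[k] <- unname(tt$statistic)
        p[k] <- tt$p.value
      }
    }
  }
  md <- rowMeans(d_val) - rowMeans(c_val)
  data.frame(
    feature = rownames(mat), compound = compound, mean_diff = md,
    statistic = stat, p_value = p, q_value = bh_adjust(p),
    direction = ifelse(md >= 0, "up", "down"), degenerate = degen,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric enrichment test
#'
#' Tests each category for overrepresentation in a foreground id set
#' relative to a background (typically: differential protein groups versus
#' all quantified groups) by the hypergeometric upper tail, BH-adjusted
#' across categories. Categories absent from the background are excluded.
#'
#' @param foreground Ids of interest; must be a subset of `background`.
#' @param background Universe of ids.
#' @param categories Data frame with `id` and `category` (an id may carry
#'   several categories on separate rows: e.g. taxon, COG category, or
#'   taxon x COG pairs).
#' @return Data frame per category: `category`, `k` (foreground in
#'   category), `n` (foreground size), `K` (background in category), `N`
#'   (background size), `p_value`, `q_value`.
#' @export
enrichment_test <- function(foreground, background, categories) {
  require_columns(categories, c("id", "category"), "`categories`")
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of background", call. = FALSE)
  }
  cat_bg <- categories[categories$id %in% background, , drop = FALSE]
  cats <- unique(cat_bg$category)
  N <- length(background)
  n <- length(foreground)
  rows <- lapply(cats, function(cc) {
    ids <- unique(cat_bg$id[cat_bg$category == cc])
    K <- length(ids)
    k <- sum(foreground %in% ids)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cc, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}

#' Taxon x function distribution of differential features
#'
#' Cross-tabulates differential protein groups by phylum and COG category,
#' split by direction — the summary used to visualize which clades carry a
#' compound's functional response.
#'
#' @param differential Data frame with `feature` (group id) and `direction`
#'   (`"up"`/`"down"`).
#' @param annotations Annotation map with `group_id`, `phylum`,
#'   `cog_category`.
#' @return Data frame: `phylum`, `cog_category`, `direction`, `count`.
#' @export
taxon_function_distribution <- function(differential, annotations) {
  require_columns(differential, c("feature", "direction"), "`differential`")
  require_columns(annotations, c("group_id", "phylum", "cog_category"),
                  "`annotations`")
  idx <- match(differential$feature, annotations$group_id)
  df <- data.frame(
    phylum = annotations$phylum[idx],
    cog_category = annotations$cog_category[idx],
    direction = differential$direction,
    stringsAsFactors = FALSE)
  df <- df[!is.na(df$phylum), , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(phylum = character(0), cog_category = character(0),
                      direction = character(0), count = integer(0)))
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          by = df, FUN = sum)
  agg[order(agg$phylum, agg$cog_category, agg$direction), , drop = FALSE]
}
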
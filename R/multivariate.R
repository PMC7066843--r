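#' PLS-DA fit by NIPALS
#'
#' Two-class partial least-squares discriminant analysis: the class vector
#' is coded 0/1 and centered, X is column-centered, and components are
#' extracted iteratively (NIPALS) with deflation of X after each component.
#' Weight vectors are unit-norm, scores are mutually orthogonal, and the
#' decomposition is deterministic.
#'
#' @param X Samples x features numeric matrix.
#' @param y Binary class labels (factor, character, or 0/1); both classes
#'   must be present.
#' @param n_components Number of latent components (default 2); cannot
#'   exceed `min(n - 1, p)`.
#' @return Object of class `mp_plsda`: weights `W` (p x A), X-loadings `P`,
#'   Y-loadings `q`, scores `T`, per-component explained Y-variance `ssy`,
#'   centers, the training `r_squared`, and the regression coefficients used
#'   for prediction.
#' @export
plsda_fit <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  cls <- class_indicator(y)
  if (nrow(X) != length(cls)) stop("X and y sizes differ", call. = FALSE)
  stop_if_not_scalar_count(n_components, "n_components")
  max_a <- min(nrow(X) - 1L, ncol(X))
  if (n_components > max_a) {
    stop(sprintf("n_components = %d exceeds the feasible rank bound %d",
                 n_components, max_a), call. = FALSE)
  }
  x_center <- colMeans(X)
  y_center <- mean(cls)
  Xc <- sweep(X, 2L, x_center)
  yc <- cls - y_center

  p <- ncol(X)
  W <- P <- matrix(0, p, n_components,
                   dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, nrow(X), n_components)
  q <- ssy <- numeric(n_components)
  used <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # no covariance left to model
    w <- w / nw
    t_a <- as.numeric(Xc %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- as.numeric(crossprod(Xc, t_a)) / tt
    q_a <- sum(yc * t_a) / tt
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - q_a * t_a
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    q[a] <- q_a
    ssy[a] <- q_a^2 * tt
    used <- a
  }
  if (used == 0L) stop("no predictive structure: X'y is zero", call. = FALSE)
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  Tm <- Tm[, seq_len(used), drop = FALSE]
  q <- q[seq_len(used)]
  ssy <- ssy[seq_len(used)]
  # regression coefficients b = W (P'W)^-1 q for prediction on new samples
  beta <- W %*% solve(crossprod(P, W), q)
  fitted <- as.numeric(sweep(X, 2L, x_center) %*% beta) + y_center
  tss <- sum((cls - y_center)^2)
  r2 <- 1 - sum((cls - fitted)^2) / tss

  structure(
    list(W = W, P = P, q = q, scores = Tm, ssy = ssy,
         n_components = used, x_center = x_center, y_center = y_center,
         beta = beta, fitted = fitted, y = cls, r_squared = r2,
         levels = attr(cls, "levels")),
    class = "mp_plsda")
}

class_indicator <- function(y) {
  f <- factor(y)
  if (nlevels(f) != 2L) {
    stop("y must contain exactly two classes", call. = FALSE)
  }
  structure(as.numeric(f) - 1, levels = levels(f))
}

#' @export
print.mp_plsda <- function(x, ...) {
  cat(sprintf("mp_plsda: %d component(s), %d features, R2 = %.3f\n",
              x$n_components, nrow(x$W), x$r_squared))
  invisible(x)
}

#' Predict class scores from a PLS-DA model
#'
#' @param object An `mp_plsda` fit.
#' @param newdata Samples x features matrix with the training feature order.
#' @param ... Unused.
#' @return Numeric vector of predicted class scores (0/1 scale).
#' @export
predict.mp_plsda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.numeric(sweep(newdata, 2L, object$x_center) %*% object$beta) +
    object$y_center
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a ssy_a (w_ja)^2 / sum_a ssy_a)` with unit-norm
#' per-component weights, so `sum_j VIP_j^2 = p` for every fit. Features
#' with VIP > 1 are conventionally called differential.
#'
#' @param model An `mp_plsda` fit.
#' @return Named numeric vector of VIP scores per feature.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "mp_plsda"))
  if (sum(model$ssy) <= 0) {
    stop("model explains no Y-variance; VIP undefined", call. = FALSE)
  }
  p <- nrow(model$W)
  contrib <- model$W^2 %*% model$ssy / sum(model$ssy)
  v <- sqrt(p * as.numeric(contrib))
  stats::setNames(v, rownames(model$W))
}

#' Cross-validated R2 and Q2 of a PLS-DA model
#'
#' R2 comes from the full-data fit; Q2 = 1 - PRESS/TSS from held-out
#' predictions under leave-one-out (default, suited to the ~10-sample
#' per-compound contrasts) or seeded k-fold cross-validation. Folds whose
#' training split would lose a class are rejected (LOO keeps both classes
#' whenever each class has >= 2 samples).
#'
#' @param X Samples x features matrix.
#' @param y Binary class labels.
#' @param n_components Components for every fold.
#' @param folds `"loo"` or an integer number of folds.
#' @param seed Seed for the k-fold shuffle (ignored for LOO).
#' @return List with `r_squared`, `q_squared`, `press`, `n_components`.
#' @export
cross_validate_plsda <- function(X, y, n_components = 2, folds = "loo",
                                 seed = 1) {
  X <- as.matrix(X)
  cls <- class_indicator(y)
  n <- nrow(X)
  full <- plsda_fit(X, y, n_components)
  fold_of <- if (identical(folds, "loo")) {
    seq_len(n)
  } else {
    stop_if_not_scalar_count(folds, "folds")
    with_seed(seed, sample(rep_len(seq_len(folds), n)))
  }
  press <- 0
  for (f in unique(fold_of)) {
    test <- fold_of == f
    if (length(unique(cls[!test])) < 2L) {
      stop("a training split lost one class; use fewer folds", call. = FALSE)
    }
    a <- min(n_components, sum(!test) - 1L, ncol(X))
    fit <- plsda_fit(X[!test, , drop = FALSE], cls[!test], a)
    pred <- predict(fit, X[test, , drop = FALSE])
    press <- press + sum((cls[test] - pred)^2)
  }
  tss <- sum((cls - mean(cls))^2)
  list(r_squared = full$r_squared, q_squared = 1 - press / tss,
       press = press, n_components = full$n_components)
}

#' PerMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (Anderson's pseudo-F):
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` analogously per group,
#' `F = (SS_between / (a - 1)) / (SS_within / (n - a))`. The p-value is
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)` over seeded random label
#' permutations, so its floor with 999 permutations is 0.001; with
#' `exact = TRUE` all `n!` label permutations are enumerated instead and
#' the p-value is the exact proportion of permutations (including the
#' identity) with `F >= F_obs`.
#'
#' @param D Symmetric distance matrix (or `dist`) with zero diagonal.
#' @param groups Group label per sample (>= 2 groups).
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param exact Enumerate all permutations (only for small n; capped at
#'   n = 8).
#' @return Object of class `mp_permanova`: `f_statistic`, `ss_between`,
#'   `ss_within`, `ss_total`, `n_perm`, `p_value`, `seed`.
#' @export
permanova <- function(D, groups, n_perm = 999, seed = 1, exact = FALSE) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D))
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8 ||
      any(abs(diag(D)) > 1e-12)) {
    stop("D must be a symmetric distance matrix with zero diagonal",
         call. = FALSE)
  }
  groups <- as.character(groups)
  n <- nrow(D)
  stopifnot(length(groups) == n)
  a <- length(unique(groups))
  if (a < 2L) stop("need >= 2 groups", call. = FALSE)
  D2 <- D^2

  f_stat <- function(g) {
    ss_total <- sum(D2[upper.tri(D2)]) / n
    ss_within <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1L) {
        sub <- D2[idx, idx, drop = FALSE]
        ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    ss_between <- ss_total - ss_within
    c(F = (ss_between / (a - 1)) / (ss_within / (n - a)),
      ssb = ss_between, ssw = ss_within, sst = ss_total)
  }
  obs <- f_stat(groups)

  if (exact) {
    if (n > 8L) stop("exact enumeration limited to n <= 8", call. = FALSE)
    perms <- all_permutations(n)
    fs <- apply(perms, 1L, function(ix) f_stat(groups[ix])[["F"]])
    p <- mean(fs >= obs[["F"]] - 1e-12)
    n_perm <- nrow(perms)
  } else {
    stop_if_not_scalar_count(n_perm, "n_perm")
    fs <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      f_stat(groups[sample.int(n)])[["F"]]
    }, numeric(1)))
    p <- (1 + sum(fs >= obs[["F"]] - 1e-12)) / (1 + n_perm)
  }
  structure(
    list(f_statistic = unname(obs[["F"]]), ss_between = unname(obs[["ssb"]]),
         ss_within = unname(obs[["ssw"]]), ss_total = unname(obs[["sst"]]),
         n_perm = n_perm, p_value = p, seed = seed, exact = exact),
    class = "mp_permanova")
}

#' @export
print.mp_permanova <- function(x, ...) {
  cat(sprintf("PerMANOVA: pseudo-F = %.3f, p = %.4g (%s%d permutations)\n",
              x$f_statistic, x$p_value, if (x$exact) "all " else "",
              x$n_perm))
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)
    if (pos < n) {
      tmp <- block[, pos]
      block[, pos] <- n
      block[, n] <- tmp
    }
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Compound class call from multivariate metrics
#'
#' A compound is called class I — inducing a consistent, cross-individual
#' metaproteomic shift — when its cross-validated Q2 reaches the threshold
#' (boundary value included) OR its community-shift test is significant at
#' the FDR threshold; otherwise class II. The thresholds are conventional
#' chemometrics defaults and are fully configurable.
#'
#' @param q2 Cross-validated Q2 of the compound's PLS-DA model.
#' @param shift_q BH-adjusted p of the compound's Bray-Curtis shift test.
#' @param q2_threshold Default 0.4.
#' @param fdr_threshold Default 0.05.
#' @return List with `class` (`"I"` or `"II"`) and a human-readable
#'   `reason`.
#' @export
classify_compound <- function(q2, shift_q, q2_threshold = 0.4,
                              fdr_threshold = 0.05) {
  if (is.na(q2) || is.na(shift_q)) stop("missing metric", call. = FALSE)
  by_q2 <- q2 >= q2_threshold
  by_shift <- shift_q < fdr_threshold
  cls <- if (by_q2 || by_shift) "I" else "II"
  reason <- sprintf("Q2 = %.3f (threshold %.2f, %s); shift q = %.3g (threshold %.2f, %s)",
                    q2, q2_threshold, if (by_q2) "met" else "not met",
                    shift_q, fdr_threshold, if (by_shift) "met" else "not met")
  list(class = cls, reason = reason)
}
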
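# Independent reference implementations used to cross-check the package.
# These deliberately take different algorithmic routes than the package code.

# LCA via intersection of lineage prefix chains encoded as strings.
oracle_lca <- function(lineages) {
  ranks <- tax_ranks()
  chains <- lapply(seq_len(nrow(lineages)), function(i) {
    vals <- as.character(unlist(lineages[i, ranks]))
    depth <- which(is.na(vals))[1]
    depth <- if (is.na(depth)) length(vals) else depth - 1L
    if (depth == 0L) return(character(0))
    vapply(seq_len(depth), function(d)
      paste(vals[seq_len(d)], collapse = "\r"), character(1))
  })
  common <- Reduce(intersect, chains)
  out <- stats::setNames(rep(NA_character_, length(ranks)), ranks)
  if (length(common) > 0L) {
    deepest <- common[which.max(nchar(gsub("[^\r]", "", common)))]
    parts <- strsplit(deepest, "\r", fixed = TRUE)[[1]]
    out[seq_along(parts)] <- parts
  }
  out
}

# Exact Mann-Whitney p by full enumeration of group assignments (untied).
oracle_ranksum <- function(x, y, alternative = "two.sided") {
  u_stat <- function(a, b) sum(outer(a, b, ">"))
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2L, function(ii) u_stat(pooled[ii], pooled[-ii]))
  w <- u_stat(x, y)
  p_le <- mean(us <= w)
  p_ge <- mean(us >= w)
  switch(alternative,
         less = p_le,
         greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# Quadratic-time BH step-up.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    q[ord[i]] <- min(1, min(vals))
  }
  q
}

# Hypergeometric upper tail by direct combinatorial summation.
oracle_hyper <- function(k, K, N, n) {
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
}

# PerMANOVA pseudo-F via Gower-centered inner-product traces.
oracle_permanova_f <- function(D, groups) {
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  X <- stats::model.matrix(~ factor(groups))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  a <- length(unique(groups))
  ssb <- sum(diag(H %*% G %*% H))
  ssw <- sum(diag((diag(n) - H) %*% G %*% (diag(n) - H)))
  (ssb / (a - 1)) / (ssw / (n - a))
}

# All permutations of 1..n by simple recursion (insertion construction).
oracle_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  prev <- oracle_permutations(n - 1L)
  out <- NULL
  for (i in seq_len(nrow(prev))) {
    for (pos in seq_len(n)) {
      out <- rbind(out, append(prev[i, ], n, after = pos - 1L))
    }
  }
  out
}

# Two-class dataset with a controllable number of informative features.
sep_data <- function(n = 12, p = 30, n_sig = 5, gap = 3, sd = 0.3,
                     seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), each = n / 2)
    X <- matrix(stats::rnorm(n * p, sd = 1), n, p)
    X[, 1:n_sig] <- X[, 1:n_sig] * sd + gap * y
    colnames(X) <- sprintf("f%02d", 1:p)
    list(X = X, y = y)
  })
}

# Hand-built lineage database spanning two superkingdoms.
toy_lineage_db <- function() {
  data.frame(
    taxon_id = c("bf", "bv", "fp", "sc"),
    superkingdom = c("Bacteria", "Bacteria", "Bacteria", "Eukaryota"),
    phylum = c("Bacteroidetes", "Bacteroidetes", "Firmicutes", "Ascomycota"),
    class = c("Bacteroidia", "Bacteroidia", "Clostridia", "Saccharomycetes"),
    order = c("Bacteroidales", "Bacteroidales", "Eubacteriales",
              "Saccharomycetales"),
    family = c("Bacteroidaceae", "Bacteroidaceae", "Oscillospiraceae",
               "Saccharomycetaceae"),
    genus = c("Bacteroides", "Bacteroides", "Faecalibacterium",
              "Saccharomyces"),
    species = c("Bacteroides fragilis", "Bacteroides vulgatus",
                "Faecalibacterium prausnitzii", "Saccharomyces cerevisiae"),
    stringsAsFactors = FALSE)
}
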
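#' Lowest common ancestor of ranked lineages
#'
#' Computes the deepest taxonomy node shared by all input lineages on the
#' fixed seven-rank ladder: the result is the longest common prefix of the
#' lineages, rank by rank. Lineages that disagree already at superkingdom
#' return the root (all ranks `NA`).
#'
#' @param lineages A data frame or matrix whose columns include the seven
#'   ranks of [tax_ranks()], one row per candidate lineage. Entries below a
#'   lineage's assignment depth are `NA`.
#' @return Named character vector over the seven ranks; `NA` below the LCA
#'   depth.
#' @export
compute_lca <- function(lineages) {
  ranks <- tax_ranks()
  if (is.matrix(lineages)) lineages <- as.data.frame(lineages,
                                                     stringsAsFactors = FALSE)
  if (!is.data.frame(lineages) || nrow(lineages) == 0L) {
    stop("`lineages` must be a non-empty data frame of ranked lineages",
         call. = FALSE)
  }
  require_columns(lineages, ranks, "`lineages`")
  out <- stats::setNames(rep(NA_character_, length(ranks)), ranks)
  for (r in ranks) {
    v <- unique(as.character(lineages[[r]]))
    if (length(v) != 1L || is.na(v)) break
    out[[r]] <- v
  }
  out
}

lca_rank <- function(lca) {
  nn <- which(!is.na(lca))
  if (length(nn) == 0L) NA_character_ else tax_ranks()[max(nn)]
}

#' Assign peptides to their lowest common ancestor
#'
#' Every peptide carries a set of candidate taxa (the owners of the proteins
#' it could originate from); its taxonomic assignment is the LCA of their
#' lineages. Peptides with an empty candidate set are marked unassigned
#' (root).
#'
#' @param peptides Data frame with columns `peptide_id` and `taxa`
#'   (semicolon-separated candidate taxon ids); rows beyond the first per
#'   peptide id (e.g. a long quantification table) are collapsed.
#' @param lineage_db Data frame with `taxon_id` plus the seven rank columns.
#' @return Data frame with one row per peptide: `peptide_id`, the seven rank
#'   columns of the LCA lineage, and `lca_rank` (deepest assigned rank, `NA`
#'   when unassigned at every named rank).
#' @export
assign_peptides <- function(peptides, lineage_db) {
  ranks <- tax_ranks()
  require_columns(peptides, c("peptide_id", "taxa"), "`peptides`")
  require_columns(lineage_db, c("taxon_id", ranks), "`lineage_db`")
  up <- peptides[!duplicated(peptides$peptide_id), c("peptide_id", "taxa")]
  lin <- as.matrix(lineage_db[, ranks])
  rownames(lin) <- lineage_db$taxon_id

  cand <- strsplit(as.character(up$taxa), ";", fixed = TRUE)
  cand <- lapply(cand, function(x) x[nzchar(x)])
  all_ids <- unique(unlist(cand))
  unresolved <- setdiff(all_ids, lineage_db$taxon_id)
  if (length(unresolved) > 0L) {
    stop(sprintf("candidate taxon id(s) not in lineage database: %s",
                 paste(unresolved, collapse = ", ")), call. = FALSE)
  }

  # Collapse duplicate candidate sets: the LCA only depends on the set.
  key <- vapply(cand, function(x) paste(sort(x), collapse = ";"), character(1))
  uniq_keys <- unique(key)
  lca_by_key <- matrix(NA_character_, nrow = length(uniq_keys),
                       ncol = length(ranks),
                       dimnames = list(uniq_keys, ranks))
  for (k in uniq_keys) {
    ids <- strsplit(k, ";", fixed = TRUE)[[1]]
    if (length(ids) == 0L) next  # empty candidate set -> root
    sub <- lin[ids, , drop = FALSE]
    for (j in seq_along(ranks)) {
      v <- unique(sub[, j])
      if (length(v) != 1L || is.na(v)) break
      lca_by_key[k, j] <- v
    }
  }
  res <- lca_by_key[match(key, uniq_keys), , drop = FALSE]
  out <- data.frame(peptide_id = up$peptide_id, res,
                    stringsAsFactors = FALSE, row.names = NULL)
  depth <- apply(!is.na(res), 1L, function(z) if (any(z)) max(which(z)) else 0L)
  out$lca_rank <- ifelse(depth > 0L, ranks[pmax(depth, 1L)], NA_character_)
  out
}

#' Taxon biomass matrix at a chosen rank
#'
#' Sums peptide intensities per taxon at the requested rank: a peptide
#' contributes its full intensity to the taxon named at that rank in its LCA
#' lineage (i.e. its LCA is that taxon or below it). Peptides whose LCA lies
#' above the rank go into the `"unassigned"` row, so column sums equal the
#' total assigned peptide intensity of each sample at every rank, and no
#' intensity is split or double counted.
#'
#' @param peptides Long quantification table (`peptide_id`, `sample_id`,
#'   `intensity`); missing observations are absent rows and count as zero.
#' @param assignment Per-peptide LCA table from [assign_peptides()].
#' @param rank One of [tax_ranks()].
#' @return Numeric matrix, taxa (plus `"unassigned"`) x samples.
#' @export
taxon_biomass <- function(peptides, assignment, rank = "genus") {
  ranks <- tax_ranks()
  if (!rank %in% ranks) {
    stop(sprintf("unknown rank '%s'; must be one of: %s", rank,
                 paste(ranks, collapse = ", ")), call. = FALSE)
  }
  require_columns(peptides, c("peptide_id", "sample_id", "intensity"),
                  "`peptides`")
  lab <- assignment[[rank]][match(peptides$peptide_id,
                                  assignment$peptide_id)]
  lab[is.na(lab)] <- "unassigned"
  mat <- tapply(peptides$intensity,
                list(taxon = lab, sample = peptides$sample_id),
                sum, default = 0)
  mat <- as.matrix(mat)
  if (!"unassigned" %in% rownames(mat)) {
    mat <- rbind(mat, unassigned = 0)
  }
  # keep taxa alphabetical with the unassigned row last
  taxa <- sort(setdiff(rownames(mat), "unassigned"))
  mat[c(taxa, "unassigned"), , drop = FALSE]
}
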
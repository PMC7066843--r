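#' Generate a synthetic gut community model
#'
#' Builds a community of `n_taxa` species with realistic seven-rank lineages
#' (drawn from a fixed table of common gut genera, so congeneric species and
#' shared families/phyla occur naturally), a protein catalog with COG/KO/EC
#' annotations and per-taxon expression fractions, and a peptide catalog in
#' which a controllable fraction of peptides is shared between taxa that have
#' a genus or phylum in common (the substrate for lowest-common-ancestor
#' assignment).
#'
#' Baseline absolute abundances are log-normally distributed, reflecting the
#' orders-of-magnitude biomass differences between gut community members.
#' Expression fractions per taxon sum to one; peptide ionization factors are
#' log-normal, modelling peptide-specific MS response.
#'
#' @param n_taxa Number of species (>= 2).
#' @param n_proteins_per_taxon Proteins per species.
#' @param shared_peptide_fraction Target fraction of peptides whose candidate
#'   set spans >= 2 taxa; must be in `[0, 1)`. Sharing partners are restricted
#'   to taxa having at least a genus or phylum in common, so the realized
#'   fraction can fall slightly short when a taxon has no eligible partner.
#' @param n_peptides_per_protein Peptides per protein.
#' @param seed Integer seed; the same seed reproduces the community exactly.
#' @return An object of class `mp_community`: a list with data frames
#'   `taxa` (taxon_id, abundance, seven rank columns), `proteins`
#'   (protein_id, taxon_id, cog_id, cog_category, ko_id, ec_id,
#'   expression_fraction), `peptides` (peptide_id, ionization, shared,
#'   taxa — semicolon-joined candidate taxon ids) and `peptide_map`
#'   (peptide_id, protein_id).
#' @export
generate_community <- function(n_taxa,
                               n_proteins_per_taxon = 20,
                               shared_peptide_fraction = 0.2,
                               n_peptides_per_protein = 3,
                               seed = 1) {
  stop_if_not_scalar_count(n_taxa, "n_taxa")
  stop_if_not_scalar_count(n_proteins_per_taxon, "n_proteins_per_taxon")
  stop_if_not_scalar_count(n_peptides_per_protein, "n_peptides_per_protein")
  if (n_taxa < 2) stop("`n_taxa` must be >= 2", call. = FALSE)
  if (!is.numeric(shared_peptide_fraction) ||
      shared_peptide_fraction < 0 || shared_peptide_fraction >= 1) {
    stop("`shared_peptide_fraction` must be in [0, 1)", call. = FALSE)
  }

  with_seed(seed, {
    pool <- gut_genus_table()
    # Pick genera, then assign species to them with replacement so that some
    # genera carry several species (needed for genus-level LCA collapse).
    n_genera <- max(1L, min(nrow(pool), ceiling(0.7 * n_taxa)))
    genera <- pool[sample.int(nrow(pool), n_genera), , drop = FALSE]
    # every sampled genus carries >= 1 species; the surplus species land in
    # random genera, creating the congeneric pairs LCA collapse relies on
    genus_of_species <- c(seq_len(min(n_genera, n_taxa)),
                          if (n_taxa > n_genera)
                            sample.int(n_genera, n_taxa - n_genera,
                                       replace = TRUE))
    taxa <- genera[genus_of_species, , drop = FALSE]
    rownames(taxa) <- NULL
    sp_index <- stats::ave(seq_len(n_taxa), genus_of_species, FUN = seq_along)
    taxa$species <- sprintf("%s sp%02d", taxa$genus, sp_index)
    taxa$taxon_id <- sprintf("T%03d", seq_len(n_taxa))
    taxa$abundance <- stats::rlnorm(n_taxa, meanlog = log(1e7), sdlog = 1.5)
    taxa <- taxa[, c("taxon_id", "abundance", tax_ranks())]

    # Protein catalog: COG ids are drawn from a shared ortholog pool so that
    # the same COG recurs across taxa; each COG has one fixed category.
    n_cogs <- max(4L, ceiling(n_proteins_per_taxon * 3))
    cog_pool <- sprintf("COG%04d", sample.int(4000, n_cogs))
    cat_pool <- sample(cog_categories(), n_cogs, replace = TRUE)
    ko_pool <- ifelse(stats::runif(n_cogs) < 0.6,
                      sprintf("K%05d", sample.int(20000, n_cogs)), NA_character_)
    ec_pool <- ifelse(stats::runif(n_cogs) < 0.4,
                      sprintf("%d.%d.%d.%d",
                              sample(1:6, n_cogs, TRUE), sample(1:9, n_cogs, TRUE),
                              sample(1:9, n_cogs, TRUE), sample(1:99, n_cogs, TRUE)),
                      NA_character_)

    proteins <- do.call(rbind, lapply(seq_len(n_taxa), function(i) {
      idx <- sample.int(n_cogs, n_proteins_per_taxon,
                        replace = n_proteins_per_taxon > n_cogs)
      frac <- stats::rgamma(n_proteins_per_taxon, shape = 1)
      frac <- frac / sum(frac)
      data.frame(
        protein_id = sprintf("%s_P%02d", taxa$taxon_id[i],
                             seq_len(n_proteins_per_taxon)),
        taxon_id = taxa$taxon_id[i],
        cog_id = cog_pool[idx],
        cog_category = cat_pool[idx],
        ko_id = ko_pool[idx],
        ec_id = ec_pool[idx],
        expression_fraction = frac,
        stringsAsFactors = FALSE
      )
    }))
    rownames(proteins) <- NULL

    # Eligible sharing partners per taxon: same genus preferred, else same
    # phylum. Sharing probability is rescaled so the overall shared fraction
    # hits the target even when some taxa have no partner.
    same_genus <- outer(taxa$genus, taxa$genus, "==")
    same_phylum <- outer(taxa$phylum, taxa$phylum, "==")
    diag(same_genus) <- diag(same_phylum) <- FALSE
    eligible <- rowSums(same_genus | same_phylum) > 0

    n_pep_total <- nrow(proteins) * n_peptides_per_protein
    owner_taxon <- rep(proteins$taxon_id, each = n_peptides_per_protein)
    owner_protein <- rep(proteins$protein_id, each = n_peptides_per_protein)
    owner_row <- match(owner_taxon, taxa$taxon_id)
    frac_eligible <- mean(eligible[owner_row])
    p_share <- if (frac_eligible > 0) {
      min(0.95, shared_peptide_fraction / frac_eligible)
    } else 0

    share <- eligible[owner_row] & (stats::runif(n_pep_total) < p_share)
    partner_protein <- rep(NA_character_, n_pep_total)
    partner_taxon <- rep(NA_character_, n_pep_total)
    for (k in which(share)) {
      i <- owner_row[k]
      cand <- which(same_genus[i, ])
      if (length(cand) == 0L) cand <- which(same_phylum[i, ])
      j <- if (length(cand) == 1L) cand else sample(cand, 1L)
      partner_taxon[k] <- taxa$taxon_id[j]
      ppool <- proteins$protein_id[proteins$taxon_id == taxa$taxon_id[j]]
      partner_protein[k] <- if (length(ppool) == 1L) ppool else sample(ppool, 1L)
    }

    peptide_id <- sprintf("PEP%06d", seq_len(n_pep_total))
    cand_taxa <- ifelse(share,
                        paste(pmin(owner_taxon, partner_taxon),
                              pmax(owner_taxon, partner_taxon), sep = ";"),
                        owner_taxon)
    peptides <- data.frame(
      peptide_id = peptide_id,
      ionization = stats::rlnorm(n_pep_total, meanlog = 0, sdlog = 0.7),
      shared = share,
      taxa = cand_taxa,
      stringsAsFactors = FALSE
    )
    peptide_map <- rbind(
      data.frame(peptide_id = peptide_id, protein_id = owner_protein,
                 stringsAsFactors = FALSE),
      data.frame(peptide_id = peptide_id[share],
                 protein_id = partner_protein[share],
                 stringsAsFactors = FALSE)
    )
    peptide_map <- peptide_map[order(peptide_map$peptide_id,
                                     peptide_map$protein_id), ]
    rownames(peptide_map) <- NULL

    structure(
      list(taxa = taxa, proteins = proteins, peptides = peptides,
           peptide_map = peptide_map),
      class = "mp_community"
    )
  })
}

#' @export
print.mp_community <- function(x, ...) {
  cat(sprintf(
    "mp_community: %d taxa (%d genera, %d phyla), %d proteins, %d peptides (%.1f%% shared)\n",
    nrow(x$taxa), length(unique(x$taxa$genus)), length(unique(x$taxa$phylum)),
    nrow(x$proteins), nrow(x$peptides), 100 * mean(x$peptides$shared)))
  invisible(x)
}

#' Extract the lineage table of a community
#'
#' @param community An `mp_community`.
#' @return Data frame with `taxon_id` and the seven rank columns, suitable as
#'   the lineage database for [assign_peptides()].
#' @export
lineage_table <- function(community) {
  stopifnot(inherits(community, "mp_community"))
  community$taxa[, c("taxon_id", tax_ranks())]
}

#' Specify a drug effect
#'
#' A drug effect combines the three response modes observed in cultured
#' microbiome drug screens: a global biomass scale factor (overall growth
#' inhibition or stimulation), per-taxon survival fractions (selective,
#' antibacterial-like depletion), and per-(taxon, COG category) regulation
#' factors that change protein expression without changing the taxon's
#' biomass allocation rule. The default arguments encode the null effect.
#'
#' @param compound Compound identifier.
#' @param global_scale Global biomass scale factor g > 0 (default 1).
#' @param survival Named numeric vector of survival fractions s in `[0, 1]`
#'   keyed by taxon id; taxa not named survive fully. `s = 0` is a complete
#'   kill.
#' @param regulation Data frame with columns `taxon_id`, `cog_category`,
#'   `factor` (> 0): expression of matching proteins is multiplied by
#'   `factor`. Other proteins are not renormalized, so a taxon's total
#'   biomass shifts slightly when `factor != 1`; this keeps ground truth
#'   exactly computable.
#' @return An object of class `mp_drug_effect`.
#' @export
drug_effect <- function(compound, global_scale = 1, survival = NULL,
                        regulation = NULL) {
  stopifnot(is.character(compound), length(compound) == 1L)
  if (!is.numeric(global_scale) || length(global_scale) != 1L ||
      !is.finite(global_scale) || global_scale <= 0) {
    stop("`global_scale` must be a finite positive number", call. = FALSE)
  }
  if (!is.null(survival)) {
    if (is.null(names(survival)) || any(!nzchar(names(survival)))) {
      stop("`survival` must be a named numeric vector keyed by taxon id",
           call. = FALSE)
    }
    if (any(!is.finite(survival)) || any(survival < 0) || any(survival > 1)) {
      stop("survival fractions must be finite and in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(regulation)) {
    require_columns(regulation, c("taxon_id", "cog_category", "factor"),
                    "`regulation`")
    if (any(!is.finite(regulation$factor)) || any(regulation$factor <= 0)) {
      stop("regulation factors must be finite and positive", call. = FALSE)
    }
  }
  structure(
    list(compound = compound, global_scale = global_scale,
         survival = survival, regulation = regulation),
    class = "mp_drug_effect"
  )
}

is_null_effect <- function(effect) {
  is.null(effect) ||
    (effect$global_scale == 1 &&
       (is.null(effect$survival) || all(effect$survival == 1)) &&
       (is.null(effect$regulation) || nrow(effect$regulation) == 0L ||
          all(effect$regulation$factor == 1)))
}

#' Apply a drug effect to a community
#'
#' Computes the perturbed per-taxon absolute abundances and per-protein
#' absolute amounts: taxon abundance becomes `baseline * g * s_t`, and a
#' protein's amount becomes `taxon abundance * expression_fraction * r`,
#' where `r` is the regulation factor matching the protein's (taxon, COG
#' category) pair (1 if none matches). A null effect returns baseline values
#' exactly.
#'
#' @param community An `mp_community`.
#' @param effect An `mp_drug_effect`, or `NULL` for the null effect.
#' @return List with named numeric vectors `taxon_abundance` (by taxon id)
#'   and `protein_amount` (by protein id).
#' @export
apply_drug_effect <- function(community, effect = NULL) {
  stopifnot(inherits(community, "mp_community"))
  taxa <- community$taxa
  prot <- community$proteins
  g <- 1
  s <- stats::setNames(rep(1, nrow(taxa)), taxa$taxon_id)
  r <- rep(1, nrow(prot))
  if (!is.null(effect)) {
    stopifnot(inherits(effect, "mp_drug_effect"))
    g <- effect$global_scale
    if (!is.null(effect$survival)) {
      unknown <- setdiff(names(effect$survival), taxa$taxon_id)
      if (length(unknown) > 0L) {
        stop(sprintf("unknown taxon id(s) in survival spec: %s",
                     paste(unknown, collapse = ", ")), call. = FALSE)
      }
      s[names(effect$survival)] <- effect$survival
    }
    if (!is.null(effect$regulation) && nrow(effect$regulation) > 0L) {
      reg <- effect$regulation
      unknown <- setdiff(reg$taxon_id, taxa$taxon_id)
      if (length(unknown) > 0L) {
        stop(sprintf("unknown taxon id(s) in regulation spec: %s",
                     paste(unknown, collapse = ", ")), call. = FALSE)
      }
      key <- paste(prot$taxon_id, prot$cog_category, sep = "\r")
      reg_key <- paste(reg$taxon_id, reg$cog_category, sep = "\r")
      hit <- match(key, reg_key)
      r[!is.na(hit)] <- reg$factor[hit[!is.na(hit)]]
    }
  }
  abundance <- stats::setNames(taxa$abundance * g * s[taxa$taxon_id],
                               taxa$taxon_id)
  amount <- abundance[prot$taxon_id] * prot$expression_fraction * r
  list(taxon_abundance = abundance,
       protein_amount = stats::setNames(as.numeric(amount), prot$protein_id))
}

#' Specify the observation noise model
#'
#' Label-free quantification noise is modelled as multiplicative log-normal
#' error on the log2 scale, an individual-specific batch offset per protein
#' (the between-microbiome batch structure that ComBat-style correction
#' removes), and intensity-dependent left-censoring-like missingness: a
#' peptide observation is dropped with probability
#' `plogis(miss_slope * (log2(intensity) - miss_mid))`, which is
#' non-increasing in intensity for `miss_slope <= 0`. Missing observations
#' are absent rows, never zeros.
#'
#' @param sigma Log2-scale standard deviation of the multiplicative peptide
#'   noise (>= 0).
#' @param batch_sigma Log2-scale standard deviation of per-(protein,
#'   individual) batch offsets (>= 0).
#' @param indiv_sigma Log2-scale standard deviation of per-(taxon,
#'   individual) abundance offsets (>= 0): different individuals harbour
#'   the same taxa at very different levels, which is what makes samples
#'   cluster by microbiome of origin. Drug and control wells of one
#'   individual share the same offsets, so within-individual fold changes
#'   are unaffected.
#' @param miss_mid Log2 intensity at which the missingness probability is
#'   50%.
#' @param miss_slope Logistic slope on log2 intensity; must be <= 0. A slope
#'   of exactly 0 disables missingness.
#' @return An object of class `mp_noise`.
#' @export
noise_model <- function(sigma = 0.3, batch_sigma = 0.5, indiv_sigma = 1,
                        miss_mid = 14, miss_slope = -1) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            is.numeric(batch_sigma), length(batch_sigma) == 1L,
            batch_sigma >= 0,
            is.numeric(indiv_sigma), length(indiv_sigma) == 1L,
            indiv_sigma >= 0,
            is.numeric(miss_mid), length(miss_mid) == 1L,
            is.numeric(miss_slope), length(miss_slope) == 1L)
  if (miss_slope > 0) {
    stop("`miss_slope` must be <= 0 (missingness cannot increase with intensity)",
         call. = FALSE)
  }
  structure(list(sigma = sigma, batch_sigma = batch_sigma,
                 indiv_sigma = indiv_sigma,
                 miss_mid = miss_mid, miss_slope = miss_slope),
            class = "mp_noise")
}

#' Noise-free observation model
#'
#' Convenience constructor: no multiplicative noise, no batch or individual
#' offsets, no missingness. Useful for exactness tests and ground-truth
#' checks.
#' @return An `mp_noise` object.
#' @export
zero_noise <- function() {
  noise_model(sigma = 0, batch_sigma = 0, indiv_sigma = 0, miss_slope = 0)
}
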
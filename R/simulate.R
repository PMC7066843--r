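#' Simulate peptide and protein-group quantification tables
#'
#' Generates the observed data of an equal-volume metaproteomic screen: for
#' each sample, per-protein absolute amounts are computed from the community
#' baseline and the sample's drug effect, multiplied by the individual's
#' per-protein batch offset, summed into peptide amounts over parent
#' proteins, scaled by the peptide's ionization factor, and perturbed by
#' multiplicative log-normal noise; intensity-dependent missingness then
#' drops rows. Observed intensities are proportional to absolute amounts —
#' there is no per-sample renormalization (the equal-volume observation
#' contract). Protein-group intensity is the sum of its member peptides'
#' observed intensities.
#'
#' @param community An `mp_community`.
#' @param design Sample design from [make_design()].
#' @param effects Named list of [drug_effect()] objects keyed by compound id;
#'   compounds without an entry (and all control samples) get the null
#'   effect.
#' @param noise An `mp_noise` model.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return An object of class `mp_quant`: list with long-format data frames
#'   `peptides` (`peptide_id`, `sample_id`, `intensity`, `taxa`),
#'   `proteins` (`group_id`, `sample_id`, `intensity`), the protein
#'   `annotations` table (group id, taxon, lineage string, COG/KO/EC),
#'   `lineages` (taxon lineage database), and the `design`.
#' @export
simulate_quant_tables <- function(community, design, effects = list(),
                                  noise = noise_model(), seed = 1) {
  stopifnot(inherits(community, "mp_community"), inherits(noise, "mp_noise"))
  design <- validate_design(design)
  if (length(effects) > 0L) {
    if (is.null(names(effects)) ||
        !all(vapply(effects, inherits, logical(1), "mp_drug_effect"))) {
      stop("`effects` must be a named list of drug_effect objects",
           call. = FALSE)
    }
    unknown <- setdiff(names(effects), design$compound)
    if (length(unknown) > 0L) {
      stop(sprintf("effects given for compounds absent from the design: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    bad <- names(effects)[names(effects) %in%
                            design$compound[design$is_control]]
    if (length(bad) > 0L) {
      stop("control samples cannot carry a drug effect", call. = FALSE)
    }
  }

  prot <- community$proteins
  pep <- community$peptides
  map <- community$peptide_map
  map_prot_idx <- match(map$protein_id, prot$protein_id)
  map_pep_idx <- match(map$peptide_id, pep$peptide_id)
  individuals <- unique(design$individual)

  with_seed(seed, {
    offsets <- matrix(stats::rnorm(nrow(prot) * length(individuals),
                                   sd = noise$batch_sigma),
                      nrow = nrow(prot),
                      dimnames = list(prot$protein_id, individuals))
    taxon_offsets <- matrix(
      stats::rnorm(nrow(community$taxa) * length(individuals),
                   sd = noise$indiv_sigma),
      nrow = nrow(community$taxa),
      dimnames = list(community$taxa$taxon_id, individuals))
    # per-protein total offset for each individual (taxon + protein level)
    prot_taxon_idx <- match(prot$taxon_id, community$taxa$taxon_id)

    # Per-compound perturbed protein amounts (deterministic part).
    amounts <- new.env(parent = emptyenv())
    amount_for <- function(compound, is_control) {
      key <- if (is_control) ".control" else compound
      if (!is.null(amounts[[key]])) return(amounts[[key]])
      eff <- if (is_control) NULL else effects[[compound]]
      amounts[[key]] <- apply_drug_effect(community, eff)$protein_amount
      amounts[[key]]
    }

    pep_rows <- vector("list", nrow(design))
    prot_rows <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      smp <- design$sample_id[i]
      amt <- amount_for(design$compound[i], design$is_control[i])
      ind <- design$individual[i]
      amt <- amt * 2^(offsets[, ind] + taxon_offsets[prot_taxon_idx, ind])
      pep_true <- as.numeric(
        rowsum(amt[map_prot_idx], group = map_pep_idx, reorder = TRUE))
      # rowsum reorders by group index; map back onto the peptide catalog
      idx_present <- sort(unique(map_pep_idx))
      full <- numeric(nrow(pep))
      full[idx_present] <- pep_true
      obs <- full * pep$ionization
      if (noise$sigma > 0) {
        obs <- obs * 2^stats::rnorm(nrow(pep), sd = noise$sigma)
      }
      keep <- obs > 0
      if (noise$miss_slope < 0) {
        p_miss <- stats::plogis(noise$miss_slope *
                                  (log2(pmax(obs, .Machine$double.xmin)) -
                                     noise$miss_mid))
        keep <- keep & (stats::runif(nrow(pep)) >= p_miss)
      }
      if (!any(keep)) next
      pep_rows[[i]] <- data.frame(
        peptide_id = pep$peptide_id[keep], sample_id = smp,
        intensity = obs[keep], taxa = pep$taxa[keep],
        stringsAsFactors = FALSE)
      # Protein-group intensity: sum of member observed peptide intensities.
      obs_kept <- ifelse(keep, obs, 0)
      grp <- rowsum(obs_kept[map_pep_idx], group = map$protein_id,
                    reorder = TRUE)
      grp_val <- as.numeric(grp)
      nz <- grp_val > 0
      if (any(nz)) {
        prot_rows[[i]] <- data.frame(
          group_id = rownames(grp)[nz], sample_id = smp,
          intensity = grp_val[nz], stringsAsFactors = FALSE)
      }
    }
    peptides <- do.call(rbind, pep_rows[!vapply(pep_rows, is.null, logical(1))])
    proteins <- do.call(rbind, prot_rows[!vapply(prot_rows, is.null, logical(1))])
    rownames(peptides) <- rownames(proteins) <- NULL

    structure(
      list(peptides = peptides, proteins = proteins,
           annotations = protein_annotations(community),
           lineages = lineage_table(community), design = design),
      class = "mp_quant"
    )
  })
}

# Annotation map: one row per protein group with lineage + function labels.
protein_annotations <- function(community) {
  prot <- community$proteins
  taxa <- community$taxa
  idx <- match(prot$taxon_id, taxa$taxon_id)
  lineage <- apply(taxa[idx, tax_ranks()], 1L, paste, collapse = "|")
  data.frame(
    group_id = prot$protein_id,
    taxon_id = prot$taxon_id,
    phylum = taxa$phylum[idx],
    genus = taxa$genus[idx],
    lineage = as.character(lineage),
    cog_id = prot$cog_id,
    cog_category = prot$cog_category,
    ko_id = prot$ko_id,
    ec_id = prot$ec_id,
    stringsAsFactors = FALSE
  )
}

#' @export
print.mp_quant <- function(x, ...) {
  cat(sprintf("mp_quant: %d peptide rows, %d protein-group rows, %d samples\n",
              nrow(x$peptides), nrow(x$proteins), nrow(x$design)))
  invisible(x)
}

#' Simulate an equal-volume dilution series
#'
#' One microbiome is observed at a ladder of known relative concentrations
#' (the benchmark for the equal-volume strategy): every protein amount is
#' scaled by the gradient factor, and samples are generated per gradient x
#' replicate with the given noise model. The known concentration of each
#' sample is returned as ground truth for [linearity_check()].
#'
#' @param community An `mp_community`.
#' @param gradients Positive, strictly monotone vector of relative
#'   concentrations.
#' @param replicates Replicate wells per gradient.
#' @param noise An `mp_noise` model (batch offsets do not apply: a single
#'   microbiome).
#' @param seed Integer seed.
#' @return List with `peptides` and `proteins` long tables, `annotations`,
#'   `lineages`, and `concentrations` (`sample_id`, `concentration`).
#' @export
make_dilution_series <- function(community, gradients, replicates = 3,
                                 noise = noise_model(), seed = 1) {
  stopifnot(inherits(community, "mp_community"), inherits(noise, "mp_noise"))
  if (length(gradients) == 0L) stop("`gradients` must be non-empty", call. = FALSE)
  if (any(!is.finite(gradients)) || any(gradients <= 0)) {
    stop("`gradients` must be positive", call. = FALSE)
  }
  d <- diff(gradients)
  if (length(gradients) > 1L && !(all(d > 0) || all(d < 0))) {
    stop("`gradients` must be strictly monotone", call. = FALSE)
  }
  stop_if_not_scalar_count(replicates, "replicates")

  grid <- expand.grid(replicate = seq_len(replicates),
                      gradient = seq_along(gradients))
  design <- data.frame(
    sample_id = sprintf("GRD%d_r%d", grid$gradient, grid$replicate),
    individual = "V1",
    compound = sprintf("GRD%d", grid$gradient),
    replicate = grid$replicate,
    batch = "V1",
    is_control = grid$gradient == 1L,  # undiluted sample anchors the series
    stringsAsFactors = FALSE
  )
  conc <- gradients[grid$gradient]

  base <- apply_drug_effect(community, NULL)$protein_amount
  pep <- community$peptides
  map <- community$peptide_map
  map_prot_idx <- match(map$protein_id, names(base))
  map_pep_idx <- match(map$peptide_id, pep$peptide_id)

  with_seed(seed, {
    pep_rows <- vector("list", nrow(design))
    prot_rows <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      amt <- base * conc[i]
      pep_true <- numeric(nrow(pep))
      acc <- rowsum(amt[map_prot_idx], group = map_pep_idx, reorder = TRUE)
      pep_true[sort(unique(map_pep_idx))] <- as.numeric(acc)
      obs <- pep_true * pep$ionization
      if (noise$sigma > 0) obs <- obs * 2^stats::rnorm(nrow(pep), sd = noise$sigma)
      keep <- obs > 0
      if (noise$miss_slope < 0) {
        p_miss <- stats::plogis(noise$miss_slope *
                                  (log2(pmax(obs, .Machine$double.xmin)) -
                                     noise$miss_mid))
        keep <- keep & (stats::runif(nrow(pep)) >= p_miss)
      }
      pep_rows[[i]] <- data.frame(
        peptide_id = pep$peptide_id[keep], sample_id = design$sample_id[i],
        intensity = obs[keep], taxa = pep$taxa[keep], stringsAsFactors = FALSE)
      obs_kept <- ifelse(keep, obs, 0)
      grp <- rowsum(obs_kept[map_pep_idx], group = map$protein_id,
                    reorder = TRUE)
      nz <- as.numeric(grp) > 0
      prot_rows[[i]] <- data.frame(
        group_id = rownames(grp)[nz], sample_id = design$sample_id[i],
        intensity = as.numeric(grp)[nz], stringsAsFactors = FALSE)
    }
    list(
      peptides = do.call(rbind, pep_rows),
      proteins = do.call(rbind, prot_rows),
      annotations = protein_annotations(community),
      lineages = lineage_table(community),
      design = design,
      concentrations = data.frame(sample_id = design$sample_id,
                                  concentration = conc,
                                  stringsAsFactors = FALSE)
    )
  })
}
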
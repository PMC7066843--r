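#' Default pipeline configuration
#'
#' All thresholds the workflow uses live in one configuration object (no
#' hidden defaults in code paths): presence filter fraction, per-mode
#' significance thresholds, the VIP cutoff, the Q2 class-call threshold,
#' PLS-DA component count, PerMANOVA permutations, and the seed. The
#' `synthetic` block describes a small demonstration screen; replace it
#' with an `inputs` block of file paths to analyze measured tables.
#'
#' @return Nested configuration list; serializable to YAML/JSON and back.
#' @export
default_config <- function() {
  list(
    seed = 1,
    thresholds = list(
      fdr = 0.05,          # BH q cutoff for FDR-controlled calls
      cog_p = 0.05,        # raw-p cutoff for COG-level counts
      vip = 1,             # PLS-DA differential-feature cutoff
      q2 = 0.4,            # class-I Q2 threshold
      presence = 0.8       # protein-group presence filter fraction
    ),
    pseudocount = NULL,    # NULL = half the smallest nonzero intensity
    n_components = 2,
    n_perm = 999,
    control = "DMSO",
    rank = "genus",
    synthetic = list(
      n_taxa = 20,
      n_proteins_per_taxon = 15,
      shared_peptide_fraction = 0.2,
      n_individuals = 5,
      n_replicates = 1,
      compounds = c("drugA", "drugB", "drugC"),
      noise = list(sigma = 0.3, batch_sigma = 0.5, indiv_sigma = 1,
                   miss_mid = 14, miss_slope = -1),
      effects = list(
        list(compound = "drugA", global_scale = 0.4)
      )
    ),
    inputs = NULL
  )
}

#' Load and validate a pipeline configuration
#'
#' @param config A configuration list, or a path to a YAML or JSON file.
#' @return The validated configuration (defaults filled in).
#' @export
load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  base <- default_config()
  config <- utils::modifyList(base, config)
  th <- config$thresholds
  for (nm in c("fdr", "cog_p", "presence")) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(sprintf("threshold `%s` = %s is outside [0, 1]", nm,
                   format(v)), call. = FALSE)
    }
  }
  if (!is.numeric(th$vip) || th$vip < 0) {
    stop("threshold `vip` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(th$q2) || th$q2 > 1) {
    stop("threshold `q2` must be a number <= 1", call. = FALSE)
  }
  if (!config$rank %in% tax_ranks()) {
    stop(sprintf("unknown rank '%s'", config$rank), call. = FALSE)
  }
  stop_if_not_scalar_count(config$n_perm, "n_perm")
  stop_if_not_scalar_count(config$n_components, "n_components")
  config
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  unname(tools::md5sum(tmp))
}

build_effects <- function(spec_list) {
  if (is.null(spec_list) || length(spec_list) == 0L) return(list())
  effects <- list()
  for (e in spec_list) {
    surv <- NULL
    if (!is.null(e$survival)) surv <- unlist(e$survival)
    reg <- NULL
    if (!is.null(e$regulation)) {
      reg <- do.call(rbind, lapply(e$regulation, as.data.frame))
    }
    effects[[e$compound]] <- drug_effect(
      compound = e$compound,
      global_scale = e$global_scale %||% 1,
      survival = surv, regulation = reg)
  }
  effects
}

#' Generate synthetic quantification tables from a configuration
#'
#' Convenience wrapper over [generate_community()], [make_design()] and
#' [simulate_quant_tables()] driven by the `synthetic` block of a pipeline
#' configuration.
#'
#' @param config Configuration list or path, see [default_config()].
#' @return An `mp_quant` list.
#' @export
simulate_from_config <- function(config = default_config()) {
  config <- load_config(config)
  syn <- config$synthetic
  community <- generate_community(
    n_taxa = syn$n_taxa,
    n_proteins_per_taxon = syn$n_proteins_per_taxon,
    shared_peptide_fraction = syn$shared_peptide_fraction,
    seed = config$seed)
  design <- make_design(syn$n_individuals, syn$compounds,
                        n_replicates = syn$n_replicates,
                        control = config$control)
  simulate_quant_tables(community, design,
                        effects = build_effects(syn$effects),
                        noise = do.call(noise_model, syn$noise),
                        seed = config$seed + 1)
}

#' Run the full drug-response workflow
#'
#' Executes the stage order taxonomy -> biomass -> composition -> function
#' -> multivariate on synthetic or user-supplied tables, and writes a
#' report bundle: `biomass.tsv` (per-sample totals and drug/control
#' ratios), `taxon_differential.tsv` (per-genus rank-sum contrasts with BH
#' q), `taxon_log2fc.tsv` (heatmap-ready mean log2 fold changes),
#' `shift_test.tsv` (Bray-Curtis community-shift test), `function_
#' differential.tsv` (protein-group contrasts on batch-corrected data), and
#' `multivariate.tsv` (per-compound PLS-DA R2/Q2, VIP>cutoff counts, shift
#' q, class call), plus `permanova.tsv` and a `manifest.json` recording the
#' configuration hash, seed and stage-by-stage feature/sample counts.
#' Identical configuration (including seed) reproduces a byte-identical
#' bundle.
#'
#' @param config Configuration list or path, see [default_config()].
#' @param output_dir Directory for the report bundle.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = default_config(), output_dir) {
  config <- load_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  log_counts <- list()

  # ---- inputs ----
  if (!is.null(config$inputs)) {
    quant <- read_quant_tables(
      peptides = config$inputs$peptides, proteins = config$inputs$proteins,
      design = config$inputs$design, lineages = config$inputs$lineages,
      annotations = config$inputs$annotations)
  } else {
    quant <- simulate_from_config(config)
  }
  design <- quant$design
  log_counts$samples <- nrow(design)
  log_counts$peptide_rows <- nrow(quant$peptides)
  log_counts$protein_rows <- nrow(quant$proteins)

  # ---- taxonomy + biomass ----
  assignment <- assign_peptides(quant$peptides, quant$lineages)
  tb <- taxon_biomass(quant$peptides, assignment, rank = config$rank)
  tb <- tb[, design$sample_id, drop = FALSE]
  biomass <- total_biomass(quant$peptides, samples = design$sample_id)
  bfc <- biomass_fold_change(biomass, design)
  biomass_report <- data.frame(
    sample_id = design$sample_id, individual = design$individual,
    compound = design$compound, total_intensity = biomass[design$sample_id],
    stringsAsFactors = FALSE)
  write_report(biomass_report, file.path(output_dir, "biomass.tsv"))
  write_report(bfc[, c("individual", "compound", "ratio", "log2_ratio")],
               file.path(output_dir, "biomass_ratio.tsv"))

  # ---- composition ----
  tdiff <- taxon_differential(tb, design, alternative = "two.sided",
                              pseudocount = config$pseudocount,
                              min_presence = th$presence)
  write_report(tdiff, file.path(output_dir, "taxon_differential.tsv"))
  l2 <- log2_fold_change_vs_control(tb, design, config$pseudocount)
  l2w <- tapply(l2$log2fc, list(l2$feature, l2$compound), mean, na.rm = TRUE)
  write_report(data.frame(feature = rownames(l2w), as.data.frame(l2w),
                          check.names = FALSE),
               file.path(output_dir, "taxon_log2fc.tsv"))
  shift_tax <- drug_shift_test(tb, design)
  write_report(shift_tax$test, file.path(output_dir, "shift_test.tsv"))

  # ---- function ----
  filt <- filter_protein_groups(quant$proteins, design,
                                min_fraction = th$presence)
  log_counts$groups_after_filter <- length(attr(filt, "retained"))
  pm <- quant_matrix(filt, samples = design$sample_id, fill = NA)
  norm <- normalize_log_quotient(ifelse(is.na(pm), 0, pm),
                                 pseudocount = config$pseudocount %||% 1)
  norm[is.na(pm)] <- NA
  imp <- impute_by_batch(norm, design$batch)
  adj <- combat_adjust(imp$mat, design$batch)
  compounds <- setdiff(unique(design$compound), config$control)
  fdiff <- do.call(rbind, lapply(compounds, function(cmp) {
    differential_features(adj, design, cmp, mode = "across_individuals")
  }))
  write_report(fdiff, file.path(output_dir, "function_differential.tsv"))
  shift_prot <- drug_shift_test(quant_matrix(filt,
                                             samples = design$sample_id,
                                             fill = 0), design)

  # ---- multivariate ----
  # Bray-Curtis on relative protein-group profiles for the individual test
  relp <- relative_abundance(quant_matrix(filt, samples = design$sample_id,
                                          fill = 0))
  n_s <- ncol(relp)
  rel_dist <- matrix(0, n_s, n_s, dimnames = list(colnames(relp),
                                                  colnames(relp)))
  for (i in seq_len(n_s - 1L)) {
    for (j in seq(i + 1L, n_s)) {
      rel_dist[i, j] <- rel_dist[j, i] <- bray_curtis(relp[, i], relp[, j])
    }
  }
  perm <- permanova(rel_dist, design$individual, n_perm = config$n_perm,
                    seed = config$seed + 2)
  write_report(data.frame(term = "individual", pseudo_F = perm$f_statistic,
                          ss_between = perm$ss_between,
                          ss_within = perm$ss_within,
                          n_perm = perm$n_perm, p_value = perm$p_value),
               file.path(output_dir, "permanova.tsv"))

  mv_rows <- lapply(compounds, function(cmp) {
    cols <- design$sample_id[design$compound %in% c(cmp, config$control)]
    y <- design$compound[match(cols, design$sample_id)] == cmp
    X <- t(adj[, cols, drop = FALSE])
    a <- min(config$n_components, length(cols) - 2L)
    fit <- plsda_fit(X, y, a)
    cv <- cross_validate_plsda(X, y, a, folds = "loo")
    vip <- vip_scores(fit)
    sq <- shift_prot$test$q_value[shift_prot$test$compound == cmp]
    cls <- classify_compound(cv$q_squared, sq, q2_threshold = th$q2,
                             fdr_threshold = th$fdr)
    data.frame(compound = cmp, r_squared = cv$r_squared,
               q_squared = cv$q_squared, n_components = fit$n_components,
               n_vip_above_cutoff = sum(vip > th$vip),
               shift_q = sq, class = cls$class, stringsAsFactors = FALSE)
  })
  mv <- do.call(rbind, mv_rows)
  write_report(mv, file.path(output_dir, "multivariate.tsv"))

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("mpscreen")),
    counts = log_counts,
    reports = c("biomass.tsv", "biomass_ratio.tsv", "taxon_differential.tsv",
                "taxon_log2fc.tsv", "shift_test.tsv",
                "function_differential.tsv", "permanova.tsv",
                "multivariate.tsv"))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(config = config, biomass = biomass_report, ratios = bfc,
                 taxon_differential = tdiff, shift = shift_tax,
                 function_differential = fdiff, permanova = perm,
                 multivariate = mv, manifest = manifest))
}
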
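#' Total biomass per sample
#'
#' Under equal-volume processing, summed peptide intensity is proportional
#' to the absolute microbial protein amount of a sample, so the per-sample
#' sum over all peptides estimates total microbiome biomass. Missing
#' observations (absent rows) count as zero.
#'
#' @param peptides Long quantification table (`peptide_id`, `sample_id`,
#'   `intensity`).
#' @param samples Optional character vector fixing the output order and
#'   guaranteeing a (zero) entry for samples with no observations.
#' @return Named numeric vector, sample id -> total intensity.
#' @export
total_biomass <- function(peptides, samples = NULL) {
  require_columns(peptides, c("sample_id", "intensity"), "`peptides`")
  if (nrow(peptides) == 0L && is.null(samples)) {
    stop("`peptides` is empty and no sample set was given", call. = FALSE)
  }
  if (any(peptides$intensity < 0)) {
    stop("negative intensities in peptide table", call. = FALSE)
  }
  sums <- tapply(peptides$intensity, peptides$sample_id, sum, default = 0)
  out <- stats::setNames(as.numeric(sums), names(sums))
  if (!is.null(samples)) {
    out <- stats::setNames(ifelse(samples %in% names(out), out[samples], 0),
                           samples)
  }
  out
}

#' Drug/control biomass ratio per individual and compound
#'
#' Each drug-treated sample's total biomass is divided by the mean control
#' biomass of the same individual (replicate controls are averaged;
#' replicate drug wells are averaged before the ratio as well). A zero
#' control biomass yields `NA` with a flag.
#'
#' @param biomass Named vector from [total_biomass()].
#' @param design Sample design table.
#' @return Data frame with `individual`, `compound`, `ratio`, `log2_ratio`,
#'   `undefined` (TRUE where the control biomass was zero).
#' @export
biomass_fold_change <- function(biomass, design) {
  design <- validate_design(design)
  missing <- setdiff(design$sample_id, names(biomass))
  if (length(missing) > 0L) {
    biomass <- c(biomass, stats::setNames(rep(0, length(missing)), missing))
  }
  ctrl <- design[design$is_control, ]
  ctrl_mean <- tapply(biomass[ctrl$sample_id], ctrl$individual, mean)
  drug <- design[!design$is_control, ]
  agg <- stats::aggregate(
    list(total = biomass[drug$sample_id]),
    by = list(individual = drug$individual, compound = drug$compound),
    FUN = mean)
  denom <- as.numeric(ctrl_mean[agg$individual])
  ratio <- ifelse(denom > 0, agg$total / denom, NA_real_)
  data.frame(
    individual = agg$individual, compound = agg$compound,
    ratio = ratio, log2_ratio = log2(ratio),
    undefined = denom <= 0, stringsAsFactors = FALSE)
}

#' Linearity of summed intensity against known concentration
#'
#' Ordinary least-squares fit (free intercept) of total peptide intensity on
#' known relative concentration, as in a dilution-series benchmark of the
#' equal-volume strategy.
#'
#' @param biomass Named vector of total intensities.
#' @param concentration Named (or equally ordered) positive vector of known
#'   concentrations.
#' @return List with `r_squared`, `slope`, `intercept`, and the fitted `lm`
#'   object as `fit`.
#' @export
linearity_check <- function(biomass, concentration) {
  if (!is.null(names(concentration)) && !is.null(names(biomass))) {
    concentration <- concentration[names(biomass)]
  }
  stopifnot(length(biomass) == length(concentration))
  if (length(unique(concentration)) < 3L) {
    stop("need >= 3 distinct concentration levels", call. = FALSE)
  }
  fit <- stats::lm(biomass ~ concentration)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       fit = fit)
}
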
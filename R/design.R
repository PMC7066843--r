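#' Build a sample design table
#'
#' One row per culture well: individual microbiome, compound (or vehicle
#' control), replicate index, and batch label (defaults to the individual,
#' which is the batch structure of a plate-per-individual screen). Every
#' individual receives control wells automatically.
#'
#' @param individuals Number of individuals, or a character vector of
#'   individual ids.
#' @param compounds Character vector of compound ids (excluding the control).
#' @param n_replicates Wells per individual x compound (also applied to the
#'   control).
#' @param control Label of the vehicle control (default `"DMSO"`).
#' @return Data frame with columns `sample_id`, `individual`, `compound`,
#'   `replicate`, `batch`, `is_control`.
#' @export
make_design <- function(individuals, compounds, n_replicates = 1,
                        control = "DMSO") {
  if (is.numeric(individuals) && length(individuals) == 1L) {
    individuals <- sprintf("V%d", seq_len(individuals))
  }
  stopifnot(is.character(individuals), length(individuals) >= 1L,
            !anyDuplicated(individuals))
  stop_if_not_scalar_count(n_replicates, "n_replicates")
  compounds <- setdiff(unique(as.character(compounds)), control)
  conds <- c(control, compounds)
  out <- expand.grid(replicate = seq_len(n_replicates), compound = conds,
                     individual = individuals, stringsAsFactors = FALSE)
  out <- out[, c("individual", "compound", "replicate")]
  out$sample_id <- sprintf("%s_%s_r%d", out$individual, out$compound,
                           out$replicate)
  out$batch <- out$individual
  out$is_control <- out$compound == control
  validate_design(out, control = control)
}

validate_design <- function(design, control = "DMSO") {
  require_columns(design, c("sample_id", "individual", "compound"),
                  "sample design")
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample ids in design", call. = FALSE)
  }
  if (is.null(design$replicate)) design$replicate <- 1L
  if (is.null(design$batch)) design$batch <- design$individual
  if (is.null(design$is_control)) design$is_control <- design$compound == control
  no_ctrl <- setdiff(design$individual,
                     design$individual[design$is_control])
  if (length(no_ctrl) > 0L) {
    stop(sprintf("individual(s) without a control sample: %s",
                 paste(no_ctrl, collapse = ", ")), call. = FALSE)
  }
  design[, c("sample_id", "individual", "compound", "replicate", "batch",
             "is_control")]
}
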
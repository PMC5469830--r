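#' Container for a two-group beta-value study
#'
#' Bundles the three probes-x-samples matrices of a methylation-array
#' experiment (beta-values, detection p-values, bead counts) with the
#' two-group sample sheet. Matrices must be congruent in shape and share
#' probe (row) and sample (column) names; every sample must carry one of
#' exactly two group labels.
#'
#' @param beta Numeric matrix of beta-values in `[0, 1]`, probes as rows.
#' @param detection_p Numeric matrix of detection p-values, same shape.
#' @param beads Integer matrix of bead counts, same shape.
#' @param samples `data.frame` with columns `sample_id` and `group`.
#' @param ref_group,case_group The two group labels; group means and delta
#'   beta are always reported as case minus reference.
#' @return An object of class `BetaStudy`.
#' @export
beta_study <- function(beta, detection_p, beads, samples,
                       ref_group, case_group) {
  stopifnot(is.matrix(beta), is.matrix(detection_p), is.matrix(beads))
  if (!all(dim(detection_p) == dim(beta)) || !all(dim(beads) == dim(beta))) {
    stop("beta, detection_p and beads matrices must have identical dimensions")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("beta matrix must carry probe rownames and sample colnames")
  }
  if (!identical(colnames(beta), samples$sample_id)) {
    stop("sample sheet order must match matrix columns")
  }
  groups <- unique(samples$group)
  if (length(groups) != 2L) {
    stop("exactly two groups required, got: ", paste(groups, collapse = ", "))
  }
  if (anyNA(samples$group)) stop("every sample must have a group label")
  if (!all(c(ref_group, case_group) %in% groups)) {
    stop(
      "ref_group/case_group must match the sample sheet groups (",
      paste(groups, collapse = ", "), ")"
    )
  }
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("beta-values must lie in [0, 1]")
  structure(
    list(
      beta = beta, detection_p = detection_p, beads = beads,
      samples = samples, ref_group = ref_group, case_group = case_group
    ),
    class = "BetaStudy"
  )
}

#' @export
print.BetaStudy <- function(x, ...) {
  tab <- table(x$samples$group)
  cat(
    "BetaStudy:", nrow(x$beta), "probes x", ncol(x$beta), "samples (",
    paste(names(tab), tab, sep = "=", collapse = ", "), ")\n"
  )
  cat("  reference:", x$ref_group, " case:", x$case_group, "\n")
  invisible(x)
}

#' Probe identifiers of a study
#' @param study A [beta_study()].
#' @return Character vector of probe ids (matrix rownames).
#' @export
probe_ids <- function(study) rownames(study$beta)

#' Restrict a study to a subset of probes
#'
#' @param study A [beta_study()].
#' @param probes Character vector of probe ids to keep (order preserved).
#' @return A new `BetaStudy`; the `truth` table, when present, is subset
#'   alongside.
#' @export
subset_study <- function(study, probes) {
  missing <- setdiff(probes, probe_ids(study))
  if (length(missing)) {
    stop(
      "probes not present in study: ",
      paste(utils::head(missing, 5L), collapse = ", ")
    )
  }
  out <- beta_study(
    beta = study$beta[probes, , drop = FALSE],
    detection_p = study$detection_p[probes, , drop = FALSE],
    beads = study$beads[probes, , drop = FALSE],
    samples = study$samples,
    ref_group = study$ref_group, case_group = study$case_group
  )
  if (!is.null(study$truth)) {
    out$truth <- study$truth[match(probes, study$truth$probe_id), , drop = FALSE]
    rownames(out$truth) <- NULL
  }
  out
}

group_columns <- function(study, group) {
  which(study$samples$group == group)
}
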
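#' Build a design matrix with cluster labels for edgewise fitting
#'
#' Assembles the subjects-by-predictors matrix used by every edgewise fit:
#' an intercept, the predictor of interest, and nuisance covariates.
#' Factor covariates are expanded to indicator columns. The cluster label
#' attached to each subject determines the grouping used by the
#' cluster-robust sandwich estimator and the wild cluster bootstrap;
#' `"site"` (the coarsest level of the site/family nesting) is the
#' default, so robust standard errors absorb both site- and family-level
#' dependence.
#'
#' @param cohort a `"cohort_design"` data.frame (see [gen_cohort()]).
#' @param interest_term column name of the predictor of interest.
#' @param covariates character vector of nuisance covariate columns.
#' @param cluster_by `"site"`, `"family"`, or `"family_within_site"`.
#' @return list of class `"design_matrix"`: `X` (subjects x p, full column
#'   rank), `coef_names`, `interest_index`, `cluster_ids`, `cluster_by`.
#' @export
build_design <- function(cohort, interest_term = "stimulant",
                         covariates = c("age_months", "sex", "fd_mean"),
                         cluster_by = c("site", "family", "family_within_site")) {
  cluster_by <- match.arg(cluster_by)
  terms <- c(interest_term, covariates)
  missing_terms <- setdiff(terms, names(cohort))
  if (length(missing_terms) > 0) {
    stop_nla("nla_bad_design", paste0("terms not in cohort: ",
                                      paste(missing_terms, collapse = ", ")))
  }
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(fml, data = as.data.frame(cohort))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    stop_nla("nla_rank_deficient",
             paste0("design matrix is rank deficient; collinear column(s): ",
                    paste(dropped, collapse = ", ")))
  }
  interest_cols <- which(attr(X, "assign") == 1L)
  if (length(interest_cols) != 1L) {
    stop_nla("nla_bad_design",
             "predictor of interest must contribute exactly one column")
  }
  cluster_ids <- switch(cluster_by,
    site = cohort$site_id,
    family = cohort$family_id,
    family_within_site = paste(cohort$site_id, cohort$family_id, sep = ":")
  )
  structure(list(
    X = X, coef_names = colnames(X), interest_index = interest_cols,
    cluster_ids = as.character(cluster_ids), cluster_by = cluster_by
  ), class = "design_matrix")
}
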
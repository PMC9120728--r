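#' Cohort covariate table
#'
#' Validates a subjects table for morphometric modelling. Required
#' columns: `subject_id`, `group` ("case"/"control"), `severity`
#' (symptom severity score in \[0, 54\], NA allowed for controls or
#' unrated cases), `age` (years), `sex` (0/1), `etiv` (estimated total
#' intracranial volume, mm^3). Optional columns: `bdi`, `stai_trait`,
#' `antidepressant` (0/1), `subtype_weakness` (0/1).
#'
#' @param df data.frame of subjects.
#' @return the validated data.frame with class `cohort_table`.
#' @export
cohort_table <- function(df) {
  req <- c("subject_id", "group", "severity", "age", "sex", "etiv")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("cohort missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id in cohort: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  }
  if (!all(df$group %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'")
  }
  sev <- df$severity[!is.na(df$severity)]
  if (any(sev < 0 | sev > 54)) stop("severity must lie in [0, 54]")
  for (cl in c("age", "sex", "etiv")) {
    if (any(!is.finite(df[[cl]]))) stop("non-finite values in ", cl)
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Model specification for a vertex-wise GLM
#'
#' @param effect "group_contrast" (two-class case vs control model) or
#'   "severity" (one-class correlation with symptom severity).
#' @param nuisance covariates regressed out alongside the effect;
#'   defaults to age, sex and eTIV.
#' @param extra_nuisance optional additional covariates for post hoc
#'   adjustment (e.g. `c("bdi", "stai_trait")`, `"antidepressant"`,
#'   `"subtype_weakness"`).
#' @param subset optional logical vector (or function of the cohort
#'   returning one) restricting the analysis rows, e.g. the
#'   functional-weakness subgroup.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(effect = c("severity", "group_contrast"),
                        nuisance = c("age", "sex", "etiv"),
                        extra_nuisance = NULL, subset = NULL) {
  effect <- match.arg(effect)
  all_nuis <- c(nuisance, extra_nuisance)
  if (effect == "severity" && "severity" %in% all_nuis) {
    stop("effect column may not also appear among the nuisance columns")
  }
  structure(list(effect = effect, nuisance = nuisance,
                 extra_nuisance = extra_nuisance, subset = subset),
            class = "design_spec")
}

# Build the design matrix [intercept | effect | nuisance...] from a
# cohort; errors on missing values rather than silently dropping rows.
build_design <- function(cohort, design) {
  rows <- design$subset
  if (is.function(rows)) rows <- rows(cohort)
  if (is.null(rows)) rows <- rep(TRUE, nrow(cohort))
  co <- cohort[rows, , drop = FALSE]
  eff <- switch(design$effect,
    group_contrast = as.numeric(co$group == "case"),
    severity = co$severity
  )
  nuis_names <- c(design$nuisance, design$extra_nuisance)
  miss <- nuis_names[!nuis_names %in% names(co)]
  if (length(miss)) stop("cohort lacks nuisance columns: ",
                         paste(miss, collapse = ", "))
  X <- cbind(intercept = 1, effect = eff)
  for (nm in nuis_names) X <- cbind(X, co[[nm]])
  colnames(X) <- c("intercept", design$effect, nuis_names)
  bad <- colnames(X)[colSums(!is.finite(X)) > 0]
  if (length(bad)) {
    stop("missing or non-finite covariate values in: ",
         paste(bad, collapse = ", "),
         " (subset the cohort explicitly; no silent casewise deletion)")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dg <- abs(diag(qr.R(qrX)))
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[qrX$pivot[dg < max(dg) * 1e-10]],
               collapse = ", "))
  }
  list(X = X, rows = which(rows), qr = qrX)
}

#' Mass-univariate vertex-wise general linear model
#'
#' Fits, at every vertex, ordinary least squares of volume on
#' \[intercept, effect, nuisance covariates\], returning the effect
#' estimate, its t statistic, the partial correlation
#' `r = sign(t) * sqrt(t^2 / (t^2 + df))` and a two-sided p-value from
#' the t distribution with `df = n - p` degrees of freedom.
#'
#' @param data subjects x vertices matrix of volumes, rows aligned with
#'   the cohort.
#' @param cohort a [cohort_table()].
#' @param design a [design_spec()].
#' @return a `stat_map`: data.frame with columns `vertex`, `estimate`,
#'   `t`, `r_partial`, `p`, carrying attributes `df`, `n` and `effect`.
#' @export
fit_vertex_glm <- function(data, cohort, design) {
  stopifnot(is.matrix(data))
  if (nrow(data) != nrow(cohort)) {
    stop("data rows must match cohort rows")
  }
  d <- build_design(cohort, design)
  Y <- data[d$rows, , drop = FALSE]
  X <- d$X
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 2) stop("too few subjects for the requested design")
  df <- n - p
  qrX <- d$qr
  coefs <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  sigma2 <- colSums(res^2) / df
  xtx_inv <- solve(crossprod(X))
  se <- sqrt(pmax(sigma2 * xtx_inv[2, 2], 0))
  est <- coefs[2, ]
  tstat <- ifelse(se > 0, est / se, 0)
  # exact dependence: residual variance 0 with nonzero estimate
  tstat[se == 0 & abs(est) > 1e-12 * (1 + abs(est))] <- Inf
  r <- sign(tstat) * sqrt(tstat^2 / (tstat^2 + df))
  r[!is.finite(tstat)] <- sign(est[!is.finite(tstat)])
  pval <- 2 * stats::pt(-abs(tstat), df)
  out <- data.frame(vertex = seq_len(ncol(Y)), estimate = est,
                    t = tstat, r_partial = r, p = pval)
  rownames(out) <- NULL
  attr(out, "df") <- df
  attr(out, "n") <- n
  attr(out, "effect") <- design$effect
  attr(out, "columns") <- colnames(X)
  class(out) <- c("stat_map", "data.frame")
  out
}

#' Rows usable for the one-class severity analysis
#'
#' Cases with a recorded severity score; the number of excluded cases
#' is reported via `message()`, mirroring the situation where some
#' enrolled patients lack a severity rating.
#'
#' @param cohort a [cohort_table()].
#' @param quiet suppress the message.
#' @return logical vector over cohort rows.
#' @export
severity_subset <- function(cohort, quiet = FALSE) {
  cases <- cohort$group == "case"
  ok <- cases & !is.na(cohort$severity)
  if (!quiet) {
    message(sum(ok), " of ", sum(cases),
            " cases have severity scores; ", sum(cases) - sum(ok),
            " excluded from the one-class analysis")
  }
  ok
}
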
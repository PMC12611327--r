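#' Read-depth-weighted binomial GLM of methylation on amyloid burden
#'
#' Fits one CpG: methylation proportion as binomial response with prior
#' weights equal to the read depth, linear predictor on amyloid percent
#' area plus age, sex and diet. The default link is logarithmic (as in the
#' published model), with a logistic fallback when the log-link fit does
#' not converge to valid fitted values; \code{link_used} in the record says
#' which converged. Wild-type samples (amyloid undefined/zero) are excluded
#' by the caller; the predictor must vary.
#'
#' @param meth,total integer read-count vectors for the site, one per
#'   sample.
#' @param samples data.frame with \code{amyloid_pct_area} and the covariate
#'   columns.
#' @param link \code{"log"} (default) or \code{"logit"}.
#' @param covariates covariate columns (defaults to age, sex, diet; columns
#'   absent or constant are dropped).
#' @param min_n minimum usable observations.
#' @return one-row data.frame: \code{beta_amyloid, se, p_value, n_used,
#'   link_used, reason}.
#' @export
fitPac <- function(meth, total, samples, link = c("log", "logit"),
                   covariates = c("age_months", "sex", "diet"),
                   min_n = 8L) {
  link <- match.arg(link)
  na_rec <- function(reason)
    data.frame(beta_amyloid = NA_real_, se = NA_real_, p_value = NA_real_,
               n_used = 0L, link_used = NA_character_, reason = reason,
               stringsAsFactors = FALSE)
  amy <- samples$amyloid_pct_area
  use <- total > 0L & !is.na(amy)
  if (sum(use) < min_n) return(na_rec("too_few_obs"))
  if (stats::sd(amy[use]) == 0) stop("no variation in amyloid predictor")
  df <- data.frame(amyloid = amy[use])
  for (v in intersect(covariates, names(samples))) {
    col <- samples[[v]][use]
    if (length(unique(col)) > 1) df[[v]] <- col
  }
  if ("age_months" %in% names(df))
    df$age_months <- df$age_months - mean(df$age_months)
  y <- meth[use] / total[use]; w <- total[use]
  X <- stats::model.matrix(~ ., df)
  fit <- NULL; link_used <- link
  if (link == "log") {
    start <- c(log(max(1e-3, stats::weighted.mean(y, w))),
               rep(0, ncol(X) - 1))
    fit <- .try_glm(X, y, w, stats::binomial(link = "log"), start)
    if (is.null(fit)) { # damped restart from half the intercept
      fit <- .try_glm(X, y, w, stats::binomial(link = "log"), start / 2)
    }
    if (is.null(fit)) link_used <- "logit"
  }
  if (is.null(fit))
    fit <- .try_glm(X, y, w, stats::binomial(), NULL)
  if (is.null(fit)) return(na_rec("fit_failed"))
  V <- .glmfit_vcov(fit, ncol(X))
  if (is.null(V) || fit$rank < ncol(X)) return(na_rec("rank_deficient"))
  se <- sqrt(diag(V))[2]
  b <- fit$coefficients[2]
  data.frame(beta_amyloid = b, se = se,
             p_value = 2 * stats::pnorm(-abs(b / se)),
             n_used = sum(use), link_used = link_used,
             reason = NA_character_, stringsAsFactors = FALSE)
}

.try_glm <- function(X, y, w, family, start) {
  fit <- tryCatch(suppressWarnings(
    stats::glm.fit(X, y, weights = w, family = family, start = start,
                   control = stats::glm.control(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  mu <- fit$fitted.values
  # a log-link fit pinned at the mu = 1 boundary "converges" numerically but
  # is invalid; treat near-boundary fitted values as failure
  bad <- if (family$link == "log") mu >= 1 - 1e-6 else mu >= 1
  if (any(!is.finite(mu)) || any(bad) || any(mu <= 0)) return(NULL)
  fit
}

#' Plaque-associated CpG scan over a site set
#'
#' Runs [fitPac()] at each supplied site (typically the ECpG set) in mutant
#' samples, optionally within one diet, and corrects p-values by
#' Benjamini-Hochberg within the (diet scope) family.
#'
#' @param mm \linkS4class{MethylMatrix} with the design in colData.
#' @param sites data.frame \code{chrom, pos} of sites to test (default: all
#'   sites in \code{mm}).
#' @param diet_scope \code{"all"}, \code{"control"} or
#'   \code{"supplemented"}.
#' @param link,covariates passed to [fitPac()] (diet is dropped from the
#'   covariates automatically when stratifying by diet).
#' @param q_cutoff PAC call threshold.
#' @return data.frame of records: \code{chrom, pos, beta_amyloid, se,
#'   p_value, q_value, n_used, diet_scope, link_used, is_pac, reason}.
#' @export
testPacs <- function(mm, sites = NULL,
                     diet_scope = c("all", "control", "supplemented"),
                     link = "log",
                     covariates = c("age_months", "sex", "diet"),
                     q_cutoff = 0.05) {
  diet_scope <- match.arg(diet_scope)
  cd <- as.data.frame(SummarizedExperiment::colData(mm))
  keep <- if ("genotype" %in% names(cd)) cd$genotype == "AppNLGF"
          else rep(TRUE, nrow(cd))
  if (diet_scope != "all") {
    keep <- keep & cd$diet == diet_scope
    covariates <- setdiff(covariates, "diet")
  }
  mm <- mm[, keep]; cd <- cd[keep, , drop = FALSE]
  lab <- siteLabels(mm)
  if (is.null(sites)) {
    rows <- seq_along(lab)
    sites <- data.frame(chrom = sub(":.*", "", lab),
                        pos = as.integer(sub(".*:", "", lab)))
  } else {
    rows <- match(paste0(sites$chrom, ":", sites$pos), lab)
  }
  meth <- methReads(mm); total <- totalReads(mm)
  recs <- lapply(seq_along(rows), function(k) {
    if (is.na(rows[k]))
      return(data.frame(beta_amyloid = NA_real_, se = NA_real_,
                        p_value = NA_real_, n_used = 0L,
                        link_used = NA_character_, reason = "site_absent"))
    fitPac(meth[rows[k], ], total[rows[k], ], cd, link = link,
           covariates = covariates)
  })
  out <- cbind(sites[, c("chrom", "pos")], do.call(rbind, recs),
               diet_scope = diet_scope)
  ok <- !is.na(out$p_value)
  out$q_value <- NA_real_
  out$q_value[ok] <- stats::p.adjust(out$p_value[ok], "BH")
  out$is_pac <- !is.na(out$q_value) & out$q_value < q_cutoff
  rownames(out) <- NULL
  out
}

#' Diet-specific classification of amyloid-associated CpGs
#'
#' Stratifies mutants by diet, runs [testPacs()] within each stratum and
#' classifies each site by its per-diet q-values at \code{q_cutoff}:
#' significant in exactly one stratum gives \code{control_only} or
#' \code{supplemented_only}; otherwise \code{both} or \code{neither}. An
#' additional amyloid-by-diet interaction fit on the pooled mutants is
#' reported alongside.
#'
#' @param mm MethylMatrix.
#' @param sites data.frame \code{chrom, pos}.
#' @param link,q_cutoff as in [testPacs()].
#' @return data.frame with per-diet estimates (\code{beta_control,
#'   q_control, beta_supplemented, q_supplemented}),
#'   \code{diet_specific_class}, and interaction term estimates
#'   (\code{beta_interaction, p_interaction}).
#' @export
classifyDietSpecific <- function(mm, sites, link = "log", q_cutoff = 0.05) {
  cd <- as.data.frame(SummarizedExperiment::colData(mm))
  app <- if ("genotype" %in% names(cd)) cd$genotype == "AppNLGF"
         else rep(TRUE, nrow(cd))
  for (dd in c("control", "supplemented"))
    if (sum(app & cd$diet == dd) < 6)
      stop("need >= 6 mutant samples per diet stratum")
  ctl <- testPacs(mm, sites, diet_scope = "control", link = link,
                  q_cutoff = q_cutoff)
  sup <- testPacs(mm, sites, diet_scope = "supplemented", link = link,
                  q_cutoff = q_cutoff)
  inter <- .pac_interaction(mm[, app], sites, link)
  cls <- mapply(function(qc, qs) {
    if (is.na(qc) || is.na(qs)) return(NA_character_)
    sc <- qc < q_cutoff; ss <- qs < q_cutoff
    if (sc && !ss) "control_only"
    else if (!sc && ss) "supplemented_only"
    else if (sc && ss) "both" else "neither"
  }, ctl$q_value, sup$q_value)
  data.frame(chrom = ctl$chrom, pos = ctl$pos,
             beta_control = ctl$beta_amyloid, q_control = ctl$q_value,
             beta_supplemented = sup$beta_amyloid,
             q_supplemented = sup$q_value,
             diet_specific_class = cls,
             beta_interaction = inter$beta, p_interaction = inter$p,
             stringsAsFactors = FALSE)
}

# amyloid x diet interaction on pooled mutant samples
.pac_interaction <- function(mm, sites, link) {
  cd <- as.data.frame(SummarizedExperiment::colData(mm))
  lab <- siteLabels(mm)
  rows <- match(paste0(sites$chrom, ":", sites$pos), lab)
  meth <- methReads(mm); total <- totalReads(mm)
  res <- vapply(rows, function(r) {
    if (is.na(r)) return(c(NA_real_, NA_real_))
    use <- total[r, ] > 0L & !is.na(cd$amyloid_pct_area)
    if (sum(use) < 10) return(c(NA_real_, NA_real_))
    df <- data.frame(amyloid = cd$amyloid_pct_area[use],
                     diet = cd$diet[use],
                     age_c = cd$age_months[use] - mean(cd$age_months[use]),
                     sex = cd$sex[use])
    X <- stats::model.matrix(~ amyloid * diet + age_c + sex, df)
    fam <- if (link == "log") stats::binomial("log") else stats::binomial()
    start <- if (link == "log")
      c(log(max(1e-3, stats::weighted.mean(meth[r, use] / total[r, use],
                                           total[r, use]))),
        rep(0, ncol(X) - 1)) else NULL
    fit <- .try_glm(X, meth[r, use] / total[r, use], total[r, use], fam,
                    start)
    if (is.null(fit))
      fit <- .try_glm(X, meth[r, use] / total[r, use], total[r, use],
                      stats::binomial(), NULL)
    if (is.null(fit) || fit$rank < ncol(X)) return(c(NA_real_, NA_real_))
    V <- .glmfit_vcov(fit, ncol(X))
    if (is.null(V)) return(c(NA_real_, NA_real_))
    j <- which(colnames(X) == "amyloid:dietsupplemented")
    if (!length(j)) return(c(NA_real_, NA_real_))
    b <- fit$coefficients[j]; se <- sqrt(diag(V))[j]
    c(b, 2 * stats::pnorm(-abs(b / se)))
  }, numeric(2))
  list(beta = res[1, ], p = res[2, ])
}
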
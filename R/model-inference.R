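#' Standardize predictors to zero mean and unit variance
#'
#' Column-wise `(x - mean) / sd` (sd with the `n - 1` denominator), so that
#' regression coefficients are comparable across predictors. The centering
#' and scaling constants are attached for back-transformation.
#'
#' @param X data.frame or matrix of numeric predictors; no column may be
#'   constant.
#' @return object of the same shape with attributes `"center"` and
#'   `"scale"`.
#' @export
standardizePredictors <- function(X) {
  Xm <- as.matrix(X)
  ctr <- colMeans(Xm)
  scl <- apply(Xm, 2, stats::sd)
  if (any(scl == 0))
    stop("constant column(s): ",
         paste(colnames(Xm)[scl == 0], collapse = ", "))
  out <- sweep(sweep(Xm, 2, ctr), 2, scl, "/")
  if (is.data.frame(X)) out <- as.data.frame(out)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Fit a Gaussian GLM and compute information criteria
#'
#' Ordinary least squares via [stats::lm()], summarised on the Gaussian
#' maximum-likelihood scale: `loglik = -n/2 (log(2 pi) + log(rss/n) + 1)`,
#' `AIC = -2 loglik + 2k` and `AICc = AIC + 2k(k+1)/(n-k-1)`, where the
#' parameter count `k` includes the intercept, the slope terms and the
#' residual variance. `R2 = 1 - rss/tss`. A perfect fit (`rss = 0`) is
#' reported with `loglik = Inf` and `AIC = -Inf`.
#'
#' @param y numeric response.
#' @param data data.frame holding the predictor columns.
#' @param terms character vector of column names to include (empty for the
#'   intercept-only model).
#' @param response label stored in the fit.
#' @return a \linkS4class{ModelFit}.
#' @examples
#' fitGaussian(c(1, 2, 2, 4), data.frame(x = 1:4), "x")
#' @export
fitGaussian <- function(y, data = NULL, terms = character(0),
                        response = "y") {
  n <- length(y)
  terms <- as.character(terms)
  if (length(terms)) {
    stopifnot(!is.null(data), all(terms %in% names(data)))
    df <- data.frame(.y = y, as.data.frame(data)[terms],
                     check.names = FALSE)
    fit <- stats::lm(.y ~ ., data = df)
  } else {
    fit <- stats::lm(y ~ 1)
  }
  b <- stats::coef(fit)
  if (anyNA(b))
    stop("rank-deficient design; aliased terms: ",
         paste(names(b)[is.na(b)], collapse = ", "))
  k <- length(b) + 1L          # + residual variance
  if (n <= k - 1L) stop("more parameters than observations")
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  if (rss < 1e-12 * max(tss, 1)) {
    ll <- Inf; aic <- -Inf; aicc <- -Inf
  } else {
    ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    aic <- -2 * ll + 2 * k
    aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  }
  se <- tryCatch(suppressWarnings(summary(fit))$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(b)))
  if (length(se) != length(b)) se <- rep(NA_real_, length(b))
  methods::new("ModelFit", response = response, terms = terms,
               coefficients = b, se = stats::setNames(se, names(b)),
               n = as.integer(n), k = as.integer(k), rss = rss,
               loglik = ll, aic = aic, aicc = aicc,
               r2 = if (is.na(r2)) NA_real_ else max(min(r2, 1), 0),
               fitted = as.numeric(stats::fitted(fit)))
}

#' Compare nested models by AIC
#'
#' Fits the base model and the base model extended by `extraTerms`
#' (typically a quadratic term) and returns the fit with the lower AIC;
#' ties go to the smaller model.
#'
#' @param y response.
#' @param data predictor data.frame.
#' @param baseTerms,extraTerms character term sets.
#' @param response label.
#' @return list with `chosen` (\linkS4class{ModelFit}), `base`, `extended`
#'   and a two-row `table` of AIC values.
#' @export
compareNestedByAIC <- function(y, data, baseTerms, extraTerms,
                               response = "y") {
  f0 <- fitGaussian(y, data, baseTerms, response)
  f1 <- fitGaussian(y, data, c(baseTerms, extraTerms), response)
  tab <- data.frame(model = c("base", "extended"),
                    k = c(f0@k, f1@k),
                    aic = c(f0@aic, f1@aic),
                    r2 = c(f0@r2, f1@r2))
  chosen <- if (f1@aic < f0@aic - 1e-12) f1 else f0
  list(chosen = chosen, base = f0, extended = f1, table = tab)
}

#' Screen predictors for collinearity
#'
#' Flags predictor pairs whose absolute Pearson correlation exceeds `rMax`,
#' then iteratively removes the predictor with the largest variance
#' inflation factor (`VIF_k = 1 / (1 - R2_k)`, regressing predictor `k` on
#' the remaining ones) until all VIFs are at most `vifMax`.
#'
#' @param X data.frame/matrix of at least two numeric predictors, none
#'   constant.
#' @param rMax pairwise correlation threshold (default 0.75).
#' @param vifMax VIF threshold (default 5).
#' @return list with `retained`, `removed` (in removal order),
#'   `correlationFlags` (data.frame of offending pairs) and `vif` (final
#'   VIFs of the retained set).
#' @export
screenCollinearity <- function(X, rMax = 0.75, vifMax = 5) {
  Xm <- as.matrix(X)
  if (ncol(Xm) < 2) stop("at least two predictors are required")
  if (any(apply(Xm, 2, stats::sd) == 0)) stop("constant predictor")
  cm <- stats::cor(Xm)
  hi <- which(abs(cm) > rMax & upper.tri(cm), arr.ind = TRUE)
  flags <- data.frame(var1 = colnames(cm)[hi[, 1]],
                      var2 = colnames(cm)[hi[, 2]],
                      r = cm[hi])
  vifOf <- function(cols) {
    vapply(cols, function(v) {
      r2 <- suppressWarnings(
        summary(stats::lm(Xm[, v] ~ Xm[, setdiff(cols, v),
                                       drop = FALSE])))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  keep <- colnames(Xm)
  removed <- character(0)
  while (length(keep) >= 2) {
    v <- vifOf(keep)
    if (max(v) <= vifMax) break
    worst <- names(v)[which.max(v)]
    removed <- c(removed, worst)
    keep <- setdiff(keep, worst)
  }
  finalVif <- if (length(keep) >= 2) vifOf(keep)
              else stats::setNames(rep(1, length(keep)), keep)
  list(retained = keep, removed = removed, correlationFlags = flags,
       vif = finalVif)
}

.modelLabel <- function(terms) {
  if (length(terms)) paste(terms, collapse = " + ") else "(intercept)"
}

.rankFits <- function(fits, response, meta = list()) {
  aicc <- vapply(fits, function(f) f@aicc, numeric(1))
  ord <- order(aicc)
  fits <- fits[ord]
  aicc <- aicc[ord]
  delta <- aicc - aicc[1]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  tab <- data.frame(model = vapply(fits, function(f) .modelLabel(f@terms),
                                   character(1)),
                    k = vapply(fits, function(f) f@k, integer(1)),
                    aicc = aicc, delta = delta, weight = w)
  rownames(tab) <- NULL
  methods::new("ModelSet", fits = fits, table = tab,
               meta = c(meta, list(response = response)))
}

#' All-subsets Gaussian GLM candidate set
#'
#' Fits every additive combination of the supplied terms (2^p models,
#' including the intercept-only model), optionally considering a quadratic
#' term for one predictor. Following the marginality principle the squared
#' term only enters together with its linear term, so each subset
#' containing `quadraticFor` is fitted both with and without the square.
#' Models are ranked by AICc with Akaike weights.
#'
#' @param y response.
#' @param data predictor data.frame.
#' @param terms character vector of candidate (linear) terms, `p <= 20`.
#' @param quadraticFor optional name of the predictor whose square is
#'   considered; a column `<name>_sq` is created internally.
#' @param response label.
#' @return a \linkS4class{ModelSet}. Subsets too large for the sample size
#'   are skipped with a warning.
#' @export
allSubsets <- function(y, data, terms, quadraticFor = NULL, response = "y") {
  p <- length(terms)
  if (p > 20) stop("too many predictors for exhaustive enumeration")
  data <- as.data.frame(data)
  sq <- NULL
  if (!is.null(quadraticFor)) {
    stopifnot(quadraticFor %in% terms)
    sq <- paste0(quadraticFor, "_sq")
    data[[sq]] <- data[[quadraticFor]]^2
  }
  subsets <- list(character(0))
  for (h in seq_len(p))
    subsets <- c(subsets,
                 utils::combn(terms, h, simplify = FALSE))
  termSets <- subsets
  if (!is.null(sq))
    termSets <- c(termSets,
                  lapply(Filter(function(s) quadraticFor %in% s, subsets),
                         function(s) c(s, sq)))
  fits <- list()
  skipped <- 0L
  for (s in termSets) {
    if (length(y) - (length(s) + 2L) - 1L <= 0) { skipped <- skipped + 1L; next }
    fits[[length(fits) + 1L]] <- fitGaussian(y, data, s, response)
  }
  if (skipped)
    warning(sprintf("%d subset(s) skipped: too few observations", skipped))
  if (!length(fits)) stop("no feasible subset")
  .rankFits(fits, response)
}

#' Confidence set of plausible models
#'
#' Retains the models within `deltaMax` AICc units of the best model (the
#' best model always included) and renormalizes the Akaike weights within
#' the subset.
#'
#' @param ms a \linkS4class{ModelSet}.
#' @param deltaMax ΔAICc cut-off (default 2).
#' @return the reduced \linkS4class{ModelSet}.
#' @export
confidenceSet <- function(ms, deltaMax = 2) {
  keep <- ms@table$delta <= deltaMax + 1e-12
  fits <- ms@fits[keep]
  out <- .rankFits(fits, ms@meta$response,
                   meta = list(confidenceSet = TRUE, deltaMax = deltaMax))
  out
}

#' Model-averaged coefficients, intervals and relative importance
#'
#' Conditional (natural) averaging over a confidence set: for each term,
#' the estimate is the weighted mean of the coefficients of the models
#' containing it (weights renormalized over that subset); the unconditional
#' standard error follows the Burnham-Anderson formula
#' `se = sum_i w_i sqrt(se_i^2 + (b_i - b_bar)^2)`; the 95% CI is the
#' normal approximation `b_bar +/- 1.96 se`; the relative importance is the
#' sum of the (confidence-set renormalized) weights of the models
#' containing the term, so a term present in every model has RI 1.
#'
#' @param cs a \linkS4class{ModelSet}, typically from [confidenceSet()].
#' @return an \linkS4class{AveragedModel}.
#' @export
averageModel <- function(cs) {
  w <- cs@table$weight
  allTerms <- unique(unlist(lapply(cs@fits, function(f) names(f@coefficients))))
  rows <- lapply(allTerms, function(t) {
    has <- vapply(cs@fits, function(f) t %in% names(f@coefficients),
                  logical(1))
    wi <- w[has] / sum(w[has])
    bi <- vapply(cs@fits[has], function(f) f@coefficients[[t]], numeric(1))
    si <- vapply(cs@fits[has], function(f) f@se[[t]], numeric(1))
    bbar <- sum(wi * bi)
    se <- sum(wi * sqrt(si^2 + (bi - bbar)^2))
    data.frame(term = t, estimate = bbar, se = se,
               ci_lower = bbar - 1.96 * se, ci_upper = bbar + 1.96 * se,
               ri = sum(w[has]))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  methods::new("AveragedModel", table = tab,
               nModels = length(cs@fits))
}

#' Hierarchical partitioning of explained variance
#'
#' Decomposes the full-model R2 into per-predictor independent effects by
#' averaging, over all subset sizes and all subsets of the other
#' predictors, the R2 improvement obtained by adding the focal predictor
#' (the Chevan-Sutherland algorithm over all `2^p` least-squares fits):
#' \deqn{I_k = \frac{1}{p} \sum_{h=0}^{p-1} \mathrm{mean}_{|S| = h,\,
#'   k \notin S} \left[R^2(S \cup \{k\}) - R^2(S)\right]}
#' The joint effect is `J_k = R2({k}) - I_k`. The independent effects sum
#' exactly to the full-model R2.
#'
#' @param y response.
#' @param data predictor data.frame.
#' @param terms predictors to partition (`p <= 12`).
#' @return data.frame with `term`, `independent`, `joint`,
#'   `independent_pct`; full-model R2 in attribute `"full_r2"`.
#' @export
hierarchicalPartition <- function(y, data, terms) {
  p <- length(terms)
  if (p < 1) stop("at least one predictor is required")
  if (p > 12) stop("too many predictors for exhaustive partitioning")
  data <- as.data.frame(data)
  r2 <- numeric(2^p)
  for (m in 0:(2^p - 1)) {
    s <- terms[bitwAnd(m, bitwShiftL(1, 0:(p - 1))) > 0]
    r2[m + 1] <- if (length(s)) fitGaussian(y, data, s)@r2 else 0
  }
  indep <- numeric(p)
  for (kk in seq_len(p)) {
    bit <- bitwShiftL(1, kk - 1)
    acc <- 0
    for (m in 0:(2^p - 1)) {
      if (bitwAnd(m, bit) > 0) next
      h <- sum(bitwAnd(m, bitwShiftL(1, 0:(p - 1))) > 0)
      wgt <- 1 / (p * choose(p - 1, h))
      acc <- acc + wgt * (r2[m + bit + 1] - r2[m + 1])
    }
    indep[kk] <- acc
  }
  marg <- vapply(seq_len(p),
                 function(kk) r2[bitwShiftL(1, kk - 1) + 1], numeric(1))
  out <- data.frame(term = terms, independent = indep,
                    joint = marg - indep,
                    independent_pct = 100 * indep / sum(indep))
  attr(out, "full_r2") <- r2[2^p]
  out
}

#' Select a buffer radius by AIC and R2
#'
#' For each response and each candidate buffer-specific metric, fits the
#' simple Gaussian GLM `response ~ metric` and tabulates AIC and R2. The
#' chosen radius is the one with the lowest mean AIC rank across responses,
#' ties broken by the higher mean R2.
#'
#' @param responses named list of per-site response vectors.
#' @param candidates named list (one entry per radius) of site-aligned
#'   metric vectors.
#' @return list with `chosen` (name of the selected radius) and `table`
#'   (response x radius rows of AIC and R2).
#' @export
selectBuffer <- function(responses, candidates) {
  if (length(candidates) < 1) stop("no candidate radii")
  nSite <- length(responses[[1]])
  ok <- vapply(candidates, length, integer(1)) == nSite &
    vapply(responses, length, integer(1))[1] == nSite
  if (!all(vapply(responses, length, integer(1)) == nSite) ||
      !all(vapply(candidates, length, integer(1)) == nSite))
    stop("responses and candidate metrics must align to the same sites")
  rows <- list()
  for (r in names(responses)) for (b in names(candidates)) {
    f <- fitGaussian(responses[[r]], data.frame(m = candidates[[b]]), "m",
                     response = r)
    rows[[length(rows) + 1L]] <-
      data.frame(response = r, radius = b, aic = f@aic, r2 = f@r2)
  }
  tab <- do.call(rbind, rows)
  tab$rank <- stats::ave(tab$aic, tab$response, FUN = rank)
  mrank <- tapply(tab$rank, tab$radius, mean)
  mr2 <- tapply(tab$r2, tab$radius, mean)
  best <- names(mrank)[mrank == min(mrank)]
  chosen <- if (length(best) > 1) best[which.max(mr2[best])] else best
  list(chosen = chosen, table = tab[, c("response", "radius", "aic", "r2")])
}

#' Refit after declared outlier exclusion
#'
#' Refits a model with explicitly named sites removed and reports the R2
#' change. Exclusions are user input (no automatic outlier detection) and
#' are echoed in the result for the record.
#'
#' @param y response (named by site, or supply `siteIDs`).
#' @param data predictor data.frame.
#' @param terms model terms.
#' @param exclude character ids of sites to drop.
#' @param siteIDs site ids aligned to `y` (default `names(y)`).
#' @param response label.
#' @return list with `before`, `after` (\linkS4class{ModelFit}),
#'   `delta_r2` and `excluded`.
#' @export
refitExcluding <- function(y, data, terms, exclude,
                           siteIDs = names(y), response = "y") {
  if (is.null(siteIDs)) stop("site ids are required")
  if (!all(exclude %in% siteIDs))
    stop("unknown site id(s): ",
         paste(setdiff(exclude, siteIDs), collapse = ", "))
  keep <- !(siteIDs %in% exclude)
  k <- length(terms) + 2L
  if (sum(keep) - k - 1L <= 0)
    stop("exclusion leaves too few sites for the model")
  before <- fitGaussian(y, data, terms, response)
  after <- fitGaussian(y[keep], as.data.frame(data)[keep, , drop = FALSE],
                       terms, response)
  list(before = before, after = after,
       delta_r2 = after@r2 - before@r2, excluded = exclude)
}
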
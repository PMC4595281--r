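#' Repeated-measures ANOVA on a cohort table
#'
#' Univariate repeated-measures ANOVA with subject-partitioned error
#' strata, for the group comparisons of ROI activation: within-subject
#' factors (e.g. ROI with 6 levels, hemisphere with 2, amplitude/force
#' level with 3) crossed with a between-subject group factor. For the
#' laterality index, which is a segment-pair-level quantity, the
#' hemisphere factor must be omitted.
#'
#' The design must be complete: every subject needs one observation per
#' within-cell. Sums of squares follow the standard subject-partitioned
#' univariate decomposition (as computed by \code{aov} with an
#' \code{Error(subject/...)} term); no sphericity correction is applied
#' by default, matching common reporting practice, with
#' Greenhouse-Geisser available via \code{ggCorrect} for the
#' one-within-factor strata.
#'
#' @param table data.frame with one row per subject x within-cell;
#'   must contain \code{subject} and the named factor columns.
#' @param dv name of the dependent-variable column (e.g.
#'   \code{"mean_beta"} or \code{"li"}).
#' @param within character vector of within-subject factor columns.
#' @param between optional between-subject factor column (e.g.
#'   \code{"group"}).
#' @param ggCorrect logical, apply a Greenhouse-Geisser epsilon
#'   correction to within-stratum p-values (default FALSE).
#' @return data.frame with columns \code{effect}, \code{F},
#'   \code{df_num}, \code{df_den}, \code{p}, one row per main effect and
#'   interaction (between-factor effects appear crossed into the
#'   within-strata, e.g. \code{group:roi}).
#' @export
rmAnova <- function(table, dv, within, between = NULL, ggCorrect = FALSE) {
  stopifnot(is.data.frame(table), dv %in% names(table),
            all(within %in% names(table)))
  if (!"subject" %in% names(table)) stop("table must have a subject column")
  tab <- table
  tab$subject <- factor(tab$subject)
  for (f in c(within, between)) tab[[f]] <- factor(tab[[f]])
  ## completeness check: every subject must fill every within-cell once
  cell <- interaction(tab[within], drop = FALSE)
  counts <- table(tab$subject, cell)
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)
    miss <- paste(rownames(counts)[bad[, 1]], colnames(counts)[bad[, 2]],
                  sep = ":")
    stop("unbalanced design; cells not observed exactly once: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) " ...")
  }
  if (stats::sd(tab[[dv]]) == 0) {
    warning("dependent variable has zero variance; F undefined, ",
            "returning empty result")
    return(data.frame(effect = character(), F = numeric(),
                      df_num = numeric(), df_den = numeric(),
                      p = numeric()))
  }
  withinTerm <- paste(within, collapse = "*")
  fixed <- if (is.null(between)) withinTerm
           else paste0(between, "*", withinTerm)
  form <- stats::as.formula(paste0(
    dv, " ~ ", fixed, " + Error(subject/(", withinTerm, "))"
  ))
  fit <- stats::aov(form, data = tab)
  out <- do.call(rbind, lapply(summary(fit), function(stratum) {
    s <- stratum[[1]]
    eff <- trimws(rownames(s))
    keep <- eff != "Residuals" & !is.na(s[["F value"]])
    if (!any(keep)) return(NULL)
    dfDen <- s[eff == "Residuals", "Df"]
    data.frame(
      effect = eff[keep], F = s[keep, "F value"],
      df_num = s[keep, "Df"], df_den = dfDen,
      p = s[keep, "Pr(>F)"], stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  if (ggCorrect) out <- applyGgCorrection(out, tab, dv, within, between)
  out
}

## Greenhouse-Geisser epsilon per single within factor; interactions of
## several within factors keep uncorrected p (epsilon of their product
## cells is not identified without the full covariance model)
applyGgCorrection <- function(out, tab, dv, within, between) {
  for (f in within) {
    wide <- stats::reshape(
      stats::aggregate(tab[[dv]], list(subject = tab$subject,
                                       lev = tab[[f]]), mean),
      idvar = "subject", timevar = "lev", direction = "wide"
    )
    S <- stats::cov(wide[, -1, drop = FALSE])
    p <- ncol(S)
    if (p < 2) next
    dbar <- mean(diag(S)); gbar <- mean(S)
    rowm <- rowMeans(S)
    eps <- (p * (dbar - gbar))^2 /
      ((p - 1) * (sum(S^2) - 2 * p * sum(rowm^2) + p^2 * gbar^2))
    hit <- vapply(strsplit(out$effect, ":"), function(parts)
      f %in% parts && all(parts %in% c(f, between)), logical(1))
    out$p[hit] <- stats::pf(out$F[hit], eps * out$df_num[hit],
                            eps * out$df_den[hit], lower.tail = FALSE)
  }
  out
}

#' Student t-tests with the cohort missing-value policy
#'
#' Classic Student statistics (equal-variance two-sample, paired, or
#' one-sample against \code{mu}), with missing values removed pairwise
#' for paired tests and per-sample otherwise — the complete-case policy
#' used for performance tables with equipment-failure gaps.
#'
#' @param a numeric sample.
#' @param b optional second sample; NULL for a one-sample test.
#' @param paired logical; pair \code{a} and \code{b} by position.
#' @param mu null value for the one-sample test (default 0).
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
tTests <- function(a, b = NULL, paired = FALSE, mu = 0) {
  if (is.null(b)) {
    a <- a[!is.na(a)]
    if (length(a) < 2) stop("need at least 2 non-missing values")
    ht <- stats::t.test(a, mu = mu)
  } else if (paired) {
    if (length(a) != length(b))
      stop("paired test requires equal-length samples")
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2) stop("fewer than 2 complete pairs")
    d <- a[ok] - b[ok]
    if (stats::sd(d) == 0 && mean(d) == 0)
      return(list(t = 0, df = sum(ok) - 1, p = 1)) # identical samples
    ht <- stats::t.test(a[ok], b[ok], paired = TRUE)
  } else {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2)
      stop("need at least 2 non-missing values per sample")
    ht <- stats::t.test(a, b, var.equal = TRUE)
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' One-sample Wilcoxon signed-rank test against a scale value
#'
#' Tests whether a clinical score sample differs from a reference value
#' (typically the scale maximum, e.g. 57 for the ARAT or 66 for the
#' Fugl-Meyer arm score). Zero differences are dropped (classic
#' signed-rank convention). Clinical scales produce heavy ties, so the
#' default is the tie-corrected normal approximation without continuity
#' correction — the form used by mainstream statistics packages for this
#' test; the exact null distribution is available for small untied
#' samples.
#'
#' @param x numeric sample (missing values dropped).
#' @param mu reference value.
#' @param exact logical; force the exact distribution (only valid
#'   without ties). Default FALSE.
#' @param correct continuity correction for the normal approximation.
#' @return list with \code{W} (signed-rank statistic), \code{p}
#'   (two-sided), and \code{n} (nonzero differences used).
#' @export
oneSampleWilcoxon <- function(x, mu, exact = FALSE, correct = FALSE) {
  x <- x[!is.na(x)]
  d <- x - mu
  nz <- sum(d != 0)
  if (nz < 1) stop("all differences from mu are zero")
  ht <- suppressWarnings(
    stats::wilcox.test(x, mu = mu, exact = exact, correct = correct)
  )
  list(W = unname(ht$statistic), p = ht$p.value, n = nz)
}

#' Stepwise brain-behavior regression
#'
#' Forward-entry, backward-removal stepwise linear regression of a
#' clinical score on per-ROI activation levels: at each step the
#' candidate with the smallest partial-F p-value enters if p < pIn;
#' after every entry, any retained factor whose partial-F p exceeds pOut
#' is removed; iterate to a fixed point. Ties between equally
#' significant candidates are broken by the lowest column index, so the
#' procedure is deterministic. Candidates whose entry would make the
#' design rank-deficient (collinear predictors) are skipped with a
#' warning.
#'
#' @param predictors numeric matrix (subjects x ROIs), preferably with
#'   column names.
#' @param y numeric response (clinical score), same length as
#'   \code{nrow(predictors)}.
#' @param pIn entry threshold (default 0.05).
#' @param pOut removal threshold (default 0.10).
#' @return list of class \code{"StepwiseResult"}: \code{selected}
#'   (column names in entry order), \code{coefficients} of the final
#'   model, \code{steps} (data.frame log of entries/removals with
#'   p-values), and \code{fit} (the final \code{lm}, or NULL if empty).
#' @export
stepwiseRegression <- function(predictors, y, pIn = 0.05, pOut = 0.10) {
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(y) == nrow(X), pIn > 0, pOut >= pIn)
  ok <- stats::complete.cases(X, y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  current <- integer() # column indices in entry order
  log <- list()
  partialP <- function(cols, cand) {
    ## p-value of the last predictor given the others
    Xm <- cbind(1, X[, c(cols, cand), drop = FALSE])
    if (qr(Xm)$rank < ncol(Xm)) return(NA_real_) # collinear
    fit <- stats::lm.fit(Xm, y)
    dfRes <- length(y) - ncol(Xm)
    if (dfRes < 1) return(NA_real_)
    rss1 <- sum(fit$residuals^2)
    Xr <- cbind(1, X[, cols, drop = FALSE])
    rss0 <- sum(stats::lm.fit(Xr, y)$residuals^2)
    Fv <- (rss0 - rss1) / (rss1 / dfRes)
    stats::pf(Fv, 1, dfRes, lower.tail = FALSE)
  }
  repeat {
    changed <- FALSE
    ## forward entry
    cands <- setdiff(seq_len(ncol(X)), current)
    if (length(cands) && length(y) > length(current) + 3) {
      ps <- vapply(cands, function(j) partialP(current, j), numeric(1))
      if (anyNA(ps))
        warning("skipped collinear candidate(s): ",
                paste(colnames(X)[cands[is.na(ps)]], collapse = ", "))
      psOk <- ps; psOk[is.na(psOk)] <- Inf
      best <- which.min(psOk) # ties -> lowest index
      if (psOk[best] < pIn) {
        current <- c(current, cands[best])
        log[[length(log) + 1]] <- data.frame(
          step = length(log) + 1, action = "enter",
          term = colnames(X)[cands[best]], p = ps[best]
        )
        changed <- TRUE
      }
    }
    ## backward removal
    repeat {
      if (length(current) < 1) break
      ps <- vapply(seq_along(current), function(i)
        partialP(current[-i], current[i]), numeric(1))
      worst <- which.max(ifelse(is.na(ps), -Inf, ps))
      if (!is.na(ps[worst]) && ps[worst] > pOut) {
        log[[length(log) + 1]] <- data.frame(
          step = length(log) + 1, action = "remove",
          term = colnames(X)[current[worst]], p = ps[worst]
        )
        current <- current[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- if (length(current)) {
    d <- data.frame(y = y, X[, current, drop = FALSE])
    stats::lm(y ~ ., data = d)
  } else NULL
  structure(
    list(
      selected = colnames(X)[current],
      coefficients = if (is.null(fit)) numeric() else stats::coef(fit),
      steps = if (length(log)) do.call(rbind, log)
              else data.frame(step = integer(), action = character(),
                              term = character(), p = numeric()),
      fit = fit
    ),
    class = "StepwiseResult"
  )
}

#' @export
print.StepwiseResult <- function(x, ...) {
  if (!length(x$selected)) {
    cat("StepwiseResult: empty model (no factor met the entry",
        "threshold)\n")
  } else {
    cat("StepwiseResult:", length(x$selected), "factor(s) retained:",
        paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Voxelwise two-sample t-test with permutation family-wise correction
#'
#' Smooths every volume, computes a per-voxel equal-variance two-sample
#' t statistic between groups, and controls the family-wise error by the
#' permutation distribution of the maximum |t| over voxels: group labels
#' are permuted \code{nPerm} times and the observed map is thresholded
#' at the (1 - alpha) quantile of the max-|t| null. This is a
#' self-contained, assumption-light substitute for parametric corrected
#' thresholds, and is recorded as such in the result metadata.
#'
#' @param betas list of \linkS4class{BetaVolume}s on a common grid.
#' @param groups factor or character vector of length
#'   \code{length(betas)} with exactly two levels.
#' @param fwhmMm smoothing kernel FWHM in mm (default 8; 0 disables).
#' @param nPerm number of label permutations (default 1000; below 100 a
#'   warning is issued).
#' @param alpha family-wise error level (default 0.05).
#' @param seed integer seed for the permutation draws.
#' @return list with \code{tmap} (3-D array), \code{threshold},
#'   \code{surviving} (logical array), \code{maxNull} (the permutation
#'   null sample), and \code{method} metadata.
#' @export
voxelwiseGroupTtest <- function(betas, groups, fwhmMm = 8, nPerm = 1000,
                                alpha = 0.05, seed = NULL) {
  stopifnot(length(betas) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (min(table(groups)) < 2) stop("need >= 2 subjects per group")
  dims <- dim(voxelGrid(betas[[1]]))
  okDims <- vapply(betas, function(b) all(dim(voxelGrid(b)) == dims),
                   logical(1))
  if (!all(okDims)) stop("volumes are not on a common grid")
  if (nPerm < 100) warning("nPerm = ", nPerm, " is low for family-wise ",
                           "correction; consider >= 1000")
  sm <- lapply(betas, smoothVolume, fwhmMm = fwhmMm)
  M <- vapply(sm, function(b) as.vector(voxelGrid(b)),
              numeric(prod(dims))) # voxels x subjects
  g <- as.integer(groups) == 1L
  tObs <- rowTtest(M, g)
  maxNull <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      gp <- sample(g)
      max(abs(rowTtest(M, gp)))
    }, numeric(1))
  })
  thr <- stats::quantile(maxNull, 1 - alpha, names = FALSE, type = 1)
  list(
    tmap = array(tObs, dims),
    threshold = thr,
    surviving = array(abs(tObs) > thr, dims),
    maxNull = maxNull,
    method = list(
      correction = "permutation max-|t| family-wise",
      fwhm_mm = fwhmMm, n_perm = nPerm, alpha = alpha
    )
  )
}

## vectorized per-row equal-variance two-sample t
rowTtest <- function(M, g) {
  n1 <- sum(g); n2 <- sum(!g)
  m1 <- rowMeans(M[, g, drop = FALSE])
  m2 <- rowMeans(M[, !g, drop = FALSE])
  v1 <- rowSums((M[, g, drop = FALSE] - m1)^2)
  v2 <- rowSums((M[, !g, drop = FALSE] - m2)^2)
  sp2 <- (v1 + v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0] <- 0
  t
}
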
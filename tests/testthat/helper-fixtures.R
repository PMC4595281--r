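# Small deterministic fixtures shared across test files.

# short paradigm: 10 s blocks over 80 s, 2 Hz sampling
shortBoxcar <- function() makeTaskBoxcar(blockS = 10, totalS = 80, dt = 0.5)

# standard paradigm
fullBoxcar <- function() makeTaskBoxcar()

smallAtlas <- function(shape = c(8, 8, 6)) makeLabelAtlas(shape)

# a sinusoid wrapped as a SampledSeries
sineSeries <- function(freqHz, durS, fs, amp = 1) {
  t <- seq(0, durS - 1 / fs, by = 1 / fs)
  sampledSeries(amp * sin(2 * pi * freqHz * t), fs)
}

# brute-force top-k selection by full sort (independent of the package path)
bruteTopK <- function(values, indices, k) {
  ord <- order(-values[indices], indices)
  indices[ord[seq_len(k)]]
}

# Independent sums-of-squares oracle for a balanced mixed design:
# one between factor (group) and one within factor (a), subjects nested.
mixedAnovaOracle <- function(d) {
  ybar <- mean(d$y)
  G <- sort(unique(d$group)); A <- sort(unique(d$a))
  S <- sort(unique(d$subject))
  a <- length(A)
  mG <- tapply(d$y, d$group, mean)
  mA <- tapply(d$y, d$a, mean)
  mS <- tapply(d$y, d$subject, mean)
  mGA <- tapply(d$y, list(d$group, d$a), mean)
  gOf <- tapply(d$group, d$subject, function(g) g[1])
  nG <- table(gOf)[G]
  ssG <- a * sum(nG * (mG[G] - ybar)^2)
  ssSubj <- a * sum((mS[S] - mG[gOf[S]])^2)
  ssA <- length(S) * sum((mA[A] - ybar)^2)
  ssGA <- 0
  for (g in G) for (aa in A)
    ssGA <- ssGA + nG[[g]] * (mGA[g, aa] - mG[[g]] - mA[[aa]] + ybar)^2
  ssWithinErr <- sum((d$y - mS[d$subject] - mGA[cbind(d$group, d$a)] +
                        mG[d$group])^2)
  dfG <- length(G) - 1; dfSubj <- length(S) - length(G)
  dfA <- a - 1; dfGA <- dfG * dfA; dfErr <- dfSubj * dfA
  list(
    F_group = (ssG / dfG) / (ssSubj / dfSubj),
    F_a = (ssA / dfA) / (ssWithinErr / dfErr),
    F_ga = (ssGA / dfGA) / (ssWithinErr / dfErr)
  )
}

# brute-force forward selection: refit every candidate, enter min-p
forwardOracle <- function(X, y, pIn) {
  sel <- integer()
  repeat {
    cands <- setdiff(seq_len(ncol(X)), sel)
    if (!length(cands)) break
    ps <- vapply(cands, function(j) {
      f <- summary(lm(y ~ X[, c(sel, j), drop = FALSE]))
      cf <- coef(f)
      cf[nrow(cf), 4]
    }, numeric(1))
    if (min(ps) >= pIn) break
    sel <- c(sel, cands[which.min(ps)])
  }
  colnames(X)[sel]
}
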
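#' @include ExpressionStudy-methods.R
#' @importFrom stats p.adjust digamma trigamma psigamma
NULL

#' Quantile-normalize an expression matrix
#'
#' Forces every column to the same distribution: each column's sorted
#' values are replaced by the row-wise mean of all columns' sorted values;
#' tied values receive the average of the quantiles they span. Offered as a
#' light-weight normalization for matrices that did not go through a full
#' array-summarization pipeline.
#'
#' @param m numeric matrix (genes x samples), all values finite.
#' @return matrix of the same shape and dimnames.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantileNormalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need >= 2 samples")
  if (!all(is.finite(m))) stop("non-finite values in matrix")
  ref <- rowMeans(apply(m, 2L, sort))
  out <- apply(m, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    # average the reference quantiles a tie group spans
    lo <- floor(r); hi <- ceiling(r)
    (ref[lo] + ref[hi]) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: \eqn{q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j},
#' capped at 1 and mapped back to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @export
bhFdr <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Moment-match the scaled inverse chi-square prior on gene variances:
# log s^2 is shifted log-chi^2; matching mean and variance of
# e = log s^2 - digamma(d/2) + log(d/2) gives d0 and s0^2.
.fitVariancePrior <- function(s2, df) {
  z <- log(s2)
  z <- z[is.finite(z)]
  if (length(z) < 2L)
    return(list(d0 = 0, s0_sq = NA_real_))
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (evar <= 0) {
    # sample variances no more dispersed than chi^2 alone: infinite prior df,
    # point-mass prior at the average sample variance
    return(list(d0 = Inf, s0_sq = mean(s2[is.finite(log(s2))])))
  }
  d0 <- 2 * .trigammaInverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton solve trigamma(x) = y (y > 0), monotone decreasing in x.
.trigammaInverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Two-group (moderated) contrast statistics
#'
#' Per-gene differential expression between two sample groups of a study:
#' log2 fold change = mean(test) - mean(reference); t statistic from the
#' pooled within-group variance, optionally moderated by shrinking each
#' gene's variance toward a prior estimated from all genes by moment
#' matching on the log sample variances,
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d),}
#' with the t statistic on \eqn{d_0 + d} degrees of freedom. Two-sided
#' p-values; q-values by Benjamini-Hochberg. Significance calls follow
#' strict cutoffs |log2FC| > `fc_cut` and p < `p_cut` (and additionally
#' q < `q_cut` for `sig_fdr`).
#'
#' @param study an [ExpressionStudy-class].
#' @param test_samples,ref_samples character vectors of sample ids.
#' @param contrast_id label for the contrast, e.g. `"WS_135_vs_90"`.
#' @param moderated logical; `FALSE` gives the ordinary pooled-variance t
#'   (d0 = 0).
#' @param fc_cut,p_cut,q_cut significance cutoffs (strict inequalities).
#' @return a [ContrastResult-class].
#' @examples
#' sim <- simulateExpression(exprSimConfig(n_genes = 100, seed = 1))
#' cr <- contrastStats(sim$study, cellSamples(sim$study, "WS", 135),
#'                     cellSamples(sim$study, "WS", 90), "WS_135_vs_90")
#' cr
#' @export
contrastStats <- function(study, test_samples, ref_samples,
                          contrast_id = "contrast", moderated = TRUE,
                          fc_cut = 1.0, p_cut = 0.05, q_cut = 0.05) {
  stopifnot(is(study, "ExpressionStudy"))
  m <- exprValues(study)
  unknown <- setdiff(c(test_samples, ref_samples), colnames(m))
  if (length(unknown))
    stop("unknown samples: ", paste(unknown, collapse = ", "))
  if (length(intersect(test_samples, ref_samples)))
    stop("test and reference groups overlap")
  n1 <- length(test_samples); n2 <- length(ref_samples)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 replicates")
  x1 <- m[, test_samples, drop = FALSE]
  x2 <- m[, ref_samples, drop = FALSE]
  log2fc <- rowMeans(x1) - rowMeans(x2)
  d <- n1 + n2 - 2L
  s2 <- (rowSums((x1 - rowMeans(x1))^2) + rowSums((x2 - rowMeans(x2))^2)) / d
  if (moderated) {
    prior <- .fitVariancePrior(s2, d)
    d0 <- prior$d0; s0_sq <- prior$s0_sq
    if (is.infinite(d0)) {
      s2_tilde <- rep(s0_sq, length(s2))
      df_t <- Inf
    } else if (d0 > 0) {
      s2_tilde <- (d0 * s0_sq + d * s2) / (d0 + d)
      df_t <- d0 + d
    } else {
      s2_tilde <- s2
      df_t <- d
    }
  } else {
    d0 <- 0; s0_sq <- NA_real_
    s2_tilde <- s2
    df_t <- d
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t <- log2fc / se
  p <- 2 * pt(abs(t), df = df_t, lower.tail = FALSE)
  # zero residual variance without shrinkage: call by convention
  zero <- se == 0
  if (any(zero)) {
    t[zero] <- ifelse(log2fc[zero] == 0, 0, sign(log2fc[zero]) * Inf)
    p[zero] <- ifelse(log2fc[zero] == 0, 1, 0)
  }
  q <- bhFdr(p)
  sig <- abs(log2fc) > fc_cut & p < p_cut
  st <- S4Vectors::DataFrame(
    log2fc = unname(log2fc), t = unname(t), p = unname(p), q = unname(q),
    sig = unname(sig), sig_fdr = unname(sig & q < q_cut),
    direction = unname(ifelse(log2fc >= 0, "up", "down")),
    row.names = rownames(m))
  new("ContrastResult", contrastId = contrast_id,
      testGroup = paste(test_samples, collapse = ","),
      refGroup = paste(ref_samples, collapse = ","),
      nTest = n1, nRef = n2,
      moderation = list(moderated = moderated, d0 = d0, s0_sq = s0_sq,
                        df = df_t),
      stats = st)
}

#' @export
setMethod("resultTable", "ContrastResult", function(x) x@stats)

#' @export
setMethod("contrastId", "ContrastResult", function(x) x@contrastId)

#' Moderation parameters of a contrast
#' @param x a [ContrastResult-class].
#' @return list with `moderated`, `d0`, `s0_sq`, `df`.
#' @export
moderationParams <- function(x) x@moderation

setMethod("show", "ContrastResult", function(object) {
  st <- object@stats
  cat("ContrastResult '", object@contrastId, "': ", nrow(st), " genes (",
      object@nTest, " test vs ", object@nRef, " reference samples)\n", sep = "")
  if (object@moderation$moderated)
    cat(sprintf("moderated t: d0 = %.3g, s0^2 = %.3g, df = %.3g\n",
                object@moderation$d0, object@moderation$s0_sq,
                object@moderation$df))
  cat(sum(st$sig), "significant (", sum(st$sig & st$direction == "up"), "up,",
      sum(st$sig & st$direction == "down"), "down),",
      sum(st$sig_fdr), "also at q < 0.05\n")
  invisible(NULL)
})

#' Differentially expressed gene set of a contrast
#'
#' Genes called significant under the strict cutoffs |log2FC| > `fc_cut`
#' and p < `p_cut`, with direction and an FDR flag (q < `q_cut`).
#'
#' @param result a [ContrastResult-class].
#' @param fc_cut,p_cut,q_cut cutoffs (strict).
#' @return data.frame with `gene_id`, `log2fc`, `p`, `q`, `direction`,
#'   `sig_fdr`, ordered by p.
#' @export
callDE <- function(result, fc_cut = 1.0, p_cut = 0.05, q_cut = 0.05) {
  stopifnot(is(result, "ContrastResult"))
  if (fc_cut <= 0 || p_cut <= 0 || q_cut <= 0)
    stop("cutoffs must be positive")
  st <- resultTable(result)
  keep <- abs(st$log2fc) > fc_cut & st$p < p_cut
  out <- data.frame(gene_id = rownames(st)[keep],
                    log2fc = st$log2fc[keep], p = st$p[keep], q = st$q[keep],
                    direction = st$direction[keep],
                    sig_fdr = keep[keep] & st$q[keep] < q_cut,
                    row.names = NULL)
  out[order(out$p), , drop = FALSE]
}
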
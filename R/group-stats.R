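#' @include morphometrics.R
#' @importFrom stats lm qt pt pf sd var aggregate as.formula complete.cases
NULL

#' Group means and 95% confidence intervals
#'
#' Summarises a per-root metric over the (ecotype x growth-plate angle)
#' cells: n, mean and a Student-t 95% confidence interval per cell. Cells
#' with a single observation report the mean with an absent (NA) interval;
#' empty cells are reported with n = 0.
#'
#' @param metrics a data.frame as returned by [morphoMetrics()] (must carry
#'   `ecotype` and `angle_gp`).
#' @param metric name of the metric column to summarise.
#' @param conf confidence level, default 0.95.
#' @param letters optional named character vector of compact-letter-display
#'   strings (names = `"ecotype:angle"`) to attach, e.g. from
#'   [scheffePosthoc()].
#' @return data.frame with columns `ecotype`, `angle_gp`, `n`, `mean`,
#'   `ci95_low`, `ci95_high` and (if supplied) `letters`.
#' @export
summarizeGroups <- function(metrics, metric, conf = 0.95, letters = NULL) {
  if (!metric %in% colnames(metrics))
    stop("no column '", metric, "' in metrics")
  cells <- expand.grid(ecotype = .ECOTYPES, angle_gp = .ANGLES,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[order(cells$ecotype, cells$angle_gp), ]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    v <- metrics[metrics$ecotype == cells$ecotype[i] &
                   metrics$angle_gp == cells$angle_gp[i], metric]
    v <- v[is.finite(v)]
    n <- length(v)
    if (n == 0L)
      return(data.frame(cells[i, ], n = 0L, mean = NA_real_,
                        ci95_low = NA_real_, ci95_high = NA_real_))
    m <- mean(v)
    if (n < 2L)
      return(data.frame(cells[i, ], n = n, mean = m,
                        ci95_low = NA_real_, ci95_high = NA_real_))
    half <- qt(1 - (1 - conf) / 2, n - 1L) * sd(v) / sqrt(n)
    data.frame(cells[i, ], n = n, mean = m,
               ci95_low = m - half, ci95_high = m + half)
  }))
  rownames(out) <- NULL
  if (!is.null(letters)) {
    key <- paste(out$ecotype, out$angle_gp, sep = ":")
    out$letters <- unname(letters[key])
  }
  out
}

#' Two-way Type-II ANOVA on a root metric
#'
#' Fits `metric ~ ecotype * angle_gp` and reports Type-II sums of squares
#' (each main effect adjusted for the other; the interaction from the full
#' model), F statistics and p-values. Works for balanced and unbalanced
#' designs.
#'
#' @inheritParams summarizeGroups
#' @return data.frame with rownames `ecotype`, `angle_gp`,
#'   `ecotype:angle_gp`, `Residuals` and columns `SS`, `df`, `F`, `p`.
#' @export
anovaTypeII <- function(metrics, metric) {
  if (!metric %in% colnames(metrics))
    stop("no column '", metric, "' in metrics")
  d <- data.frame(y = metrics[[metric]],
                  ecotype = factor(metrics$ecotype),
                  angle_gp = factor(metrics$angle_gp))
  d <- d[complete.cases(d), ]
  if (nlevels(droplevels(d$ecotype)) < 2L || nlevels(droplevels(d$angle_gp)) < 2L)
    stop("need >= 2 observed levels per factor")
  fit <- lm(y ~ ecotype * angle_gp, data = d)
  if (fit$df.residual <= 0L || anyNA(coef(fit)))
    stop("rank-deficient design: some cells are empty or confounded")
  a2 <- car::Anova(fit, type = 2)
  out <- data.frame(SS = a2[["Sum Sq"]], df = a2[["Df"]],
                    F = a2[["F value"]], p = a2[["Pr(>F)"]],
                    row.names = rownames(a2))
  out
}

# Insert-and-absorb compact letter display. `signif` is a logical matrix
# (k x k) of pairwise significance; groups are assumed ordered by
# descending mean already.
.letterDisplay <- function(signif, labels) {
  k <- nrow(signif)
  cols <- list(rep(TRUE, k))
  absorb <- function(cols) {
    keep <- rep(TRUE, length(cols))
    for (u in seq_along(cols)) for (v in seq_along(cols)) {
      if (u == v || !keep[u] || !keep[v]) next
      subset_uv <- all(cols[[v]][cols[[u]]])   # u contained in v
      if (subset_uv && (!identical(cols[[u]], cols[[v]]) || u > v))
        keep[u] <- FALSE
    }
    cols[keep]
  }
  for (i in seq_len(max(k - 1L, 0L))) for (j in seq(i + 1L, k)) {
    if (!signif[i, j]) next
    hit <- which(vapply(cols, function(cl) cl[i] && cl[j], logical(1)))
    for (h in hit) {
      a <- cols[[h]]; b <- a
      a[i] <- FALSE; b[j] <- FALSE
      cols[[h]] <- a
      cols[[length(cols) + 1L]] <- b
    }
    cols <- absorb(cols)
  }
  lets <- letters[seq_along(cols)]
  out <- vapply(seq_len(k), function(g)
    paste0(lets[vapply(cols, `[`, logical(1), g)], collapse = ""), character(1))
  names(out) <- labels
  out
}

#' Scheffe post hoc comparisons with compact letter display
#'
#' All pairwise comparisons among groups using Scheffe's method: for the
#' pair (i, j) the contrast statistic
#' \deqn{F_{ij} = (\bar y_i - \bar y_j)^2 / (MSE (1/n_i + 1/n_j))}
#' is referred to \eqn{(k-1) F_{k-1,\,df_{err}}}, i.e. the adjusted p-value
#' is the upper tail of \eqn{F_{ij}/(k-1)} on \eqn{(k-1, df_{err})} degrees
#' of freedom. MSE and its df come from the full two-way interaction model.
#' Letters come from an insert-and-absorb compact letter display at
#' `alpha`, with groups processed in descending mean order.
#'
#' @inheritParams summarizeGroups
#' @param grouping `"cells"` compares the six (ecotype x angle) cell means
#'   (use when the ANOVA interaction is significant); `"ecotype"` or
#'   `"angle_gp"` compare the marginal means of that factor.
#' @param alpha significance level for the letter display.
#' @return list with `pairs` (data.frame: group1, group2, diff, F, p_adj)
#'   and `letters` (named character vector, names = group labels; for
#'   `grouping = "cells"` the labels are `"ecotype:angle"`).
#' @export
scheffePosthoc <- function(metrics, metric, grouping = c("cells", "ecotype", "angle_gp"),
                           alpha = 0.05) {
  grouping <- match.arg(grouping)
  if (!metric %in% colnames(metrics))
    stop("no column '", metric, "' in metrics")
  d <- data.frame(y = metrics[[metric]],
                  ecotype = factor(metrics$ecotype),
                  angle_gp = factor(metrics$angle_gp))
  d <- d[complete.cases(d), ]
  g <- switch(grouping,
              cells = interaction(d$ecotype, d$angle_gp, sep = ":", drop = TRUE),
              ecotype = droplevels(d$ecotype),
              angle_gp = droplevels(d$angle_gp))
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  # error term from the full two-way model (falls back to one-way when a
  # factor has a single observed level)
  full <- if (nlevels(droplevels(d$ecotype)) > 1L &&
              nlevels(droplevels(d$angle_gp)) > 1L)
    lm(y ~ ecotype * angle_gp, data = d) else lm(d$y ~ g)
  dfe <- full$df.residual
  if (dfe <= 0L) stop("no residual degrees of freedom")
  mse <- sum(full$residuals^2) / dfe
  means <- tapply(d$y, g, mean)
  ns <- tapply(d$y, g, length)
  k <- nlevels(g)
  ord <- order(means, decreasing = TRUE)
  labs <- levels(g)[ord]
  means <- means[ord]; ns <- ns[ord]
  pairs <- t(utils::combn(k, 2))
  Fij <- (means[pairs[, 1]] - means[pairs[, 2]])^2 /
    (mse * (1 / ns[pairs[, 1]] + 1 / ns[pairs[, 2]]))
  p_adj <- pf(Fij / (k - 1), k - 1, dfe, lower.tail = FALSE)
  sig <- matrix(FALSE, k, k)
  sig[pairs] <- p_adj < alpha
  sig <- sig | t(sig)
  letters <- .letterDisplay(sig, labs)
  list(pairs = data.frame(group1 = labs[pairs[, 1]], group2 = labs[pairs[, 2]],
                          diff = unname(means[pairs[, 1]] - means[pairs[, 2]]),
                          F = unname(Fij), p_adj = unname(p_adj)),
       letters = letters, mse = mse, df_err = dfe, k = k)
}

#' Full Fig-2-style summary for one metric
#'
#' Runs the two-way Type-II ANOVA, chooses the post hoc grouping by the
#' interaction rule (cell means when the ecotype x angle interaction has
#' p < 0.05, marginal means otherwise) and attaches Scheffe letters to the
#' group summary.
#'
#' @inheritParams summarizeGroups
#' @param alpha interaction / letter significance level.
#' @return list with `anova`, `posthoc`, `grouping` and `summary`.
#' @export
metricSummary <- function(metrics, metric, alpha = 0.05) {
  an <- anovaTypeII(metrics, metric)
  inter_p <- an["ecotype:angle_gp", "p"]
  grouping <- if (is.finite(inter_p) && inter_p < alpha) "cells" else "angle_gp"
  ph <- scheffePosthoc(metrics, metric, grouping = grouping, alpha = alpha)
  letters <- if (grouping == "cells") ph$letters else NULL
  list(anova = an, posthoc = ph, grouping = grouping,
       summary = summarizeGroups(metrics, metric, letters = letters))
}
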
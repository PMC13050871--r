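# Statistical comparisons used on the pipeline outputs, in a uniform report
# format: two-group tests (Mann-Whitney U, Welch's t, paired t), one- and
# two-way ANOVA with Sidak-family post-hoc corrections, and Shapiro-Wilk
# normality. Group effects are summarized as median + IQR and mean +- SEM.

.group_summary <- function(x) {
  list(n = length(x), mean = mean(x), sem = sd(x) / sqrt(length(x)),
       median = median(x), iqr = IQR(x))
}

#' Compare two samples
#'
#' Mann-Whitney U (two-sided; exact enumeration when both groups have no
#' ties and the smaller group has <= 8 observations, otherwise midrank
#' normal approximation with continuity correction), Welch's t, or paired
#' t-test.
#'
#' @param a,b numeric samples (paired tests require equal lengths).
#' @param method "mann-whitney", "welch" or "paired-t".
#' @return list of class `rq_comparison`: `test`, `statistic`, `p`,
#'   `group_sizes`, `summary_a`, `summary_b` (median/IQR and mean/SEM).
#' @export
compare_two <- function(a, b, method = c("mann-whitney", "welch",
                                         "paired-t")) {
  method <- match.arg(method)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (method == "paired-t" && length(a) != length(b))
    stop("paired samples must have equal lengths")
  res <- switch(
    method,
    "mann-whitney" = {
      exact <- min(length(a), length(b)) <= 8 &&
        !any(duplicated(c(a, b)))
      ht <- suppressWarnings(wilcox.test(a, b, exact = exact,
                                         correct = TRUE))
      list(test = "Mann-Whitney U", statistic = unname(ht$statistic),
           p = ht$p.value)
    },
    "welch" = {
      ht <- t.test(a, b, var.equal = FALSE)
      list(test = "Welch's t", statistic = unname(ht$statistic),
           p = ht$p.value)
    },
    "paired-t" = {
      d <- a - b
      if (all(d == 0)) {
        # zero variance: no difference by construction
        list(test = "Paired t", statistic = 0, p = 1)
      } else {
        ht <- t.test(a, b, paired = TRUE)
        list(test = "Paired t", statistic = unname(ht$statistic),
             p = ht$p.value)
      }
    })
  structure(c(res, list(group_sizes = c(length(a), length(b)),
                        summary_a = .group_summary(a),
                        summary_b = .group_summary(b))),
            class = "rq_comparison")
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m` with `m = length(p)`.
#'
#' @param p raw p-values.
#' @return adjusted p-values.
#' @export
p_adjust_sidak <- function(p) {
  pmin(1, 1 - (1 - p)^length(p))
}

#' Holm-Sidak step-down adjustment
#'
#' Ordered p-values receive `1 - (1 - p_(i))^(m - i + 1)`, enforced
#' monotone non-decreasing in the ranking.
#'
#' @param p raw p-values.
#' @return adjusted p-values (in the input order).
#' @export
p_adjust_holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' One- or two-way ANOVA with pairwise post-hoc comparisons
#'
#' Omnibus ANOVA (two-way designs use type-II sums of squares, with an
#' interaction term) followed by pairwise post-hoc comparisons between the
#' groups (cells of the design), corrected with the chosen method:
#' "sidak" / "holm-sidak" on Welch pairwise t-tests, "dunn" (rank-based z
#' pairwise tests with Sidak correction), or "dunnett-t3" (Welch-type
#' pairwise tests with a Sidak bound on the studentized-maximum-modulus
#' critical level -- a documented approximation).
#'
#' @param values numeric response.
#' @param factor1 first grouping factor.
#' @param factor2 optional second factor (two-way design).
#' @param correction post-hoc correction method.
#' @return list of class `rq_anova`: `omnibus` (data.frame of terms, F, p),
#'   `posthoc` (data.frame: group1, group2, statistic, p, p_adj),
#'   `group_summaries`.
#' @export
compare_factorial <- function(values, factor1, factor2 = NULL,
                              correction = c("sidak", "holm-sidak", "dunn",
                                             "dunnett-t3")) {
  correction <- match.arg(correction)
  factor1 <- factor(factor1)
  if (nlevels(factor1) < 2) stop("factor1 needs >= 2 levels")
  if (!is.null(factor2)) {
    factor2 <- factor(factor2)
    if (nlevels(factor2) < 2) stop("factor2 needs >= 2 levels")
    cells <- interaction(factor1, factor2, drop = TRUE, sep = ":")
  } else {
    cells <- factor1
  }
  if (any(table(cells) < 2)) stop("every cell needs >= 2 observations")

  if (is.null(factor2)) {
    fit <- aov(values ~ factor1)
    at <- anova(fit)
    omnibus <- data.frame(term = "factor1",
                          F = at[1, "F value"], p = at[1, "Pr(>F)"])
  } else {
    fit <- lm(values ~ factor1 * factor2)
    at <- car::Anova(fit, type = 2)
    terms <- rownames(at)
    keep <- terms != "Residuals"
    omnibus <- data.frame(term = terms[keep], F = at[keep, "F value"],
                          p = at[keep, "Pr(>F)"])
  }

  lev <- levels(cells)
  cmb <- utils::combn(lev, 2)
  raw <- apply(cmb, 2, function(gg) {
    x <- values[cells == gg[1]]
    y <- values[cells == gg[2]]
    if (correction == "dunn") {
      # rank all observations together; z-test on mean-rank difference
      rk <- rank(values)
      n <- length(values)
      ties <- table(rk)
      tiecor <- sum(ties^3 - ties) / (12 * (n - 1))
      se <- sqrt((n * (n + 1) / 12 - tiecor) *
                   (1 / length(x) + 1 / length(y)))
      z <- (mean(rk[cells == gg[1]]) - mean(rk[cells == gg[2]])) / se
      c(stat = z, p = 2 * pnorm(-abs(z)))
    } else {
      ht <- t.test(x, y, var.equal = FALSE)
      c(stat = unname(ht$statistic), p = ht$p.value)
    }
  })
  p_adj <- switch(correction,
                  "sidak" = p_adjust_sidak(raw["p", ]),
                  "holm-sidak" = p_adjust_holm_sidak(raw["p", ]),
                  "dunn" = p_adjust_sidak(raw["p", ]),
                  "dunnett-t3" = p_adjust_sidak(raw["p", ]))
  posthoc <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                        statistic = raw["stat", ], p = raw["p", ],
                        p_adj = p_adj)
  structure(list(omnibus = omnibus, posthoc = posthoc,
                 group_summaries = lapply(split(values, cells),
                                          .group_summary),
                 correction = correction),
            class = "rq_anova")
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return list of class `rq_comparison`: `test`, `statistic` (W), `p`.
#' @export
normality <- function(x) {
  if (length(x) < 3 || length(x) > 5000)
    stop("sample size must be in [3, 5000]")
  ht <- shapiro.test(x)
  structure(list(test = "Shapiro-Wilk", statistic = unname(ht$statistic),
                 p = ht$p.value, group_sizes = length(x),
                 summary_a = .group_summary(x)),
            class = "rq_comparison")
}
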
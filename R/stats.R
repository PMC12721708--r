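## Normality-gated statistical test selection: Lilliefors gates parametric
## vs non-parametric comparisons; an F-ratio test gates Student vs Welch for
## unpaired normal samples; chi-squared for categorical tables and two-way
## ANOVA for factorial designs.

#' Lilliefors normality test
#'
#' Kolmogorov-Smirnov-type test of composite normality with estimated mean
#' and variance. Constant samples are degenerate and reported non-normal;
#' fewer than five observations leave the test undefined.
#'
#' @param x numeric sample.
#' @param alpha significance level for the `normal` verdict (default 0.05).
#' @return A list: `statistic`, `pValue`, `normal`, `degenerate`.
#' @export
lillieforsTest <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 5L)
    stop("Lilliefors test requires at least 5 observations")
  if (stats::sd(x) == 0)
    return(list(statistic = NA_real_, pValue = 0, normal = FALSE,
                degenerate = TRUE))
  ht <- nortest::lillie.test(x)
  list(statistic = unname(ht$statistic), pValue = ht$p.value,
       normal = ht$p.value >= alpha, degenerate = FALSE)
}

#' Significance label for a p value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `n.s.`
#' otherwise.
#'
#' @param p p value.
#' @return Character label.
#' @export
significanceLabel <- function(p) {
  if (is.na(p)) return("n.s.")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "n.s."
}

#' Normality-gated test selection
#'
#' Applies the Lilliefors test to each sample at `alpha` and selects the
#' comparison accordingly. Paired design: paired t-test when both samples
#' are normal, Wilcoxon signed-rank otherwise. Unpaired design: Student's
#' t-test when both samples are normal with equal variances (F-ratio test at
#' `alpha`), Welch's t-test when normal with unequal variances, Wilcoxon
#' rank-sum otherwise. Categorical: chi-squared test (no continuity
#' correction) on the supplied table. Factorial: fixed-effects two-way
#' ANOVA with interaction on `data` (columns `y`, `a`, `b`); the reported
#' statistic/p are the interaction row, with the full table in `details`.
#' Samples too small for Lilliefors (n < 5) fall back to the
#' non-parametric branch with a warning.
#'
#' @param design `"paired"`, `"unpaired"`, `"categorical"`, or
#'   `"factorial"`.
#' @param a,b numeric samples (paired/unpaired designs).
#' @param table contingency table (categorical design).
#' @param data data.frame with `y`, `a`, `b` (factorial design).
#' @param alpha gate level for the normality and variance tests.
#' @return A [TestDecision-class].
#' @examples
#' selectAndRun("categorical", table = rbind(c(10, 0), c(0, 10)))
#' @export
selectAndRun <- function(design = c("paired", "unpaired", "categorical",
                                    "factorial"),
                         a = NULL, b = NULL, table = NULL, data = NULL,
                         alpha = 0.05) {
  design <- match.arg(design)
  mk <- function(chosenTest, statistic, pValue, normalA = NA, normalB = NA,
                 equalVar = NA, details = list()) {
    new("TestDecision", design = design, normalA = normalA,
        normalB = normalB, equalVar = equalVar, chosenTest = chosenTest,
        statistic = statistic, pValue = pValue,
        label = significanceLabel(pValue), details = details)
  }

  if (design == "categorical") {
    if (is.null(table)) stop("categorical design requires 'table'")
    ht <- stats::chisq.test(table, correct = FALSE)
    return(mk("chi-squared", unname(ht$statistic), ht$p.value,
              details = list(htest = ht)))
  }
  if (design == "factorial") {
    if (is.null(data) || !all(c("y", "a", "b") %in% names(data)))
      stop("factorial design requires 'data' with columns y, a, b")
    fit <- stats::aov(y ~ a * b, data = transform(
      data, a = factor(a), b = factor(b)))
    tab <- summary(fit)[[1]]
    i <- which(trimws(rownames(tab)) == "a:b")
    return(mk("two-way ANOVA", tab[i, "F value"], tab[i, "Pr(>F)"],
              details = list(anova = tab)))
  }

  if (is.null(a) || is.null(b) || !length(a) || !length(b))
    stop("'a' and 'b' must be non-empty samples")
  if (design == "paired" && length(a) != length(b))
    stop("paired samples must have equal length")

  small <- length(a) < 5L || length(b) < 5L
  if (small) {
    warning("samples too small for the Lilliefors gate; ",
            "falling back to the non-parametric test")
    normA <- normB <- NA
    bothNormal <- FALSE
  } else {
    la <- lillieforsTest(a, alpha)
    lb <- lillieforsTest(b, alpha)
    normA <- la$normal
    normB <- lb$normal
    bothNormal <- normA && normB
  }

  if (design == "paired") {
    d <- a - b
    if (all(d == 0))  # identical samples: null centre by convention
      return(mk(if (bothNormal) "paired t-test" else
                "Wilcoxon signed-rank", 0, 1, normA, normB))
    if (bothNormal) {
      ht <- stats::t.test(a, b, paired = TRUE)
      return(mk("paired t-test", unname(ht$statistic), ht$p.value,
                normA, normB, details = list(htest = ht)))
    }
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    return(mk("Wilcoxon signed-rank", unname(ht$statistic), ht$p.value,
              normA, normB, details = list(htest = ht)))
  }

  ## unpaired
  if (bothNormal) {
    vt <- stats::var.test(a, b)
    equalVar <- vt$p.value >= alpha
    ht <- stats::t.test(a, b, var.equal = equalVar)
    return(mk(if (equalVar) "unpaired t-test" else "Welch's t-test",
              unname(ht$statistic), ht$p.value, normA, normB, equalVar,
              details = list(htest = ht, varTest = vt)))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b))
  mk("Wilcoxon rank-sum", unname(ht$statistic), ht$p.value, normA, normB,
     details = list(htest = ht))
}
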
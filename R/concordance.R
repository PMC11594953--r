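#' @importFrom stats pchisq dhyper qt pt sd
NULL

#' Cross-tabulate short-form against long-form categories
#'
#' @param sf,lf Equal-length, non-empty vectors of self-management
#'   categories (ordered factors or integer codes 0--3).
#' @return An `sm_crosstab`: the 4x4 count matrix (rows = short form,
#'   columns = long form), `n`, and both category margins.
#' @export
sf_lf_crosstab <- function(sf, lf) {
  sf <- sm_category(category_code(sf))
  lf <- sm_category(category_code(lf))
  if (length(sf) == 0L) stop("empty category lists")
  if (length(sf) != length(lf)) {
    stop("short-form and long-form category lists differ in length (",
         length(sf), " vs ", length(lf), ")")
  }
  if (anyNA(sf) || anyNA(lf)) stop("categories contain missing values")
  counts <- table(sf = sf, lf = lf)
  counts <- matrix(as.integer(counts), 4, 4,
                   dimnames = list(sf = SM_LEVELS, lf = SM_LEVELS))
  structure(
    list(counts = counts, n = length(sf),
         sf_margin = rowSums(counts), lf_margin = colSums(counts)),
    class = "sm_crosstab"
  )
}

#' @export
print.sm_crosstab <- function(x, ...) {
  cat(sprintf("SF x LF category cross-tabulation (n = %d)\n", x$n))
  print(x$counts)
  invisible(x)
}

#' Concordance between the two instruments
#'
#' Exact agreement is the proportion of patients assigned the same
#' category by both tools (the diagonal of the cross-tabulation).
#' Extreme agreement restricts to patients whom either scale rates good
#' or poor -- the two categories carrying the study's headline risk
#' contrast. The pre-specified primary endpoint is 80% exact agreement.
#'
#' @param tab An `sm_crosstab` from [sf_lf_crosstab()].
#' @param endpoint Agreement proportion defining the primary endpoint.
#' @return A `concordance_report` list: `exact_agreement`,
#'   `extreme_agreement` (NA when no patient is rated extreme),
#'   `meets_primary_endpoint`, `n`.
#' @export
concordance_proportion <- function(tab, endpoint = 0.80) {
  stopifnot(inherits(tab, "sm_crosstab"))
  if (tab$n <= 0) stop("concordance undefined for an empty cross-tabulation")
  cm <- tab$counts
  exact <- sum(diag(cm)) / tab$n
  ext <- c(1L, 4L) # good, poor
  in_extreme <- outer(seq_len(4) %in% ext, seq_len(4) %in% ext, `|`)
  n_extreme <- sum(cm[in_extreme])
  agree_extreme <- cm["good", "good"] + cm["poor", "poor"]
  extreme <- if (n_extreme > 0) agree_extreme / n_extreme else NA_real_
  structure(
    list(exact_agreement = exact,
         extreme_agreement = extreme,
         meets_primary_endpoint = exact >= endpoint,
         endpoint = endpoint,
         n = tab$n),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance (n = %d)\n", x$n))
  cat(sprintf("  exact agreement:   %.3f\n", x$exact_agreement))
  cat(sprintf("  extreme agreement: %s\n",
              ifelse(is.na(x$extreme_agreement), "NA",
                     sprintf("%.3f", x$extreme_agreement))))
  cat(sprintf("  primary endpoint (>= %.0f%%): %s\n", 100 * x$endpoint,
              ifelse(x$meets_primary_endpoint, "met", "not met")))
  invisible(x)
}

#' Construct a 2x2 contingency table
#'
#' Rows index the two category groups being contrasted (e.g. good vs
#' poor self-managers); columns index event yes/no.
#'
#' @param a,b Events / non-events in the first group.
#' @param c,d Events / non-events in the second group.
#' @return Integer 2x2 matrix.
#' @examples
#' contingency_2x2(5, 8, 31, 7) # good 5/13 vs poor 31/38 readmitted
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(is.na(counts) | counts < 0 | counts != round(counts))) {
    stop("contingency counts must be non-negative integers")
  }
  matrix(as.integer(counts), 2, 2, byrow = TRUE,
         dimnames = list(group = c("g1", "g2"), event = c("yes", "no")))
}

as_2x2 <- function(tab) {
  if (is.matrix(tab) && all(dim(tab) == 2L)) {
    return(contingency_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  }
  stop("expected a 2x2 count matrix (see contingency_2x2())")
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Computes the uncorrected Pearson statistic
#' `n * (ad - bc)^2 / (r1 * r2 * c1 * c2)` at 1 degree of freedom.
#' Continuity correction is off by default: the uncorrected statistic is
#' the one the banded readmission contrast reproduces. Yates' correction
#' is available behind `correct = TRUE`.
#'
#' @param tab 2x2 count matrix ([contingency_2x2()]).
#' @param correct Apply Yates' continuity correction.
#' @return List with `statistic`, `df` (always 1) and `p_value`.
#' @examples
#' pearson_chi2_2x2(contingency_2x2(5, 8, 31, 7))
#' @export
pearson_chi2_2x2 <- function(tab, correct = FALSE) {
  tab <- as_2x2(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) {
    stop("a table margin is zero; the chi-squared approximation is undefined ",
         "-- use exact_test_2x2() instead")
  }
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, df = 1L,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Exact test on a 2x2 table by hypergeometric enumeration
#'
#' Two-sided Fisher-style p value: enumerates every table with the
#' observed margins and sums the hypergeometric probabilities of those
#' no more probable than the observed table (with a small relative
#' tolerance for floating-point ties).
#'
#' @param tab 2x2 count matrix ([contingency_2x2()]).
#' @return Two-sided p value in (0, 1].
#' @examples
#' exact_test_2x2(contingency_2x2(5, 0, 0, 5)) # 1/126
#' @export
exact_test_2x2 <- function(tab) {
  tab <- as_2x2(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Mean, SD and range of a banded category distribution
#'
#' Treats per-category counts as repeated observations of the category
#' scores and returns the mean, sample (n - 1) standard deviation and
#' the min--max range over categories with non-zero count.
#'
#' @param counts Non-negative integer counts per category, summing to a
#'   positive total.
#' @param scores Numeric score attached to each category; defaults to
#'   the risk codes `0, 1, 2, ...`.
#' @return List with `mean`, `sd` (NA when the total is 1) and `range`.
#' @examples
#' category_distribution_stats(c(13, 46, 20, 38)) # mean 1.71, SD 1.04
#' @export
category_distribution_stats <- function(counts, scores = seq_along(counts) - 1) {
  if (length(counts) != length(scores)) stop("counts and scores differ in length")
  if (any(is.na(counts) | counts < 0 | counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("category counts sum to zero")
  m <- sum(counts * scores) / n
  s <- if (n > 1) sqrt(sum(counts * (scores - m)^2) / (n - 1)) else NA_real_
  list(mean = m, sd = s, range = range(scores[counts > 0]))
}
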
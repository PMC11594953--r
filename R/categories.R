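#' Self-management category levels
#'
#' Both instruments grade patients into the same four ordinal
#' self-management categories, coded 0 (good) through 3 (poor).
#' Higher codes mean higher readmission risk.
#'
#' @format Character vector of the four category labels, ordered from
#'   lowest to highest risk.
#' @export
SM_LEVELS <- c("good", "average", "borderline", "poor")

#' Construct an ordinal self-management category
#'
#' Converts integer risk codes (0 = good ... 3 = poor) or category labels
#' into an ordered factor with levels `good < average < borderline < poor`.
#'
#' @param x Integer vector of codes in 0..3, or character vector of labels.
#' @return Ordered factor with levels [SM_LEVELS].
#' @examples
#' sm_category(c(0, 3, 1))
#' @export
sm_category <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    bad <- !x %in% SM_LEVELS & !is.na(x)
    if (any(bad)) {
      stop("unknown category label(s): ", paste(unique(x[bad]), collapse = ", "))
    }
    return(factor(x, levels = SM_LEVELS, ordered = TRUE))
  }
  x <- as.integer(x)
  if (any(!is.na(x) & (x < 0L | x > 3L))) {
    stop("category codes must be integers in 0..3")
  }
  factor(SM_LEVELS[x + 1L], levels = SM_LEVELS, ordered = TRUE)
}

#' Integer risk code of a self-management category
#'
#' @param x Ordered factor from [sm_category()], or an integer code vector
#'   (returned unchanged after validation).
#' @return Integer vector with values in 0..3 (0 = good, 3 = poor).
#' @export
category_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(!is.na(x) & (x < 0L | x > 3L))) stop("category codes must be in 0..3")
    return(x)
  }
  code <- as.integer(sm_category(x)) - 1L
  code
}
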
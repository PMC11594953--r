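#' @importFrom stats setNames
NULL

PIH_N_ITEMS <- 12L
PIH_ITEM_MAX <- 8L

#' Column names of the 12 PIH item responses
#'
#' @return Character vector `pih_item_1` ... `pih_item_12`.
#' @export
pih_item_names <- function() paste0("pih_item_", seq_len(PIH_N_ITEMS))

# Items feeding each LF domain. K = knowledge, P = partnership in
# treatment, M = symptom recognition/management, C = coping.
PIH_DOMAIN_ITEMS <- list(
  K = 1:2,
  P = 3:6,
  M = 7:8,
  C = 9:12
)

#' Validate a matrix of PIH item responses
#'
#' Every response must be an integer on the 0--8 Likert scale
#' (0 = worst, 8 = best). Missing or out-of-range values are rejected,
#' never imputed; the error names the offending item (and row, when the
#' input has several).
#'
#' @param responses Numeric vector of length 12, or a matrix/data frame
#'   with one patient per row. Data-frame input may carry the items in
#'   columns named by [pih_item_names()]; otherwise the first 12 columns
#'   are used.
#' @return Integer matrix with one patient per row and 12 item columns.
#' @export
validate_pih_items <- function(responses) {
  if (is.data.frame(responses)) {
    nm <- pih_item_names()
    if (all(nm %in% names(responses))) {
      responses <- responses[nm]
    }
    responses <- as.matrix(responses)
  }
  if (is.null(dim(responses))) {
    responses <- matrix(responses, nrow = 1)
  }
  if (ncol(responses) != PIH_N_ITEMS) {
    stop("expected exactly ", PIH_N_ITEMS, " PIH items, got ", ncol(responses))
  }
  storage <- suppressWarnings(as.numeric(responses))
  m <- matrix(storage, nrow = nrow(responses))
  bad <- is.na(m) | m != round(m) | m < 0 | m > PIH_ITEM_MAX
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf(
      "invalid PIH response at row %d, pih_item_%d: must be an integer in 0..%d (no imputation of missing items)",
      idx[["row"]], idx[["col"]], PIH_ITEM_MAX
    ))
  }
  mode(m) <- "integer"
  colnames(m) <- pih_item_names()
  m
}

#' Score the 12-item PIH questionnaire into domain subtotals
#'
#' Sums the Likert responses into the four long-form domains and their
#' composites: knowledge `K` (items 1--2, max 16), partnership `P`
#' (items 3--6, max 32), symptom recognition/management `M` (items 7--8,
#' max 16), coping `C` (items 9--12, max 32), plus `KC = K + C`,
#' `PM = P + M` (max 48 each) and the 96-point `total`.
#'
#' @param responses Item responses accepted by [validate_pih_items()].
#' @return A `domain_scores` data frame with columns `K`, `P`, `M`, `C`,
#'   `KC`, `PM`, `total`, one row per patient.
#' @examples
#' score_pih(rep(8, 12)) # perfect self-management: total 96
#' @export
score_pih <- function(responses) {
  m <- validate_pih_items(responses)
  sums <- vapply(
    PIH_DOMAIN_ITEMS,
    function(items) as.integer(rowSums(m[, items, drop = FALSE])),
    integer(nrow(m))
  )
  if (nrow(m) == 1L) sums <- matrix(sums, nrow = 1, dimnames = list(NULL, names(PIH_DOMAIN_ITEMS)))
  out <- as.data.frame(sums)
  out$KC <- out$K + out$C
  out$PM <- out$P + out$M
  out$total <- out$K + out$P + out$M + out$C
  class(out) <- c("domain_scores", "data.frame")
  out
}

#' Assemble domain scores directly
#'
#' Builds a `domain_scores` frame from the four domain subtotals, for use
#' when item-level data are unavailable. Bounds are checked per domain.
#'
#' @param K,P,M,C Integer domain subtotals (max 16, 32, 16, 32).
#' @return A `domain_scores` data frame as from [score_pih()].
#' @export
domain_scores <- function(K, P, M, C) {
  maxes <- c(K = 16L, P = 32L, M = 16L, C = 32L)
  vals <- list(K = K, P = P, M = M, C = C)
  n <- unique(lengths(vals))
  if (length(n) != 1L) stop("K, P, M, C must have equal length")
  for (d in names(vals)) {
    v <- vals[[d]]
    if (any(is.na(v) | v != round(v) | v < 0 | v > maxes[[d]])) {
      stop(sprintf("domain %s out of range 0..%d", d, maxes[[d]]))
    }
  }
  out <- data.frame(K = as.integer(K), P = as.integer(P),
                    M = as.integer(M), C = as.integer(C))
  out$KC <- out$K + out$C
  out$PM <- out$P + out$M
  out$total <- out$K + out$P + out$M + out$C
  class(out) <- c("domain_scores", "data.frame")
  out
}

#' Banding schemes: score intervals per self-management category
#'
#' Each long-form scale (16, 32, 48 or 96 points) is banded into the
#' four ordinal categories. The published band edges overlap at two
#' boundaries; bands are therefore resolved best-first (good, then
#' average, then borderline, then poor), preserving every published
#' lower bound for the better category and yielding disjoint intervals
#' that exactly partition `0..scale_max`:
#'
#' * 16-pt: good >= 12, average 9--11, borderline 6--8, poor <= 5
#' * 32-pt: good >= 20, average 17--19, borderline 12--16, poor <= 11
#' * 48-pt: good >= 30, average 24--29, borderline 18--23, poor <= 17
#' * 96-pt: good >= 56, average 49--55, borderline 41--48, poor <= 40
#'
#' Schemes are data, not code: they load from a YAML configuration so the
#' boundary resolution can be revisited without code change.
#'
#' @param path Optional path to a YAML file of schemes; defaults to the
#'   configuration shipped with the package.
#' @return Named list of `banding_scheme` objects keyed by scale maximum
#'   (`"16"`, `"32"`, `"48"`, `"96"`).
#' @export
banding_schemes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "banding_schemes.yaml", package = "scrinhf")
  }
  raw <- yaml::read_yaml(path)
  schemes <- lapply(raw, function(s) {
    banding_scheme(
      scale_max = s$scale_max,
      lower = vapply(SM_LEVELS, function(k) s$bands[[k]]$lower, numeric(1)),
      upper = vapply(SM_LEVELS, function(k) s$bands[[k]]$upper, numeric(1))
    )
  })
  setNames(schemes, vapply(raw, function(s) as.character(s$scale_max), character(1)))
}

#' Construct and validate a single banding scheme
#'
#' @param scale_max Maximum attainable score (16, 32, 48 or 96).
#' @param lower,upper Named numeric vectors (names in [SM_LEVELS]) of
#'   inclusive interval bounds per category.
#' @return A `banding_scheme` object.
#' @export
banding_scheme <- function(scale_max, lower, upper) {
  lower <- lower[SM_LEVELS]
  upper <- upper[SM_LEVELS]
  if (any(is.na(lower)) || any(is.na(upper))) {
    stop("banding scheme must define lower and upper bounds for all of: ",
         paste(SM_LEVELS, collapse = ", "))
  }
  # partition check: every integer in 0..scale_max maps to exactly one band
  hits <- vapply(0:scale_max, function(s) {
    sum(s >= lower & s <= upper)
  }, numeric(1))
  if (any(hits != 1)) {
    s <- (0:scale_max)[hits != 1][1]
    stop(sprintf("banding scheme for %d-point scale is not a partition at score %d", scale_max, s))
  }
  # monotone: every good score above every average score, and so on
  ord <- order(-lower)
  if (!identical(SM_LEVELS[ord], SM_LEVELS)) {
    stop("banding intervals must be ordered good > average > borderline > poor")
  }
  structure(
    list(scale_max = as.integer(scale_max),
         lower = as.integer(lower), upper = as.integer(upper)),
    class = "banding_scheme"
  )
}

#' @export
print.banding_scheme <- function(x, ...) {
  cat(sprintf("Banding scheme (%d-point scale)\n", x$scale_max))
  for (i in seq_along(SM_LEVELS)) {
    cat(sprintf("  %-10s %2d-%2d\n", SM_LEVELS[i], x$lower[i], x$upper[i]))
  }
  invisible(x)
}

#' Band a score into its self-management category
#'
#' @param score Integer score vector, each in `0..scale_max`.
#' @param scheme A `banding_scheme`, or a scale maximum (16/32/48/96) to
#'   use the default scheme for that scale.
#' @return Ordered factor of categories ([sm_category()]).
#' @examples
#' band_score(58, 96) # good
#' band_score(47, 96) # borderline
#' @export
band_score <- function(score, scheme) {
  if (is.numeric(scheme) && length(scheme) == 1L) {
    scheme <- banding_schemes()[[as.character(scheme)]]
    if (is.null(scheme)) stop("no default banding scheme for that scale")
  }
  stopifnot(inherits(scheme, "banding_scheme"))
  if (any(is.na(score) | score != round(score) | score < 0 | score > scheme$scale_max)) {
    stop(sprintf("score out of range 0..%d for this scale", scheme$scale_max))
  }
  idx <- vapply(as.integer(score), function(s) {
    which(s >= scheme$lower & s <= scheme$upper)
  }, integer(1))
  sm_category(idx - 1L)
}

# scale used to band each domain-score column
LF_SCALE_BY_COLUMN <- c(K = 16L, P = 32L, M = 16L, C = 32L,
                        KC = 48L, PM = 48L, total = 96L)

#' Band every long-form scale of a cohort's domain scores
#'
#' Applies the matching banding scheme to each of `K`, `P`, `M`, `C`,
#' `KC`, `PM` and `total`. The banded 96-point `total` is the long-form
#' headline category used in concordance analyses.
#'
#' @param scores A `domain_scores` data frame ([score_pih()]).
#' @param schemes Banding schemes as from [banding_schemes()].
#' @return Data frame of ordered-factor categories, one column per scale,
#'   plus `lf_category` duplicating the banded total.
#' @export
categorize_lf <- function(scores, schemes = banding_schemes()) {
  stopifnot(is.data.frame(scores))
  missing_cols <- setdiff(names(LF_SCALE_BY_COLUMN), names(scores))
  if (length(missing_cols)) {
    stop("domain scores missing columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- lapply(names(LF_SCALE_BY_COLUMN), function(col) {
    band_score(scores[[col]], schemes[[as.character(LF_SCALE_BY_COLUMN[[col]])]])
  })
  names(out) <- names(LF_SCALE_BY_COLUMN)
  out <- as.data.frame(out)
  out$lf_category <- out$total
  out
}
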
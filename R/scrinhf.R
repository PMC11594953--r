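#' Construct a short-form (SCRinHF) assessment
#'
#' The SCRinHF triage tool scores three self-management domains in a
#' binary fashion: `ma` self-maintenance/monitoring, `mx`
#' self-management/tailoring, `mse` self-efficacy. Each domain is 0
#' (competent) or 1 (poor); their sum is the 0--3 risk score, which
#' doubles as the short-form self-management category code.
#'
#' @param ma,mx,mse Binary (0/1) domain scores, equal-length vectors.
#' @return An `sf_assessment` data frame with columns `ma`, `mx`, `mse`,
#'   `sf_total`.
#' @examples
#' sf_assessment(1, 0, 1) # risk score 2, borderline
#' @export
sf_assessment <- function(ma, mx, mse) {
  vals <- list(ma = ma, mx = mx, mse = mse)
  if (length(unique(lengths(vals))) != 1L) stop("ma, mx, mse must have equal length")
  for (d in names(vals)) {
    v <- vals[[d]]
    if (any(is.na(v) | !v %in% c(0, 1))) {
      stop(sprintf("short-form domain %s must be 0 or 1", d))
    }
  }
  out <- data.frame(ma = as.integer(ma), mx = as.integer(mx), mse = as.integer(mse))
  out$sf_total <- out$ma + out$mx + out$mse
  class(out) <- c("sf_assessment", "data.frame")
  out
}

#' Short-form total risk score
#'
#' @param assessment An `sf_assessment` ([sf_assessment()]), or a data
#'   frame carrying `sf_ma`, `sf_mx`, `sf_mse` (or `ma`, `mx`, `mse`)
#'   columns.
#' @return Ordered factor of self-management categories; the underlying
#'   integer code equals `ma + mx + mse`.
#' @export
sf_total <- function(assessment) {
  stopifnot(is.data.frame(assessment))
  nm <- if (all(c("sf_ma", "sf_mx", "sf_mse") %in% names(assessment))) {
    c("sf_ma", "sf_mx", "sf_mse")
  } else {
    c("ma", "mx", "mse")
  }
  if (!all(nm %in% names(assessment))) stop("no short-form domain columns found")
  a <- sf_assessment(assessment[[nm[1]]], assessment[[nm[2]]], assessment[[nm[3]]])
  sm_category(a$sf_total)
}

#' Long-form pass thresholds for the short-form mapping
#'
#' A long-form domain "passes" when its score strictly exceeds half the
#' scale maximum: above 8 on a 16-point domain, above 16 on a 32-point
#' domain, above 24 on the 48-point composites and above 48 on the
#' 96-point total.
#'
#' @param domain_16 Strict pass threshold for 16-point domains.
#' @param domain_32 Strict pass threshold for 32-point domains.
#' @param composite_48 Strict pass threshold for the `KC`/`PM` composites.
#' @param total_96 Strict pass threshold for the 96-point total.
#' @return A `pass_thresholds` list.
#' @export
pass_thresholds <- function(domain_16 = 8, domain_32 = 16,
                            composite_48 = 24, total_96 = 48) {
  structure(
    list(domain_16 = domain_16, domain_32 = domain_32,
         composite_48 = composite_48, total_96 = total_96),
    class = "pass_thresholds"
  )
}

#' Derive the short-form equivalent of long-form domain scores
#'
#' Maps PIH domain scores onto the three SCRinHF domains: `ma` mirrors
#' knowledge + coping (`KC`), `mx` mirrors partnership + symptom
#' management (`PM`), and `mse` mirrors the 96-point total. A domain is
#' scored 0 (competent) when its long-form counterpart passes, 1
#' otherwise.
#'
#' Two pass rules are provided. The default `"composite"` rule passes on
#' the composite sum (`KC > 24`, `PM > 24`, `total > 48`), matching the
#' composite domain definitions used in the scale comparison. The
#' `"conjunctive"` alternative requires each constituent domain to pass
#' individually (e.g. `ma = 0` iff `K > 8` and `C > 16`).
#'
#' A patient whose long-form total bands as poor (<= 40) can never map to
#' short-form good: the total cannot exceed 48.
#'
#' @param scores A `domain_scores` data frame.
#' @param mapping `"composite"` (default) or `"conjunctive"`.
#' @param thresholds A `pass_thresholds` list.
#' @return An `sf_assessment` data frame.
#' @examples
#' lf_to_sf_equivalent(domain_scores(K = 16, P = 32, M = 16, C = 32)) # (0,0,0)
#' @export
lf_to_sf_equivalent <- function(scores,
                                mapping = c("composite", "conjunctive"),
                                thresholds = pass_thresholds()) {
  mapping <- match.arg(mapping)
  stopifnot(is.data.frame(scores))
  need <- c("K", "P", "M", "C", "KC", "PM", "total")
  if (!all(need %in% names(scores))) {
    stop("domain scores missing columns: ",
         paste(setdiff(need, names(scores)), collapse = ", "))
  }
  th <- thresholds
  if (mapping == "composite") {
    ma <- as.integer(!(scores$KC > th$composite_48))
    mx <- as.integer(!(scores$PM > th$composite_48))
  } else {
    ma <- as.integer(!(scores$K > th$domain_16 & scores$C > th$domain_32))
    mx <- as.integer(!(scores$P > th$domain_32 & scores$M > th$domain_16))
  }
  mse <- as.integer(!(scores$total > th$total_96))
  sf_assessment(ma, mx, mse)
}
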
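#' Triple-contrast corrected interaction effect
#'
#' The corrected bait-proximity effect subtracts the biotin-background
#' and bait over-expression contrasts from the main bait-vs-ligase
#' contrast:
#' \deqn{corrected = log2FC(BAG3\_Biotin\ vs\ BioID)
#'   - log2FC(AC16\_Biotin\ vs\ AC16) - log2FC(BAG3\ vs\ BioID)}
#' Under an additive log2 model with proximity effect t, biotin
#' background b and over-expression effect o, the three contrasts have
#' expectations t + o, b and o - b, so the corrected effect recovers t
#' exactly: (t + o) - b - (o - b) = t.
#'
#' @param fc_main Log2FC of the main contrast (bait+biotin vs ligase+biotin).
#' @param fc_biotin Log2FC of the biotin-background contrast
#'   (biotin-only vs untreated).
#' @param fc_oe Log2FC of the over-expression contrast
#'   (bait-no-biotin vs ligase+biotin).
#' @return \code{fc_main - fc_biotin - fc_oe} (vectorized).
#' @export
corrected_effect <- function(fc_main, fc_biotin, fc_oe) {
  for (nm in c("fc_main", "fc_biotin", "fc_oe")) {
    v <- get(nm)
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop("non-finite log2FC in contrast '", nm, "'")
    }
  }
  fc_main - fc_biotin - fc_oe
}

#' Call bait-interacting proteins from the three contrasts
#'
#' Joins the three contrast result tables on protein id, computes the
#' corrected effect, and calls a protein an interactor when the main
#' contrast's BH-adjusted p is below \code{alpha} and the effect is
#' positive. Proteins untestable in the main contrast are never called;
#' a protein untestable in a correction contrast has that term treated
#' as 0 and is flagged.
#'
#' @param res_main Contrast result for bait+biotin vs ligase+biotin
#'   (see \code{\link{contrast_groups}}).
#' @param res_biotin Contrast result for biotin-only vs untreated.
#' @param res_oe Contrast result for bait-no-biotin vs ligase+biotin.
#' @param alpha Significance threshold on the main contrast's q.
#' @param positive Which effect must be positive for a call:
#'   \code{"corrected"} (default; corrected effect > 0) or
#'   \code{"main"} (raw main-contrast log2FC > 0).
#' @return Data frame sorted by corrected effect descending (ties by
#'   protein id): \code{protein}, \code{fc_main}, \code{fc_biotin},
#'   \code{fc_oe}, \code{corrected}, \code{q_main}, \code{called},
#'   \code{correction_imputed} (TRUE when a missing correction term was
#'   zeroed).
#' @export
call_interactors <- function(res_main, res_biotin, res_oe, alpha = 0.05,
                             positive = c("corrected", "main")) {
  positive <- match.arg(positive)
  ids <- res_main$feature
  if (!length(intersect(ids, intersect(res_biotin$feature, res_oe$feature)))) {
    stop("contrast results share no protein ids")
  }
  fc_b <- res_biotin$log2fc[match(ids, res_biotin$feature)]
  ok_b <- res_biotin$testable[match(ids, res_biotin$feature)]
  fc_o <- res_oe$log2fc[match(ids, res_oe$feature)]
  ok_o <- res_oe$testable[match(ids, res_oe$feature)]
  ok_b[is.na(ok_b)] <- FALSE
  ok_o[is.na(ok_o)] <- FALSE
  imputed <- !ok_b | !ok_o
  fc_b[!ok_b] <- 0
  fc_o[!ok_o] <- 0
  if (any(imputed & res_main$testable)) {
    warning(sum(imputed & res_main$testable),
            " protein(s) missing a correction contrast; term treated as 0",
            call. = FALSE)
  }

  corrected <- ifelse(res_main$testable,
                      res_main$log2fc - fc_b - fc_o, NA_real_)
  effect_pos <- if (positive == "corrected") corrected > 0 else
    res_main$log2fc > 0
  called <- res_main$testable & !is.na(res_main$q) &
    res_main$q < alpha & effect_pos
  called[is.na(called)] <- FALSE

  out <- data.frame(protein = ids,
                    fc_main = res_main$log2fc,
                    fc_biotin = fc_b, fc_oe = fc_o,
                    corrected = corrected,
                    q_main = res_main$q,
                    called = called,
                    correction_imputed = imputed,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-xtfrm(out$corrected), out$protein), , drop = FALSE]
}
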
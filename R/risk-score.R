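# Unweighted composite risk score over a selected transcript panel.
# Transcripts down-regulated in sPTB ("protective") enter reflected about an
# integer ceiling of their observed maximum, so that lower expression of a
# protective transcript raises the score.

#' Build a risk-score panel from selected transcripts
#'
#' Direction is `protective` for transcripts with a negative case-minus-
#' control effect (down in sPTB) and `risk` otherwise. Protective
#' transcripts get a reflection constant: the smallest integer at or above
#' their observed maximum expression across all samples (`ceil_max`), or the
#' exact maximum (`exact_max`). The two modes shift every sample's score by
#' the same constant, so correlations with the score are unaffected.
#'
#' @param de A `de_table` (or any data frame with columns `id` and `effect`)
#'   of panel transcripts.
#' @param expr A [cohort_expr()] holding all panel transcripts.
#' @param reflection Reflection-constant mode, `"ceil_max"` or `"exact_max"`.
#' @return A `score_panel` data frame with columns `id`, `direction`,
#'   `constant` (`NA` for risk transcripts).
#' @export
build_panel <- function(de, expr, reflection = c("ceil_max", "exact_max")) {
  reflection <- match.arg(reflection)
  stopifnot(is.data.frame(de), all(c("id", "effect") %in% names(de)))
  expr <- as_expr_input(expr)
  missing <- setdiff(de$id, rownames(expr$values))
  if (length(missing))
    cl_stop(sprintf("panel transcript(s) absent from expression matrix: %s",
                    paste(missing, collapse = ", ")),
            "circlinc_validation_error")
  protective <- de$effect < 0
  maxima <- apply(expr$values[de$id, , drop = FALSE], 1, max)
  constant <- ifelse(protective,
                     if (reflection == "ceil_max") ceiling(maxima) else maxima,
                     NA_real_)
  out <- data.frame(id = de$id,
                    direction = ifelse(protective, "protective", "risk"),
                    constant = constant,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("score_panel", "data.frame")
  out
}

#' Manually specify a risk-score panel
#'
#' For scoring with published panels whose reflection constants are given
#' (e.g. a printed score formula) rather than derived from data.
#'
#' @param id Transcript identifiers.
#' @param constant Reflection constant per transcript, `NA` for risk
#'   (up-regulated) transcripts.
#' @return A `score_panel` data frame.
#' @export
score_panel <- function(id, constant) {
  stopifnot(length(id) == length(constant), !anyDuplicated(id))
  out <- data.frame(id = as.character(id),
                    direction = ifelse(is.na(constant), "risk", "protective"),
                    constant = as.numeric(constant),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("score_panel", "data.frame")
  out
}

#' Compute the unweighted composite risk score
#'
#' `score(j) = sum_risk x(g, j) + sum_protective (c_g - x(g, j))`. With all
#' transcripts protective and constants at or above the observed maxima, the
#' score is non-negative. Expression exceeding a constant indicates a
#' panel/population mismatch and triggers a warning (the score is still
#' computed).
#'
#' @param expr A [cohort_expr()] (or matrix) holding the panel transcripts.
#' @param panel A `score_panel` from [build_panel()] or [score_panel()].
#' @return An object of class `risk_score`: list with `score` (named numeric
#'   per sample), `panel`, and `group` (or `NULL` for a plain matrix input
#'   without groups).
#' @export
compute_risk_score <- function(expr, panel) {
  stopifnot(inherits(panel, "score_panel"))
  grp <- NULL
  if (inherits(expr, c("cohort_expr", "pathway_scores"))) {
    grp <- expr$group
    expr <- expr$values
  }
  expr <- as.matrix(expr)
  missing <- setdiff(panel$id, rownames(expr))
  if (length(missing))
    cl_stop(sprintf("panel transcript(s) absent from expression matrix: %s",
                    paste(missing, collapse = ", ")),
            "circlinc_validation_error")
  x <- expr[panel$id, , drop = FALSE]
  prot <- panel$direction == "protective"
  if (any(prot)) {
    over <- x[prot, , drop = FALSE] > panel$constant[prot] + 1e-12
    if (any(over))
      warning("expression exceeds a reflection constant; panel and population may mismatch")
  }
  contrib <- x
  contrib[prot, ] <- panel$constant[prot] - x[prot, , drop = FALSE]
  structure(list(score = colSums(contrib), panel = panel, group = grp),
            class = "risk_score")
}

#' @export
print.risk_score <- function(x, ...) {
  cat(sprintf("risk_score over %d transcripts (%d protective), %d samples\n",
              nrow(x$panel), sum(x$panel$direction == "protective"),
              length(x$score)))
  print(summary(x$score))
  invisible(x)
}
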
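#' Closed label sets used by the diagnostic engine
#'
#' `ed_labels()` returns the eight formal DSM-5 eating-disorder categories the
#' engine can assign, in the default precedence order; `ed_labels_all()`
#' additionally includes the residual `"UFED"` category and `"NONE"`.
#' `followup_states()` is the label set used by the longitudinal module:
#' every assignable label plus the `"REMISSION"` state.
#'
#' Labels: `RAN` restrictive anorexia nervosa; `ANBP` anorexia nervosa
#' binge/purge subtype; `BN` bulimia nervosa; `BED` binge eating disorder;
#' `PD` purging disorder; `AAN` atypical anorexia nervosa; `SUBBN`/`SUBBED`
#' sub-threshold (below weekly frequency) bulimia nervosa / binge eating
#' disorder; `UFED` unspecified feeding or eating disorder (assigned via the
#' EDNOS-Other minimal-symptom rule); `NONE` no eating-disorder presentation.
#'
#' @return Character vector of labels.
#' @export
ed_labels <- function() {
  c("RAN", "ANBP", "BN", "BED", "PD", "AAN", "SUBBN", "SUBBED")
}

#' @rdname ed_labels
#' @export
ed_labels_all <- function() {
  c(ed_labels(), "UFED", "NONE")
}

#' @rdname ed_labels
#' @export
followup_states <- function() {
  c(ed_labels(), "UFED", "REMISSION")
}

#' Default category precedence
#'
#' The order in which diagnostic categories are tried: the first category
#' whose rule passes is assigned. The default places purging disorder before
#' atypical anorexia, the resolution of the PD/AAN overlap that maximizes the
#' purging-disorder group (the PD rule is complete while the atypical-anorexia
#' rule rests on a weight-loss surrogate).
#'
#' @return Character vector, a permutation of `ed_labels()`.
#' @export
default_precedence <- function() {
  c("RAN", "ANBP", "BN", "BED", "PD", "AAN", "SUBBN", "SUBBED")
}

#' Validate a category precedence ordering
#'
#' A valid precedence is a permutation of the eight formal labels in which
#' both anorexia subtypes precede bulimia nervosa (anorexia trumps bulimia
#' when both rule sets pass).
#'
#' @param precedence character vector of labels.
#' @return The precedence, invisibly, after validation.
#' @export
validate_precedence <- function(precedence) {
  if (!setequal(precedence, ed_labels()) ||
      length(precedence) != length(ed_labels())) {
    stop("precedence must be a permutation of: ",
         paste(ed_labels(), collapse = ", "))
  }
  bn_pos <- match("BN", precedence)
  if (match("RAN", precedence) > bn_pos || match("ANBP", precedence) > bn_pos) {
    stop("invalid precedence: anorexia subtypes (RAN, ANBP) must precede BN")
  }
  invisible(precedence)
}

#' Round half away from zero
#'
#' Display rounding convention for reported percentages: .5 always rounds up
#' (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
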
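# Outlier handling for 28-day behavior frequencies: cap at a pre-defined
# plausible maximum, then per-group z-transform and iteratively delete the
# top value (or tied block) whenever it sits more than 1 SD above the next
# highest distinct value.

#' Cap extreme values and gap-delete isolated maxima
#'
#' Two-step cleaning used on questionnaire frequency variables. Step 1
#' truncates values above `cap` to `cap`. Step 2, within each group,
#' z-transforms the values (sample SD, n-1 denominator) and deletes the
#' highest distinct value — together with any ties — whenever its z-score
#' exceeds the z-score of the next highest distinct value by more than 1;
#' the scan repeats on the reduced group until no such gap remains. Groups
#' with fewer than 3 observations, or with zero variance, are passed through
#' unchanged (with a warning for the former: the SD is too unstable to
#' standardize against).
#'
#' @param values_by_group named list of numeric vectors.
#' @param cap positive pre-defined maximum.
#' @return list with `values` (cleaned list) and `log` (data.frame of every
#'   capping and deletion event: `group`, `action`, `original`, `result`).
#' @export
cap_and_gap_delete <- function(values_by_group, cap) {
  if (!is.list(values_by_group) || !length(values_by_group)) {
    stop("values_by_group must be a non-empty list")
  }
  if (!is.numeric(cap) || cap <= 0) stop("cap must be positive")
  log <- list()
  note <- function(group, action, original, result) {
    log[[length(log) + 1L]] <<- data.frame(
      group = group, action = action, original = original, result = result,
      stringsAsFactors = FALSE)
  }
  cleaned <- lapply(names(values_by_group), function(g) {
    x <- values_by_group[[g]]
    over <- x > cap
    if (any(over)) {
      for (v in x[over]) note(g, "cap", v, cap)
      x[over] <- cap
    }
    if (length(x) < 3L) {
      warning("group '", g, "' has fewer than 3 values; gap deletion skipped")
      return(x)
    }
    repeat {
      s <- stats::sd(x)
      if (length(x) < 3L || is.na(s) || s == 0) break
      z <- (x - mean(x)) / s
      ord <- order(z, decreasing = TRUE)
      top_z <- z[ord[1]]
      below <- z[z < top_z]
      if (!length(below)) break  # all values tied
      gap <- top_z - max(below)
      if (gap > 1) {
        drop <- z == top_z
        for (v in x[drop]) note(g, "delete", v, NA_real_)
        x <- x[!drop]
      } else {
        break
      }
    }
    x
  })
  names(cleaned) <- names(values_by_group)
  log_df <- if (length(log)) {
    do.call(rbind, log)
  } else {
    data.frame(group = character(0), action = character(0),
               original = numeric(0), result = numeric(0))
  }
  list(values = cleaned, log = log_df)
}
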
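#' Inter-rater agreement: percent agreement and Cohen's kappa
#'
#' Percent agreement is `100 * matches / n`. Cohen's kappa corrects for
#' chance agreement: `kappa = (p_o - p_e) / (1 - p_e)`, with the expected
#' agreement `p_e` computed from the product of the raters' marginal label
#' frequencies. When `p_e = 1` (both raters constant on the same label)
#' kappa is defined as 1 if the raters agree perfectly and 0 otherwise,
#' with a warning. With `by`, agreement is reported per group (e.g. per
#' defacing method and criterion).
#'
#' @param a,b equal-length label vectors from two raters.
#' @param by optional grouping vector (same length) for per-group reports.
#' @return a one-row data.frame with `agreement` (percent), `kappa` and
#'   `n`; with `by`, one row per group plus the group column.
#' @examples
#' a <- c(0, 0, 1, 1, 1, 0, 1, 0, 1, 1)
#' b <- c(0, 1, 1, 1, 0, 0, 1, 0, 1, 1)
#' raterAgreement(a, b)   # 80% agreement
#' @export
raterAgreement <- function(a, b, by = NULL) {
  if (length(a) == 0) stop("empty label vectors")
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (!is.null(by)) {
    stopifnot(length(by) == length(a))
    out <- do.call(rbind, lapply(split(seq_along(a), by), function(idx)
      raterAgreement(a[idx], b[idx])))
    out <- cbind(data.frame(group = names(split(seq_along(a), by))), out)
    rownames(out) <- NULL
    return(out)
  }
  n <- length(a)
  po <- mean(a == b)
  classes <- union(a, b)
  pe <- sum(vapply(classes, function(cl)
    mean(a == cl) * mean(b == cl), numeric(1)))
  kappa <- if (abs(1 - pe) < .Machine$double.eps) {
    warning("expected agreement is 1; kappa set to ",
            if (po == 1) "1" else "0")
    if (po == 1) 1 else 0
  } else {
    (po - pe) / (1 - pe)
  }
  data.frame(agreement = 100 * po, kappa = kappa, n = n)
}
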
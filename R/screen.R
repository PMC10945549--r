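# Secretome screen statistics: normalization to the stimulated control and
# differential secretion testing.

.check_secretome <- function(raw) {
  need <- c("factor", "condition", "replicate", "value")
  if (!is.data.frame(raw) || !all(need %in% names(raw)))
    stop("secretome table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyNA(raw$value) || !all(is.finite(raw$value)) || any(raw$value < 0))
    stop("secretome readouts must be finite and >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Normalize secretome readouts to a control condition
#'
#' Divides each factor's per-condition mean readout by that factor's mean
#' level under the control condition (typically the LPS-only stimulation), so
#' the control maps to 1.0. Factors whose control mean is zero cannot be
#' quantified on this scale and are excluded (recorded in the `"excluded"`
#' attribute).
#'
#' @param raw long-format `data.frame(factor, condition, replicate, value)`.
#' @param control_label the condition used as denominator.
#' @return Numeric matrix, conditions in rows and factors in columns, of
#'   levels relative to the control.
#' @export
normalize_to_control <- function(raw, control_label = "LPS") {
  .check_secretome(raw)
  if (!control_label %in% raw$condition)
    stop("control condition '", control_label, "' not present", call. = FALSE)
  means <- tapply(raw$value, list(raw$condition, raw$factor), mean)
  ctrl <- means[control_label, ]
  ok <- !is.na(ctrl) & ctrl > 0
  if (any(!ok))
    warning("factor(s) with zero/absent control level excluded: ",
            paste(colnames(means)[!ok], collapse = ", "), call. = FALSE)
  out <- sweep(means[, ok, drop = FALSE], 2L, ctrl[ok], "/")
  attr(out, "excluded") <- colnames(means)[!ok]
  out
}

#' Differential secretion between two conditions
#'
#' Per-factor two-sided Welch (unequal-variance) t-test on
#' `log2(value + log_offset)` readouts, with Benjamini-Hochberg adjustment
#' across all tested factors. A factor is flagged significant when its
#' adjusted p-value falls below `fdr`. Factors with fewer than 2 replicates in
#' either condition are excluded with a reason; factors with zero variance in
#' both conditions get p = 1 when the means agree (no evidence of change) and
#' p = 0 for perfect separation.
#'
#' @param raw long-format `data.frame(factor, condition, replicate, value)`.
#' @param cond_a,cond_b condition labels; fold changes are `cond_b` over
#'   `cond_a` (e.g. `cond_a = "control"`, `cond_b = "LPS"`).
#' @param fdr Benjamini-Hochberg significance level.
#' @param log_offset added before the log transform to tolerate zeros.
#' @return `data.frame(factor, n_a, n_b, log2fc, p, q, significant, reason)`,
#'   one row per factor; excluded factors carry `NA` statistics and a reason.
#' @export
differential_secretion <- function(raw, cond_a = "control", cond_b = "LPS",
                                   fdr = 0.05, log_offset = 1) {
  .check_secretome(raw)
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)", call. = FALSE)
  for (cl in c(cond_a, cond_b))
    if (!cl %in% raw$condition)
      stop("condition '", cl, "' not present", call. = FALSE)
  factors <- unique(raw$factor)
  res <- lapply(factors, function(f) {
    va <- raw$value[raw$factor == f & raw$condition == cond_a]
    vb <- raw$value[raw$factor == f & raw$condition == cond_b]
    if (length(va) < 2 || length(vb) < 2)
      return(data.frame(factor = f, n_a = length(va), n_b = length(vb),
                        log2fc = NA_real_, p = NA_real_,
                        reason = "fewer than 2 replicates"))
    la <- log2(va + log_offset); lb <- log2(vb + log_offset)
    lfc <- mean(lb) - mean(la)
    p <- if (sd(la) == 0 && sd(lb) == 0) {
      if (lfc == 0) 1 else 0
    } else {
      t.test(lb, la, var.equal = FALSE)$p.value
    }
    data.frame(factor = f, n_a = length(va), n_b = length(vb),
               log2fc = lfc, p = p, reason = NA_character_)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- p.adjust(out$p[tested], method = "BH")
  out$significant <- !is.na(out$q) & out$q < fdr
  out[, c("factor", "n_a", "n_b", "log2fc", "p", "q", "significant",
          "reason")]
}
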
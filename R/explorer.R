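# Result surfaces: kinase-cytokine hit matrix, drug efficacy, rankings.

#' Build the binary kinase-by-cytokine hit matrix
#'
#' Entry (j, c) is 1 exactly when kinase j is in the informative set of
#' cytokine c's model, 0 otherwise. Per-kinase counts summarize how many
#' cytokines a kinase could regulate, both within a user selection of
#' cytokines of interest and among all modeled cytokines.
#'
#' @param models a `"kir_model_set"`, list of `"kir_model"`, or one model.
#' @param selection optional cytokine ids of interest for the `n_selected`
#'   count (default: all).
#' @param accepted_only use only models passing the quality gate (default).
#' @return An object of class `"kinase_cytokine_matrix"`: `matrix` (binary,
#'   kinases x cytokines) and `counts`
#'   (`data.frame(kinase, n_selected, n_all)`, sorted by `n_selected` then
#'   `n_all`, descending).
#' @export
build_kinase_cytokine_matrix <- function(models, selection = NULL,
                                         accepted_only = TRUE) {
  lst <- .as_model_list(models, accepted_only)
  if (!length(lst))
    stop("no models available (all rejected by the quality gate?)",
         call. = FALSE)
  kinases <- sort(unique(unlist(lapply(lst, `[[`, "kinase_ids"))))
  cytokines <- names(lst)
  if (is.null(selection)) selection <- cytokines
  unknown <- setdiff(selection, cytokines)
  if (length(unknown))
    stop("unknown cytokine(s) in selection: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  M <- matrix(0L, length(kinases), length(cytokines),
              dimnames = list(kinases, cytokines))
  for (cy in cytokines)
    M[lst[[cy]]$informative_kinases, cy] <- 1L
  counts <- data.frame(kinase = kinases,
                       n_selected = rowSums(M[, selection, drop = FALSE]),
                       n_all = rowSums(M), row.names = NULL)
  counts <- counts[order(-counts$n_selected, -counts$n_all, counts$kinase), ]
  rownames(counts) <- NULL
  structure(list(matrix = M, counts = counts, selection = selection),
            class = "kinase_cytokine_matrix")
}

#' @export
print.kinase_cytokine_matrix <- function(x, ...) {
  cat(sprintf("Kinase-cytokine hit matrix: %d kinases x %d cytokines, %d hits\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$matrix)))
  print(head(x$counts, 10))
  invisible(x)
}

#' Convert predicted levels to percent efficacy
#'
#' Efficacy is the percent suppression relative to the LPS-only control:
#' `100 * (1 - level)`, so a level of 1 (no change) is 0% and complete
#' suppression is 100%. Negative predicted levels are clipped to 0 before
#' conversion (with a message); efficacies can be clipped below at `floor`
#' for display.
#'
#' @param predicted matrix of levels on the fraction-of-control scale, drugs
#'   in rows, cytokines in columns.
#' @param floor lower display clip for efficacies (default `-Inf`, no clip).
#' @return Matrix of efficacies (percent), same shape as `predicted`.
#' @export
compute_efficacy <- function(predicted, floor = -Inf) {
  if (!is.matrix(predicted)) predicted <- as.matrix(predicted)
  nneg <- sum(predicted < 0)
  if (nneg > 0) {
    message(nneg, " negative predicted level(s) clipped to 0")
    predicted <- pmax(predicted, 0)
  }
  pmax(100 * (1 - predicted), floor)
}

# 1 - normalized Shannon entropy of a drug's positive efficacy profile;
# 1 = all suppression concentrated on one factor, 0 = spread evenly.
.profile_specificity <- function(eff_row) {
  p <- pmax(eff_row, 0)
  m <- length(p)
  if (m < 2 || sum(p) == 0) return(NA_real_)
  p <- p / sum(p)
  h <- -sum(p[p > 0] * log(p[p > 0]))
  1 - h / log(m)
}

#' Rank drugs by average predicted efficacy on selected cytokines
#'
#' Summarizes every drug over the cytokines of interest: average efficacy,
#' percent of the selection affected (efficacy at or above
#' `inhibition_threshold`), whether the drug affects all modeled cytokines or
#' a narrower scope, a specificity index (1 - normalized Shannon entropy of
#' the efficacy profile), optional kinase selectivity (fraction of panel
#' kinases with residual activity < 50) and FDA approval status. Drugs are
#' sorted by average efficacy, ties broken by percent affected and then drug
#' id; the top `k` form the chart table while the full table keeps every drug.
#'
#' @param eff efficacy matrix from [compute_efficacy()].
#' @param selection cytokine ids of interest (must exist in `eff`).
#' @param k size of the top list.
#' @param inhibition_threshold percent efficacy at which a cytokine counts as
#'   affected.
#' @param annotations optional `data.frame(drug_id, fda_approved)`.
#' @param X_panel optional residual-activity matrix used for the kinase
#'   selectivity column.
#' @return An object of class `"drug_ranking"`: `top` (k rows), `table` (all
#'   drugs) and the threshold used.
#' @export
rank_drugs <- function(eff, selection = colnames(eff), k = 10,
                       inhibition_threshold = 50, annotations = NULL,
                       X_panel = NULL) {
  if (!is.matrix(eff) || is.null(colnames(eff)) || is.null(rownames(eff)))
    stop("eff must be a matrix with drug and cytokine names", call. = FALSE)
  if (!length(selection)) stop("selection must be non-empty", call. = FALSE)
  unknown <- setdiff(selection, colnames(eff))
  if (length(unknown))
    stop("unknown cytokine(s) in selection: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sel <- eff[, selection, drop = FALSE]
  tab <- data.frame(
    drug_id = rownames(eff),
    avg_efficacy = rowMeans(sel),
    n_affected = rowSums(sel >= inhibition_threshold),
    pct_selection_affected =
      100 * rowMeans(sel >= inhibition_threshold),
    affects_all_cytokines =
      rowSums(eff >= inhibition_threshold) == ncol(eff),
    specificity = apply(eff, 1, .profile_specificity),
    row.names = NULL)
  if (!is.null(X_panel)) {
    idx <- match(tab$drug_id, rownames(X_panel))
    tab$selectivity <- rowMeans(X_panel < 50)[idx]
  }
  if (!is.null(annotations)) {
    if (!all(c("drug_id", "fda_approved") %in% names(annotations)))
      stop("annotations need columns drug_id and fda_approved", call. = FALSE)
    tab$fda_approved <-
      annotations$fda_approved[match(tab$drug_id, annotations$drug_id)]
  }
  tab <- tab[order(-tab$avg_efficacy, -tab$pct_selection_affected,
                   tab$drug_id), ]
  rownames(tab) <- NULL
  structure(list(top = head(tab, k), table = tab,
                 inhibition_threshold = inhibition_threshold,
                 selection = selection),
            class = "drug_ranking")
}

#' @export
print.drug_ranking <- function(x, ...) {
  cat(sprintf("Drug ranking on %d cytokine(s), affected = efficacy >= %g%%\n",
              length(x$selection), x$inhibition_threshold))
  print(x$top)
  invisible(x)
}

#' Count broadly inhibited cytokines per drug
#'
#' Per drug, the number of cytokines whose predicted efficacy is at or above
#' `inhibition_threshold` percent; the count is non-increasing in the
#' threshold.
#'
#' @inheritParams rank_drugs
#' @return Named integer vector, one count per drug.
#' @export
count_broadly_inhibited <- function(eff, inhibition_threshold = 50) {
  if (inhibition_threshold <= 0 || inhibition_threshold > 100)
    stop("inhibition_threshold must be in (0, 100]", call. = FALSE)
  rowSums(eff >= inhibition_threshold)
}

#' Per-drug efficacy profile
#'
#' The drill-down behind a ranked drug: its efficacy on each cytokine.
#'
#' @param eff efficacy matrix.
#' @param drug_id one drug.
#' @return `data.frame(cytokine, efficacy)` sorted by efficacy, descending.
#' @export
efficacy_profile <- function(eff, drug_id) {
  if (!drug_id %in% rownames(eff))
    stop("unknown drug: ", drug_id, call. = FALSE)
  out <- data.frame(cytokine = colnames(eff), efficacy = eff[drug_id, ],
                    row.names = NULL)
  out[order(-out$efficacy), ]
}
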
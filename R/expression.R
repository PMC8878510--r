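# Relative normalized expression by the delta-delta-Cq method with two
# housekeeping genes, and the dual biological/statistical cut-off
# (fold change > 2 in either direction AND p < 0.05).

#' Validate a Cq table
#'
#' Expects columns sample_id, condition, gene, replicate, cq. Checks that Cq
#' values are finite and positive, that every sample carries both housekeeping
#' genes, and warns when the replicate structure is not triplicate.
#'
#' @param cq data.frame of Cq measurements.
#' @param housekeeping character vector of exactly 2 housekeeping gene names.
#' @return the validated data.frame, invisibly.
#' @export
validate_cq_table <- function(cq, housekeeping) {
  need <- c("sample_id", "condition", "gene", "replicate", "cq")
  if (!all(need %in% names(cq)))
    stop(sprintf("Cq table must have columns %s", paste(need, collapse = ", ")), call. = FALSE)
  if (length(housekeeping) != 2)
    stop("exactly 2 housekeeping genes are required", call. = FALSE)
  if (any(!is.finite(cq$cq)) || any(cq$cq <= 0))
    stop("Cq values must be finite and > 0", call. = FALSE)
  for (s in unique(cq$sample_id)) {
    gs <- unique(cq$gene[cq$sample_id == s])
    miss <- setdiff(housekeeping, gs)
    if (length(miss))
      stop(sprintf("sample '%s' is missing housekeeping gene(s) %s",
                   s, paste(miss, collapse = ", ")), call. = FALSE)
  }
  reps <- stats::aggregate(replicate ~ sample_id + gene, cq, length)
  if (any(reps$replicate != 3))
    warning("non-triplicate Cq measurements present")
  invisible(cq)
}

#' Per-sample delta-Cq against two housekeeping genes
#'
#' For each sample and target gene:
#' `dCq = mean(Cq_target) - mean(mean(Cq_HK1), mean(Cq_HK2))`
#' (replicates averaged first; the arithmetic mean of the two housekeeping Cq
#' means is equivalent to geometric-mean normalization of quantities).
#'
#' @param cq validated Cq table.
#' @param housekeeping the 2 housekeeping gene names.
#' @param targets target genes (default: every non-housekeeping gene present).
#' @return data.frame: sample_id, condition, gene, delta_cq.
#' @export
delta_cq <- function(cq, housekeeping, targets = NULL) {
  validate_cq_table(cq, housekeeping)
  if (is.null(targets)) targets <- setdiff(unique(cq$gene), housekeeping)
  out <- list()
  for (s in unique(cq$sample_id)) {
    sub <- cq[cq$sample_id == s, , drop = FALSE]
    hk <- mean(vapply(housekeeping, function(g) mean(sub$cq[sub$gene == g]), numeric(1)))
    for (g in intersect(targets, unique(sub$gene))) {
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, condition = sub$condition[1], gene = g,
        delta_cq = mean(sub$cq[sub$gene == g]) - hk)
    }
  }
  do.call(rbind, out)
}

#' Fold change between treated and control delta-Cq sets
#'
#' `ddCq = mean(dCq_treated) - mean(dCq_control)`; fold = `efficiency^(-ddCq)`
#' (efficiency 2 is the classic delta-delta-Cq assumption). The p-value comes
#' from a two-sided Welch t-test on the per-sample dCq values; with a
#' singleton group the fold is still computed and the p is `NA`.
#'
#' @param dcq_treated,dcq_control numeric vectors of per-sample delta-Cq.
#' @param efficiency amplification efficiency (default 2).
#' @return data.frame: delta_delta_cq, fold_change, p_value.
#' @export
fold_change <- function(dcq_treated, dcq_control, efficiency = 2) {
  if (!length(dcq_treated) || !length(dcq_control))
    stop("both groups need at least one sample", call. = FALSE)
  dd <- mean(dcq_treated) - mean(dcq_control)
  p <- if (length(dcq_treated) >= 2 && length(dcq_control) >= 2)
    tryCatch(stats::t.test(dcq_treated, dcq_control)$p.value,
             error = function(e) NA_real_)  # zero-variance groups
  else NA_real_
  data.frame(delta_delta_cq = dd, fold_change = efficiency^(-dd), p_value = p)
}

#' Dual biological/statistical cut-off
#'
#' A gene is flagged iff the fold change exceeds `fold_cut` in either
#' direction (`|log2 fold| > log2(fold_cut)`, both directions — up- and
#' down-regulation treated symmetrically) AND `p < p_cut`; both strict.
#' A missing p-value yields `FALSE` with a note.
#'
#' @param fold fold change (> 0).
#' @param p p-value (may be `NA`).
#' @param fold_cut fold-change cut (default 2).
#' @param p_cut significance cut (default 0.05).
#' @return logical flag.
#' @export
apply_cutoff <- function(fold, p, fold_cut = 2, p_cut = 0.05) {
  stopifnot(fold > 0)
  if (is.na(p)) {
    message("p-value missing: gene not flagged")
    return(FALSE)
  }
  abs(log2(fold)) > log2(fold_cut) && p < p_cut
}

#' Relative normalized expression for all target genes
#'
#' Runs the full delta-delta-Cq analysis of a Cq table: per-sample delta-Cq
#' against the two housekeeping genes, fold change of the treated condition
#' against untreated controls (fold 1 = untreated), Welch p-value, and the
#' dual cut-off flag.
#'
#' @param cq Cq table (see [validate_cq_table()]).
#' @param housekeeping the 2 housekeeping gene names.
#' @param treated,control condition labels (defaults "CAP" and "UT").
#' @param efficiency amplification efficiency (default 2).
#' @param fold_cut,p_cut cut-off parameters.
#' @return data.frame, one row per gene: n per group, delta_delta_cq,
#'   fold_change, p_value, flagged.
#' @export
relative_expression <- function(cq, housekeeping, treated = "CAP", control = "UT",
                                efficiency = 2, fold_cut = 2, p_cut = 0.05) {
  d <- delta_cq(cq, housekeeping)
  out <- list()
  for (g in unique(d$gene)) {
    dg <- d[d$gene == g, , drop = FALSE]
    tr <- dg$delta_cq[dg$condition == treated]
    ut <- dg$delta_cq[dg$condition == control]
    fc <- fold_change(tr, ut, efficiency)
    fc$gene <- g
    fc$n_treated <- length(tr)
    fc$n_control <- length(ut)
    fc$flagged <- suppressMessages(
      apply_cutoff(fc$fold_change, fc$p_value, fold_cut, p_cut))
    out[[length(out) + 1L]] <- fc
  }
  res <- do.call(rbind, out)
  res[, c("gene", "n_treated", "n_control", "delta_delta_cq",
          "fold_change", "p_value", "flagged")]
}
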
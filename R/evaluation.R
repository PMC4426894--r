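#' @title Prediction performance assessment
#' @name evaluation
#' @description
#' Confusion-matrix metrics (accuracy, sensitivity/TPR, FPR/specificity,
#' MCC), operating-point selection at a pooled 5% false-positive-rate cap
#' or at maximum MCC, the leave-one-out driver, balanced subsampling,
#' per-amino-acid breakdown and adjacency-tolerant relabeling.
NULL

#' Confusion-matrix metrics
#'
#' @param counts list or vector with `tp`, `tn`, `fp`, `fn`.
#' @return list with `acc`, `tpr` (sensitivity), `fpr`, `specificity` and
#'   `mcc` (0 when any denominator factor vanishes).
#' @export
confusion_metrics <- function(counts) {
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  total <- tp + tn + fp + fn
  if (total <= 0) stop("no evaluated residues")
  acc <- (tp + tn) / total
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  list(acc = acc, tpr = tpr, fpr = fpr,
       specificity = if (is.na(fpr)) NA_real_ else 1 - fpr, mcc = mcc)
}

counts_at_threshold <- function(z, label, t) {
  call <- z >= t
  list(tp = sum(call & label), tn = sum(!call & !label),
       fp = sum(call & !label), fn = sum(!call & label))
}

check_two_classes <- function(label) {
  if (!any(label) || all(label)) stop("both classes must be present")
}

#' Score threshold at a false-positive-rate cap
#'
#' Scans the observed scores as candidate thresholds (a residue is called
#' when its score is >= the threshold) and returns the smallest threshold
#' whose pooled FPR is at or below the cap; since FPR and TPR both fall
#' as the threshold rises, this is the feasible threshold of maximal TPR.
#'
#' @param z numeric scores.
#' @param label logical truth labels.
#' @param fpr_cap maximum tolerated FPR, default 0.05.
#' @return the selected threshold.
#' @export
threshold_at_fpr <- function(z, label, fpr_cap = 0.05) {
  check_two_classes(label)
  keep <- is.finite(z)
  z <- z[keep]; label <- label[keep]
  cand <- sort(unique(z))
  nneg <- sum(!label)
  fpr <- vapply(cand, function(t) sum(!label & z >= t) / nneg, numeric(1))
  ok <- fpr <= fpr_cap
  if (!any(ok)) {
    # fall back to the strictest threshold (call only the top score)
    return(max(cand))
  }
  min(cand[ok])
}

#' Score threshold maximizing the MCC
#'
#' Exhaustive scan over the observed scores; ties are broken towards the
#' higher threshold.  A degenerate input (all scores equal) is flagged
#' with a warning and yields the single observed score.
#'
#' @inheritParams threshold_at_fpr
#' @return the selected threshold.
#' @export
threshold_at_max_mcc <- function(z, label) {
  check_two_classes(label)
  keep <- is.finite(z)
  z <- z[keep]; label <- label[keep]
  cand <- sort(unique(z))
  if (length(cand) == 1) {
    warning("all scores equal; MCC threshold degenerate", call. = FALSE)
    return(cand)
  }
  mcc <- vapply(cand, function(t) {
    confusion_metrics(counts_at_threshold(z, label, t))$mcc
  }, numeric(1))
  max(cand[mcc == max(mcc)])
}

#' Leave-one-out evaluation over a dataset
#'
#' Scores every protein against the template database with all templates
#' from the query's own PDB entry excluded, z-normalizes per protein,
#' pools all residues and reports metrics at the pooled 5%-FPR and
#' maximum-MCC operating points.
#'
#' @param dataset list of entries `list(model, annotations)` where
#'   `annotations` is a list of binding annotations defining the truth
#'   labels (a residue is binding when its sequence key appears in any
#'   annotation for its chain).  Secondary structure is assigned with the
#'   built-in fallback when residues carry no labels.
#' @param db a `template_database`.
#' @param params overrides of [default_params()].
#' @return list with `score_table` (per-residue pooled table),
#'   `threshold_fpr`, `threshold_mcc`, `metrics_fpr`, `metrics_mcc`.
#' @export
leave_one_out <- function(dataset, db, params = list()) {
  if (length(dataset) < 2) stop("leave-one-out needs at least 2 proteins")
  p <- merge_params(params)
  tabs <- list()
  for (entry in dataset) {
    model <- entry$model
    model <- apply_ss_labels(model, assign_secondary_structure(model, entry$dssp_text))
    anns <- entry$annotations
    if (!is.null(anns$binding_positions)) anns <- list(anns)
    chain_tabs <- list()
    for (cid in names(model$chains)) {
      chain <- model$chains[[cid]]
      pred <- residue_binding_scores(chain, db,
                                     c(params, list(exclude_pdb = model$pdb_id)))
      pred <- apply_moiety_boost(pred, range = p$boost_range, mode = p$boost_mode)
      truth_keys <- unique(unlist(lapply(anns, function(a) {
        if (identical(a$chain_id, cid)) as.character(a$binding_positions) else character(0)
      })))
      pred$label <- pred$seq_key %in% truth_keys
      pred$pdb_id <- model$pdb_id
      chain_tabs[[length(chain_tabs) + 1L]] <- pred
    }
    tab <- do.call(rbind, chain_tabs)
    tab$z <- tryCatch(normalize_scores(tab$score_boosted),
                      fragsite_degenerate_scores = function(e) {
                        warning(model$pdb_id, ": ", conditionMessage(e), call. = FALSE)
                        rep(NA_real_, nrow(tab))
                      })
    tabs[[length(tabs) + 1L]] <- tab
  }
  score_table <- do.call(rbind, tabs)
  # leakage guard: no surviving score may come from a template of the query
  leak <- !is.na(score_table$template_id) &
    mapply(function(tid, pid) startsWith(tolower(tid), tolower(pid)),
           score_table$template_id, score_table$pdb_id)
  if (any(leak)) stop("leave-one-out violation: self-template contributed a score")
  pool <- score_table[is.finite(score_table$z), , drop = FALSE]
  t_fpr <- threshold_at_fpr(pool$z, pool$label, p$fpr_cap)
  t_mcc <- threshold_at_max_mcc(pool$z, pool$label)
  score_table$call <- is.finite(score_table$z) & score_table$z >= t_fpr
  list(score_table = score_table,
       threshold_fpr = t_fpr, threshold_mcc = t_mcc,
       metrics_fpr = confusion_metrics(counts_at_threshold(pool$z, pool$label, t_fpr)),
       metrics_mcc = confusion_metrics(counts_at_threshold(pool$z, pool$label, t_mcc)))
}

#' Balanced-subsample evaluation
#'
#' For each repeat, samples (without replacement) per protein as many
#' nonbinding residues as it has binding residues, pools the balanced
#' set, evaluates at that pool's maximum-MCC threshold and reports the
#' per-repeat metrics plus their average.
#'
#' @param score_table per-residue table with `pdb_id`, `z`, `label`.
#' @param n_repeats number of random subsamples, default 5.
#' @param seed RNG seed, default 42.
#' @return data.frame of metrics with one row per repeat and an
#'   `average` row.
#' @export
balanced_subsample_eval <- function(score_table, n_repeats = 5L, seed = 42L) {
  st <- score_table[is.finite(score_table$z), , drop = FALSE]
  set.seed(seed)
  rows <- list()
  for (r in seq_len(n_repeats)) {
    sel <- list()
    for (pid in unique(st$pdb_id)) {
      sub <- st[st$pdb_id == pid, , drop = FALSE]
      pos <- which(sub$label); neg <- which(!sub$label)
      if (!length(pos)) next
      if (length(neg) < length(pos)) {
        warning("protein ", pid, " has more binding than nonbinding residues; skipped",
                call. = FALSE)
        next
      }
      keep <- c(pos, sample(neg, length(pos)))
      sel[[length(sel) + 1L]] <- sub[keep, , drop = FALSE]
    }
    pool <- do.call(rbind, sel)
    t_mcc <- threshold_at_max_mcc(pool$z, pool$label)
    m <- confusion_metrics(counts_at_threshold(pool$z, pool$label, t_mcc))
    rows[[r]] <- data.frame(repeat_id = as.character(r), acc = m$acc,
                            sensitivity = m$tpr, specificity = m$specificity,
                            mcc = m$mcc, n = nrow(pool), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  avg <- data.frame(repeat_id = "average", acc = mean(out$acc),
                    sensitivity = mean(out$sensitivity),
                    specificity = mean(out$specificity), mcc = mean(out$mcc),
                    n = round(mean(out$n)), stringsAsFactors = FALSE)
  rbind(out, avg)
}

#' Adjacency-tolerant relabeling of false positives
#'
#' Any false-positive residue directly adjacent in sequence (same protein
#' and chain, residue number +/- 1) to a true positive is reclassified as
#' a true positive; both the original and adjusted counts and metrics are
#' returned.
#'
#' @param score_table per-residue table with `pdb_id`, `chain_id`,
#'   `seq_pos`, `label`, `call`.
#' @return list with `original`/`adjusted` counts, `metrics_original`/
#'   `metrics_adjusted`, and the table with a `reclassified` column.
#' @export
adjacency_relabel <- function(score_table) {
  st <- score_table
  tp <- st$call & st$label
  fp <- st$call & !st$label
  key <- paste(st$pdb_id %||% "", st$chain_id, st$seq_pos)
  tp_keys <- c(paste(st$pdb_id[tp] %||% "", st$chain_id[tp], st$seq_pos[tp] - 1),
               paste(st$pdb_id[tp] %||% "", st$chain_id[tp], st$seq_pos[tp] + 1))
  recl <- fp & key %in% tp_keys
  orig <- list(tp = sum(tp), tn = sum(!st$call & !st$label),
               fp = sum(fp), fn = sum(!st$call & st$label))
  adj <- orig
  adj$tp <- adj$tp + sum(recl)
  adj$fp <- adj$fp - sum(recl)
  st$reclassified <- recl
  list(original = orig, adjusted = adj,
       metrics_original = confusion_metrics(orig),
       metrics_adjusted = confusion_metrics(adj),
       table = st)
}

#' Per-amino-acid sensitivity and specificity
#'
#' @param score_table per-residue table with `res_name`, `label`, `call`.
#' @return data.frame per residue type: counts, sensitivity (`NA` when the
#'   type has no positives) and specificity.
#' @export
per_residue_breakdown <- function(score_table) {
  rows <- list()
  for (rn in sort(unique(score_table$res_name))) {
    sub <- score_table[score_table$res_name == rn, , drop = FALSE]
    tp <- sum(sub$call & sub$label); fn <- sum(!sub$call & sub$label)
    fp <- sum(sub$call & !sub$label); tn <- sum(!sub$call & !sub$label)
    rows[[length(rows) + 1L]] <- data.frame(
      res_name = rn, n = nrow(sub), tp = tp, fn = fn, fp = fp, tn = tn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
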
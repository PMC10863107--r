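#' Junction-level recall and precision against simulation truth
#'
#' Matches called junctions to true junctions per individual and
#' chromosome with greedy one-to-one nearest matching at tolerance
#' `tol` bp. Recall is matched truths over all truths; precision is
#' matched calls over all (primary, non-env-flagged) calls.
#'
#' @param called data.frame of called sites (with `individual`,
#'   `junction`, `chrom`; env-flagged rows are dropped if the column is
#'   present).
#' @param truth truth table from [simulate_cohort()] (`individual`,
#'   `chrom`, `junction`).
#' @param tol matching tolerance in bp (default 5).
#' @return list with `recall`, `precision`, `n_truth`, `n_called`,
#'   `n_matched`.
#' @export
evaluate_recovery <- function(called, truth, tol = 5L) {
  if ("env_flagged" %in% names(called)) called <- primary_sites(called)
  n_matched <- 0L
  for (ind in unique(truth$individual)) {
    tr <- truth[truth$individual == ind, , drop = FALSE]
    ca <- called[called$individual == ind, , drop = FALSE]
    for (ch in unique(tr$chrom)) {
      tj <- sort(tr$junction[tr$chrom == ch])
      cj <- sort(ca$junction[ca$chrom == ch])
      for (t in tj) {
        if (length(cj) == 0) break
        d <- abs(cj - t)
        k <- which.min(d)
        if (d[k] <= tol) {
          n_matched <- n_matched + 1L
          cj <- cj[-k]
        }
      }
    }
  }
  list(recall = if (nrow(truth)) n_matched / nrow(truth) else NA_real_,
       precision = if (nrow(called)) n_matched / nrow(called) else NA_real_,
       n_truth = nrow(truth), n_called = nrow(called),
       n_matched = n_matched)
}
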
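#' Area under the ROC curve
#'
#' Nonparametric AUC equal to the Mann-Whitney pair statistic: the mean over
#' all (presence, absence) score pairs of 1 if the presence scores higher,
#' 1/2 on ties, 0 otherwise.  Computed via mid-ranks, so ties follow the
#' standard ROC estimator.  Invariant under strictly increasing transforms
#' of the scores.
#'
#' @param scores Numeric prediction scores (e.g. probabilities of presence).
#' @param labels Binary labels (0/1 or logical), same length as `scores`.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC requires at least one presence and one absence", call. = FALSE)
  r <- rank(scores)                      # mid-ranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Validate hindcast surfaces against fossil-type records
#'
#' For each fossil record, extracts the probability of presence from the
#' surface of the record's period; records on nodata (or ice-masked) cells
#' or outside the grid are dropped and counted.  AUC is reported per period
#' and pooled by concatenating all (score, label) pairs across periods.
#' Per-period AUC is `NA` (with a note in the table) when a period retains
#' only one label class.
#'
#' @param surfaces Named list of probability surfaces ([predict_surface()]
#'   results), names matching the period tags in `fossils`.
#' @param fossils Data frame with `lon`, `lat`, `period`, `label` (0/1),
#'   e.g. from [make_fossil_records()] or [read_fossil_csv()].
#' @return An object of class `validation_result`: list with `pooled_auc`,
#'   `per_period` (data frame: period, n_used, n_dropped, auc) and totals.
#' @export
validate_hindcast <- function(surfaces, fossils) {
  periods <- unique(as.character(fossils$period))
  missing_p <- setdiff(periods, names(surfaces))
  if (length(missing_p))
    stop(sprintf("no surface supplied for period(s): %s",
                 paste(missing_p, collapse = ", ")), call. = FALSE)
  all_scores <- numeric(0); all_labels <- integer(0)
  tab <- data.frame(period = periods, n_used = 0L, n_dropped = 0L,
                    auc = NA_real_)
  for (i in seq_along(periods)) {
    p <- periods[i]
    rec <- fossils[fossils$period == p, ]
    s <- values_at_xy(surfaces[[p]], rec$lon, rec$lat)
    ok <- !is.na(s)
    tab$n_used[i] <- sum(ok); tab$n_dropped[i] <- sum(!ok)
    lab <- as.integer(rec$label[ok])
    if (length(unique(lab)) == 2L)
      tab$auc[i] <- auc(s[ok], lab)
    all_scores <- c(all_scores, s[ok])
    all_labels <- c(all_labels, lab)
  }
  if (!length(all_scores))
    stop("all fossil records fell on nodata cells", call. = FALSE)
  structure(list(pooled_auc = auc(all_scores, all_labels),
                 per_period = tab,
                 n_used = sum(tab$n_used), n_dropped = sum(tab$n_dropped)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> pooled AUC %.3f over %d records (%d dropped)\n",
              x$pooled_auc, x$n_used, x$n_dropped))
  print(x$per_period, row.names = FALSE)
  invisible(x)
}
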
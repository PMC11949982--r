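#' DeLong test for two correlated AUROCs
#'
#' Compares the AUROCs of two score vectors evaluated on the same subjects
#' using DeLong's structural-components variance estimate for correlated
#' ROC curves; ties in the Mann-Whitney kernel count 1/2.
#'
#' @param scores_a,scores_b numeric scores of the two models for the same
#'   subjects, in the same order.
#' @param positive logical vector marking positive cases.
#' @return list with `auc_a`, `auc_b`, `delta` (a minus b), `var_delta`,
#'   `z`, and two-sided `p`. Identical score vectors give `delta = 0`,
#'   `p = 1`.
#' @export
delong_test <- function(scores_a, scores_b, positive) {
  positive <- as.logical(positive)
  stopifnot(length(scores_a) == length(positive),
            length(scores_b) == length(positive))
  xs <- cbind(scores_a, scores_b)[positive, , drop = FALSE]
  ys <- cbind(scores_a, scores_b)[!positive, , drop = FALSE]
  m <- nrow(xs)
  n <- nrow(ys)
  if (m == 0 || n == 0) stop("need both positive and negative cases")
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- matrix(0, m, 2)
  v01 <- matrix(0, n, 2)
  for (r in 1:2) {
    P <- outer(xs[, r], ys[, r], psi)     # m x n kernel matrix
    v10[, r] <- rowMeans(P)
    v01[, r] <- colMeans(P)
  }
  theta <- colMeans(v10)
  s10 <- stats::cov(v10)
  s01 <- stats::cov(v01)
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- theta[1] - theta[2]
  if (var_delta <= 0) {
    z <- if (abs(delta) < .Machine$double.eps^0.5) 0 else Inf * sign(delta)
  } else {
    z <- delta / sqrt(var_delta)
  }
  p <- if (is.finite(z)) 2 * pnorm(-abs(z)) else 0
  if (z == 0) p <- 1
  list(auc_a = unname(theta[1]), auc_b = unname(theta[2]),
       delta = unname(delta), var_delta = unname(var_delta),
       z = unname(z), p = p)
}

#' Compare two model reports class by class
#'
#' Applies [delong_test()] to the pooled out-of-fold scores of two reports
#' built on the same subjects (per class one-vs-rest for the multiclass
#' task, single comparison for the binary task).
#'
#' @param report_a,report_b `osa_model_report` objects on the same subjects
#'   and task.
#' @return data.frame with columns `class`, `delta_auroc`, `p_raw`.
#' @export
compare_models <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "osa_model_report"),
            inherits(report_b, "osa_model_report"))
  if (!identical(report_a$ids, report_b$ids) ||
      !identical(as.character(report_a$y), as.character(report_b$y)))
    stop("reports were not built from the same subjects")
  if (report_a$spec$task != report_b$spec$task)
    stop("reports have different tasks")
  classes <- if (report_a$spec$task == "binary") binary_levels[2]
    else levels(report_a$y)
  rows <- lapply(classes, function(cl) {
    dl <- delong_test(report_a$scores[, cl], report_b$scores[, cl],
                      report_a$y == cl)
    data.frame(class = if (report_a$spec$task == "binary") "binary" else cl,
               delta_auroc = dl$delta, p_raw = dl$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' All pairwise model comparisons with multiplicity correction
#'
#' Runs [compare_models()] for every pair of reports and applies
#' Benjamini-Hochberg correction across the whole comparison family.
#'
#' @param reports named list of `osa_model_report` objects on the same
#'   subjects and task (e.g. the three feature-set models).
#' @return data.frame with columns `model_a`, `model_b`, `class`,
#'   `delta_auroc`, `p_raw`, `p_corrected`.
#' @export
pairwise_model_comparisons <- function(reports) {
  stopifnot(length(reports) >= 2)
  nm <- names(reports)
  if (is.null(nm)) nm <- paste0("model", seq_along(reports))
  pairs <- utils::combn(seq_along(reports), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    cmp <- compare_models(reports[[a]], reports[[b]])
    cbind(data.frame(model_a = nm[a], model_b = nm[b],
                     stringsAsFactors = FALSE), cmp)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- stats::p.adjust(out$p_raw, method = "BH")
  out
}
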
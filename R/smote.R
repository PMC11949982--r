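#' SMOTE oversampling of minority classes
#'
#' Brings every class up to the size of the majority class by synthesising
#' new rows on the segments between minority-class rows and their k nearest
#' same-class neighbours (Euclidean distance on standardised features; the
#' synthetic point is a uniform random point on the segment, generated in
#' the original feature space).
#'
#' @param X numeric data.frame or matrix of features (rows = samples).
#' @param y class labels (factor or coercible).
#' @param k number of nearest neighbours; reduced with a warning for
#'   classes with fewer than `k + 1` members.
#' @return list with `X` (original rows first, then synthetic rows), `y`,
#'   and `synthetic` (logical flag per row of the output).
#' @export
smote_oversample <- function(X, y, k = 5) {
  X <- as.data.frame(X)
  y <- factor(y)
  stopifnot(nrow(X) == length(y))
  counts <- table(y)
  n_maj <- max(counts)
  mu <- vapply(X, mean, 0)
  sig <- vapply(X, sd, 0)
  sig[sig == 0 | !is.finite(sig)] <- 1
  Z <- sweep(sweep(as.matrix(X), 2, mu), 2, sig, "/")
  synth_X <- list()
  synth_y <- list()
  for (cl in names(counts)) {
    n_new <- n_maj - counts[[cl]]
    if (n_new == 0) next
    idx <- which(y == cl)
    n_c <- length(idx)
    if (n_c == 1) {
      warning("class '", cl, "' has a single member; duplicating it")
      synth_X[[cl]] <- X[rep(idx, n_new), , drop = FALSE]
      synth_y[[cl]] <- rep(cl, n_new)
      next
    }
    k_eff <- k
    if (n_c < k + 1) {
      k_eff <- n_c - 1
      warning("class '", cl, "' has ", n_c,
              " members; reducing k to ", k_eff)
    }
    D <- as.matrix(dist(Z[idx, , drop = FALSE]))
    diag(D) <- Inf
    nn <- apply(D, 1, function(row) order(row)[seq_len(k_eff)])
    nn <- matrix(nn, nrow = k_eff)            # k_eff x n_c
    base <- sample.int(n_c, n_new, replace = TRUE)
    pick <- vapply(base, function(b) nn[sample.int(k_eff, 1), b], 0L)
    u <- runif(n_new)
    A <- as.matrix(X[idx[base], , drop = FALSE])
    B <- as.matrix(X[idx[pick], , drop = FALSE])
    S <- A + u * (B - A)
    synth_X[[cl]] <- as.data.frame(S)
    synth_y[[cl]] <- rep(cl, n_new)
  }
  if (length(synth_X)) {
    Xs <- do.call(rbind, synth_X)
    names(Xs) <- names(X)
    X_out <- rbind(X, Xs)
    y_out <- factor(c(as.character(y), unlist(synth_y)),
                    levels = levels(y))
    syn <- c(rep(FALSE, length(y)), rep(TRUE, nrow(Xs)))
  } else {
    X_out <- X
    y_out <- y
    syn <- rep(FALSE, length(y))
  }
  rownames(X_out) <- NULL
  list(X = X_out, y = y_out, synthetic = syn)
}
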
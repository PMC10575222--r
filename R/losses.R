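#' Loss term weights
#'
#' Weights of the composite training objective
#' `Loss = L_class + alpha * L_domain + beta * L_domain_class + gamma * L_dist`.
#' The experimental setting for the full network is `alpha = beta = gamma = 1`.
#'
#' @param alpha weight of the domain classification loss (head `h3`).
#' @param beta weight of the joint domain-class loss (head `h1`).
#' @param gamma weight of the shared-feature alignment loss.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(alpha = 1, beta = 1, gamma = 1) {
  w <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(w)) || any(w < 0)) {
    abort("Loss weights must be finite and nonnegative.")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "loss_weights")
}

#' Cosine alignment loss between shared features
#'
#' The distribution-alignment term on the shared subspace: the cosine
#' distance `1 - (a . b) / (||a|| ||b||)` between the shared feature vectors
#' of a paired source and target sample, averaged over pairs when matrices
#' are given. Range \[0, 2\]: 0 for parallel, 1 for orthogonal, 2 for
#' anti-parallel vectors. Scale-invariant and symmetric.
#'
#' @param fn_source,fn_target numeric vectors, or matrices with one pair per
#'   row.
#' @return Mean cosine distance (single nonnegative number).
#' @export
alignment_loss <- function(fn_source, fn_target) {
  a <- if (is.null(dim(fn_source))) matrix(fn_source, 1L) else fn_source
  b <- if (is.null(dim(fn_target))) matrix(fn_target, 1L) else fn_target
  if (ncol(a) != ncol(b) || nrow(a) != nrow(b)) {
    abort("Paired feature inputs must have matching dimensions.")
  }
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  if (any(na == 0) || any(nb == 0)) {
    abort("Zero-norm feature vector in alignment loss.",
          class = "adfs_degenerate_error")
  }
  mean(1 - rowSums(a * b) / (na * nb))
}

# Gradient of the mean pairwise cosine distance w.r.t. both feature
# matrices. Returned gradients have the shape of the inputs.
alignment_loss_grad <- function(a, b) {
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  dot <- rowSums(a * b)
  n <- nrow(a)
  da <- -(b / (na * nb) - a * (dot / (na^3 * nb))) / n
  db <- -(a / (na * nb) - b * (dot / (nb^3 * na))) / n
  list(da = da, db = db)
}

#' Cross-entropy between a one-hot label and a probability vector
#'
#' `-sum(y * log(p))` with probabilities clamped to `[1e-12, 1]` before the
#' log so a degenerate head cannot produce `-Inf`. Zero exactly when all
#' probability mass sits on the true class.
#'
#' @param y_onehot 0/1 vector with exactly one 1 (one-hot true label), or a
#'   matrix of such rows.
#' @param p probability vector summing to 1 (or matrix of rows); same length
#'   as `y_onehot`.
#' @return Nonnegative scalar (mean over rows for matrix input).
#' @export
cross_entropy <- function(y_onehot, p) {
  y <- if (is.null(dim(y_onehot))) matrix(y_onehot, 1L) else y_onehot
  pm <- if (is.null(dim(p))) matrix(p, 1L) else p
  if (!all(dim(y) == dim(pm))) abort("Label and probability shapes differ.",
                                     class = "adfs_label_error")
  if (any(y != 0 & y != 1) || any(rowSums(y) != 1)) {
    abort("`y_onehot` rows must be one-hot (exactly one 1).",
          class = "adfs_label_error")
  }
  pc <- pmin(pmax(pm, 1e-12), 1)
  mean(-rowSums(y * log(pc)))
}

#' Composite training objective
#'
#' Combines the four loss components into the weighted total
#' `L_class + alpha * L_domain + beta * L_domain_class + gamma * L_dist`,
#' retaining the breakdown for logging.
#'
#' @param l_class class cross-entropy (head `h2`, labeled samples).
#' @param l_domain domain cross-entropy (head `h3`, all samples).
#' @param l_domain_class joint domain-class cross-entropy (head `h1`,
#'   labeled samples).
#' @param l_dist shared-feature alignment loss over sample pairs.
#' @param weights a [loss_weights()].
#' @return A `loss_breakdown` list with the four components and `total`.
#' @export
total_loss <- function(l_class, l_domain, l_domain_class, l_dist,
                       weights = loss_weights()) {
  comps <- c(l_class, l_domain, l_domain_class, l_dist)
  if (any(!is.finite(comps))) {
    nm <- c("l_class", "l_domain", "l_domain_class", "l_dist")
    abort(sprintf("Non-finite loss component: %s",
                  nm[which(!is.finite(comps))[1]]),
          class = "adfs_numeric_error")
  }
  structure(list(
    l_class = l_class, l_domain = l_domain, l_domain_class = l_domain_class,
    l_dist = l_dist,
    total = l_class + weights$alpha * l_domain +
      weights$beta * l_domain_class + weights$gamma * l_dist
  ), class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<loss: class %.4f + domain %.4f + domain-class %.4f + dist %.4f -> total %.4f>\n",
    x$l_class, x$l_domain, x$l_domain_class, x$l_dist, x$total))
  invisible(x)
}

one_hot <- function(idx, k) {
  y <- matrix(0, length(idx), k)
  y[cbind(seq_along(idx), idx + 1L)] <- 1
  y
}
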
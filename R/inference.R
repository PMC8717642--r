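# Walk aggregation over the edge tensor, entity-pair classification, and the
# training losses (cross-entropy plus a differentiable soft F-measure).

#' One walk-aggregation step
#'
#' Combines all length-l paths through a shared intermediate node into
#' length-2l path representations.  Two segments are combined as
#' \eqn{f(v_{ik}, v_{kj}) = \sigma(v_{ik} \odot (W v_{kj}))} (elementwise
#' sigmoid and product), and aggregated with a linear interpolation that
#' keeps part of the shorter paths:
#' \eqn{v_{ij}^{(2l)} = \alpha v_{ij}^{(l)} + (1-\alpha) \sum_{k \ne i,j}
#' f(v_{ik}^{(l)}, v_{kj}^{(l)})}.  The result is re-symmetrized by
#' averaging the (i, j) and (j, i) entries, preserving the undirected-graph
#' contract.  With `alpha = 1` the step is the identity; on a 2-node graph
#' the sum is empty and the result is `alpha * V`.
#'
#' @param V numeric array `N x N x d`: the node-pair edge tensor at path
#'   length l (symmetric in the pair index; zero vectors mean "no path").
#' @param W numeric `d x d` combination matrix.
#' @param alpha interpolation scalar in `[0, 1]`.
#' @return the `N x N x d` tensor at path length 2l.
#' @export
walk_step <- function(V, W, alpha) {
  stopifnot(length(dim(V)) == 3L, dim(V)[1L] == dim(V)[2L],
            nrow(W) == dim(V)[3L], ncol(W) == dim(V)[3L],
            alpha >= 0, alpha <= 1)
  N <- dim(V)[1L]; d <- dim(V)[3L]
  Vm <- V; dim(Vm) <- c(N * N, d)
  M2 <- Vm %*% t(W); dim(M2) <- c(N, N, d)
  .walk_forward(V, M2, alpha, .walk_mask4(N, d))$out
}

#' Iterated walk aggregation
#'
#' Applies [walk_step()] `log2(final_length)` times, doubling the path
#' length from 1 up to `final_length`.
#'
#' @param V1 initial `N x N x d` edge tensor (path length 1).
#' @param W combination matrix.
#' @param alpha interpolation scalar.
#' @param final_length target path length; a power of 2, at least 2.
#' @return the edge tensor at path length `final_length`.
#' @export
aggregate_walks <- function(V1, W, alpha, final_length = 4L) {
  steps <- log2(final_length)
  if (final_length < 2 || steps != round(steps)) {
    stop("final_length must be a power of 2, >= 2")
  }
  V <- V1
  for (s in seq_len(steps)) V <- walk_step(V, W, alpha)
  V
}

# ad versions used in training
.aggregate_forward <- function(V1, W, alpha, final_length) {
  steps <- as.integer(log2(final_length))
  V <- V1
  for (s in seq_len(steps)) V <- ad_walk_step(V, W, alpha)
  V
}

#' Classify entity pairs from the aggregated edge tensor
#'
#' Reads each candidate pair's representation from the entity-node pair
#' entry of the aggregated tensor and applies a linear map followed by a
#' softmax over the label set.
#'
#' @param VL aggregated `N x N x d` tensor.
#' @param pairs integer matrix with two columns of node indices (entity
#'   nodes), one row per candidate pair.
#' @param W_cls classifier weights, `n_labels x d`.
#' @param b_cls classifier bias, length `n_labels`.
#' @return matrix of class probabilities, one row per pair (rows sum to 1).
#' @export
classify_pairs <- function(VL, pairs, W_cls, b_cls) {
  N <- dim(VL)[1L]
  if (any(pairs < 1L | pairs > N)) stop("pair index outside the graph")
  P <- matrix(0, nrow(pairs), dim(VL)[3L])
  for (r in seq_len(nrow(pairs))) P[r, ] <- VL[pairs[r, 1L], pairs[r, 2L], ]
  logits <- sweep(P %*% t(W_cls), 2L, b_cls, "+")
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

#' Soft F-measure loss
#'
#' Differentiable surrogate of the F1 score on the positive class:
#' \deqn{1 - \frac{2 \sum_i p_i y_i}{\sum_i p_i + \sum_i y_i + \beta}}
#' where p are predicted positive probabilities and y the 0/1 gold labels.
#' The loss lies in `[0, 1]`; it tends to 0 for a perfect hard prediction
#' and to 1 when predictions and gold are disjoint.
#'
#' @param prob_positive numeric vector of predicted positive probabilities.
#' @param gold_binary 0/1 vector of the same length.
#' @param beta smoothing constant.
#' @return scalar loss.
#' @export
soft_f_loss <- function(prob_positive, gold_binary, beta = 1e-8) {
  if (length(prob_positive) != length(gold_binary)) {
    stop("length mismatch between predictions and gold")
  }
  1 - 2 * sum(prob_positive * gold_binary) /
    (sum(prob_positive) + sum(gold_binary) + beta)
}

#' Combined training loss
#'
#' Convex combination of the mean cross-entropy over all candidate pairs and
#' the soft F-measure loss, the latter computed one-vs-rest for every
#' non-null label and averaged.
#'
#' @param probs probability matrix (pairs x labels), columns in `label_set`
#'   order.
#' @param gold character vector of gold labels per pair.
#' @param label_set label set whose first element is the null label.
#' @param lambda_ce weight of the cross-entropy term, in `[0, 1]`.
#' @param beta soft-F smoothing constant.
#' @return scalar loss.
#' @export
total_loss <- function(probs, gold, label_set, lambda_ce = 0.7, beta = 1e-8) {
  stopifnot(lambda_ce >= 0, lambda_ce <= 1)
  gi <- match(gold, label_set)
  ce <- -mean(log(pmax(probs[cbind(seq_along(gi), gi)], 1e-300)))
  pos_labels <- label_set[-1L]
  sf <- vapply(pos_labels, function(lb) {
    soft_f_loss(probs[, match(lb, label_set)], as.numeric(gold == lb), beta)
  }, 0)
  lambda_ce * ce + (1 - lambda_ce) * mean(sf)
}

# ad version of the combined loss; logits is a (pairs x labels) node
.loss_forward <- function(logits, gold_idx, n_labels, lambda_ce, beta) {
  probs <- ad_softmax_rows(logits)
  ce <- ad_smul(ad_sum(ad_log(ad_pick(probs, gold_idx))),
                -1 / length(gold_idx))
  sfs <- list()
  for (lb in 2:n_labels) {
    y <- as.numeric(gold_idx == lb)
    p <- ad_col(probs, lb)
    num <- ad_smul(ad_dot(p, ad_const(y)), 2)
    den <- ad_add(ad_sum(p), ad_const(sum(y) + beta))
    sfs[[length(sfs) + 1L]] <- ad_sub(ad_const(1), ad_div(num, den))
  }
  sf <- ad_smul(ad_concat(sfs), 1 / length(sfs))
  list(loss = ad_add(ad_smul(ce, lambda_ce),
                     ad_smul(ad_sum(sf), 1 - lambda_ce)),
       probs = probs)
}
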
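# Reverse-mode automatic differentiation on dense numeric values.
#
# Nodes are environments carrying a value, an accumulated gradient, links to
# parent nodes and a backward function.  Creation order gives a topological
# order (each node's id exceeds its parents'), so backward passes collect the
# reachable subgraph and replay it in decreasing id order.  Values are plain
# numeric vectors, matrices or 3-d arrays; gradients always match the value's
# shape.  Hot spots of the model (walk aggregation, masked softmax,
# softmax/cross-entropy) are fused single ops with hand-derived gradients.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L
.ad$pass <- 0L

ad_node <- function(val, parents = NULL, bw = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$bw <- bw
  n$requires <- TRUE
  .ad$counter <- .ad$counter + 1L
  n$id <- .ad$counter
  n
}

ad_param <- function(val) ad_node(val)

ad_const <- function(val) {
  n <- ad_node(val)
  n$requires <- FALSE
  n
}

is_ad <- function(x) is.environment(x) && !is.null(x$id)

ad_wrap <- function(x) if (is_ad(x)) x else ad_const(x)

push_grad <- function(n, g) {
  if (!n$requires) return(invisible(NULL))
  n$grad <- if (is.null(n$grad)) g else n$grad + g
  invisible(NULL)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Backward pass from a scalar (or given seed gradient) root.
ad_backward <- function(root, grad = NULL) {
  if (is.null(grad)) {
    grad <- root$val
    grad[] <- 1
  }
  root$grad <- grad
  .ad$pass <- .ad$pass + 1L
  tok <- .ad$pass
  nodes <- vector("list", 512L)
  cnt <- 0L
  queue <- vector("list", 512L)
  qh <- 1L; qt <- 1L
  queue[[1L]] <- root
  root$seen <- tok
  while (qh <= qt) {
    nd <- queue[[qh]]; qh <- qh + 1L
    cnt <- cnt + 1L
    if (cnt > length(nodes)) length(nodes) <- 2L * length(nodes)
    nodes[[cnt]] <- nd
    for (p in nd$parents) {
      if (!is.null(p$bw) && !identical(p$seen, tok)) {
        p$seen <- tok
        qt <- qt + 1L
        if (qt > length(queue)) length(queue) <- 2L * length(queue)
        queue[[qt]] <- p
      }
    }
  }
  nodes <- nodes[seq_len(cnt)]
  ids <- vapply(nodes, function(n) n$id, 0L)
  for (i in order(ids, decreasing = TRUE)) {
    nd <- nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd)
  }
  invisible(NULL)
}

# ---- elementwise and linear ops ---------------------------------------------

ad_add <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_node(a$val + b$val, list(a, b), function(n) {
    push_grad(n$parents[[1L]], n$grad)
    push_grad(n$parents[[2L]], n$grad)
  })
}

ad_sub <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_node(a$val - b$val, list(a, b), function(n) {
    push_grad(n$parents[[1L]], n$grad)
    push_grad(n$parents[[2L]], -n$grad)
  })
}

ad_mul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_node(a$val * b$val, list(a, b), function(n) {
    push_grad(n$parents[[1L]], n$grad * n$parents[[2L]]$val)
    push_grad(n$parents[[2L]], n$grad * n$parents[[1L]]$val)
  })
}

ad_div <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_node(a$val / b$val, list(a, b), function(n) {
    push_grad(n$parents[[1L]], n$grad / n$parents[[2L]]$val)
    push_grad(n$parents[[2L]],
              -n$grad * n$parents[[1L]]$val / n$parents[[2L]]$val^2)
  })
}

# scale by a fixed numeric scalar
ad_smul <- function(a, s) {
  ad_node(a$val * s, list(a), function(n) push_grad(n$parents[[1L]], n$grad * s))
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$val))
  n <- ad_node(v, list(a), function(n) {
    push_grad(n$parents[[1L]], n$grad * n$val * (1 - n$val))
  })
  n
}

ad_tanh <- function(a) {
  v <- tanh(a$val)
  ad_node(v, list(a), function(n) {
    push_grad(n$parents[[1L]], n$grad * (1 - n$val^2))
  })
}

ad_lrelu <- function(a, slope = 0.2) {
  v <- ifelse(a$val > 0, a$val, slope * a$val)
  ad_node(v, list(a), function(n) {
    push_grad(n$parents[[1L]], n$grad * ifelse(n$parents[[1L]]$val > 0, 1, slope))
  })
}

ad_abs <- function(a) {
  ad_node(abs(a$val), list(a), function(n) {
    push_grad(n$parents[[1L]], n$grad * sign(n$parents[[1L]]$val))
  })
}

ad_log <- function(a) {
  ad_node(log(a$val), list(a), function(n) {
    push_grad(n$parents[[1L]], n$grad / n$parents[[1L]]$val)
  })
}

ad_sum <- function(a) {
  ad_node(sum(a$val), list(a), function(n) {
    g <- n$parents[[1L]]$val
    g[] <- n$grad
    push_grad(n$parents[[1L]], g)
  })
}

ad_mean <- function(a) {
  k <- length(a$val)
  ad_node(sum(a$val) / k, list(a), function(n) {
    g <- n$parents[[1L]]$val
    g[] <- n$grad / k
    push_grad(n$parents[[1L]], g)
  })
}

ad_dot <- function(a, b) {
  ad_node(sum(a$val * b$val), list(a, b), function(n) {
    push_grad(n$parents[[1L]], n$grad * n$parents[[2L]]$val)
    push_grad(n$parents[[2L]], n$grad * n$parents[[1L]]$val)
  })
}

ad_matmul <- function(A, B) {
  ad_node(A$val %*% B$val, list(A, B), function(n) {
    push_grad(n$parents[[1L]], n$grad %*% t(n$parents[[2L]]$val))
    push_grad(n$parents[[2L]], t(n$parents[[1L]]$val) %*% n$grad)
  })
}

# matrix %*% vector -> vector
ad_matvec <- function(A, x) {
  ad_node(as.vector(A$val %*% x$val), list(A, x), function(n) {
    push_grad(n$parents[[1L]], outer(n$grad, n$parents[[2L]]$val))
    push_grad(n$parents[[2L]], as.vector(crossprod(n$parents[[1L]]$val, n$grad)))
  })
}

# t(M) %*% x -> vector
ad_tmatvec <- function(M, x) {
  ad_node(as.vector(crossprod(M$val, x$val)), list(M, x), function(n) {
    push_grad(n$parents[[1L]], outer(n$parents[[2L]]$val, n$grad))
    push_grad(n$parents[[2L]], as.vector(n$parents[[1L]]$val %*% n$grad))
  })
}

# add a row vector to every row of a matrix
ad_addvec <- function(M, v) {
  ad_node(sweep(M$val, 2L, v$val, "+"), list(M, v), function(n) {
    push_grad(n$parents[[1L]], n$grad)
    push_grad(n$parents[[2L]], colSums(n$grad))
  })
}

# ---- structural ops ---------------------------------------------------------

# concatenate vector nodes
ad_concat <- function(nodes) {
  lens <- vapply(nodes, function(n) length(n$val), 0L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  ad_node(unlist(lapply(nodes, function(n) n$val), use.names = FALSE),
          nodes, function(n) {
    for (i in seq_along(n$parents)) {
      push_grad(n$parents[[i]], n$grad[starts[i]:ends[i]])
    }
  })
}

# stack vector nodes as rows of a matrix
ad_rbind <- function(nodes) {
  ad_node(do.call(rbind, lapply(nodes, function(n) n$val)),
          nodes, function(n) {
    for (i in seq_along(n$parents)) push_grad(n$parents[[i]], n$grad[i, ])
  })
}

# select rows of a matrix (embedding lookup); idx may repeat
ad_rows <- function(M, idx) {
  ad_node(M$val[idx, , drop = FALSE], list(M), function(n) {
    p <- n$parents[[1L]]
    if (!p$requires) return(invisible(NULL))
    g <- matrix(0, nrow(p$val), ncol(p$val))
    for (r in seq_along(idx)) g[idx[r], ] <- g[idx[r], ] + n$grad[r, ]
    push_grad(p, g)
  })
}

# single row of a matrix as a vector
ad_row <- function(M, i) {
  ad_node(M$val[i, ], list(M), function(n) {
    p <- n$parents[[1L]]
    if (!p$requires) return(invisible(NULL))
    g <- matrix(0, nrow(p$val), ncol(p$val))
    g[i, ] <- n$grad
    push_grad(p, g)
  })
}

# mean of selected rows of a matrix -> vector
ad_row_mean <- function(M, idx) {
  k <- length(idx)
  ad_node(colSums(M$val[idx, , drop = FALSE]) / k, list(M), function(n) {
    p <- n$parents[[1L]]
    if (!p$requires) return(invisible(NULL))
    g <- matrix(0, nrow(p$val), ncol(p$val))
    gi <- n$grad / k
    for (r in idx) g[r, ] <- g[r, ] + gi
    push_grad(p, g)
  })
}

# elementwise mean of a list of vector nodes
ad_mean_list <- function(nodes) {
  k <- length(nodes)
  v <- nodes[[1L]]$val
  if (k > 1L) for (i in 2:k) v <- v + nodes[[i]]$val
  ad_node(v / k, nodes, function(n) {
    g <- n$grad / k
    for (p in n$parents) push_grad(p, g)
  })
}

# mean of matrix rows -> vector (used for pooling RNN states)
ad_colmeans <- function(M) {
  k <- nrow(M$val)
  ad_node(colSums(M$val) / k, list(M), function(n) {
    p <- n$parents[[1L]]
    g <- matrix(rep(n$grad / k, each = nrow(p$val)), nrow(p$val))
    push_grad(p, g)
  })
}

# ---- fused ops --------------------------------------------------------------

# softmax of a vector restricted to `support` (logical); off-support weights 0
ad_masked_softmax <- function(logits, support) {
  x <- logits$val[support]
  x <- x - max(x)
  e <- exp(x)
  w <- numeric(length(logits$val))
  w[support] <- e / sum(e)
  n <- ad_node(w, list(logits), function(n) {
    ws <- n$val[support]
    gs <- n$grad[support]
    d <- numeric(length(n$val))
    d[support] <- ws * (gs - sum(gs * ws))
    push_grad(n$parents[[1L]], d)
  })
  n
}

# row-wise softmax of a matrix
ad_softmax_rows <- function(M) {
  x <- M$val - apply(M$val, 1L, max)
  e <- exp(x)
  v <- e / rowSums(e)
  ad_node(v, list(M), function(n) {
    s <- rowSums(n$grad * n$val)
    push_grad(n$parents[[1L]], n$val * (n$grad - s))
  })
}

# pick one entry per row: out[i] = M[i, idx[i]]
ad_pick <- function(M, idx) {
  r <- seq_along(idx)
  ad_node(M$val[cbind(r, idx)], list(M), function(n) {
    p <- n$parents[[1L]]
    g <- matrix(0, nrow(p$val), ncol(p$val))
    g[cbind(r, idx)] <- n$grad
    push_grad(p, g)
  })
}

# column of a matrix as a vector
ad_col <- function(M, j) {
  ad_node(M$val[, j], list(M), function(n) {
    p <- n$parents[[1L]]
    g <- matrix(0, nrow(p$val), ncol(p$val))
    g[, j] <- n$grad
    push_grad(p, g)
  })
}

# Scatter per-edge-type transformed representations into the symmetric
# node-pair tensor V (N x N x d).  `mats` is a list of matrix nodes (rows =
# edges of that type), `idx` a parallel list of 2-column index matrices.
ad_scatter_pairs <- function(mats, idx, n_nodes, d) {
  V <- array(0, c(n_nodes, n_nodes, d))
  for (t in seq_along(mats)) {
    m <- mats[[t]]$val
    ij <- idx[[t]]
    for (r in seq_len(nrow(ij))) {
      i <- ij[r, 1L]; j <- ij[r, 2L]
      V[i, j, ] <- V[i, j, ] + m[r, ]
      V[j, i, ] <- V[j, i, ] + m[r, ]
    }
  }
  n <- ad_node(V, mats, function(n) {
    for (t in seq_along(n$parents)) {
      ij <- idx[[t]]
      g <- matrix(0, nrow(ij), d)
      for (r in seq_len(nrow(ij))) {
        g[r, ] <- n$grad[ij[r, 1L], ij[r, 2L], ] + n$grad[ij[r, 2L], ij[r, 1L], ]
      }
      push_grad(n$parents[[t]], g)
    }
  })
  n
}

# gather node-pair vectors: out[p, ] = V[ij[p,1], ij[p,2], ]
ad_gather_pairs <- function(V, ij) {
  d <- dim(V$val)[3L]
  out <- matrix(0, nrow(ij), d)
  for (r in seq_len(nrow(ij))) out[r, ] <- V$val[ij[r, 1L], ij[r, 2L], ]
  ad_node(out, list(V), function(n) {
    p <- n$parents[[1L]]
    g <- array(0, dim(p$val))
    for (r in seq_len(nrow(ij))) {
      g[ij[r, 1L], ij[r, 2L], ] <- g[ij[r, 1L], ij[r, 2L], ] + n$grad[r, ]
    }
    push_grad(p, g)
  })
}

# One walk-aggregation step (doubling path length), fused.
# V: N x N x d array node; W: d x d matrix node; alpha in [0,1] (numeric or
# scalar node).  Forward/backward share .walk_forward(), also used by the
# public numeric walk_step().
.walk_forward <- function(V, M2, alpha, mask4) {
  N <- dim(V)[1L]; d <- dim(V)[3L]
  A1 <- aperm(array(V, c(N, N, d, N)), c(1L, 2L, 4L, 3L))      # [i,k,j,c]
  A2 <- aperm(array(M2, c(N, N, d, N)), c(4L, 1L, 2L, 3L))     # [i,k,j,c]
  Sig <- (1 / (1 + exp(-(A1 * A2)))) * mask4
  S <- colSums(aperm(Sig, c(2L, 1L, 3L, 4L)), dims = 1L)       # sum over k
  F <- S
  out <- alpha * V + (1 - alpha) * F
  out <- (out + aperm(out, c(2L, 1L, 3L))) / 2
  list(out = out, Sig = Sig, F = F, A1 = A1, A2 = A2)
}

.walk_mask4 <- function(N, d) {
  m3 <- array(1, c(N, N, N))                                    # [i,k,j]
  for (k in seq_len(N)) {
    m3[k, k, ] <- 0
    m3[, k, k] <- 0
  }
  array(m3, c(N, N, N, d))
}

ad_walk_step <- function(V, W, alpha) {
  N <- dim(V$val)[1L]; d <- dim(V$val)[3L]
  alpha_node <- if (is_ad(alpha)) alpha else NULL
  a <- if (is.null(alpha_node)) alpha else alpha_node$val
  Vm <- V$val; dim(Vm) <- c(N * N, d)
  M2 <- Vm %*% t(W$val); dim(M2) <- c(N, N, d)
  mask4 <- .walk_mask4(N, d)
  fw <- .walk_forward(V$val, M2, a, mask4)
  parents <- c(list(V, W), if (!is.null(alpha_node)) list(alpha_node))
  n <- ad_node(fw$out, parents, function(n) {
    G <- (n$grad + aperm(n$grad, c(2L, 1L, 3L))) / 2
    dV <- a * G
    dF <- (1 - a) * G
    # broadcast dF over k: [i,j,c] -> [i,k,j,c]
    dFexp <- aperm(array(dF, c(N, N, d, N)), c(1L, 4L, 2L, 3L))
    # Sig is already masked: off support Sig = 0, so Sig - Sig^2 vanishes
    # there and equals sigmoid'(P) on the support.
    dP <- dFexp * (fw$Sig - fw$Sig^2)
    dA1 <- dP * fw$A2
    dA2 <- dP * fw$A1
    dV <- dV + colSums(aperm(dA1, c(3L, 1L, 2L, 4L)), dims = 1L)  # sum over j
    dM2 <- colSums(dA2, dims = 1L)                                 # sum over i
    dM2m <- dM2; dim(dM2m) <- c(N * N, d)
    Vm2 <- n$parents[[1L]]$val; dim(Vm2) <- c(N * N, d)
    dVm <- dM2m %*% W$val
    dim(dVm) <- c(N, N, d)
    push_grad(n$parents[[1L]], dV + dVm)
    push_grad(n$parents[[2L]], t(dM2m) %*% Vm2)
    if (!is.null(alpha_node)) {
      push_grad(n$parents[[3L]], sum(G * (n$parents[[1L]]$val - fw$F)))
    }
  })
  n
}
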
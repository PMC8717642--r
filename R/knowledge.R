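# External knowledge: triple stores, knowledge-graph embeddings (TransE,
# RESCAL, graph-attention) and entity-description embeddings (a simplified
# distributed-memory paragraph embedder, and an end-to-end recurrent
# description encoder).

#' Read a knowledge-graph triple store
#'
#' Three-column TAB-separated file `head<TAB>relation<TAB>tail`.
#'
#' @param path TSV path.
#' @return object of class `docrel_kg`: list with `triples` (data frame
#'   `head`, `relation`, `tail`), `entities` and `relations` (character
#'   index vectors).
#' @export
read_triples <- function(path) {
  t <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("head", "relation", "tail"),
                         colClasses = "character", quote = "")
  as_kg(t)
}

#' Build a `docrel_kg` from a triple data frame
#' @param triples data frame with columns `head`, `relation`, `tail`.
#' @return a `docrel_kg`.
#' @export
as_kg <- function(triples) {
  stopifnot(all(c("head", "relation", "tail") %in% names(triples)),
            all(nzchar(triples$head)), all(nzchar(triples$tail)),
            all(nzchar(triples$relation)))
  structure(list(triples = triples,
                 entities = sort(unique(c(triples$head, triples$tail))),
                 relations = sort(unique(triples$relation))),
            class = "docrel_kg")
}

#' @export
print.docrel_kg <- function(x, ...) {
  cat("<docrel_kg> ", nrow(x$triples), " triples, ", length(x$entities),
      " entities, ", length(x$relations), " relations\n", sep = "")
  invisible(x)
}

#' Write triples to TSV
#' @param kg a `docrel_kg`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_triples <- function(kg, path) {
  utils::write.table(kg$triples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read entity descriptions
#'
#' Two-column TAB-separated file `entity_id<TAB>description text`.
#'
#' @param path TSV path.
#' @return named character vector of descriptions keyed by entity id.
#' @export
read_descriptions <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("entity_id", "text"),
                         colClasses = "character", quote = "")
  stats::setNames(d$text, d$entity_id)
}

#' Read/write an embedding cache in word2vec text format
#'
#' First line `n dim`, then one line per key: `key v1 v2 ... vdim`.
#'
#' @param path file path.
#' @return for the reader, a numeric matrix with one named row per key.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1L], " ", fixed = TRUE)[[1L]])
  out <- matrix(0, hdr[1L], hdr[2L])
  keys <- character(hdr[1L])
  for (i in seq_len(hdr[1L])) {
    f <- strsplit(lines[i + 1L], " ", fixed = TRUE)[[1L]]
    keys[i] <- f[1L]
    out[i, ] <- as.numeric(f[-1L])
  }
  rownames(out) <- keys
  out
}

#' @rdname read_embeddings
#' @param embeddings a numeric matrix with named rows.
#' @export
write_embeddings <- function(embeddings, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(embeddings), ncol(embeddings)), con)
  for (i in seq_len(nrow(embeddings))) {
    writeLines(paste(rownames(embeddings)[i],
                     paste(format(embeddings[i, ], digits = 17, scientific = TRUE,
                                  trim = TRUE), collapse = " ")), con)
  }
  invisible(path)
}

# ---- TransE -----------------------------------------------------------------

#' Translation-distance score of a triple
#'
#' Under the translation hypothesis h + r = t for a true triple, the score is
#' the L2 distance \eqn{\|h + r - t\|_2}; lower means more plausible.  The
#' additive transitivity of translations lets a chain of relations compose:
#' if h1 + r1 = t1 and t1 + r2 = t2 then h1 + (r1 + r2) scores 0 against t2.
#'
#' @param h,r,t numeric vectors of equal length (head entity, relation, tail
#'   entity embeddings).
#' @return non-negative scalar distance.
#' @export
transe_score <- function(h, r, t) {
  if (length(h) != length(r) || length(r) != length(t)) {
    stop("dimension mismatch between h, r, t")
  }
  sqrt(sum((h + r - t)^2))
}

#' Margin loss of one positive/negative triple pair
#'
#' \eqn{\max(f_r(h,t) + \gamma - f_{r'}(h',t'), 0)} with the translation
#' distance as score; summed over a training set this is the max-margin
#' negative-sampling objective.
#'
#' @param pos,neg lists with elements `h`, `r`, `t` (numeric vectors).
#' @param gamma margin (default 1).
#' @return scalar loss term.
#' @export
transe_margin_loss <- function(pos, neg, gamma = 1) {
  max(transe_score(pos$h, pos$r, pos$t) + gamma -
        transe_score(neg$h, neg$r, neg$t), 0)
}

#' Train translation embeddings on a triple store
#'
#' Stochastic gradient descent on the max-margin negative-sampling objective.
#' Negatives corrupt the head or the tail (chosen uniformly) of a true triple
#' with a uniformly sampled entity; corruptions that land on another true
#' triple are rejected (filtered sampling).  Entity vectors are re-normalized
#' to unit L2 length at the start of every epoch.
#'
#' @param kg a `docrel_kg` with at least one triple.
#' @param dim embedding dimension.
#' @param gamma margin (default 1).
#' @param epochs number of passes over the triples.
#' @param lr SGD learning rate.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return object of class `docrel_kge`: list with `method = "transe"`,
#'   `entities` (matrix, named rows), `relations` (matrix, named rows),
#'   `dim`, and `loss` (per-epoch mean loss).
#' @export
train_transe <- function(kg, dim = 8, gamma = 1, epochs = 100, lr = 0.05,
                         seed = 1) {
  if (!inherits(kg, "docrel_kg")) kg <- as_kg(kg)
  if (!nrow(kg$triples)) stop("empty knowledge graph")
  set.seed(seed)
  ne <- length(kg$entities); nr <- length(kg$relations)
  E <- matrix(stats::runif(ne * dim, -6 / sqrt(dim), 6 / sqrt(dim)), ne, dim,
              dimnames = list(kg$entities, NULL))
  R <- matrix(stats::runif(nr * dim, -6 / sqrt(dim), 6 / sqrt(dim)), nr, dim,
              dimnames = list(kg$relations, NULL))
  R <- R / pmax(sqrt(rowSums(R^2)), 1e-12)
  hi <- match(kg$triples$head, kg$entities)
  ri <- match(kg$triples$relation, kg$relations)
  ti <- match(kg$triples$tail, kg$entities)
  true_key <- paste(hi, ri, ti)
  nt <- length(hi)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    E <- E / pmax(sqrt(rowSums(E^2)), 1e-12)
    tot <- 0
    for (b in sample.int(nt)) {
      h <- hi[b]; r <- ri[b]; t <- ti[b]
      # filtered corruption of head or tail
      hn <- h; tn <- t
      for (try in 1:20) {
        if (stats::runif(1) < 0.5) {
          hn <- sample.int(ne, 1L); tn <- t
        } else {
          hn <- h; tn <- sample.int(ne, 1L)
        }
        if (!(paste(hn, r, tn) %in% true_key)) break
      }
      dp <- E[h, ] + R[r, ] - E[t, ]
      dn <- E[hn, ] + R[r, ] - E[tn, ]
      fp <- sqrt(sum(dp^2)); fn_ <- sqrt(sum(dn^2))
      loss <- fp + gamma - fn_
      if (loss > 0) {
        gp <- dp / max(fp, 1e-12)
        gn <- dn / max(fn_, 1e-12)
        E[h, ] <- E[h, ] - lr * gp
        E[t, ] <- E[t, ] + lr * gp
        R[r, ] <- R[r, ] - lr * (gp - gn)
        E[hn, ] <- E[hn, ] + lr * gn
        E[tn, ] <- E[tn, ] - lr * gn
        tot <- tot + loss
      }
    }
    losses[ep] <- tot / nt
  }
  structure(list(method = "transe", entities = E, relations = R, dim = dim,
                 loss = losses),
            class = "docrel_kge")
}

#' @export
print.docrel_kge <- function(x, ...) {
  cat("<docrel_kge> method=", x$method, ", ", nrow(x$entities),
      " entities, dim=", ncol(x$entities), "\n", sep = "")
  invisible(x)
}

# ---- RESCAL -----------------------------------------------------------------

#' Bilinear relational score
#'
#' \eqn{f_r(h, t) = h^T M_r t}.
#'
#' @param h,t numeric vectors (entity factors).
#' @param M relation matrix, `length(h)` x `length(t)`.
#' @return scalar score.
#' @export
rescal_score <- function(h, M, t) {
  if (length(h) != nrow(M) || length(t) != ncol(M)) {
    stop("dimension mismatch between h, M, t")
  }
  as.numeric(h %*% M %*% t)
}

#' Factorize a relational tensor
#'
#' The triple store is encoded as a binary three-way tensor X with
#' X[i, j, k] = 1 iff (e_i, r_k, e_j) is a true triple.  Each frontal slice
#' is factorized as \eqn{X_k \approx A R_k A^T} by gradient descent on the
#' squared reconstruction loss
#' \eqn{f(A, R) = 1/2 \sum_{ijk} (X_{ijk} - a_i^T R_k a_j)^2}, with a
#' step-size safeguard that halves the learning rate (and rolls the step
#' back) whenever the loss would increase, so the recorded loss sequence is
#' non-increasing.  The entity factor rows of A are the knowledge-node
#' representations.
#'
#' @param kg a `docrel_kg`.
#' @param rank factor rank (must not exceed the number of entities).
#' @param epochs gradient steps.
#' @param lr initial learning rate.
#' @param seed integer seed.
#' @return object of class `docrel_kge` with `method = "rescal"`, `entities`
#'   (A, named rows), `relation_matrices` (named list of R_k), and `loss`
#'   (per-epoch loss, non-increasing).
#' @export
factorize_rescal <- function(kg, rank = 4, epochs = 300, lr = 0.01, seed = 1) {
  if (!inherits(kg, "docrel_kg")) kg <- as_kg(kg)
  if (rank < 1) stop("rank must be >= 1")
  ne <- length(kg$entities)
  if (rank > ne) stop("rank exceeds number of entities")
  set.seed(seed)
  nr <- length(kg$relations)
  X <- lapply(seq_len(nr), function(k) matrix(0, ne, ne))
  for (b in seq_len(nrow(kg$triples))) {
    i <- match(kg$triples$head[b], kg$entities)
    j <- match(kg$triples$tail[b], kg$entities)
    k <- match(kg$triples$relation[b], kg$relations)
    X[[k]][i, j] <- 1
  }
  A <- matrix(stats::rnorm(ne * rank, sd = 0.3), ne, rank,
              dimnames = list(kg$entities, NULL))
  Rk <- lapply(seq_len(nr), function(k) matrix(stats::rnorm(rank^2, sd = 0.3),
                                               rank, rank))
  loss_of <- function(A, Rk) {
    0.5 * sum(vapply(seq_len(nr), function(k) {
      sum((X[[k]] - A %*% Rk[[k]] %*% t(A))^2)
    }, 0))
  }
  losses <- numeric(epochs)
  cur <- loss_of(A, Rk)
  for (ep in seq_len(epochs)) {
    dA <- matrix(0, ne, rank)
    dR <- vector("list", nr)
    for (k in seq_len(nr)) {
      Ek <- X[[k]] - A %*% Rk[[k]] %*% t(A)
      dA <- dA - Ek %*% A %*% t(Rk[[k]]) - t(Ek) %*% A %*% Rk[[k]]
      dR[[k]] <- -t(A) %*% Ek %*% A
    }
    repeat {
      A2 <- A - lr * dA
      Rk2 <- lapply(seq_len(nr), function(k) Rk[[k]] - lr * dR[[k]])
      new <- loss_of(A2, Rk2)
      if (new <= cur || lr < 1e-10) break
      lr <- lr / 2
    }
    if (new <= cur) {
      A <- A2; Rk <- Rk2; cur <- new
    }
    losses[ep] <- cur
  }
  names(Rk) <- kg$relations
  structure(list(method = "rescal", entities = A, relation_matrices = Rk,
                 dim = rank, loss = losses),
            class = "docrel_kge")
}

#' Reconstruct the relational tensor from RESCAL factors
#' @param kge a `docrel_kge` with `method = "rescal"`.
#' @return list of reconstructed slices \eqn{A R_k A^T}, named by relation.
#' @export
rescal_reconstruct <- function(kge) {
  stopifnot(kge$method == "rescal")
  lapply(kge$relation_matrices, function(Rk) {
    kge$entities %*% Rk %*% t(kge$entities)
  })
}

# ---- graph attention --------------------------------------------------------

#' Initialize graph-attention encoder parameters for a knowledge graph
#'
#' One attention layer with a learnable entity feature table: features are
#' projected by W, attention logits over the neighborhood (self-loop
#' included) come from a LeakyReLU-scored concatenation, and the centre
#' representation is the attention-weighted neighbour aggregate.
#'
#' @param kg a `docrel_kg`.
#' @param dim output dimension.
#' @param seed integer seed.
#' @return list of numeric parameters (`features`, `W`, `attn`).
#' @export
gat_params <- function(kg, dim = 8, seed = 1) {
  set.seed(seed)
  ne <- length(kg$entities)
  list(features = matrix(stats::runif(ne * dim, -0.5, 0.5), ne, dim,
                         dimnames = list(kg$entities, NULL)),
       W = matrix(stats::rnorm(dim * dim, sd = 1 / sqrt(dim)), dim, dim),
       attn = stats::rnorm(2 * dim, sd = 1 / sqrt(dim)))
}

# neighbors of an entity within `radius` hops (undirected), excluding itself
.kg_neighborhood <- function(kg, entity_id, radius = 1L) {
  cur <- entity_id
  seen <- entity_id
  for (h in seq_len(radius)) {
    nb <- unique(c(kg$triples$tail[kg$triples$head %in% cur],
                   kg$triples$head[kg$triples$tail %in% cur]))
    nb <- setdiff(nb, seen)
    if (!length(nb)) break
    seen <- c(seen, nb)
    cur <- nb
  }
  setdiff(seen, entity_id)
}

# ad-graph forward of the single attention layer for one centre entity;
# params entries may be ad nodes (end-to-end) or plain numerics
.gat_forward <- function(kg, entity_id, radius, feat_node, W_node, a_node) {
  idx <- match(c(entity_id, .kg_neighborhood(kg, entity_id, radius)),
               rownames(feat_node$val))
  Hn <- ad_matmul(ad_rows(feat_node, idx), W_node)   # (1+n) x dim, row 1 = centre
  ctr <- ad_row(Hn, 1L)
  k <- length(idx)
  logits <- vector("list", k)
  for (i in seq_len(k)) {
    cat_i <- ad_concat(list(ctr, ad_row(Hn, i)))
    logits[[i]] <- ad_lrelu(ad_dot(a_node, cat_i), 0.2)
  }
  w <- ad_masked_softmax(ad_concat(logits), rep(TRUE, k))
  # attention-weighted aggregate tanh(sum_i w_i h_i)
  agg <- NULL
  d <- length(ctr$val)
  for (i in seq_len(k)) {
    term <- ad_mul(ad_rows_broadcast(w, i, d), ad_row(Hn, i))
    agg <- if (is.null(agg)) term else ad_add(agg, term)
  }
  ad_tanh(agg)
}

# broadcast scalar element i of vector node w to a vector of length d
ad_rows_broadcast <- function(w, i, d) {
  ad_node(rep(w$val[i], d), list(w), function(n) {
    p <- n$parents[[1L]]
    g <- numeric(length(p$val))
    g[i] <- sum(n$grad)
    push_grad(p, g)
  })
}

#' Graph-attention embedding of a knowledge-graph entity
#'
#' Runs the attention layer over the radius-hop neighborhood subgraph
#' centred on the entity (self-loop included) and returns the centre node's
#' representation.  Deterministic given the parameters.
#'
#' @param kg a `docrel_kg`.
#' @param entity_id entity to embed (must be in the graph).
#' @param radius neighborhood radius in hops (default 1).
#' @param params parameters from [gat_params()].
#' @return numeric vector of length `dim`.
#' @export
gat_embed <- function(kg, entity_id, radius = 1L, params) {
  if (!entity_id %in% kg$entities) stop("unknown entity '", entity_id, "'")
  node <- .gat_forward(kg, entity_id, radius,
                       ad_const(params$features), ad_const(params$W),
                       ad_const(params$attn))
  node$val
}

# ---- description embeddings -------------------------------------------------

.desc_tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9_']+")[[1L]]
  toks[nzchar(toks)]
}

#' Paragraph embeddings for entity descriptions
#'
#' A simplified distributed-memory paragraph embedder: each description gets
#' a learnable vector that is averaged with the context word vectors to
#' predict the centre word through a softmax over the description vocabulary,
#' trained by stochastic gradient descent.  Exact parity with any external
#' tool is not a goal; the output is a fixed-length vector per entity,
#' deterministic given the seed.
#'
#' @param descriptions named character vector (entity id -> description) as
#'   from [read_descriptions()].
#' @param dim embedding dimension.
#' @param epochs training passes.
#' @param window context half-width.
#' @param lr learning rate.
#' @param seed integer seed.
#' @return numeric matrix, one named row per entity.
#' @export
embed_description_doc2vec <- function(descriptions, dim = 8, epochs = 40,
                                      window = 2L, lr = 0.05, seed = 1) {
  if (any(!nzchar(descriptions))) stop("empty description")
  set.seed(seed)
  toks <- lapply(descriptions, .desc_tokenize)
  if (any(lengths(toks) == 0L)) stop("empty description")
  vocab <- sort(unique(unlist(toks)))
  nv <- length(vocab); nd <- length(descriptions)
  Wd <- matrix(stats::runif(nd * dim, -0.05, 0.05), nd, dim,
               dimnames = list(names(descriptions), NULL))
  Ww <- matrix(stats::runif(nv * dim, -0.05, 0.05), nv, dim)
  Wo <- matrix(stats::runif(nv * dim, -0.05, 0.05), nv, dim)
  for (ep in seq_len(epochs)) {
    for (d in sample.int(nd)) {
      ids <- match(toks[[d]], vocab)
      for (p in seq_along(ids)) {
        ctx <- ids[setdiff(max(1L, p - window):min(length(ids), p + window), p)]
        h <- Wd[d, ]
        if (length(ctx)) h <- (h + colSums(Ww[ctx, , drop = FALSE])) /
            (1 + length(ctx))
        z <- as.vector(Wo %*% h)
        z <- exp(z - max(z)); pr <- z / sum(z)
        gr <- pr; gr[ids[p]] <- gr[ids[p]] - 1
        gh <- as.vector(crossprod(Wo, gr))
        Wo <- Wo - lr * outer(gr, h)
        k <- 1 + length(ctx)
        Wd[d, ] <- Wd[d, ] - lr * gh / k
        if (length(ctx)) {
          for (c in ctx) Ww[c, ] <- Ww[c, ] - lr * gh / k
        }
      }
    }
  }
  Wd
}

#' Recurrent description encoder
#'
#' End-to-end description encoder: token embeddings feed a bidirectional
#' recurrent layer whose states are mean-pooled into a fixed-length vector.
#' When used as a knowledge provider inside [docrel()] its parameters are
#' trained jointly with the rest of the model (gradients flow through it);
#' this function runs the same network with the supplied parameters.
#'
#' @param description_tokens character vector of tokens (non-empty).
#' @param params parameters from [emb_params()].
#' @return numeric vector of length `2 * rnn_dim`.
#' @export
embed_description_emb <- function(description_tokens, params) {
  node <- .emb_forward(description_tokens, lapply(params, ad_const))
  node$val
}

#' Initialize description-encoder parameters
#'
#' @param vocab character vector of description tokens to support (an
#'   unknown-token row is added).
#' @param emb_dim token embedding dimension.
#' @param rnn_dim recurrent state size per direction.
#' @param seed integer seed.
#' @return named list of numeric parameters.
#' @export
emb_params <- function(vocab, emb_dim = 8, rnn_dim = 4, seed = 1) {
  set.seed(seed)
  vocab <- c("<unk>", vocab)
  E <- matrix(stats::runif(length(vocab) * emb_dim, -0.05, 0.05),
              length(vocab), emb_dim, dimnames = list(vocab, NULL))
  ru <- function(m, n) matrix(stats::runif(m * n, -0.5, 0.5) / sqrt(n), m, n)
  list(emb = E,
       Wxf = ru(rnn_dim, emb_dim), Uhf = ru(rnn_dim, rnn_dim),
       bf = numeric(rnn_dim),
       Wxb = ru(rnn_dim, emb_dim), Uhb = ru(rnn_dim, rnn_dim),
       bb = numeric(rnn_dim))
}

# ad forward of the description encoder; pnodes entries are ad nodes
.emb_forward <- function(tokens, pnodes) {
  if (!length(tokens)) stop("empty token list")
  idx <- match(tokens, rownames(pnodes$emb$val))
  idx[is.na(idx)] <- 1L
  X <- ad_rows(pnodes$emb, idx)
  H <- .birnn_forward(X, pnodes$Wxf, pnodes$Uhf, pnodes$bf,
                      pnodes$Wxb, pnodes$Uhb, pnodes$bb)
  ad_colmeans(H)
}

# shared bidirectional tanh recurrence: X (T x e) -> H (T x 2r)
.birnn_forward <- function(X, Wxf, Uhf, bf, Wxb, Uhb, bb) {
  T <- nrow(X$val)
  r <- length(bf$val)
  fwd <- vector("list", T); bwd <- vector("list", T)
  h <- ad_const(numeric(r))
  for (t in seq_len(T)) {
    h <- ad_tanh(ad_add(ad_add(ad_matvec(Wxf, ad_row(X, t)),
                               ad_matvec(Uhf, h)), bf))
    fwd[[t]] <- h
  }
  h <- ad_const(numeric(r))
  for (t in rev(seq_len(T))) {
    h <- ad_tanh(ad_add(ad_add(ad_matvec(Wxb, ad_row(X, t)),
                               ad_matvec(Uhb, h)), bb))
    bwd[[t]] <- h
  }
  ad_rbind(lapply(seq_len(T), function(t) ad_concat(list(fwd[[t]], bwd[[t]]))))
}
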
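# Model assembly: hyper-parameter control, parameter initialization, the
# per-document forward pass shared by training and prediction, and numeric
# inspection wrappers.

#' Control parameters for [docrel()]
#'
#' @param emb_dim word embedding dimension.
#' @param rnn_dim encoder state size per direction (`hidden_dim = 2 * rnn_dim`).
#' @param type_dim node-type embedding dimension.
#' @param dist_dim distance embedding dimension.
#' @param d_z common edge representation dimension.
#' @param kg_dim knowledge-graph embedding dimension.
#' @param desc_dim description embedding dimension (even).
#' @param alpha walk interpolation scalar in `[0, 1]`.
#' @param final_length walk path length (power of 2); `NULL` selects 4, or 8
#'   when a knowledge provider is enabled so knowledge-node content can reach
#'   the entity-pair entries.
#' @param lambda_ce weight of the cross-entropy term of the loss.
#' @param beta soft-F smoothing constant.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param clip global gradient-norm clip.
#' @param kg_provider knowledge-graph representation: `"none"`, `"transe"`,
#'   `"rescal"` (pre-trained, frozen) or `"gat"` (trained end-to-end).
#' @param desc_provider description representation: `"none"`, `"doc2vec"`
#'   (pre-trained, frozen) or `"emb"` (trained end-to-end).
#' @param encoder `"birnn"` or `"none"` (no recurrence; raw embeddings).
#' @param max_bucket largest power-of-two distance bucket index.
#' @param head_type,tail_type candidate-pair entity types (`NULL`: inferred
#'   from the gold annotations, falling back to all ordered pairs).
#' @param eval_every development-set evaluation period in epochs.
#' @param kg_epochs,desc_epochs pre-training epochs for frozen providers.
#' @param verbose print progress.
#' @return a list of class `docrel_control`.
#' @export
docrel_control <- function(emb_dim = 16, rnn_dim = 8, type_dim = 4,
                           dist_dim = 4, d_z = 16, kg_dim = 8, desc_dim = 8,
                           alpha = 0.8, final_length = NULL, lambda_ce = 0.7,
                           beta = 1e-8, lr = 0.01, epochs = 60, clip = 5,
                           kg_provider = c("none", "transe", "rescal", "gat"),
                           desc_provider = c("none", "doc2vec", "emb"),
                           encoder = c("birnn", "none"), max_bucket = 5L,
                           head_type = NULL, tail_type = NULL,
                           eval_every = 5L, kg_epochs = 60, desc_epochs = 30,
                           verbose = FALSE) {
  kg_provider <- match.arg(kg_provider)
  desc_provider <- match.arg(desc_provider)
  encoder <- match.arg(encoder)
  stopifnot(alpha >= 0, alpha <= 1, lambda_ce >= 0, lambda_ce <= 1,
            desc_dim %% 2 == 0)
  if (is.null(final_length)) {
    final_length <- if (kg_provider != "none" || desc_provider != "none") 8L else 4L
  }
  stopifnot(final_length >= 2, log2(final_length) == round(log2(final_length)))
  structure(list(emb_dim = emb_dim, rnn_dim = rnn_dim, type_dim = type_dim,
                 dist_dim = dist_dim, d_z = d_z, kg_dim = kg_dim,
                 desc_dim = desc_dim, alpha = alpha,
                 final_length = as.integer(final_length),
                 lambda_ce = lambda_ce, beta = beta, lr = lr, epochs = epochs,
                 clip = clip, kg_provider = kg_provider,
                 desc_provider = desc_provider, encoder = encoder,
                 max_bucket = as.integer(max_bucket), head_type = head_type,
                 tail_type = tail_type, eval_every = as.integer(eval_every),
                 kg_epochs = kg_epochs, desc_epochs = desc_epochs,
                 verbose = verbose),
            class = "docrel_control")
}

# numeric parameter initialization; Wz and W_cls are stored transposed
# (input-dim x output-dim) so forward passes are plain right-multiplications
docrel_params_init <- function(vocab, label_set, control, seed,
                               desc_vocab = NULL) {
  set.seed(seed)
  ru <- function(m, n, s = 0.05) matrix(stats::runif(m * n, -s, s), m, n)
  rw <- function(m, n, s = 0.5) matrix(stats::runif(m * n, -s, s) / sqrt(m), m, n)
  vocab <- c("<pad>", "<unk>", setdiff(vocab, c("<pad>", "<unk>")))
  hid <- 2L * control$rnn_dim
  raw <- edge_raw_dims(control)
  p <- list(
    emb = `rownames<-`(ru(length(vocab), control$emb_dim), vocab),
    enc = encoder_params(control$emb_dim, control$rnn_dim,
                         seed = seed + 17L),
    type = `rownames<-`(ru(7L, control$type_dim), NODE_KINDS),
    dist_m = ru(control$max_bucket + 1L, control$dist_dim),
    dist_s = ru(control$max_bucket + 1L, control$dist_dim),
    W_att = rw(hid, hid),
    # edge transforms are scaled so initial edge-tensor entries are O(1) and
    # the first walk step's sigmoid products stay in their active range;
    # the walk matrix is scaled down because aggregated path values grow
    # with the node count
    WzT = lapply(raw, function(k) rw(k, control$d_z, s = 3)),
    W_walk = rw(control$d_z, control$d_z, s = 0.15),
    W_cls = rw(control$d_z, length(label_set)),
    b_cls = numeric(length(label_set)))
  names(p$WzT) <- names(raw)
  if (control$kg_provider == "gat") p$gat <- NULL     # filled at fit time
  if (control$desc_provider == "emb" && !is.null(desc_vocab)) {
    p$demb <- emb_params(desc_vocab, emb_dim = control$desc_dim,
                         rnn_dim = control$desc_dim %/% 2L, seed = seed + 31L)
  }
  p
}

# wrap a numeric parameter list into ad leaves (recursively over sublists)
.as_pnodes <- function(params, make = ad_param) {
  lapply(params, function(x) {
    if (is.list(x)) lapply(x, make) else make(x)
  })
}

# flatten the leaf nodes of a parameter-node tree into one list
.leaf_nodes <- function(pn) {
  out <- list()
  walk <- function(x) {
    if (is_ad(x)) out[[length(out) + 1L]] <<- x
    else if (is.list(x)) for (e in x) walk(e)
  }
  walk(pn)
  out
}

# knowledge content closures for one model state
.knowledge_closures <- function(pn, providers, control) {
  ks <- NULL; kd <- NULL
  if (!is.null(providers$ks_mat)) {
    ksm <- providers$ks_mat
    ks <- function(id) ad_const(ksm[id, ])
  } else if (!is.null(providers$kg) && !is.null(pn$gat)) {
    kgv <- providers$kg
    ks <- function(id) .gat_forward(kgv, id, 1L, pn$gat$features, pn$gat$W,
                                    pn$gat$attn)
  }
  if (!is.null(providers$kd_mat)) {
    kdm <- providers$kd_mat
    kd <- function(id) ad_const(kdm[id, ])
  } else if (!is.null(providers$desc_tokens) && !is.null(pn$demb)) {
    dt <- providers$desc_tokens
    kd <- function(id) .emb_forward(dt[[id]], pn$demb)
  }
  list(ks = ks, kd = kd)
}

# full per-document forward: returns probs node, loss node and pair table
.model_forward <- function(cache, pn, control, providers, with_loss = TRUE) {
  kn <- .knowledge_closures(pn, providers, control)
  fw <- .document_forward(cache$doc, cache$graph, pn, control, kn)
  VL <- .aggregate_forward(fw$V1, pn$W_walk, control$alpha,
                           control$final_length)
  P <- ad_gather_pairs(VL, cache$pair_idx)
  logits <- ad_addvec(ad_matmul(P, pn$W_cls), pn$b_cls)
  if (!with_loss) {
    probs <- ad_softmax_rows(logits)
    return(list(probs = probs))
  }
  .loss_forward(logits, cache$gold_idx, ncol(pn$W_cls$val),
                control$lambda_ce, control$beta)
}

# static per-document cache: graph, candidate pairs, node index lookups
.doc_cache <- function(doc, label_set, control, ks_ids, kd_ids) {
  graph <- document_graph(doc)
  graph <- attach_knowledge_nodes(graph, ks_ids, kd_ids)
  pairs <- enumerate_candidate_pairs(doc, control$head_type, control$tail_type)
  if (!nrow(pairs)) return(NULL)
  erow <- which(graph$nodes$kind == "E")
  eid <- graph$nodes$ref[erow]
  pair_idx <- cbind(erow[match(pairs$head, eid)], erow[match(pairs$tail, eid)])
  list(doc = doc, graph = graph, pairs = pairs, pair_idx = pair_idx,
       gold_idx = match(pairs$label, label_set))
}

#' Node representations of a document under a fitted model
#'
#' Runs the representation forward pass (encoder, node construction,
#' knowledge attachment) and returns the numeric node contents and full
#' representations for inspection.
#'
#' @param doc a segmented `docrel_document`.
#' @param model a fitted [docrel()] model.
#' @return list with `graph`, `contents` (list of numeric vectors),
#'   `reps` (contents with the node-type embedding appended) and
#'   `encodings` (per-sentence token encoding matrices).
#' @export
node_representations <- function(doc, model) {
  pn <- .as_pnodes(model$params, ad_const)
  kn <- .knowledge_closures(pn, model$providers, model$control)
  graph <- document_graph(doc)
  graph <- attach_knowledge_nodes(graph, model$providers$ks_ids,
                                  model$providers$kd_ids)
  fw <- .document_forward(doc, graph, pn, model$control, kn)
  list(graph = graph,
       contents = lapply(fw$contents, function(n) n$val),
       reps = lapply(fw$reps, function(n) n$val),
       encodings = lapply(fw$H, function(n) n$val))
}

#' Initial edge tensor of a document under a fitted model
#'
#' Applies the per-type linear transform to every constructed edge
#' representation and scatters the results into the symmetric node-pair
#' tensor; pairs without an edge hold the zero vector.
#'
#' @inheritParams node_representations
#' @return list with `graph` and `V1` (numeric `N x N x d_z` array).
#' @export
initial_edge_tensor <- function(doc, model) {
  pn <- .as_pnodes(model$params, ad_const)
  kn <- .knowledge_closures(pn, model$providers, model$control)
  graph <- document_graph(doc)
  graph <- attach_knowledge_nodes(graph, model$providers$ks_ids,
                                  model$providers$kd_ids)
  fw <- .document_forward(doc, graph, pn, model$control, kn)
  list(graph = graph, V1 = fw$V1$val)
}

#' Transform raw edge representations into the initial edge tensor
#'
#' Low-level numeric counterpart of the transform step: each edge type's raw
#' concatenated representations are mapped by its learnable matrix into the
#' common dimension and written symmetrically into the node-pair tensor.
#'
#' @param raw named list (by edge type) of matrices, one row per edge.
#' @param transforms named list of `d_z x raw_len` matrices.
#' @param pairs named list of 2-column endpoint index matrices.
#' @param n_nodes number of graph nodes.
#' @return `n_nodes x n_nodes x d_z` array.
#' @export
transform_edges <- function(raw, transforms, pairs, n_nodes) {
  types <- names(raw)
  missing <- setdiff(types, names(transforms))
  if (length(missing)) {
    stop("missing edge transform for type(s): ", paste(missing, collapse = ", "))
  }
  d_z <- unique(vapply(transforms[types], nrow, 0L))
  if (length(d_z) != 1L) stop("edge transforms must share the output dimension")
  V <- array(0, c(n_nodes, n_nodes, d_z))
  for (ty in types) {
    M <- raw[[ty]] %*% t(transforms[[ty]])
    ij <- pairs[[ty]]
    for (r in seq_len(nrow(ij))) {
      i <- ij[r, 1L]; j <- ij[r, 2L]
      V[i, j, ] <- V[i, j, ] + M[r, ]
      V[j, i, ] <- V[j, i, ] + M[r, ]
    }
  }
  V
}
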
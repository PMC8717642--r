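# Typed document graphs: mention (M), entity (E), sentence (S), chapter (C)
# and document (D) nodes from the document hierarchy, plus knowledge nodes
# from a triple store (KS) and from entity descriptions (KD).  Edges carry
# concatenated representations that a per-type linear map projects into a
# common dimension, giving the initial node-pair edge tensor.

NODE_KINDS <- c("M", "E", "S", "C", "D", "KS", "KD")
EDGE_TYPES <- c("MS", "MM", "ME", "SS", "ES", "SC", "CC", "CD", "EKS", "EKD")

# distance bucketing at powers of two; bucket 0 for distance 0, distances
# beyond 2^(max_bucket - 1) clamp to the last bucket
distance_bucket <- function(d, max_bucket = 5L) {
  ifelse(d <= 0L, 0L, pmin(floor(log2(d)) + 1L, max_bucket))
}

#' Build the structural graph of a document
#'
#' Creates one node per mention, entity, sentence and chapter plus a single
#' document node, and the structural edge set: mention-sentence (MS) for
#' containment, mention-mention (MM) for co-sentential mention pairs,
#' mention-entity (ME), sentence-sentence (SS) between all sentence pairs,
#' entity-sentence (ES) where an entity has a mention in the sentence,
#' sentence-chapter (SC) for containment, chapter-chapter (CC) between all
#' chapter pairs and chapter-document (CD).  Edges are undirected; each
#' unordered pair is stored once.
#'
#' @param doc a segmented `docrel_document`.
#' @return object of class `docrel_graph`: list with `doc_id`, `nodes`
#'   (data frame `kind`, `ref` where `ref` indexes mentions/sentences/
#'   chapters or names entities), and `edges` (data frame `type`, `i`, `j`,
#'   `dist` with node indices and the unbucketed distance for MM/SS edges,
#'   `NA` elsewhere).
#' @export
document_graph <- function(doc) {
  if (is.null(doc$sentences)) stop("document must be segmented first")
  m <- doc$mentions
  ents <- document_entities(doc)
  ns <- length(doc$sentences)
  nc <- max(vapply(doc$sentences, function(s) s$chapter, 0L))
  nm <- nrow(m); ne <- nrow(ents)
  nodes <- data.frame(
    kind = c(rep("M", nm), rep("E", ne), rep("S", ns), rep("C", nc), "D"),
    ref = c(as.character(seq_len(nm)), ents$entity_id,
            as.character(seq_len(ns)), as.character(seq_len(nc)), "1"),
    stringsAsFactors = FALSE)
  off_e <- nm; off_s <- nm + ne; off_c <- nm + ne + ns
  idx_d <- nm + ne + ns + nc + 1L
  edges <- list()
  add <- function(type, i, j, dist = NA_integer_) {
    edges[[length(edges) + 1L]] <<- data.frame(
      type = type, i = i, j = j, dist = dist, stringsAsFactors = FALSE)
  }
  if (nm) {
    for (r in seq_len(nm)) {
      add("MS", r, off_s + m$sentence[r])
      add("ME", r, off_e + match(m$entity_id[r], ents$entity_id))
    }
    for (s in seq_len(ns)) {
      in_s <- which(m$sentence == s)
      if (length(in_s) >= 2L) {
        for (a in seq_len(length(in_s) - 1L)) for (b in (a + 1L):length(in_s)) {
          m1 <- in_s[a]; m2 <- in_s[b]
          add("MM", m1, m2, abs(m$token_from[m1] - m$token_from[m2]))
        }
      }
    }
    es <- unique(data.frame(e = match(m$entity_id, ents$entity_id),
                            s = m$sentence))
    for (r in seq_len(nrow(es))) add("ES", off_e + es$e[r], off_s + es$s[r])
  }
  if (ns >= 2L) {
    for (a in seq_len(ns - 1L)) for (b in (a + 1L):ns) {
      add("SS", off_s + a, off_s + b, b - a)
    }
  }
  for (s in seq_len(ns)) add("SC", off_s + s, off_c + doc$sentences[[s]]$chapter)
  if (nc >= 2L) {
    for (a in seq_len(nc - 1L)) for (b in (a + 1L):nc) {
      add("CC", off_c + a, off_c + b)
    }
  }
  for (cc in seq_len(nc)) add("CD", off_c + cc, idx_d)
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(type = character(), i = integer(), j = integer(),
               dist = integer(), stringsAsFactors = FALSE)
  structure(list(doc_id = doc$doc_id, nodes = nodes, edges = edges),
            class = "docrel_graph")
}

#' Attach knowledge nodes to a document graph
#'
#' For each entity node whose entity id appears in `kg_ids`, adds one KS
#' node (knowledge-graph representation) and an EKS edge to the entity;
#' likewise a KD node and EKD edge for entity ids in `desc_ids`.  Entities
#' absent from a source get no corresponding node.
#'
#' @param graph a `docrel_graph`.
#' @param kg_ids entity ids present in the knowledge graph.
#' @param desc_ids entity ids with an external description.
#' @return the augmented graph.
#' @export
attach_knowledge_nodes <- function(graph, kg_ids = NULL, desc_ids = NULL) {
  ent_rows <- which(graph$nodes$kind == "E")
  add <- function(kind, etype, ids) {
    for (r in ent_rows) {
      eid <- graph$nodes$ref[r]
      if (eid %in% ids) {
        graph$nodes <<- rbind(graph$nodes,
                              data.frame(kind = kind, ref = eid,
                                         stringsAsFactors = FALSE))
        graph$edges <<- rbind(graph$edges,
                              data.frame(type = etype, i = r,
                                         j = nrow(graph$nodes),
                                         dist = NA_integer_,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  add("KS", "EKS", kg_ids)
  add("KD", "EKD", desc_ids)
  graph
}

#' @export
print.docrel_graph <- function(x, ...) {
  cat("<docrel_graph> ", x$doc_id, ": ", nrow(x$nodes), " nodes (",
      paste(names(table(x$nodes$kind)), table(x$nodes$kind),
            sep = "=", collapse = ", "),
      "), ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Dump a graph to JSON
#'
#' Nodes are written with their kind and reference, edges with their type
#' and 1-based endpoint indices; a documented plain format for inspection
#' and testing.
#'
#' @param graph a `docrel_graph`.
#' @param path optional output file.
#' @return the JSON string, invisibly when `path` is given.
#' @export
graph_to_json <- function(graph, path = NULL) {
  js <- jsonlite::toJSON(list(doc_id = graph$doc_id, nodes = graph$nodes,
                              edges = graph$edges),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# expected raw concatenation length per edge type, given dimensions
edge_raw_dims <- function(control) {
  hid <- 2L * control$rnn_dim
  nd <- hid + control$type_dim     # structural node representation length
  c(MS = 2L * nd,
    MM = 2L * nd + hid + control$dist_dim,
    ME = 2L * nd,
    SS = 2L * nd + control$dist_dim + nd,
    ES = 2L * nd,
    SC = 2L * nd,
    CC = 2L * nd,
    CD = 2L * nd,
    EKS = nd + control$kg_dim + control$type_dim,
    EKD = nd + control$desc_dim + control$type_dim)
}

# ---- representation forward (autodiff) --------------------------------------

# Attention between two co-sentential mentions (content parts c1, c2) over
# the sentence encoding H (|s| x hidden).  Token scores come from the
# projected mention content; each mention's weights are softmax-normalized
# over the tokens outside that mention; the pair weights are their average
# and the context vector is the weight-averaged token encoding.
.mm_attention_forward <- function(H, c1, c2, sup1, sup2, W_att) {
  l1 <- ad_matvec(H, ad_matvec(W_att, c1))
  l2 <- ad_matvec(H, ad_matvec(W_att, c2))
  a1 <- ad_masked_softmax(l1, sup1)
  a2 <- ad_masked_softmax(l2, sup2)
  a <- ad_smul(ad_add(a1, a2), 0.5)
  list(a1 = a1, a2 = a2, a = a, context = ad_tmatvec(H, a))
}

#' Attention context vector for a co-sentential mention pair
#'
#' @param H numeric sentence encoding, one row per token.
#' @param tokens1,tokens2 integer token index ranges of the two mentions.
#' @param W_att projection matrix (hidden x hidden).
#' @param c1,c2 optional mention content vectors; default is the mean of the
#'   mention's token encodings.
#' @return list with `a1`, `a2` (per-mention weights, each summing to 1 over
#'   the tokens outside its mention), `a` (their average) and `context`
#'   (the attention-weighted token encoding).
#' @export
mention_pair_attention <- function(H, tokens1, tokens2, W_att,
                                   c1 = colMeans(H[tokens1, , drop = FALSE]),
                                   c2 = colMeans(H[tokens2, , drop = FALSE])) {
  sup1 <- !(seq_len(nrow(H)) %in% tokens1)
  sup2 <- !(seq_len(nrow(H)) %in% tokens2)
  if (!any(sup1) || !any(sup2)) stop("a mention covers the whole sentence")
  out <- .mm_attention_forward(ad_const(H), ad_const(c1), ad_const(c2),
                               sup1, sup2, ad_const(W_att))
  lapply(out, function(n) n$val)
}

# Full representation forward for one document.  `pn` holds ad nodes for all
# parameters; `knowledge` optionally carries ks/kd content providers:
#   knowledge$ks(entity_id) -> ad node | NULL ; same for $kd.
# Returns node contents, full node representations and the initial edge
# tensor V1 (N x N x d_z), all as ad nodes, plus the graph.
.document_forward <- function(doc, graph, pn, control, knowledge = NULL) {
  hid <- 2L * control$rnn_dim
  m <- doc$mentions
  ns <- length(doc$sentences)
  # encodings per sentence
  emb_rows <- rownames(pn$emb$val)
  H <- lapply(doc$sentences, function(s) {
    idx <- match(s$tokens$token, emb_rows)
    idx[is.na(idx)] <- match("<unk>", emb_rows)
    .encode_forward(idx, pn$emb, pn$enc, control$encoder)
  })
  nodes <- graph$nodes
  N <- nrow(nodes)
  contents <- vector("list", N)
  for (r in which(nodes$kind == "M")) {
    mi <- as.integer(nodes$ref[r])
    contents[[r]] <- ad_row_mean(H[[m$sentence[mi]]],
                                 m$token_from[mi]:m$token_to[mi])
  }
  for (r in which(nodes$kind == "S")) {
    contents[[r]] <- ad_colmeans(H[[as.integer(nodes$ref[r])]])
  }
  ment_rows <- which(nodes$kind == "M")
  for (r in which(nodes$kind == "E")) {
    own <- ment_rows[m$entity_id[as.integer(nodes$ref[ment_rows])] ==
                       nodes$ref[r]]
    contents[[r]] <- ad_mean_list(contents[own])
  }
  sent_rows <- which(nodes$kind == "S")
  sent_ch <- vapply(doc$sentences, function(s) s$chapter, 0L)
  for (r in which(nodes$kind == "C")) {
    own <- sent_rows[sent_ch == as.integer(nodes$ref[r])]
    contents[[r]] <- ad_mean_list(contents[own])
  }
  ch_rows <- which(nodes$kind == "C")
  for (r in which(nodes$kind == "D")) {
    contents[[r]] <- ad_mean_list(contents[ch_rows])
  }
  for (r in which(nodes$kind == "KS")) {
    contents[[r]] <- knowledge$ks(nodes$ref[r])
  }
  for (r in which(nodes$kind == "KD")) {
    contents[[r]] <- knowledge$kd(nodes$ref[r])
  }
  type_rows <- rownames(pn$type$val)
  reps <- vector("list", N)
  for (r in seq_len(N)) {
    reps[[r]] <- ad_concat(list(contents[[r]],
                                ad_row(pn$type, match(nodes$kind[r], type_rows))))
  }
  # raw edge representations
  edges <- graph$edges
  raw <- vector("list", nrow(edges))
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]
    raw[[k]] <- switch(edges$type[k],
      MM = {
        mi <- as.integer(nodes$ref[i]); mj <- as.integer(nodes$ref[j])
        s <- m$sentence[mi]
        ntok <- nrow(doc$sentences[[s]]$tokens)
        sup1 <- !(seq_len(ntok) %in% (m$token_from[mi]:m$token_to[mi]))
        sup2 <- !(seq_len(ntok) %in% (m$token_from[mj]:m$token_to[mj]))
        ctx <- if (any(sup1) && any(sup2)) {
          .mm_attention_forward(H[[s]], contents[[i]], contents[[j]],
                                sup1, sup2, pn$W_att)$context
        } else {
          ad_const(numeric(hid))
        }
        b <- distance_bucket(edges$dist[k], control$max_bucket)
        ad_concat(list(reps[[i]], reps[[j]], ctx, ad_row(pn$dist_m, b + 1L)))
      },
      SS = {
        b <- distance_bucket(edges$dist[k], control$max_bucket)
        ad_concat(list(reps[[i]], reps[[j]], ad_row(pn$dist_s, b + 1L),
                       ad_abs(ad_sub(reps[[i]], reps[[j]]))))
      },
      CD = ad_concat(list(reps[[j]], reps[[i]])),   # [n_d; n_c]
      ad_concat(list(reps[[i]], reps[[j]])))
  }
  # per-type linear transform into the common edge dimension
  types <- unique(edges$type)
  missing <- setdiff(types, names(pn$Wz))
  if (length(missing)) {
    stop("missing edge transform for type(s): ", paste(missing, collapse = ", "))
  }
  mats <- list(); idx <- list()
  for (ty in types) {
    rows <- which(edges$type == ty)
    Rm <- ad_rbind(raw[rows])
    mats[[ty]] <- ad_matmul(Rm, pn$WzT[[ty]])
    idx[[ty]] <- cbind(edges$i[rows], edges$j[rows])
  }
  V1 <- ad_scatter_pairs(mats, idx, N, control$d_z)
  list(graph = graph, H = H, contents = contents, reps = reps, V1 = V1)
}
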
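# Typed graph construction: node contents, attention, edge sets, knowledge
# attachment and the initial edge tensor.

make_graph_doc <- function(seed = 1, n_docs = 1) {
  generate_corpus(synth_config(n_docs = n_docs, seed = seed))$corpus$documents
}

edge_count <- function(graph, type) sum(graph$edges$type == type)

test_that("a minimal document yields the five structural nodes with shared content", {
  text <- "T. ENTA here."
  m <- mention_rows(text, "ENTA", "C1", "Chemical")
  doc <- make_doc("d", "T.", "ENTA here.", m)
  g <- document_graph(doc)
  expect_setequal(unique(g$nodes$kind), c("M", "E", "S", "C", "D"))
  expect_equal(nrow(g$nodes), 1 + 1 + 2 + 2 + 1)
  tm <- tiny_model()
  reps <- node_representations(doc, tm$model)
  km <- which(g$nodes$kind == "M")
  ke <- which(g$nodes$kind == "E")
  # single-mention entity content equals the mention content
  expect_equal(reps$contents[[ke]], reps$contents[[km]])
  # single-token mention content equals that token's encoding row
  s <- doc$mentions$sentence[1]
  expect_equal(reps$contents[[km]],
               reps$encodings[[s]][doc$mentions$token_from[1], ])
})

test_that("chapter and document contents are the hand-computed means", {
  doc <- make_graph_doc(seed = 8)[[1]]
  tm <- tiny_model()
  reps <- node_representations(doc, tm$model)
  g <- reps$graph
  sent_ch <- vapply(doc$sentences, function(s) s$chapter, 0L)
  srows <- which(g$nodes$kind == "S")
  crows <- which(g$nodes$kind == "C")
  drow <- which(g$nodes$kind == "D")
  for (ci in seq_along(crows)) {
    own <- srows[sent_ch == ci]
    expect_equal(reps$contents[[crows[ci]]],
                 colMeans(do.call(rbind, reps$contents[own])), tolerance = 1e-12)
  }
  expect_equal(reps$contents[[drow]],
               colMeans(do.call(rbind, reps$contents[crows])), tolerance = 1e-12)
})

test_that("edge sets follow the closed-form combinatorics", {
  for (doc in make_graph_doc(seed = 12, n_docs = 5)) {
    g <- document_graph(doc)
    ns <- length(doc$sentences)
    nc <- length(unique(vapply(doc$sentences, function(s) s$chapter, 0L)))
    nm <- nrow(doc$mentions)
    expect_equal(edge_count(g, "SS"), choose(ns, 2))
    expect_equal(edge_count(g, "SC"), ns)
    expect_equal(edge_count(g, "CC"), choose(nc, 2))
    expect_equal(edge_count(g, "CD"), nc)
    expect_equal(edge_count(g, "MS"), nm)
    expect_equal(edge_count(g, "ME"), nm)
    mm <- sum(vapply(seq_len(ns), function(s) {
      choose(sum(doc$mentions$sentence == s), 2)
    }, 0))
    expect_equal(edge_count(g, "MM"), mm)
    es <- nrow(unique(doc$mentions[, c("entity_id", "sentence")]))
    expect_equal(edge_count(g, "ES"), es)
  }
})

test_that("single-mention documents carry no mention-pair edge", {
  text <- "T. ENTA here."
  m <- mention_rows(text, "ENTA", "C1", "Chemical")
  doc <- make_doc("d", "T.", "ENTA here.", m)
  g <- document_graph(doc)
  expect_equal(edge_count(g, "MS"), 1L)
  expect_equal(edge_count(g, "ME"), 1L)
  expect_equal(edge_count(g, "ES"), 1L)
  expect_equal(edge_count(g, "MM"), 0L)
})

test_that("collapsing to one chapter leaves the flat graph plus degenerate C/D", {
  body <- "ENTA acts. ENTB reacts. Nothing else."
  m <- rbind(mention_rows(paste("", body), "ENTA", "C1", "Chemical"),
             mention_rows(paste("", body), "ENTB", "D1", "Disease"))
  doc <- structure(list(doc_id = "d", title = "", abstract = body,
                        text = paste("", body), mentions = m,
                        gold = data.frame(head = character(),
                                          label = character(),
                                          tail = character(),
                                          stringsAsFactors = FALSE),
                        sentences = NULL), class = "docrel_document")
  doc <- segment_document(doc)
  g <- document_graph(doc)
  expect_equal(sum(g$nodes$kind == "C"), 1L)
  expect_equal(edge_count(g, "CC"), 0L)
  expect_equal(edge_count(g, "CD"), 1L)
  expect_equal(edge_count(g, "SC"), length(doc$sentences))
})

test_that("mention-pair attention is normalized and matches a hand computation", {
  set.seed(3)
  H <- matrix(rnorm(16), 4, 4)
  W <- matrix(rnorm(16), 4, 4)
  out <- mention_pair_attention(H, tokens1 = 1L, tokens2 = 3L, W_att = W)
  expect_equal(sum(out$a1), 1, tolerance = 1e-12)
  expect_equal(sum(out$a2), 1, tolerance = 1e-12)
  expect_true(all(out$a1 >= 0) && out$a1[1] == 0 && out$a2[3] == 0)
  expect_equal(out$a, (out$a1 + out$a2) / 2, tolerance = 1e-12)
  # hand computation of the same quantities
  c1 <- H[1, ]; c2 <- H[3, ]
  l1 <- as.vector(H %*% (W %*% c1)); l2 <- as.vector(H %*% (W %*% c2))
  sm <- function(l, drop) {
    e <- exp(l[-drop] - max(l[-drop]))
    w <- numeric(length(l)); w[-drop] <- e / sum(e); w
  }
  a <- (sm(l1, 1) + sm(l2, 3)) / 2
  expect_equal(out$a, a, tolerance = 1e-12)
  expect_equal(out$context, as.vector(t(H) %*% a), tolerance = 1e-12)
})

test_that("uniform attention logits spread weight evenly outside the mention", {
  H <- matrix(1, 5, 3)         # identical token encodings -> equal logits
  W <- diag(3)
  out <- mention_pair_attention(H, tokens1 = 2L, tokens2 = 4L, W_att = W)
  expect_equal(out$a1[-2], rep(1 / 4, 4), tolerance = 1e-12)
  expect_equal(out$a2[-4], rep(1 / 4, 4), tolerance = 1e-12)
})

test_that("knowledge nodes attach per source exactly as in the layout example", {
  doc <- make_graph_doc(seed = 5)[[1]]
  ents <- document_entities(doc)$entity_id
  # three entities have descriptions, the first and third are in the KG
  skip_if(length(ents) < 3)
  g0 <- document_graph(doc)
  g <- attach_knowledge_nodes(g0, kg_ids = ents[c(1, 3)], desc_ids = ents[1:3])
  expect_equal(sum(g$nodes$kind == "KS"), 2L)
  expect_equal(sum(g$nodes$kind == "KD"), 3L)
  expect_equal(edge_count(g, "EKS"), 2L)
  expect_equal(edge_count(g, "EKD"), 3L)
  # an entity in neither source gains nothing
  g2 <- attach_knowledge_nodes(g0, kg_ids = character(), desc_ids = character())
  expect_equal(g2$nodes, g0$nodes)
})

test_that("edge transformation is linear, local and symmetric", {
  raw <- list(MS = matrix(1:6, 2, 3))
  pairs <- list(MS = rbind(c(1, 2), c(2, 3)))
  Wz0 <- list(MS = matrix(0, 4, 3))
  expect_equal(transform_edges(raw, Wz0, pairs, 3), array(0, c(3, 3, 4)))
  # single edge -> exactly one symmetric nonzero pair entry
  raw1 <- list(MS = matrix(c(1, 0, 2), 1, 3))
  W1 <- list(MS = rbind(diag(3), 0))
  V <- transform_edges(raw1, W1, list(MS = rbind(c(1, 3))), 3)
  expect_equal(V[1, 3, ], c(1, 0, 2, 0))
  expect_equal(V[3, 1, ], c(1, 0, 2, 0))
  V[1, 3, ] <- V[3, 1, ] <- 0
  expect_true(all(V == 0))
  expect_error(transform_edges(raw1, list(), list(MS = rbind(c(1, 3))), 3),
               "missing edge transform")
})

test_that("initial edge tensor has an entry exactly where an edge exists", {
  tm <- tiny_model()
  doc <- tm$corpus$documents[[1]]
  et <- initial_edge_tensor(doc, tm$model)
  nz <- apply(abs(et$V1), c(1, 2), sum) > 0
  has_edge <- matrix(FALSE, nrow(et$graph$nodes), nrow(et$graph$nodes))
  for (r in seq_len(nrow(et$graph$edges))) {
    i <- et$graph$edges$i[r]; j <- et$graph$edges$j[r]
    has_edge[i, j] <- has_edge[j, i] <- TRUE
  }
  expect_equal(nz, has_edge)
})

test_that("graph JSON dump lists every node and edge", {
  tm <- tiny_model()
  g <- document_graph(tm$corpus$documents[[1]])
  js <- jsonlite::fromJSON(graph_to_json(g))
  expect_equal(nrow(js$nodes), nrow(g$nodes))
  expect_equal(nrow(js$edges), nrow(g$edges))
  expect_equal(js$doc_id, g$doc_id)
})
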
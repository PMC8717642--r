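# Knowledge-graph embeddings and description embedders.

test_that("translation score is the L2 residual and composes over chains", {
  expect_equal(transe_score(c(1, 1), c(1, 0), c(2, 1)), 0)
  expect_equal(transe_score(c(1, 0), c(0, 0), c(0, 0)), 1)
  expect_error(transe_score(1:2, 1:3, 1:2), "mismatch")
  # two exact triples compose: h1 + r1 + r2 = t2
  set.seed(2)
  h1 <- rnorm(4); r1 <- rnorm(4); t1 <- h1 + r1
  r2 <- rnorm(4); t2 <- t1 + r2
  expect_equal(transe_score(h1, r1 + r2, t2), 0, tolerance = 1e-12)
})

test_that("margin loss degenerates as prescribed", {
  trip <- list(h = c(1, 2), r = c(0, 1), t = c(1, 3))
  # identical positive and negative: max(gamma, 0)
  expect_equal(transe_margin_loss(trip, trip, gamma = 1), 1)
  # pre-satisfied embeddings with zero margin: loss 0
  neg <- list(h = c(1, 2), r = c(0, 1), t = c(5, 5))
  expect_equal(transe_margin_loss(trip, neg, gamma = 0), 0)
})

test_that("trained translations separate true from corrupted triples", {
  kg <- toy_kg(n_entities = 20, n_relations = 2, n_triples = 40, seed = 7)
  kge <- train_transe(kg, dim = 8, epochs = 80, seed = 1)
  set.seed(3)
  f_true <- f_corr <- numeric(0)
  for (b in seq_len(nrow(kg$triples))) {
    h <- kge$entities[kg$triples$head[b], ]
    r <- kge$relations[kg$triples$relation[b], ]
    t <- kge$entities[kg$triples$tail[b], ]
    f_true <- c(f_true, transe_score(h, r, t))
    f_corr <- c(f_corr, transe_score(h, r,
                                     kge$entities[sample(kg$entities, 1), ]))
  }
  expect_lt(mean(f_true), mean(f_corr))
  expect_error(train_transe(as_kg(data.frame(head = character(),
                                             relation = character(),
                                             tail = character())[0, ])),
               "empty")
  # deterministic given the seed
  kge2 <- train_transe(kg, dim = 8, epochs = 80, seed = 1)
  expect_identical(kge$entities, kge2$entities)
})

test_that("bilinear score matches the naive double loop", {
  expect_equal(rescal_score(c(1, 2), diag(2), c(3, 4)), 11)
  expect_equal(rescal_score(c(0, 0), matrix(rnorm(4), 2), c(1, 1)), 0)
  set.seed(4)
  h <- rnorm(3); M <- matrix(rnorm(9), 3); t <- rnorm(3)
  brute <- 0
  for (i in 1:3) for (j in 1:3) brute <- brute + h[i] * M[i, j] * t[j]
  expect_equal(rescal_score(h, M, t), brute, tolerance = 1e-12)
  expect_error(rescal_score(1:2, diag(3), 1:3), "mismatch")
})

test_that("tensor factorization loss is monotone and reconstructs the toy tensor", {
  kg <- toy_kg(n_entities = 8, n_relations = 2, n_triples = 14, seed = 5)
  kge <- factorize_rescal(kg, rank = length(kg$entities), epochs = 250, seed = 1)
  expect_true(all(diff(kge$loss) <= 1e-12))
  rec <- rescal_reconstruct(kge)
  X <- lapply(kg$relations, function(r) {
    M <- matrix(0, length(kg$entities), length(kg$entities))
    tr <- kg$triples[kg$triples$relation == r, ]
    M[cbind(match(tr$head, kg$entities), match(tr$tail, kg$entities))] <- 1
    M
  })
  acc <- mean(unlist(Map(function(a, b) (a > 0.5) == (b > 0.5), rec, X)))
  expect_gte(acc, 0.9)
  expect_error(factorize_rescal(kg, rank = 99), "rank")
})

test_that("single-triple full-rank factorization fits exactly", {
  kg <- as_kg(data.frame(head = "A", relation = "r", tail = "B",
                         stringsAsFactors = FALSE))
  kge <- factorize_rescal(kg, rank = 2, epochs = 400, lr = 0.1, seed = 2)
  expect_lt(tail(kge$loss, 1), 1e-3)
})

test_that("graph attention handles isolation, uniformity and a hand-set star", {
  kg <- as_kg(data.frame(head = c("A", "A", "Z"),
                         relation = "r",
                         tail = c("B", "C", "Q"), stringsAsFactors = FALSE))
  par <- gat_params(kg, dim = 3, seed = 1)
  # isolated-ish entity Q: neighborhood = {Z}; isolate it fully
  kg2 <- as_kg(data.frame(head = c("A", "A"), relation = "r",
                          tail = c("B", "C"), stringsAsFactors = FALSE))
  par2 <- gat_params(kg2, dim = 3, seed = 1)
  solo <- gat_embed(kg2, "B", radius = 0, params = par2)
  expect_equal(solo, tanh(as.vector(par2$features["B", ] %*% par2$W)),
               tolerance = 1e-12)
  # uniform logits (zero attention vector) -> plain neighborhood mean
  par2$attn <- rep(0, 6)
  ctr <- gat_embed(kg2, "A", radius = 1, params = par2)
  Hn <- par2$features[c("A", "B", "C"), ] %*% par2$W
  expect_equal(ctr, tanh(colMeans(Hn)), tolerance = 1e-12)
  # 1-layer/1-head star against a fully hand-computed attention aggregate
  par$attn <- rnorm(6)
  out <- gat_embed(kg, "A", radius = 1, params = par)
  Hs <- par$features[c("A", "B", "C"), ] %*% par$W
  lg <- vapply(1:3, function(i) {
    v <- sum(par$attn * c(Hs[1, ], Hs[i, ]))
    if (v > 0) v else 0.2 * v
  }, 0)
  w <- exp(lg - max(lg)); w <- w / sum(w)
  expect_equal(out, tanh(as.vector(t(Hs) %*% w)), tolerance = 1e-12)
  expect_error(gat_embed(kg, "missing", params = par), "unknown entity")
})

test_that("paragraph embeddings meet the shape, determinism and purity contracts", {
  set.seed(9)
  mk <- function(cls, i) paste(sample(sprintf("%s%02d", cls, 1:6), 8, TRUE),
                               collapse = " ")
  desc <- c(vapply(1:4, function(i) mk("alpha", i), ""),
            vapply(1:4, function(i) mk("beta", i), ""),
            vapply(1:4, function(i) mk("gamma", i), ""))
  names(desc) <- sprintf("E%02d", 1:12)
  emb <- embed_description_doc2vec(desc, dim = 6, epochs = 30, seed = 2)
  expect_equal(dim(emb), c(12L, 6L))
  emb2 <- embed_description_doc2vec(desc, dim = 6, epochs = 30, seed = 2)
  expect_identical(emb, emb2)
  # nearest-neighbour purity above chance (1/3)
  lab <- rep(1:3, each = 4)
  D <- as.matrix(dist(emb)); diag(D) <- Inf
  purity <- mean(lab[apply(D, 1, which.min)] == lab)
  expect_gt(purity, 1 / 3)
  expect_error(embed_description_doc2vec(c(a = "")), "empty")
})

test_that("the recurrent description encoder pools, orders and differentiates", {
  par <- emb_params(c("alpha", "beta"), emb_dim = 4, rnn_dim = 3, seed = 1)
  v1 <- embed_description_emb("alpha", par)
  expect_equal(length(v1), 6L)
  # order sensitivity of the recurrence
  vab <- embed_description_emb(c("alpha", "beta"), par)
  vba <- embed_description_emb(c("beta", "alpha"), par)
  expect_false(isTRUE(all.equal(vab, vba)))
  expect_error(embed_description_emb(character(), par), "empty")
  # gradient check through the whole encoder on a 2-token description
  pn <- lapply(par, docrel:::ad_param)
  f <- function(ps) {
    out <- docrel:::.emb_forward(c("alpha", "beta"), pn)
    docrel:::ad_sum(docrel:::ad_mul(out, out))
  }
  expect_lt(fd_check(f, pn), 1e-6)
})
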
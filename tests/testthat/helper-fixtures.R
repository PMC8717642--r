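# Shared fixtures: a tiny hand-written PubTator corpus, toy knowledge graphs,
# and a finite-difference gradient checker for the autodiff internals.

pubtator_fixture <- function() {
  path <- tempfile(fileext = ".pubtator")
  writeLines(c(
    "1001|t|Aspirin study.",
    "1001|a|Aspirin causes ulcers. Ulcers hurt badly.",
    "1001\t0\t7\tAspirin\tChemical\tC01",
    "1001\t15\t22\tAspirin\tChemical\tC01",
    "1001\t30\t36\tulcers\tDisease\tD01",
    "1001\t38\t44\tUlcers\tDisease\tD01",
    "1001\tcauses\tC01\tD01",
    "",
    "1002|t|Drugs.",
    "1002|a|Ibuprofen is safe. Headache persists.",
    "1002\t7\t16\tIbuprofen\tChemical\tC02",
    "1002\t26\t34\tHeadache\tDisease\tD02",
    ""), path)
  path
}

# one-sentence-per-line document built from whitespace tokens; title is the
# first element
make_doc <- function(doc_id, title, body_sentences, mentions = NULL) {
  abstract <- paste(body_sentences, collapse = " ")
  text <- paste(title, abstract, sep = " ")
  m <- if (is.null(mentions)) {
    data.frame(start = integer(), end = integer(), surface = character(),
               entity_id = character(), entity_type = character(),
               stringsAsFactors = FALSE)
  } else {
    mentions
  }
  doc <- structure(list(doc_id = doc_id, title = title, abstract = abstract,
                        text = text, mentions = m,
                        gold = data.frame(head = character(),
                                          label = character(),
                                          tail = character(),
                                          stringsAsFactors = FALSE),
                        sentences = NULL),
                   class = "docrel_document")
  segment_document(doc)
}

# locate every occurrence of `surface` in the text and return mention rows
mention_rows <- function(text, surface, entity_id, entity_type) {
  hits <- gregexpr(surface, text, fixed = TRUE)[[1L]]
  data.frame(start = as.integer(hits) - 1L,
             end = as.integer(hits) + nchar(surface) - 1L,
             surface = surface, entity_id = entity_id,
             entity_type = entity_type, stringsAsFactors = FALSE)
}

toy_kg <- function(n_entities = 20, n_relations = 2, n_triples = 30, seed = 42) {
  set.seed(seed)
  ents <- sprintf("E%02d", seq_len(n_entities))
  rels <- sprintf("r%d", seq_len(n_relations))
  tr <- unique(data.frame(
    head = sample(ents, n_triples, replace = TRUE),
    relation = sample(rels, n_triples, replace = TRUE),
    tail = sample(ents, n_triples, replace = TRUE),
    stringsAsFactors = FALSE))
  tr <- tr[tr$head != tr$tail, ]
  as_kg(tr)
}

# numeric gradient check of a scalar-valued autodiff computation
fd_check <- function(f, params, eps = 1e-6) {
  loss <- f(params)
  docrel:::ad_zero_grad(params)
  docrel:::ad_backward(loss)
  worst <- 0
  for (p in params) {
    g <- p$grad
    if (is.null(g)) g <- p$val * 0
    for (i in seq_along(p$val)) {
      v0 <- p$val[i]
      p$val[i] <- v0 + eps
      lp <- f(params)$val
      p$val[i] <- v0 - eps
      lm <- f(params)$val
      p$val[i] <- v0
      worst <- max(worst, abs((lp - lm) / (2 * eps) - g[i]))
    }
  }
  worst
}

# reference implementation of one walk-aggregation step by explicit loops
brute_walk <- function(V, W, alpha) {
  N <- dim(V)[1L]; d <- dim(V)[3L]
  out <- array(0, dim(V))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    s <- numeric(d)
    for (k in setdiff(seq_len(N), c(i, j))) {
      s <- s + 1 / (1 + exp(-(V[i, k, ] * as.vector(W %*% V[k, j, ]))))
    }
    out[i, j, ] <- alpha * V[i, j, ] + (1 - alpha) * s
  }
  (out + aperm(out, c(2L, 1L, 3L))) / 2
}

random_edge_tensor <- function(N, d) {
  V <- array(stats::rnorm(N * N * d), c(N, N, d))
  (V + aperm(V, c(2L, 1L, 3L))) / 2
}

# small fitted model shared across inspection tests (1 epoch, cached)
tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_docs = 4, seed = 3)
      corpus <- generate_corpus(cfg)$corpus
      cache <<- list(
        corpus = corpus,
        model = docrel(corpus, control = docrel_control(epochs = 1), seed = 1))
    }
    cache
  }
})
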
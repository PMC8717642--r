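# Locality splitting, evaluation arithmetic and the training protocol.

test_that("pair locality follows shared-sentence membership", {
  text <- "T. ENTA with ENTB fine. ENTC alone here."
  m <- rbind(mention_rows(text, "ENTA", "C1", "Chemical"),
             mention_rows(text, "ENTB", "D1", "Disease"),
             mention_rows(text, "ENTC", "D2", "Disease"))
  doc <- make_doc("d", "T.", "ENTA with ENTB fine. ENTC alone here.", m)
  expect_equal(split_intra_inter(doc, "C1", "D1"), "intra")
  expect_equal(split_intra_inter(doc, "C1", "D2"), "inter")
})

test_that("evaluation arithmetic, invariances and count decomposition hold", {
  out <- generate_corpus(synth_config(n_docs = 6, seed = 41))
  corpus <- out$corpus
  gold_pred <- do.call(rbind, lapply(corpus$documents, function(d) {
    if (!nrow(d$gold)) return(NULL)
    data.frame(doc_id = d$doc_id, head = d$gold$head, label = d$gold$label,
               tail = d$gold$tail, stringsAsFactors = FALSE)
  }))
  perfect <- evaluate_relations(gold_pred, corpus)
  expect_equal(unname(perfect$table["overall", ]), c(100, 100, 100))
  # permutation invariance
  shuf <- gold_pred[sample(nrow(gold_pred)), ]
  expect_equal(evaluate_relations(shuf, corpus)$table, perfect$table)
  # drop some, add a false positive; intra + inter counts == overall counts
  ents1 <- document_entities(corpus$documents[[1]])
  fp <- data.frame(doc_id = corpus$documents[[1]]$doc_id,
                   head = ents1$entity_id[ents1$entity_type == "Chemical"][1],
                   label = "wrong",
                   tail = ents1$entity_id[ents1$entity_type == "Disease"][1],
                   stringsAsFactors = FALSE)
  partial <- rbind(gold_pred[seq_len(nrow(gold_pred) %/% 2), ], fp)
  m <- evaluate_relations(partial, corpus)
  expect_equal(m$counts["intra", ] + m$counts["inter", ], m$counts["overall", ])
  expect_error(evaluate_relations(
    data.frame(doc_id = corpus$documents[[1]]$doc_id, head = "NOPE",
               label = "causes", tail = "NOPE2", stringsAsFactors = FALSE),
    corpus), "unknown entity")
})

test_that("F from printed precision/recall reproduces the harmonic mean", {
  expect_equal(f_measure(50, 50), 50)
  expect_equal(f_measure(0, 0), 0)
  expect_equal(round(f_measure(64.5, 75.5), 1), 69.6)
})

test_that("training reduces the loss on a one-document corpus", {
  corpus <- subset_corpus(generate_corpus(synth_config(n_docs = 2, seed = 13))$corpus, 1)
  m <- docrel(corpus, control = docrel_control(epochs = 15), seed = 2)
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
  expect_error(docrel(structure(list(documents = list(),
                                     label_set = c("null", "x")),
                                class = "docrel_corpus")), "empty")
})

test_that("predictions round-trip through the TSV format and re-score identically", {
  tm <- tiny_model()
  pred <- predict(tm$model, tm$corpus)
  expect_equal(nrow(pred), sum(vapply(tm$corpus$documents, function(d) {
    nrow(enumerate_candidate_pairs(d, tm$model$control$head_type,
                                   tm$model$control$tail_type))
  }, 0L)))
  m1 <- evaluate_relations(pred, tm$corpus)
  p <- tempfile()
  write_predictions(pred, p)
  m2 <- evaluate_relations(read_predictions(p), tm$corpus)
  expect_equal(m1$table, m2$table)
})

test_that("a classifier biased to the null label predicts no positives", {
  tm <- tiny_model()
  m <- tm$model
  m$params$b_cls <- c(25, -25)
  pred <- predict(m, tm$corpus)
  expect_true(all(pred$label == "null"))
  expect_true(all(pred$prob > 0.99))
})

test_that("prediction-time hypernym filtering equals the standalone filter", {
  tm <- tiny_model()
  m <- tm$model
  m$params$b_cls <- c(-25, 25)        # force all-positive predictions
  pred0 <- predict(m, tm$corpus)
  heads <- unique(pred0$head)
  hier <- data.frame(child = heads[2], parent = heads[1],
                     stringsAsFactors = FALSE)
  pred1 <- predict(m, tm$corpus, hierarchy = hier)
  pos0 <- pred0[pred0$label != "null", ]
  expected <- hypernym_filter(pos0, hier)
  got <- pred1[pred1$label != "null", ]
  expect_setequal(paste(got$doc_id, got$head, got$tail),
                  paste(expected$doc_id, expected$head, expected$tail))
  expect_lt(nrow(got), nrow(pos0))
})

test_that("the train/develop/retrain protocol runs end to end", {
  corpus <- generate_corpus(synth_config(n_docs = 10, seed = 17))$corpus
  train <- subset_corpus(corpus, 1:6)
  dev <- subset_corpus(corpus, 7:8)
  test <- subset_corpus(corpus, 9:10)
  res <- docrel_protocol(train, dev, test,
                         control = docrel_control(epochs = 4, eval_every = 2),
                         seed = 1)
  expect_s3_class(res$model, "docrel")
  expect_true(res$best_epoch %in% 1:4)
  expect_equal(max(res$model$history$epoch), res$best_epoch)
  expect_s3_class(res$metrics, "docrel_metrics")
  expect_true(all(dim(res$metrics$table) == c(3, 3)))
  js <- jsonlite::fromJSON(metrics_to_json(res$metrics))
  expect_named(js, c("overall", "intra", "inter"))
})

test_that("model accessors expose history and coefficients", {
  tm <- tiny_model()
  expect_named(coef(tm$model)$WzT, docrel:::EDGE_TYPES, ignore.order = TRUE)
  expect_output(print(tm$model), "edge-oriented graph")
  expect_s3_class(tm$model$history, "data.frame")
})
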
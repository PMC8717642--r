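# PubTator parsing, segmentation, candidate pairs and preprocessing filters.

test_that("a minimal well-formed block parses into one document", {
  p <- tempfile()
  writeLines(c("7|t|One.", "7|a|Two B here.",
               "7\t9\t10\tB\tChemical\tC1", ""), p)
  corpus <- read_pubtator(p)
  doc <- corpus$documents[["7"]]
  expect_equal(length(corpus$documents), 1L)
  expect_equal(nrow(doc$mentions), 1L)
  expect_equal(nrow(doc$gold), 0L)
  expect_equal(doc$text, "One. Two B here.")
  expect_equal(substr(doc$text, doc$mentions$start + 1, doc$mentions$end), "B")
})

test_that("offset/surface mismatches and malformed lines are rejected", {
  p <- tempfile()
  writeLines(c("7|t|One.", "7|a|Two B here.",
               "7\t9\t10\tX\tChemical\tC1", ""), p)
  expect_error(read_pubtator(p), "validation error.*7")
  writeLines(c("7|t|One.", "oops"), p)
  expect_error(read_pubtator(p), "parse error")
})

test_that("composite entity ids split and id -1 mentions drop", {
  p <- tempfile()
  writeLines(c("9|t|T.", "9|a|Alpha beta.",
               "9\t3\t8\tAlpha\tChemical\tC1|C2",
               "9\t9\t13\tbeta\tDisease\t-1", ""), p)
  doc <- read_pubtator(p)$documents[["9"]]
  expect_equal(sort(doc$mentions$entity_id), c("C1", "C2"))
  expect_true(all(doc$mentions$surface == "Alpha"))
})

test_that("read -> write -> read is the identity on a synthetic corpus", {
  out <- generate_corpus(synth_config(n_docs = 3, seed = 21))
  f1 <- tempfile(); f2 <- tempfile()
  write_pubtator(out$corpus, f1)
  c1 <- read_pubtator(f1)
  write_pubtator(c1, f2)
  c2 <- read_pubtator(f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(c1, c2)
  for (id in names(out$corpus$documents)) {
    expect_equal(c1$documents[[id]]$mentions,
                 out$corpus$documents[[id]]$mentions)
    expect_equal(c1$documents[[id]]$gold, out$corpus$documents[[id]]$gold)
  }
})

test_that("segmentation splits chapters and sentences as specified", {
  doc <- make_doc("d", "A.", c("B fine.", "C done."))
  expect_equal(length(doc$sentences), 3L)
  expect_equal(vapply(doc$sentences, function(s) s$chapter, 0L), c(1L, 2L, 2L))
  # sum of sentences per chapter equals the sentence count
  expect_equal(sum(table(vapply(doc$sentences, function(s) s$chapter, 0L))),
               length(doc$sentences))
  expect_error(segment_document(structure(list(text = "", title = "",
                                               abstract = ""),
                                          class = "docrel_document")))
})

test_that("sentence breaks inside a mention span are suppressed", {
  title <- "T."
  body <- "Drug St. John extract works. Next sentence here."
  text <- paste(title, body)
  m <- mention_rows(text, "St. John extract", "C9", "Chemical")
  doc <- make_doc("d", title, body, m)
  # without suppression "St." would end a sentence; the mention must sit in
  # exactly one sentence
  expect_equal(nrow(doc$mentions), 1L)
  expect_false(is.na(doc$mentions$sentence[1]))
  s <- doc$sentences[[doc$mentions$sentence[1]]]
  expect_true(doc$mentions$start[1] >= s$start && doc$mentions$end[1] <= s$end)
})

test_that("every mention of a segmented corpus maps to exactly one sentence", {
  corpus <- generate_corpus(synth_config(n_docs = 5, seed = 9))$corpus
  for (doc in corpus$documents) {
    m <- doc$mentions
    expect_false(any(is.na(m$sentence)))
    for (r in seq_len(nrow(m))) {
      s <- doc$sentences[[m$sentence[r]]]
      expect_true(m$start[r] >= s$start && m$end[r] <= s$end)
    }
  }
})

test_that("candidate pairs are ordered, typed and never reflexive", {
  text <- "T. ENTA here with ENTB and ENTC now."
  m <- rbind(mention_rows(text, "ENTA", "C1", "Chemical"),
             mention_rows(text, "ENTB", "C2", "Chemical"),
             mention_rows(text, "ENTC", "D1", "Disease"))
  doc <- make_doc("d", "T.", "ENTA here with ENTB and ENTC now.", m)
  pairs <- enumerate_candidate_pairs(doc, "Chemical", "Disease")
  expect_equal(nrow(pairs), 2L)
  expect_setequal(pairs$head, c("C1", "C2"))
  expect_true(all(pairs$tail == "D1"))
  expect_true(all(pairs$label == "null"))
  all_pairs <- enumerate_candidate_pairs(doc)
  expect_equal(nrow(all_pairs), 6L)           # 3 * 2 ordered, no self pairs
  expect_false(any(all_pairs$head == all_pairs$tail))
})

test_that("hypernym filtering keeps only the most specific predictions", {
  hier <- data.frame(child = "Cchild", parent = "C",
                     stringsAsFactors = FALSE)
  pred <- data.frame(doc_id = "d", head = c("C", "Cchild"), label = "causes",
                     tail = "D", stringsAsFactors = FALSE)
  out <- hypernym_filter(pred, hier)
  expect_equal(out$head, "Cchild")
  # empty hierarchy leaves predictions unchanged
  expect_equal(hypernym_filter(pred, hier[0, ]), pred)
  # idempotent
  expect_equal(hypernym_filter(out, hier), out)
})

test_that("hypernym filtering matches a brute-force ancestor-chain filter", {
  set.seed(14)
  ids <- sprintf("N%02d", 1:12)
  hier <- data.frame(child = ids[2:12],
                     parent = ids[pmax(1, (2:12) %/% 2)],
                     stringsAsFactors = FALSE)
  anc <- function(x) {
    out <- character()
    while (x %in% hier$child) {
      x <- hier$parent[match(x, hier$child)]
      out <- c(out, x)
    }
    out
  }
  for (rep in 1:5) {
    pred <- unique(data.frame(
      doc_id = sample(c("a", "b"), 20, TRUE),
      head = sample(ids, 20, TRUE), label = "rel",
      tail = sample(ids, 20, TRUE), stringsAsFactors = FALSE))
    pred <- pred[pred$head != pred$tail, ]
    keep <- vapply(seq_len(nrow(pred)), function(r) {
      others <- pred[pred$doc_id == pred$doc_id[r], ]
      !any(others$tail == pred$tail[r] &
             vapply(others$head, function(h) pred$head[r] %in% anc(h), TRUE)) &&
        !any(others$head == pred$head[r] &
               vapply(others$tail, function(t) pred$tail[r] %in% anc(t), TRUE))
    }, TRUE)
    brute <- pred[keep, ]
    rownames(brute) <- NULL
    expect_equal(hypernym_filter(pred, hier), brute)
  }
})

test_that("hierarchy cycles are rejected", {
  hier <- data.frame(child = c("A", "B"), parent = c("B", "A"),
                     stringsAsFactors = FALSE)
  expect_error(hypernym_filter(
    data.frame(doc_id = "d", head = "A", label = "x", tail = "C",
               stringsAsFactors = FALSE), hier), "cycle")
})

test_that("triple-store preprocessing removes missing entities and self-relations", {
  out <- generate_corpus(synth_config(n_docs = 4, seed = 31))
  corpus <- out$corpus
  # add a self-relation to the first document
  d1 <- names(corpus$documents)[1]
  eid <- corpus$documents[[d1]]$mentions$entity_id[1]
  corpus$documents[[d1]]$gold <- rbind(
    corpus$documents[[d1]]$gold,
    data.frame(head = eid, label = "causes", tail = eid,
               stringsAsFactors = FALSE))
  mentioned <- unique(unlist(lapply(corpus$documents,
                                    function(d) d$mentions$entity_id)))
  keep <- mentioned[seq_len(floor(length(mentioned) / 2))]
  filtered <- chr_preprocess(corpus, keep)
  left <- unique(unlist(lapply(filtered$documents,
                               function(d) d$mentions$entity_id)))
  expect_true(all(left %in% keep))
  for (doc in filtered$documents) {
    expect_false(any(doc$gold$head == doc$gold$tail))
    expect_true(all(c(doc$gold$head, doc$gold$tail) %in% keep))
  }
  # planted removal counts: every mention of a dropped entity is gone
  dropped <- setdiff(mentioned, keep)
  n_dropped <- sum(vapply(corpus$documents,
                          function(d) sum(d$mentions$entity_id %in% dropped), 0L))
  n_before <- sum(vapply(corpus$documents, function(d) nrow(d$mentions), 0L))
  n_after <- sum(vapply(filtered$documents, function(d) nrow(d$mentions), 0L))
  expect_equal(n_before - n_after, n_dropped)
})
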
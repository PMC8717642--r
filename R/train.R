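# Model fitting, prediction and the evaluation protocol.

# most frequent head/tail entity types among gold relations, or NULLs
.infer_pair_types <- function(corpus) {
  ht <- tt <- character()
  for (doc in corpus$documents) {
    if (!nrow(doc$gold)) next
    ty <- function(id) doc$mentions$entity_type[match(id, doc$mentions$entity_id)]
    ht <- c(ht, ty(doc$gold$head))
    tt <- c(tt, ty(doc$gold$tail))
  }
  ht <- ht[!is.na(ht)]; tt <- tt[!is.na(tt)]
  if (!length(ht)) return(list(head = NULL, tail = NULL))
  list(head = names(sort(table(ht), decreasing = TRUE))[1L],
       tail = names(sort(table(tt), decreasing = TRUE))[1L])
}

.corpus_vocab <- function(corpus) {
  sort(unique(unlist(lapply(corpus$documents, function(doc) {
    unlist(lapply(doc$sentences, function(s) s$tokens$token))
  }))))
}

.pn_values <- function(pn) {
  lapply(pn, function(x) {
    if (is_ad(x)) x$val else lapply(x, function(y) y$val)
  })
}

.adam_init <- function(leaves) {
  list(m = lapply(leaves, function(l) l$val * 0),
       v = lapply(leaves, function(l) l$val * 0), t = 0L)
}

.adam_step <- function(leaves, st, lr, clip, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  sq <- 0
  for (l in leaves) if (!is.null(l$grad)) sq <- sq + sum(l$grad^2)
  scale <- if (sq > clip^2) clip / sqrt(sq) else 1
  st$t <- st$t + 1L
  for (i in seq_along(leaves)) {
    l <- leaves[[i]]
    if (is.null(l$grad)) next
    g <- l$grad * scale
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g^2
    mh <- st$m[[i]] / (1 - b1^st$t)
    vh <- st$v[[i]] / (1 - b2^st$t)
    l$val <- l$val - lr * mh / (sqrt(vh) + eps)
  }
  st
}

# argmax predictions for a list of document caches under parameter nodes
.predict_cached <- function(caches, pn, control, providers, label_set) {
  out <- list()
  for (cache in caches) {
    fw <- .model_forward(cache, pn, control, providers, with_loss = FALSE)
    probs <- fw$probs$val
    li <- max.col(probs, ties.method = "first")
    out[[length(out) + 1L]] <- data.frame(
      doc_id = cache$doc$doc_id, head = cache$pairs$head,
      tail = cache$pairs$tail, label = label_set[li],
      prob = probs[cbind(seq_along(li), li)], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Fit a document-level relation extraction model
#'
#' Trains the edge-oriented graph model end to end: each document is
#' encoded per sentence, turned into the typed node/edge graph (optionally
#' augmented with knowledge nodes), projected into the initial edge tensor,
#' aggregated by iterated walk steps, and its candidate entity pairs are
#' classified with a softmax; the loss combines cross-entropy with a soft
#' F-measure term.  Parameters are updated per document by Adam with
#' gradient-norm clipping.  With a development corpus, macro progress is
#' monitored and the parameters of the best development F1 epoch are kept.
#'
#' TransE, RESCAL and paragraph-vector providers are pre-trained once and
#' frozen; the graph-attention and recurrent-description providers are
#' trained jointly with the model.
#'
#' @param corpus training `docrel_corpus` (segmented).
#' @param dev optional development corpus, disjoint from `corpus` by doc id.
#' @param kg optional `docrel_kg` (required by KG providers).
#' @param descriptions optional named character vector of entity
#'   descriptions (required by description providers).
#' @param control a [docrel_control()].
#' @param seed integer seed controlling all randomness of the fit.
#' @return an object of class `docrel`; see [predict.docrel()],
#'   [coef.docrel()], [plot.docrel()].
#' @export
docrel <- function(corpus, dev = NULL, kg = NULL, descriptions = NULL,
                   control = docrel_control(), seed = 1) {
  stopifnot(inherits(corpus, "docrel_corpus"))
  if (!length(corpus$documents)) stop("empty training set")
  if (!is.null(dev) &&
      length(intersect(names(corpus$documents), names(dev$documents)))) {
    stop("training and development corpora share document ids")
  }
  set.seed(seed)
  label_set <- corpus$label_set
  if (is.null(control$head_type)) {
    pt <- .infer_pair_types(corpus)
    control$head_type <- pt$head
    control$tail_type <- pt$tail
  }
  vocab <- .corpus_vocab(corpus)
  providers <- list(ks_ids = character(), kd_ids = character())
  kge <- NULL
  if (control$kg_provider != "none") {
    if (is.null(kg)) stop("kg_provider '", control$kg_provider,
                          "' requires a knowledge graph")
    if (control$kg_provider == "transe") {
      kge <- train_transe(kg, dim = control$kg_dim,
                          epochs = control$kg_epochs, seed = seed + 1L)
      providers$ks_mat <- kge$entities
    } else if (control$kg_provider == "rescal") {
      kge <- factorize_rescal(kg, rank = control$kg_dim,
                              epochs = control$kg_epochs, seed = seed + 1L)
      providers$ks_mat <- kge$entities
    } else {
      providers$kg <- kg
    }
    providers$ks_ids <- kg$entities
  }
  desc_vocab <- NULL
  if (control$desc_provider != "none") {
    if (is.null(descriptions)) stop("desc_provider '", control$desc_provider,
                                    "' requires descriptions")
    if (control$desc_provider == "doc2vec") {
      providers$kd_mat <- embed_description_doc2vec(
        descriptions, dim = control$desc_dim, epochs = control$desc_epochs,
        seed = seed + 2L)
    } else {
      providers$desc_tokens <- lapply(descriptions, .desc_tokenize)
      desc_vocab <- sort(unique(unlist(providers$desc_tokens)))
    }
    providers$kd_ids <- names(descriptions)
  }
  params <- docrel_params_init(vocab, label_set, control, seed,
                               desc_vocab = desc_vocab)
  if (control$kg_provider == "gat") {
    params$gat <- gat_params(kg, dim = control$kg_dim, seed = seed + 3L)
  }
  caches <- Filter(Negate(is.null),
                   lapply(corpus$documents, .doc_cache, label_set = label_set,
                          control = control, ks_ids = providers$ks_ids,
                          kd_ids = providers$kd_ids))
  if (!length(caches)) stop("no candidate pairs in the training corpus")
  dev_caches <- if (!is.null(dev)) {
    Filter(Negate(is.null),
           lapply(dev$documents, .doc_cache, label_set = label_set,
                  control = control, ks_ids = providers$ks_ids,
                  kd_ids = providers$kd_ids))
  }
  pn <- .as_pnodes(params, ad_param)
  leaves <- .leaf_nodes(pn)
  opt <- .adam_init(leaves)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        dev_f1 = numeric())
  best <- list(f1 = -Inf, epoch = NA_integer_, values = NULL)
  for (ep in seq_len(control$epochs)) {
    tot <- 0
    for (ci in sample.int(length(caches))) {
      ad_zero_grad(leaves)
      fw <- .model_forward(caches[[ci]], pn, control, providers)
      ad_backward(fw$loss)
      opt <- .adam_step(leaves, opt, control$lr, control$clip)
      tot <- tot + fw$loss$val
    }
    dev_f1 <- NA_real_
    if (!is.null(dev_caches) &&
        (ep %% control$eval_every == 0L || ep == control$epochs)) {
      pred <- .predict_cached(dev_caches, pn, control, providers, label_set)
      m <- evaluate_relations(pred, dev)
      dev_f1 <- m$table["overall", "F1"]
      if (dev_f1 > best$f1) {
        best <- list(f1 = dev_f1, epoch = ep, values = .pn_values(pn))
      }
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = tot / length(caches),
                                dev_f1 = dev_f1))
    if (control$verbose) {
      message(sprintf("epoch %3d  loss %.4f  dev F1 %s", ep,
                      tot / length(caches),
                      ifelse(is.na(dev_f1), "-", sprintf("%.1f", dev_f1))))
    }
  }
  final <- if (!is.null(best$values)) best$values else .pn_values(pn)
  structure(list(params = final, control = control, label_set = label_set,
                 providers = providers, kge = kge, history = history,
                 best_epoch = if (!is.na(best$epoch)) best$epoch else
                   control$epochs,
                 seed = seed),
            class = "docrel")
}

#' Predict relations for a corpus
#'
#' Runs the fitted model over every document and labels each candidate
#' entity pair; when a hierarchy is supplied, hypernym filtering demotes
#' predicted positives that have a more specific (descendant-entity)
#' competitor in the same document to the null label.
#'
#' @param object a fitted `docrel` model.
#' @param corpus a segmented `docrel_corpus`.
#' @param hierarchy optional `child`/`parent` data frame.
#' @param ... unused.
#' @return data frame `doc_id`, `head`, `tail`, `label`, `prob` covering
#'   every candidate pair.
#' @export
predict.docrel <- function(object, corpus, hierarchy = NULL, ...) {
  control <- object$control
  caches <- Filter(Negate(is.null),
                   lapply(corpus$documents, .doc_cache,
                          label_set = object$label_set, control = control,
                          ks_ids = object$providers$ks_ids,
                          kd_ids = object$providers$kd_ids))
  pn <- .as_pnodes(object$params, ad_const)
  pred <- .predict_cached(caches, pn, control, object$providers,
                          object$label_set)
  if (!is.null(hierarchy) && nrow(pred)) {
    null_label <- object$label_set[1L]
    pos <- pred$label != null_label
    kept <- hypernym_filter(pred[pos, , drop = FALSE], hierarchy)
    kept_key <- paste(kept$doc_id, kept$head, kept$tail)
    all_key <- paste(pred$doc_id, pred$head, pred$tail)
    pred$label[pos & !(all_key %in% kept_key)] <- null_label
  }
  pred
}

#' Write / read positive predictions as TSV
#'
#' One line per predicted positive pair: `doc_id<TAB>head<TAB>label<TAB>tail`.
#'
#' @param predictions prediction data frame from [predict.docrel()].
#' @param path file path.
#' @param null_label label regarded as "no relation".
#' @return `path` (writer) / prediction data frame (reader).
#' @export
write_predictions <- function(predictions, path, null_label = NULL_LABEL) {
  pos <- predictions[predictions$label != null_label, , drop = FALSE]
  lines <- if (nrow(pos)) {
    paste(pos$doc_id, pos$head, pos$label, pos$tail, sep = "\t")
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(doc_id = character(), head = character(),
                      label = character(), tail = character(),
                      stringsAsFactors = FALSE))
  }
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(doc_id = f[, 1L], head = f[, 2L], label = f[, 3L],
             tail = f[, 4L], stringsAsFactors = FALSE)
}

#' F-measure from precision and recall
#'
#' \eqn{F_1 = 2PR / (P + R)} (0 when P + R = 0), on whatever scale P and R
#' share (fractions or percentages).
#'
#' @param p,r precision and recall.
#' @return the harmonic mean.
#' @export
f_measure <- function(p, r) {
  ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}

#' Evaluate predictions against a gold-annotated corpus
#'
#' Positive-class precision, recall and F1 (as percentages), computed
#' overall and restricted to intra- and inter-sentence pairs; the locality
#' restriction applies to predictions and gold alike.
#'
#' @param predictions data frame `doc_id`, `head`, `tail`, `label` (rows
#'   with the null label are ignored; pairs must exist in the document).
#' @param corpus gold corpus.
#' @return object of class `docrel_metrics` with a 3 x 3 `table`
#'   (overall/intra/inter x P/R/F1) and the underlying counts.
#' @export
evaluate_relations <- function(predictions, corpus) {
  null_label <- corpus$label_set[1L]
  counts <- matrix(0L, 3L, 3L,
                   dimnames = list(c("overall", "intra", "inter"),
                                   c("TP", "FP", "FN")))
  pos <- predictions[predictions$label != null_label, , drop = FALSE]
  for (doc in corpus$documents) {
    p <- pos[pos$doc_id == doc$doc_id, , drop = FALSE]
    ents <- document_entities(doc)
    if (nrow(p) && !all(p$head %in% ents$entity_id & p$tail %in% ents$entity_id)) {
      stop("prediction references an unknown entity in doc ", doc$doc_id)
    }
    pkey <- paste(p$head, p$label, p$tail)
    gkey <- paste(doc$gold$head, doc$gold$label, doc$gold$tail)
    loc_p <- vapply(seq_len(nrow(p)), function(r) {
      split_intra_inter(doc, p$head[r], p$tail[r])
    }, "")
    loc_g <- vapply(seq_len(nrow(doc$gold)), function(r) {
      split_intra_inter(doc, doc$gold$head[r], doc$gold$tail[r])
    }, "")
    for (scope in rownames(counts)) {
      pk <- pkey[scope == "overall" | loc_p == scope]
      gk <- gkey[scope == "overall" | loc_g == scope]
      counts[scope, "TP"] <- counts[scope, "TP"] + length(intersect(pk, gk))
      counts[scope, "FP"] <- counts[scope, "FP"] + length(setdiff(pk, gk))
      counts[scope, "FN"] <- counts[scope, "FN"] + length(setdiff(gk, pk))
    }
  }
  tab <- t(apply(counts, 1L, function(x) {
    x <- unname(x)
    p <- if (x[1L] + x[2L] > 0) 100 * x[1L] / (x[1L] + x[2L]) else 0
    r <- if (x[1L] + x[3L] > 0) 100 * x[1L] / (x[1L] + x[3L]) else 0
    c(P = p, R = r, F1 = f_measure(p, r))
  }))
  structure(list(table = tab, counts = counts), class = "docrel_metrics")
}

#' @export
print.docrel_metrics <- function(x, ...) {
  cat("Relation extraction metrics (%)\n")
  print(round(x$table, 1))
  invisible(x)
}

#' Metrics as JSON
#'
#' @param metrics a `docrel_metrics`.
#' @param path optional output file.
#' @return JSON string with `overall`/`intra`/`inter` blocks of P/R/F1.
#' @export
metrics_to_json <- function(metrics, path = NULL) {
  obj <- lapply(rownames(metrics$table), function(s) {
    as.list(metrics$table[s, ])
  })
  names(obj) <- rownames(metrics$table)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Merge corpora
#' @param ... `docrel_corpus` objects with disjoint document ids.
#' @return the merged corpus.
#' @export
merge_corpora <- function(...) {
  cs <- list(...)
  docs <- do.call(c, lapply(cs, function(x) x$documents))
  if (anyDuplicated(names(docs))) stop("duplicate document ids")
  labels <- unique(unlist(lapply(cs, function(x) x$label_set[-1L])))
  structure(list(documents = docs, label_set = c(cs[[1L]]$label_set[1L],
                                                 sort(labels))),
            class = "docrel_corpus")
}

#' Train / develop / retrain evaluation protocol
#'
#' Fits on the training set while monitoring the development set, selects
#' the best development epoch, retrains with the same hyper-parameters on
#' the union of training and development sets for that many epochs, and
#' reports test-set metrics -- all in one call.
#'
#' @param train,dev,test disjoint corpora.
#' @param kg,descriptions,control,seed as in [docrel()].
#' @param hierarchy optional hierarchy for prediction-time hypernym
#'   filtering.
#' @return list with `model` (the retrained model), `selection` (the
#'   monitored history), `best_epoch`, `predictions` and `metrics`.
#' @export
docrel_protocol <- function(train, dev, test, kg = NULL, descriptions = NULL,
                            hierarchy = NULL, control = docrel_control(),
                            seed = 1) {
  sel <- docrel(train, dev, kg = kg, descriptions = descriptions,
                control = control, seed = seed)
  control$epochs <- sel$best_epoch
  model <- docrel(merge_corpora(train, dev), kg = kg,
                  descriptions = descriptions, control = control, seed = seed)
  pred <- predict(model, test, hierarchy = hierarchy)
  metrics <- evaluate_relations(pred, test)
  list(model = model, selection = sel$history, best_epoch = sel$best_epoch,
       predictions = pred, metrics = metrics)
}

# ---- S3 methods -------------------------------------------------------------

#' @export
print.docrel <- function(x, ...) {
  cat("Document-level relation extraction model (edge-oriented graph)\n")
  cat("  labels:   ", paste(x$label_set, collapse = ", "), "\n", sep = "")
  cat("  knowledge: kg=", x$control$kg_provider, ", desc=",
      x$control$desc_provider, "\n", sep = "")
  cat("  walks:     length ", x$control$final_length, ", alpha ",
      x$control$alpha, "\n", sep = "")
  cat("  training:  ", max(x$history$epoch), " epochs, final loss ",
      sprintf("%.4f", utils::tail(x$history$loss, 1L)), "\n", sep = "")
  if (any(!is.na(x$history$dev_f1))) {
    cat("  dev F1:    ", sprintf("%.1f", max(x$history$dev_f1, na.rm = TRUE)),
        " (epoch ", x$best_epoch, ")\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.docrel <- function(object, ...) {
  np <- sum(vapply(.leaf_nodes(.as_pnodes(object$params, ad_const)),
                   function(n) length(n$val), 0))
  cat("Fitted document-level relation extraction model\n\n")
  print(object)
  cat("  parameters:", np, "\n")
  cat("  vocabulary:", nrow(object$params$emb), "tokens\n")
  invisible(object)
}

#' Model coefficients
#'
#' @param object a fitted `docrel` model.
#' @param ... unused.
#' @return the named list of numeric parameter arrays (embedding table,
#'   encoder, node-type and distance embeddings, per-edge-type transforms,
#'   walk matrix, classifier).
#' @export
coef.docrel <- function(object, ...) object$params

#' Plot training history
#'
#' @param x a fitted `docrel` model.
#' @param ... passed to [plot()].
#' @export
plot.docrel <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  if (any(!is.na(h$dev_f1))) {
    ok <- !is.na(h$dev_f1)
    graphics::par(new = TRUE)
    graphics::plot(h$epoch[ok], h$dev_f1[ok], type = "b", col = "red",
                   axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4L)
    graphics::mtext("dev F1 (%)", side = 4L, line = 2L, col = "red")
  }
  invisible(x)
}
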
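# Synthetic corpus / knowledge-graph generator with planted relational
# structure.  Documents are built from pseudo-words so tokenization is
# trivial and offsets exact; positive entity pairs are realized either by a
# co-sentential trigger pattern (intra) or a mediated two-sentence pattern
# (inter), and a configurable fraction of positives is recoverable only
# through a planted knowledge-graph link (no textual trigger).

#' Generator configuration
#'
#' @param n_docs number of documents.
#' @param sentences_range min/max body sentences per document.
#' @param vocab_size number of distinct noise pseudo-words.
#' @param n_entities size of the global entity registry (half chemicals,
#'   half diseases).
#' @param entities_per_doc min/max entities mentioned per document.
#' @param n_relations number of relation types in the generated knowledge
#'   graph (3 for the "mesh" regime, 9 for "biochem").
#' @param p_positive probability that an ordered chemical-disease registry
#'   pair is a globally related fact; documents mentioning both entities of
#'   a related pair carry it as a gold relation.
#' @param p_inter fraction of positives realized inter-sententially (their
#'   entities never co-occur in a sentence).
#' @param kg_signal_strength probability that a positive pair is linked in
#'   the knowledge graph.
#' @param p_kg_only fraction of KG-linked positives realized without any
#'   textual trigger, so their recoverability depends on the knowledge
#'   graph.
#' @param noise_rate probability that a negative pair receives a spurious
#'   trigger pattern (label noise).
#' @param kg_regime `"mesh"` (few relation types, about one neighbor per
#'   entity) or `"biochem"` (nine relation types, about three neighbors per
#'   entity).
#' @param seed mandatory integer seed; generation is deterministic given it.
#' @return a list of class `docrel_synth_config`.
#' @export
synth_config <- function(n_docs = 50, sentences_range = c(3, 6),
                         vocab_size = 40, n_entities = 40,
                         entities_per_doc = c(3, 5),
                         n_relations = NULL,
                         p_positive = 0.35, p_inter = 0.3,
                         kg_signal_strength = 0.9, p_kg_only = 0.4,
                         noise_rate = 0,
                         kg_regime = c("mesh", "biochem"), seed) {
  if (missing(seed)) stop("seed is mandatory")
  kg_regime <- match.arg(kg_regime)
  if (is.null(n_relations)) n_relations <- if (kg_regime == "mesh") 3L else 9L
  probs <- c(p_positive, p_inter, kg_signal_strength, p_kg_only, noise_rate)
  stopifnot(all(probs >= 0), all(probs <= 1), n_entities >= 4,
            length(sentences_range) == 2L)
  if (p_inter > 0 && sentences_range[2L] < 2L) {
    stop("infeasible config: p_inter > 0 with single-sentence documents")
  }
  structure(list(n_docs = n_docs, sentences_range = sentences_range,
                 vocab_size = vocab_size, n_entities = n_entities,
                 entities_per_doc = entities_per_doc,
                 n_relations = n_relations, p_positive = p_positive,
                 p_inter = p_inter, kg_signal_strength = kg_signal_strength,
                 p_kg_only = p_kg_only, noise_rate = noise_rate,
                 kg_regime = kg_regime, seed = as.integer(seed)),
            class = "docrel_synth_config")
}

.synth_registry <- function(config) {
  nch <- ceiling(config$n_entities / 2)
  nds <- config$n_entities - nch
  data.frame(
    entity_id = c(sprintf("C%03d", seq_len(nch)), sprintf("D%03d", seq_len(nds))),
    entity_type = c(rep("Chemical", nch), rep("Disease", nds)),
    surface = c(sprintf("ENTC%03d", seq_len(nch)), sprintf("ENTD%03d", seq_len(nds))),
    stringsAsFactors = FALSE)
}

.noise_word <- function(config) sprintf("W%03d", sample.int(config$vocab_size, 1L))

.sample_range <- function(lo, hi) if (lo >= hi) as.integer(lo) else sample(lo:hi, 1L)

#' Generate a synthetic corpus with planted relations
#'
#' Each document has a one-sentence title chapter and a body chapter.
#' Positive chemical-disease pairs are realized intra-sententially (both
#' mentions plus a trigger token in one sentence), inter-sententially (head
#' and tail mentions in different sentences carrying a mediated source /
#' target trigger pattern), or -- for the KG-dependent fraction -- without
#' any trigger at all.  The manifest records every planted pair with its
#' locality and KG dependence, plus candidate-pair totals.
#'
#' @param config a [synth_config()].
#' @param dir optional directory; when given, `corpus.pubtator` and
#'   `manifest.json` are written there.
#' @return list with `corpus` (a segmented `docrel_corpus`), `manifest`, and
#'   `paths` (when `dir` was given).
#' @export
generate_corpus <- function(config, dir = NULL) {
  set.seed(config$seed)
  reg <- .synth_registry(config)
  # Global ground truth, drawn once.  The planted etiology is
  # attribute-factorized: a chemical is either hazardous or inert, a disease
  # either chemically inducible or not, and a hazardous chemical causes an
  # inducible disease.  Attribute rates are chosen so that a random ordered
  # chemical-disease pair is related with probability p_positive.  The
  # knowledge graph records each related fact with probability
  # kg_signal_strength; documents realize the facts they mention.
  pa <- sqrt(config$p_positive)
  hazardous <- stats::runif(sum(reg$entity_type == "Chemical")) < pa
  inducible <- stats::runif(sum(reg$entity_type == "Disease")) < pa
  names(hazardous) <- reg$entity_id[reg$entity_type == "Chemical"]
  names(inducible) <- reg$entity_id[reg$entity_type == "Disease"]
  truth <- expand.grid(head = reg$entity_id[reg$entity_type == "Chemical"],
                       tail = reg$entity_id[reg$entity_type == "Disease"],
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth$related <- hazardous[truth$head] & inducible[truth$tail]
  truth$kg_linked <- truth$related &
    stats::runif(nrow(truth)) < config$kg_signal_strength
  tkey <- paste(truth$head, truth$tail)
  docs <- list()
  mdocs <- list()
  for (d in seq_len(config$n_docs)) {
    doc_id <- sprintf("SYN%04d", d)
    ne <- .sample_range(config$entities_per_doc[1L], config$entities_per_doc[2L])
    chems <- reg[reg$entity_type == "Chemical", ]
    diss <- reg[reg$entity_type == "Disease", ]
    nch <- max(1L, min(nrow(chems), if (ne > 2L) sample.int(ne - 1L, 1L) else 1L))
    nds <- max(1L, min(nrow(diss), ne - nch))
    ents <- rbind(chems[sample.int(nrow(chems), nch), ],
                  diss[sample.int(nrow(diss), nds), ])
    pairs <- expand.grid(head = ents$entity_id[ents$entity_type == "Chemical"],
                         tail = ents$entity_id[ents$entity_type == "Disease"],
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ti <- match(paste(pairs$head, pairs$tail), tkey)
    pairs$positive <- truth$related[ti]
    pairs$kg_linked <- truth$kg_linked[ti]
    pairs$inter <- pairs$positive & stats::runif(nrow(pairs)) < config$p_inter
    pairs$kg_only <- pairs$kg_linked & stats::runif(nrow(pairs)) < config$p_kg_only
    pairs$noisy <- !pairs$positive & stats::runif(nrow(pairs)) < config$noise_rate
    # sentence slots; each records its tokens and the mentions it hosts
    slots <- list()
    push_slot <- function(tokens, ments) {
      slots[[length(slots) + 1L]] <<- list(tokens = tokens, ments = ments)
    }
    surf <- function(id) reg$surface[match(id, reg$entity_id)]
    pad <- function() replicate(sample(1:2, 1L), .noise_word(config))
    placed <- character()
    for (r in which(pairs$positive | pairs$noisy)) {
      h <- pairs$head[r]; t <- pairs$tail[r]
      trig <- !pairs$kg_only[r] || pairs$noisy[r]
      if (pairs$inter[r]) {
        push_slot(c(pad(), surf(h), if (trig) "Trigsrc"),
                  data.frame(entity_id = h, pos = NA, stringsAsFactors = FALSE))
        push_slot(c(if (trig) "Trigdst", surf(t), pad()),
                  data.frame(entity_id = t, pos = NA, stringsAsFactors = FALSE))
      } else {
        push_slot(c(pad(), surf(h), if (trig) "Causes" else pad(), surf(t),
                    pad()),
                  data.frame(entity_id = c(h, t), pos = NA,
                             stringsAsFactors = FALSE))
      }
      placed <- c(placed, h, t)
    }
    # negative pairs co-occur in a sentence at the same rate as intra
    # positives, so bare co-occurrence carries no label information; their
    # slot shape matches the trigger-less (KG-dependent) positive pattern
    neg_rows <- which(!pairs$positive & !pairs$noisy &
                        stats::runif(nrow(pairs)) < 1 - config$p_inter)
    for (r in neg_rows) {
      h <- pairs$head[r]; t <- pairs$tail[r]
      push_slot(c(pad(), surf(h), pad(), surf(t), pad()),
                data.frame(entity_id = c(h, t), pos = NA,
                           stringsAsFactors = FALSE))
      placed <- c(placed, h, t)
    }
    # background mentions for entities not placed by any pattern
    for (id in setdiff(ents$entity_id, placed)) {
      push_slot(c(pad(), surf(id), pad()),
                data.frame(entity_id = id, pos = NA, stringsAsFactors = FALSE))
    }
    # inter-pair entities must never co-occur: keep one mention per slot and
    # shuffle slots, then pad with pure-noise sentences
    slots <- sample(slots)
    ns_target <- .sample_range(config$sentences_range[1L], config$sentences_range[2L])
    while (length(slots) < ns_target) {
      push_slot(replicate(3L, .noise_word(config)), NULL)
      slots <- sample(slots)
    }
    # assemble text
    title <- paste("Record", .noise_word(config), "study.")
    abstract_tokens <- character()
    mention_rows <- list()
    planted_sent <- list()
    offset <- nchar(title) + 1L   # abstract starts after "title "
    cursor <- offset
    for (si in seq_along(slots)) {
      toks <- c(slots[[si]]$tokens, ".")
      for (tk in toks) {
        is_mention <- grepl("^ENT", tk)
        if (is_mention) {
          id <- reg$entity_id[match(tk, reg$surface)]
          mention_rows[[length(mention_rows) + 1L]] <- data.frame(
            start = cursor, end = cursor + nchar(tk), surface = tk,
            entity_id = id,
            entity_type = reg$entity_type[match(id, reg$entity_id)],
            stringsAsFactors = FALSE)
          planted_sent[[length(planted_sent) + 1L]] <-
            data.frame(entity_id = id, sentence = si + 1L,
                       stringsAsFactors = FALSE)
        }
        abstract_tokens <- c(abstract_tokens, tk)
        cursor <- cursor + nchar(tk) + 1L
      }
    }
    abstract <- paste(abstract_tokens, collapse = " ")
    mentions <- do.call(rbind, mention_rows)
    gold <- pairs[pairs$positive | pairs$noisy, c("head", "tail"), drop = FALSE]
    gold <- data.frame(head = gold$head,
                       label = rep("causes", nrow(gold)), tail = gold$tail,
                       stringsAsFactors = FALSE)
    doc <- structure(list(doc_id = doc_id, title = title, abstract = abstract,
                          text = paste(title, abstract, sep = " "),
                          mentions = mentions, gold = gold, sentences = NULL),
                     class = "docrel_document")
    doc <- segment_document(doc)
    docs[[doc_id]] <- doc
    # generator-side locality bookkeeping from the planted sentence indices
    ps <- do.call(rbind, planted_sent)
    loc_of <- function(h, t) {
      if (length(intersect(ps$sentence[ps$entity_id == h],
                           ps$sentence[ps$entity_id == t]))) "intra" else "inter"
    }
    pairs$locality <- vapply(seq_len(nrow(pairs)),
                             function(r) loc_of(pairs$head[r], pairs$tail[r]), "")
    mdocs[[doc_id]] <- list(
      doc_id = doc_id, n_sentences = length(slots) + 1L,
      entities = ents$entity_id,
      pairs = pairs[, c("head", "tail", "positive", "locality", "kg_linked",
                        "kg_only", "noisy")])
  }
  all_pairs <- do.call(rbind, lapply(mdocs, function(x) x$pairs))
  gold_mask <- all_pairs$positive | all_pairs$noisy
  manifest <- list(
    config = unclass(config),
    truth = truth,
    attributes = list(hazardous = hazardous, inducible = inducible),
    totals = list(
      n_doc = length(docs),
      n_positive = sum(gold_mask),
      n_positive_inter = sum(gold_mask & all_pairs$locality == "inter"),
      n_negative = sum(!gold_mask),
      n_negative_inter = sum(!gold_mask & all_pairs$locality == "inter"),
      n_kg_linked = sum(all_pairs$kg_linked),
      n_kg_only = sum(all_pairs$kg_only)),
    docs = mdocs)
  corpus <- structure(list(documents = docs, label_set = c(NULL_LABEL, "causes")),
                      class = "docrel_corpus")
  out <- list(corpus = corpus, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cp <- file.path(dir, "corpus.pubtator")
    mp <- file.path(dir, "manifest.json")
    write_pubtator(corpus, cp)
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA), mp)
    out$paths <- c(corpus = cp, manifest = mp)
  }
  out
}

#' Generate a synthetic knowledge graph, hierarchy and descriptions
#'
#' Triples link the KG-linked planted positive pairs through a dedicated
#' causal relation; background triples over random entity pairs are added
#' until the regime's target connectivity is reached ("mesh": about one
#' neighbor per entity and 3 relation types; "biochem": about three
#' neighbors per entity and 9 relation types).  The hierarchy contains
#' hypernym chains over the chemical and disease registries, and every
#' entity receives a description whose tokens indicate its type and whether
#' it participates in a causal relation.
#'
#' @param config a [synth_config()].
#' @param manifest manifest from [generate_corpus()] (for the planted
#'   links); `NULL` gives a label-independent knowledge graph.
#' @param dir optional output directory (`triples.tsv`, `hierarchy.tsv`,
#'   `descriptions.tsv`).
#' @return list with `kg` (a `docrel_kg`), `hierarchy` (data frame),
#'   `descriptions` (named character vector) and `paths` (when `dir` given).
#' @export
generate_kg <- function(config, manifest = NULL, dir = NULL) {
  set.seed(config$seed + 1L)
  reg <- .synth_registry(config)
  n <- nrow(reg)
  target_degree <- if (config$kg_regime == "mesh") 1 else 3
  triples <- list()
  seen <- character()
  add_triple <- function(h, r, t) {
    key <- paste(h, r, t)
    if (key %in% seen) return(invisible(FALSE))
    seen <<- c(seen, key)
    triples[[length(triples) + 1L]] <<- data.frame(
      head = h, relation = r, tail = t, stringsAsFactors = FALSE)
    invisible(TRUE)
  }
  linked <- character()
  if (!is.null(manifest)) {
    for (dm in manifest$docs) {
      p <- dm$pairs
      if (!is.data.frame(p)) p <- as.data.frame(do.call(rbind, lapply(p, as.data.frame)))
      for (r in which(p$kg_linked)) {
        add_triple(p$head[r], "rel1", p$tail[r])
        linked <- c(linked, p$head[r], p$tail[r])
      }
    }
  }
  n_target <- ceiling(target_degree * n / 2)
  rels <- sprintf("rel%d", seq_len(config$n_relations))
  guard <- 0L
  while (length(triples) < n_target && guard < 50L * n_target) {
    guard <- guard + 1L
    ht <- sample.int(n, 2L)
    # background links never use the causal relation, so a label-independent
    # graph (manifest = NULL) carries no spurious pair signal
    bg_rels <- if (length(rels) > 1L) rels[-1L] else rels
    add_triple(reg$entity_id[ht[1L]], sample(bg_rels, 1L), reg$entity_id[ht[2L]])
  }
  kg <- as_kg(do.call(rbind, triples))
  # hypernym chains: within each type, entity 2k is a child of entity 2k-1
  hier <- list()
  for (ty in unique(reg$entity_type)) {
    ids <- reg$entity_id[reg$entity_type == ty]
    for (k in seq_len(floor(length(ids) / 2))) {
      hier[[length(hier) + 1L]] <- data.frame(
        child = ids[2L * k], parent = ids[2L * k - 1L],
        stringsAsFactors = FALSE)
    }
  }
  hierarchy <- do.call(rbind, hier)
  causal <- unique(linked)
  descriptions <- vapply(seq_len(n), function(i) {
    id <- reg$entity_id[i]
    paste(tolower(reg$entity_type[i]),
          if (id %in% causal) "active causal agent" else "inert background compound",
          sprintf("token%02d", i %% 7L + 1L))
  }, "")
  names(descriptions) <- reg$entity_id
  out <- list(kg = kg, hierarchy = hierarchy, descriptions = descriptions)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    tp <- file.path(dir, "triples.tsv")
    hp <- file.path(dir, "hierarchy.tsv")
    dp <- file.path(dir, "descriptions.tsv")
    write_triples(kg, tp)
    utils::write.table(hierarchy, hp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(names(descriptions), descriptions), dp,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    out$paths <- c(triples = tp, hierarchy = hp, descriptions = dp)
  }
  out
}
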
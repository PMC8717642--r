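# PubTator-style corpus reading/writing, document segmentation, candidate
# pair enumeration and dataset-specific preprocessing.

NULL_LABEL <- "null"

#' Read a PubTator-style corpus
#'
#' Parses span-annotated abstracts in the plain-text PubTator format used by
#' the chemical-disease relation corpora: per document a `ID|t|title` line, an
#' `ID|a|abstract` line, then TAB-separated mention lines
#' (`ID start end surface type entity_id`) and document-level relation lines
#' (`ID label entity1 entity2`), with blank lines separating documents.
#'
#' The document text is the title and abstract joined by a single space;
#' mention offsets are 0-based, half-open, and validated against the text.
#' Composite entity identifiers (`"D001|D002"`) are split into one mention
#' copy per identifier, and mentions with entity id `"-1"` are dropped.
#'
#' @param path path to a PubTator text file.
#' @param segment logical; if `TRUE` (default) each document is also passed
#'   through [segment_document()].
#' @return an object of class `docrel_corpus`: a list with elements
#'   `documents` (named list of `docrel_document`) and `label_set` (character
#'   vector of relation labels whose first element is the null label).
#' @seealso [write_pubtator()], [segment_document()]
#' @export
read_pubtator <- function(path, segment = TRUE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  docs <- list()
  labels <- character()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    mt <- regmatches(lines[i], regexec("^([^|]+)\\|t\\|(.*)$", lines[i]))[[1L]]
    if (length(mt) != 3L) {
      stop("parse error at line ", i, ": expected 'ID|t|...' title line")
    }
    doc_id <- mt[2L]; title <- mt[3L]
    i <- i + 1L
    ma <- if (i <= n) regmatches(lines[i], regexec("^([^|]+)\\|a\\|(.*)$", lines[i]))[[1L]] else character()
    if (length(ma) != 3L || ma[2L] != doc_id) {
      stop("parse error at line ", i, ": expected 'ID|a|...' abstract line for doc ", doc_id)
    }
    abstract <- ma[3L]
    i <- i + 1L
    mention_rows <- list()
    gold_rows <- list()
    while (i <= n && nzchar(trimws(lines[i]))) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
      if (length(f) >= 6L && f[1L] == doc_id && grepl("^[0-9]+$", f[2L])) {
        mention_rows[[length(mention_rows) + 1L]] <-
          list(start = as.integer(f[2L]), end = as.integer(f[3L]),
               surface = f[4L], entity_type = f[5L], entity_id = f[6L])
      } else if (length(f) == 4L && f[1L] == doc_id) {
        gold_rows[[length(gold_rows) + 1L]] <-
          list(label = f[2L], head = f[3L], tail = f[4L])
      } else {
        stop("parse error at line ", i, ": unrecognized annotation line")
      }
      i <- i + 1L
    }
    text <- paste(title, abstract, sep = " ")
    mentions <- if (length(mention_rows)) {
      m <- do.call(rbind, lapply(mention_rows, function(r) {
        ids <- strsplit(r$entity_id, "|", fixed = TRUE)[[1L]]
        do.call(rbind, lapply(ids, function(id) {
          data.frame(start = r$start, end = r$end, surface = r$surface,
                     entity_id = id, entity_type = r$entity_type,
                     stringsAsFactors = FALSE)
        }))
      }))
      m <- m[m$entity_id != "-1", , drop = FALSE]
      rownames(m) <- NULL
      m
    } else {
      data.frame(start = integer(), end = integer(), surface = character(),
                 entity_id = character(), entity_type = character(),
                 stringsAsFactors = FALSE)
    }
    bad <- which(substring(text, mentions$start + 1L, mentions$end) != mentions$surface)
    if (length(bad)) {
      stop("validation error in doc ", doc_id, ": mention span text does not ",
           "match surface for mention(s) ", paste(bad, collapse = ", "))
    }
    gold <- if (length(gold_rows)) {
      g <- do.call(rbind, lapply(gold_rows, function(r) {
        data.frame(head = r$head, label = r$label, tail = r$tail,
                   stringsAsFactors = FALSE)
      }))
      rownames(g) <- NULL
      g
    } else {
      data.frame(head = character(), label = character(), tail = character(),
                 stringsAsFactors = FALSE)
    }
    labels <- union(labels, gold$label)
    doc <- structure(list(doc_id = doc_id, title = title, abstract = abstract,
                          text = text, mentions = mentions, gold = gold,
                          sentences = NULL),
                     class = "docrel_document")
    if (segment) doc <- segment_document(doc)
    docs[[doc_id]] <- doc
  }
  structure(list(documents = docs,
                 label_set = c(NULL_LABEL, sort(labels))),
            class = "docrel_corpus")
}

#' Write a corpus in PubTator format
#'
#' Inverse of [read_pubtator()]: `read_pubtator(write_pubtator(x, f))`
#' reproduces `x` up to segmentation.
#'
#' @param corpus a `docrel_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pubtator <- function(corpus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (doc in corpus$documents) {
    writeLines(c(paste0(doc$doc_id, "|t|", doc$title),
                 paste0(doc$doc_id, "|a|", doc$abstract)), con)
    m <- doc$mentions
    if (nrow(m)) {
      writeLines(paste(doc$doc_id, m$start, m$end, m$surface, m$entity_type,
                       m$entity_id, sep = "\t"), con)
    }
    g <- doc$gold
    if (nrow(g)) {
      writeLines(paste(doc$doc_id, g$label, g$head, g$tail, sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

# sentence-terminal positions (end offsets, 0-based half-open) inside `text`,
# splitting after runs of .!? followed by whitespace and an uppercase letter
# or digit
.sentence_breaks <- function(text) {
  m <- gregexpr("[.!?]+(?=[[:space:]]+[A-Z0-9])", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer())
  as.integer(m + attr(m, "match.length") - 1L)  # 0-based end offset
}

.tokenize <- function(text, offset = 0L) {
  m <- gregexpr("[A-Za-z0-9_']+|[^A-Za-z0-9_'[:space:]]", text)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(token = regmatches(text, list(m))[[1L]],
             start = offset + as.integer(m) - 1L,
             end = offset + as.integer(m) + len - 1L,
             stringsAsFactors = FALSE)
}

#' Segment a document into chapters, sentences and tokens
#'
#' Chapters for abstracts are fixed: chapter 1 is the title, chapter 2 the
#' abstract body.  Sentences are produced by rule-based splitting (terminal
#' punctuation followed by whitespace and an uppercase letter or digit);
#' splits that would fall strictly inside a mention span are suppressed so
#' mention integrity is preserved.  Every mention is assigned its sentence
#' and chapter index and the covering token range.
#'
#' @param doc a `docrel_document` with `title`, `abstract` and `mentions`.
#' @return the document with `sentences` (list of
#'   `list(start, end, chapter, tokens)`) and mention columns `sentence`,
#'   `chapter`, `token_from`, `token_to` filled in.  Indices are 1-based.
#' @export
segment_document <- function(doc) {
  if (!nzchar(doc$text)) stop("empty document text")
  title_len <- nchar(doc$title)
  chapters <- list(list(start = 0L, end = title_len),
                   list(start = title_len + 1L, end = nchar(doc$text)))
  chapters <- Filter(function(ch) ch$end > ch$start, chapters)
  sentences <- list()
  for (ci in seq_along(chapters)) {
    ch <- chapters[[ci]]
    chtext <- substr(doc$text, ch$start + 1L, ch$end)
    breaks <- .sentence_breaks(chtext) + ch$start
    # suppress breaks strictly inside a mention span
    if (nrow(doc$mentions)) {
      keep <- vapply(breaks, function(b) {
        !any(doc$mentions$start < b & b < doc$mentions$end)
      }, TRUE)
      breaks <- breaks[keep]
    }
    bounds <- c(ch$start, breaks, ch$end)
    for (k in seq_len(length(bounds) - 1L)) {
      s0 <- bounds[k]; s1 <- bounds[k + 1L]
      stext <- substr(doc$text, s0 + 1L, s1)
      lead <- nchar(stext) - nchar(sub("^[[:space:]]+", "", stext))
      s0 <- s0 + lead
      if (s1 <= s0) next
      toks <- .tokenize(substr(doc$text, s0 + 1L, s1), offset = s0)
      if (nrow(toks) == 0L) next
      sentences[[length(sentences) + 1L]] <-
        list(start = s0, end = s1, chapter = ci, tokens = toks)
    }
  }
  doc$sentences <- sentences
  m <- doc$mentions
  if (nrow(m)) {
    m$sentence <- NA_integer_; m$chapter <- NA_integer_
    m$token_from <- NA_integer_; m$token_to <- NA_integer_
    for (r in seq_len(nrow(m))) {
      si <- which(vapply(sentences, function(s) {
        m$start[r] >= s$start && m$start[r] < s$end
      }, TRUE))
      if (length(si) != 1L) {
        stop("mention at ", m$start[r], " in doc ", doc$doc_id,
             " not assignable to a sentence")
      }
      s <- sentences[[si]]
      cover <- which(s$tokens$start < m$end[r] & s$tokens$end > m$start[r])
      if (!length(cover)) {
        stop("mention at ", m$start[r], " in doc ", doc$doc_id,
             " covered by no token")
      }
      m$sentence[r] <- si
      m$chapter[r] <- s$chapter
      m$token_from[r] <- min(cover)
      m$token_to[r] <- max(cover)
    }
  } else {
    m$sentence <- integer(); m$chapter <- integer()
    m$token_from <- integer(); m$token_to <- integer()
  }
  doc$mentions <- m
  doc
}

#' Entities of a document
#'
#' @param doc a segmented `docrel_document`.
#' @return data frame with one row per distinct entity id (`entity_id`,
#'   `entity_type`, `n_mentions`).
#' @export
document_entities <- function(doc) {
  m <- doc$mentions
  if (!nrow(m)) {
    return(data.frame(entity_id = character(), entity_type = character(),
                      n_mentions = integer(), stringsAsFactors = FALSE))
  }
  ids <- unique(m$entity_id)
  data.frame(entity_id = ids,
             entity_type = m$entity_type[match(ids, m$entity_id)],
             n_mentions = as.integer(table(m$entity_id)[ids]),
             stringsAsFactors = FALSE)
}

#' Enumerate candidate entity pairs of a document
#'
#' All ordered pairs (head, tail) of distinct entities with the requested
#' head and tail types; a pair is labelled with its gold relation label if
#' one exists, else with the null label.
#'
#' @param doc a segmented `docrel_document`.
#' @param head_type,tail_type entity type labels; `NULL` means any type.
#' @return data frame with columns `head`, `tail`, `label`.
#' @export
enumerate_candidate_pairs <- function(doc, head_type = NULL, tail_type = NULL) {
  ents <- document_entities(doc)
  heads <- if (is.null(head_type)) ents$entity_id else
    ents$entity_id[ents$entity_type == head_type]
  tails <- if (is.null(tail_type)) ents$entity_id else
    ents$entity_id[ents$entity_type == tail_type]
  if (!length(heads) || !length(tails)) {
    return(data.frame(head = character(), tail = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  pairs <- expand.grid(head = heads, tail = tails,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$head != pairs$tail, , drop = FALSE]
  key <- paste(pairs$head, pairs$tail)
  gkey <- paste(doc$gold$head, doc$gold$tail)
  pairs$label <- ifelse(key %in% gkey, doc$gold$label[match(key, gkey)],
                        NULL_LABEL)
  rownames(pairs) <- NULL
  pairs
}

#' Read an entity hierarchy
#'
#' Two-column TAB-separated file `child<TAB>parent`.  The hierarchy must be
#' acyclic.
#'
#' @param path TSV path.
#' @return data frame with columns `child`, `parent`.
#' @export
read_hierarchy <- function(path) {
  h <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("child", "parent"),
                         colClasses = "character", quote = "")
  .check_acyclic(h)
  h
}

.check_acyclic <- function(hierarchy) {
  for (id in unique(hierarchy$child)) {
    if (id %in% .ancestors(id, hierarchy)) {
      stop("cycle in hierarchy involving '", id, "'")
    }
  }
  invisible(TRUE)
}

# ancestors of `id` under child -> parent links; on a cyclic hierarchy the
# result may include `id` itself, which .check_acyclic treats as a cycle
.ancestors <- function(id, hierarchy) {
  anc <- character()
  frontier <- id
  repeat {
    parents <- unique(hierarchy$parent[hierarchy$child %in% frontier])
    parents <- setdiff(parents, anc)
    if (!length(parents)) break
    anc <- c(anc, parents)
    frontier <- parents
  }
  anc
}

#' Hypernym filtering of predicted relations
#'
#' Within each document, a predicted positive pair (c, d) is removed when a
#' more specific prediction exists: another predicted pair (c', d) with c' a
#' strict descendant of c, or (c, d') with d' a strict descendant of d.  Only
#' relations between the most specific (hyponym) entities are kept.
#'
#' @param predictions data frame with columns `doc_id`, `head`, `label`,
#'   `tail` (positive predictions only).
#' @param hierarchy data frame `child`/`parent` as from [read_hierarchy()].
#' @return the filtered predictions data frame.
#' @export
hypernym_filter <- function(predictions, hierarchy) {
  if (!nrow(predictions) || !nrow(hierarchy)) return(predictions)
  .check_acyclic(hierarchy)
  anc_cache <- new.env(parent = emptyenv())
  anc <- function(id) {
    if (is.null(anc_cache[[id]])) anc_cache[[id]] <- .ancestors(id, hierarchy)
    anc_cache[[id]]
  }
  keep <- rep(TRUE, nrow(predictions))
  for (r in seq_len(nrow(predictions))) {
    same_doc <- predictions$doc_id == predictions$doc_id[r]
    # a competing pair with the same tail and a head below ours
    head_desc <- same_doc & predictions$tail == predictions$tail[r] &
      vapply(predictions$head, function(h) {
        predictions$head[r] %in% anc(h)
      }, TRUE)
    tail_desc <- same_doc & predictions$head == predictions$head[r] &
      vapply(predictions$tail, function(t) {
        predictions$tail[r] %in% anc(t)
      }, TRUE)
    if (any(head_desc) || any(tail_desc)) keep[r] <- FALSE
  }
  out <- predictions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Preprocess a corpus against a triple store
#'
#' Removes entities (with their mentions) that are absent from the triple
#' store's entity set, and removes self-relations whose head and tail entity
#' coincide; gold relations that lose an endpoint are dropped too.
#'
#' @param corpus a `docrel_corpus`.
#' @param kg a `docrel_kg` (see [read_triples()]) or a character vector of
#'   entity ids.
#' @return the filtered corpus.
#' @export
chr_preprocess <- function(corpus, kg) {
  ids <- if (is.character(kg)) kg else kg$entities
  corpus$documents <- lapply(corpus$documents, function(doc) {
    m <- doc$mentions
    doc$mentions <- m[m$entity_id %in% ids, , drop = FALSE]
    rownames(doc$mentions) <- NULL
    g <- doc$gold
    g <- g[g$head != g$tail & g$head %in% ids & g$tail %in% ids, , drop = FALSE]
    rownames(g) <- NULL
    doc$gold <- g
    if (!is.null(doc$sentences)) doc <- segment_document(doc)
    doc
  })
  corpus
}

#' Corpus statistics
#'
#' Document and candidate-pair counts in the layout of the usual corpus
#' statistics tables: number of documents, positive and negative candidate
#' pairs, each split into total and inter-sentence counts.
#'
#' @param corpus a segmented `docrel_corpus`.
#' @param head_type,tail_type candidate pair types (see
#'   [enumerate_candidate_pairs()]).
#' @return one-row data frame with columns `n_doc`, `n_positive`,
#'   `n_positive_inter`, `n_negative`, `n_negative_inter`.
#' @export
corpus_stats <- function(corpus, head_type = NULL, tail_type = NULL) {
  pos <- pos_inter <- neg <- neg_inter <- 0L
  for (doc in corpus$documents) {
    pairs <- enumerate_candidate_pairs(doc, head_type, tail_type)
    if (!nrow(pairs)) next
    loc <- vapply(seq_len(nrow(pairs)), function(r) {
      split_intra_inter(doc, pairs$head[r], pairs$tail[r])
    }, "")
    is_pos <- pairs$label != NULL_LABEL
    pos <- pos + sum(is_pos)
    pos_inter <- pos_inter + sum(is_pos & loc == "inter")
    neg <- neg + sum(!is_pos)
    neg_inter <- neg_inter + sum(!is_pos & loc == "inter")
  }
  data.frame(n_doc = length(corpus$documents), n_positive = pos,
             n_positive_inter = pos_inter, n_negative = neg,
             n_negative_inter = neg_inter)
}

#' Intra- vs inter-sentence locality of an entity pair
#'
#' A pair is intra-sentence when at least one sentence contains a mention of
#' each entity; otherwise it is inter-sentence.
#'
#' @param doc a segmented `docrel_document`.
#' @param head,tail entity ids.
#' @return `"intra"` or `"inter"`.
#' @export
split_intra_inter <- function(doc, head, tail) {
  m <- doc$mentions
  sh <- m$sentence[m$entity_id == head]
  st <- m$sentence[m$entity_id == tail]
  if (length(intersect(sh, st))) "intra" else "inter"
}

#' Subset a corpus by document id or position
#'
#' @param corpus a `docrel_corpus`.
#' @param ids document ids (character) or positions (numeric).
#' @return the reduced corpus.
#' @export
subset_corpus <- function(corpus, ids) {
  corpus$documents <- corpus$documents[ids]
  corpus
}

#' @export
print.docrel_corpus <- function(x, ...) {
  cat("<docrel_corpus> ", length(x$documents), " documents, labels: ",
      paste(x$label_set, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.docrel_document <- function(x, ...) {
  cat("<docrel_document> ", x$doc_id, ": ", length(x$sentences),
      " sentences, ", nrow(x$mentions), " mentions, ", nrow(x$gold),
      " gold relations\n", sep = "")
  invisible(x)
}
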
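# Contextual token encoding: per-sentence bidirectional recurrent layer over
# word embeddings.

#' Build a word-embedding table
#'
#' Rows are drawn from U(-0.05, 0.05) under a fixed seed.  An unknown-token
#' row (`<unk>`) and a padding row (`<pad>`) are always present.
#'
#' @param vocab character vector of tokens.
#' @param dim embedding dimension.
#' @param seed integer seed.
#' @return numeric matrix with one named row per token.
#' @export
embedding_table <- function(vocab, dim = 16, seed = 1) {
  set.seed(seed)
  vocab <- c("<pad>", "<unk>", setdiff(vocab, c("<pad>", "<unk>")))
  matrix(stats::runif(length(vocab) * dim, -0.05, 0.05), length(vocab), dim,
         dimnames = list(vocab, NULL))
}

#' Read pre-trained word embeddings in word2vec text format
#'
#' @param path text file: header `n dim`, then `token v1 ... vdim` lines.
#' @param add_special add `<pad>`/`<unk>` rows (zeros) when missing.
#' @return numeric matrix with named rows.
#' @export
read_word2vec <- function(path, add_special = TRUE) {
  E <- read_embeddings(path)
  if (add_special) {
    for (tok in c("<unk>", "<pad>")) {
      if (!tok %in% rownames(E)) {
        E <- rbind(matrix(0, 1, ncol(E), dimnames = list(tok, NULL)), E)
      }
    }
  }
  E
}

#' Initialize encoder parameters
#'
#' Parameters of the bidirectional tanh recurrence used by
#' [encode_tokens()]; the hidden dimension of the encoding is
#' `2 * rnn_dim`.
#'
#' @param emb_dim word-embedding dimension.
#' @param rnn_dim recurrent state size per direction.
#' @param seed integer seed.
#' @return named list of numeric parameter arrays.
#' @export
encoder_params <- function(emb_dim = 16, rnn_dim = 8, seed = 1) {
  set.seed(seed)
  ru <- function(m, n) matrix(stats::runif(m * n, -0.5, 0.5) / sqrt(n), m, n)
  list(Wxf = ru(rnn_dim, emb_dim), Uhf = ru(rnn_dim, rnn_dim),
       bf = numeric(rnn_dim),
       Wxb = ru(rnn_dim, emb_dim), Uhb = ru(rnn_dim, rnn_dim),
       bb = numeric(rnn_dim))
}

# internal ad forward: token indices -> (T x hidden) encoding node
.encode_forward <- function(idx, emb_node, enc, method = "birnn") {
  X <- ad_rows(emb_node, idx)
  if (identical(method, "none")) return(X)
  .birnn_forward(X, enc$Wxf, enc$Uhf, enc$bf, enc$Wxb, enc$Uhb, enc$bb)
}

#' Encode a sentence into contextual token representations
#'
#' Looks up each token in the embedding table (falling back to the
#' unknown-token row) and runs a bidirectional tanh recurrence over the
#' sentence; the encoding of token i concatenates the forward and backward
#' states, so the output has `hidden_dim = 2 * rnn_dim` columns regardless
#' of sentence length.  Deterministic given the parameters.  With
#' `method = "none"` the recurrence is bypassed and the raw embedded tokens
#' are returned (a degenerate configuration used for testing and
#' inspection).
#'
#' @param tokens character vector of tokens (non-empty).
#' @param table embedding matrix with named rows (see [embedding_table()]).
#' @param params encoder parameters from [encoder_params()] (ignored for
#'   `method = "none"`).
#' @param method `"birnn"` (default) or `"none"`.
#' @return numeric matrix, one row per token.
#' @export
encode_tokens <- function(tokens, table, params = NULL,
                          method = c("birnn", "none")) {
  method <- match.arg(method)
  if (!length(tokens)) stop("empty sentence")
  idx <- match(tokens, rownames(table))
  idx[is.na(idx)] <- match("<unk>", rownames(table))
  if (method == "birnn" && is.null(params)) {
    stop("encoder parameters required for method 'birnn'")
  }
  enc <- if (method == "birnn") lapply(params, ad_const) else NULL
  node <- .encode_forward(idx, ad_const(table), enc, method)
  out <- node$val
  rownames(out) <- tokens
  out
}
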
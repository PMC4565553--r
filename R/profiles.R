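# Profile HMMs per subfamily group, symmetrised Kullback-Leibler distances
# between them, NJ clustering of the groups, and the all-pairs local-
# alignment similarity network.

#' Build a profile HMM from a sub-alignment
#'
#' Columns with at least 50% non-gap characters become match states.  Match
#' emissions are column counts plus a pseudocount of 0.2 per residue,
#' normalised; state transitions (match/insert/delete) are estimated from
#' the observed sequence paths with +1 pseudocounts.
#'
#' @param sub_alignment character matrix (>= 2 aligned sequences).
#' @param group optional group label stored on the model.
#' @param pseudocount emission pseudocount per residue.
#' @return object of class `profile_hmm` with `length`, `emissions`
#'   (match-states x 20), `transitions`, `match_columns`, `group`.
#' @export
build_hmm <- function(sub_alignment, group = NULL, pseudocount = 0.2) {
  if (is.data.frame(sub_alignment)) sub_alignment <- alignment_matrix(sub_alignment)
  if (nrow(sub_alignment) < 2) stop("need at least 2 aligned sequences")
  nongap <- sub_alignment != "-"
  match_cols <- which(colMeans(nongap) >= 0.5)
  if (!length(match_cols)) stop("alignment has zero match columns")
  L <- length(match_cols)
  em <- t(vapply(match_cols, function(j) {
    counts <- table(factor(sub_alignment[sub_alignment[, j] %in% AA_ALPHABET, j],
                           levels = AA_ALPHABET))
    (as.numeric(counts) + pseudocount) / (sum(counts) + 20 * pseudocount)
  }, numeric(20)))
  colnames(em) <- AA_ALPHABET

  # transition counts from observed paths (states M/I/D per match interval)
  st_names <- c("M", "I", "D")
  trans <- array(1, dim = c(L + 1, 3, 3),
                 dimnames = list(NULL, st_names, st_names))  # +1 pseudocounts
  is_match <- seq_len(ncol(sub_alignment)) %in% match_cols
  for (i in seq_len(nrow(sub_alignment))) {
    prev <- "M"  # begin state treated as match of index 0
    pos <- 1L
    for (j in seq_len(ncol(sub_alignment))) {
      if (is_match[j]) {
        cur <- if (nongap[i, j]) "M" else "D"
        trans[pos, prev, cur] <- trans[pos, prev, cur] + 1
        prev <- cur
        pos <- pos + 1L
      } else if (nongap[i, j]) {
        trans[pos, prev, "I"] <- trans[pos, prev, "I"] + 1
        prev <- "I"
      }
    }
  }
  for (k in seq_len(L + 1))
    trans[k, , ] <- trans[k, , ] / rowSums(trans[k, , ])
  structure(list(length = L, emissions = em, transitions = trans,
                 match_columns = match_cols, group = group),
            class = "profile_hmm")
}

#' Symmetrised Kullback-Leibler distance between profile HMMs
#'
#' Mean over match positions of `0.5 * (KL(p||q) + KL(q||p))` between match
#' emission distributions; transition probabilities are excluded.  The two
#' HMMs must have equal match length (build them from column slices of one
#' master alignment).
#'
#' @param h1,h2 `profile_hmm` objects.
#' @return nonnegative distance.
#' @export
hmm_distance <- function(h1, h2) {
  if (h1$length != h2$length) stop("HMM match lengths differ")
  p <- h1$emissions; q <- h2$emissions
  term <- function(a, b) ifelse(a > 0, a * log(a / b), 0)  # 0 log 0 = 0
  kl_pq <- rowSums(term(p, q))
  kl_qp <- rowSums(term(q, p))
  mean(0.5 * (kl_pq + kl_qp))
}

#' NJ tree of profile HMMs
#'
#' @param hmms named list of `profile_hmm` objects (>= 3) of equal length.
#' @return unrooted `phylo` with group names as tips, plus the distance
#'   matrix as attribute `distances`.
#' @export
hmm_tree <- function(hmms) {
  if (length(hmms) < 3) stop("need at least 3 HMMs")
  labs <- names(hmms)
  if (is.null(labs))
    labs <- vapply(hmms, function(h) h$group %||% "", character(1))
  n <- length(hmms)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- hmm_distance(hmms[[i]], hmms[[j]])
  tr <- neighbor_joining(d)
  attr(tr, "distances") <- d
  tr
}

# published gapped BLOSUM62 (open 11, extend 1) Karlin-Altschul constants
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' All-pairs local-alignment similarity network
#'
#' Every unordered sequence pair is scored by Smith-Waterman local alignment
#' (BLOSUM62, gap open 11, extend 1); e-values use the Karlin-Altschul
#' approximation `K m n exp(-lambda S)` with published gapped constants.
#' Edges with e-value above the cutoff are dropped.
#'
#' @param sequences FASTA records data.frame or named character vector of
#'   protein sequences (gaps are removed before alignment).
#' @param groups optional named vector of group labels per sequence id.
#' @param evalue_cutoff retain edges with e-value <= this (default 1e-3).
#' @return object of class `similarity_network`: list with `nodes`
#'   (data.frame id, group) and `edges` (data.frame id1, id2, score,
#'   evalue).
#' @export
similarity_network <- function(sequences, groups = NULL, evalue_cutoff = 1e-3) {
  if (is.data.frame(sequences)) {
    seqs <- sequences$seq
    names(seqs) <- sequences$id
  } else seqs <- sequences
  if (length(seqs) < 2) stop("need at least 2 sequences")
  seqs <- gsub("-", "", seqs, fixed = TRUE)
  if (any(!nzchar(seqs))) stop("empty sequence")
  ids <- names(seqs)
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  B62 <- get("BLOSUM62", envir = data_env)
  pairs <- utils::combn(length(seqs), 2)
  sc <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    sc[k] <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[[i]]), Biostrings::AAString(seqs[[j]]),
      type = "local", substitutionMatrix = B62,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  }
  mlen <- nchar(seqs)
  ev <- .KA_K * mlen[pairs[1, ]] * mlen[pairs[2, ]] * exp(-.KA_LAMBDA * sc)
  keep <- ev <= evalue_cutoff
  edges <- data.frame(id1 = ids[pairs[1, keep]], id2 = ids[pairs[2, keep]],
                      score = sc[keep], evalue = ev[keep])
  nodes <- data.frame(id = ids,
                      group = if (is.null(groups)) NA_character_
                        else unname(groups[ids]))
  structure(list(nodes = nodes, edges = edges, evalue_cutoff = evalue_cutoff),
            class = "similarity_network")
}

#' Export a similarity network
#'
#' Writes GraphML (via igraph) and/or a TSV edge list.
#'
#' @param network `similarity_network`.
#' @param graphml_path optional GraphML output path.
#' @param edgelist_path optional TSV edge-list output path.
#' @return invisibly, the igraph object.
#' @export
export_network <- function(network, graphml_path = NULL, edgelist_path = NULL) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edgelist_path))
    utils::write.table(network$edges, edgelist_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(g)
}
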
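# Readers and writers for the plain-text formats the pipeline touches:
# FASTA sequence files, Newick tree sets with optional weights, and
# association-dissociation trace CSVs.

#' Read a FASTA file
#'
#' Order of records is preserved; gap dots `.` are normalised to `-`.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id`, `seq` (one row per record).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("not FASTA (first non-blank line must start with '>'): ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr])[as.character(seq_along(ids))],
                 function(x) paste(gsub("\\s", "", x), collapse = ""), character(1))
  seqs[is.na(seqs)] <- ""
  seqs <- chartr(".", "-", toupper(unname(seqs)))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records data.frame with `id` and `seq` columns.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    cat(">", records$id[i], "\n", sep = "", file = con)
    s <- records$seq[i]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a set of trees with posterior weights
#'
#' One Newick tree per line; an optional weights file carries one nonnegative
#' number per tree.  Weights are normalised to sum to one; when no weights
#' file is given the trees are weighted uniformly.
#'
#' @param newick_path path to the Newick file (one tree per line).
#' @param weights_path optional path to a whitespace-delimited weights file.
#' @return a `weighted_tree_set`: list with `trees` (list of `phylo`) and
#'   `weights` (numeric, sums to 1).
#' @export
read_tree_set <- function(newick_path, weights_path = NULL) {
  lines <- readLines(newick_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no trees in ", newick_path)
  trees <- lapply(lines, function(x) {
    tr <- tryCatch(ape::read.tree(text = x), error = function(e) NULL)
    if (is.null(tr)) stop("unparseable Newick line in ", newick_path)
    tr
  })
  if (is.null(weights_path)) {
    w <- rep(1, length(trees))
  } else {
    w <- scan(weights_path, what = numeric(), quiet = TRUE)
    if (length(w) != length(trees))
      stop("weight count (", length(w), ") != tree count (", length(trees), ")")
    if (any(w < 0)) stop("negative tree weight")
  }
  if (sum(w) <= 0) stop("tree weights sum to zero")
  weighted_tree_set(trees, w)
}

#' Construct a weighted tree set
#'
#' @param trees list of `phylo` objects sharing one taxon set.
#' @param weights nonnegative weights, recycled to uniform if missing.
#' @return `weighted_tree_set` object.
#' @export
weighted_tree_set <- function(trees, weights = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(weights)) weights <- rep(1, length(trees))
  stopifnot(length(weights) == length(trees), all(weights >= 0), sum(weights) > 0)
  taxa <- sort(trees[[1]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), taxa)) stop("trees do not share one taxon set")
  structure(list(trees = trees, weights = weights / sum(weights)),
            class = "weighted_tree_set")
}

#' Write a tree set
#'
#' @param tree_set `weighted_tree_set`.
#' @param newick_path output Newick path (one tree per line).
#' @param weights_path optional output path for the weights.
#' @return `newick_path`, invisibly.
#' @export
write_tree_set <- function(tree_set, newick_path, weights_path = NULL) {
  writeLines(vapply(tree_set$trees, ape::write.tree, character(1)), newick_path)
  if (!is.null(weights_path))
    writeLines(format(tree_set$weights, digits = 15), weights_path)
  invisible(newick_path)
}

.TRACE_COLS <- c("time", "signal", "concentration_M", "replicate", "phase")

#' Read association-dissociation traces
#'
#' Expects columns `time` (seconds), `signal` (nm shift), `concentration_M`
#' (molar), `replicate` (integer id) and `phase`
#' (`association`/`dissociation`).  Rows are sorted by (concentration,
#' replicate, phase, time) and time must strictly increase within each
#' series.
#'
#' @param csv_path path to the trace CSV.
#' @return sorted data.frame of traces.
#' @export
read_traces <- function(csv_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  missing <- setdiff(.TRACE_COLS, names(df))
  if (length(missing)) stop("trace CSV lacks column(s): ", paste(missing, collapse = ", "))
  validate_traces(df[.TRACE_COLS])
}

#' Validate and sort a trace table
#'
#' @param df data.frame with the trace columns.
#' @return sorted, validated data.frame.
#' @export
validate_traces <- function(df) {
  bad <- setdiff(unique(df$phase), c("association", "dissociation"))
  if (length(bad)) stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  df$concentration_M <- as.numeric(df$concentration_M)
  if (anyNA(df$concentration_M) || any(df$concentration_M < 0))
    stop("concentrations must be nonnegative molar values")
  df <- df[order(df$concentration_M, df$replicate, df$phase, df$time), , drop = FALSE]
  key <- interaction(df$concentration_M, df$replicate, df$phase, drop = TRUE)
  for (grp in split(df$time, key))
    if (any(diff(grp) <= 0)) stop("time must strictly increase within each trace series")
  rownames(df) <- NULL
  df
}

#' Write traces to CSV
#'
#' @param traces trace data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces[.TRACE_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# alignment helpers ---------------------------------------------------------

#' Convert FASTA records to an alignment matrix
#'
#' @param records data.frame from [read_fasta()].
#' @return character matrix (taxa x sites) of single residues, rownames = ids.
#' @export
alignment_matrix <- function(records) {
  n <- nchar(records$seq)
  if (length(unique(n)) != 1)
    stop("sequences are not aligned (unequal lengths)")
  m <- do.call(rbind, strsplit(records$seq, ""))
  rownames(m) <- records$id
  m
}

#' Convert in-frame nucleotide records to a codon matrix
#'
#' Validates that lengths are divisible by three and that no internal stop
#' codons occur; codons containing gaps or ambiguity codes become NA
#' (treated as missing data in likelihoods).
#'
#' @param records data.frame from [read_fasta()] holding aligned, in-frame DNA.
#' @return character matrix (taxa x codon sites) of codons.
#' @export
codon_matrix <- function(records) {
  n <- nchar(records$seq)
  if (length(unique(n)) != 1) stop("sequences are not aligned")
  if (n[1] %% 3 != 0) stop("alignment length not divisible by 3")
  seqs <- chartr("U", "T", toupper(records$seq))
  starts <- seq(1, n[1], by = 3)
  m <- t(vapply(seqs, function(s) substring(s, starts, starts + 2),
                character(length(starts))))
  if (length(starts) == 1) m <- matrix(m, ncol = 1)
  rownames(m) <- records$id
  stops <- c("TAA", "TAG", "TGA")
  if (any(m %in% stops)) stop("internal stop codon in codon alignment")
  m[!(m %in% sense_codons())] <- NA_character_
  m
}
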
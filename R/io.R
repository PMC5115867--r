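#' Read and write the package's tabular formats
#'
#' All tables are tab-separated with a header row. Readers reject ragged rows
#' with the offending line number (via readr's parsing problems) and validate
#' the expected columns.
#'
#' @param path File path.
#' @param x Object to write.
#' @name tsv-io
NULL

.read_tsv_strict <- function(path, col_types = NULL) {
  out <- suppressWarnings(
    readr::read_tsv(path, col_types = col_types, progress = FALSE,
                    show_col_types = FALSE)
  )
  probs <- readr::problems(out)
  if (nrow(probs)) {
    abort(paste0("malformed TSV ", path, ": row ", probs$row[1], ", ",
                 probs$expected[1], " expected."))
  }
  out
}

#' @rdname tsv-io
#' @export
read_counts <- function(path) {
  out <- .read_tsv_strict(path)
  .assert(all(c("gene", "length") %in% names(out)),
          "count table needs `gene` and `length` columns.")
  out
}

#' @rdname tsv-io
#' @export
read_metadata <- function(path) {
  out <- .read_tsv_strict(path)
  .assert(all(c("sample", "species", "treatment", "replicate") %in% names(out)),
          "metadata needs sample, species, treatment, replicate columns.")
  .assert(!anyDuplicated(out[c("species", "treatment", "replicate")]),
          "(species, treatment, replicate) must be unique.")
  out
}

#' @rdname tsv-io
#' @export
read_hits <- function(path) {
  out <- .read_tsv_strict(path)
  .assert(all(c("query", "subject", "evalue", "length", "coverage",
                "identity") %in% names(out)),
          "hits table needs query, subject, evalue, length, coverage, identity.")
  out
}

#' Read a BED-like TE insertion table
#'
#' Expected columns: `gene`, `family`, `distance` (bp upstream of the
#' transcription start, 0-based half-open interval convention already resolved
#' to a nonnegative distance) and optional `strand`.
#'
#' @rdname tsv-io
#' @export
read_te_table <- function(path) {
  out <- .read_tsv_strict(path)
  .assert(all(c("gene", "family", "distance") %in% names(out)),
          "TE table needs gene, family, distance columns.")
  .assert(all(out$distance >= 0), "TE distances must be >= 0.")
  out
}

#' @rdname tsv-io
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a newick tree
#'
#' Internal node labels that parse as numbers in \[0, 1\] are kept as branch
#' supports. Unbalanced parentheses raise a parse error with the character
#' position.
#'
#' @param text Newick string, or `NULL` when `path` is given.
#' @param path Optional file to read from.
#' @return A rooted/unrooted [ape::phylo].
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  opens <- lengths(regmatches(text, gregexpr("\\(", text)))
  closes <- lengths(regmatches(text, gregexpr("\\)", text)))
  if (opens != closes) {
    pos <- if (opens > closes) max(gregexpr("\\(", text)[[1]]) else
      max(gregexpr("\\)", text)[[1]])
    abort(paste0("unbalanced parentheses in newick near position ", pos, "."))
  }
  phy <- ape::read.tree(text = text)
  .assert(!is.null(phy), "newick parse failure.")
  phy
}

#' Write a tree to newick (supports as internal node labels)
#' @param phy An [ape::phylo].
#' @param path Optional path; when `NULL` the newick string is returned.
#' @export
write_newick <- function(phy, path = NULL) {
  nwk <- ape::write.tree(phy)
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(path)
}

#' Write / read pairwise codon alignments as FASTA
#'
#' Each pair occupies two records named `<pair>|1` and `<pair>|2`.
#'
#' @param pairs Named list of length-2 character vectors.
#' @param path FASTA path.
#' @export
write_codon_pairs <- function(pairs, path) {
  seqs <- unlist(lapply(names(pairs), function(nm) {
    setNames(pairs[[nm]], paste0(nm, "|", 1:2))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_codon_pairs
#' @export
read_codon_pairs <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\|[12]$", "", names(ss))
  split(as.character(ss), ids) |>
    lapply(function(x) unname(x))
}
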
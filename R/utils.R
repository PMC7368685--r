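#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state on exit. With `seed = NULL` the expression is
#' evaluated under the current RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific seed from a master seed
#'
#' Pipeline stages are seeded independently so that any stage can be re-run
#' in isolation and reproduce its output. The derivation hashes the stage
#' name into the master seed; results stay below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L, nzchar(stage))
  v <- utf8ToInt(stage)
  h <- sum(as.numeric(v) * (31^((seq_along(v) - 1L) %% 6L))) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

#' Construct a gene alignment
#'
#' A gene alignment is a character matrix of aligned sequences (rows = taxa,
#' columns = sites, entries = single upper-case characters) with gene,
#' functional-group and plastome-region metadata attached. Codon alignments
#' additionally assert an open reading frame (length divisible by three).
#'
#' @param x Character matrix with unique non-empty rownames, or a list of
#'   equal-length character strings named by taxon.
#' @param gene Gene name.
#' @param group Functional-group label (e.g. "PSB", "RPO").
#' @param region Plastome region label ("LSC", "SSC" or "IR").
#' @param codon Logical; is this an in-frame codon alignment?
#' @return An object of class `gene_alignment`.
#' @export
gene_alignment <- function(x, gene = NA_character_, group = NA_character_,
                           region = NA_character_, codon = FALSE) {
  if (is.list(x) || is.character(x) && !is.matrix(x)) {
    lens <- nchar(unlist(x, use.names = FALSE))
    if (length(unique(lens)) > 1L)
      stop("ragged alignment: sequence lengths differ (", paste(unique(lens), collapse = ", "), ")")
    nm <- names(x)
    x <- do.call(rbind, lapply(x, function(s) strsplit(s, "", fixed = TRUE)[[1L]]))
    rownames(x) <- nm
  }
  if (!is.matrix(x) || !is.character(x)) stop("alignment must be a character matrix")
  if (is.null(rownames(x)) || anyNA(rownames(x)) || any(!nzchar(rownames(x))))
    stop("alignment rows must be named by taxon")
  if (anyDuplicated(rownames(x))) stop("duplicate taxon names in alignment")
  x[] <- toupper(x)
  if (isTRUE(codon) && ncol(x) %% 3L != 0L)
    stop("codon alignment length ", ncol(x), " not divisible by 3 (gene ", gene, ")")
  structure(x, gene = gene, group = group, region = region, codon = codon,
            class = c("gene_alignment", "matrix", "array"))
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("gene_alignment", if (!is.na(attr(x, "gene"))) paste0("'", attr(x, "gene"), "'"),
      ":", nrow(x), "taxa x", ncol(x), "sites",
      if (isTRUE(attr(x, "codon"))) "(codon)", "\n")
  invisible(x)
}

# keep metadata through subsetting used internally
aln_keep_taxa <- function(aln, taxa) {
  y <- unclass(aln)[taxa, , drop = FALSE]
  gene_alignment(y, gene = attr(aln, "gene"), group = attr(aln, "group"),
                 region = attr(aln, "region"), codon = isTRUE(attr(aln, "codon")))
}

#' Read an aligned FASTA file as a gene alignment
#'
#' @param file Path to an uncompressed FASTA file of aligned sequences.
#' @param gene Gene name; defaults to the file name without extension.
#' @param ... Passed to [gene_alignment()].
#' @return A `gene_alignment`.
#' @export
read_fasta_alignment <- function(file, gene = sub("\\.[^.]*$", "", basename(file)), ...) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1L]) stop("not a FASTA file: ", file)
  idx <- cumsum(hdr)
  nm <- trimws(sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(s) gsub("[ \t]", "", paste(s, collapse = "")), "")
  names(seqs) <- nm
  gene_alignment(as.list(seqs), gene = gene, ...)
}

#' Write a gene alignment to FASTA
#'
#' Sequences are written unwrapped, one line per taxon, in row order, so
#' output is byte-reproducible.
#'
#' @param aln A `gene_alignment`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta_alignment <- function(aln, file) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  con <- file(file, "wb")  # fixed newline convention
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", seqs), con = con, sep = "\n")
  invisible(file)
}

#' Write a tab-separated table deterministically
#'
#' @param df Data frame.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_tsv <- function(df, file) {
  utils::write.table(df, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}
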
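#' Construct a gene signature
#'
#' A named, ordered list of unique gene symbols. `nominal_length` records the
#' published length of the signature and is preserved when the gene list is
#' shrunk by a platform intersection, so that subset-size ranges keep being
#' computed from the published length (the 50 of PAM50, even when only 44
#' genes are measured on a platform).
#'
#' @param genes Character vector of unique gene symbols.
#' @param name Signature name.
#' @param nominal_length Published length; defaults to `length(genes)`.
#' @return An object of class `GeneSignature`.
#' @export
gene_signature <- function(genes, name = "signature",
                           nominal_length = length(genes)) {
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  .stop_on_duplicates(genes, "gene symbol")
  if (length(genes) < 1L) stop("a signature needs at least one gene")
  nominal_length <- as.integer(nominal_length)
  if (nominal_length < 1L) stop("nominal_length must be >= 1")
  structure(list(name = name, genes = genes,
                 nominal_length = nominal_length),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s': %d genes (nominal length %d)\n",
              x$name, length(x$genes), x$nominal_length))
  cat(strwrap(paste(x$genes, collapse = ", "), width = 70), sep = "\n")
  invisible(x)
}

#' @export
length.GeneSignature <- function(x) length(x$genes)

#' Read a gene signature from plain text
#'
#' One gene symbol per line; blank lines and lines starting with `#` are
#' ignored. Symbols are whitespace-trimmed. Duplicate symbols and empty files
#' are errors. The nominal length is the number of symbols read.
#'
#' @param path Path to the signature file.
#' @param name Signature name; defaults to the file name.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty signature file: ", path)
  gene_signature(lines, name = name)
}

#' Write a gene signature as plain text
#' @param sig A `GeneSignature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  writeLines(sig$genes, path)
  invisible(path)
}

#' Intersect a signature with a gene universe
#'
#' Keeps, in the signature's order, exactly the symbols present in
#' `universe`. Matching is exact, case-sensitive symbol equality. The
#' nominal length carries over unchanged, so downstream subset-size ranges
#' remain anchored to the published signature length. Dropped symbols are
#' reported by name via `message()`.
#'
#' @param sig A `GeneSignature`.
#' @param universe Character vector of available gene symbols (e.g.
#'   `gene_ids(data)`).
#' @return A `GeneSignature` over `sig`'s genes present in `universe`.
#' @export
intersect_signature <- function(sig, universe) {
  universe <- trimws(as.character(universe))
  keep <- sig$genes %in% universe
  if (!any(keep))
    stop("no genes of signature '", sig$name, "' are present in the universe")
  if (any(!keep))
    message("dropped from '", sig$name, "': ",
            paste(sig$genes[!keep], collapse = ", "))
  gene_signature(sig$genes[keep], name = sig$name,
                 nominal_length = sig$nominal_length)
}

#' Genes common to two signatures
#'
#' @param a,b `GeneSignature` objects.
#' @return Character vector of the symbols present in both, in `a`'s order.
#' @export
common_genes <- function(a, b) {
  a$genes[a$genes %in% b$genes]
}

.extdata <- function(file) {
  system.file("extdata", file, package = "fewshotgenes", mustWork = TRUE)
}

#' Packaged gene signatures
#'
#' Accessors for the gene lists that ship with the package: the 50-gene
#' PAM50 intrinsic-subtype signature, the two 36-gene signatures selected on
#' the ACES and TCGA breast-cancer cohorts, and the six PAM50 genes absent
#' from the ACES platform.
#'
#' @return [pam50()] and [s36_signature()] return a `GeneSignature`;
#'   [aces_missing_genes()] returns a character vector of six symbols.
#' @export
pam50 <- function() read_signature(.extdata("pam50_signature.txt"), "PAM50")

#' @rdname pam50
#' @param cohort Which cohort's 36-gene selection to load.
#' @export
s36_signature <- function(cohort = c("ACES", "TCGA")) {
  cohort <- match.arg(cohort)
  file <- if (cohort == "ACES") "s36_aces.txt" else "s36_tcga.txt"
  read_signature(.extdata(file), paste0("S-36 ", cohort))
}

#' @rdname pam50
#' @export
aces_missing_genes <- function() {
  read_signature(.extdata("aces_missing_genes.txt"))$genes
}
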
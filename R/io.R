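#' Paired spliced/unspliced count matrices for one species
#'
#' @param species_id Species identifier.
#' @param gene_ids Ordered gene identifiers (columns).
#' @param U,S cells x genes nonnegative integer matrices (unspliced, spliced)
#'   with identical shapes and gene ordering.
#' @return A list of class `paired_counts`.
#' @export
paired_counts <- function(species_id, gene_ids, U, S) {
  U <- as.matrix(U); S <- as.matrix(S)
  if (!all(dim(U) == dim(S))) stop("U and S must share shape")
  if (ncol(U) != length(gene_ids)) stop("gene_ids length must match columns")
  if (any(U < 0) || any(S < 0)) stop("negative counts")
  if (any(U != round(U)) || any(S != round(S))) stop("counts must be integers")
  structure(list(species_id = species_id, gene_ids = as.character(gene_ids),
                 U = U, S = S),
            class = "paired_counts")
}

#' @export
print.paired_counts <- function(x, ...) {
  cat(sprintf("paired counts [%s]: %d cells x %d genes\n",
              x$species_id, nrow(x$U), length(x$gene_ids)))
  invisible(x)
}

#' Read paired counts from Matrix-Market or TSV files
#'
#' MTX mode expects `<prefix>.unspliced.mtx`, `<prefix>.spliced.mtx` (cells x
#' genes) plus `<prefix>.genes.tsv` (one gene id per line). TSV mode expects
#' `<prefix>.unspliced.tsv` / `<prefix>.spliced.tsv` dense tables with gene
#' ids as column headers.
#'
#' @param prefix Path prefix.
#' @param species_id Species label to attach.
#' @param format `"mtx"` or `"tsv"`.
#' @return A [paired_counts()] object.
#' @export
read_paired_counts <- function(prefix, species_id, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    U <- as.matrix(Matrix::readMM(paste0(prefix, ".unspliced.mtx")))
    S <- as.matrix(Matrix::readMM(paste0(prefix, ".spliced.mtx")))
    genes <- readLines(paste0(prefix, ".genes.tsv"))
  } else {
    Ut <- read.delim(paste0(prefix, ".unspliced.tsv"), check.names = FALSE)
    St <- read.delim(paste0(prefix, ".spliced.tsv"), check.names = FALSE)
    genes <- colnames(Ut)
    U <- as.matrix(Ut); S <- as.matrix(St)
  }
  paired_counts(species_id, genes, U, S)
}

#' Write paired counts to disk
#'
#' @param pc A [paired_counts()] object.
#' @param prefix Path prefix (see [read_paired_counts()] for the layout).
#' @param format `"mtx"` or `"tsv"`.
#' @return Invisibly, the written file paths.
#' @export
write_paired_counts <- function(pc, prefix, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(pc, "paired_counts"))
  if (format == "mtx") {
    fu <- paste0(prefix, ".unspliced.mtx"); fs <- paste0(prefix, ".spliced.mtx")
    fg <- paste0(prefix, ".genes.tsv")
    Matrix::writeMM(Matrix::Matrix(pc$U, sparse = TRUE), fu)
    Matrix::writeMM(Matrix::Matrix(pc$S, sparse = TRUE), fs)
    writeLines(pc$gene_ids, fg)
    files <- c(fu, fs, fg)
  } else {
    fu <- paste0(prefix, ".unspliced.tsv"); fs <- paste0(prefix, ".spliced.tsv")
    du <- as.data.frame(pc$U); ds <- as.data.frame(pc$S)
    names(du) <- names(ds) <- pc$gene_ids
    write.table(du, fu, sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(ds, fs, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(fu, fs)
  }
  invisible(files)
}

#' Reshape a long kinetics table into a phylogenetic trait table
#'
#' Builds, per gene, the length-`2n` trait vector `(log b, log gamma)` per
#' species in species-major interleaved order `(b_1, gamma_1, b_2, gamma_2,
#' ...)`, with species ordered as in `species_order` (typically the tree's tip
#' labels).
#'
#' @param table Long data.frame with `gene`, `species`, `log_b`, `log_gamma`.
#' @param species_order Character vector fixing the species ordering.
#' @return A list of class `trait_table` with `gene_ids`, `species`, and the
#'   genes x 2n matrix `Y`.
#' @export
trait_table <- function(table, species_order) {
  missing_sp <- setdiff(species_order, unique(table$species))
  if (length(missing_sp)) stop("species missing from table: ", paste(missing_sp, collapse = ", "))
  genes <- unique(table$gene)
  n <- length(species_order)
  Y <- matrix(NA_real_, length(genes), 2 * n,
              dimnames = list(genes, paste(rep(species_order, each = 2),
                                           c("log_b", "log_gamma"), sep = ".")))
  for (si in seq_len(n)) {
    sub <- table[table$species == species_order[si], , drop = FALSE]
    idx <- match(genes, sub$gene)
    Y[, 2 * si - 1] <- sub$log_b[idx]
    Y[, 2 * si]     <- sub$log_gamma[idx]
  }
  if (anyNA(Y)) stop("trait table incomplete: every gene needs every species")
  structure(list(gene_ids = genes, species = species_order, Y = Y),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait table: %d genes x %d species (log b, log gamma)\n",
              length(x$gene_ids), length(x$species)))
  invisible(x)
}

#' Read/write trait tables as long-format TSV
#'
#' @param path TSV file with columns `gene, species, log_b, log_gamma`.
#' @param species_order Species ordering for the trait matrix.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path, species_order = NULL) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "species", "log_b", "log_gamma")
  if (!all(need %in% names(tb))) stop("trait TSV needs columns: ", paste(need, collapse = ", "))
  if (is.null(species_order)) species_order <- unique(tb$species)
  trait_table(tb, species_order)
}

#' @rdname read_trait_table
#' @param traits A [trait_table()] to write.
#' @export
write_trait_table <- function(traits, path) {
  n <- length(traits$species)
  long <- do.call(rbind, lapply(seq_len(n), function(si) {
    data.frame(gene = traits$gene_ids, species = traits$species[si],
               log_b = traits$Y[, 2 * si - 1], log_gamma = traits$Y[, 2 * si],
               stringsAsFactors = FALSE)
  }))
  write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
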
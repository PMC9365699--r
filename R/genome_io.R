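#' Default chromosome ordering
#'
#' Natural human chromosome order: `chr1` .. `chr22`, `chrX`, `chrY`.
#' Used to sort gene-position tables along the genome. Chromosomes not in
#' this list are ordered after it, alphabetically.
#'
#' @return Character vector of chromosome names.
#' @export
default_chromosome_order <- function() {
  c(paste0("chr", 1:22), "chrX", "chrY")
}

#' Read a genome gene-position table
#'
#' Reads a 4-column, tab-delimited, headerless file (gene, chromosome, start,
#' stop; 1-based inclusive coordinates), drops genes on excluded chromosomes
#' (mitochondrial by default), sorts by (chromosome, start) and assigns each
#' gene its rank along the genome.
#'
#' @param path Path to the position file.
#' @param excluded_chromosomes Character vector of chromosomes to drop
#'   (default `"chrM"`).
#' @param chromosome_order Chromosome sort order; chromosomes absent from
#'   this vector sort after it alphabetically.
#' @return A `data.frame` of class `gene_positions` with columns `gene_id`,
#'   `chromosome`, `start`, `stop`, `genome_rank`.
#' @export
read_gene_positions <- function(path, excluded_chromosomes = "chrM",
                                chromosome_order = default_chromosome_order()) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene_id", "chromosome", "start", "stop"),
                           colClasses = c("character", "character", "numeric", "numeric"),
                           quote = "", comment.char = "")
  bad <- which(raw$stop < raw$start)
  if (length(bad) > 0) {
    stop("stop < start at line ", bad[1], " (gene ", raw$gene_id[bad[1]], ")")
  }
  dup <- raw$gene_id[duplicated(raw$gene_id)]
  if (length(dup) > 0) {
    stop("duplicate gene_id in position file: ", paste(unique(dup), collapse = ", "))
  }
  gene_positions(raw, excluded_chromosomes = excluded_chromosomes,
                 chromosome_order = chromosome_order)
}

#' Build a gene-position table from a data frame
#'
#' @param df Data frame with columns `gene_id`, `chromosome`, `start`, `stop`.
#' @inheritParams read_gene_positions
#' @return A `gene_positions` data frame (sorted, ranked).
#' @export
gene_positions <- function(df, excluded_chromosomes = "chrM",
                           chromosome_order = default_chromosome_order()) {
  stopifnot(all(c("gene_id", "chromosome", "start", "stop") %in% names(df)))
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  if (any(df$stop < df$start)) {
    stop("stop < start for gene ", df$gene_id[which(df$stop < df$start)[1]])
  }
  df <- df[!(df$chromosome %in% excluded_chromosomes), , drop = FALSE]
  chrom_rank <- match(df$chromosome, chromosome_order)
  extra <- sort(unique(df$chromosome[is.na(chrom_rank)]))
  chrom_rank[is.na(chrom_rank)] <-
    length(chromosome_order) + match(df$chromosome[is.na(chrom_rank)], extra)
  ord <- order(chrom_rank, df$start, df$gene_id)
  out <- df[ord, c("gene_id", "chromosome", "start", "stop"), drop = FALSE]
  out$genome_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("gene_positions", "data.frame")
  out
}

#' Construct a spot-by-gene count matrix
#'
#' The canonical count container: spots are observations (rows), genes are
#' variables (columns). Counts must be non-negative integers.
#'
#' @param counts Matrix or sparse `Matrix` (spots x genes) with barcode row
#'   names and gene column names.
#' @param section_of Optional named character vector mapping each barcode to a
#'   section label; defaults to a single section `"S1"`.
#' @return An object of class `spot_counts`.
#' @export
spot_counts <- function(counts, section_of = NULL) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry barcode rownames and gene colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate barcodes: ",
         paste(utils::head(unique(rownames(counts)[duplicated(rownames(counts))])),
               collapse = ", "))
  }
  v <- counts@x
  if (any(v < 0)) stop("negative counts are not allowed")
  if (any(v != round(v))) stop("counts must be integral")
  if (is.null(section_of)) {
    section_of <- stats::setNames(rep("S1", nrow(counts)), rownames(counts))
  }
  if (!all(rownames(counts) %in% names(section_of))) {
    stop("section_of must cover every barcode")
  }
  structure(list(counts = counts,
                 section_of = section_of[rownames(counts)]),
            class = "spot_counts")
}

#' @export
print.spot_counts <- function(x, ...) {
  cat(sprintf("spot_counts: %d spots x %d genes, %d section(s), %.0f total UMIs\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$section_of)), sum(x$counts)))
  invisible(x)
}

#' @export
dim.spot_counts <- function(x) dim(x$counts)

#' Barcodes of a count matrix
#' @param x A `spot_counts` object.
#' @return Character vector of spot barcodes.
#' @export
barcodes <- function(x) rownames(x$counts)

#' Load a spot-by-gene count matrix
#'
#' Supports the 10x-style MatrixMarket triplet directory (`matrix.mtx`,
#' `barcodes.tsv`, `features.tsv`, genes in rows of the matrix) and a dense
#' TSV with genes in rows and barcodes as column headers. The HDF5
#' filtered-matrix dialect is not supported in this build (no HDF5 reader is
#' available); requesting it is an error.
#'
#' @param path Directory (MatrixMarket) or file (dense TSV).
#' @param format One of `"auto"`, `"mtx"`, `"tsv"`.
#' @param section Optional section label applied to all barcodes.
#' @return A [spot_counts()] object (all-zero spots retained; QC is separate).
#' @export
load_count_matrix <- function(path, format = c("auto", "mtx", "tsv", "h5"),
                              section = "S1") {
  format <- match.arg(format)
  if (format == "auto") format <- if (dir.exists(path)) "mtx" else "tsv"
  if (format == "h5") {
    stop("HDF5 filtered-matrix input is not supported in this build; ",
         "export the matrix as MatrixMarket triplet or dense TSV")
  }
  if (format == "mtx") {
    mtx_file <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx_file)) stop("missing ", mtx_file)
    m <- Matrix::readMM(mtx_file)
    bc <- utils::read.table(file.path(path, "barcodes.tsv"), header = FALSE,
                            colClasses = "character")[[1]]
    ft <- utils::read.table(file.path(path, "features.tsv"), header = FALSE,
                            sep = "\t", colClasses = "character")
    if (nrow(m) != nrow(ft) || ncol(m) != length(bc)) {
      stop(sprintf("dimension mismatch: matrix is %d x %d but %d features / %d barcodes listed",
                   nrow(m), ncol(m), nrow(ft), length(bc)))
    }
    rownames(m) <- ft[[1]]
    colnames(m) <- bc
    counts <- Matrix::t(m)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE)
    counts <- Matrix::t(Matrix::Matrix(as.matrix(df), sparse = TRUE))
  }
  spot_counts(counts, stats::setNames(rep(section, nrow(counts)), rownames(counts)))
}

#' Write a count matrix
#'
#' Inverse of [load_count_matrix()]: MatrixMarket triplet directory or dense
#' TSV (genes in rows). Round-trips counts bit-exactly.
#'
#' @param x A `spot_counts` object.
#' @param path Output directory (`mtx`) or file (`tsv`).
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::t(x$counts), file.path(path, "matrix.mtx"))
    writeLines(rownames(x$counts), file.path(path, "barcodes.tsv"))
    utils::write.table(data.frame(id = colnames(x$counts), name = colnames(x$counts),
                                  type = "Gene Expression"),
                       file.path(path, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    dense <- as.matrix(Matrix::t(x$counts))
    df <- data.frame(gene = rownames(dense), dense, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Merge per-section count matrices
#'
#' Rewrites each barcode as `<section>_<barcode>`, takes the union of the
#' gene universes (filling zeros for genes absent from a section) and stacks
#' the spots. Total UMI mass is preserved.
#'
#' @param matrices Named list of `spot_counts`; names are section labels.
#' @return A merged `spot_counts`.
#' @export
merge_sections <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  labels <- names(matrices)
  if (is.null(labels) || any(labels == "")) stop("every matrix needs a section label")
  if (anyDuplicated(labels)) {
    stop("colliding section labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  genes <- unique(unlist(lapply(matrices, function(m) colnames(m$counts))))
  pieces <- lapply(labels, function(lab) {
    m <- matrices[[lab]]$counts
    full <- Matrix::Matrix(0, nrow = nrow(m), ncol = length(genes), sparse = TRUE,
                           dimnames = list(paste(lab, rownames(m), sep = "_"), genes))
    full[, colnames(m)] <- m
    full
  })
  merged <- do.call(rbind, pieces)
  sections <- rep(labels, vapply(matrices, function(m) nrow(m$counts), 1L))
  spot_counts(merged, stats::setNames(sections, rownames(merged)))
}

#' Spot quality-control configuration
#'
#' @param min_spot_counts Spots with total UMI count less than or equal to
#'   this are removed (default 500, the Visium threshold).
#' @param min_spot_genes Spots detecting fewer than this many genes are
#'   removed (default 100, the 1k-array threshold).
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_spot_counts = 500, min_spot_genes = 100) {
  stopifnot(min_spot_counts >= 0, min_spot_genes >= 0)
  structure(list(min_spot_counts = min_spot_counts,
                 min_spot_genes = min_spot_genes), class = "qc_config")
}

#' Remove low-quality spots
#'
#' Drops spots whose total UMI count is `<= min_spot_counts` or whose number
#' of detected genes is `< min_spot_genes`, and reports how many were removed.
#' Idempotent.
#'
#' @param x A `spot_counts` object.
#' @param config A [qc_config()].
#' @return The filtered `spot_counts`.
#' @export
qc_filter_spots <- function(x, config = qc_config()) {
  totals <- Matrix::rowSums(x$counts)
  n_genes <- Matrix::rowSums(x$counts > 0)
  keep <- totals > config$min_spot_counts & n_genes >= config$min_spot_genes
  if (!any(keep)) {
    stop("QC removed every spot (", length(keep), " of ", length(keep),
         "); review min_spot_counts/min_spot_genes thresholds")
  }
  message(sprintf("qc_filter_spots: removed %d of %d spots (kept %d)",
                  sum(!keep), length(keep), sum(keep)))
  spot_counts(x$counts[keep, , drop = FALSE], x$section_of[keep])
}

#' Read Loupe-style spot annotations
#'
#' CSV with header `Barcode,Annotation`.
#'
#' @param path CSV path.
#' @return Data frame with columns `barcode`, `label`.
#' @export
read_spot_annotations <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("annotation file must have columns Barcode,Annotation")
  out <- data.frame(barcode = df[[1]], label = df[[2]], stringsAsFactors = FALSE)
  if (anyDuplicated(out$barcode)) {
    stop("duplicate barcode in annotations: ",
         out$barcode[which(duplicated(out$barcode))[1]])
  }
  out
}

#' Annotation labels for a set of barcodes
#'
#' Barcodes present in the counts but absent from the annotation table are
#' labelled `"exclude"` (un-annotatable spots are discarded downstream).
#'
#' @param annotations Data frame from [read_spot_annotations()].
#' @param barcodes Character vector of barcodes to label.
#' @return Named character vector of labels.
#' @export
annotation_labels <- function(annotations, barcodes) {
  lab <- annotations$label[match(barcodes, annotations$barcode)]
  lab[is.na(lab)] <- "exclude"
  stats::setNames(lab, barcodes)
}

#' Read a tissue-positions table
#'
#' CSV dialect: barcode, in_tissue, array_row, array_col, pixel_row,
#' pixel_col (no header assumed; a header line is detected and skipped).
#'
#' @param path CSV path.
#' @return Data frame with those six columns.
#' @export
read_spot_positions <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (grepl("barcode", first, ignore.case = TRUE)) 1 else 0
  df <- utils::read.csv(path, header = FALSE, skip = skip,
                        col.names = c("barcode", "in_tissue", "array_row",
                                      "array_col", "pixel_row", "pixel_col"))
  df$barcode <- as.character(df$barcode)
  df
}
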
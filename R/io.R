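#' Read a 10x-style triplet directory
#'
#' Reads a MatrixMarket sparse count matrix plus its feature and barcode
#' tables (plain or gzipped) into a `SingleCellExperiment`. An optional
#' `metadata.tsv` (columns `cell_id`, `sample`, `region`, `age_months`,
#' `sex`) populates the per-cell annotations; without it, placeholder
#' metadata is attached so the object still validates.
#'
#' MatrixMarket files use 1-based indices on disk; all in-memory indexing
#' is 0/1-based R convention via the Matrix package.
#'
#' @param dir directory containing `matrix.mtx[.gz]`, `features.tsv[.gz]`,
#'   `barcodes.tsv[.gz]` and optionally `metadata.tsv[.gz]`.
#' @return `SingleCellExperiment` with a `counts` assay.
#' @export
read_10x_triplet <- function(dir) {
  mtx_path <- .find_triplet_file(dir, "matrix.mtx")
  feat_path <- .find_triplet_file(dir, "features.tsv")
  bc_path <- .find_triplet_file(dir, "barcodes.tsv")

  m <- if (grepl("\\.gz$", mtx_path)) {
    con <- gzfile(mtx_path)
    on.exit(try(close(con), silent = TRUE), add = TRUE)
    Matrix::readMM(con)
  } else {
    Matrix::readMM(mtx_path)
  }
  # readMM returns a triplet matrix, so duplicated coordinates are still
  # visible here; reject them before they silently sum on coercion.
  if (anyDuplicated(cbind(m@i, m@j)))
    stop("parse error in ", mtx_path, ": duplicate (row, column) coordinates")

  features <- utils::read.table(feat_path, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE, quote = "")
  barcodes <- utils::read.table(bc_path, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE, quote = "")
  if (nrow(features) != nrow(m))
    stop("parse error: ", feat_path, " has ", nrow(features),
         " features but matrix header declares ", nrow(m), " rows")
  if (nrow(barcodes) != ncol(m))
    stop("parse error: ", bc_path, " has ", nrow(barcodes),
         " barcodes but matrix header declares ", ncol(m), " columns")
  rownames(m) <- features[[1]]
  colnames(m) <- barcodes[[1]]

  meta_path <- tryCatch(.find_triplet_file(dir, "metadata.tsv"),
                        error = function(e) NULL)
  if (!is.null(meta_path)) {
    meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, quote = "")
  } else {
    meta <- data.frame(cell_id = colnames(m), sample = "sample1",
                       region = NA_character_, age_months = NA_real_,
                       sex = NA_character_, stringsAsFactors = FALSE)
  }
  as_niche_sce(m, meta)
}

#' Write a 10x-style triplet directory
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` and `metadata.tsv`
#' (optionally gzipped) so that [read_10x_triplet()] round-trips the
#' object exactly.
#'
#' @param sce `SingleCellExperiment` with a counts layer.
#' @param dir output directory (created if needed).
#' @param gzip compress the four files.
#' @return `dir`, invisibly.
#' @export
write_10x_triplet <- function(sce, dir, gzip = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- .counts(sce)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(counts, mtx)
  .write_tsv_plain(data.frame(rownames(counts)), file.path(dir, "features.tsv"),
                   col_names = FALSE)
  .write_tsv_plain(data.frame(colnames(counts)), file.path(dir, "barcodes.tsv"),
                   col_names = FALSE)
  meta <- .cell_meta(sce)
  keep <- intersect(c("cell_id", "sample", "region", "age_months", "sex"),
                    colnames(meta))
  .write_tsv_plain(meta[, keep, drop = FALSE], file.path(dir, "metadata.tsv"),
                   col_names = TRUE)
  if (gzip) {
    for (f in c("matrix.mtx", "features.tsv", "barcodes.tsv", "metadata.tsv")) {
      p <- file.path(dir, f)
      .gzip_file(p)
      unlink(p)
    }
  }
  invisible(dir)
}

.find_triplet_file <- function(dir, stem) {
  for (cand in c(file.path(dir, stem), file.path(dir, paste0(stem, ".gz")))) {
    if (file.exists(cand)) return(cand)
  }
  stop("no ", stem, "[.gz] found in ", dir)
}

.write_tsv_plain <- function(df, path, col_names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col_names)
}

.gzip_file <- function(path) {
  raw_in <- readBin(path, what = "raw", n = file.info(path)$size)
  con <- gzfile(paste0(path, ".gz"), "wb")
  writeBin(raw_in, con)
  close(con)
  invisible(paste0(path, ".gz"))
}
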
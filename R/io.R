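#' Read a single-cell copy-number table
#'
#' Loads the tabular output of an scCNA caller into a [cnv_matrix()]. Three
#' dialects are understood:
#'
#' * `"segcopy"` — Ginkgo SegCopy style: tab-separated with columns `CHR`,
#'   `START`, `END` followed by one column per cell. Coordinates are 1-based
#'   inclusive and converted to the internal 0-based half-open convention.
#' * `"generic_wide"` — like segcopy but with lower-case `chrom`/`chromosome`,
#'   `start`, `end` coordinate columns.
#' * `"generic_long"` — tab-separated with columns `cell`, `chromosome`,
#'   `start`, `end`, `copy_number` (and optionally `sample`).
#'
#' Files ending in `.gz` are decompressed transparently. Bins are sorted into
#' genomic order; all cells are given the single `sample` label unless a long
#' table carries its own `sample` column. A sidecar annotation file written by
#' [write_cnv()] (`<path>.cells.tsv`, columns `cell`, `sample`) is picked up
#' automatically to restore per-cell sample labels.
#'
#' @param path path to the table.
#' @param format one of `"segcopy"`, `"generic_wide"`, `"generic_long"`.
#' @param sample sample label applied to all cells (default: file base name).
#' @return a [cnv_matrix()].
#' @seealso [write_cnv()]
#' @export
read_cnv <- function(path, format = c("segcopy", "generic_wide",
                                      "generic_long"),
                     sample = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample))
    sample <- sub("\\.(tsv|txt|bed)(\\.gz)?$", "", basename(path))
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- if (format == "generic_long") parse_long(df) else
    parse_wide(df, segcopy = format == "segcopy")
  if (all(m$sample == "")) m$sample <- rep(sample, nrow(m$values))
  sidecar <- paste0(path, ".cells.tsv")
  if (file.exists(sidecar)) {
    ann <- read.delim(sidecar, stringsAsFactors = FALSE)
    idx <- match(rownames(m$values), ann$cell)
    if (!anyNA(idx)) m$sample <- ann$sample[idx]
  }
  m
}

parse_wide <- function(df, segcopy = TRUE) {
  nm <- tolower(names(df))
  ic <- match(c("chr", "chrom", "chromosome"), nm)
  ic <- ic[!is.na(ic)][1]
  is <- match("start", nm)
  ie <- match("end", nm)
  if (is.na(ic) || is.na(is) || is.na(ie))
    stop("malformed header: need chromosome/start/end columns, got: ",
         paste(names(df), collapse = ", "))
  coord_cols <- c(ic, is, ie)
  cell_cols <- setdiff(seq_along(df), coord_cols)
  if (!length(cell_cols)) stop("no cell columns found")
  start <- suppressWarnings(as.numeric(df[[is]]))
  end <- suppressWarnings(as.numeric(df[[ie]]))
  if (anyNA(start) || anyNA(end))
    stop("coordinate columns must be integer-valued")
  vals <- sapply(cell_cols, function(j) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v) && !anyNA(df[[j]]))
      stop("non-numeric copy-number value in column '", names(df)[j], "'")
    v
  })
  vals <- matrix(vals, ncol = length(cell_cols))
  if (anyNA(vals)) stop("missing copy-number values in input")
  # segcopy/wide tables are 1-based inclusive; internal storage 0-based
  # half-open, so start shifts down by one and end is kept.
  bins <- data.frame(chrom = as.character(df[[ic]]), start = start - 1,
                     end = end, stringsAsFactors = FALSE)
  cnv_matrix(t(vals), bins, cells = names(df)[cell_cols], sample = "")
}

parse_long <- function(df) {
  nm <- tolower(names(df))
  names(df) <- nm
  if (!"chromosome" %in% nm && "chrom" %in% nm)
    names(df)[match("chrom", names(df))] <- "chromosome"
  need <- c("cell", "chromosome", "start", "end", "copy_number")
  if (!all(need %in% names(df)))
    stop("malformed header: long format needs columns ",
         paste(need, collapse = ", "))
  df$copy_number <- suppressWarnings(as.numeric(df$copy_number))
  if (anyNA(df$copy_number)) stop("non-numeric copy-number value")
  key <- paste(df$chromosome, df$start, df$end)
  ukey <- unique(key)
  cells <- unique(df$cell)
  vals <- matrix(NA_real_, nrow = length(cells), ncol = length(ukey),
                 dimnames = list(cells, ukey))
  vals[cbind(match(df$cell, cells), match(key, ukey))] <- df$copy_number
  if (anyNA(vals)) stop("incomplete long table: not every cell covers every bin")
  first <- match(ukey, key)
  bins <- data.frame(chrom = as.character(df$chromosome[first]),
                     start = as.numeric(df$start[first]) - 1,
                     end = as.numeric(df$end[first]),
                     stringsAsFactors = FALSE)
  sample <- if ("sample" %in% names(df))
    as.character(df$sample[match(cells, df$cell)]) else ""
  cnv_matrix(vals, bins, cells = cells, sample = sample)
}

#' Write a copy-number matrix as a SegCopy-style table
#'
#' Emits a tab-separated table with columns `CHR`, `START`, `END` (1-based
#' inclusive, the Ginkgo convention) followed by one column per cell, plus a
#' sidecar `<path>.cells.tsv` with the per-cell sample labels whenever the
#' matrix holds more than one sample. Paths ending in `.gz` are compressed.
#' `read_cnv(write_cnv(m, path))` reproduces `m` exactly.
#'
#' @param x a [cnv_matrix()].
#' @param path output path.
#' @param sidecar write the per-cell annotation file (default: only when
#'   multiple sample labels are present).
#' @return `path`, invisibly.
#' @export
write_cnv <- function(x, path, sidecar = length(unique(x$sample)) > 1L) {
  stopifnot(inherits(x, "cnv_matrix"))
  out <- data.frame(CHR = x$bins$chrom,
                    START = format(x$bins$start + 1, scientific = FALSE,
                                   trim = TRUE),
                    END = format(x$bins$end, scientific = FALSE, trim = TRUE),
                    stringsAsFactors = FALSE, check.names = FALSE)
  vals <- t(x$values)
  colnames(vals) <- rownames(x$values)
  out <- cbind(out, as.data.frame(vals, check.names = FALSE))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (isTRUE(sidecar))
    write.table(data.frame(cell = rownames(x$values), sample = x$sample),
                paste0(path, ".cells.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}
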
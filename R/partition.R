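#' Define a partition of sample labels into blocks
#'
#' A partition assigns every sample of an aggregated dataset to exactly one
#' of at least two disjoint blocks; the SHscore is evaluated on cells grouped
#' by block. The canonical name joins the labels of each block with `+` and
#' the blocks with ` vs `, e.g. `"S_C+S_D+S_E vs S_B"`.
#'
#' @param blocks list of character vectors of sample labels; blocks must be
#'   non-empty, disjoint, and there must be at least two.
#' @return object of class `sample_partition` with elements `blocks` (labels
#'   sorted within blocks, blocks sorted by first label) and `name`.
#' @examples
#' sample_partition(list(c("S_C", "S_D", "S_E"), "S_B"))
#' @export
sample_partition <- function(blocks) {
  blocks <- lapply(blocks, as.character)
  if (length(blocks) < 2L) stop("a partition needs at least 2 blocks")
  if (any(!lengths(blocks))) stop("empty block in partition")
  all_labels <- unlist(blocks)
  if (anyDuplicated(all_labels))
    stop("blocks are not disjoint: ",
         paste(unique(all_labels[duplicated(all_labels)]), collapse = ", "))
  blocks <- lapply(blocks, sort)
  blocks <- blocks[order(vapply(blocks, `[`, "", 1L))]
  structure(list(blocks = blocks,
                 name = paste(vapply(blocks, paste, "", collapse = "+"),
                              collapse = " vs ")),
            class = "sample_partition")
}

#' @export
print.sample_partition <- function(x, ...) {
  cat("sample partition:", x$name, "\n")
  invisible(x)
}

# Map each cell's sample label to its block index; errors on labels
# absent from the partition or blocks absent from the data.
partition_blocks_of <- function(partition, sample_labels) {
  lookup <- rep(seq_along(partition$blocks), lengths(partition$blocks))
  names(lookup) <- unlist(partition$blocks)
  unknown <- setdiff(unique(sample_labels), names(lookup))
  if (length(unknown))
    stop("sample label(s) not covered by the partition: ",
         paste(unknown, collapse = ", "))
  blk <- unname(lookup[sample_labels])
  missing_blk <- setdiff(seq_along(partition$blocks), unique(blk))
  if (length(missing_blk))
    stop("partition block(s) contribute no cells: ",
         paste(vapply(partition$blocks[missing_blk], paste, "",
                      collapse = "+"), collapse = "; "))
  blk
}

#' Enumerate all partitions of a sample set
#'
#' Generates every set partition of the given sample labels into at least two
#' blocks — Bell(n) - 1 partitions — ordered by block count, then by
#' canonical name. This generalises the worked three-sample case (the four
#' partitions S1|S2|S3, S1+S2|S3, S1+S3|S2, S2+S3|S1) to any sample count.
#' Growth is Bell-number fast, so the enumeration refuses more than
#' `max_samples` samples unless overridden.
#'
#' @param samples character vector of sample labels (>= 2, no duplicates).
#' @param max_samples refusal threshold (default 6, Bell(6) - 1 = 202).
#' @param allow_large set `TRUE` to lift the cap explicitly.
#' @return list of [sample_partition()] objects.
#' @examples
#' length(enumerate_partitions(c("A", "B", "C")))       # 4
#' length(enumerate_partitions(c("A", "B", "C", "D")))  # 14
#' @export
enumerate_partitions <- function(samples, max_samples = 6,
                                 allow_large = FALSE) {
  samples <- as.character(samples)
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples")
  if (anyDuplicated(samples)) stop("duplicate sample labels")
  if (n > max_samples && !allow_large)
    stop(n, " samples exceed the enumeration cap of ", max_samples,
         " (Bell-number growth); pass allow_large = TRUE to override")
  # restricted growth strings: element i may join block <= max(existing) + 1
  assigns <- list(1L)
  for (i in seq_len(n - 1L)) {
    assigns <- unlist(lapply(assigns, function(a) {
      lapply(seq_len(max(a) + 1L), function(b) c(a, b))
    }), recursive = FALSE)
  }
  parts <- lapply(assigns, function(a) {
    if (max(a) < 2L) return(NULL)
    sample_partition(split(samples, a))
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  ord <- order(vapply(parts, function(p) length(p$blocks), 1L),
               vapply(parts, `[[`, "", "name"))
  parts[ord]
}
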
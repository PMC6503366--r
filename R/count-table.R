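#' Construct a two-library count table
#'
#' A count table holds, per gene, the transcript length and the raw read
#' counts observed in each of two unreplicated libraries. The convention
#' throughout the package is that library A is the nonpregnant-condition
#' library and library B the pregnant-condition library, so downstream
#' log2 ratios are oriented pregnant over nonpregnant.
#'
#' Library totals default to the column sums of the counts, which equals the
#' "reads uniquely aligned to all genes" definition whenever the table covers
#' all detected genes. They can be overridden (e.g. with externally known
#' mapped-read totals) via `lib_total_a` / `lib_total_b`.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param length_bp positive integer vector of gene lengths in base pairs.
#' @param count_a,count_b nonnegative integer read counts in library A
#'   (nonpregnant) and library B (pregnant).
#' @param lib_total_a,lib_total_b optional positive totals of reads in each
#'   library; default to `sum(count_a)` / `sum(count_b)`.
#' @return a `count_table`: a data.frame with columns `gene_id`, `length_bp`,
#'   `count_a`, `count_b` and attributes `lib_total_a`, `lib_total_b`.
#' @examples
#' ct <- count_table(c("g1", "g2"), c(1000L, 2000L), c(10L, 0L), c(5L, 8L))
#' lib_totals(ct)
#' @export
count_table <- function(gene_id, length_bp, count_a, count_b,
                        lib_total_a = NULL, lib_total_b = NULL) {
  gene_id <- as.character(gene_id)
  n <- length(gene_id)
  if (length(length_bp) != n || length(count_a) != n || length(count_b) != n)
    stop("gene_id, length_bp, count_a and count_b must have equal length")
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1L])
  if (any(!is.finite(length_bp)) || any(length_bp <= 0))
    stop("all gene lengths must be positive")
  if (any(!is.finite(count_a)) || any(count_a < 0) ||
      any(!is.finite(count_b)) || any(count_b < 0))
    stop("counts must be nonnegative")
  if (is.null(lib_total_a)) lib_total_a <- sum(count_a)
  if (is.null(lib_total_b)) lib_total_b <- sum(count_b)
  if (lib_total_a <= 0 || lib_total_b <= 0)
    stop("library totals must be positive")
  out <- data.frame(gene_id = gene_id,
                    length_bp = as.integer(round(length_bp)),
                    count_a = as.numeric(count_a),
                    count_b = as.numeric(count_b),
                    stringsAsFactors = FALSE)
  attr(out, "lib_total_a") <- as.numeric(lib_total_a)
  attr(out, "lib_total_b") <- as.numeric(lib_total_b)
  class(out) <- c("count_table", "data.frame")
  out
}

#' Library totals of a count table
#'
#' @param x a `count_table`.
#' @return named numeric vector `c(lib_total_a = ..., lib_total_b = ...)`.
#' @export
lib_totals <- function(x) {
  stopifnot(inherits(x, "count_table"))
  c(lib_total_a = attr(x, "lib_total_a"),
    lib_total_b = attr(x, "lib_total_b"))
}

#' Read a count table from TSV
#'
#' The dialect is UTF-8, tab-separated, with a header line
#' `gene_id  length  count_a  count_b`. Optional `#`-prefixed metadata lines
#' before the header may carry library totals as `#lib_total_a=...` and
#' `#lib_total_b=...`; without them the totals default to the column sums.
#'
#' @param path file path.
#' @return a [count_table()].
#' @export
read_count_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines)
  lib_total_a <- lib_total_b <- NULL
  for (i in meta) {
    kv <- sub("^#\\s*", "", lines[i])
    if (grepl("^lib_total_a=", kv)) lib_total_a <- as.numeric(sub("^lib_total_a=", "", kv))
    if (grepl("^lib_total_b=", kv)) lib_total_b <- as.numeric(sub("^lib_total_b=", "", kv))
  }
  body_idx <- setdiff(seq_along(lines), meta)
  body <- lines[body_idx]
  body <- body[nzchar(body)]
  if (length(body) < 1L) stop("count table file has no header: ", path)
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  required <- c("gene_id", "length", "count_a", "count_b")
  if (!all(required %in% header))
    stop("count table header must contain columns: ",
         paste(required, collapse = ", "))
  col <- match(required, header)
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  parse_num <- function(values, what, line_no) {
    x <- suppressWarnings(as.numeric(values))
    bad <- which(is.na(x))
    if (length(bad) > 0L)
      stop(sprintf("malformed %s '%s' at line %d", what,
                   values[bad[1L]], line_no[bad[1L]]))
    x
  }
  # line numbers in the original file, for error messages
  line_no <- body_idx[match(body[-1L], lines[body_idx])]
  nfield <- lengths(rows)
  if (any(nfield < length(header)))
    stop("missing column at line ", line_no[which(nfield < length(header))[1L]])
  get <- function(j) vapply(rows, `[[`, character(1L), col[j])
  gene_id <- get(1L)
  dup <- which(duplicated(gene_id))
  if (length(dup) > 0L)
    stop(sprintf("duplicate gene_id '%s' at line %d", gene_id[dup[1L]], line_no[dup[1L]]))
  length_bp <- parse_num(get(2L), "length", line_no)
  ca <- parse_num(get(3L), "count_a", line_no)
  cb <- parse_num(get(4L), "count_b", line_no)
  neg <- which(ca < 0 | cb < 0)
  if (length(neg) > 0L) stop("negative count at line ", line_no[neg[1L]])
  count_table(gene_id, length_bp, ca, cb,
              lib_total_a = lib_total_a, lib_total_b = lib_total_b)
}

#' Write a count table to TSV
#'
#' Writes the dialect read by [read_count_table()], including the library
#' totals as metadata lines, so that a read/write cycle round-trips exactly.
#'
#' @param x a `count_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  totals <- lib_totals(x)
  writeLines(c(sprintf("#lib_total_a=%s", format(totals[["lib_total_a"]], scientific = FALSE)),
               sprintf("#lib_total_b=%s", format(totals[["lib_total_b"]], scientific = FALSE)),
               "gene_id\tlength\tcount_a\tcount_b"), con)
  writeLines(sprintf("%s\t%d\t%s\t%s", x$gene_id, x$length_bp,
                     format(x$count_a, scientific = FALSE, trim = TRUE),
                     format(x$count_b, scientific = FALSE, trim = TRUE)), con)
  invisible(path)
}
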
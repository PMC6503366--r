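#' RPKM expression level
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `10^9 * C / (N * L)` for a gene with `C` uniquely aligned reads and length
#' `L` bp in a library with `N` uniquely aligned reads in total. This is
#' algebraically the usual `10^6 * C / (N * L / 10^3)` form.
#'
#' @param count nonnegative read count(s) `C`.
#' @param lib_total positive library total `N`.
#' @param length_bp positive gene length `L` in bp.
#' @return RPKM value(s), vectorized over the arguments.
#' @examples
#' compute_rpkm(10, 1e6, 1000)  # 10
#' @export
compute_rpkm <- function(count, lib_total, length_bp) {
  if (any(count < 0)) stop("count must be nonnegative")
  if (any(lib_total <= 0)) stop("lib_total must be positive")
  if (any(length_bp <= 0)) stop("length_bp must be positive")
  1e9 * count / (lib_total * length_bp)
}

#' Log2 fold change between two RPKM values
#'
#' Oriented pregnant over nonpregnant, matching the study's fold-change
#' definition. Zero RPKM values are floored at `zero_floor` before taking the
#' ratio so that genes expressed in only one library receive a large but
#' finite log2 ratio rather than +/-Inf.
#'
#' @param rpkm_pregnant,rpkm_nonpregnant nonnegative RPKM values.
#' @param zero_floor positive floor applied to both values. A natural choice
#'   is the RPKM a single read would produce in the smaller library
#'   (see [rpkm_table()], which uses that default).
#' @return `log2(pmax(rpkm_pregnant, zero_floor) / pmax(rpkm_nonpregnant,
#'   zero_floor))`.
#' @export
log2_fold_change <- function(rpkm_pregnant, rpkm_nonpregnant, zero_floor) {
  if (any(rpkm_pregnant < 0) || any(rpkm_nonpregnant < 0))
    stop("RPKM values must be nonnegative")
  if (any(zero_floor <= 0)) stop("zero_floor must be positive")
  log2(pmax(rpkm_pregnant, zero_floor) / pmax(rpkm_nonpregnant, zero_floor))
}

#' Per-gene RPKM and log2 ratio for a count table
#'
#' Computes RPKM in both libraries and the pregnant/nonpregnant log2 ratio
#' for every gene. The default `zero_floor` is per-gene: the RPKM that a
#' single read would yield for that gene in the smaller of the two libraries,
#' the most conservative finite stand-in for "not observed".
#'
#' @param counts a [count_table()] (library A nonpregnant, B pregnant).
#' @param zero_floor positive scalar floor, or `NULL` (default) for the
#'   per-gene single-read floor.
#' @return data.frame with columns `gene_id`, `rpkm_a`, `rpkm_b`,
#'   `log2_ratio`, `floored` (logical: was the floor active for this gene).
#' @export
rpkm_table <- function(counts, zero_floor = NULL) {
  stopifnot(inherits(counts, "count_table"))
  totals <- lib_totals(counts)
  rpkm_a <- compute_rpkm(counts$count_a, totals[["lib_total_a"]], counts$length_bp)
  rpkm_b <- compute_rpkm(counts$count_b, totals[["lib_total_b"]], counts$length_bp)
  if (is.null(zero_floor)) {
    floor_g <- compute_rpkm(1, min(totals), counts$length_bp)
  } else {
    if (any(zero_floor <= 0)) stop("zero_floor must be positive")
    floor_g <- rep_len(zero_floor, nrow(counts))
  }
  floored <- rpkm_a < floor_g | rpkm_b < floor_g
  data.frame(gene_id = counts$gene_id,
             rpkm_a = rpkm_a,
             rpkm_b = rpkm_b,
             log2_ratio = log2_fold_change(rpkm_b, rpkm_a, floor_g),
             floored = floored,
             stringsAsFactors = FALSE)
}

#' Write per-gene expression records to TSV
#'
#' Columns `(gene_id, rpkm_a, rpkm_b, log2_ratio, floored)`; RPKM and ratios
#' are written with 6 significant digits.
#'
#' @param records output of [rpkm_table()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(records, path) {
  out <- records
  for (col in c("rpkm_a", "rpkm_b", "log2_ratio"))
    out[[col]] <- signif(out[[col]], 6L)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
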
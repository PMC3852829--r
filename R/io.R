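#' Read a gene annotation file
#'
#' Two dialects are supported. `tsv` is a headered table with columns
#' `gene_id`, `chrom`, `strand`, `tss` (tss already 0-based). `bed6` is a
#' headerless BED6 file whose name column supplies the gene id; the TSS is
#' derived from the strand: `start` for `+` genes and `end - 1` for `-`
#' genes (0-based half-open arithmetic).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"bed6"`.
#' @return A [GenomeAnnotation]. Row order of the file is preserved.
#' @export
read_gene_annotation <- function(path, dialect = c("tsv", "bed6")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_parse("annotation file not found: %s", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "tss")
    if (!all(need %in% names(df)))
      stop_parse("annotation tsv must have columns %s", paste(need, collapse = ", "))
    tss <- suppressWarnings(as.numeric(df$tss))
    if (any(is.na(tss)))
      stop_parse("malformed tss at line %d of %s",
                 which(is.na(tss))[1] + 1L, path)  # +1 for header
    GenomeAnnotation(df$gene_id, df$chrom, df$strand, tss)
  } else {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "name",
                                          "score", "strand"),
                            colClasses = c("character", "numeric", "numeric",
                                           "character", "character", "character"))
    bad <- which(is.na(df$start) | is.na(df$end) | df$start >= df$end)
    if (length(bad))
      stop_parse("malformed bed6 interval at line %d of %s", bad[1], path)
    tss <- ifelse(df$strand == "+", df$start, df$end - 1)
    GenomeAnnotation(df$name, df$chrom, df$strand, tss)
  }
}

#' Read a peak file
#'
#' `narrowPeak` is the ENCODE BED6+4 dialect: column 9 is the -log10
#' q-value (back-transformed here to a raw probability, `q = 10^-col9`)
#' and column 10 the summit offset from `start` (`-1` means no summit).
#' `bed5q` is a plain 5-column table `chrom start end score q` with the
#' q-value already on the raw probability scale.
#'
#' @param path file path.
#' @param dialect `"narrowPeak"` or `"bed5q"`.
#' @param tf_name,replicate labels stored on the returned set.
#' @return A [PeakSet] with raw q-values.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "bed5q"),
                       tf_name = "", replicate = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_parse("peak file not found: %s", path)
  if (dialect == "narrowPeak") {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "name",
                                          "score", "strand", "signal",
                                          "p_log10", "q_log10", "summit_off"))
    bad <- which(df$start >= df$end)
    if (length(bad)) stop_parse("peak start >= end at line %d of %s", bad[1], path)
    q <- 10^(-df$q_log10)
    if (any(!(q > 0 & q <= 1)))
      stop_validation("q-value outside (0, 1] after back-transform in %s", path)
    summit <- ifelse(df$summit_off >= 0, df$start + df$summit_off, NA_integer_)
    PeakSet(df$chrom, df$start, df$end, summit = summit, score = df$score,
            q_value = q, tf_name = tf_name, replicate = replicate)
  } else {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "score", "q"))
    bad <- which(df$start >= df$end)
    if (length(bad)) stop_parse("peak start >= end at line %d of %s", bad[1], path)
    if (any(!(df$q > 0 & df$q <= 1)))
      stop_validation("q-value outside (0, 1] in %s", path)
    PeakSet(df$chrom, df$start, df$end, score = df$score, q_value = df$q,
            tf_name = tf_name, replicate = replicate)
  }
}

#' Write a peak set as narrowPeak
#'
#' Inverse of [read_peaks] for the `narrowPeak` dialect; q-values are
#' written as -log10, missing summits as offset -1.
#'
#' @param ps a [PeakSet].
#' @param path output path.
#' @export
write_narrowpeak <- function(ps, path) {
  off <- ifelse(is.na(ps$summit), -1L, ps$summit - ps$start)
  df <- data.frame(ps$chrom, ps$start, ps$end, ".", ps$score, ".",
                   0, -1, format(-log10(ps$q_value), digits = 17), off)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample expression matrix
#'
#' Expects a headered TSV whose first column holds gene ids and remaining
#' columns one sample each.
#'
#' @param path file path.
#' @param group_map either a named character vector mapping sample id to
#'   `"control"`/`"treatment"`, or the path of a two-column headered TSV
#'   (`sample_id`, `group`).
#' @return An [ExpressionMatrix].
#' @export
read_expression_matrix <- function(path, group_map) {
  if (!file.exists(path)) stop_parse("expression file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m)))
    stop_validation("duplicate gene ids in expression matrix %s", path)
  if (is.character(group_map) && is.null(names(group_map)) &&
      length(group_map) == 1 && file.exists(group_map)) {
    g <- utils::read.delim(group_map, stringsAsFactors = FALSE)
    group_map <- stats::setNames(g[[2]], g[[1]])
  }
  unknown <- setdiff(names(group_map), colnames(m))
  if (length(unknown))
    stop_validation("group_map names samples absent from the matrix: %s",
                    paste(unknown, collapse = ", "))
  ExpressionMatrix(m, group_map)
}

#' Write an expression matrix (and optionally its group labels)
#'
#' @param m an [ExpressionMatrix].
#' @param path output TSV path.
#' @param groups_path optional path for a two-column `sample_id`/`group`
#'   TSV.
#' @export
write_expression_matrix <- function(m, path, groups_path = NULL) {
  df <- data.frame(gene_id = rownames(m$values),
                   format(m$values, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    utils::write.table(
      data.frame(sample_id = names(m$groups), group = unname(m$groups)),
      groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a plain gene-list file
#'
#' One gene id per line; blank lines and duplicates are dropped.
#'
#' @param path file path.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_parse("gene list not found: %s", path)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines `category_id<TAB>name<TAB>gene1<TAB>gene2...`.
#' Empty lines are skipped with a warning.
#'
#' @param path file path.
#' @return A [FunctionalCategorySet].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_parse("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  empty <- !nzchar(trimws(lines))
  if (any(empty)) {
    warning(sprintf("skipping %d empty line(s) in %s", sum(empty), path))
    lines <- lines[!empty]
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short))
    stop_parse("GMT line %d has fewer than 3 fields in %s", short[1], path)
  FunctionalCategorySet(
    ids = vapply(parts, `[[`, "", 1L),
    names = vapply(parts, `[[`, "", 2L),
    genes = lapply(parts, function(p) unique(p[-(1:2)])))
}

#' Write gene sets in GMT format
#'
#' @param cats a [FunctionalCategorySet].
#' @param path output path.
#' @export
write_gmt <- function(cats, path) {
  lines <- vapply(cats, function(cc)
    paste(c(cc$category_id, cc$name, cc$genes), collapse = "\t"), "")
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write a result table as deterministic TSV
#'
#' Writes any of the package's tabular results with a stable column order
#' and rows sorted by primary key, so identical inputs give byte-identical
#' files. Numeric columns keep full double precision.
#'
#' @param x a `data.frame` (e.g. a regulatory-potential, differential
#'   expression, impact or enrichment table) or a [PeakSet].
#' @param path output path.
#' @param sort_by columns to sort rows by; defaults to the first column
#'   (`chrom`, `start` for a [PeakSet]).
#' @export
write_table <- function(x, path, sort_by = NULL) {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(sort_by))
    sort_by <- if (inherits(x, "PeakSet")) c("chrom", "start") else names(df)[1]
  ord <- do.call(order, c(unname(df[sort_by]), list(method = "radix")))
  df <- df[ord, , drop = FALSE]
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
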
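#' Gene annotation table
#'
#' Container for one transcription start site (TSS) per gene. All
#' peak-to-gene distances in the package are measured from these anchors,
#' so the annotation must already be collapsed to a single representative
#' TSS per gene (picking a transcript is data preparation, not method).
#'
#' Coordinates are 0-based half-open (BED convention) throughout the
#' package; `tss` is a 0-based position.
#'
#' @param gene_id character, unique gene identifiers (matched
#'   case-sensitively everywhere; no alias resolution is attempted).
#' @param chrom character, chromosome names.
#' @param strand character, `"+"` or `"-"`.
#' @param tss integer, 0-based TSS coordinates, non-negative.
#' @param chrom_sizes optional named integer vector of chromosome lengths;
#'   when present every TSS must fall inside its chromosome.
#' @return A `GenomeAnnotation`: a `data.frame` with columns `gene_id`,
#'   `chrom`, `strand`, `tss` and attribute `chrom_sizes`.
#' @export
GenomeAnnotation <- function(gene_id, chrom, strand, tss, chrom_sizes = NULL) {
  gene_id <- as.character(gene_id)
  chrom <- as.character(chrom)
  strand <- as.character(strand)
  tss <- as.numeric(tss)
  if (anyDuplicated(gene_id))
    stop_validation("duplicate gene_id in annotation: %s",
                    paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (!all(strand %in% c("+", "-")))
    stop_validation("strand must be '+' or '-'")
  if (any(is.na(tss)) || any(tss < 0))
    stop_validation("tss must be a non-negative coordinate")
  if (!is.null(chrom_sizes)) {
    sz <- chrom_sizes[chrom]
    if (any(is.na(sz)))
      stop_validation("chrom_sizes missing for chromosome(s): %s",
                      paste(unique(chrom[is.na(sz)]), collapse = ", "))
    if (any(tss >= sz))
      stop_validation("tss beyond chromosome end for gene(s): %s",
                      paste(gene_id[tss >= sz], collapse = ", "))
  }
  ann <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                    tss = as.integer(tss), stringsAsFactors = FALSE)
  attr(ann, "chrom_sizes") <- chrom_sizes
  class(ann) <- c("GenomeAnnotation", "data.frame")
  ann
}

#' Peak set for one factor and replicate
#'
#' Genomic binding-site intervals from a peak caller, 0-based half-open.
#' `q_value` stores the raw FDR-adjusted significance of each peak (not its
#' -log10); `summit` is the point-source estimate when the caller reports
#' one, `NA` otherwise.
#'
#' @param chrom,start,end interval coordinates, `start < end`.
#' @param summit optional integer summit positions in `[start, end)`; `NA`
#'   when the caller reported none.
#' @param score numeric peak scores.
#' @param q_value raw q-values in (0, 1].
#' @param tf_name,replicate labels carried through the pipeline.
#' @return A `PeakSet`: a `data.frame` with the above columns and
#'   attributes `tf_name` and `replicate`.
#' @export
PeakSet <- function(chrom, start, end, summit = NA_integer_, score = 0,
                    q_value = 1, tf_name = "", replicate = "") {
  n <- length(start)
  ps <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.integer(start),
                   end = as.integer(end),
                   summit = as.integer(rep_len(summit, n)),
                   score = as.numeric(rep_len(score, n)),
                   q_value = as.numeric(rep_len(q_value, n)),
                   stringsAsFactors = FALSE)
  bad <- which(ps$start >= ps$end)
  if (length(bad))
    stop_validation("peak start >= end at row(s) %s",
                    paste(utils::head(bad, 5), collapse = ", "))
  with_summit <- !is.na(ps$summit)
  bad <- which(with_summit & (ps$summit < ps$start | ps$summit >= ps$end))
  if (length(bad))
    stop_validation("summit outside [start, end) at row(s) %s",
                    paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!(ps$q_value > 0 & ps$q_value <= 1))
  if (length(bad))
    stop_validation("q_value outside (0, 1] at row(s) %s",
                    paste(utils::head(bad, 5), collapse = ", "))
  attr(ps, "tf_name") <- tf_name
  attr(ps, "replicate") <- replicate
  class(ps) <- c("PeakSet", "data.frame")
  ps
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet: %s / %s, %d peaks\n",
              attr(x, "tf_name"), attr(x, "replicate"), nrow(x)))
  NextMethod()
}

#' Expression matrix with a two-group design
#'
#' @param values numeric gene x sample matrix of log-scale intensities with
#'   gene ids as rownames and sample ids as colnames.
#' @param groups named character vector mapping every sample id to
#'   `"control"` or `"treatment"`; both groups must be non-empty.
#' @return An `ExpressionMatrix`: a list with elements `values` and
#'   `groups`.
#' @export
ExpressionMatrix <- function(values, groups) {
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("values must be a matrix with gene rownames and sample colnames")
  groups <- groups[colnames(values)]
  if (any(is.na(groups)) || is.null(names(groups)))
    stop_validation("every sample needs a group label; missing: %s",
                    paste(colnames(values)[is.na(groups)], collapse = ", "))
  if (!all(groups %in% c("control", "treatment")))
    stop_validation("group labels must be 'control' or 'treatment'")
  if (!all(c("control", "treatment") %in% groups))
    stop_validation("both groups must be non-empty")
  structure(list(values = values, groups = groups), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d control, %d treatment)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "control"), sum(x$groups == "treatment")))
  invisible(x)
}

#' Functional category collection
#'
#' @param ids,names character vectors of category ids and display names.
#' @param genes list of character vectors, the (non-empty) member genes.
#' @return A `FunctionalCategorySet`: a list of per-category lists with
#'   elements `category_id`, `name`, `genes`.
#' @export
FunctionalCategorySet <- function(ids, names, genes) {
  if (length(ids) != length(names) || length(ids) != length(genes))
    stop_validation("ids, names and genes must have equal length")
  if (any(vapply(genes, length, 1L) == 0L))
    stop_validation("functional categories must have at least one gene")
  out <- Map(function(i, n, g)
    list(category_id = i, name = n, genes = unique(as.character(g))),
    as.character(ids), as.character(names), genes)
  names(out) <- as.character(ids)
  class(out) <- "FunctionalCategorySet"
  out
}

#' @export
print.FunctionalCategorySet <- function(x, ...) {
  cat(sprintf("FunctionalCategorySet: %d categories\n", length(x)))
  invisible(x)
}
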
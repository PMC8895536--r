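#' Read gene sets from a GMT file
#'
#' Standard GMT layout: one set per line, tab-separated as
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}. The description column
#' is discarded and duplicate genes within a line are deduplicated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(setNames(list(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line(s) with fewer than 3 tab-separated fields: line ",
         paste(short, collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene set names in GMT file")
  sets
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based running-sum statistic over one expression profile. Genes are
#' ordered by decreasing value (ties broken by original feature order); the
#' walk accumulates the weighted in-set cumulative fraction (increments
#' proportional to \eqn{|x|^{weight}}, normalized to sum to one) minus the
#' uniform out-set cumulative fraction. \code{stat = "integral"} returns the
#' sum of the running differences over all positions; \code{stat = "sup"}
#' returns the running difference of largest magnitude (classic enrichment
#' score).
#'
#' @param values Named numeric vector (one profile over measured genes).
#' @param genes Character vector of gene symbols in the set.
#' @param weight Exponent on the absolute expression values (default 0.25).
#' @param stat \code{"integral"} or \code{"sup"}.
#' @return A single numeric score.
#' @export
ssgsea_score <- function(values, genes, weight = 0.25,
                         stat = c("integral", "sup")) {
  stat <- match.arg(stat)
  if (is.null(names(values))) stop("values must be named by gene")
  in_set <- names(values) %in% genes
  m <- sum(in_set)
  if (m == 0L) stop("gene set does not intersect the measured genes")
  if (m == length(values))
    stop("gene set covers all measured genes: out-set walk is undefined")
  ord <- order(values, decreasing = TRUE)   # stable for ties
  in_ord <- in_set[ord]
  w <- abs(values[ord])^weight
  w[!in_ord] <- 0
  denom <- sum(w)
  p_in <- if (denom > 0) cumsum(w) / denom else cumsum(in_ord) / m
  p_out <- cumsum(!in_ord) / (length(values) - m)
  d <- unname(p_in - p_out)
  if (stat == "integral") sum(d) else d[which.max(abs(d))]
}

#' Pathway score matrix from gene-level expression
#'
#' Computes one [ssgsea_score()] row per gene set (restricted to sets with
#' at least one measured member) for every profile column.
#'
#' @param x An [expr_mat()] of gene-level values.
#' @param gene_sets Named list of gene symbol vectors (see [read_gmt()]).
#' @param weight,stat Passed to [ssgsea_score()].
#' @return An [expr_mat()] with \code{feature_class = "pathway"}. Scores are
#'   returned raw; standardize them exactly like gene features (see
#'   [select_feature_space()]).
#' @export
pathway_matrix <- function(x, gene_sets, weight = 0.25, stat = "integral") {
  stopifnot(inherits(x, "expr_mat"))
  genes <- rownames(x$values)
  keep <- vapply(gene_sets, function(g) any(genes %in% g), TRUE)
  if (!any(keep))
    stop("no gene set intersects the measured genes")
  gene_sets <- gene_sets[keep]
  scores <- matrix(0, length(gene_sets), ncol(x$values),
                   dimnames = list(names(gene_sets), colnames(x$values)))
  for (j in seq_len(ncol(x$values))) {
    v <- x$values[, j]
    names(v) <- genes
    scores[, j] <- vapply(gene_sets, function(g)
      ssgsea_score(v, g, weight = weight, stat = stat), 0)
  }
  expr_mat(scores, rep("pathway", nrow(scores)))
}
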
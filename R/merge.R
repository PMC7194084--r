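# Cross-caller merging: same-type predictions from several callers are
# combined, linked whenever their reciprocal overlap strictly exceeds the
# threshold, clustered, and clusters supported by >= min_methods distinct
# callers are collapsed into unified SVs with mean breakpoints.

#' Pairwise 0/1 distance matrix for same-type SV records
#'
#' Distance 0 when two records share a chromosome and have reciprocal
#' overlap strictly greater than `overlap_frac`, else 1; the diagonal is
#' 0.  This is the matrix the hierarchical-clustering route consumes.
#'
#' @param records Data frame with columns `chromosome`, `pos1`, `pos2`.
#' @param overlap_frac Reciprocal overlap threshold (default 0.8).
#' @return An n x n symmetric 0/1 matrix.
#' @export
build_distance_matrix <- function(records, overlap_frac = 0.8) {
  n <- nrow(records)
  ro <- outer(seq_len(n), seq_len(n), function(i, j)
    reciprocal_overlap(records$pos1[i], records$pos2[i],
                       records$pos1[j], records$pos2[j]))
  same <- outer(records$chromosome, records$chromosome, "==")
  d <- ifelse(same & ro > overlap_frac, 0, 1)
  diag(d) <- 0
  d
}

# walk a union-find parent vector to the root (no mutation; the edge sets
# here are small enough that path compression is not worth the copies)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cluster same-type SV records by reciprocal overlap
#'
#' Single-linkage hierarchical clustering on the 0/1 distance matrix, cut
#' strictly below height 1.  With 0/1 distances this is exactly the set of
#' connected components of the graph whose edges join record pairs with
#' reciprocal overlap > `overlap_frac` on the same chromosome; the default
#' `linkage = "components"` route computes the components via union-find
#' over the candidate pairs found by [GenomicRanges::findOverlaps()],
#' which scales past the dense-matrix regime.  The `"hclust"` route keeps
#' the dense [stats::hclust()] formulation for cross-checking.
#'
#' @param records Data frame with columns `chromosome`, `pos1`, `pos2`.
#' @param overlap_frac Reciprocal overlap threshold.
#' @param linkage `"components"` (default) or `"hclust"`.
#' @return Integer vector of cluster ids aligned with the rows of
#'   `records`, numbered by first appearance.
#' @export
cluster_svs <- function(records, overlap_frac = 0.8,
                        linkage = c("components", "hclust")) {
  linkage <- match.arg(linkage)
  n <- nrow(records)
  if (n == 0L) return(integer())
  if (n == 1L) return(1L)
  if (linkage == "hclust") {
    d <- build_distance_matrix(records, overlap_frac)
    cl <- stats::cutree(stats::hclust(stats::as.dist(d),
                                      method = "single"), h = 0.5)
  } else {
    gr <- GenomicRanges::GRanges(records$chromosome,
                                 IRanges::IRanges(records$pos1,
                                                  records$pos2))
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        drop.redundant = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ro <- reciprocal_overlap(records$pos1[qi], records$pos2[qi],
                             records$pos1[si], records$pos2[si])
    keep <- ro > overlap_frac
    parent <- seq_len(n)
    for (k in which(keep)) {
      ra <- uf_find(parent, qi[k]); rb <- uf_find(parent, si[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    cl <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  }
  as.integer(factor(cl, levels = unique(cl)))
}

#' Merge one cluster of same-type SV records
#'
#' A cluster supported by at least `min_methods` distinct callers becomes
#' one unified SV: `pos1`/`pos2` are the means of all member breakpoints
#' (every member's coordinates count as evidence, rounded half-up to an
#' integer base); the `methods` string joins the distinct caller names
#' with `":"` in first-appearance order of the caller inputs; `info` joins
#' — in the same order — the info string of each caller's best-supported
#' member (a caller contributing several members is listed once).
#' Clusters below `min_methods` are discarded.
#'
#' @param members Data frame with columns `chromosome`, `pos1`, `pos2`,
#'   `info`, `method` (display name), `caller` (caller key) and
#'   `source_order` (position of the caller in the input order).
#' @param min_methods Minimum distinct supporting callers.
#' @return One-row data frame (`chromosome`, `pos1`, `pos2`, `methods`,
#'   `info`) or `NULL` when the cluster is discarded.
#' @export
merge_cluster <- function(members, min_methods = 2L) {
  if (length(unique(members$method)) < min_methods) return(NULL)
  sup <- support_score(members$info, "unknown")
  for (cl in unique(members$caller)) {
    ix <- members$caller == cl
    sup[ix] <- support_score(members$info[ix], cl)
  }
  ord <- order(members$source_order, -sup, members$pos1, members$pos2)
  first <- members[ord, ][!duplicated(members$method[ord]), ]
  data.frame(chromosome = members$chromosome[1L],
             pos1 = round_half_up(mean(members$pos1)),
             pos2 = round_half_up(mean(members$pos2)),
             methods = paste(first$method, collapse = ":"),
             info = paste(first$info, collapse = ":"),
             stringsAsFactors = FALSE)
}

#' Merge the predictions of multiple SV callers
#'
#' For each SV type independently: combine the records of every CallSet,
#' cluster them by reciprocal overlap ([cluster_svs()]), merge clusters
#' supported by at least `params$min_methods` distinct callers
#' ([merge_cluster()]) and discard the rest.  A deletion never clusters
#' with a duplication.
#'
#' @param ... Two or more `CallSet` objects (or a single list of them).
#' @param params A [merge_params()] object.
#' @param linkage Clustering route, see [cluster_svs()].
#' @return Object of class `MergedSVList`: a list with one data frame per
#'   SV type (`del`, `dup`, `inv`), columns `chromosome`, `pos1`, `pos2`,
#'   `methods`, `info`, sorted by (`chromosome`, `pos1`).
#' @examples
#' a <- callset("breakdancer", list(del = data.frame(
#'   chromosome = "chr1", pos1 = 100L, pos2 = 199L, size = 100,
#'   info = "score=99;PE=5")))
#' b <- callset("lumpy", list(del = data.frame(
#'   chromosome = "chr1", pos1 = 102L, pos2 = 201L, size = NA_real_,
#'   info = "SU=7")))
#' methods_merge(a, b)$del
#' @export
methods_merge <- function(..., params = merge_params(),
                          linkage = c("components", "hclust")) {
  linkage <- match.arg(linkage)
  callsets <- list(...)
  if (length(callsets) == 1L && !inherits(callsets[[1L]], "CallSet"))
    callsets <- callsets[[1L]]
  if (!all(vapply(callsets, inherits, TRUE, "CallSet")))
    stop_config("methods_merge expects CallSet inputs")
  if (length(callsets) < 2L)
    stop_config("methods_merge needs at least two CallSets")
  out <- lapply(SV_TYPES, function(tp) {
    combined <- do.call(rbind, lapply(seq_along(callsets), function(i) {
      cs <- callsets[[i]]
      df <- cs[[tp]]
      if (is.null(df) || !nrow(df)) return(NULL)
      cbind(df[, c("chromosome", "pos1", "pos2", "info")],
            method = attr(cs, "method"), caller = attr(cs, "caller"),
            source_order = i, stringsAsFactors = FALSE)
    }))
    empty <- data.frame(chromosome = character(), pos1 = numeric(),
                        pos2 = numeric(), methods = character(),
                        info = character(), stringsAsFactors = FALSE)
    if (is.null(combined) || !nrow(combined)) return(empty)
    cl <- cluster_svs(combined, params$overlap_frac, linkage)
    merged <- lapply(split(seq_len(nrow(combined)), cl), function(ix)
      merge_cluster(combined[ix, , drop = FALSE], params$min_methods))
    merged <- do.call(rbind, merged)
    if (is.null(merged)) return(empty)
    merged <- merged[order(merged$chromosome, merged$pos1, merged$pos2), ,
                     drop = FALSE]
    rownames(merged) <- NULL
    merged
  })
  names(out) <- SV_TYPES
  structure(out, params = params, class = "MergedSVList")
}

#' @export
print.MergedSVList <- function(x, ...) {
  cat("MergedSVList\n")
  for (tp in names(x)) cat(sprintf("  %s: %d merged SVs\n", tp,
                                   nrow(x[[tp]])))
  invisible(x)
}

#' Write merged SVs to disk
#'
#' * `tsv` — columns `chromosome`, `pos1`, `pos2`, `methods`, `info`,
#'   `sv_type`; round-trips through [read_merged()].
#' * `vcf` — VCF 4.2 with symbolic ALT alleles and INFO keys `SVTYPE`,
#'   `END`, `METHODS`; `POS = pos1 - 1` and `END = pos2` (last affected
#'   base).
#' * `bed` — BED6 (0-based half-open, `start = pos1 - 1`), name
#'   `sv_type|methods`.
#'
#' @param merged A `MergedSVList`.
#' @param path Output file.
#' @param format One of `"tsv"`, `"vcf"`, `"bed"`.
#' @return The path, invisibly.
#' @export
write_merged <- function(merged, path, format = c("tsv", "vcf", "bed")) {
  if (!is.character(format) ||
      !format[1L] %in% c("tsv", "vcf", "bed"))
    stop_config("unknown output format: ", format[1L])
  format <- match.arg(format)
  rows <- do.call(rbind, lapply(names(merged), function(tp) {
    df <- merged[[tp]]
    if (!nrow(df)) return(NULL)
    cbind(df, sv_type = tp, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(chromosome = character(), pos1 = numeric(),
                       pos2 = numeric(), methods = character(),
                       info = character(), sv_type = character())
  rows <- rows[order(rows$chromosome, rows$pos1, rows$pos2, rows$sv_type), ,
               drop = FALSE]
  if (format == "tsv") {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "vcf") {
    hdr <- c("##fileformat=VCFv4.2",
             "##source=svintegrate",
             paste0("##INFO=<ID=SVTYPE,Number=1,Type=String,",
                    "Description=\"Type of structural variant\">"),
             paste0("##INFO=<ID=END,Number=1,Type=Integer,",
                    "Description=\"End position of the variant\">"),
             paste0("##INFO=<ID=METHODS,Number=1,Type=String,",
                    "Description=\"Colon-joined supporting callers\">"),
             "##ALT=<ID=DEL,Description=\"Deletion\">",
             "##ALT=<ID=DUP,Description=\"Duplication\">",
             "##ALT=<ID=INV,Description=\"Inversion\">",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"))
    alt <- c(del = "<DEL>", dup = "<DUP>", inv = "<INV>")[rows$sv_type]
    body <- sprintf("%s\t%d\t%s\tN\t%s\t.\t.\tSVTYPE=%s;END=%d;METHODS=%s",
                    rows$chromosome, as.integer(rows$pos1) - 1L,
                    sprintf("sv%04d", seq_len(nrow(rows))), alt,
                    toupper(rows$sv_type), as.integer(rows$pos2),
                    rows$methods)
    writeLines(c(hdr, body), path)
  } else {
    bed <- data.frame(chrom = rows$chromosome,
                      start = as.integer(rows$pos1) - 1L,
                      end = as.integer(rows$pos2),
                      name = paste(rows$sv_type, rows$methods, sep = "|"),
                      score = 0L, strand = ".")
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read back a merged-SV TSV written by [write_merged()]
#'
#' @param path TSV file.
#' @return A `MergedSVList`.
#' @export
read_merged <- function(path) {
  if (!file.exists(path)) stop_data("cannot read merged TSV: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "character",
                                         "character"),
                          quote = "")
  out <- lapply(SV_TYPES, function(tp) {
    sub <- df[df$sv_type == tp,
              c("chromosome", "pos1", "pos2", "methods", "info"),
              drop = FALSE]
    sub <- sub[order(sub$chromosome, sub$pos1, sub$pos2), , drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
  names(out) <- SV_TYPES
  structure(out, class = "MergedSVList")
}
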
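# Annotation of merged SVs against gene models: every (SV, gene element)
# interval intersection is reported, one row per overlap.  A single shared
# base suffices; there is no minimum-fraction rule for annotation.

ELEMENT_TAGS <- c("gene", "exon", "intron", "five_prime_UTR",
                  "three_prime_UTR", "CDS", "upstream", "downstream")

#' Read gene models from GFF3 and flatten them to gene elements
#'
#' Extracts genes, exons, CDS and UTRs from a canonical GFF3
#' (gene/mRNA/exon hierarchy, 1-based inclusive), derives introns as the
#' gaps between consecutive exons of each transcript (deduplicated per
#' gene by coordinates), and optionally adds strand-aware
#' upstream/downstream flanks of each gene.
#'
#' @param path GFF3 file.
#' @param flank Width in bp of the upstream/downstream elements emitted
#'   beyond each gene's ends (0 disables them).  Default 2000, a standard
#'   promoter-proximal window.
#' @param chrom_sizes Optional named vector of chromosome lengths used to
#'   clip flanks at chromosome bounds (they are always clipped at 1).
#' @return Data frame of gene elements with columns `tag`, `chromosome`,
#'   `start`, `end`, `strand`, `ID`, `parent_gene`, sorted by
#'   (`chromosome`, `start`).  Sub-gene features lacking a resolvable
#'   Parent link are skipped with a warning.
#' @export
read_gene_models <- function(path, flank = 2000, chrom_sizes = NULL) {
  if (!file.exists(path)) stop_data("cannot read GFF3: ", path)
  gff <- tryCatch(rtracklayer::import(path, format = "gff3"),
                  error = function(e)
                    stop_data(path, ": GFF3 parse failure: ",
                              conditionMessage(e)))
  typ <- as.character(gff$type)
  ids <- if (is.null(gff$ID)) rep(NA_character_, length(gff))
         else as.character(gff$ID)
  par <- if (is.null(gff$Parent)) rep(NA_character_, length(gff))
         else vapply(as.list(gff$Parent), function(p)
           if (length(p)) as.character(p[[1L]]) else NA_character_, "")
  chrom <- as.character(GenomeInfoDb::seqnames(gff))
  strand <- as.character(BiocGenerics::strand(gff))
  starts <- BiocGenerics::start(gff); ends <- BiocGenerics::end(gff)

  gene_ix <- which(typ == "gene")
  tx_ix <- which(typ %in% c("mRNA", "transcript"))
  tx2gene <- stats::setNames(par[tx_ix], ids[tx_ix])
  n_skipped <- sum(is.na(tx2gene))
  tx2gene <- tx2gene[!is.na(tx2gene)]

  elem <- function(tag, ix, id, parent)
    if (length(ix)) data.frame(tag = unname(tag), chromosome = chrom[ix],
                               start = starts[ix], end = ends[ix],
                               strand = strand[ix], ID = unname(id),
                               parent_gene = unname(parent),
                               stringsAsFactors = FALSE) else NULL

  out <- list(elem("gene", gene_ix, ids[gene_ix], ids[gene_ix]))

  sub_types <- c(exon = "exon", CDS = "CDS",
                 five_prime_UTR = "five_prime_UTR",
                 three_prime_UTR = "three_prime_UTR")
  for (tt in names(sub_types)) {
    ix <- which(typ == tt)
    if (!length(ix)) next
    parent_tx <- par[ix]
    gene <- tx2gene[parent_tx]
    keep <- !is.na(parent_tx) & !is.na(gene)
    n_skipped <- n_skipped + sum(!keep)
    ix <- ix[keep]; parent_tx <- parent_tx[keep]; gene <- gene[keep]
    id <- ids[ix]
    auto <- is.na(id)
    if (any(auto))
      id[auto] <- paste0(parent_tx[auto], ".", sub_types[tt], ".",
                         stats::ave(seq_along(ix), parent_tx,
                                    FUN = seq_along)[auto])
    out[[length(out) + 1L]] <- elem(sub_types[tt], ix, id, unname(gene))
  }

  # introns: per-transcript gaps between consecutive exons, deduplicated
  # per gene by coordinates; strand passes through from the exons
  exon_ix <- which(typ == "exon")
  exon_tx <- par[exon_ix]
  keep <- !is.na(exon_tx) & exon_tx %in% names(tx2gene)
  exon_ix <- exon_ix[keep]; exon_tx <- exon_tx[keep]
  introns <- NULL
  if (length(exon_ix)) {
    introns <- do.call(rbind, lapply(split(exon_ix, exon_tx), function(ix) {
      if (length(ix) < 2L) return(NULL)
      o <- ix[order(starts[ix])]
      gs <- ends[o][-length(o)] + 1L
      ge <- starts[o][-1L] - 1L
      ok <- gs <= ge
      if (!any(ok)) return(NULL)
      tx <- par[o[1L]]
      data.frame(tag = "intron", chromosome = chrom[o[1L]],
                 start = gs[ok], end = ge[ok], strand = strand[o[1L]],
                 ID = paste0(tx, ".intron.", seq_len(sum(ok))),
                 parent_gene = unname(tx2gene[tx]),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(introns)) {
      dup <- duplicated(introns[, c("parent_gene", "chromosome",
                                    "start", "end")])
      introns <- introns[!dup, , drop = FALSE]
    }
  }
  out[[length(out) + 1L]] <- introns

  if (flank > 0 && length(gene_ix)) {
    g <- out[[1L]]
    minus <- g$strand == "-"
    up_start <- ifelse(minus, g$end + 1, g$start - flank)
    up_end <- ifelse(minus, g$end + flank, g$start - 1)
    dn_start <- ifelse(minus, g$start - flank, g$end + 1)
    dn_end <- ifelse(minus, g$start - 1, g$end + flank)
    clip <- function(s, e, chromv) {
      s <- pmax(s, 1)
      if (!is.null(chrom_sizes)) {
        lim <- chrom_sizes[chromv]
        e <- ifelse(is.na(lim), e, pmin(e, lim))
      }
      list(s = unname(s), e = unname(e), ok = unname(s <= e))
    }
    u <- clip(up_start, up_end, g$chromosome)
    d <- clip(dn_start, dn_end, g$chromosome)
    out[[length(out) + 1L]] <- data.frame(
      tag = "upstream", chromosome = g$chromosome[u$ok],
      start = u$s[u$ok], end = u$e[u$ok], strand = g$strand[u$ok],
      ID = paste0(g$ID[u$ok], ".upstream"),
      parent_gene = g$parent_gene[u$ok], stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      tag = "downstream", chromosome = g$chromosome[d$ok],
      start = d$s[d$ok], end = d$e[d$ok], strand = g$strand[d$ok],
      ID = paste0(g$ID[d$ok], ".downstream"),
      parent_gene = g$parent_gene[d$ok], stringsAsFactors = FALSE)
  }

  if (n_skipped > 0)
    warning(n_skipped, " feature(s) without resolvable Parent links were skipped")
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(tag = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      strand = character(), ID = character(),
                      parent_gene = character(), stringsAsFactors = FALSE)
  res <- res[order(res$chromosome, res$start, res$end, res$tag), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

annotate_one_type <- function(sv, elements) {
  empty <- data.frame(chromosome = character(), pos1 = numeric(),
                      pos2 = numeric(), info = character(),
                      tag = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      ID = character(), parent_gene = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(sv)) return(empty)
  if (nrow(elements)) {
    svr <- GenomicRanges::GRanges(sv$chromosome,
                                  IRanges::IRanges(sv$pos1, sv$pos2))
    elr <- GenomicRanges::GRanges(elements$chromosome,
                                  IRanges::IRanges(elements$start,
                                                   elements$end))
    hits <- GenomicRanges::findOverlaps(svr, elr)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  } else {
    qi <- integer(); si <- integer()
  }
  rows <- data.frame(sv_row = qi,
                     tag = elements$tag[si], start = elements$start[si],
                     end = elements$end[si], strand = elements$strand[si],
                     ID = elements$ID[si],
                     parent_gene = elements$parent_gene[si],
                     stringsAsFactors = FALSE)
  none <- setdiff(seq_len(nrow(sv)), qi)
  if (length(none))
    rows <- rbind(rows, data.frame(sv_row = none, tag = "",
                                   start = NA_real_, end = NA_real_,
                                   strand = "", ID = "", parent_gene = "",
                                   stringsAsFactors = FALSE))
  rows <- rows[order(rows$sv_row, rows$start, rows$end, rows$tag,
                     rows$ID), , drop = FALSE]
  res <- cbind(sv[rows$sv_row, c("chromosome", "pos1", "pos2", "info"),
                  drop = FALSE],
               rows[, c("tag", "start", "end", "strand", "ID",
                        "parent_gene"), drop = FALSE])
  rownames(res) <- NULL
  res
}

#' Annotate merged SVs with overlapping gene elements
#'
#' Emits one row per (SV, element) pair whose intervals share at least one
#' base on the same chromosome; SVs overlapping nothing are emitted once
#' with empty element fields.  Rows are ordered by SV, then element start.
#'
#' @param merged A `MergedSVList` (or a single per-type data frame with
#'   columns `chromosome`, `pos1`, `pos2`, `info`).
#' @param elements Gene-element data frame from [read_gene_models()].
#' @return Data frame with columns `sv_type` (when `merged` is a list),
#'   `chromosome`, `pos1`, `pos2`, `info`, `tag`, `start`, `end`,
#'   `strand`, `ID`, `parent_gene`.
#' @export
annotate_svs <- function(merged, elements) {
  if (is.data.frame(merged)) return(annotate_one_type(merged, elements))
  out <- do.call(rbind, lapply(names(merged), function(tp) {
    res <- annotate_one_type(merged[[tp]], elements)
    if (!nrow(res)) return(NULL)
    cbind(sv_type = tp, res, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- cbind(sv_type = character(),
                 annotate_one_type(empty_records()[0, ],
                                   data.frame(tag = character(),
                                              chromosome = character(),
                                              start = numeric(),
                                              end = numeric(),
                                              strand = character(),
                                              ID = character(),
                                              parent_gene = character())))
  rownames(out) <- NULL
  out
}

#' Count genes affected by SVs, per SV type
#'
#' A gene counts as affected by a type when at least one SV of that type
#' overlaps any of its elements; genes are counted once per type however
#' many SVs or elements are involved.
#'
#' @param annotated Output of [annotate_svs()] (list form, with
#'   `sv_type`).
#' @return Named integer vector (`del`, `dup`, `inv`) of distinct
#'   affected-gene counts.
#' @export
count_affected_genes <- function(annotated) {
  vapply(SV_TYPES, function(tp) {
    g <- annotated$parent_gene[annotated$sv_type == tp]
    length(unique(g[!is.na(g) & nzchar(g)]))
  }, integer(1))
}

#' Write an annotation table in the nine-column supplementary schema
#'
#' Columns: `Chromosome`, `Pos1`, `Pos2`, `info`, `tag`, `start`, `end`,
#' `strand`, `ID`.
#'
#' @param annotated Output of [annotate_svs()].
#' @param path Output TSV.
#' @return The path, invisibly.
#' @export
write_annotated <- function(annotated, path) {
  out <- data.frame(Chromosome = annotated$chromosome,
                    Pos1 = annotated$pos1, Pos2 = annotated$pos2,
                    info = annotated$info, tag = annotated$tag,
                    start = annotated$start, end = annotated$end,
                    strand = annotated$strand, ID = annotated$ID,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
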